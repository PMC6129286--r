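#' Derive mapping parameters from the alignment requirements
#'
#' Auto-tunes the internal thresholds from the user-facing requirements: the
#' minimum local alignment length `l0` and the maximum per-base error rate
#' `eps_max` (equivalently, minimum identity `100 * (1 - eps_max)` percent).
#'
#' The fragment length is `l0 %/% 2`.  The winnowing window `w` is chosen so
#' that the expected minimizer count of one fragment, about `2 * flen /
#' (w + 1)`, is at least the sketch size `s`.  The Jaccard acceptance cutoff
#' `tau` is relaxed below the nominal `J(eps_max)` so that a true borderline
#' alignment at `eps_max` is still accepted with probability at least
#' `confidence`: with `X ~ Binomial(s, J(eps_max))` counting shared sketch
#' hashes, `m` is the `1 - confidence` lower quantile of `X` (one-sided
#' convention; the two-sided convention uses the `(1 - confidence)/2`
#' quantile) and `tau = m / s`.
#'
#' @param l0 minimum alignment length in bp; must be at least `2 * k`.
#' @param eps_max maximum per-base error rate, in `[0, 1)`.
#' @param k k-mer length (default 16).
#' @param s sketch size (default 200).
#' @param confidence confidence level for the threshold relaxation.
#' @param w winnowing window; computed from `l0` and `s` when `NULL`.
#' @param relaxation quantile convention for the relaxed cutoff.
#' @return An object of class `map_params`: a list with elements `k`, `w`,
#'   `s`, `l0`, `eps_max`, `confidence`, `relaxation`, `flen` (fragment
#'   length), `tau` (Jaccard cutoff) and `m` (minimum shared-hash count).
#' @examples
#' p <- auto_tune(10000, 0.10)
#' p$flen  # 5000
#' p$w     # 49
#' @export
auto_tune <- function(l0, eps_max, k = 16L, s = 200L, confidence = 0.90,
                      w = NULL, relaxation = c("one-sided", "two-sided")) {
  relaxation <- match.arg(relaxation)
  stopifnot(l0 >= 2 * k, eps_max >= 0, eps_max < 1, s >= 1L,
            confidence > 0, confidence < 1)
  l0 <- as.integer(l0)
  flen <- l0 %/% 2L
  if (is.null(w)) {
    w <- (2L * flen) %/% as.integer(s) - 1L
    if (w < 1L) {
      warning("derived winnowing window < 1; clamped to 1")
      w <- 1L
    }
  }
  stopifnot(w >= 1L)
  j_max <- jaccard_from_error(eps_max, k)
  alpha <- switch(relaxation,
                  "one-sided" = 1 - confidence,
                  "two-sided" = (1 - confidence) / 2)
  q <- qbinom(alpha, as.integer(s), j_max)
  if (q < 1) {
    warning("relaxed shared-hash threshold < 1; clamped to 1")
    q <- 1
  }
  m <- as.integer(q)
  structure(list(k = as.integer(k), w = as.integer(w), s = as.integer(s),
                 l0 = l0, eps_max = eps_max, confidence = confidence,
                 relaxation = relaxation, flen = flen,
                 tau = m / as.integer(s), m = m),
            class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat("Mapping parameters\n")
  cat(sprintf("  l0 = %d bp (fragment length %d bp), min identity %.2f%%\n",
              x$l0, x$flen, 100 * (1 - x$eps_max)))
  cat(sprintf("  k = %d, w = %d, sketch size s = %d\n", x$k, x$w, x$s))
  cat(sprintf("  Jaccard cutoff tau = %.4f (m = %d shared hashes, %s %.0f%% confidence)\n",
              x$tau, x$m, x$relaxation, 100 * x$confidence))
  invisible(x)
}

#' Number of fragments fully spanned by an alignment
#'
#' An alignment of length `L` bp fully contains
#' `floor((L - l0/2 + 1) / (l0/2))` of the non-overlapping `l0/2`-bp query
#' fragments, regardless of its phase relative to the fragment grid; this is
#' at least 1 whenever `L >= l0`.
#'
#' @param L alignment length in bp (vectorised).
#' @param l0 minimum alignment length in bp.
#' @return Integer vector of fragment counts (0 when `L < l0/2`).
#' @export
fragment_count <- function(L, l0) {
  stopifnot(all(L >= 0), l0 >= 2)
  flen <- as.integer(l0) %/% 2L
  as.integer(pmax(0, floor((L - flen + 1) / flen)))
}

#' Probability that one fragment maps to its true locus
#'
#' Under the binomial sketch model, the number of sketch hashes a fragment
#' shares with its true reference window is `X ~ Binomial(s, J(eps, k))`,
#' and the fragment is mapped when `X >= m` (the relaxed cutoff from
#' [auto_tune()]).
#'
#' @param eps true per-base error rate(s), each at most `params$eps_max`.
#' @param params a `map_params` object.
#' @return Probability vector in `[0, 1]`, non-increasing in `eps`.
#' @export
per_fragment_prob <- function(eps, params) {
  stopifnot(inherits(params, "map_params"))
  if (any(eps > params$eps_max + 1e-12))
    stop(errorCondition(
      sprintf("true error rate above eps_max = %g: sensitivity undefined",
              params$eps_max),
      class = c("sweepmap_param_error", "error", "condition")))
  J <- jaccard_from_error(pmin(eps, params$eps_max), params$k)
  1 - pbinom(params$m - 1, params$s, J)
}

#' Probability of reporting at least one seed fragment mapping
#'
#' The headline sensitivity guarantee: an alignment of length `L >= l0` at
#' true error rate `eps <= eps_max` fully contains `n = fragment_count(L,
#' l0)` fragments, each mapping independently with probability `p`, so at
#' least one seed mapping is reported with probability `1 - (1 - p)^n`.
#'
#' @param L alignment length(s) in bp, each at least `l0`.
#' @param eps true per-base error rate(s).
#' @param params a `map_params` object.
#' @return Probability vector in `[0, 1]`.
#' @export
seed_sensitivity <- function(L, eps, params) {
  stopifnot(inherits(params, "map_params"))
  if (any(L < params$l0))
    stop(errorCondition("alignment length below minimum length l0",
                        class = c("sweepmap_below_min_length", "error",
                                  "condition")))
  n <- fragment_count(L, params$l0)
  p <- per_fragment_prob(eps, params)
  1 - (1 - p)^n
}

#' Tabulate seed sensitivity over error rates and alignment lengths
#'
#' @param params a `map_params` object.
#' @param eps_grid true error rates, each in `(0, eps_max]`.
#' @param lengths alignment lengths in bp, each at least `l0`.
#' @return A data.frame with columns `eps`, `length`, `n_fragments` and
#'   `prob`; `prob` is non-increasing in `eps` and non-decreasing in
#'   `length`.
#' @export
sensitivity_curve <- function(params, eps_grid, lengths) {
  stopifnot(inherits(params, "map_params"))
  g <- expand.grid(eps = eps_grid, length = lengths,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_fragments <- fragment_count(g$length, params$l0)
  g$prob <- seed_sensitivity(g$length, g$eps, params)
  g
}
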