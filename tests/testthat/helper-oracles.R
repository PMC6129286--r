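# Independent oracles and small generators used across the suite.

# Brute-force filtering oracle, straight from the redundancy definition:
# a segment (closed interval) is good iff it has a position where no
# strictly higher-scoring segment covers it.  Since coverage only changes
# at endpoints, checking all endpoints inside the segment suffices.
sweep_oracle <- function(begin, end, score) {
  n <- length(begin)
  pts <- sort(unique(c(begin, end)))
  cov <- outer(begin, pts, "<=") & outer(end, pts, ">=")
  ms <- vapply(seq_along(pts),
               function(j) max(score[cov[, j]]), numeric(1))
  # i covers pt j => ms[j] >= score[i]; good iff some covered j has no
  # strictly higher-scoring cover, i.e. ms[j] == score[i]
  vapply(seq_len(n),
         function(i) any(cov[i, ] & ms <= score[i]),
         logical(1))
}

# random weighted segments with deliberate score ties
random_segments <- function(n, max_coord = 1e4, n_scores = NULL) {
  b <- sample.int(max_coord, n, replace = TRUE)
  len <- sample.int(max_coord %/% 4L, n, replace = TRUE) - 1L
  if (is.null(n_scores)) n_scores <- max(1L, n %/% 3L)
  data.frame(begin = b, end = pmin(b + len, max_coord),
             score = sample.int(n_scores, n, replace = TRUE))
}

# logical good-vector wrapper around plane_sweep()
plane_sweep_good <- function(segs) {
  segs$..id <- seq_len(nrow(segs))
  seq_len(nrow(segs)) %in% plane_sweep(segs)$..id
}

# exact binomial upper tail by direct summation (oracle for pbinom-based p)
binom_tail <- function(m, s, prob) {
  if (m <= 0) return(1)
  i <- m:s
  sum(choose(s, i) * prob^i * (1 - prob)^(s - i))
}

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

# params object with explicitly pinned thresholds, for arithmetic tests
manual_params <- function(l0, eps_max, k = 16L, s = 200L, m,
                          w = 1L, confidence = 0.90) {
  structure(list(k = as.integer(k), w = as.integer(w), s = as.integer(s),
                 l0 = as.integer(l0), eps_max = eps_max,
                 confidence = confidence, relaxation = "one-sided",
                 flen = as.integer(l0) %/% 2L, tau = m / s,
                 m = as.integer(m)),
            class = "map_params")
}
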