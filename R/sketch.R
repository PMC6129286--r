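#' Canonical k-mer hash
#'
#' Hashes a k-mer and its reverse complement with a fixed-seed 64-bit mixing
#' function and returns the smaller of the two values, so a k-mer and its
#' reverse complement always hash identically.  Values are reported as the
#' top 53 bits of the 64-bit hash, which are exactly representable as R
#' doubles.
#'
#' @param kmer character vector of k-mers (all the same length, at most 32).
#' @return Numeric vector of hash values; `NA` where the k-mer contains a
#'   non-ACGT character (the caller is expected to skip those).
#' @examples
#' canonical_hash("ACGT") == canonical_hash("ACGT")
#' canonical_hash("AACCGGTT") == canonical_hash("AACCGGTT")
#' @export
canonical_hash <- function(kmer) {
  k <- unique(nchar(kmer))
  stopifnot(length(k) == 1L, k >= 1L, k <= 32L)
  vapply(kmer, function(x) canonical_hashes_cpp(x, k)[1L], numeric(1),
         USE.NAMES = FALSE)
}

#' Canonical hashes of all k-mers of a sequence
#'
#' @param seq a single DNA string.
#' @param k k-mer length (<= 32).
#' @return Numeric vector of length `nchar(seq) - k + 1` (empty if the
#'   sequence is shorter than `k`); `NA` at positions whose k-mer contains an
#'   ambiguous base.
#' @export
kmer_hashes <- function(seq, k = 16L) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L, k <= 32L)
  canonical_hashes_cpp(seq, as.integer(k))
}

#' Sample minimizers from a sequence
#'
#' Standard winnowing: in every window of `w` consecutive k-mers the k-mer
#' with the smallest canonical hash is selected (leftmost on ties);
#' duplicate selections are reported once.  K-mers containing non-ACGT
#' characters are never selected.  The expected density on random sequence
#' is about `2/(w+1)` minimizers per position.
#'
#' @param seq a single DNA string.
#' @param k k-mer length.
#' @param w window size, in k-mers; `w = 1` selects every k-mer.
#' @return A data.frame with columns `hash` (numeric), `pos` (0-based offset
#'   of the k-mer's first base) and `strand` (+1 if the forward k-mer
#'   attained the canonical hash, -1 otherwise), sorted by `pos`.  Empty if
#'   `nchar(seq) < k`.
#' @export
winnow_minimizers <- function(seq, k = 16L, w = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L, k <= 32L, w >= 1L)
  winnow_cpp(seq, as.integer(k), as.integer(w))
}

#' Build a MinHash sketch from minimizers
#'
#' The sketch is the set of the `s` numerically smallest *distinct*
#' minimizer hashes (all of them when fewer than `s` exist).  Each retained
#' hash keeps the strand of its first (leftmost) occurrence.
#'
#' @param minimizers data.frame as returned by [winnow_minimizers()].
#' @param s sketch size (number of hashes to keep).
#' @return A data.frame with columns `hash` and `strand`, ordered by
#'   increasing hash; zero rows for an empty minimizer list (a valid,
#'   unmappable sketch).
#' @export
build_sketch <- function(minimizers, s = 200L) {
  stopifnot(s >= 1L)
  if (NROW(minimizers) == 0L)
    return(data.frame(hash = numeric(0), strand = integer(0)))
  o <- order(minimizers$hash, minimizers$pos)
  h <- minimizers$hash[o]
  st <- minimizers$strand[o]
  keep <- !duplicated(h)
  h <- h[keep]
  st <- st[keep]
  n <- min(length(h), as.integer(s))
  data.frame(hash = h[seq_len(n)], strand = st[seq_len(n)])
}

#' Estimate Jaccard similarity from a sketch
#'
#' Winnowed-MinHash estimate: the fraction of sketch hashes present in the
#' candidate reference window's minimizer hash set.
#'
#' @param query_sketch sketch data.frame from [build_sketch()], or a numeric
#'   vector of sketch hashes.
#' @param ref_hashes numeric vector of minimizer hashes of the reference
#'   window (duplicates allowed; set semantics apply).
#' @return Estimated Jaccard similarity in `[0, 1]`.
#' @export
jaccard_estimate <- function(query_sketch, ref_hashes) {
  h <- if (is.data.frame(query_sketch)) query_sketch$hash else query_sketch
  if (length(h) == 0L)
    stop(errorCondition("empty query sketch: unmappable fragment",
                        class = c("sweepmap_empty_sketch", "error", "condition")))
  mean(h %in% ref_hashes)
}

#' Convert between Jaccard similarity and per-base error rate
#'
#' Under the Poisson error model with independent k-mers, an alignment with
#' per-base error rate `eps` has expected k-mer Jaccard similarity
#' `J = 1 / (2 exp(eps * k) - 1)`; the inverse is
#' `eps = -(1/k) log(2J / (1 + J))`.  The two closed forms are mutual
#' inverses on `(0, 1]`, and `J` is strictly decreasing in `eps`.
#'
#' @param eps per-base error rate in `[0, 1]`.
#' @param J Jaccard similarity in `[0, 1]`; `J = 0` maps to `eps = 1`
#'   (no detectable similarity).
#' @param k k-mer length.
#' @return `jaccard_from_error()`: Jaccard similarity; `error_from_jaccard()`:
#'   error rate, clamped to `[0, 1]`.
#' @examples
#' jaccard_from_error(0.10, 16)             # ~0.1123
#' error_from_jaccard(jaccard_from_error(0.10, 16), 16)  # 0.10
#' @export
jaccard_from_error <- function(eps, k = 16L) {
  stopifnot(all(eps >= 0 & eps <= 1), k >= 1L)
  1 / (2 * exp(eps * k) - 1)
}

#' @rdname jaccard_from_error
#' @export
error_from_jaccard <- function(J, k = 16L) {
  stopifnot(all(J >= 0 & J <= 1), k >= 1L)
  out <- ifelse(J == 0, 1, -(1 / k) * log(2 * J / (1 + J)))
  pmin(1, pmax(0, out))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
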