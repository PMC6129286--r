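#' Mark highest-scoring segments in a sweep status as good
#'
#' Operates on one snapshot of the sweep-line status: all segments tied at
#' the maximum score are marked good.  The traversal descends from the
#' maximum of the status order (score, then begin, then id) and stops at the
#' first segment already marked good — safe because whenever a segment was
#' marked in an earlier snapshot, every segment below it at the same score
#' must have been marked then too.
#'
#' @param status data.frame with columns `score`, `begin` and logical
#'   `good` (initialised to `FALSE` when absent); an `id` column is used as
#'   the final tiebreaker (row number when absent).
#' @return A list with elements `status` (the updated data.frame) and
#'   `n_marked` (count of newly marked segments).
#' @export
mark_good <- function(status) {
  if (NROW(status) == 0L) return(list(status = status, n_marked = 0L))
  if (is.null(status$good)) status$good <- FALSE
  id <- if (is.null(status$id)) seq_len(nrow(status)) else status$id
  o <- order(-status$score, -status$begin, -id)
  maxs <- status$score[o[1L]]
  n_marked <- 0L
  for (i in o) {
    if (status$score[i] < maxs || status$good[i]) break
    status$good[i] <- TRUE
    n_marked <- n_marked + 1L
  }
  list(status = status, n_marked = n_marked)
}

#' Plane-sweep filter over weighted intervals
#'
#' Returns exactly the segments that are not redundant, where a segment is
#' redundant if and only if it is covered at every one of its positions by a
#' strictly higher-scoring segment.  Endpoints are processed in ascending
#' order (2n halting points, insertions before removals at equal
#' coordinates); the sweep status is an ordered set under (score, begin, id)
#' and the highest-scoring resident segments are marked good at each halting
#' point, giving O(n log n) total work.  Intervals are treated as closed:
#' two segments sharing only a boundary coordinate overlap at that event.
#'
#' @param segments data.frame with columns `begin`, `end` (closed
#'   coordinates, `begin <= end`; zero-length segments allowed) and `score`
#'   (non-negative; ties allowed).
#' @return The subset of rows marked good, in the original order.
#' @export
plane_sweep <- function(segments) {
  if (NROW(segments) == 0L) return(segments)
  stopifnot(all(segments$begin <= segments$end), all(segments$score >= 0))
  good <- plane_sweep_cpp(as.numeric(segments$begin),
                          as.numeric(segments$end),
                          as.numeric(segments$score))
  segments[good, , drop = FALSE]
}

#' Filter mapping segments on the query axis (`map` mode)
#'
#' The plane-sweep filter is applied independently per query sequence to the
#' query-axis intervals `[q_begin, q_end)`; appropriate for read mapping,
#' where the best mappings of each query are wanted.
#'
#' @param segments a segment data.frame (see [merge_mappings()]).
#' @return The surviving subset, per-query.
#' @export
filter_map <- function(segments) {
  if (NROW(segments) == 0L) return(segments)
  keep <- unlist(lapply(split(seq_len(nrow(segments)), segments$query_id),
                        function(i) {
    g <- plane_sweep_cpp(as.numeric(segments$q_begin[i]),
                         as.numeric(segments$q_end[i] - 1L),
                         as.numeric(segments$score[i]))
    i[g]
  }), use.names = FALSE)
  segments[sort(keep), , drop = FALSE]
}

#' Filter mapping segments on both axes (`one-to-one` mode)
#'
#' Runs the query-axis filter first, then re-filters its survivors per
#' reference sequence on the reference-axis intervals `[r_begin, r_end)`.
#' Mappings passing both filters constitute the orthologous matches of a
#' one-to-one homology map.  The result is always a subset of
#' [filter_map()]'s output.
#'
#' @param segments a segment data.frame (see [merge_mappings()]).
#' @return The subset surviving both passes.
#' @export
filter_one_to_one <- function(segments) {
  qs <- filter_map(segments)
  if (NROW(qs) == 0L) return(qs)
  keep <- unlist(lapply(split(seq_len(nrow(qs)), qs$ref_id), function(i) {
    g <- plane_sweep_cpp(as.numeric(qs$r_begin[i]),
                         as.numeric(qs$r_end[i] - 1L),
                         as.numeric(qs$score[i]))
    i[g]
  }), use.names = FALSE)
  qs[sort(keep), , drop = FALSE]
}
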