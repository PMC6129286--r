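#' Build a minimizer index of the reference sequences
#'
#' Winnows every reference sequence under the tuned `(k, w)` and stores all
#' minimizer occurrences sorted by hash for exact lookup.
#'
#' @param ref named character vector of reference sequences (or anything
#'   coercible with `as.character()`, e.g. a `DNAStringSet`).
#' @param params a `map_params` object from [auto_tune()].
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(ref, params) {
  stopifnot(inherits(params, "map_params"))
  ref <- as_seqs(ref, "ref")
  mins <- lapply(seq_along(ref), function(i) {
    m <- winnow_minimizers(ref[[i]], params$k, params$w)
    if (nrow(m)) m$ref <- i
    m
  })
  mins <- mins[vapply(mins, nrow, integer(1)) > 0L]
  if (length(mins)) {
    all <- data.table::rbindlist(mins)
    o <- order(all$hash, all$ref, all$pos)
    hash <- all$hash[o]; pos <- all$pos[o]
    strand <- all$strand[o]; refid <- all$ref[o]
    starts <- which(!duplicated(hash))
    ends <- c(starts[-1L] - 1L, length(hash))
    uh <- hash[starts]
  } else {
    hash <- uh <- numeric(0)
    pos <- strand <- refid <- starts <- ends <- integer(0)
  }
  structure(list(pos = pos, strand = strand, ref = refid,
                 uh = uh, starts = starts, ends = ends,
                 ref_names = names(ref),
                 ref_lengths = setNames(nchar(ref), names(ref)),
                 k = params$k, w = params$w),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("Minimizer reference index: %d sequence(s), %.3g Mbp, %d minimizer occurrences (k = %d, w = %d)\n",
              length(x$ref_names), sum(x$ref_lengths) / 1e6,
              length(x$pos), x$k, x$w))
  invisible(x)
}

#' Split a query sequence into non-overlapping fragments
#'
#' Produces the maximal set of consecutive `l0/2`-bp windows starting at
#' offset 0; a trailing remainder shorter than `l0/2` is discarded.
#'
#' @param Q a single query sequence (string), or its length.
#' @param l0 minimum alignment length in bp.
#' @return A data.frame with columns `fragment_index` (0-based), `begin` and
#'   `end` (0-based, half-open); zero rows when the query is shorter than
#'   `l0/2` (such a query is unmappable).
#' @export
fragment_query <- function(Q, l0) {
  len <- if (is.character(Q)) nchar(Q) else as.integer(Q)
  flen <- as.integer(l0) %/% 2L
  nf <- len %/% flen
  if (nf == 0L)
    return(data.frame(fragment_index = integer(0), begin = integer(0),
                      end = integer(0)))
  i <- seq_len(nf) - 1L
  data.frame(fragment_index = i, begin = i * flen, end = (i + 1L) * flen)
}

#' Map one query fragment against the reference index
#'
#' Sketches the fragment (the `s` smallest distinct minimizer hashes) and
#' scans the matched reference minimizer positions with a sliding window of
#' the fragment length: windows sharing at least `m` distinct sketch hashes
#' are candidates, each run of overlapping candidates is reduced to the
#' position maximising the Jaccard estimate (leftmost on ties), and windows
#' with estimate at least `tau` are emitted.  Strand is the majority vote of
#' the products of the matched minimizers' query and reference strands.
#'
#' @param fragment_seq fragment sequence (string of length `l0/2`).
#' @param index a `reference_index`.
#' @param params a `map_params` object.
#' @param query_id,fragment_index identifiers copied into the output.
#' @return A data.frame with columns `query_id`, `fragment_index`, `ref_id`,
#'   `ref_begin`, `strand` ("+"/"-"), `jaccard` and `identity` (percent);
#'   zero rows when nothing passes the cutoff or the fragment sketch is
#'   empty (e.g. an all-N fragment).
#' @export
map_fragment <- function(fragment_seq, index, params,
                         query_id = "query", fragment_index = 0L) {
  stopifnot(inherits(index, "reference_index"), inherits(params, "map_params"))
  empty <- data.frame(query_id = character(0), fragment_index = integer(0),
                      ref_id = character(0), ref_begin = integer(0),
                      strand = character(0), jaccard = numeric(0),
                      identity = numeric(0))
  mins <- winnow_minimizers(fragment_seq, params$k, params$w)
  sk <- build_sketch(mins, params$s)
  s_used <- nrow(sk)
  if (s_used == 0L) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  # exact hash lookup against the sorted index
  j <- findInterval(sk$hash, index$uh)
  hit <- j > 0L & index$uh[pmax(j, 1L)] == sk$hash
  if (!any(hit)) return(empty)
  jh <- j[hit]
  lens <- index$ends[jh] - index$starts[jh] + 1L
  rows <- sequence(lens, from = index$starts[jh])
  hid <- rep(which(hit), lens)              # sketch index per occurrence
  qstrand <- rep(sk$strand[hit], lens)
  m_used <- max(1L, as.integer(ceiling(s_used * params$tau - 1e-9)))
  out <- lapply(unique(index$ref[rows]), function(ri) {
    sel <- rows[index$ref[rows] == ri]
    hsel <- hid[index$ref[rows] == ri]
    qsel <- qstrand[index$ref[rows] == ri]
    o <- order(index$pos[sel])
    w <- scan_windows_cpp(index$pos[sel][o], hsel[o] - 1L,
                          qsel[o] * index$strand[sel][o],
                          params$flen, m_used, s_used,
                          unname(index$ref_lengths[ri]))
    if (nrow(w) == 0L) return(NULL)
    jac <- w$shared / s_used
    keep <- jac >= params$tau - 1e-12
    if (!any(keep)) return(NULL)
    data.frame(query_id = query_id, fragment_index = fragment_index,
               ref_id = index$ref_names[ri], ref_begin = w$r_begin[keep],
               strand = ifelse(w$strand[keep] > 0L, "+", "-"),
               jaccard = jac[keep],
               identity = 100 * (1 - error_from_jaccard(jac[keep], params$k)))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  as.data.frame(data.table::rbindlist(out))
}

#' Merge consecutive fragment mappings into local alignment segments
#'
#' Mappings of consecutive query fragments on the same reference sequence
#' and strand are grouped into one segment when their reference begin
#' positions are monotone in the strand's direction (non-decreasing on "+",
#' non-increasing on "-") and adjacent begins differ by at most `l0`.
#' Boundaries are the first and last member offsets extended by the fragment
#' length; the segment identity is the arithmetic mean of the member
#' identities and the score is the identity fraction multiplied by the total
#' fragment length.  Singleton runs become 1-fragment segments.
#'
#' @param mappings data.frame of fragment mappings (see [map_fragment()]).
#' @param params a `map_params` object.
#' @return A data.frame of segments with columns `query_id`, `q_begin`,
#'   `q_end`, `ref_id`, `r_begin`, `r_end` (0-based, half-open), `strand`,
#'   `n_fragments`, `identity` (percent) and `score` (bp-equivalents).
#' @export
merge_mappings <- function(mappings, params) {
  stopifnot(inherits(params, "map_params"))
  flen <- params$flen
  l0 <- params$l0
  if (NROW(mappings) == 0L) return(empty_segments())
  o <- order(mappings$query_id, mappings$ref_id, mappings$strand,
             mappings$fragment_index, mappings$ref_begin)
  mp <- mappings[o, , drop = FALSE]
  key <- paste(mp$query_id, mp$ref_id, mp$strand, sep = "\r")
  segs <- list()
  for (g in split(seq_len(nrow(mp)), key)) {
    strand <- mp$strand[g[1L]]
    chains <- list()   # each: list(fis, ps, ids (identities))
    for (r in g) {
      fi <- mp$fragment_index[r]
      p <- mp$ref_begin[r]
      best <- 0L
      best_dev <- Inf
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        lfi <- ch$fis[length(ch$fis)]
        lp <- ch$ps[length(ch$ps)]
        if (fi != lfi + 1L) next
        ok <- if (strand == "+") p >= lp && p - lp <= l0
              else               p <= lp && lp - p <= l0
        if (!ok) next
        dev <- abs(if (strand == "+") p - lp - flen else lp - p - flen)
        if (dev < best_dev) { best_dev <- dev; best <- ci }
      }
      if (best > 0L) {
        chains[[best]]$fis <- c(chains[[best]]$fis, fi)
        chains[[best]]$ps <- c(chains[[best]]$ps, p)
        chains[[best]]$ids <- c(chains[[best]]$ids, mp$identity[r])
      } else {
        chains[[length(chains) + 1L]] <-
          list(fis = fi, ps = p, ids = mp$identity[r])
      }
    }
    for (ch in chains) {
      nf <- length(ch$fis)
      identity <- mean(ch$ids)
      q_begin <- ch$fis[1L] * flen
      q_end <- (ch$fis[nf] + 1L) * flen
      segs[[length(segs) + 1L]] <- data.frame(
        query_id = mp$query_id[g[1L]],
        q_begin = q_begin, q_end = q_end,
        ref_id = mp$ref_id[g[1L]],
        r_begin = if (strand == "+") ch$ps[1L] else ch$ps[nf],
        r_end = (if (strand == "+") ch$ps[nf] else ch$ps[1L]) + flen,
        strand = strand, n_fragments = nf,
        identity = identity,
        score = identity / 100 * (q_end - q_begin))
    }
  }
  out <- as.data.frame(data.table::rbindlist(segs))
  out[order(out$query_id, out$q_begin, out$ref_id, out$r_begin), ,
      drop = FALSE]
}

empty_segments <- function() {
  data.frame(query_id = character(0), q_begin = integer(0),
             q_end = integer(0), ref_id = character(0),
             r_begin = integer(0), r_end = integer(0),
             strand = character(0), n_fragments = integer(0),
             identity = numeric(0), score = numeric(0))
}

as_seqs <- function(x, what) {
  x <- toupper(as.character(x))
  if (length(x) == 0L) stop(sprintf("empty %s sequence set", what))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0(what, seq_along(x))
  if (anyDuplicated(names(x)))
    stop(sprintf("duplicate %s sequence names", what))
  as.list(x)
}

#' Map all query sequences against all reference sequences
#'
#' Indexes the reference once, fragments every query into `l0/2` windows,
#' maps each fragment end-to-end and merges consecutive fragment mappings
#' into scored segments.  The result is unfiltered; apply [filter_map()] or
#' [filter_one_to_one()] afterwards.
#'
#' @param query,ref named character vectors of sequences (or a
#'   `DNAStringSet`).
#' @param params a `map_params` object from [auto_tune()].
#' @param self logical; in self-comparison mode the trivial diagonal
#'   (identical query/reference id and identical coordinates on "+") is
#'   dropped, keeping symmetric pairs.
#' @param verbose print progress messages.
#' @return A segment data.frame (see [merge_mappings()]) with extra columns
#'   `query_length` and `ref_length`; attributes `n_fragment_mappings`
#'   (fragment mappings before merging) and `n_fragments_skipped` (fragments
#'   with an empty sketch).
#' @export
map_all <- function(query, ref, params, self = FALSE, verbose = FALSE) {
  stopifnot(inherits(params, "map_params"))
  ref <- as_seqs(ref, "ref")
  query <- as_seqs(query, "query")
  index <- build_reference_index(ref, params)
  n_fm <- 0L
  n_skip <- 0L
  per_query <- lapply(names(query), function(qn) {
    Q <- query[[qn]]
    fr <- fragment_query(Q, params$l0)
    if (nrow(fr) == 0L) {
      if (verbose) message(sprintf("query %s shorter than l0/2: unmapped", qn))
      return(empty_segments())
    }
    if (nchar(Q) %% params$flen > 0L && verbose)
      message(sprintf("query %s: %d bp tail dropped", qn,
                      nchar(Q) %% params$flen))
    maps <- lapply(seq_len(nrow(fr)), function(i) {
      m <- map_fragment(substr(Q, fr$begin[i] + 1L, fr$end[i]), index,
                        params, qn, fr$fragment_index[i])
      if (isTRUE(attr(m, "skipped"))) n_skip <<- n_skip + 1L
      m
    })
    maps <- as.data.frame(data.table::rbindlist(maps))
    n_fm <<- n_fm + nrow(maps)
    merge_mappings(maps, params)
  })
  out <- as.data.frame(data.table::rbindlist(per_query))
  if (nrow(out) == 0L) out <- empty_segments()
  if (self && nrow(out) > 0L) {
    trivial <- out$query_id == out$ref_id & out$q_begin == out$r_begin &
      out$q_end == out$r_end & out$strand == "+"
    out <- out[!trivial, , drop = FALSE]
  }
  if (nrow(out) > 0L) {
    out$query_length <- vapply(out$query_id,
                               function(n) nchar(query[[n]]), integer(1),
                               USE.NAMES = FALSE)
    out$ref_length <- unname(index$ref_lengths[out$ref_id])
  } else {
    out$query_length <- integer(0)
    out$ref_length <- integer(0)
  }
  rownames(out) <- NULL
  attr(out, "n_fragment_mappings") <- n_fm
  attr(out, "n_fragments_skipped") <- n_skip
  out
}
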