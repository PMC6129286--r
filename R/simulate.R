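#' @noRd
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random genome sequence
#'
#' I.i.d. uniform A/C/G/T string, a pure function of the seed.
#'
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                               replace = TRUE), collapse = ""))
}

#' Mutate a sequence under the Poisson error model
#'
#' Each position independently suffers an error with probability `eps`; the
#' error type is drawn from the substitution/insertion/deletion mixture
#' (insertions add one random base after the position).  The realized
#' per-base error rate is the event count divided by the input length.
#'
#' @param seq a single DNA string.
#' @param eps target per-base error rate in `[0, 1)`.
#' @param mix named numeric mixture over `sub`, `ins`, `del`; must sum to 1.
#' @param seed integer seed.
#' @return A list with `seq` (mutated string), `n_events` and
#'   `realized_eps`.
#' @export
mutate_sequence <- function(seq, eps,
                            mix = c(sub = 0.8, ins = 0.1, del = 0.1),
                            seed = 1L) {
  stopifnot(eps >= 0, eps < 1, abs(sum(mix) - 1) < 1e-9,
            all(c("sub", "ins", "del") %in% names(mix)))
  n <- nchar(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(n) < eps)
    if (length(hit)) {
      type <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                     prob = mix[c("sub", "ins", "del")])
      bases <- c("A", "C", "G", "T")
      subs <- hit[type == "sub"]
      if (length(subs)) {
        cur <- match(chars[subs], bases)
        shift <- sample.int(3L, length(subs), replace = TRUE)
        chars[subs] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
      ins <- hit[type == "ins"]
      if (length(ins))
        chars[ins] <- paste0(chars[ins],
                             sample(bases, length(ins), replace = TRUE))
      del <- hit[type == "del"]
      keep <- rep(TRUE, n)
      keep[del] <- FALSE
      chars <- chars[keep]
    }
    list(seq = paste(chars, collapse = ""),
         n_events = length(hit),
         realized_eps = length(hit) / n)
  })
}

#' Plant mutated homologous copies of reference loci into a query
#'
#' Builds a random reference of the requested length, selects
#' non-overlapping loci, and constructs a query as alternating random
#' spacers and mutated copies of those loci (reverse-complemented for "-"
#' strand).  Spacers are drawn independently of the reference so accidental
#' homology is negligible.  Ground-truth intervals are returned for recall
#' scoring.
#'
#' @param ref_length reference length in bp.
#' @param homologies data.frame with columns `length` (bp), `eps` (true
#'   error rate) and `strand` ("+" or "-"), one planted copy per row.
#' @param seed integer seed.
#' @param spacer spacer length between planted copies in the query (and the
#'   minimum gap between loci on the reference).
#' @param mix mutation mixture, see [mutate_sequence()].
#' @return A list with `reference` and `query` (named character vectors of
#'   one sequence each) and `truth`, a data.frame with columns `query_id`,
#'   `q_begin`, `q_end`, `ref_id`, `r_begin`, `r_end` (0-based, half-open),
#'   `strand`, `eps` and `realized_eps`.
#' @export
plant_homologies <- function(ref_length, homologies, seed,
                             spacer = 10000L,
                             mix = c(sub = 0.8, ins = 0.1, del = 0.1)) {
  stopifnot(is.data.frame(homologies),
            all(c("length", "eps", "strand") %in% names(homologies)),
            all(homologies$strand %in% c("+", "-")))
  nh <- nrow(homologies)
  spacer <- as.integer(spacer)
  homologies$length <- as.integer(homologies$length)
  gap <- max(100L, spacer %/% 10L)
  if (sum(homologies$length) + (nh + 1L) * gap > ref_length)
    stop("infeasible packing: loci plus gaps exceed the reference length")
  reference <- random_genome(ref_length, seed)
  slack <- ref_length - sum(homologies$length) - (nh + 1L) * gap
  with_seed(seed + 1L, {
    u <- runif(nh + 1L)
    extra <- as.integer(slack * u / sum(u))
    r_begin <- integer(nh)
    at <- 0L
    for (i in seq_len(nh)) {
      at <- at + gap + extra[i]
      r_begin[i] <- at
      at <- at + homologies$length[i]
    }
  })
  pieces <- character(2L * nh + 1L)
  q_begin <- q_end <- integer(nh)
  realized <- numeric(nh)
  at <- 0L
  for (i in seq_len(nh)) {
    sp <- random_genome(spacer, seed * 1000L + 2L * i)
    pieces[2L * i - 1L] <- sp
    at <- at + spacer
    locus <- substr(reference, r_begin[i] + 1L,
                    r_begin[i] + homologies$length[i])
    mut <- mutate_sequence(locus, homologies$eps[i], mix = mix,
                           seed = seed * 1000L + 2L * i + 1L)
    copy <- if (homologies$strand[i] == "-") revcomp(mut$seq) else mut$seq
    pieces[2L * i] <- copy
    q_begin[i] <- at
    at <- at + nchar(copy)
    q_end[i] <- at
    realized[i] <- mut$realized_eps
  }
  pieces[2L * nh + 1L] <- random_genome(spacer, seed * 1000L + 2L * nh + 2L)
  query <- paste(pieces, collapse = "")
  list(reference = c(ref1 = reference),
       query = c(query1 = query),
       truth = data.frame(query_id = "query1", q_begin = q_begin,
                          q_end = q_end, ref_id = "ref1",
                          r_begin = r_begin,
                          r_end = r_begin + homologies$length,
                          strand = homologies$strand,
                          eps = homologies$eps, realized_eps = realized))
}

#' Score recall of planted homologies
#'
#' A planted homology counts as recalled when some reported segment
#' overlaps it on both the query and the reference axis and the mapping
#' strand matches.
#'
#' @param segments a segment data.frame (see [map_all()]).
#' @param truth ground-truth data.frame from [plant_homologies()].
#' @return A list with `per_locus` (logical vector) and `recall`
#'   (fraction recalled).
#' @export
score_recall <- function(segments, truth) {
  per <- vapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    any(segments$query_id == t$query_id &
          segments$ref_id == t$ref_id &
          segments$strand == t$strand &
          segments$q_begin < t$q_end & segments$q_end > t$q_begin &
          segments$r_begin < t$r_end & segments$r_end > t$r_begin)
  }, logical(1))
  list(per_locus = per, recall = mean(per))
}

#' Write a planted-homology fixture to disk
#'
#' Writes the reference and query FASTA files plus a BED-like TSV of the
#' ground-truth intervals.
#'
#' @param fixture result of [plant_homologies()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$reference, file.path(dir, "reference.fa"))
  write_fasta(fixture$query, file.path(dir, "query.fa"))
  write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
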