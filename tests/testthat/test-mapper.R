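params10k <- auto_tune(10000, 0.10)

test_that("fragment_query tiles the query and drops the tail", {
  flen <- params10k$flen
  f3 <- fragment_query(strrep("A", 3 * flen), 10000)
  expect_identical(nrow(f3), 3L)
  expect_identical(f3$begin, c(0L, 5000L, 10000L))
  expect_identical(f3$end, c(5000L, 10000L, 15000L))
  expect_identical(nrow(fragment_query(strrep("A", 3 * flen + 7), 10000)), 3L)
  expect_identical(nrow(fragment_query(strrep("A", 9999), 10000)), 1L)
  expect_identical(nrow(fragment_query(strrep("A", 4999), 10000)), 0L)
})

test_that("a verbatim fragment maps at its source with Jaccard 1", {
  ref <- c(r1 = random_genome(60000, 21))
  idx <- build_reference_index(ref, params10k)
  frag <- substr(ref[[1]], 20001, 25000)
  m <- map_fragment(frag, idx, params10k, "q", 3L)
  expect_identical(nrow(m), 1L)
  expect_equal(m$jaccard, 1)
  expect_equal(m$identity, 100)
  expect_identical(m$strand, "+")
  # boundary estimate within one winnowing window of the true offset
  expect_lt(abs(m$ref_begin - 20000), params10k$w + params10k$k)

  # reverse-complemented fragment: same locus, "-" strand
  mr <- map_fragment(revcomp(frag), idx, params10k, "q", 3L)
  expect_identical(nrow(mr), 1L)
  expect_equal(mr$jaccard, 1)
  expect_identical(mr$strand, "-")
  expect_lt(abs(mr$ref_begin - 20000), params10k$w + params10k$k)

  # an all-N fragment is skipped, not an error
  mn <- map_fragment(strrep("N", 5000), idx, params10k)
  expect_identical(nrow(mn), 0L)
  expect_true(isTRUE(attr(mn, "skipped")))
})

test_that("fragment mapping agrees with the standalone Jaccard estimator", {
  params <- auto_tune(2000, 0.10)
  ref <- c(r1 = random_genome(20000, 22))
  idx <- build_reference_index(ref, params)
  mut <- mutate_sequence(substr(ref[[1]], 8001, 9000), 0.05, seed = 5)
  frag <- substr(paste0(mut$seq, strrep("A", 1000)), 1, 1000)
  m <- map_fragment(frag, idx, params, "q", 0L)
  expect_gte(nrow(m), 1L)
  best <- m[which.max(m$jaccard), ]
  sk <- build_sketch(winnow_minimizers(frag, params$k, params$w), params$s)
  win <- substr(ref[[1]], best$ref_begin + 1, best$ref_begin + params$flen)
  # window minimizers re-extracted independently from the reference slice:
  # every index minimizer inside the window is also a slice minimizer
  ref_h <- winnow_minimizers(win, params$k, params$w)$hash
  expect_equal(best$jaccard, jaccard_estimate(sk, ref_h), tolerance = 0.02)
  expect_equal(best$identity,
               100 * (1 - error_from_jaccard(best$jaccard, params$k)))
})

test_that("mutated fragments are recovered at the analytic rate", {
  params <- auto_tune(5000, 0.10)
  ref <- c(r1 = random_genome(80000, 23))
  idx <- build_reference_index(ref, params)
  M <- 60L
  hits <- 0L
  for (i in seq_len(M)) {
    at <- 1000L + (i %% 20L) * 3000L
    frag <- mutate_sequence(substr(ref[[1]], at + 1L, at + params$flen),
                            0.05, mix = c(sub = 1, ins = 0, del = 0),
                            seed = 900 + i)$seq
    frag <- substr(frag, 1, params$flen)
    m <- map_fragment(frag, idx, params)
    if (nrow(m) && any(abs(m$ref_begin - at) < params$flen)) hits <- hits + 1L
  }
  p <- per_fragment_prob(0.05, params)
  expect_gte(hits / M, p - 3 * sqrt(p * (1 - p) / M))
})

test_that("merge rule groups monotone close mappings and scores them", {
  mk <- function(fi, p, ident = 96, strand = "+")
    data.frame(query_id = "q", fragment_index = fi, ref_id = "r",
               ref_begin = p, strand = strand,
               jaccard = 0.5, identity = ident)
  # consecutive fragments, gap 5000 <= l0: merged
  s <- merge_mappings(rbind(mk(0L, 100), mk(1L, 5100)), params10k)
  expect_identical(nrow(s), 1L)
  expect_identical(s$q_end - s$q_begin, 10000L)
  expect_equal(s$r_begin, 100)
  expect_equal(s$r_end - s$r_begin, 5000 + 5000)
  # decreasing reference begins on "+": NOT merged
  s2 <- merge_mappings(rbind(mk(0L, 5100), mk(1L, 100)), params10k)
  expect_identical(nrow(s2), 2L)
  expect_true(all(s2$n_fragments == 1L))
  # gap above l0: not merged
  s3 <- merge_mappings(rbind(mk(0L, 100), mk(1L, 100 + 10001)), params10k)
  expect_identical(nrow(s3), 2L)
  # score formula: mean identity times total fragment length
  s4 <- merge_mappings(rbind(mk(0L, 100, 95), mk(1L, 5100, 97)), params10k)
  expect_equal(s4$identity, 96)
  expect_equal(s4$score, 0.96 * 10000)
  # "-" strand merges on non-increasing begins with the mirrored gap bound
  s5 <- merge_mappings(rbind(mk(0L, 8000, strand = "-"),
                             mk(1L, 3000, strand = "-")), params10k)
  expect_identical(nrow(s5), 1L)
  expect_equal(s5$r_begin, 3000)
  expect_equal(s5$r_end, 8000 + 5000)
  # increasing begins on "-": not merged
  s6 <- merge_mappings(rbind(mk(0L, 3000, strand = "-"),
                             mk(1L, 8000, strand = "-")), params10k)
  expect_identical(nrow(s6), 2L)
  # different reference sequences never merge
  s7 <- merge_mappings(rbind(mk(0L, 100),
                             within(mk(1L, 5100), ref_id <- "r2")),
                       params10k)
  expect_identical(nrow(s7), 2L)
})

test_that("merge is idempotent under input order", {
  set.seed(31)
  mp <- data.frame(query_id = "q",
                   fragment_index = c(0L, 1L, 2L, 4L, 5L, 1L),
                   ref_id = "r",
                   ref_begin = c(100, 5100, 10100, 50000, 55100, 90000),
                   strand = "+", jaccard = 0.5,
                   identity = c(95, 96, 97, 94, 95, 99))
  a <- merge_mappings(mp, params10k)
  b <- merge_mappings(mp[sample(nrow(mp)), ], params10k)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_identical(nrow(a), 3L)
  # every segment satisfies the span and score identities
  expect_equal(a$q_end - a$q_begin, a$n_fragments * params10k$flen)
  expect_equal(a$score, a$identity / 100 * (a$q_end - a$q_begin))
})

test_that("map_all reports no segments between unrelated sequences", {
  params <- auto_tune(10000, 0.05)
  q <- c(qa = random_genome(100000, 41))
  r <- c(ra = random_genome(100000, 42))
  segs <- map_all(q, r, params)
  expect_identical(nrow(segs), 0L)
})

test_that("self-comparison excludes the diagonal but keeps planted repeats", {
  params <- auto_tune(4000, 0.10)
  base <- random_genome(30000, 51)
  dup <- substr(base, 5001, 10000)                  # 5 kb internal repeat
  g <- c(g1 = paste0(base, dup))
  segs <- map_all(g, g, params, self = TRUE)
  expect_gt(nrow(segs), 0L)
  expect_false(any(segs$q_begin == segs$r_begin &
                     segs$q_end == segs$r_end & segs$strand == "+"))
  # the planted duplication is found in both symmetric orientations
  hit <- segs$q_begin < 10000 & segs$r_begin >= 28000 |
    segs$q_begin >= 28000 & segs$r_begin < 10000
  expect_true(any(hit))
  expect_true(all(segs$identity >=
                    100 * (1 - error_from_jaccard(params$tau, params$k)) - 1e-9))
})

test_that("emitted segments satisfy the structural invariants", {
  params <- auto_tune(5000, 0.10)
  hom <- data.frame(length = c(10000, 15000, 10000), eps = c(0.02, 0.05, 0.08),
                    strand = c("+", "-", "+"))
  fx <- plant_homologies(80000, hom, seed = 61, spacer = 10000)
  segs <- map_all(fx$query, fx$reference, params)
  expect_gte(nrow(segs), 3L)
  expect_true(all(segs$q_end - segs$q_begin >= params$flen))
  expect_true(all(segs$q_end - segs$q_begin ==
                    segs$n_fragments * params$flen))
  expect_true(all(segs$r_begin >= 0 &
                    segs$r_end <= segs$ref_length))
  expect_equal(segs$score, segs$identity / 100 * (segs$q_end - segs$q_begin))
  expect_gte(attr(segs, "n_fragment_mappings"), nrow(segs))
  expect_identical(score_recall(segs, fx$truth)$recall, 1)
})
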