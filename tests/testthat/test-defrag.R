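test_that("disjoint fragments pass through overlap resolution unchanged", {
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1500L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 500L),
    list(g_start = 2001L, g_end = 2400L, family = "Osr1", part = "IN",
         c_start = 501L, c_end = 900L))
  expect_equal(resolve_overlaps(frags), frags)
})

test_that("the higher-scoring of two identical-interval fragments survives", {
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1500L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 500L, score = 1000),
    list(g_start = 1001L, g_end = 1500L, family = "Osr2", part = "IN",
         c_start = 1L, c_end = 500L, score = 500))
  out <- resolve_overlaps(frags)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 1000)
  expect_equal(out$family, "Osr1")
})

test_that("a lower-scoring overlapping fragment is trimmed to its remainder", {
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1500L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 500L, score = 900),
    list(g_start = 1451L, g_end = 1800L, family = "Osr1", part = "IN",
         c_start = 451L, c_end = 800L, score = 600))
  out <- resolve_overlaps(frags)
  expect_equal(nrow(out), 2L)
  expect_equal(out$g_start, c(1001L, 1501L))
  expect_equal(out$g_end, c(1500L, 1800L))
  # consensus trimmed proportionally: 50 of 350 genome bases cut in front
  expect_equal(out$c_start[2], 501L)
  expect_equal(out$c_end[2], 800L)
})

test_that("length and identity filters drop fragments", {
  frags <- make_fragments(
    list(g_start = 1L, g_end = 80L, family = "A", part = "LTR",
         c_start = 1L, c_end = 80L),                       # too short
    list(g_start = 200L, g_end = 500L, family = "A", part = "LTR",
         c_start = 1L, c_end = 300L, divergence = 25),      # identity 75
    list(g_start = 700L, g_end = 1000L, family = "A", part = "LTR",
         c_start = 1L, c_end = 300L))
  out <- resolve_overlaps(frags, min_len = 100, min_identity = 80)
  expect_equal(nrow(out), 1L)
  expect_equal(out$g_start, 700L)
  # a trimmed remainder below min_len is dropped too
  frags2 <- make_fragments(
    list(g_start = 1000L, g_end = 1500L, family = "A", part = "IN",
         c_start = 1L, c_end = 501L, score = 1000),
    list(g_start = 1450L, g_end = 1580L, family = "A", part = "IN",
         c_start = 450L, c_end = 580L, score = 400))
  expect_equal(nrow(resolve_overlaps(frags2)), 1L)
})

test_that("equal-score overlap ties keep the lower g_start fragment", {
  frags <- make_fragments(
    list(g_start = 1100L, g_end = 1500L, family = "B", part = "IN",
         c_start = 100L, c_end = 500L, score = 700),
    list(g_start = 1001L, g_end = 1400L, family = "A", part = "IN",
         c_start = 1L, c_end = 400L, score = 700))
  out <- resolve_overlaps(frags)
  expect_equal(out$family[1], "A")
  expect_equal(out$g_end[1], 1400L)   # kept intact
  expect_equal(out$g_start[2], 1401L) # trimmed
})

test_that("split hits merge into one candidate with correct completeness", {
  lib <- make_library(c(Osr1_LTR = 300L, Osr1_IN = 1000L))
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1400L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 400L),
    list(g_start = 1406L, g_end = 2000L, family = "Osr1", part = "IN",
         c_start = 401L, c_end = 995L))
  cands <- merge_adjacent(frags, gap_tol = 5, cons_tol = 30, lib = lib)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$g_start, 1001L)
  expect_equal(cands$g_end, 2000L)
  expect_equal(cands$covered[[1]], cbind(1, 995), ignore_attr = TRUE)
  expect_equal(cands$completeness, 0.995)
  expect_equal(nrow(cands$members[[1]]), 2L)
})

test_that("family or part mismatches never merge", {
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1400L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 400L),
    list(g_start = 1406L, g_end = 2000L, family = "Osr2", part = "IN",
         c_start = 401L, c_end = 995L))
  expect_equal(nrow(merge_adjacent(frags)), 2L)
  frags$family <- "Osr1"
  frags$part <- c("IN", "LTR")
  expect_equal(nrow(merge_adjacent(frags)), 2L)
})

test_that("minus-strand merging is orientation-aware", {
  lib <- make_library(c(Osr1_LTR = 300L, Osr1_IN = 1000L))
  # genome-later fragment continues at *lower* consensus coordinates
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1500L, strand = "-", family = "Osr1",
         part = "IN", c_start = 501L, c_end = 1000L),
    list(g_start = 1501L, g_end = 2000L, strand = "-", family = "Osr1",
         part = "IN", c_start = 1L, c_end = 500L))
  cands <- merge_adjacent(frags, lib = lib)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$completeness, 1)
  # the naive plus-strand reading of the same coordinates must not merge
  frags$strand <- "+"
  expect_equal(nrow(merge_adjacent(frags, lib = lib)), 2L)
})

test_that("merge_adjacent is idempotent and honours zero tolerances", {
  set.seed(7)
  lib <- make_library(c(F1_LTR = 300L, F1_IN = 1000L))
  for (rep in 1:5) {
    g <- sort(sample.int(50000, 12))
    frags <- do.call(rbind, lapply(seq_along(g), function(i) {
      cs <- sample(1:500, 1)
      make_fragments(list(g_start = g[i], g_end = g[i] + 199L,
                          family = "F1", part = "IN",
                          c_start = cs, c_end = cs + 199L))
    }))
    frags <- resolve_overlaps(frags)
    cands <- merge_adjacent(frags, lib = lib)
    flat <- do.call(rbind, cands$members)
    rownames(flat) <- NULL
    recands <- merge_adjacent(flat, lib = lib)
    expect_equal(recands[c("g_start", "g_end", "score")],
                 cands[c("g_start", "g_end", "score")])
    # no two candidates overlap on the genome
    expect_true(all(cands$g_start[-1] > cands$g_end[-nrow(cands)]))
  }
  # gap_tol = 0, cons_tol = 0: only perfectly abutting hits fuse
  frags <- make_fragments(
    list(g_start = 1L, g_end = 200L, family = "F1", part = "IN",
         c_start = 1L, c_end = 200L),
    list(g_start = 201L, g_end = 400L, family = "F1", part = "IN",
         c_start = 201L, c_end = 400L),
    list(g_start = 402L, g_end = 600L, family = "F1", part = "IN",
         c_start = 402L, c_end = 600L))
  out <- merge_adjacent(frags, gap_tol = 0, cons_tol = 0, lib = lib)
  expect_equal(nrow(out), 2L)   # third hit has a 1 bp genomic gap
})
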