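test_that("the worked IN-IN example yields link(a,b) = 2 and link(a,c) = 1", {
  cands <- worked_example_candidates()
  lib <- worked_example_library()
  expect_equal(nrow(cands), 3L)
  expect_equal(link_state(1, 2, cands, lib), 2L)
  expect_equal(link_state(1, 3, cands, lib), 1L)
  # b has no continuation of its own LTR anywhere downstream
  expect_equal(link_state(2, 3, cands, lib), 0L)
})

test_that("the reverse-complemented worked example yields mirrored states", {
  cands <- worked_example_candidates_rc()
  lib <- worked_example_library()
  # genome order is now c', b', a'
  expect_equal(cands$strand, rep("-", 3))
  expect_equal(link_state(1, 2, cands, lib), 2L)  # mirror of link(a,b)
  expect_equal(link_state(1, 3, cands, lib), 1L)  # mirror of link(a,c)
})

test_that("unlinkable pairs of different families give state 0", {
  lib <- make_library(c(FamA_LTR = 300L, FamA_IN = 1000L,
                        FamB_LTR = 300L, FamB_IN = 1000L))
  frags <- make_fragments(
    list(g_start = 1000L, g_end = 1299L, family = "FamA", part = "LTR",
         c_start = 1L, c_end = 300L),
    list(g_start = 1400L, g_end = 1699L, family = "FamB", part = "LTR",
         c_start = 1L, c_end = 300L))
  cands <- merge_adjacent(frags, lib = lib)
  expect_equal(link_state(1, 2, cands, lib), 0L)
})

test_that("part transitions fire only at consensus ends", {
  lib <- make_library(c(FamA_LTR = 300L, FamA_IN = 1000L))
  mk <- function(ltr_c_end, in_c_start) {
    frags <- make_fragments(
      list(g_start = 1000L, g_end = 1000L + ltr_c_end - 1L,
           family = "FamA", part = "LTR", c_start = 1L, c_end = ltr_c_end),
      list(g_start = 1000L + ltr_c_end + 9L, g_end = 2500L,
           family = "FamA", part = "IN", c_start = in_c_start,
           c_end = 1000L))
    merge_adjacent(frags, lib = lib)
  }
  expect_equal(link_state(1, 2, mk(300L, 1L), lib), 1L)    # LTR-IN junction
  expect_equal(link_state(1, 2, mk(285L, 12L), lib), 1L)   # within end_tol
  expect_equal(link_state(1, 2, mk(200L, 1L), lib), 0L)    # LTR end missing
  expect_equal(link_state(1, 2, mk(300L, 150L), lib), 0L)  # IN start missing
})

test_that("cross-contig and misordered queries are caller errors", {
  cands <- worked_example_candidates()
  expect_error(link_state(3, 1, cands, worked_example_library()), "precede")
  cands$contig <- c("chr1", "chr2", "chr1")
  expect_error(link_state(1, 2, cands, worked_example_library()), "contig")
})

test_that("the printed seven-fragment states build three dynamic link lists", {
  ordered <- data.frame(id = 1:7, contig = "chr1",
                        g_start = seq(1000L, 7000L, by = 1000L),
                        g_end = seq(1900L, 7900L, by = 1000L),
                        strand = "+", stringsAsFactors = FALSE)
  res <- build_chains(ordered, state_fn = seven_fragment_states())
  expect_equal(res$chains, list(c(1L, 2L, 5L, 6L), 7L))   # (a-b-e-f), (g)
  expect_equal(res$inserted, c(3L, 4L))                   # c, d
  # second pass over the inserted pool links (c-d)
  pool <- ordered[res$inserted, , drop = FALSE]
  sf <- seven_fragment_states()
  res2 <- build_chains(pool, state_fn = function(i, j)
    sf(res$inserted[i], res$inserted[j]))
  expect_equal(res2$chains, list(c(1L, 2L)))
  expect_equal(res2$inserted, integer())
})

test_that("degenerate chain inputs behave as stated", {
  one <- data.frame(id = 1L, contig = "chr1", g_start = 10L, g_end = 20L,
                    strand = "+", stringsAsFactors = FALSE)
  res <- build_chains(one, state_fn = function(i, j) 0L)
  expect_equal(res$chains, list(1L))
  expect_equal(res$inserted, integer())
  five <- data.frame(id = 1:5, contig = "chr1",
                     g_start = 10L * (1:5), g_end = 10L * (1:5) + 5L,
                     strand = "+", stringsAsFactors = FALSE)
  res <- build_chains(five, state_fn = function(i, j) 0L)
  expect_equal(res$chains, as.list(1:5))
})

test_that("resolve_layers reproduces the worked examples", {
  cands <- worked_example_candidates()
  chains <- resolve_layers(cands, worked_example_library())
  layers <- vapply(chains, `[[`, 1L, "layer")
  members <- lapply(chains, `[[`, "members")
  expect_equal(members[layers == 1L], list(c(1L, 3L)))   # a-c
  expect_equal(members[layers == 2L], list(2L))          # b inserted
  host <- chains[[which(layers == 2L)]]$host
  expect_equal(chains[[host]]$members, c(1L, 3L))
})

test_that("every candidate lands in exactly one chain across layers", {
  for (seed in c(2, 6, 11)) {
    sim <- simulate_genome(sim_config(seed = seed))
    res <- run_sim_pipeline(sim, seed = seed)
    ids <- sort(unlist(lapply(res$elements$pieces, function(p) p$candidate_id)))
    expect_equal(ids, res$candidates$id)
  }
})

test_that("hosts contain their nested elements and layers are bounded", {
  sim <- simulate_genome(sim_config(seed = 8,
                                    nest_weights = c(0.4, 0.3, 0.3, 0, 0)))
  expect_gte(max(sim$truth$elements$layer), 3L)
  res <- run_sim_pipeline(sim, seed = 8)
  el <- res$elements
  expect_equal(max(el$layer), max(sim$truth$elements$layer))
  expect_lte(max(el$layer), nrow(res$candidates))
  nested <- el[el$layer >= 2L, ]
  for (k in seq_len(nrow(nested))) {
    host <- el[el$element_id == nested$host[k], ]
    expect_equal(host$layer, nested$layer[k] - 1L)
    expect_lte(host$start, nested$start[k])
    expect_gte(host$end, nested$end[k])
  }
})

test_that("state 1 demands equal strand and family", {
  for (seed in c(3, 9)) {
    sim <- simulate_genome(sim_config(seed = seed))
    res <- run_sim_pipeline(sim, seed = seed)
    for (el in res$elements$pieces) {
      m <- res$candidates[match(el$candidate_id, res$candidates$id), ]
      expect_equal(length(unique(m$strand)), 1L)
      expect_equal(length(unique(m$family)), 1L)
    }
  }
})
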