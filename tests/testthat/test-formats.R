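test_that("library FASTA parsing enforces the naming contract", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">Osr1_IN", fixed_seq(1000, 1), ">Osr1_LTR",
               fixed_seq(300, 2)), fa)
  lib <- read_ltr_library(fa)
  expect_s3_class(lib, "ltr_library")
  expect_setequal(lib$info$part, c("IN", "LTR"))
  expect_equal(lib_length(lib, "Osr1", "IN"), 1000L)
  expect_true(all(lib$info$paired))

  # unpaired family kept with a warning
  writeLines(c(">Osr1_IN", "ACGT", ">Lone_LTR", "ACGT"), fa)
  expect_warning(lib <- read_ltr_library(fa), "Lone")
  expect_equal(nrow(lib$info), 2L)
  expect_false(lib$info$paired[lib$info$family == "Lone"])

  # offending headers are named in the error
  writeLines(c(">Osr1|LTR", "ACGT"), fa)
  expect_error(read_ltr_library(fa), "Osr1\\|LTR")
  writeLines(c(">Osr1 LTR_LTR", "ACGT"), fa)
  expect_error(read_ltr_library(fa), "whitespace")
  writeLines(c(">Osr1_SOLO", "ACGT"), fa)
  expect_error(read_ltr_library(fa), "Osr1_SOLO")
})

test_that("an empty library file yields an empty library, no error", {
  fa <- withr::local_tempfile(fileext = ".fa")
  file.create(fa)
  lib <- read_ltr_library(fa)
  expect_equal(nrow(lib$info), 0L)
})

test_that(".out records round-trip through write_rm_out/read_rm_out", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 15L
    g_start <- as.integer(sort(sample.int(100000, n)))
    len <- as.integer(sample(100:900, n, replace = TRUE))
    clen <- as.integer(pmin(len, sample(100:500, n, replace = TRUE)))
    c_start <- as.integer(sample(1:200, n, replace = TRUE))
    frags <- data.frame(
      contig = sample(c("chr1", "chr2"), n, replace = TRUE),
      g_start = g_start, g_end = g_start + len - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = sample(c("FamA", "FamB"), n, replace = TRUE),
      part = sample(c("LTR", "IN"), n, replace = TRUE),
      c_start = c_start, c_end = c_start + clen - 1L,
      divergence = round(runif(n, 0, 25), 1),
      score = as.numeric(sample(600:5000, n)),
      stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".out")
    write_rm_out(frags, path)
    expect_equal(read_rm_out(path), frags)
  }
})

test_that("C-strand records are normalised to forward consensus", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc ...", "score  div. ...", "",
    " 1000  8.0 0.0 0.0 chr1 5001 5300 (0) C Osr1_LTR LTR/Unknown (0) 300 1"
  ), path)
  f <- read_rm_out(path)
  expect_equal(f$strand, "-")
  expect_equal(f$c_start, 1L)
  expect_equal(f$c_end, 300L)
  expect_equal(f$g_start, 5001L)
})

test_that(".out parse errors and skips are reported precisely", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header", "header", ""), path)
  expect_equal(nrow(read_rm_out(path)), 0L)

  writeLines(c("", " 1000 8.0 0.0 0.0 chr1 100 xyz"), path)
  expect_error(read_rm_out(path), "line 2")

  writeLines(
    " 1000 8.0 0.0 0.0 chr1 100 400 (0) + NoSuffix Unknown 1 300 (0)",
    path)
  expect_warning(f <- read_rm_out(path), "NoSuffix")
  expect_equal(nrow(f), 0L)
})

test_that("fragments overrunning the consensus are reported, not clamped", {
  lib <- make_library(c(Osr1_LTR = 300L, Osr1_IN = 1000L))
  frags <- make_fragments(
    list(g_start = 1L, g_end = 400L, family = "Osr1", part = "LTR",
         c_start = 1L, c_end = 400L))
  expect_warning(bad <- check_fragments(frags, lib), "overrun")
  expect_equal(bad, 1L)
  expect_equal(frags$c_end, 400L)   # untouched
})

test_that("GFF3 output re-parses with spans, layers and hosts intact", {
  sim <- simulate_genome(sim_config(seed = 5))
  res <- run_sim_pipeline(sim, seed = 5)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_elements_gff3(res$elements, path)
  gr <- rtracklayer::import(path)
  el <- gr[gr$type == "repeat_region"]
  expect_equal(length(el), nrow(res$elements))
  ord <- match(res$elements$element_id, el$ID)
  expect_equal(GenomicRanges::start(el)[ord], res$elements$start)
  expect_equal(GenomicRanges::end(el)[ord], res$elements$end)
  nested <- res$elements[res$elements$layer >= 2L, ]
  expect_gt(nrow(nested), 0L)
  for (k in seq_len(nrow(nested))) {
    par <- unlist(el$Parent[el$ID == nested$element_id[k]])
    expect_equal(par, nested$host[k])
  }
  # every candidate piece is a child of its element
  kids <- gr[gr$type == "repeat_fragment"]
  expect_equal(length(kids), sum(vapply(res$elements$pieces, nrow, 1L)))
})

test_that("empty element list writes a bare GFF3 directive", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_elements_gff3(ltrnest:::empty_elements(), path)
  expect_equal(readLines(path), "##gff-version 3")
})

test_that("type tables exist per layer and are internally consistent", {
  sim <- simulate_genome(sim_config(seed = 3))
  res <- run_sim_pipeline(sim, seed = 3)
  out <- withr::local_tempdir()
  write_type_tables(res$summary, out)
  n_layers <- res$summary$n_layers
  expect_gte(n_layers, 2L)
  expect_false(file.exists(file.path(out, paste0("type.num.", n_layers + 1L))))
  for (x in seq_len(n_layers)) {
    num <- read.delim(file.path(out, paste0("type.num.", x)))
    all_tab <- read.delim(file.path(out, paste0("type.all.", x)))
    expect_equal(sum(num$count), nrow(all_tab))
    got <- table(all_tab$type)
    expect_equal(num$count, as.integer(got[num$type]),
                 ignore_attr = TRUE)
  }
})
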