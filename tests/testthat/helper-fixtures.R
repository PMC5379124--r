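# in-memory fixture builders shared across test files

make_fragments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      contig = r$contig %||% "chr1",
      g_start = r$g_start, g_end = r$g_end,
      strand = r$strand %||% "+",
      family = r$family, part = r$part,
      c_start = r$c_start, c_end = r$c_end,
      divergence = r$divergence %||% 5,
      score = r$score %||% 1000,
      stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sequences so library fixtures are reproducible
fixed_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_library <- function(lengths) {
  # lengths: named integer vector, names like "Osr1_LTR"
  seqs <- Biostrings::DNAStringSet(vapply(
    seq_along(lengths), function(i) fixed_seq(lengths[i], seed = 1000 + i),
    character(1)))
  names(seqs) <- names(lengths)
  info <- data.frame(
    family = sub("_(LTR|IN)$", "", names(lengths)),
    part = ifelse(grepl("_LTR$", names(lengths)), "LTR", "IN"),
    length = unname(lengths),
    stringsAsFactors = FALSE)
  n_parts <- stats::aggregate(part ~ family, info,
                              FUN = function(p) length(unique(p)))
  info$paired <- info$family %in% n_parts$family[n_parts$part == 2L]
  structure(list(info = info, seqs = seqs), class = "ltr_library")
}

# the worked IN-IN example: fragments a, b, c with the printed
# coordinates, and an internal-region consensus of 1000 bp for Osr1
worked_example_library <- function() {
  make_library(c(Osr1_LTR = 300L, Osr1_IN = 1000L,
                 Osr2_LTR = 300L, Osr2_IN = 1000L))
}

worked_example_candidates <- function() {
  frags <- make_fragments(
    list(g_start = 1001L, g_end = 1500L, family = "Osr1", part = "IN",
         c_start = 1L, c_end = 500L),
    list(g_start = 1501L, g_end = 1800L, family = "Osr2", part = "LTR",
         c_start = 1L, c_end = 300L),
    list(g_start = 1801L, g_end = 2300L, family = "Osr1", part = "IN",
         c_start = 501L, c_end = 1000L))
  merge_adjacent(frags, lib = worked_example_library())
}

# the same fixture reverse-complemented onto a 3300 bp region: genome
# order becomes c' < b' < a', all on the minus strand, consensus
# coordinates unchanged
worked_example_candidates_rc <- function(genome_len = 3300L) {
  flip <- function(s, e) c(genome_len - e + 1L, genome_len - s + 1L)
  a <- flip(1001L, 1500L); b <- flip(1501L, 1800L); c <- flip(1801L, 2300L)
  frags <- make_fragments(
    list(g_start = c[1], g_end = c[2], strand = "-", family = "Osr1",
         part = "IN", c_start = 501L, c_end = 1000L),
    list(g_start = b[1], g_end = b[2], strand = "-", family = "Osr2",
         part = "LTR", c_start = 1L, c_end = 300L),
    list(g_start = a[1], g_end = a[2], strand = "-", family = "Osr1",
         part = "IN", c_start = 1L, c_end = 500L))
  merge_adjacent(frags, lib = worked_example_library())
}

# the seven-fragment worked example: a..g with the printed pairwise
# link states; unlisted pairs are state 0
seven_fragment_states <- function() {
  states <- list(
    c("a", "b", 1), c("b", "c", 2), c("b", "d", 2), c("b", "e", 1),
    c("c", "d", 1), c("d", "e", 0), c("e", "f", 1), c("f", "g", 0))
  key <- vapply(states, function(s) paste(s[1], s[2]), character(1))
  val <- vapply(states, function(s) as.integer(s[3]), integer(1))
  labels <- letters[1:7]
  function(i, j) {
    k <- match(paste(labels[i], labels[j]), key)
    if (is.na(k)) 0L else val[k]
  }
}

# quadratic-space Needleman-Wunsch oracle: match +1, mismatch -1,
# linear gap -2 (independent of the Biostrings-backed implementation)
nw_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- -2 * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- -2 * i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(prev[j] + ifelse(A[i] == B[j], 1, -1),
                        prev[j + 1] - 2,
                        cur[j] - 2)
    }
    prev <- cur
  }
  prev[m + 1]
}

# run the full pipeline on a simulation; returns the run_pipeline()
# result list
run_sim_pipeline <- function(sim, noise = 0, seed = 1L, dir = tempfile(),
                             genome = FALSE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib_fa <- file.path(dir, "lib.fa")
  Biostrings::writeXStringSet(sim$library$seqs, lib_fa)
  rm_out <- file.path(dir, "RM.out")
  emit_alignments(sim, rm_out, noise = noise, seed = seed)
  genome_fa <- NULL
  if (genome) {
    genome_fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, genome_fa)
  }
  run_pipeline(run_config(library_path = lib_fa, out_path = rm_out,
                          genome_path = genome_fa,
                          out_dir = file.path(dir, "out"), ...))
}

layer_type_table <- function(elements) {
  tab <- as.data.frame(table(layer = elements$layer,
                             type = elements$type),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  tab[order(tab$layer, tab$type), , drop = FALSE]
}

expect_same_counts <- function(elements, truth_elements) {
  a <- layer_type_table(elements)
  b <- layer_type_table(truth_elements)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
}
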