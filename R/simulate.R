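#' Simulation configuration
#'
#' Describes a synthetic genome carrying planted LTR retrotransposons
#' of every structural type the annotator recovers: full-length
#' (LTR-IN-LTR), solo-LTR, shared-LTR complex (LTR-IN-LTR-IN-LTR),
#' 5'- and 3'-truncated, internal-only, and multi-layer nested
#' insertions with target-site duplications.  The seed fully
#' determines the output.
#'
#' @param seed Integer seed; drives every random choice.
#' @param genome_length Final genome length in bp, inserted material
#'   included (default 200000).
#' @param n_families Number of consensus families in the library.
#' @param n_normal,n_solo,n_complex3,n_trunc5,n_trunc3,n_internal
#'   Planted copy numbers per structural type (full-length, solo-LTR,
#'   three-LTR complex, 5'-truncated, 3'-truncated, internal-only).
#' @param nest_weights Sampling weights over nesting depths 1..5; an
#'   element of depth k is inserted inside a depth k-1 element.
#' @param tsd_range Target-site-duplication length range in bp
#'   (default 4-6).
#' @param ltr_range,in_range Consensus length ranges for LTRs and
#'   internal regions, bp.
#' @param mutation_rate Per-site substitution probability applied to
#'   each planted copy relative to its consensus (default 0.02).
#' @param fragmentation_noise Probability that [emit_alignments()]
#'   splits an emitted record into two abutting sub-records.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L, n_families = 3L,
                       n_normal = 6L, n_solo = 4L, n_complex3 = 1L,
                       n_trunc5 = 2L, n_trunc3 = 2L, n_internal = 2L,
                       nest_weights = c(0.6, 0.25, 0.1, 0.04, 0.01),
                       tsd_range = c(4L, 6L),
                       ltr_range = c(200L, 600L),
                       in_range = c(1000L, 4000L),
                       mutation_rate = 0.02,
                       fragmentation_noise = 0) {
  stopifnot(length(nest_weights) == 5L, all(nest_weights >= 0),
            sum(nest_weights) > 0,
            n_normal >= 0, n_solo >= 0, n_complex3 >= 0,
            n_trunc5 >= 0, n_trunc3 >= 0, n_internal >= 0,
            mutation_rate >= 0, mutation_rate < 1,
            fragmentation_noise >= 0, fragmentation_noise <= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

seq_divergence <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# an assembly is a sequence plus a table of part segments; `start`/
# `end` are positions within `seq`, `c_start`/`c_end` the consensus
# interval the segment represents, `strand` the orientation within the
# current frame
new_assembly <- function(seq, segs = NULL) {
  if (is.null(segs)) {
    segs <- data.frame(element = integer(), part = character(),
                       c_start = integer(), c_end = integer(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  }
  list(seq = seq, segs = segs)
}

assembly_from_parts <- function(elem_id, parts) {
  # parts: list of list(part, c_start, c_end, seq)
  offs <- 0L
  segs <- list()
  seqs <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    len <- nchar(p$seq)
    segs[[i]] <- data.frame(element = elem_id, part = p$part,
                            c_start = p$c_start, c_end = p$c_end,
                            start = offs + 1L, end = offs + len,
                            strand = "+", stringsAsFactors = FALSE)
    seqs[i] <- p$seq
    offs <- offs + len
  }
  new_assembly(paste(seqs, collapse = ""), do.call(rbind, segs))
}

revcomp_assembly <- function(a) {
  n <- nchar(a$seq)
  a$seq <- revcomp_chr(a$seq)
  if (nrow(a$segs)) {
    s <- a$segs
    new_start <- n - s$end + 1L
    s$end <- n - s$start + 1L
    s$start <- new_start
    s$strand <- ifelse(s$strand == "+", "-", "+")
    s <- s[order(s$start), , drop = FALSE]
    rownames(s) <- NULL
    a$segs <- s
  }
  a
}

# insert `donor` into `host` after position `pos`, duplicating the
# `tsd_len` bases ending at `pos` (target-site duplication)
insert_assembly <- function(host, donor, pos, tsd_len) {
  n <- nchar(host$seq)
  Ld <- nchar(donor$seq)
  stopifnot(pos >= tsd_len, pos < n)
  shift <- Ld + tsd_len
  host_seq <- paste0(substr(host$seq, 1L, pos), donor$seq,
                     substr(host$seq, pos - tsd_len + 1L, n))
  segs <- list()
  for (i in seq_len(nrow(host$segs))) {
    sg <- host$segs[i, ]
    if (sg$end <= pos) {
      segs[[length(segs) + 1L]] <- sg
    } else if (sg$start > pos) {
      sg$start <- sg$start + shift
      sg$end <- sg$end + shift
      segs[[length(segs) + 1L]] <- sg
    } else {
      # split; the duplicated target site stays part of both halves
      left <- sg; right <- sg
      left$end <- pos
      right$start <- pos - tsd_len + 1L + shift
      right$end <- sg$end + shift
      if (sg$strand == "+") {
        left$c_end <- sg$c_start + (pos - sg$start)
        right$c_start <- left$c_end - tsd_len + 1L
      } else {
        left$c_start <- sg$c_end - (pos - sg$start)
        right$c_end <- left$c_start + tsd_len - 1L
      }
      segs[[length(segs) + 1L]] <- left
      segs[[length(segs) + 1L]] <- right
    }
  }
  dsegs <- donor$segs
  if (nrow(dsegs)) {
    dsegs$start <- dsegs$start + pos
    dsegs$end <- dsegs$end + pos
  }
  segs <- rbind(do.call(rbind, segs), dsegs)
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  new_assembly(host_seq, segs)
}

# minimum length a split piece may have; keeps every emitted record
# comfortably above the default length/score filters
SIM_MARGIN <- 120L
SIM_MIN_GAP <- 500L

eligible_segs <- function(assembly, elem_id) {
  s <- assembly$segs
  which(s$element == elem_id & s$part %in% c("LTR", "IN") &
          (s$end - s$start + 1L) >= 2L * SIM_MARGIN + 2L)
}

build_base_assembly <- function(id, type, fam, lib_seqs, cfg) {
  ltr <- lib_seqs$LTR[[fam]]
  inr <- lib_seqs$IN[[fam]]
  M <- nchar(inr)
  mk <- function(part, c_start, c_end, src) {
    list(part = part, c_start = c_start, c_end = c_end,
         seq = mutate_seq(substr(src, c_start, c_end), cfg$mutation_rate))
  }
  parts <- switch(type,
    normal = list(mk("LTR", 1L, nchar(ltr), ltr),
                  mk("IN", 1L, M, inr),
                  mk("LTR", 1L, nchar(ltr), ltr)),
    solo = list(mk("LTR", 1L, nchar(ltr), ltr)),
    complex3 = list(mk("LTR", 1L, nchar(ltr), ltr),
                    mk("IN", 1L, M, inr),
                    mk("LTR", 1L, nchar(ltr), ltr),
                    mk("IN", 1L, M, inr),
                    mk("LTR", 1L, nchar(ltr), ltr)),
    trunc5 = {
      q <- sample(seq(round(0.3 * M), round(0.6 * M)), 1L)
      list(mk("IN", q, M, inr), mk("LTR", 1L, nchar(ltr), ltr))
    },
    trunc3 = {
      q <- sample(seq(round(0.3 * M), round(0.6 * M)), 1L)
      list(mk("LTR", 1L, nchar(ltr), ltr), mk("IN", 1L, q, inr))
    },
    internal = list(mk("IN", 1L, M, inr)),
    stop("unknown element type: ", type)
  )
  ltr_parts <- which(vapply(parts, function(p) p$part, "") == "LTR")
  ltr_div <- if (length(ltr_parts) >= 2L) {
    seq_divergence(parts[[ltr_parts[1]]]$seq, parts[[ltr_parts[2]]]$seq)
  } else NA_real_
  list(assembly = assembly_from_parts(id, parts),
       type = paste(rle(vapply(parts, function(p) p$part, ""))$values,
                    collapse = "-"),
       ltr_div = ltr_div)
}

#' Simulate a genome with planted LTR retrotransposons
#'
#' Generates an i.i.d.-uniform background sequence, a consensus
#' library, and planted element copies per [sim_config()]: per-copy
#' substitutions at the configured rate, target-site duplications at
#' every insertion point, and nested insertions that split their
#' host's sequence.  Nesting never lands within 120 bp of a part
#' boundary, so every split piece stays above the default length
#' filters and breakpoint ownership is unambiguous.
#'
#' @param config A [sim_config()].
#' @return A list of class `ltr_simulation`: `genome` (named
#'   [Biostrings::DNAStringSet], one contig `chr1`), `library` (an
#'   `ltr_library`), and `truth` — a list with `elements` (same schema
#'   as [build_elements()] plus `tsd_len` and `ltr_divergence`) and
#'   `pieces` (one row per planted part piece with genome and
#'   consensus coordinates).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fams <- sprintf("Fam%02d", seq_len(config$n_families))
  ltr_len <- sample(seq(config$ltr_range[1], config$ltr_range[2]),
                    config$n_families, replace = TRUE)
  in_len <- sample(seq(config$in_range[1], config$in_range[2]),
                   config$n_families, replace = TRUE)
  lib_seqs <- list(
    LTR = stats::setNames(lapply(ltr_len, random_seq), fams),
    IN = stats::setNames(lapply(in_len, random_seq), fams))
  lib <- make_sim_library(fams, lib_seqs)

  types <- rep(c("normal", "solo", "complex3", "trunc5", "trunc3",
                 "internal"),
               c(config$n_normal, config$n_solo, config$n_complex3,
                 config$n_trunc5, config$n_trunc3, config$n_internal))
  n_elem <- length(types)
  if (n_elem == 0L) {
    genome <- Biostrings::DNAStringSet(random_seq(config$genome_length))
    names(genome) <- "chr1"
    return(structure(list(genome = genome, library = lib,
                          truth = list(elements = empty_elements(),
                                       pieces = empty_truth_pieces())),
                     class = "ltr_simulation"))
  }
  elem <- data.frame(
    id = seq_len(n_elem),
    type = types,
    family = sample(fams, n_elem, replace = TRUE),
    rel_strand = sample(c("+", "-"), n_elem, replace = TRUE),
    tsd_len = sample(seq(config$tsd_range[1], config$tsd_range[2]),
                     n_elem, replace = TRUE),
    layer = sample(1:5, n_elem, replace = TRUE,
                   prob = config$nest_weights),
    stringsAsFactors = FALSE
  )
  # nesting needs a host one layer up; demote orphans
  for (k in 2:5) {
    if (any(elem$layer == k) && !any(elem$layer == k - 1L)) {
      elem$layer[elem$layer >= k] <- elem$layer[elem$layer >= k] - 1L
    }
  }
  base <- lapply(seq_len(n_elem), function(i) {
    build_base_assembly(i, elem$type[i], elem$family[i], lib_seqs, config)
  })
  elem$type_string <- vapply(base, function(b) b$type, "")
  elem$ltr_div <- vapply(base, function(b) b$ltr_div, 1)
  assemblies <- lapply(base, function(b) b$assembly)
  for (i in seq_len(n_elem)) {
    if (elem$rel_strand[i] == "-") {
      assemblies[[i]] <- revcomp_assembly(assemblies[[i]])
    }
  }
  elem$host <- NA_integer_
  # deepest layer first: donors are complete before their hosts move
  for (k in sort(unique(elem$layer[elem$layer >= 2L]), decreasing = TRUE)) {
    for (i in which(elem$layer == k)) {
      hosts <- which(elem$layer == k - 1L)
      hosts <- hosts[vapply(hosts, function(h) {
        length(eligible_segs(assemblies[[h]], h)) > 0L
      }, logical(1))]
      if (!length(hosts)) {          # nothing can carry it: promote
        elem$layer[i] <- 1L
        next
      }
      h <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
      segi <- eligible_segs(assemblies[[h]], h)
      segi <- if (length(segi) == 1L) segi else sample(segi, 1L)
      sg <- assemblies[[h]]$segs[segi, ]
      pos <- sample(seq(sg$start + SIM_MARGIN, sg$end - SIM_MARGIN - 1L), 1L)
      assemblies[[h]] <- insert_assembly(assemblies[[h]], assemblies[[i]],
                                         pos, elem$tsd_len[i])
      elem$host[i] <- h
    }
  }
  top <- which(elem$layer == 1L)
  top_len <- vapply(top, function(i) nchar(assemblies[[i]]$seq), 1L)
  bg_len <- config$genome_length - sum(top_len + elem$tsd_len[top])
  k <- length(top)
  if (bg_len < (k + 1L) * SIM_MIN_GAP) {
    stop("requested content exceeds genome_length (need background of ",
         (k + 1L) * SIM_MIN_GAP + sum(top_len + elem$tsd_len[top]),
         " bp, have ", config$genome_length, ")")
  }
  extra <- bg_len - (k + 1L) * SIM_MIN_GAP
  u <- sort(stats::runif(k))
  sites <- SIM_MIN_GAP * seq_len(k) + floor(u * extra)
  genome_asm <- new_assembly(random_seq(bg_len))
  for (j in rev(seq_len(k))) {       # right-to-left: sites stay valid
    genome_asm <- insert_assembly(genome_asm, assemblies[[top[j]]],
                                  sites[j], elem$tsd_len[top[j]])
  }
  genome <- Biostrings::DNAStringSet(genome_asm$seq)
  names(genome) <- "chr1"
  truth <- truth_from_assembly(genome_asm, elem)
  structure(list(genome = genome, library = lib, truth = truth),
            class = "ltr_simulation")
}

make_sim_library <- function(fams, lib_seqs) {
  seqs <- Biostrings::DNAStringSet(c(
    stats::setNames(unlist(lib_seqs$LTR), paste0(fams, "_LTR")),
    stats::setNames(unlist(lib_seqs$IN), paste0(fams, "_IN"))))
  info <- data.frame(
    family = rep(fams, 2L),
    part = rep(c("LTR", "IN"), each = length(fams)),
    length = Biostrings::width(seqs),
    paired = TRUE,
    stringsAsFactors = FALSE)
  structure(list(info = info, seqs = seqs), class = "ltr_library")
}

empty_truth_pieces <- function() {
  data.frame(element = integer(), part = character(),
             c_start = integer(), c_end = integer(),
             g_start = integer(), g_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

truth_from_assembly <- function(genome_asm, elem) {
  segs <- genome_asm$segs
  pieces <- data.frame(element = segs$element, part = segs$part,
                       c_start = segs$c_start, c_end = segs$c_end,
                       g_start = segs$start, g_end = segs$end,
                       strand = segs$strand, stringsAsFactors = FALSE)
  ids <- sprintf("elem_%04d", elem$id)
  rows <- lapply(seq_len(nrow(elem)), function(i) {
    ps <- pieces[pieces$element == elem$id[i], , drop = FALSE]
    ps <- ps[order(ps$g_start), , drop = FALSE]
    strand <- ps$strand[1]
    # type strings are always element (5'->3') order, strand-independent
    out <- data.frame(
      element_id = ids[i], layer = elem$layer[i], contig = "chr1",
      start = min(ps$g_start), end = max(ps$g_end), strand = strand,
      family = elem$family[i], type = elem$type_string[i],
      category = categorize_type(elem$type_string[i]),
      nested = elem$layer[i] >= 2L,
      host = if (is.na(elem$host[i])) NA_character_ else ids[elem$host[i]],
      completeness = NA_real_, stringsAsFactors = FALSE)
    out$pieces <- list(data.frame(candidate_id = NA_integer_,
                                  g_start = ps$g_start, g_end = ps$g_end,
                                  part = ps$part, stringsAsFactors = FALSE))
    out$tsd_len <- elem$tsd_len[i]
    out$ltr_divergence <- elem$ltr_div[i]
    out
  })
  elements <- do.call(rbind, rows)
  elements <- elements[order(elements$start, elements$layer), , drop = FALSE]
  rownames(elements) <- NULL
  list(elements = elements, pieces = pieces)
}

#' Emit exact alignments of a simulation as a `.out` table
#'
#' Stands in for running an external aligner: every planted part piece
#' becomes one record with exact genome and consensus coordinates; the
#' divergence column is the realised per-copy mismatch proportion and
#' the score 10x the aligned length.  With `noise > 0` records are
#' randomly split into abutting sub-records (never shorter than 120
#' bp) to exercise defragmentation.
#'
#' @param sim An `ltr_simulation` from [simulate_genome()].
#' @param path Output `.out` path.
#' @param noise Per-record split probability; defaults to the value in
#'   the simulation's config at generation time (0 unless set).
#' @param seed Seed for the split choices.
#' @return The fragment data.frame that was written, invisibly.
#' @export
emit_alignments <- function(sim, path, noise = 0, seed = 1L) {
  set.seed(seed)
  pieces <- sim$truth$pieces
  lib <- sim$library
  key <- paste0(lib$info$family, "_", lib$info$part)
  fam_of <- function(eid) {
    sim$truth$elements$family[match(sprintf("elem_%04d", eid),
                                    sim$truth$elements$element_id)]
  }
  recs <- list()
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    fam <- fam_of(p$element)
    cons <- as.character(lib$seqs[[match(paste0(fam, "_", p$part), key)]])
    sub_recs <- list(p)
    len <- p$g_end - p$g_start + 1L
    if (noise > 0 && len >= 2L * SIM_MARGIN && stats::runif(1) < noise) {
      d <- sample(seq(SIM_MARGIN, len - SIM_MARGIN), 1L)
      left <- p; right <- p
      left$g_end <- p$g_start + d - 1L
      right$g_start <- p$g_start + d
      if (p$strand == "+") {
        left$c_end <- p$c_start + d - 1L
        right$c_start <- p$c_start + d
      } else {
        left$c_start <- p$c_end - d + 1L
        right$c_end <- p$c_end - d
      }
      sub_recs <- list(left, right)
    }
    for (sr in sub_recs) {
      gseq <- as.character(Biostrings::subseq(sim$genome[["chr1"]],
                                              sr$g_start, sr$g_end))
      if (sr$strand == "-") gseq <- revcomp_chr(gseq)
      cseq <- substr(cons, sr$c_start, sr$c_end)
      div <- 100 * seq_divergence(gseq, cseq)
      recs[[length(recs) + 1L]] <- data.frame(
        contig = "chr1", g_start = sr$g_start, g_end = sr$g_end,
        strand = sr$strand, family = fam, part = sr$part,
        c_start = sr$c_start, c_end = sr$c_end,
        divergence = round(div, 1), score = 10 * (sr$g_end - sr$g_start + 1L),
        stringsAsFactors = FALSE)
    }
  }
  frags <- if (length(recs)) do.call(rbind, recs) else empty_fragments()
  frags <- frags[order(frags$contig, frags$g_start, frags$g_end), ,
                 drop = FALSE]
  rownames(frags) <- NULL
  write_rm_out(frags, path)
  invisible(frags)
}

#' Simulate intra-element LTR pairs at a planted divergence
#'
#' Generates `n` LTR pairs: a random ancestral copy and a descendant
#' mutated at per-site substitution probability `divergence` (each
#' substitution drawn uniformly from the three alternative bases).
#' Used to check dating recovery.
#'
#' @param n Number of pairs.
#' @param length LTR length in bp.
#' @param divergence Per-site substitution probability.
#' @param seed Integer seed.
#' @return A list of `n` lists with `seq5` and `seq3`.
#' @export
simulate_ltr_pairs <- function(n, length = 500L, divergence = 0.02,
                               seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- random_seq(length)
    list(seq5 = s, seq3 = mutate_seq(s, divergence))
  })
}

#' Write a simulation to disk
#'
#' @param sim An `ltr_simulation`.
#' @param dir Output directory (created if missing): `genome.fa`,
#'   `library.fa`, `truth.gff3`, `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(sim$library$seqs, file.path(dir, "library.fa"))
  write_elements_gff3(sim$truth$elements, file.path(dir, "truth.gff3"))
  flat <- sim$truth$elements
  flat$pieces <- NULL
  utils::write.table(flat, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
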