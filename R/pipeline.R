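#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run.  The alignment-stage
#' defaults mirror the classic masking thresholds: maximum divergence
#' 20 percent (`-D`), minimum score 600 (`-C`), minimum fragment
#' length 100 bp (`-L`), minimum overlap 80 percent (`-s`, used by the
#' optional library dedup pre-step) and minimum identity 80 percent
#' (`-I`).
#'
#' @param library_path Consensus library FASTA (required).
#' @param out_path Precomputed alignment table in RepeatMasker `.out`
#'   format (default `"RM.out"`).
#' @param genome_path Genome FASTA; optional, needed only for K2P
#'   dating.
#' @param out_dir Output directory.
#' @param max_divergence,min_score,min_length,min_coverage,min_identity
#'   Fragment/library filters as above.
#' @param gap_tol,cons_tol Defragmentation tolerances, bp (see
#'   [merge_adjacent()]).
#' @param params A [link_params()] object.
#' @param dedupe Run [dedupe_library()] before alignment parsing
#'   (default `FALSE`).
#' @param table1_compat Fold `Others` into `Truncated` in the category
#'   rollup.
#' @param rates Substitution rates for dating.
#' @param threads Accepted for interface parity; the implementation is
#'   single-threaded and deterministic.
#' @return A list of class `run_config`.
#' @export
run_config <- function(library_path, out_path = "RM.out",
                       genome_path = NULL, out_dir = "ltrnest_out",
                       max_divergence = 20, min_score = 600,
                       min_length = 100, min_coverage = 80,
                       min_identity = 80, gap_tol = 100, cons_tol = 30,
                       params = link_params(), dedupe = FALSE,
                       table1_compat = FALSE,
                       rates = c(1.3e-8, 7e-9), threads = 6L) {
  if (missing(library_path)) stop("option -i (library FASTA) is required")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full annotation pipeline
#'
#' parse -> filter (divergence, score) -> resolve overlaps (length,
#' identity) -> merge adjacent fragments -> resolve nested layers ->
#' classify -> write per-layer `type.num.x` / `type.all.x` tables, a
#' consolidated GFF3, a dating TSV (when a genome is supplied) and a
#' stage-count log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (a `type_summary`),
#'   `elements`, `candidates`, `ages` (or `NULL`) and `log` (named
#'   stage counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lib <- read_ltr_library(config$library_path)
  if (isTRUE(config$dedupe)) {
    lib <- dedupe_library(lib, min_overlap = config$min_coverage,
                          min_identity = config$min_identity)
  }
  fragments <- read_rm_out(config$out_path)
  n_in <- nrow(fragments)
  check_fragments(fragments, lib)
  fragments <- fragments[fragments$divergence < config$max_divergence &
                           fragments$score >= config$min_score, ,
                         drop = FALSE]
  n_filtered <- nrow(fragments)
  fragments <- resolve_overlaps(fragments, min_len = config$min_length,
                                min_identity = config$min_identity)
  n_resolved <- nrow(fragments)
  candidates <- merge_adjacent(fragments, gap_tol = config$gap_tol,
                               cons_tol = config$cons_tol, lib = lib)
  chains <- resolve_layers(candidates, lib, config$params)
  elements <- build_elements(chains, candidates)
  summary <- summarize_elements(elements,
                                table1_compat = config$table1_compat)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_type_tables(summary, config$out_dir)
  write_elements_gff3(elements, file.path(config$out_dir, "elements.gff3"))
  ages <- NULL
  if (!is.null(config$genome_path)) {
    genome <- Biostrings::readDNAStringSet(config$genome_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ages <- date_elements(elements, candidates, genome,
                          rates = config$rates)
    num_cols <- vapply(ages, is.numeric, logical(1))
    ages_out <- ages
    ages_out[num_cols] <- lapply(ages_out[num_cols], signif, digits = 8)
    utils::write.table(ages_out, file.path(config$out_dir, "ages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- c(fragments_in = n_in, fragments_after_filters = n_filtered,
           fragments_after_overlap = n_resolved,
           candidates = nrow(candidates),
           chain_members = sum(lengths(lapply(chains, `[[`, "members"))),
           elements = nrow(elements), layers = summary$n_layers)
  writeLines(paste(names(log), log, sep = "\t"),
             file.path(config$out_dir, "run.log"))
  invisible(list(summary = summary, elements = elements,
                 candidates = candidates, ages = ages, log = log))
}
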