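#' Write annotated elements as GFF3
#'
#' One `repeat_region` feature per element, with one `repeat_fragment`
#' child per candidate piece (`Parent` = element ID).  A nested element
#' additionally carries a `Parent` attribute naming its host element,
#' and every element records `layer`, `structural_type` and `category`
#' attributes.
#'
#' @param elements Element data.frame from [build_elements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path) {
  if (!nrow(elements)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  el_gr <- GenomicRanges::GRanges(
    seqnames = elements$contig,
    ranges = IRanges::IRanges(elements$start, elements$end),
    strand = elements$strand)
  S4Vectors::mcols(el_gr) <- S4Vectors::DataFrame(
    source = "ltrnest",
    type = "repeat_region",
    ID = elements$element_id,
    Name = paste0(elements$family, ":", elements$type),
    Parent = ifelse(is.na(elements$host), NA_character_, elements$host),
    layer = elements$layer,
    structural_type = elements$type,
    category = elements$category)
  kids <- lapply(seq_len(nrow(elements)), function(k) {
    ps <- elements$pieces[[k]]
    gr <- GenomicRanges::GRanges(
      seqnames = elements$contig[k],
      ranges = IRanges::IRanges(ps$g_start, ps$g_end),
      strand = elements$strand[k])
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "ltrnest",
      type = "repeat_fragment",
      ID = sprintf("%s.p%d", elements$element_id[k], seq_len(nrow(ps))),
      Name = ps$part,
      Parent = elements$element_id[k],
      layer = elements$layer[k],
      structural_type = NA_character_,
      category = NA_character_)
    gr
  })
  gr <- c(el_gr, do.call(c, kids))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write per-layer structural type tables
#'
#' For every layer `x` present in the summary, writes two tab-separated
#' tables with header rows: `type.num.x` (copy number of each
#' structural type at that layer) and `type.all.x` (physical position
#' and content of every element at that layer: contig, span, strand,
#' family, type, category, host, and the member candidate spans).
#'
#' @param summary A `type_summary` from [summarize_elements()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_type_tables <- function(summary, out_dir) {
  stopifnot(inherits(summary, "type_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  elements <- summary$elements
  for (x in seq_len(summary$n_layers)) {
    num <- summary$per_layer_type[summary$per_layer_type$layer == x,
                                  c("type", "count"), drop = FALSE]
    p1 <- file.path(out_dir, paste0("type.num.", x))
    utils::write.table(num, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    el <- elements[elements$layer == x, , drop = FALSE]
    members <- vapply(el$pieces, function(ps) {
      paste(sprintf("%s:%d-%d", ps$part, ps$g_start, ps$g_end),
            collapse = ";")
    }, character(1))
    all_tab <- data.frame(contig = el$contig, start = el$start,
                          end = el$end, strand = el$strand,
                          family = el$family, type = el$type,
                          category = el$category,
                          element_id = el$element_id, host = el$host,
                          completeness = round(el$completeness, 4),
                          members = members, stringsAsFactors = FALSE)
    p2 <- file.path(out_dir, paste0("type.all.", x))
    utils::write.table(all_tab, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
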