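#' Structural type string of a chain
#'
#' Reads the chain members in element (5'->3') order — genome order on
#' the plus strand, reversed on the minus strand — and collapses
#' consecutive members of the same part (which, within a chain, are
#' always continuation pieces of one copy) into a single label.  Part
#' transitions emit a new label, yielding strings such as
#' `"LTR-IN-LTR"`, `"IN-LTR"` or `"LTR"`.
#'
#' @param chain A chain from [resolve_layers()] (list with `members`
#'   candidate ids and `strand`), or a plain integer vector of
#'   candidate ids (strand then taken from the candidates).
#' @param candidates The candidate data.frame the chain indexes into.
#' @return A single type string.
#' @export
type_string <- function(chain, candidates) {
  if (!is.list(chain)) chain <- list(members = chain, strand = NULL)
  m <- candidates[match(chain$members, candidates$id), , drop = FALSE]
  m <- m[order(m$g_start), , drop = FALSE]
  strand <- if (is.null(chain$strand)) m$strand[1] else chain$strand
  parts <- if (identical(strand, "-")) rev(m$part) else m$part
  paste(rle(parts)$values, collapse = "-")
}

#' Map a structural type string to its summary category
#'
#' * `LTR-IN-LTR` — Normal (full-length element).
#' * `LTR` — SoloLTR (unequal-recombination product).
#' * alternating strings with three or more LTR labels (e.g.
#'   `LTR-IN-LTR-IN-LTR`) — Complex (shared-LTR recombinants).
#' * every other alternating partial form (`LTR-IN`, `IN-LTR`, `IN`,
#'   `LTR-IN-LTR-IN`, `IN-LTR-IN-LTR`, `IN-LTR-IN`, ...) — Truncated.
#' * anything else (non-alternating labels) — Others.
#'
#' @param type Character vector of type strings.
#' @return Character vector over
#'   `{"Normal","Truncated","SoloLTR","Complex","Others"}`.
#' @export
categorize_type <- function(type) {
  if (any(!nzchar(type))) stop("empty type string")
  vapply(type, function(ts) {
    labs <- strsplit(ts, "-", fixed = TRUE)[[1]]
    if (!all(labs %in% c("LTR", "IN"))) return("Others")
    alternating <- all(labs[-1] != labs[-length(labs)])
    if (!alternating) return("Others")
    n_ltr <- sum(labs == "LTR")
    if (n_ltr >= 3L) return("Complex")
    if (ts == "LTR-IN-LTR") return("Normal")
    if (ts == "LTR") return("SoloLTR")
    "Truncated"
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble annotated elements from chains
#'
#' @param chains Chains from [resolve_layers()].
#' @param candidates Candidate data.frame the chains index into.
#' @return A data.frame with one row per element: `element_id`,
#'   `layer`, `contig`, `start`, `end`, `strand`, `family`, `type`,
#'   `category`, `nested` (layer >= 2), `host` (element_id or `NA`),
#'   `completeness` (mean member completeness) and a list-column
#'   `pieces` (per-member data.frame of candidate id, span and part,
#'   genome order).
#' @export
build_elements <- function(chains, candidates) {
  if (!length(chains)) return(empty_elements())
  ids <- sprintf("elem_%04d", seq_along(chains))
  rows <- lapply(seq_along(chains), function(k) {
    ch <- chains[[k]]
    m <- candidates[match(ch$members, candidates$id), , drop = FALSE]
    m <- m[order(m$g_start), , drop = FALSE]
    ts <- type_string(ch, candidates)
    out <- data.frame(
      element_id = ids[k],
      layer = ch$layer,
      contig = ch$contig,
      start = min(m$g_start),
      end = max(m$g_end),
      strand = ch$strand,
      family = m$family[1],
      type = ts,
      category = categorize_type(ts),
      nested = ch$layer >= 2L,
      host = if (is.na(ch$host)) NA_character_ else ids[ch$host],
      completeness = mean(m$completeness),
      stringsAsFactors = FALSE
    )
    out$pieces <- list(data.frame(
      candidate_id = m$id, g_start = m$g_start, g_end = m$g_end,
      part = m$part, stringsAsFactors = FALSE))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$layer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_elements <- function() {
  out <- data.frame(element_id = character(), layer = integer(),
                    contig = character(), start = integer(),
                    end = integer(), strand = character(),
                    family = character(), type = character(),
                    category = character(), nested = logical(),
                    host = character(), completeness = numeric(),
                    stringsAsFactors = FALSE)
  out$pieces <- list()
  out
}

#' Summarise elements per layer, type and category
#'
#' Builds the per-layer copy-number rollup.  `Nested` counts every
#' element of layer >= 2 and is an overlay, not a fifth structural
#' category: `Normal + Truncated + SoloLTR + Complex + Others = Total`.
#' With `table1_compat = TRUE` the `Others` count is folded into
#' `Truncated`, reproducing the headline four-category arithmetic.
#'
#' @param elements Element data.frame from [build_elements()].
#' @param table1_compat Fold `Others` into `Truncated` in the category
#'   rollup (default `FALSE`).
#' @return A list of class `type_summary`: `per_layer_type`
#'   (data.frame `layer`, `type`, `count`), `categories` (named
#'   vector), `nested`, `total`, `n_layers`, and the `elements` table
#'   itself.
#' @export
summarize_elements <- function(elements, table1_compat = FALSE) {
  cats <- c("Normal", "Truncated", "SoloLTR", "Complex", "Others")
  if (!nrow(elements)) {
    plt <- data.frame(layer = integer(), type = character(),
                      count = integer(), stringsAsFactors = FALSE)
    cat_counts <- stats::setNames(integer(length(cats)), cats)
    if (table1_compat) cat_counts <- cat_counts[cats != "Others"]
    return(structure(list(per_layer_type = plt, categories = cat_counts,
                          nested = 0L, total = 0L, n_layers = 0L,
                          elements = elements),
                     class = "type_summary"))
  }
  plt <- stats::aggregate(cbind(count = element_id) ~ layer + type,
                          data = elements, FUN = length)
  plt <- plt[order(plt$layer, plt$type), , drop = FALSE]
  rownames(plt) <- NULL
  cat_counts <- vapply(cats, function(cc) sum(elements$category == cc), 1L)
  if (table1_compat) {
    cat_counts["Truncated"] <- cat_counts["Truncated"] + cat_counts["Others"]
    cat_counts <- cat_counts[cats != "Others"]
  }
  structure(list(
    per_layer_type = plt,
    categories = cat_counts,
    nested = sum(elements$layer >= 2L),
    total = nrow(elements),
    n_layers = max(elements$layer),
    elements = elements
  ), class = "type_summary")
}

#' @export
print.type_summary <- function(x, ...) {
  cat("LTR retrotransposon structural summary\n")
  cat("  total elements:", x$total, "over", x$n_layers, "layer(s);",
      x$nested, "nested\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-10s %d\n", nm, x$categories[[nm]]))
  }
  invisible(x)
}
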