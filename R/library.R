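#' Read an LTR retrotransposon consensus library
#'
#' Reads a FASTA file in which every record is one part of a family
#' consensus: the long terminal repeat (`<family>_LTR`) or the internal
#' region between the two LTRs (`<family>_IN`).  The known consensus
#' lengths stored here drive fragment merging, the discriminating-tree
#' link rules, and completeness reporting.
#'
#' Family identifiers may not contain whitespace or `|` (they are used
#' verbatim in downstream tables), and every header must end in `_LTR`
#' or `_IN`.  Families present with only one of the two parts are kept,
#' with a warning: the linker simply never fires internal-region
#' branches for them.
#'
#' @param path Path to the library FASTA file.
#' @return An object of class `ltr_library`: a list with elements
#'   `info` (data.frame with columns `family`, `part`, `length`,
#'   `paired`) and `seqs` (a [Biostrings::DNAStringSet] named
#'   `<family>_<part>`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">Osr1_LTR", "ACGTACGT", ">Osr1_IN", "GGGGCCCC"), fa)
#' lib <- read_ltr_library(fa)
#' lib$info
#' @export
read_ltr_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  if (file.size(path) == 0L) {
    return(empty_library())
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) return(empty_library())
  headers <- names(seqs)
  bad <- grepl("[[:space:]]|\\|", headers)
  if (any(bad)) {
    stop("library header contains whitespace or '|': ",
         paste(sQuote(headers[bad]), collapse = ", "))
  }
  has_suffix <- grepl("_(LTR|IN)$", headers)
  if (any(!has_suffix)) {
    stop("library header lacks the '_LTR'/'_IN' suffix: ",
         paste(sQuote(headers[!has_suffix]), collapse = ", "))
  }
  part <- ifelse(grepl("_LTR$", headers), "LTR", "IN")
  family <- sub("_(LTR|IN)$", "", headers)
  if (any(family == "")) {
    stop("library header has an empty family name: ",
         paste(sQuote(headers[family == ""]), collapse = ", "))
  }
  dup <- duplicated(headers)
  if (any(dup)) {
    stop("duplicated library entry: ",
         paste(sQuote(unique(headers[dup])), collapse = ", "))
  }
  info <- data.frame(
    family = family,
    part = part,
    length = Biostrings::width(seqs),
    stringsAsFactors = FALSE
  )
  n_parts <- stats::aggregate(part ~ family, info,
                              FUN = function(p) length(unique(p)))
  paired_fams <- n_parts$family[n_parts$part == 2L]
  info$paired <- info$family %in% paired_fams
  unpaired <- unique(info$family[!info$paired])
  if (length(unpaired)) {
    warning("library families without a matching LTR/IN partner: ",
            paste(unpaired, collapse = ", "))
  }
  structure(list(info = info, seqs = seqs), class = "ltr_library")
}

empty_library <- function() {
  structure(list(
    info = data.frame(family = character(), part = character(),
                      length = integer(), paired = logical(),
                      stringsAsFactors = FALSE),
    seqs = Biostrings::DNAStringSet()
  ), class = "ltr_library")
}

#' @export
print.ltr_library <- function(x, ...) {
  cat("LTR consensus library:", nrow(x$info), "entries,",
      length(unique(x$info$family)), "families",
      sprintf("(%d paired)\n", sum(x$info$paired & x$info$part == "LTR")))
  invisible(x)
}

#' Consensus length lookup
#'
#' @param lib An `ltr_library`.
#' @param family Family identifier(s).
#' @param part `"LTR"` or `"IN"` (recycled against `family`).
#' @return Integer vector of consensus lengths; `NA` where the library
#'   has no such entry.
#' @export
lib_length <- function(lib, family, part) {
  key <- paste0(lib$info$family, "_", lib$info$part)
  idx <- match(paste0(family, "_", part), key)
  lib$info$length[idx]
}

#' Collapse near-redundant library entries
#'
#' Optional pre-step mirroring library merging by overlap length and
#' sequence similarity: a shorter entry is absorbed by a longer entry of
#' the same part when their global alignment shows at least
#' `min_identity` percent identity over at least `min_overlap` percent
#' of the shorter sequence.  Greedy, longest-first, deterministic.
#'
#' @param lib An `ltr_library`.
#' @param min_overlap Minimum aligned fraction of the shorter entry, in
#'   percent (default 80, the `-s` pipeline default).
#' @param min_identity Minimum percent identity over aligned columns
#'   (default 80, the `-I` pipeline default).
#' @return A reduced `ltr_library` containing the surviving entries.
#' @export
dedupe_library <- function(lib, min_overlap = 80, min_identity = 80) {
  info <- lib$info
  if (nrow(info) < 2L) return(lib)
  keep <- rep(TRUE, nrow(info))
  ord <- order(-info$length, info$family)   # longest first, then name
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (!keep[i]) next
    for (pos2 in seq_along(ord)) {
      if (pos2 <= pos) next
      j <- ord[pos2]
      if (!keep[j] || info$part[i] != info$part[j]) next
      al <- align_ltr_pair(as.character(lib$seqs[[i]]),
                           as.character(lib$seqs[[j]]))
      cols <- comparable_columns(al)
      n_cols <- sum(cols$ok)
      if (n_cols == 0L) next
      ident <- 100 * sum(cols$match[cols$ok]) / n_cols
      overlap <- 100 * n_cols / min(info$length[i], info$length[j])
      if (ident >= min_identity && overlap >= min_overlap) {
        keep[j] <- FALSE
      }
    }
  }
  structure(list(info = droplevels(info[keep, , drop = FALSE]),
                 seqs = lib$seqs[keep]),
            class = "ltr_library")
}
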