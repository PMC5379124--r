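#' Read a RepeatMasker `.out` alignment table
#'
#' Parses the classic `.out` layout (two header lines plus a blank line,
#' then one whitespace-separated record per hit) into a fragment table.
#' Both tightly aligned columns and loosely whitespace-separated records
#' are accepted; trailing ID and overlap-star columns are ignored.
#'
#' Minus-strand records (`C` in the orientation column, repeat
#' coordinates printed as `(left) end begin`) are normalised at parse
#' time: consensus coordinates are always reported in forward consensus
#' orientation with `c_start <= c_end` and `strand == "-"`, so
#' downstream code never branches on the raw `C` layout.
#'
#' The repeat name is split into `family` and `part` by its trailing
#' `_LTR`/`_IN` suffix; records whose repeat name carries no such suffix
#' are skipped with a warning.
#'
#' @param path Path to the `.out` file.
#' @return A data.frame of fragments with columns `contig`, `g_start`,
#'   `g_end` (1-based inclusive genome coordinates), `strand`
#'   (`"+"`/`"-"`), `family`, `part`, `c_start`, `c_end` (1-based
#'   inclusive forward consensus coordinates), `divergence` (percent)
#'   and `score`.
#' @export
read_rm_out <- function(path) {
  if (!file.exists(path)) stop(".out file not found: ", path)
  lines <- readLines(path)
  recs <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) return(NULL)
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    # header lines start with a non-numeric token ("SW", "score", ...)
    if (is.na(suppressWarnings(as.numeric(tok[1])))) return(NULL)
    if (length(tok) < 14L) {
      stop("unparseable .out record at line ", i, ": too few fields")
    }
    num <- function(k, what) {
      v <- suppressWarnings(as.numeric(gsub("[()]", "", tok[k])))
      if (is.na(v)) stop("unparseable .out record at line ", i,
                         ": bad ", what, " field ", sQuote(tok[k]))
      v
    }
    strand_tok <- tok[9]
    if (!strand_tok %in% c("+", "C")) {
      stop("unparseable .out record at line ", i,
           ": bad orientation field ", sQuote(strand_tok))
    }
    repname <- tok[10]
    if (!grepl("_(LTR|IN)$", repname)) {
      warning(".out line ", i, ": repeat name ", sQuote(repname),
              " has no _LTR/_IN suffix; record skipped")
      return(NULL)
    }
    if (strand_tok == "+") {
      c_start <- num(12, "repeat begin")
      c_end <- num(13, "repeat end")
      strand <- "+"
    } else {
      # C layout: (left) end begin
      c_end <- num(13, "repeat end")
      c_start <- num(14, "repeat begin")
      strand <- "-"
    }
    data.frame(
      contig = tok[5],
      g_start = as.integer(num(6, "query begin")),
      g_end = as.integer(num(7, "query end")),
      strand = strand,
      family = sub("_(LTR|IN)$", "", repname),
      part = ifelse(grepl("_LTR$", repname), "LTR", "IN"),
      c_start = as.integer(c_start),
      c_end = as.integer(c_end),
      divergence = num(2, "divergence"),
      score = num(1, "score"),
      stringsAsFactors = FALSE
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty_fragments())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_fragments <- function() {
  data.frame(contig = character(), g_start = integer(), g_end = integer(),
             strand = character(), family = character(), part = character(),
             c_start = integer(), c_end = integer(),
             divergence = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write fragments as a RepeatMasker `.out` table
#'
#' Emits the canonical `.out` layout (header, then one record per
#' fragment).  Minus-strand fragments are written in the `C` column
#' order `(left) end begin`, so [read_rm_out()] round-trips the table
#' field-by-field.  The `del`/`ins` columns and the `(left)` counts,
#' which the pipeline does not consume, are written as zeros.
#'
#' @param fragments Fragment data.frame (see [read_rm_out()] for the
#'   column contract).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rm_out <- function(fragments, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)   repeat    class/family  begin  end (left)  ID",
    ""
  )
  recs <- character(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    repname <- paste0(f$family, "_", f$part)
    if (f$strand == "+") {
      rep_cols <- c(f$c_start, f$c_end, "(0)")
      strand_tok <- "+"
    } else {
      rep_cols <- c("(0)", f$c_end, f$c_start)
      strand_tok <- "C"
    }
    recs[i] <- paste(
      format(f$score, scientific = FALSE), sprintf("%.1f", f$divergence),
      "0.0", "0.0", f$contig, f$g_start, f$g_end, "(0)", strand_tok,
      repname, "LTR/Unknown", rep_cols[1], rep_cols[2], rep_cols[3], i
    )
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Validate fragments against library consensus lengths
#'
#' Reports (does not clamp) fragments whose consensus coordinates
#' exceed the library length of their `(family, part)` consensus.
#'
#' @param fragments Fragment data.frame.
#' @param lib An `ltr_library`.
#' @return Invisibly, the integer indices of offending rows.  A warning
#'   is raised when any fragment overruns its consensus.
#' @export
check_fragments <- function(fragments, lib) {
  if (!nrow(fragments)) return(invisible(integer()))
  len <- lib_length(lib, fragments$family, fragments$part)
  bad <- which(!is.na(len) & fragments$c_end > len)
  if (length(bad)) {
    warning(length(bad), " fragment(s) overrun their consensus length ",
            "(rows ", paste(bad, collapse = ", "), ")")
  }
  invisible(bad)
}
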