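#' Globally align an intra-element LTR pair
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap penalty of -2 per base.  Insertion ages are estimated
#' from 5' and 3' LTRs of one element, which were identical at
#' insertion time, so a simple global alignment is appropriate.
#'
#' @param seq5,seq3 Nucleotide strings (5' and 3' LTR copies).
#' @return A list of class `ltr_alignment` with `aligned5`, `aligned3`
#'   (equal-length gapped strings) and `score`.
#' @export
align_ltr_pair <- function(seq5, seq3) {
  if (!nzchar(seq5) || !nzchar(seq3)) stop("empty LTR sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq5), Biostrings::DNAString(seq3),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  structure(list(
    aligned5 = as.character(Biostrings::alignedPattern(al)),
    aligned3 = as.character(Biostrings::alignedSubject(al)),
    score = Biostrings::score(al)
  ), class = "ltr_alignment")
}

# per-column bookkeeping: columns with a gap or ambiguity code on
# either side are excluded from distance counting (standard K2P
# practice)
comparable_columns <- function(al) {
  a <- strsplit(toupper(al$aligned5), "")[[1]]
  b <- strsplit(toupper(al$aligned3), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  purine <- c("A", "G")
  transition <- ok & a != b &
    ((a %in% purine) == (b %in% purine))
  transversion <- ok & a != b & !transition
  list(ok = ok, match = a == b, transition = transition,
       transversion = transversion)
}

#' Kimura two-parameter distance of an aligned LTR pair
#'
#' Over comparable columns (no gap, no ambiguity code on either
#' sequence) counts the proportion of transition-differing sites `P`
#' and transversion-differing sites `Q` and returns the K2P distance
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param al An `ltr_alignment` from [align_ltr_pair()], or a list
#'   with `aligned5`/`aligned3` gapped strings.
#' @return A list with `P`, `Q`, `K` and `compared_sites`.
#' @section Saturation: when `2P + Q >= 1` or `2Q >= 1` the logarithm
#'   is undefined and an error of class `ltrnest_saturated` is thrown;
#'   such elements are reported undated.
#' @export
k2p_distance <- function(al) {
  cols <- comparable_columns(al)
  n <- sum(cols$ok)
  if (n == 0L) stop("no comparable alignment columns")
  P <- sum(cols$transition) / n
  Q <- sum(cols$transversion) / n
  K <- k2p_from_pq(P, Q)
  list(P = P, Q = Q, K = K, compared_sites = n)
}

#' @rdname k2p_distance
#' @param P,Q Proportions of transition- and transversion-differing
#'   sites.
#' @export
k2p_from_pq <- function(P, Q) {
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop(structure(class = c("ltrnest_saturated", "error", "condition"),
                   list(message = sprintf(
                     "K2P distance saturated (P = %.4f, Q = %.4f)", P, Q),
                     call = sys.call(-1))))
  }
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

#' Insertion time from a K2P distance
#'
#' `T = K / (2 r)`: the two LTRs were identical at insertion and have
#' each accumulated substitutions at rate `r` since.
#'
#' @param K K2P distance, substitutions/site (>= 0).
#' @param r Substitution rate, substitutions/site/year; may be a
#'   vector to evaluate several clock calibrations at once.  Default
#'   reports both rates commonly applied to plant LTR dating,
#'   1.3e-8 and 7e-9.
#' @return Time(s) in years, named by rate.
#' @export
insertion_time <- function(K, r = c(1.3e-8, 7e-9)) {
  stopifnot(K >= 0)
  if (any(r <= 0)) stop("substitution rate must be positive")
  stats::setNames(K / (2 * r), paste0("T_r", formatC(r, format = "g")))
}

#' Date elements with two or more LTRs
#'
#' For each element whose type string carries at least two LTR labels,
#' extracts every LTR copy's genomic sequence (concatenating split
#' pieces in element orientation), globally aligns each adjacent pair
#' of copies (5'-mid and mid-3' for shared-LTR complex elements), and
#' reports P, Q, K and `T = K/2r` for both clock rates.  Saturated
#' pairs are reported with `NA` distances.
#'
#' @param elements Element data.frame from [build_elements()].
#' @param candidates Candidate data.frame the elements reference.
#' @param genome A named [Biostrings::DNAStringSet] of the genome.
#' @param rates Substitution rates in substitutions/site/year.
#' @return A data.frame with one row per dated LTR pair: `element_id`,
#'   `pair`, `P`, `Q`, `K`, `compared_sites` and one `T_*` column per
#'   rate (years).
#' @export
date_elements <- function(elements, candidates, genome,
                          rates = c(1.3e-8, 7e-9)) {
  rows <- list()
  for (k in seq_len(nrow(elements))) {
    el <- elements[k, ]
    labs <- strsplit(el$type, "-", fixed = TRUE)[[1]]
    if (sum(labs == "LTR") < 2L) next
    copies <- ltr_copy_seqs(el, candidates, genome)
    if (length(copies) < 2L) next
    for (p in seq_len(length(copies) - 1L)) {
      row <- data.frame(element_id = el$element_id,
                        pair = sprintf("%d-%d", p, p + 1L),
                        P = NA_real_, Q = NA_real_, K = NA_real_,
                        compared_sites = NA_integer_,
                        stringsAsFactors = FALSE)
      d <- tryCatch(
        k2p_distance(align_ltr_pair(copies[[p]], copies[[p + 1L]])),
        ltrnest_saturated = function(e) NULL)
      if (!is.null(d)) {
        row$P <- d$P; row$Q <- d$Q; row$K <- d$K
        row$compared_sites <- d$compared_sites
        tt <- insertion_time(d$K, rates)
        for (nm in names(tt)) row[[nm]] <- tt[[nm]]
      } else {
        for (nm in names(insertion_time(0, rates))) row[[nm]] <- NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(element_id = character(), pair = character(),
                      P = numeric(), Q = numeric(), K = numeric(),
                      compared_sites = integer(), stringsAsFactors = FALSE)
    for (nm in names(insertion_time(0, rates))) out[[nm]] <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic sequence of each LTR copy of one element, in element
# (5'->3') orientation; consecutive chain members of part LTR form one
# copy (continuation pieces of a split copy are concatenated)
ltr_copy_seqs <- function(el, candidates, genome) {
  pieces <- el$pieces[[1]]
  pieces <- pieces[order(pieces$g_start), , drop = FALSE]
  runs <- rle(pieces$part)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ltr_runs <- which(runs$values == "LTR")
  seqs <- lapply(ltr_runs, function(ri) {
    idx <- starts[ri]:ends[ri]
    s <- paste(vapply(idx, function(i) {
      as.character(Biostrings::subseq(genome[[el$contig]],
                                      pieces$g_start[i], pieces$g_end[i]))
    }, character(1)), collapse = "")
    if (el$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  })
  if (el$strand == "-") seqs <- rev(seqs)
  seqs
}
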