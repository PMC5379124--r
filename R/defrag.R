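#' Resolve overlapping alignment fragments
#'
#' Preprocesses raw hits by eliminating genomic overlaps: within each
#' contig, fragments are considered in decreasing score order (ties
#' broken by lower genome start) and kept intact; a lower-scoring
#' fragment overlapping already-kept intervals is trimmed to its largest
#' non-overlapping remainder, with consensus coordinates shrunk
#' proportionally to the genomic trim.  Fragments whose remainder is
#' shorter than `min_len`, or whose identity (100 - divergence) falls
#' below `min_identity`, are dropped.
#'
#' @param fragments Fragment data.frame (see [read_rm_out()]).
#' @param min_len Minimum genomic length in bp to keep a fragment
#'   (default 100, the `-L` pipeline default).
#' @param min_identity Minimum percent identity, i.e. 100 minus the
#'   divergence column (default 80, the `-I` pipeline default).
#' @return The surviving fragments, genome-sorted and pairwise
#'   non-overlapping within each contig.
#' @export
resolve_overlaps <- function(fragments, min_len = 100, min_identity = 80) {
  if (!nrow(fragments)) return(empty_fragments())
  f <- fragments[(100 - fragments$divergence) >= min_identity &
                   (fragments$g_end - fragments$g_start + 1L) >= min_len, ,
                 drop = FALSE]
  if (!nrow(f)) return(empty_fragments())
  out <- lapply(split(f, f$contig), resolve_overlaps_contig,
                min_len = min_len)
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$g_start, out$g_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_overlaps_contig <- function(f, min_len) {
  ord <- order(-f$score, f$g_start, f$g_end)
  kept <- list()
  kept_iv <- matrix(numeric(0), ncol = 2)   # occupied genome intervals
  for (i in ord) {
    s <- f$g_start[i]; e <- f$g_end[i]
    free <- free_subintervals(s, e, kept_iv)
    if (!nrow(free)) next
    lens <- free[, 2] - free[, 1] + 1
    best <- which.max(lens)                  # largest remainder survives
    if (lens[best] < min_len) next
    row <- f[i, , drop = FALSE]
    if (free[best, 1] != s || free[best, 2] != e) {
      row <- trim_fragment(row, free[best, 1], free[best, 2])
    }
    kept[[length(kept) + 1L]] <- row
    kept_iv <- rbind(kept_iv, c(row$g_start, row$g_end))
  }
  do.call(rbind, kept)
}

# maximal subintervals of [s, e] not covered by intervals `iv`
free_subintervals <- function(s, e, iv) {
  if (!nrow(iv)) return(matrix(c(s, e), ncol = 2))
  iv <- iv[iv[, 1] <= e & iv[, 2] >= s, , drop = FALSE]
  if (!nrow(iv)) return(matrix(c(s, e), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  res <- matrix(numeric(0), ncol = 2)
  cur <- s
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1] > cur) res <- rbind(res, c(cur, iv[k, 1] - 1))
    cur <- max(cur, iv[k, 2] + 1)
  }
  if (cur <= e) res <- rbind(res, c(cur, e))
  res
}

# shrink a fragment to genome window [gs, ge]; consensus coordinates are
# trimmed proportionally (orientation-aware), which is adequate because
# covered intervals only feed completeness and continuity checks that
# carry their own tolerance.
trim_fragment <- function(row, gs, ge) {
  glen <- row$g_end - row$g_start + 1
  clen <- row$c_end - row$c_start + 1
  lead <- (gs - row$g_start) / glen
  trail <- (row$g_end - ge) / glen
  cut_lead <- round(lead * clen)
  cut_trail <- round(trail * clen)
  if (row$strand == "+") {
    row$c_start <- as.integer(row$c_start + cut_lead)
    row$c_end <- as.integer(row$c_end - cut_trail)
  } else {
    # genome-leading bases sit at the consensus end on the minus strand
    row$c_end <- as.integer(row$c_end - cut_lead)
    row$c_start <- as.integer(row$c_start + cut_trail)
  }
  if (row$c_end < row$c_start) row$c_end <- row$c_start
  row$score <- row$score * (ge - gs + 1) / glen
  row$g_start <- as.integer(gs)
  row$g_end <- as.integer(ge)
  row
}

#' Merge adjacent fragments into candidate LTR/IN pieces
#'
#' Aligners usually split a complete LTR or internal-region copy into
#' several hits.  Consecutive overlap-resolved fragments with identical
#' `(contig, family, part, strand)`, a genomic gap of at most `gap_tol`,
#' and consensus continuation (the next fragment resumes within
#' `cons_tol` of where the previous one stopped, orientation-aware on
#' the minus strand) are fused into one candidate; all other fragments
#' become singleton candidates.
#'
#' @param fragments Overlap-resolved, genome-sorted fragments.
#' @param gap_tol Maximum genomic gap bridged by a merge, bp
#'   (default 100).
#' @param cons_tol Maximum consensus discontinuity tolerated, bp
#'   (default 30).
#' @param lib Optional `ltr_library`; when supplied, each candidate's
#'   `completeness` is covered length / consensus length, otherwise
#'   `NA`.
#' @return A data.frame of candidates, genome-sorted, with columns
#'   `id`, `contig`, `g_start`, `g_end`, `strand`, `family`, `part`,
#'   `score` (sum of member scores), `completeness`, and list-columns
#'   `covered` (two-column matrix of sorted, non-overlapping consensus
#'   intervals) and `members` (the source fragment rows, genome
#'   order).
#' @export
merge_adjacent <- function(fragments, gap_tol = 100, cons_tol = 30,
                           lib = NULL) {
  if (!nrow(fragments)) return(empty_candidates())
  f <- fragments[order(fragments$contig, fragments$g_start, fragments$g_end),
                 , drop = FALSE]
  rownames(f) <- NULL
  groups <- list()
  cur <- 1L                                  # indices of current run
  for (i in seq_len(nrow(f))[-1]) {
    prev <- cur[length(cur)]
    if (can_merge(f[prev, ], f[i, ], f[cur, , drop = FALSE],
                  gap_tol, cons_tol)) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
    }
  }
  groups[[length(groups) + 1L]] <- cur
  cands <- lapply(groups, function(idx) make_candidate(f[idx, , drop = FALSE], lib))
  out <- do.call(rbind, cands)
  out <- out[order(out$contig, out$g_start, out$g_end), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

can_merge <- function(prev, nxt, run, gap_tol, cons_tol) {
  if (prev$contig != nxt$contig || prev$family != nxt$family ||
      prev$part != nxt$part || prev$strand != nxt$strand) return(FALSE)
  gap <- nxt$g_start - prev$g_end - 1L
  if (gap < 0L || gap > gap_tol) return(FALSE)
  if (prev$strand == "+") {
    expected <- max(run$c_end) + 1L
    abs(nxt$c_start - expected) <= cons_tol
  } else {
    # later genome position = earlier consensus position on minus strand
    expected <- min(run$c_start) - 1L
    abs(nxt$c_end - expected) <= cons_tol
  }
}

make_candidate <- function(members, lib) {
  iv <- cbind(members$c_start, members$c_end)
  iv <- merge_intervals(iv)
  cov_len <- sum(iv[, 2] - iv[, 1] + 1)
  cons_len <- if (is.null(lib)) NA_integer_ else
    lib_length(lib, members$family[1], members$part[1])
  comp <- if (is.na(cons_len)) NA_real_ else min(1, cov_len / cons_len)
  out <- data.frame(
    id = NA_integer_,
    contig = members$contig[1],
    g_start = min(members$g_start),
    g_end = max(members$g_end),
    strand = members$strand[1],
    family = members$family[1],
    part = members$part[1],
    score = sum(members$score),
    completeness = comp,
    stringsAsFactors = FALSE
  )
  out$covered <- list(iv)
  out$members <- list(members)
  out
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  res <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(res)
    if (iv[k, 1] <= res[last, 2] + 1) {
      res[last, 2] <- max(res[last, 2], iv[k, 2])
    } else {
      res <- rbind(res, iv[k, , drop = FALSE])
    }
  }
  res
}

empty_candidates <- function() {
  out <- data.frame(id = integer(), contig = character(),
                    g_start = integer(), g_end = integer(),
                    strand = character(), family = character(),
                    part = character(), score = numeric(),
                    completeness = numeric(), stringsAsFactors = FALSE)
  out$covered <- list()
  out$members <- list()
  out
}
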