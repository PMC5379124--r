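#' Linker tolerances
#'
#' Tolerances used by the discriminating tree and the chain builder.
#'
#' * `cons_tol` — maximum consensus discontinuity for a continuation
#'   link (two pieces of one interrupted LTR or IN copy), bp.
#' * `end_tol` — how close an LTR/IN must reach its consensus end (and
#'   its partner must start to consensus position 1) for a part
#'   transition (LTR-IN or IN-LTR junction), bp.
#' * `g_direct` — maximum *unexplained* genomic gap between linked
#'   candidates, i.e. gap not occupied by other candidates, bp.
#'   Intervening candidates (putative insertions) do not count against
#'   this budget.
#' * `g_insert` — maximum total genomic span scanned for a continuation
#'   across inserted material, bp.  Bounds the lookahead so distant
#'   unrelated copies of one family are never fused.
#'
#' @param cons_tol,end_tol,g_direct,g_insert Non-negative tolerances in
#'   bp; `g_direct` must not exceed `g_insert`.
#' @return A list of class `link_params`.
#' @export
link_params <- function(cons_tol = 30, end_tol = 20,
                        g_direct = 200, g_insert = 20000) {
  stopifnot(cons_tol >= 0, end_tol >= 0, g_direct >= 0,
            g_direct <= g_insert)
  structure(list(cons_tol = cons_tol, end_tol = end_tol,
                 g_direct = g_direct, g_insert = g_insert),
            class = "link_params")
}

cand_cov_start <- function(cand) min(cand$covered[[1]][, 1])
cand_cov_end <- function(cand) max(cand$covered[[1]][, 2])

# genomic gap between candidates i < j not accounted for by candidates
# lying strictly between them
unexplained_gap <- function(ordered, i, j) {
  xi <- ordered[i, ]; yj <- ordered[j, ]
  total <- yj$g_start - xi$g_end - 1L
  if (total <= 0L) return(max(total, 0L))
  between <- ordered$g_start > xi$g_end & ordered$g_end < yj$g_start
  if (!any(between)) return(total)
  iv <- merge_intervals(cbind(ordered$g_start[between],
                              ordered$g_end[between]))
  iv[, 1] <- pmax(iv[, 1], xi$g_end + 1L)
  iv[, 2] <- pmin(iv[, 2], yj$g_start - 1L)
  total - sum(iv[, 2] - iv[, 1] + 1)
}

# is candidate z already claimed by a nearer partner?  A continuation
# across inserted material is only credible when no candidate lying
# between x and z is itself state-1 linked to z: a nested insertion
# splits its host, so the inserted material never links to the host's
# continuation, whereas the internal pieces of a distinct neighbouring
# element of the same family do link to each other.
claimed_between <- function(x, z, state1_fn) {
  for (w in seq(x, z)) {
    if (w == x || w == z) next
    if (state1_fn(w, z)) return(TRUE)
  }
  FALSE
}

# state-1 test for the ordered pair (i, j): are these two candidates
# adjacent pieces of one element copy (continuation) or an LTR/IN
# junction of one element (transition)?
state1 <- function(ordered, i, j, lib, params) {
  x <- ordered[i, ]; y <- ordered[j, ]
  if (x$strand != y$strand || x$family != y$family) return(FALSE)
  total_gap <- y$g_start - x$g_end - 1L
  if (total_gap > params$g_insert) return(FALSE)
  if (unexplained_gap(ordered, i, j) > params$g_direct) return(FALSE)
  # evaluate branch rules in element (5'->3') order: on the minus
  # strand the genome-later candidate is the element-earlier one
  if (x$strand == "+") { p <- x; q <- y } else { p <- y; q <- x }
  if (p$part == q$part) {
    # branches LTR-LTR / IN-IN: consensus continuation within one copy
    expected <- cand_cov_end(p) + 1L
    abs(cand_cov_start(q) - expected) <= params$cons_tol &&
      cand_cov_end(q) > cand_cov_end(p)
  } else {
    # branches LTR-IN / IN-LTR: p reaches its consensus end, q starts
    # at consensus position 1
    p_len <- lib_length(lib, p$family, p$part)
    if (is.na(p_len)) return(FALSE)
    cand_cov_end(p) >= p_len - params$end_tol &&
      cand_cov_start(q) <= 1L + params$end_tol
  }
}

#' Discriminating-tree link state of a candidate pair
#'
#' Assigns one of the three link states to the ordered pair `(x, y)`:
#'
#' * `1` (linked) — `x` and `y` are pieces of one element copy
#'   (consensus continuation within one LTR or IN copy) or meet at an
#'   LTR-IN / IN-LTR junction of one element, on the same strand, with
#'   an unexplained genomic gap of at most `g_direct`.
#' * `2` (inserted) — `y` itself is not linked to `x`, but some later
#'   candidate `z` within `g_insert` of `x` is, so everything between
#'   `x` and `z` is material inserted into the element being chained.
#'   `z` must not be claimed by a nearer partner: if any candidate
#'   between `x` and `z` is itself state-1 linked to `z`, the
#'   intervening material is a distinct neighbouring element rather
#'   than an insertion, and the lookahead keeps scanning.
#' * `0` (not linked) — neither of the above.
#'
#' @param x,y Row indices into `ordered`; `x` must precede `y` in
#'   genome order on the same contig.
#' @param ordered Genome-sorted candidate data.frame for one contig
#'   (from [merge_adjacent()]).
#' @param lib An `ltr_library` providing consensus lengths.
#' @param params A [link_params()] object.
#' @return Integer 0, 1 or 2.
#' @export
link_state <- function(x, y, ordered, lib, params = link_params()) {
  if (ordered$contig[x] != ordered$contig[y]) {
    stop("link_state called on candidates from different contigs")
  }
  if (!(ordered$g_start[x] <= ordered$g_start[y] && x != y)) {
    stop("x must precede y in genome order")
  }
  if (state1(ordered, x, y, lib, params)) return(1L)
  s1 <- function(i, j) state1(ordered, i, j, lib, params)
  for (z in seq_len(nrow(ordered))) {
    if (z <= y || ordered$contig[z] != ordered$contig[x]) next
    if (ordered$g_start[z] - ordered$g_end[x] - 1L > params$g_insert) break
    if (s1(x, z) && !claimed_between(x, z, s1)) return(2L)
  }
  0L
}

#' Build dynamic link lists from link states
#'
#' Greedy left-to-right scan over genome-sorted candidates of one
#' contig: a chain starts at the first unconsumed candidate; from the
#' chain end `x`, the next unconsumed candidate `y` extends the chain
#' on state 1; on state 2 the scan locates the nearest later candidate
#' `z` that is state-1 linked to `x`, sends every candidate between
#' `x` and `z` to the inserted pool, and continues the chain at `z`;
#' otherwise the chain closes and a new one starts at `y`.  Every
#' candidate ends up in exactly one chain or in the inserted pool.
#'
#' @param ordered Genome-sorted candidates of one contig.
#' @param state_fn Function `(x, y) -> 0/1/2` giving the link state of
#'   the ordered index pair; injectable so printed state matrices can
#'   be replayed directly.  Defaults to [link_state()] with `lib` and
#'   `params`.
#' @param lib,params Used only by the default `state_fn`.
#' @return A list with `chains` (list of integer index vectors, genome
#'   order) and `inserted` (integer indices sent to the inserted pool).
#' @export
build_chains <- function(ordered, state_fn = NULL, lib = NULL,
                         params = link_params()) {
  n <- nrow(ordered)
  if (is.null(state_fn)) {
    state_fn <- function(i, j) link_state(i, j, ordered, lib, params)
  }
  if (n == 0L) return(list(chains = list(), inserted = integer()))
  consumed <- logical(n)
  inserted <- logical(n)
  chains <- list()
  repeat {
    start <- which(!consumed)[1]
    if (is.na(start)) break
    chain <- start
    consumed[start] <- TRUE
    x <- start
    repeat {
      nxt <- which(!consumed & seq_len(n) > x)
      if (!length(nxt)) break
      y <- nxt[1]
      s <- state_fn(x, y)
      if (s == 1L) {
        chain <- c(chain, y); consumed[y] <- TRUE; x <- y
      } else if (s == 2L) {
        later <- nxt[nxt > y]
        z <- NA_integer_
        for (cand in later) {                 # nearest continuation wins
          if (state_fn(x, cand) != 1L) next
          if (claimed_between(x, cand,
                              function(i, j) state_fn(i, j) == 1L)) next
          z <- cand
          break
        }
        if (is.na(z)) break
        skipped <- nxt[nxt < z]
        inserted[skipped] <- TRUE
        consumed[skipped] <- TRUE
        chain <- c(chain, z); consumed[z] <- TRUE; x <- z
      } else break
    }
    chains[[length(chains) + 1L]] <- chain
  }
  list(chains = chains, inserted = which(inserted))
}

#' Resolve nested insertion layers
#'
#' Repeatedly applies [build_chains()]: layer 1 chains over all
#' candidates of a contig; the candidates marked inserted during layer
#' `k` form the pool chained at layer `k + 1`; recursion stops when a
#' pass marks nothing inserted.  Elements of layer `i` are interrupted
#' only by elements of layers `> i`.  Each chain of layer >= 2 records
#' the innermost lower-layer chain whose genomic span contains it.
#'
#' @param candidates Candidate data.frame from [merge_adjacent()] (any
#'   number of contigs; chains never cross contigs).
#' @param lib An `ltr_library`.
#' @param params A [link_params()] object.
#' @return A list of chains, each a list with `members` (candidate
#'   `id` values, genome order), `contig`, `strand`, `layer` and
#'   `host` (index into the returned list, or `NA` for layer 1).
#' @export
resolve_layers <- function(candidates, lib, params = link_params()) {
  if (!nrow(candidates)) return(list())
  all_chains <- list()
  for (ctg in unique(candidates$contig)) {
    ordered <- candidates[candidates$contig == ctg, , drop = FALSE]
    ordered <- ordered[order(ordered$g_start, ordered$g_end), , drop = FALSE]
    rownames(ordered) <- NULL
    pool <- seq_len(nrow(ordered))
    layer <- 1L
    while (length(pool)) {
      sub <- ordered[pool, , drop = FALSE]
      res <- build_chains(sub, lib = lib, params = params)
      for (ch in res$chains) {
        ids <- ordered$id[pool[ch]]
        all_chains[[length(all_chains) + 1L]] <- list(
          members = ids, contig = ctg,
          strand = sub$strand[ch[1]], layer = layer, host = NA_integer_)
      }
      pool <- pool[res$inserted]
      layer <- layer + 1L
    }
  }
  assign_hosts(all_chains, candidates)
}

assign_hosts <- function(chains, candidates) {
  if (!length(chains)) return(chains)
  span <- t(vapply(chains, function(ch) {
    m <- candidates[match(ch$members, candidates$id), , drop = FALSE]
    c(min(m$g_start), max(m$g_end))
  }, numeric(2)))
  for (k in seq_along(chains)) {
    if (chains[[k]]$layer < 2L) next
    lower <- which(vapply(chains, function(c2) c2$layer, 1L) < chains[[k]]$layer &
                     vapply(chains, function(c2) c2$contig, "") == chains[[k]]$contig)
    contains <- lower[span[lower, 1] <= span[k, 1] & span[lower, 2] >= span[k, 2]]
    if (length(contains)) {
      widths <- span[contains, 2] - span[contains, 1]
      chains[[k]]$host <- contains[which.min(widths)]
    }
  }
  chains
}
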