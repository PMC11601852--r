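# Run-length move tables: the (c, p, pi, xi) row structure that evaluates
# LF (forward and reverse) and phi / phi^-1 as table jumps, plus interval
# balancing and the moveStep / fastForward primitives.

## ---- step-count instrumentation -------------------------------------------

.bm_counters <- new.env(parent = emptyenv())

#' Step-count instrumentation
#'
#' The index counts the linear "walk" steps taken while scanning runs for a
#' character and the fast-forward steps taken inside every `move_step`.
#' These mirror the per-extension and per-phi step distributions that
#' motivate balancing the phi tables.
#'
#' @return `step_counters()` returns a list with `walk_steps`, `ff_steps`,
#'   `ff_calls`, `ff_max` (maximum fast-forward steps observed in a single
#'   call) and `extensions`.
#' @export
step_counters <- function() {
  as.list(.bm_counters)
}

#' @rdname step_counters
#' @export
reset_step_counters <- function() {
  .bm_counters$walk_steps <- 0
  .bm_counters$ff_steps <- 0
  .bm_counters$ff_calls <- 0
  .bm_counters$ff_max <- 0
  .bm_counters$extensions <- 0
  invisible(NULL)
}
reset_step_counters()

## ---- table representation --------------------------------------------------

# A move table is a list with integer vectors p, pi, xi covering rows
# 0..R (row R is the sentinel row with p = pi = n), an integer vector ch of
# run character codes (NA for the sentinel row, NULL for phi tables),
# the domain size n, a kind tag and a balanced flag. Row j lives at R
# index j + 1. Accessors mt_* are shared with the bit-packed representation
# so move_step & co. run unchanged on either.

new_move_table <- function(kind, n, p, pi, xi, ch = NULL, balanced = FALSE) {
  structure(list(kind = kind, n = as.integer(n),
                 p = as.integer(p), pi = as.integer(pi), xi = as.integer(xi),
                 ch = if (is.null(ch)) NULL else as.integer(ch),
                 balanced = balanced),
            class = "move_table")
}

# number of run rows (excluding the sentinel row)
mt_runs <- function(tab) UseMethod("mt_runs")
#' @export
mt_runs.move_table <- function(tab) length(tab$p) - 1L

mt_p <- function(tab, j) UseMethod("mt_p")
#' @export
mt_p.move_table <- function(tab, j) tab$p[j + 1L]
mt_pi <- function(tab, j) UseMethod("mt_pi")
#' @export
mt_pi.move_table <- function(tab, j) tab$pi[j + 1L]
mt_xi <- function(tab, j) UseMethod("mt_xi")
#' @export
mt_xi.move_table <- function(tab, j) tab$xi[j + 1L]
mt_ch <- function(tab, j) UseMethod("mt_ch")
#' @export
mt_ch.move_table <- function(tab, j) if (is.null(tab$ch)) NA_integer_ else tab$ch[j + 1L]

#' @export
print.move_table <- function(x, ...) {
  cat(sprintf("<move_table %s: n = %d, rows = %d%s%s>\n",
              x$kind, x$n, mt_runs(x),
              if (isTRUE(x$balanced)) " (balanced)" else "",
              if (is.null(x$ch)) "" else ", run characters"))
  invisible(x)
}

#' Dump a move table as a data.frame
#'
#' One row per table row in the layout `j, c, p, pi, xi`; the final row is
#' the sentinel row with `p = pi = n`.
#' @param tab a `move_table` or `packed_table`.
#' @return data.frame.
#' @export
inspect_table <- function(tab) {
  R <- mt_runs(tab)
  js <- 0:R
  data.frame(
    j = js,
    c = vapply(js, function(j) {
      cc <- mt_ch(tab, j)
      if (is.na(cc)) "" else BM_ALPHABET[cc + 1L]
    }, character(1)),
    p = vapply(js, function(j) mt_p(tab, j), integer(1)),
    pi = vapply(js, function(j) mt_pi(tab, j), integer(1)),
    xi = vapply(js, function(j) mt_xi(tab, j), integer(1)),
    stringsAsFactors = FALSE)
}

## ---- construction ----------------------------------------------------------

#' Maximal equal-character runs of a BWT
#'
#' @param bwt integer code vector (or character string) of BWT symbols.
#' @return list with `ch` (integer codes) and `start` (0-based start
#'   positions) of the maximal runs; `length(ch)` is the run count r.
#' @export
compute_runs <- function(bwt) {
  if (is.character(bwt))
    bwt <- bm_encode(strsplit(bwt, "", fixed = TRUE)[[1L]], "BWT")
  n <- length(bwt)
  if (n == 0L) stop("empty BWT", call. = FALSE)
  starts <- c(0L, which(bwt[-1L] != bwt[-n]))
  list(ch = bwt[starts + 1L], start = starts)
}

# xi = index of the row whose input interval contains each pi value.
compute_xi <- function(p_starts, pi_vals) {
  findInterval(pi_vals, p_starts) - 1L
}

finish_table <- function(kind, n, starts, pis, ch = NULL, balanced = FALSE) {
  R <- length(starts)
  p <- c(starts, n)
  pi <- c(pis, n)
  xi <- c(compute_xi(starts, pis), R)   # sentinel row points at itself
  new_move_table(kind, n, p, pi, xi,
                 ch = if (is.null(ch)) NULL else c(ch, NA_integer_),
                 balanced = balanced)
}

#' Build the LF move table
#'
#' One row per maximal BWT run: character `c`, input-interval start `p`,
#' output-interval start `pi = LF(p)` and the run index `xi` containing
#' `pi`, plus a sentinel bottom row with `p = n` that keeps fast-forwarding
#' in bounds. LF tables are left unbalanced: BWT runs of a pan-genome are
#' of comparable size, so splitting them buys nothing.
#'
#' @param ss a `bm_suffix`.
#' @param kind tag, `"LF"` or `"LFrev"`.
#' @return a `move_table`.
#' @export
build_lf_table <- function(ss, kind = "LF") {
  runs <- compute_runs(ss$bwt)
  lf <- lf_all(ss)
  finish_table(kind, ss$n, runs$start, lf[runs$start + 1L], ch = runs$ch)
}

#' Build the phi and inverse-phi move tables
#'
#' The phi input intervals start at the text positions `SA[i]` where `i`
#' starts a BWT run; within each interval phi maps consecutively, so a
#' run-indexed table evaluates it exactly like LF. The inverse table is
#' built from its own decomposition — input starts `SA[i]` for `i` a BWT
#' run *end* (equivalently the sorted phi output starts) — rather than by
#' inverting rows. Both are returned unbalanced; see [balance_table()].
#'
#' @param ss a `bm_suffix`.
#' @return list with elements `phi` and `phi_inv` (`move_table`s).
#' @export
build_phi_tables <- function(ss) {
  n <- ss$n
  run_starts <- c(0L, which(ss$bwt[-1L] != ss$bwt[-n]))
  run_ends <- c(run_starts[-1L] - 1L, n - 1L)
  phi <- phi_all(ss)
  phi_inv <- phi_inv_all(ss)

  ps <- sort(ss$sa[run_starts + 1L])
  phi_tab <- finish_table("phi", n, ps, phi[ps + 1L])

  qs <- sort(ss$sa[run_ends + 1L])
  phi_inv_tab <- finish_table("phi_inv", n, qs, phi_inv[qs + 1L])

  list(phi = phi_tab, phi_inv = phi_inv_tab)
}

## ---- balancing -------------------------------------------------------------

#' Balance a move table
#'
#' Repeatedly splits any input interval whose output interval contains more
#' than `d` later input-interval start points, cutting both the input and
#' the output interval at the `(d+1)`-th contained start, until no such
#' interval remains. Rows are processed left to right with a rescan after
#' every split, so the result is deterministic. The mapping computed by
#' [move_step()] is unchanged; afterwards every fast-forward takes at most
#' `d` steps, and the row count at most doubles.
#'
#' @param tab a `move_table`.
#' @param d split threshold, at least 2 (default 2).
#' @return a balanced `move_table`.
#' @export
balance_table <- function(tab, d = 2L) {
  stopifnot(inherits(tab, "move_table"))
  if (d < 2L) stop("balancing threshold d must be >= 2", call. = FALSE)
  n <- tab$n
  p <- tab$p
  pi <- tab$pi
  ch <- tab$ch
  repeat {
    R <- length(p) - 1L
    w <- p[-1L] - p[-(R + 1L)]
    # per row: input starts q with pi < q <= pi + w - 1 (contained in the
    # output interval beyond its left edge)
    lo <- findInterval(pi[seq_len(R)], p)
    hi <- findInterval(pi[seq_len(R)] + w - 1L, p)
    over <- which(hi - lo > d)
    if (length(over) == 0L) break
    j <- over[1L]                         # leftmost offending row
    q <- p[lo[j] + d + 1L]                # the (d+1)-th contained start
    newp <- p[j] + (q - pi[j])
    p <- append(p, newp, after = j)
    pi <- append(pi, q, after = j)
    if (!is.null(ch)) ch <- append(ch, ch[j], after = j)
  }
  R <- length(p) - 1L
  xi <- c(compute_xi(p[seq_len(R)], pi[seq_len(R)]), R)
  new_move_table(tab$kind, n, p, pi, xi, ch = ch, balanced = TRUE)
}

## ---- primitives ------------------------------------------------------------

#' Fast forward to the row containing a position
#'
#' Starting from candidate row `j` (which must start at or before `i`),
#' scans subsequent rows until the input interval containing `i` is found.
#' The scan length is counted in the step instrumentation.
#'
#' @param tab a `move_table` or `packed_table`.
#' @param i position in the table's domain, `0 <= i < n`.
#' @param j candidate row with `tab[j].p <= i`.
#' @return list with `row` (containing row index) and `steps`.
#' @export
fast_forward <- function(tab, i, j) {
  if (i >= tab$n) stop("fast_forward: position out of range", call. = FALSE)
  steps <- 0L
  while (mt_p(tab, j + 1L) <= i) {
    j <- j + 1L
    steps <- steps + 1L
  }
  .bm_counters$ff_calls <- .bm_counters$ff_calls + 1
  .bm_counters$ff_steps <- .bm_counters$ff_steps + steps
  if (steps > .bm_counters$ff_max) .bm_counters$ff_max <- steps
  list(row = j, steps = steps)
}

#' One move-table step
#'
#' Given a position `i` and the row `j` whose input interval contains it,
#' returns the mapped position `pi_j + (i - p_j)` together with the row
#' containing that mapped position (located by fast-forwarding from
#' `xi_j`). Evaluates LF, reverse LF, phi or phi^-1 depending on the
#' table.
#'
#' @param tab a `move_table` or `packed_table`.
#' @param i position with `tab[j].p <= i < tab[j+1].p`.
#' @param j row index containing `i`.
#' @return integer vector `c(pos, row)`.
#' @export
move_step <- function(tab, i, j) {
  if (i < mt_p(tab, j) || i >= mt_p(tab, j + 1L))
    stop(sprintf("move_step contract violated: row %d does not contain %d",
                 j, i), call. = FALSE)
  mapped <- mt_pi(tab, j) + (i - mt_p(tab, j))
  ff <- fast_forward(tab, mapped, mt_xi(tab, j))
  c(pos = mapped, row = ff$row)
}

#' Recover the run index containing a position by binary search
#'
#' Used when run indices have gone stale after extensions on the other
#' side: searches rows `[lo, hi]` (which must bracket `i`) for the row `j`
#' with `tab[j].p <= i < tab[j+1].p`.
#'
#' @param tab a `move_table` or `packed_table`.
#' @param i position.
#' @param lo,hi bracketing row indices.
#' @return row index.
#' @export
update_run_indices <- function(tab, i, lo, hi) {
  if (mt_p(tab, lo) > i || i >= mt_p(tab, hi + 1L))
    stop("update_run_indices: bracket [lo, hi] does not contain i",
         call. = FALSE)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (mt_p(tab, mid) <= i) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Whole-domain mapping of a table, computed by interval arithmetic
# (independently of move_step); used for construction-time verification.
table_mapping <- function(tab) {
  R <- length(tab$p) - 1L
  w <- tab$p[-1L] - tab$p[-(R + 1L)]
  out <- integer(tab$n)
  for (j in seq_len(R))
    if (w[j] > 0L)
      out[tab$p[j] + seq_len(w[j])] <- tab$pi[j] + 0:(w[j] - 1L)
  out
}
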