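# Synchronized bidirectional character extensions over the forward and
# reverse LF move tables, with single-walk memoization, lazy run-index
# maintenance across direction switches, and toehold updates.

#' Initial bidirectional state
#'
#' The state for the empty pattern: both SA intervals span `[0, n-1]`, all
#' four run indices are fresh, the matched length is 0 and the toehold is
#' the stored suffix-array sample of the first forward run (`SA[0]`).
#'
#' @param index a `bmove_index`.
#' @return an object of class `bistate` with fields `s`, `e`, `Rs`, `Re`,
#'   `srev`, `erev`, `Rsrev`, `Rerev`, `m`, `toehold`, `fwd_fresh`,
#'   `rev_fresh`.
#' @export
bistate_init <- function(index) {
  structure(list(
    s = 0L, e = index$n - 1L,
    Rs = 0L, Re = mt_runs(index$mlf) - 1L,
    srev = 0L, erev = index$n - 1L,
    Rsrev = 0L, Rerev = mt_runs(index$mlfrev) - 1L,
    m = 0L, toehold = index$samples$fwd_start[1L],
    fwd_fresh = TRUE, rev_fresh = TRUE), class = "bistate")
}

#' @export
print.bistate <- function(x, ...) {
  cat(sprintf(
    "<bistate: [%d,%d] runs (%s,%s) | rev [%d,%d] runs (%s,%s) | m=%d toehold=%d>\n",
    x$s, x$e, x$Rs, x$Re, x$srev, x$erev, x$Rsrev, x$Rerev, x$m, x$toehold))
  invisible(x)
}

state_width <- function(state) state$e - state$s + 1L

## ---- run walking -----------------------------------------------------------

#' Walk to the next / previous run of a character
#'
#' `walk_to_next_run` scans rows downward from `Rs` for the smallest
#' position `sc` in `[s, e]` lying in a run of character `c`; it returns
#' `NULL` when `c` does not occur in `BWT[s..e]`. `walk_to_previous_run`
#' scans upward from `Re` for the largest such position `ec`; its contract
#' requires that `c` is known to occur at or before `e` (normally
#' guaranteed by a prior successful `walk_to_next_run`). Run ends are not
#' stored, so the end of a run is read from the next row's start.
#'
#' @param tab an LF `move_table` (must carry run characters).
#' @param s,e interval bounds.
#' @param Rs,Re run indices containing `s` resp. `e`.
#' @param c character code (1..4) or single character.
#' @return list `(pos, row)`, or `NULL` (next-run variant only) when absent.
#' @export
walk_to_next_run <- function(tab, s, Rs, e, c) {
  c <- as_code(c)
  j <- Rs
  if (mt_ch(tab, j) == c) return(list(pos = s, row = j))
  repeat {
    j <- j + 1L
    .bm_counters$walk_steps <- .bm_counters$walk_steps + 1
    if (j > mt_runs(tab) - 1L || mt_p(tab, j) > e) return(NULL)
    if (mt_ch(tab, j) == c) return(list(pos = mt_p(tab, j), row = j))
  }
}

#' @rdname walk_to_next_run
#' @export
walk_to_previous_run <- function(tab, e, Re, c) {
  c <- as_code(c)
  j <- Re
  if (mt_ch(tab, j) == c) return(list(pos = e, row = j))
  repeat {
    j <- j - 1L
    .bm_counters$walk_steps <- .bm_counters$walk_steps + 1
    if (j < 0L)
      stop("walk_to_previous_run: character absent at or before e",
           call. = FALSE)
    if (mt_ch(tab, j) == c)
      return(list(pos = mt_p(tab, j + 1L) - 1L, row = j))
  }
}

as_code <- function(c) {
  if (is.character(c)) {
    code <- match(c, BM_ALPHABET) - 1L
    if (is.na(code)) stop(sprintf("unknown character '%s'", c), call. = FALSE)
    code
  } else {
    as.integer(c)
  }
}

#' Unidirectional backward extension on one LF table
#'
#' Extends the pattern represented by SA interval `[s, e]` to `cP`: walks
#' both boundaries to the smallest subinterval of `c`-runs, then applies
#' [move_step()] to each end.
#'
#' @inheritParams walk_to_next_run
#' @return list `(s, e, Rs, Re)` or `NULL` when `c` is absent in
#'   `BWT[s..e]`.
#' @export
add_char <- function(tab, s, e, Rs, Re, c) {
  c <- as_code(c)
  nxt <- walk_to_next_run(tab, s, Rs, e, c)
  if (is.null(nxt)) return(NULL)
  prv <- walk_to_previous_run(tab, e, Re, c)
  a <- move_step(tab, nxt$pos, nxt$row)
  b <- move_step(tab, prv$pos, prv$row)
  list(s = a[[1L]], e = b[[1L]], Rs = a[[2L]], Re = b[[2L]])
}

# Single memoized walk over the runs intersecting [s, e]: per-character
# occupancy counts plus first/last run of each character. This is the
# O(r) pass that replaces |Sigma| separate walks in the bidirectional
# extension.
walk_census <- function(tab, s, e, Rs) {
  cnt <- numeric(5L)
  first_run <- rep(NA_integer_, 5L)
  last_run <- rep(NA_integer_, 5L)
  j <- Rs
  R <- mt_runs(tab)
  repeat {
    if (j > R - 1L) break
    pj <- mt_p(tab, j)
    if (pj > e) break
    seg_s <- max(s, pj)
    seg_e <- min(e, mt_p(tab, j + 1L) - 1L)
    cc <- mt_ch(tab, j) + 1L
    cnt[cc] <- cnt[cc] + (seg_e - seg_s + 1L)
    if (is.na(first_run[cc])) first_run[cc] <- j
    last_run[cc] <- j
    j <- j + 1L
    .bm_counters$walk_steps <- .bm_counters$walk_steps + 1
  }
  list(cnt = cnt, first_run = first_run, last_run = last_run)
}

# Toehold update helper. Given the *pre-extension* state and the census of
# the relevant table's interval, returns the new toehold (text position of
# one occurrence of the extended pattern).
toehold_after <- function(index, state, side, c, census) {
  c <- as_code(c)
  if (side == "left") {
    tab <- index$mlf
    if (state$Rs == state$Re) {
      # whole interval inside one BWT run (necessarily of c): the previous
      # toehold's BWT character is c, so its occurrence extends in place.
      return(state$toehold - 1L)
    }
    jc <- census$first_run[c + 1L]
    sc <- max(state$s, mt_p(tab, jc))
    sample <- if (sc > mt_p(tab, jc)) {
      index$samples$fwd_end[jc + 1L]      # s mid-run: run end lies in [s,e]
    } else {
      index$samples$fwd_start[jc + 1L]
    }
    sample - 1L
  } else {
    tab <- index$mlfrev
    if (state$Rsrev == state$Rerev) {
      return(state$toehold)               # occurrence start unchanged by Pc
    }
    jc <- census$first_run[c + 1L]
    sc <- max(state$srev, mt_p(tab, jc))
    sample <- if (sc > mt_p(tab, jc)) {
      index$samples$rev_end[jc + 1L]
    } else {
      index$samples$rev_start[jc + 1L]
    }
    # reverse-text occurrence start of (Pc)^rev, mapped back to T via
    # j = n - 1 - i - |Q| with |Q| = m + 1
    index$n - 1L - (sample - 1L) - (state$m + 1L)
  }
}

#' Toehold update for a pending extension
#'
#' Computes the text position of one occurrence of the extended pattern
#' (`cP` for `side = "left"`, `Pc` for `side = "right"`) from the
#' *pre-extension* state. If the relevant SA interval lies inside a single
#' BWT run the previous toehold is reused (shifted by one for a left
#' extension); otherwise the stored suffix-array sample at a run boundary
#' of `c` inside the interval is taken. A contract error is raised when
#' the extension would be empty.
#'
#' @param index a `bmove_index`.
#' @param state a `bistate` (pre-extension).
#' @param side `"left"` or `"right"`.
#' @param c character or code.
#' @return text position (0-based).
#' @export
update_toehold <- function(index, state, side = c("left", "right"), c) {
  side <- match.arg(side)
  c <- as_code(c)
  tab <- if (side == "left") index$mlf else index$mlfrev
  cen <- if (side == "left") {
    walk_census(tab, state$s, state$e, state$Rs)
  } else {
    walk_census(tab, state$srev, state$erev, state$Rsrev)
  }
  if (cen$cnt[c + 1L] == 0)
    stop("update_toehold: extension with this character is empty",
         call. = FALSE)
  toehold_after(index, state, side, c, cen)
}

## ---- bidirectional extensions ----------------------------------------------

#' Bidirectional character extensions
#'
#' `add_char_left` extends the matched pattern `P` to `cP`; `add_char_right`
#' extends it to `Pc`. Both keep the forward and reverse SA intervals
#' synchronized: the interval on the extension's own table is updated with
#' [move_step()]; the companion interval shrinks to
#' `[s + x, s + x + y - 1]` where `x` counts interval positions carrying a
#' character smaller than `c` (sentinel included) and `y` is the new
#' width. A single memoized walk over the runs yields the subinterval
#' boundaries and all the counts at once, so an extension costs one pass
#' over at most `r` rows rather than one per alphabet character. The run
#' indices of the companion side are left stale (they still bracket the
#' shrunken interval) until [switch_direction()] refreshes them. The
#' toehold and matched length are updated on every successful extension.
#'
#' @param index a `bmove_index`.
#' @param state a `bistate`; `add_char_left` requires fresh forward run
#'   indices, `add_char_right` fresh reverse ones.
#' @param c character (`"A"`, `"C"`, `"G"`, `"T"`) or code 1..4.
#' @return the extended `bistate`, or `NULL` when `c` cannot extend the
#'   pattern.
#' @export
add_char_left <- function(index, state, c) {
  c <- as_code(c)
  if (!state$fwd_fresh)
    stop("add_char_left: forward run indices are stale; switch_direction first",
         call. = FALSE)
  tab <- index$mlf
  cen <- walk_census(tab, state$s, state$e, state$Rs)
  y <- cen$cnt[c + 1L]
  if (y == 0) return(NULL)
  .bm_counters$extensions <- .bm_counters$extensions + 1
  toehold <- toehold_after(index, state, "left", c, cen)
  jf <- cen$first_run[c + 1L]
  jl <- cen$last_run[c + 1L]
  sc <- max(state$s, mt_p(tab, jf))
  ec <- min(state$e, mt_p(tab, jl + 1L) - 1L)
  a <- move_step(tab, sc, jf)
  b <- move_step(tab, ec, jl)
  x <- sum(cen$cnt[seq_len(c)])          # characters strictly smaller than c
  state$s <- a[[1L]]; state$Rs <- a[[2L]]
  state$e <- b[[1L]]; state$Re <- b[[2L]]
  state$srev <- state$srev + as.integer(x)
  state$erev <- state$srev + as.integer(y) - 1L
  state$m <- state$m + 1L
  state$toehold <- toehold
  state$fwd_fresh <- TRUE
  state$rev_fresh <- FALSE
  state
}

#' @rdname add_char_left
#' @export
add_char_right <- function(index, state, c) {
  c <- as_code(c)
  if (!state$rev_fresh)
    stop("add_char_right: reverse run indices are stale; switch_direction first",
         call. = FALSE)
  tab <- index$mlfrev
  cen <- walk_census(tab, state$srev, state$erev, state$Rsrev)
  y <- cen$cnt[c + 1L]
  if (y == 0) return(NULL)
  .bm_counters$extensions <- .bm_counters$extensions + 1
  toehold <- toehold_after(index, state, "right", c, cen)
  jf <- cen$first_run[c + 1L]
  jl <- cen$last_run[c + 1L]
  sc <- max(state$srev, mt_p(tab, jf))
  ec <- min(state$erev, mt_p(tab, jl + 1L) - 1L)
  a <- move_step(tab, sc, jf)
  b <- move_step(tab, ec, jl)
  x <- sum(cen$cnt[seq_len(c)])
  state$srev <- a[[1L]]; state$Rsrev <- a[[2L]]
  state$erev <- b[[1L]]; state$Rerev <- b[[2L]]
  state$s <- state$s + as.integer(x)
  state$e <- state$s + as.integer(y) - 1L
  state$m <- state$m + 1L
  state$toehold <- toehold
  state$rev_fresh <- TRUE
  state$fwd_fresh <- FALSE
  state
}

#' Refresh stale run indices before switching search direction
#'
#' Extensions update run indices only on their own side; the other side's
#' indices go stale but keep bracketing the shrinking interval. When the
#' search changes direction, the stale side's indices are recovered by
#' binary search ([update_run_indices()]) within that bracket.
#'
#' @param index a `bmove_index`.
#' @param state a `bistate`.
#' @param to `"forward"` or `"reverse"`: the side whose indices must be
#'   fresh afterwards.
#' @return the updated `bistate` (idempotent when already fresh).
#' @export
switch_direction <- function(index, state, to = c("forward", "reverse")) {
  to <- match.arg(to)
  if (to == "forward" && !state$fwd_fresh) {
    state$Rs <- update_run_indices(index$mlf, state$s, state$Rs, state$Re)
    state$Re <- update_run_indices(index$mlf, state$e, state$Rs, state$Re)
    state$fwd_fresh <- TRUE
  } else if (to == "reverse" && !state$rev_fresh) {
    state$Rsrev <- update_run_indices(index$mlfrev, state$srev,
                                      state$Rsrev, state$Rerev)
    state$Rerev <- update_run_indices(index$mlfrev, state$erev,
                                      state$Rsrev, state$Rerev)
    state$rev_fresh <- TRUE
  }
  state
}
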