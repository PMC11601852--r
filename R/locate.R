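# Locating: map a final bidirectional state to every occurrence in the
# text using the toehold, the (balanced) phi / phi^-1 move tables and the
# sparse permuted LCP array.

#' Sparse PLCP lookup
#'
#' The permuted LCP array (`PLCP[i] = LCP[ISA[i]]`) is stored only at the
#' phi input-interval starts — exactly the irreducible positions where
#' PLCP may jump upward. Between samples PLCP decreases by one per
#' position, so `PLCP[i] = PLCP[p] - (i - p)` for the largest sample
#' position `p <= i`. Position 0 of the sample set is always present
#' (`SA[i]` for `i` the start of the first BWT run covers the minimum), so
#' the predecessor always exists.
#'
#' @param index a `bmove_index`.
#' @param i text position, 0-based.
#' @return the PLCP value at `i`.
#' @export
plcp <- function(index, i) {
  i <- check_pos(i, index$n)
  k <- findInterval(i, index$plcp$pos)
  index$plcp$val[k] - (i - index$plcp$pos[k])
}

#' phi and inverse-phi via move tables
#'
#' `phi(i)` is the suffix-array value preceding `i`'s entry in SA;
#' `phi_inv(i)` the succeeding one. Both are evaluated with one
#' [move_step()] on the corresponding balanced move table. The containing
#' row can be carried between consecutive calls (`row`); when unknown it
#' is recovered by binary search over all rows.
#'
#' @param index a `bmove_index` built with phi tables.
#' @param i text position.
#' @param row row index containing `i`, or `NULL` to look it up.
#' @return list `(pos, row)`: the mapped position and its containing row.
#' @export
phi_move <- function(index, i, row = NULL) {
  tab <- index$mphi
  if (is.null(tab))
    stop("index was built without phi tables; use locate_all_no_tables",
         call. = FALSE)
  i <- check_pos(i, index$n)
  if (is.null(row)) row <- update_run_indices(tab, i, 0L, mt_runs(tab) - 1L)
  st <- move_step(tab, i, row)
  list(pos = st[[1L]], row = st[[2L]])
}

#' @rdname phi_move
#' @export
phi_inv_move <- function(index, i, row = NULL) {
  tab <- index$mphi_inv
  if (is.null(tab))
    stop("index was built without phi tables; use locate_all_no_tables",
         call. = FALSE)
  i <- check_pos(i, index$n)
  if (is.null(row)) row <- update_run_indices(tab, i, 0L, mt_runs(tab) - 1L)
  st <- move_step(tab, i, row)
  list(pos = st[[1L]], row = st[[2L]])
}

locate_walk <- function(index, state, phi_fun, phi_inv_fun) {
  if (state$m <= 0L)
    stop("locate: state matches the empty pattern", call. = FALSE)
  width <- state_width(state)
  if (width <= 0L) stop("locate: empty state", call. = FALSE)
  out <- integer(width)
  out[1L] <- state$toehold
  k <- 1L
  # Backward: while the current value's PLCP is >= m we are above the
  # interval's first entry, so phi yields another in-interval SA value.
  cur <- state$toehold
  row <- NULL
  while (plcp(index, cur) >= state$m) {
    stp <- phi_fun(index, cur, row)
    cur <- stp$pos; row <- stp$row
    k <- k + 1L
    if (k > width)
      stop("locate: interval width and PLCP walk disagree", call. = FALSE)
    out[k] <- cur
  }
  # Forward: the remaining count is fixed by the interval width, so the
  # two walks together perform exactly e - s phi / phi^-1 operations.
  remaining <- width - k
  cur <- state$toehold
  row <- NULL
  for (q in seq_len(remaining)) {
    stp <- phi_inv_fun(index, cur, row)
    cur <- stp$pos; row <- stp$row
    k <- k + 1L
    out[k] <- cur
  }
  sort(out)
}

#' Locate every occurrence of a final state
#'
#' Reports the toehold, then walks backward with phi while the PLCP of the
#' current value stays at or above the matched length (each step yielding
#' the previous suffix-array entry), and forward with phi^-1 for the
#' remaining entries of the interval. The result is exactly
#' `{SA[i] : i in [s, e]}` — one start per occurrence of the matched
#' string — computed with exactly `e - s` phi / phi^-1 operations.
#'
#' `locate_all` uses the balanced phi move tables; `locate_all_no_tables`
#' evaluates phi / phi^-1 from the dense suffix-array structures retained
#' at construction when the index was built without phi tables (the
#' lower-memory configuration).
#'
#' @param index a `bmove_index`.
#' @param state a non-empty `bistate` with `m >= 1`.
#' @return sorted integer vector of occurrence start positions.
#' @export
locate_all <- function(index, state) {
  if (is.null(index$mphi))
    stop("index was built without phi tables; use locate_all_no_tables",
         call. = FALSE)
  locate_walk(index, state, phi_move, phi_inv_move)
}

#' @rdname locate_all
#' @export
locate_all_no_tables <- function(index, state) {
  fb <- index$fallback
  if (is.null(fb))
    stop("index retains no dense fallback (built with phi tables)",
         call. = FALSE)
  phi_f <- function(index, i, row) {
    r <- fb$isa[i + 1L]
    list(pos = if (r > 0L) fb$sa[r] else fb$sa[index$n], row = NULL)
  }
  phi_inv_f <- function(index, i, row) {
    r <- fb$isa[i + 1L]
    list(pos = if (r < index$n - 1L) fb$sa[r + 2L] else fb$sa[1L], row = NULL)
  }
  locate_walk(index, state, phi_f, phi_inv_f)
}
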