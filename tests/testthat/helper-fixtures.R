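# Shared fixtures and independent reference implementations for the test
# suite. Everything is generated in code; the small example text below is
# the one whose index structures are checked value-for-value.

EXAMPLE_TEXT <- "CTATGTCATATGTTGGTC$"

rand_text <- function(n) {
  paste0(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = ""), "$")
}

rand_pangenome_text <- function(base_length, copies, seed,
                                substitution_rate = 0.01,
                                indel_rate = 0.001) {
  frags <- synth_pangenome(base_length = base_length, copies = copies,
                           substitution_rate = substitution_rate,
                           indel_rate = indel_rate, seed = seed)
  concat_with_sentinel(frags)
}

# 1-based SA ranks of suffixes prefixed by the pattern (brute force).
sa_interval_oracle <- function(ss, pattern) {
  pc <- strtoi(chartr("$ACGT", "01234",
                      strsplit(toupper(pattern), "")[[1L]]))
  hit <- vapply(0:(ss$n - 1L), function(r) {
    sfx <- ss$codes[(ss$sa[r + 1L] + 1L):ss$n]
    length(sfx) >= length(pc) && all(sfx[seq_along(pc)] == pc)
  }, logical(1))
  which(hit)
}

# Full-domain mapping of a move table computed by iterating move_step over
# every (position, containing row) pair, tracking the row incrementally.
move_step_sweep <- function(tab) {
  n <- tab$n
  out <- integer(n)
  j <- 0L
  for (i in 0:(n - 1L)) {
    while (i >= bimove:::mt_p(tab, j + 1L)) j <- j + 1L
    out[i + 1L] <- move_step(tab, i, j)[[1L]]
  }
  out
}

# Naive |Sigma|-pass bidirectional left extension: x is accumulated from
# one add_char call per smaller character. Kept as the reference the
# memoized single-walk implementation must reproduce byte-identically.
naive_add_char_left <- function(index, state, c) {
  c <- bimove:::as_code(c)
  tab <- index$mlf
  res <- add_char(tab, state$s, state$e, state$Rs, state$Re, c)
  if (is.null(res)) return(NULL)
  x <- 0L
  for (a in 0:(c - 1L)) {
    ra <- add_char(tab, state$s, state$e, state$Rs, state$Re, a)
    if (!is.null(ra)) x <- x + (ra$e - ra$s + 1L)
  }
  toehold <- update_toehold(index, state, "left", c)
  y <- res$e - res$s + 1L
  state$s <- res$s; state$e <- res$e
  state$Rs <- res$Rs; state$Re <- res$Re
  state$srev <- state$srev + x
  state$erev <- state$srev + y - 1L
  state$m <- state$m + 1L
  state$toehold <- toehold
  state$fwd_fresh <- TRUE
  state$rev_fresh <- FALSE
  state
}

# Apply an interleaved extension sequence (characters tagged by side) with
# the needed direction switches; returns NULL if any extension is empty.
extend_sequence <- function(index, sides, chars) {
  st <- bistate_init(index)
  for (i in seq_along(sides)) {
    st <- if (sides[i] == "left") {
      add_char_left(index, switch_direction(index, st, "forward"), chars[i])
    } else {
      add_char_right(index, switch_direction(index, st, "reverse"), chars[i])
    }
    if (is.null(st)) return(NULL)
  }
  st
}

# Strand-tagged brute-force alignment of a read (both strands).
align_oracle <- function(text, read, k, metric) {
  fwd <- occurrences_oracle(text, read, k, metric)
  rc <- occurrences_oracle(text, revcomp(read), k, metric)
  if (nrow(rc) > 0L) rc$strand <- "-"
  out <- rbind(fwd, rc)
  out[order(out$strand, out$start), , drop = FALSE]
}

expect_same_occurrences <- function(got, expected) {
  rownames(got) <- NULL
  rownames(expected) <- NULL
  expect_identical(got[c("start", "length", "distance", "strand")],
                   expected[c("start", "length", "distance", "strand")])
}
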