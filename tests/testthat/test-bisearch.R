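example_index <- function(...) move_index(bm_text(EXAMPLE_TEXT), ...)

test_that("run walking finds the c-subinterval boundaries", {
  idx <- example_index()
  nxt <- walk_to_next_run(idx$mlf, 0L, 0L, 18L, "A")
  expect_identical(nxt, list(pos = 12L, row = 7L))
  # s already inside a run of c: zero walking
  expect_identical(walk_to_next_run(idx$mlf, 3L, 1L, 18L, "T"),
                   list(pos = 3L, row = 1L))
  # the single-row interval [6,6] holds only '$'
  expect_null(walk_to_next_run(idx$mlf, 6L, 2L, 6L, "A"))
  prv <- walk_to_previous_run(idx$mlf, 18L, 11L, "A")
  expect_identical(prv, list(pos = 17L, row = 10L))
  expect_identical(walk_to_previous_run(idx$mlf, 17L, 10L, "A"),
                   list(pos = 17L, row = 10L))
})

test_that("walking agrees with a position-by-position BWT scan", {
  set.seed(21)
  for (rep in 1:20) {
    txt <- rand_text(sample(5:150, 1))
    ss <- build_suffix_structures(txt)
    mlf <- build_lf_table(ss)
    s <- sample(0:(ss$n - 2L), 1)
    e <- sample(s:(ss$n - 1L), 1)
    Rs <- update_run_indices(mlf, s, 0L, bimove:::mt_runs(mlf) - 1L)
    Re <- update_run_indices(mlf, e, Rs, bimove:::mt_runs(mlf) - 1L)
    for (cc in 1:4) {
      hits <- which(ss$bwt[(s + 1L):(e + 1L)] == cc) + s - 1L
      nxt <- walk_to_next_run(mlf, s, Rs, e, cc)
      if (length(hits) == 0L) {
        expect_null(nxt)
      } else {
        expect_identical(nxt$pos, hits[1L])
        expect_identical(walk_to_previous_run(mlf, e, Re, cc)$pos,
                         hits[length(hits)])
      }
    }
  }
})

test_that("unidirectional add_char narrows to the pattern's SA interval", {
  idx <- example_index()
  res <- add_char(idx$mlf, 0L, 18L, 0L, 11L, "T")
  expect_identical(res[c("s", "e")], list(s = 11L, e = 18L))
  expect_null(add_char(idx$mlf, 6L, 6L, 2L, 2L, "A"))
  set.seed(31)
  for (rep in 1:15) {
    txt <- rand_text(sample(10:200, 1))
    ss <- build_suffix_structures(txt)
    mlf <- build_lf_table(ss)
    for (cc in 1:4) {
      res <- add_char(mlf, 0L, ss$n - 1L, 0L, bimove:::mt_runs(mlf) - 1L, cc)
      cnt <- sum(ss$bwt == cc)
      if (cnt == 0L) expect_null(res)
      else expect_identical(res$e - res$s + 1L, cnt)
    }
  }
})

test_that("five left extensions reach the printed state; switch recovers run indices", {
  idx <- example_index()
  st <- bistate_init(idx)
  for (c in rev(strsplit("TATGT", "")[[1L]]))
    st <- add_char_left(idx, st, c)
  expect_identical(st[c("s", "e", "Rs", "Re")],
                   list(s = 11L, e = 12L, Rs = 6L, Re = 7L))
  expect_identical(st[c("srev", "erev", "Rsrev", "Rerev")],
                   list(srev = 16L, erev = 17L, Rsrev = 0L, Rerev = 12L))
  expect_false(st$rev_fresh)
  st2 <- switch_direction(idx, st, "reverse")
  expect_identical(st2[c("Rsrev", "Rerev")], list(Rsrev = 10L, Rerev = 11L))
  expect_identical(switch_direction(idx, st2, "reverse"), st2)  # idempotent
  # extending to "TATGTT" narrows to the single occurrence
  st3 <- add_char_right(idx, st2, "T")
  expect_identical(st3$e - st3$s, 0L)
})

test_that("memoized extensions equal the naive per-character reference", {
  set.seed(41)
  for (rep in 1:25) {
    txt <- rand_text(sample(10:250, 1))
    idx <- move_index(bm_text(txt))
    st <- bistate_init(idx)
    for (step in 1:8) {
      cc <- sample(1:4, 1)
      mem <- add_char_left(idx, st, cc)
      ref <- naive_add_char_left(idx, st, cc)
      expect_identical(mem, ref)
      if (is.null(mem)) break
      st <- mem
      expect_identical(st$e - st$s, st$erev - st$srev)  # synchronization
    }
  }
})

test_that("any interleaving of extensions yields the substring's SA interval", {
  set.seed(51)
  for (rep in 1:30) {
    txt <- rand_text(sample(10:300, 1))
    idx <- move_index(bm_text(txt))
    ss <- build_suffix_structures(txt)
    n <- idx$n
    len <- sample(1:8, 1)
    from <- sample(0:(n - 1L - len), 1)
    sub <- substr(txt, from + 1L, from + len)
    split <- sample(0:len, 1)
    # left part prepended right-to-left, right part appended, random merge
    left_chars <- rev(strsplit(substr(sub, 1L, split), "")[[1L]])
    right_chars <- if (split < len)
      strsplit(substr(sub, split + 1L, len), "")[[1L]] else character(0)
    sides <- sample(c(rep("left", split), rep("right", len - split)))
    chars <- character(len)
    chars[sides == "left"] <- left_chars
    chars[sides == "right"] <- right_chars
    st <- extend_sequence(idx, sides, chars)
    expect_false(is.null(st))
    ranks <- sa_interval_oracle(ss, sub)
    expect_identical(st$s, min(ranks) - 1L)
    expect_identical(st$e, max(ranks) - 1L)
    # left-then-right equals right-then-left
    st_lr <- extend_sequence(idx,
                             c(rep("left", split), rep("right", len - split)),
                             c(left_chars, right_chars))
    st_rl <- extend_sequence(idx,
                             c(rep("right", len - split), rep("left", split)),
                             c(right_chars, left_chars))
    expect_identical(st_lr[c("s", "e", "srev", "erev", "m")],
                     st_rl[c("s", "e", "srev", "erev", "m")])
  }
})

test_that("toehold names a true occurrence after every extension and switch", {
  set.seed(61)
  for (rep in 1:30) {
    txt <- rand_text(sample(10:250, 1))
    idx <- move_index(bm_text(txt))
    ss <- build_suffix_structures(txt)
    tc <- bm_text(txt)$codes
    st <- bistate_init(idx)
    pat <- integer(0)
    for (step in 1:12) {
      side <- sample(c("left", "right"), 1)
      cc <- sample(1:4, 1)
      st2 <- if (side == "left")
        add_char_left(idx, switch_direction(idx, st, "forward"), cc)
      else
        add_char_right(idx, switch_direction(idx, st, "reverse"), cc)
      if (is.null(st2)) next
      st <- st2
      pat <- if (side == "left") c(cc, pat) else c(pat, cc)
      expect_identical(st$e - st$s, st$erev - st$srev)
      # toehold = SA[k] for some k in [s, e]
      expect_true(ss$isa[st$toehold + 1L] >= st$s &&
                  ss$isa[st$toehold + 1L] <= st$e)
      expect_identical(tc[st$toehold + seq_along(pat)], pat)
    }
  }
})

test_that("standalone update_toehold matches the toehold installed by extension", {
  set.seed(71)
  for (rep in 1:15) {
    txt <- rand_text(sample(20:200, 1))
    idx <- move_index(bm_text(txt))
    st <- bistate_init(idx)
    for (step in 1:6) {
      cc <- sample(1:4, 1)
      st_f <- switch_direction(idx, st, "forward")
      nxt <- add_char_left(idx, st_f, cc)
      if (is.null(nxt)) {
        expect_error(update_toehold(idx, st_f, "left", cc), "empty")
        break
      }
      expect_identical(update_toehold(idx, st_f, "left", cc), nxt$toehold)
      st <- nxt
    }
  }
})
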