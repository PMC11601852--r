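test_that("run computation matches the example BWT and degenerate inputs", {
  ss <- build_suffix_structures(EXAMPLE_TEXT)
  runs <- compute_runs(ss$bwt)
  expect_length(runs$ch, 12L)
  expect_identical(BM_ALPHABET[runs$ch[2L] + 1L], "T")  # run 1 = (T, 2)
  expect_identical(runs$start[2L], 2L)
  expect_identical(BM_ALPHABET[runs$ch[8L] + 1L], "A")  # run 7 = (A, 12)
  expect_identical(runs$start[8L], 12L)

  ss2 <- build_suffix_structures("AAAA$")
  expect_length(compute_runs(ss2$bwt)$ch, 2L)
  expect_length(compute_runs("$")$ch, 1L)
})

test_that("LF tables reproduce the printed rows including the sentinel row", {
  ss <- build_suffix_structures(EXAMPLE_TEXT)
  mlf <- build_lf_table(ss)
  tab <- inspect_table(mlf)
  expect_identical(tab[tab$j == 1L, c("c", "p", "pi", "xi")],
                   data.frame(c = "T", p = 2L, pi = 11L, xi = 6L,
                              row.names = 2L))
  expect_identical(tab$p[tab$j == 12L], 19L)           # sentinel row
  ssr <- build_suffix_structures(reverse_text(EXAMPLE_TEXT))
  tabr <- inspect_table(build_lf_table(ssr, "LFrev"))
  expect_identical(tabr[tabr$j == 1L, c("c", "p", "pi", "xi")],
                   data.frame(c = "T", p = 1L, pi = 11L, xi = 6L,
                              row.names = 2L))
})

test_that("phi tables derive from BWT run boundaries and match the example", {
  ss <- build_suffix_structures(EXAMPLE_TEXT)
  pt <- build_phi_tables(ss)
  expect_identical(pt$phi$p[1L], 0L)
  expect_identical(pt$phi$pi[1L], 6L)
  expect_identical(pt$phi$xi[1L], 4L)
  expect_identical(pt$phi_inv$pi[1L], 14L)
  expect_identical(pt$phi_inv$xi[1L], 10L)
  # defining property: every row's pi is the oracle value at p
  R <- bimove:::mt_runs(pt$phi)
  expect_identical(pt$phi$pi[seq_len(R)],
                   vapply(pt$phi$p[seq_len(R)],
                          function(p) phi_oracle(ss, p), integer(1)))
  expect_identical(pt$phi_inv$pi[seq_len(R)],
                   vapply(pt$phi_inv$p[seq_len(R)],
                          function(p) phi_inv_oracle(ss, p), integer(1)))
})

test_that("fast_forward lands on the containing row and counts steps", {
  mlf <- build_lf_table(build_suffix_structures(EXAMPLE_TEXT))
  ff <- fast_forward(mlf, 14L, 6L)
  expect_identical(ff$row, 8L)
  expect_identical(fast_forward(mlf, mlf$p[4L], 3L)$steps, 0L)
  expect_error(fast_forward(mlf, 19L, 0L), "out of range")
})

test_that("move_step maps by offset and rejects a wrong containing row", {
  ss <- build_suffix_structures(EXAMPLE_TEXT)
  mlf <- build_lf_table(ss)
  st <- move_step(mlf, 5L, 1L)
  expect_identical(st[[1L]], 14L)
  expect_identical(st[[2L]], 8L)
  pt <- build_phi_tables(ss)
  expect_identical(move_step(pt$phi, 0L, 0L)[[1L]], 6L)
  expect_error(move_step(mlf, 5L, 0L), "contract")
})

test_that("move tables tile the domain and reproduce the oracles", {
  set.seed(101)
  for (rep in 1:40) {
    txt <- if (rep %% 4 == 0)
      as.character(rand_pangenome_text(60, 3, seed = rep))
    else rand_text(sample(2:400, 1))
    ss <- build_suffix_structures(txt)
    mlf <- build_lf_table(ss)
    pt <- build_phi_tables(ss)
    tabs <- list(LF = mlf, phi = pt$phi, phi_inv = pt$phi_inv,
                 phi_b = balance_table(pt$phi),
                 phi_inv_b = balance_table(pt$phi_inv))
    oracles <- list(LF = lf_all(ss), phi = bimove:::phi_all(ss),
                    phi_inv = bimove:::phi_inv_all(ss),
                    phi_b = bimove:::phi_all(ss),
                    phi_inv_b = bimove:::phi_inv_all(ss))
    for (nm in names(tabs)) {
      tb <- tabs[[nm]]
      R <- bimove:::mt_runs(tb)
      expect_identical(tb$p[1L], 0L)
      expect_true(all(diff(tb$p) > 0L))
      expect_identical(tb$p[R + 1L], ss$n)
      # input and output intervals each tile [0, n-1]
      w <- diff(tb$p)
      expect_identical(sum(w), ss$n)
      expect_identical(sort(unlist(mapply(function(s, wd) s + seq_len(wd) - 1L,
                                          tb$pi[seq_len(R)], w,
                                          SIMPLIFY = FALSE))), 0:(ss$n - 1L))
      # xi genuinely contains pi
      expect_true(all(tb$p[tb$xi[seq_len(R)] + 1L] <= tb$pi[seq_len(R)] &
                      tb$pi[seq_len(R)] < tb$p[tb$xi[seq_len(R)] + 2L]))
      expect_identical(move_step_sweep(tb), oracles[[nm]])
    }
    # unbalanced LF tables keep maximal runs
    R <- bimove:::mt_runs(mlf)
    if (R > 1L)
      expect_true(all(mlf$ch[seq_len(R - 1L)] != mlf$ch[2:R]))
  }
})

test_that("balancing caps contained starts, preserves the map, at most doubles rows", {
  ss <- build_suffix_structures(EXAMPLE_TEXT)
  pt <- build_phi_tables(ss)
  for (d in c(2L, 3L)) {
    b <- balance_table(pt$phi, d)
    R <- bimove:::mt_runs(b)
    w <- diff(b$p)
    for (j in seq_len(R)) {
      cnt <- sum(b$p > b$pi[j] & b$p <= b$pi[j] + w[j] - 1L)
      expect_lte(cnt, d)
    }
    expect_identical(bimove:::table_mapping(b), bimove:::phi_all(ss))
  }
  # fixed point: balancing a balanced table changes nothing
  b2 <- balance_table(balance_table(pt$phi), 2L)
  expect_identical(b2$p, balance_table(pt$phi)$p)

  set.seed(77)
  for (rep in 1:60) {
    txt <- if (rep %% 3 == 0)
      as.character(rand_pangenome_text(80, 4, seed = rep))
    else rand_text(sample(2:300, 1))
    ss <- build_suffix_structures(txt)
    pt <- build_phi_tables(ss)
    for (tb in pt) {
      b <- balance_table(tb)
      expect_lte(length(b$p), 2L * length(tb$p))
      expect_identical(bimove:::table_mapping(b), bimove:::table_mapping(tb))
    }
  }
})

test_that("run-index recovery by binary search honours its bracket", {
  ssr <- build_suffix_structures(reverse_text(EXAMPLE_TEXT))
  mlfrev <- build_lf_table(ssr, "LFrev")
  expect_identical(update_run_indices(mlfrev, 16L, 0L, 12L), 10L)
  expect_identical(update_run_indices(mlfrev, 17L, 0L, 12L), 11L)
  expect_identical(update_run_indices(mlfrev, mlfrev$p[4L], 3L, 12L), 3L)
  expect_error(update_run_indices(mlfrev, 0L, 3L, 12L), "bracket")
})
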