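test_that("pigeonhole schemes have the stated shape and are lossless", {
  s0 <- pigeonhole_scheme(0)
  expect_identical(s0$parts, 1L)
  expect_identical(s0$searches[[1L]], list(pi = 0L, L = 0L, U = 0L))
  s1 <- pigeonhole_scheme(1)
  expect_identical(lapply(s1$searches, `[[`, "pi"), list(0:1, c(1L, 0L)))
  expect_identical(s1$searches[[1L]]$U, c(0L, 1L))
  for (k in 0:3) expect_true(validate_scheme(pigeonhole_scheme(k)))
})

test_that("scheme validation rejects disconnected, lossy and malformed schemes", {
  bad_pi <- structure(list(parts = 3L, k = 1L, searches = list(
    list(pi = c(0L, 2L, 1L), L = c(0L, 0L, 0L), U = c(1L, 1L, 1L)))),
    class = "search_scheme")
  expect_error(validate_scheme(bad_pi), "not connected")
  lossy <- structure(list(parts = 2L, k = 1L, searches = list(
    list(pi = 0:1, L = c(0L, 0L), U = c(0L, 1L)))),
    class = "search_scheme")
  expect_error(validate_scheme(lossy), "lossy")
  bad_bounds <- structure(list(parts = 2L, k = 1L, searches = list(
    list(pi = 0:1, L = c(1L, 0L), U = c(1L, 1L)))),
    class = "search_scheme")
  expect_error(validate_scheme(bad_bounds), "non-decreasing")
})

test_that("custom schemes load from JSON and drive the search", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"pi":[0,1],"L":[0,0],"U":[0,1]},',
    ' {"pi":[1,0],"L":[0,0],"U":[0,1]}]'), f)
  scheme <- read_search_scheme(f, 1L)
  expect_identical(scheme$parts, 2L)
  idx <- move_index(bm_text(EXAMPLE_TEXT))
  got <- run_search_scheme(idx, "TATGA", 1L, "hamming", scheme)
  expect_same_occurrences(got,
                          occurrences_oracle(EXAMPLE_TEXT, "TATGA", 1L,
                                             "hamming"))
})

test_that("uniform partition distributes the remainder leftmost", {
  expect_identical(partition_pattern("TATGTTGGT", 2L), c(5L, 4L))
  expect_identical(partition_pattern(10L, 2L), c(5L, 5L))
  expect_identical(partition_pattern(7L, 3L), c(3L, 2L, 2L))
  expect_error(partition_pattern(2L, 3L), "cannot be split")
})

test_that("the worked example searches find the printed occurrences", {
  idx <- move_index(bm_text(EXAMPLE_TEXT))
  exact <- run_search_scheme(idx, "TATGT", 0L, "hamming")
  expect_identical(exact$start, c(1L, 8L))
  one_mm <- run_search_scheme(idx, "TATGA", 1L, "hamming")
  expect_true(1L %in% one_mm$start)
  expect_identical(one_mm$distance[one_mm$start == 1L], 1L)
})

test_that("dedup keeps the minimum-distance, shortest occurrence per start", {
  raw <- data.frame(start = c(3L, 3L, 3L, 7L),
                    length = c(9L, 8L, 8L, 5L),
                    distance = c(2L, 1L, 1L, 0L),
                    strand = "+", stringsAsFactors = FALSE)
  got <- dedup_occurrences(raw, "edit")
  expect_identical(got$start, c(3L, 7L))
  expect_identical(got$distance, c(1L, 0L))
  expect_identical(got$length, c(8L, 5L))
  dup <- raw[c(1L, 1L), ]
  expect_identical(nrow(dedup_occurrences(dup, "hamming")), 1L)
})

test_that("align_read handles strands, invalid reads and absent patterns", {
  idx <- move_index(bm_text(EXAMPLE_TEXT))
  # a read that is the reverse complement of a substring maps to "-"
  sub <- "TATGTTGG"
  hits <- align_read(idx, revcomp(sub), 0L)
  expect_true(any(hits$strand == "-" & hits$start == 8L))
  expect_identical(nrow(align_read(idx, "ANCGT", 1L)), 0L)   # N -> unmapped
  expect_identical(nrow(align_read(idx, "AAAAAAAA", 0L)), 0L)
  # strand symmetry: aligning the reverse complement swaps labels only
  fwd <- align_read(idx, sub, 1L, "hamming")
  swp <- align_read(idx, revcomp(sub), 1L, "hamming")
  expect_identical(fwd$start[fwd$strand == "+"], swp$start[swp$strand == "-"])
  expect_identical(fwd$start[fwd$strand == "-"], swp$start[swp$strand == "+"])
})

test_that("search equals the exhaustive oracle on random texts and reads", {
  set.seed(131)
  for (rep in 1:10) {
    txt <- if (rep %% 2 == 0)
      as.character(rand_pangenome_text(150, 3, seed = rep, indel_rate = 0.005))
    else rand_text(sample(80:400, 1))
    idx <- move_index(bm_text(txt))
    reads <- synth_reads(bm_text(txt), count = 3L, length = 16L,
                         error_rate = 0.08, indels = (rep %% 2 == 0),
                         seed = rep)
    for (i in seq_len(nrow(reads))) {
      for (k in 0:2) for (metric in c("hamming", "edit")) {
        got <- align_read(idx, reads$seq[i], k, metric)
        expect_same_occurrences(got,
                                align_oracle(txt, reads$seq[i], k, metric))
      }
    }
  }
})

test_that("occurrence sets grow monotonically with the error budget", {
  set.seed(141)
  for (rep in 1:8) {
    txt <- rand_text(300)
    idx <- move_index(bm_text(txt))
    pat <- substr(txt, 30L, 45L)
    prev <- NULL
    for (k in 0:3) {
      cur <- run_search_scheme(idx, pat, k, "hamming")
      if (!is.null(prev)) expect_true(all(prev$start %in% cur$start))
      prev <- cur
    }
  }
})

test_that("direction switches per search stay below the piece count", {
  # pigeonhole search i needs one switch to the right pieces and one back
  for (k in 1:3) {
    scheme <- pigeonhole_scheme(k)
    for (srch in scheme$searches) {
      segs <- bimove:::search_segments(srch, partition_pattern(40L, scheme$parts))
      switches <- sum(segs$side[-1L] != segs$side[-length(segs$side)])
      expect_lte(switches, scheme$parts - 1L)
    }
  }
})

test_that("SAM output resolves fragments, strands and unmapped reads", {
  frags <- c(chrA = "ACGTACGTGGA", chrB = "TTGACGTACGA")
  idx <- move_index(frags)
  reads <- c(r1 = "ACGTACG", r2 = substr(revcomp(frags[["chrB"]]), 1, 8),
             r3 = "NNNNNNN")
  hits <- align_reads(idx, reads, k = 0L)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(idx, hits, reads, sam)
  lines <- readLines(sam)
  expect_identical(sum(startsWith(lines, "@SQ")), 2L)
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t")
  r1 <- fields[vapply(fields, `[[`, "", 1L) == "r1"]
  expect_true(any(vapply(r1, `[[`, "", 3L) == "chrA" &
                  vapply(r1, `[[`, "", 4L) == "1"))
  r2 <- fields[vapply(fields, `[[`, "", 1L) == "r2"]
  expect_true(all(vapply(r2, `[[`, "", 2L) == "16"))   # reverse strand
  r3 <- fields[vapply(fields, `[[`, "", 1L) == "r3"]
  expect_identical(vapply(r3, `[[`, "", 2L), "4")      # unmapped
  # occurrences spanning the fragment boundary are discarded
  spanning <- align_read(idx, paste0(substr(frags[[1]], 9, 11),
                                     substr(frags[[2]], 1, 3)), 0L)
  if (nrow(spanning) > 0L) {
    h2 <- align_reads(idx, c(sp = paste0(substr(frags[[1]], 9, 11),
                                         substr(frags[[2]], 1, 3))), k = 0L)
    sam2 <- withr::local_tempfile(fileext = ".sam")
    write_sam(idx, h2, c(sp = "GGATTG"), sam2)
    b2 <- readLines(sam2)
    b2 <- b2[!startsWith(b2, "@")]
    expect_true(all(vapply(strsplit(b2, "\t"), `[[`, "", 2L) %in%
                    c("4")))
  }
})
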