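# Text ingestion, suffix-structure construction, and the exhaustive
# reference computations ("oracles") that the compressed index is
# validated against.
#
# Conventions used throughout the package:
#   * all published positions/indices are 0-based (R vectors are accessed
#     with an explicit +1);
#   * SA intervals are closed [s, e]; text spans are half-open
#     [start, start + len);
#   * symbol order is $ < A < C < G < T with internal codes 0..4.

#' Symbol alphabet
#'
#' The indexed alphabet in lexicographic order. The sentinel `$` terminates
#' the concatenated text, occurs exactly once, and sorts before every
#' nucleotide. Internal integer codes are 0 (`$`) through 4 (`T`).
#' @export
BM_ALPHABET <- c("$", "A", "C", "G", "T")

bm_encode <- function(chars, context = "sequence") {
  codes <- match(chars, BM_ALPHABET) - 1L
  if (anyNA(codes)) {
    bad <- chars[which(is.na(codes))[1L]]
    stop(sprintf("invalid symbol '%s' in %s (alphabet is A,C,G,T,$)",
                 bad, context), call. = FALSE)
  }
  codes
}

bm_decode <- function(codes) paste(BM_ALPHABET[codes + 1L], collapse = "")

#' Construct a sentinel-terminated text
#'
#' Wraps a character string over `{A,C,G,T}` plus a single trailing `$`
#' into the internal integer-coded representation.
#'
#' @param x a single string ending in `$`, or an existing `bm_text`.
#' @param name label used in error messages.
#' @return an object of class `bm_text` with fields `codes` (integer codes
#'   0..4), `n` (length including the sentinel) and `name`.
#' @export
bm_text <- function(x, name = "text") {
  if (inherits(x, "bm_text")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L || chars[n] != "$")
    stop("text must be nonempty and end with the sentinel '$'", call. = FALSE)
  if (sum(chars == "$") != 1L)
    stop("text must contain exactly one sentinel '$'", call. = FALSE)
  codes <- bm_encode(chars, name)
  structure(list(codes = codes, n = n, name = name), class = "bm_text")
}

#' @export
print.bm_text <- function(x, ...) {
  cat(sprintf("<bm_text '%s': n = %d>\n", x$name, x$n))
  invisible(x)
}

#' @export
as.character.bm_text <- function(x, ...) bm_decode(x$codes)

#' Read reference sequences from a FASTA file
#'
#' Records are upper-cased and all `N` characters are removed; any symbol
#' outside `{A,C,G,T,N}` is rejected with an error naming the record and
#' the offending symbol.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return named character vector of fragments in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  nonempty <- which(nzchar(trimws(head_lines)))
  if (length(nonempty) == 0L)
    stop(sprintf("malformed FASTA '%s': file is empty", path), call. = FALSE)
  if (!startsWith(trimws(head_lines[nonempty[1L]]), ">"))
    stop(sprintf("malformed FASTA '%s': expected '>' header at line %d",
                 path, nonempty[1L]), call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  frags <- toupper(as.character(seqs))
  for (i in seq_along(frags)) {
    bad <- setdiff(unique(strsplit(frags[i], "", fixed = TRUE)[[1L]]),
                   c("A", "C", "G", "T", "N"))
    if (length(bad) > 0L)
      stop(sprintf("invalid symbol '%s' in record '%s'",
                   bad[1L], names(frags)[i]), call. = FALSE)
  }
  gsub("N", "", frags, fixed = TRUE)
}

#' Read query reads from a FASTQ (or FASTA) file
#'
#' Qualities are ignored. Reads may contain arbitrary symbols; reads with
#' characters outside `{A,C,G,T}` are reported as unmapped at alignment
#' time rather than rejected here.
#'
#' @param path FASTQ file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path, format = "fastq") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop(sprintf("malformed %s '%s': %s",
                                     toupper(format), path,
                                     conditionMessage(e)), call. = FALSE))
  toupper(as.character(seqs))
}

#' Concatenate fragments into one sentinel-terminated text
#'
#' Fragments (e.g. chromosomes or strains of a pan-genome) are joined in
#' order and a single `$` is appended. The fragment boundary table is kept
#' on the result so occurrences can later be resolved back to fragment
#' coordinates.
#'
#' @param fragments character vector, at least one nonempty element.
#' @param name label for the text.
#' @return a `bm_text`; `$fragments` holds a data.frame with columns
#'   `name`, `offset` (0-based start in the concatenation) and `length`.
#' @export
concat_with_sentinel <- function(fragments, name = "concat") {
  if (length(fragments) == 0L || sum(nchar(fragments)) == 0L)
    stop("need at least one nonempty fragment", call. = FALSE)
  fn <- names(fragments)
  if (is.null(fn)) fn <- sprintf("frag%d", seq_along(fragments))
  lens <- unname(nchar(fragments))
  txt <- bm_text(paste0(paste(fragments, collapse = ""), "$"), name = name)
  txt$fragments <- data.frame(
    name = unname(fn),
    offset = cumsum(c(0L, lens[-length(lens)])),
    length = lens,
    row.names = NULL,
    stringsAsFactors = FALSE)
  txt
}

#' Reverse a text, keeping the sentinel trailing
#'
#' Returns the reverse of `T[0..n-2]` followed by `$`.
#' @param text a `bm_text` or string.
#' @return a `bm_text`.
#' @export
reverse_text <- function(text) {
  text <- bm_text(text)
  n <- text$n
  codes <- c(rev(text$codes[seq_len(n - 1L)]), 0L)
  structure(list(codes = codes, n = n, name = paste0(text$name, "_rev")),
            class = "bm_text")
}

## ---- suffix structures ----------------------------------------------------

# Deterministic prefix-doubling suffix array (O(n log n)); radix order makes
# the result byte-identical across runs and platforms.
build_sa <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(0L)
  rk <- as.integer(codes)
  k <- 1L
  repeat {
    rk2 <- if (k < n) c(rk[(k + 1L):n], rep.int(-1L, k)) else rep.int(-1L, n)
    o <- order(rk, rk2, method = "radix")
    neq <- (rk[o][-1L] != rk[o][-n]) | (rk2[o][-1L] != rk2[o][-n])
    nr <- c(0L, cumsum(neq))
    rk[o] <- nr
    if (nr[n] == n - 1L) break
    k <- k * 2L
    if (k > 2L * n) stop("suffix ranking failed to converge")  # unreachable
  }
  sa <- integer(n)
  sa[rk + 1L] <- 0:(n - 1L)
  sa
}

# Kasai's algorithm; LCP[0] = 0 by convention.
build_lcp <- function(codes, sa, isa) {
  n <- length(codes)
  lcp <- integer(n)
  h <- 0L
  for (i in 0:(n - 1L)) {
    r <- isa[i + 1L]
    if (r > 0L) {
      j <- sa[r]                      # SA[r-1]
      while (i + h < n && j + h < n && codes[i + h + 1L] == codes[j + h + 1L])
        h <- h + 1L
      lcp[r + 1L] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Build suffix array, inverse, BWT and LCP for a text
#'
#' The suffix array is constructed by deterministic prefix doubling; the
#' BWT is read off as `T[(SA[i] + n - 1) mod n]` and the LCP array with
#' Kasai's algorithm. These dense structures drive index construction and
#' serve as the ground truth the run-length compressed tables are checked
#' against.
#'
#' @param text a `bm_text` or string ending in `$`.
#' @return an object of class `bm_suffix` with 0-based `sa`, `isa`, integer
#'   `bwt` codes, `lcp`, the text `codes` and `n`.
#' @export
build_suffix_structures <- function(text) {
  text <- bm_text(text)
  codes <- text$codes
  n <- text$n
  sa <- build_sa(codes)
  isa <- integer(n)
  isa[sa + 1L] <- 0:(n - 1L)
  bwt <- codes[((sa + n - 1L) %% n) + 1L]
  lcp <- build_lcp(codes, sa, isa)
  structure(list(sa = sa, isa = isa, bwt = bwt, lcp = lcp,
                 codes = codes, n = n),
            class = "bm_suffix")
}

#' @export
print.bm_suffix <- function(x, ...) {
  cat(sprintf("<bm_suffix: n = %d, BWT runs = %d>\n", x$n,
              sum(x$bwt[-1L] != x$bwt[-x$n]) + 1L))
  invisible(x)
}

## ---- oracles --------------------------------------------------------------

check_pos <- function(i, n) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 0 || i >= n)
    stop(sprintf("index %s out of range [0, %d)", format(i), n), call. = FALSE)
  as.integer(i)
}

#' LF oracle from dense suffix structures
#'
#' `LF(i) = ISA[(SA[i] + n - 1) mod n]`: maps BWT position `i` to the
#' position of the same text character in the first column.
#' @param ss a `bm_suffix`.
#' @param i SA index, 0-based.
#' @return SA index.
#' @export
lf_oracle <- function(ss, i) {
  i <- check_pos(i, ss$n)
  ss$isa[((ss$sa[i + 1L] + ss$n - 1L) %% ss$n) + 1L]
}

#' @rdname lf_oracle
#' @export
phi_oracle <- function(ss, i) {
  i <- check_pos(i, ss$n)
  r <- ss$isa[i + 1L]
  if (r > 0L) ss$sa[r] else ss$sa[ss$n]
}

#' @rdname lf_oracle
#' @export
phi_inv_oracle <- function(ss, i) {
  i <- check_pos(i, ss$n)
  r <- ss$isa[i + 1L]
  if (r < ss$n - 1L) ss$sa[r + 2L] else ss$sa[1L]
}

# Vectorized whole-domain variants used for construction and verification.
lf_all <- function(ss) ss$isa[((ss$sa + ss$n - 1L) %% ss$n) + 1L]

phi_all <- function(ss) {
  res <- integer(ss$n)
  res[ss$sa[-1L] + 1L] <- ss$sa[-ss$n]   # SA[ISA[i]-1] for ISA[i]>0
  res[ss$sa[1L] + 1L] <- ss$sa[ss$n]
  res
}

phi_inv_all <- function(ss) {
  res <- integer(ss$n)
  res[ss$sa[-ss$n] + 1L] <- ss$sa[-1L]
  res[ss$sa[ss$n] + 1L] <- ss$sa[1L]
  res
}

empty_occurrences <- function() {
  data.frame(start = integer(0), length = integer(0), distance = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# Semi-global edit-distance scan against the reversed text: one DP sweep
# yields, for every start position, the lexicographically best
# (distance, length) over all substrings beginning there. Cell values are
# coded dist * BIG + len so a single integer pmin realizes the
# lexicographic minimum; the in-row dependency (consuming a text character
# as an insertion) is folded into a cummin.
edit_scan <- function(tc, pc, k) {
  nt <- length(tc)
  m <- length(pc)
  BIG <- 1024L
  if (m + k >= BIG) stop("pattern too long for edit scan")
  rt <- rev(tc)
  rp <- rev(pc)
  step <- BIG + 1L
  jj <- 0:nt
  prev <- integer(nt + 1L)              # row 0: empty pattern, dist 0 len 0
  for (i in seq_len(m)) {
    diagc <- prev[seq_len(nt)] + ifelse(rp[i] == rt, 0L, BIG) + 1L
    V <- prev + BIG                     # pattern char deleted
    V[2L:(nt + 1L)] <- pmin.int(V[2L:(nt + 1L)], diagc)
    prev <- cummin(V - step * jj) + step * jj
  }
  dist <- prev %/% BIG
  len <- prev %% BIG
  keep <- which(dist <= k)
  keep <- keep[keep > 1L]               # drop the "no text" column
  if (length(keep) == 0L) return(empty_occurrences())
  data.frame(start = nt - (keep - 1L),
             length = len[keep],
             distance = dist[keep],
             strand = "+",
             stringsAsFactors = FALSE)
}

#' Exhaustive-scan occurrence oracle
#'
#' Brute-force enumeration of all occurrences of `pattern` in `text` within
#' distance `k`, used as the independent reference for the compressed
#' index. Hamming: every start whose full-length window has at most `k`
#' mismatches. Edit: for every start, the best (distance, then length)
#' substring beginning there with edit distance at most `k` — the same
#' reduction rule [dedup_occurrences()] applies to the index output, so set
#' equality between the two is well defined.
#'
#' @param text `bm_text` or string.
#' @param pattern string over `{A,C,G,T}`.
#' @param k maximum distance.
#' @param metric `"hamming"` or `"edit"`.
#' @return occurrence data.frame (`start`, `length`, `distance`, `strand`),
#'   strand fixed to `"+"`.
#' @export
occurrences_oracle <- function(text, pattern, k = 0L,
                               metric = c("hamming", "edit")) {
  text <- bm_text(text)
  metric <- match.arg(metric)
  pc <- bm_encode(strsplit(toupper(pattern), "", fixed = TRUE)[[1L]],
                  "pattern")
  if (any(pc == 0L)) stop("pattern may not contain the sentinel", call. = FALSE)
  m <- length(pc)
  tl <- text$n - 1L                     # exclude the sentinel
  if (metric == "hamming") {
    if (m > tl) return(empty_occurrences())
    starts <- 0:(tl - m)
    mm <- integer(length(starts))
    for (q in seq_len(m))
      mm <- mm + (text$codes[starts + q] != pc[q])
    keep <- mm <= k
    if (!any(keep)) return(empty_occurrences())
    occ <- data.frame(start = starts[keep], length = m,
                      distance = mm[keep], strand = "+",
                      stringsAsFactors = FALSE)
  } else {
    occ <- edit_scan(text$codes[seq_len(tl)], pc, k)
  }
  dedup_occurrences(occ, metric)
}

#' Reverse complement
#' @param x string over `{A,C,G,T,N}`.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
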