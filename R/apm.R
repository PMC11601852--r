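# Lossless approximate pattern matching: search schemes executed over the
# bidirectional index, Hamming and edit distance, strand handling,
# occurrence reporting and SAM output.
#
# A search scheme is a set of searches (pi, L, U): pi orders the pattern
# pieces, L and U give cumulative lower/upper error bounds after each
# processed piece. Together the searches cover every distribution of up
# to K errors over the pieces, so pooling their results yields every
# occurrence within distance K (losslessness).

#' Pigeonhole search scheme
#'
#' Splits the pattern into `k + 1` pieces and generates one search per
#' piece: search `i` anchors piece `i` error-free, then extends to the
#' higher pieces and finally the lower ones, allowing up to `k` errors.
#' If the pattern matches with at most `k` errors, at least one piece is
#' error-free, so every error distribution is covered.
#'
#' @param k maximum number of errors (>= 0).
#' @return a `search_scheme`: list with `parts`, `k` and `searches`, each
#'   search a list `(pi, L, U)` with 0-based piece order.
#' @export
pigeonhole_scheme <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  parts <- k + 1L
  searches <- lapply(0:k, function(i) {
    ord <- c(i:k, if (i > 0L) (i - 1L):0L else integer(0))
    list(pi = ord,
         L = rep(0L, parts),
         U = c(0L, rep(k, parts - 1L)))
  })
  structure(list(parts = parts, k = k, searches = searches),
            class = "search_scheme")
}

#' Validate a search scheme
#'
#' Checks connectivity of every piece order (each prefix of `pi` covers a
#' contiguous range), monotone non-decreasing `L` and `U` with `L <= U`,
#' and — exhaustively, for the scheme's `k` — losslessness: every error
#' distribution over the pieces summing to at most `k` must satisfy the
#' cumulative bounds of at least one search.
#'
#' @param scheme a `search_scheme`.
#' @param k maximum error count the scheme must cover (default `scheme$k`).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_scheme <- function(scheme, k = scheme$k) {
  parts <- scheme$parts
  for (srch in scheme$searches) {
    ord <- srch$pi
    if (length(ord) != parts || !setequal(ord, 0:(parts - 1L)))
      stop("search order pi must be a permutation of the pieces", call. = FALSE)
    for (t in seq_along(ord)) {
      pref <- ord[seq_len(t)]
      if (max(pref) - min(pref) + 1L != t)
        stop("search order pi is not connected", call. = FALSE)
    }
    if (length(srch$L) != parts || length(srch$U) != parts)
      stop("L and U must have one bound per piece", call. = FALSE)
    if (is.unsorted(srch$L) || is.unsorted(srch$U) || any(srch$L > srch$U))
      stop("L and U must be non-decreasing with L <= U", call. = FALSE)
  }
  # exhaustive coverage of all error distributions with sum <= k
  dists <- as.matrix(do.call(expand.grid, rep(list(0:k), parts)))
  dists <- dists[rowSums(dists) <= k, , drop = FALSE]
  for (r in seq_len(nrow(dists))) {
    e <- dists[r, ]
    covered <- any(vapply(scheme$searches, function(srch) {
      cum <- cumsum(e[srch$pi + 1L])
      all(cum >= srch$L) && all(cum <= srch$U)
    }, logical(1)))
    if (!covered)
      stop(sprintf("scheme is lossy: error distribution (%s) uncovered",
                   paste(e, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a search scheme from a JSON file
#'
#' The file holds an array of searches, each an object with integer arrays
#' `pi` (0-based piece order), `L` and `U`. The scheme is validated for
#' the requested `k` before use.
#'
#' @param path JSON file.
#' @param k the error budget the scheme must cover.
#' @return a `search_scheme`.
#' @export
read_search_scheme <- function(path, k) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  searches <- lapply(raw, function(s)
    list(pi = as.integer(s$pi), L = as.integer(s$L), U = as.integer(s$U)))
  parts <- length(searches[[1L]]$pi)
  scheme <- structure(list(parts = parts, k = as.integer(k),
                           searches = searches), class = "search_scheme")
  validate_scheme(scheme, k)
  scheme
}

#' Uniform pattern partition
#'
#' Splits a pattern of length `m` into `parts` contiguous pieces of near
#' equal size; any remainder is distributed to the leftmost pieces.
#'
#' @param m pattern length (or a pattern string).
#' @param parts number of pieces (>= 1).
#' @return integer vector of piece lengths.
#' @export
partition_pattern <- function(m, parts) {
  if (is.character(m)) m <- nchar(m)
  m <- as.integer(m); parts <- as.integer(parts)
  if (parts < 1L) stop("parts must be >= 1", call. = FALSE)
  if (m < parts)
    stop(sprintf("pattern of length %d cannot be split into %d parts",
                 m, parts), call. = FALSE)
  base <- m %/% parts
  rem <- m %% parts
  base + as.integer(seq_len(parts) <= rem)
}

# Decompose one search into processing segments. The first piece is
# matched leftward starting at its right edge (the anchor); later pieces
# extend left of the current span or right of it depending on pi.
# Returns per-piece rows: side ("L"/"R"), q = cumulative pattern length
# consumed on that side after the piece, L/U bounds, plus the anchor
# position bpos.
search_segments <- function(srch, psizes) {
  parts <- length(psizes)
  cs <- cumsum(c(0L, psizes))             # piece i spans [cs[i+1], cs[i+2])
  f <- srch$pi[1L]
  bpos <- cs[f + 2L]
  side <- character(parts)
  q <- integer(parts)
  consumedL <- 0L
  consumedR <- 0L
  mx <- f; mn <- f
  for (t in seq_len(parts)) {
    p <- srch$pi[t]
    if (t == 1L || p < mn) {
      side[t] <- "L"
      consumedL <- consumedL + psizes[p + 1L]
      q[t] <- consumedL
    } else {
      side[t] <- "R"
      consumedR <- consumedR + psizes[p + 1L]
      q[t] <- consumedR
    }
    mx <- max(mx, p); mn <- min(mn, p)
  }
  list(piece = srch$pi, side = side, q = q,
       L = as.integer(srch$L), U = as.integer(srch$U), bpos = bpos)
}

## ---- Hamming search --------------------------------------------------------

# Flat per-character plan: for each extension step its side, the pattern
# character it aligns to, the piece bounds, and whether it closes a piece.
ham_plan <- function(pc, segs, psizes) {
  cs <- cumsum(c(0L, psizes))
  side <- character(0); code <- integer(0)
  U <- integer(0); L <- integer(0); closes <- logical(0)
  for (t in seq_along(segs$piece)) {
    p <- segs$piece[t]
    chars <- pc[(cs[p + 1L] + 1L):cs[p + 2L]]
    if (segs$side[t] == "L") chars <- rev(chars)
    len <- length(chars)
    side <- c(side, rep(segs$side[t], len))
    code <- c(code, chars)
    U <- c(U, rep(segs$U[t], len))
    L <- c(L, rep(segs$L[t], len))
    closes <- c(closes, c(rep(FALSE, len - 1L), TRUE))
  }
  list(side = side, code = code, U = U, L = L, closes = closes,
       nstep = length(code))
}

run_ham_search <- function(index, pc, srch, psizes, sink) {
  segs <- search_segments(srch, psizes)
  plan <- ham_plan(pc, segs, psizes)
  m <- length(pc)
  recurse <- function(state, idx, errs) {
    if (idx > plan$nstep) {
      starts <- locate_for(index, state)
      sink(data.frame(start = starts, length = m, distance = errs,
                      stringsAsFactors = FALSE))
      return(invisible(NULL))
    }
    state <- switch_direction(index, state,
                              if (plan$side[idx] == "L") "forward" else "reverse")
    for (cc in 1:4) {
      e2 <- errs + (cc != plan$code[idx])
      if (e2 > plan$U[idx]) next
      st2 <- if (plan$side[idx] == "L") add_char_left(index, state, cc)
             else add_char_right(index, state, cc)
      if (is.null(st2)) next
      if (plan$closes[idx] && e2 < plan$L[idx]) next
      recurse(st2, idx + 1L, e2)
    }
  }
  recurse(bistate_init(index), 1L, 0L)
}

## ---- edit-distance search --------------------------------------------------

# One banded DP row extension: row = D[i-1][0..L] against side pattern
# pat; returns D[i][0..L] after consuming text character c. Values
# saturate at k + 1, which realizes the +-k band.
dp_extend <- function(row, pat, c, k) {
  L <- length(pat)
  first <- row[1L] + 1L
  if (L == 0L) return(pmin.int(first, k + 1L))
  cand <- pmin.int(row[seq_len(L)] + (pat != c), row[2L:(L + 1L)] + 1L)
  val <- c(first, cand)
  idx <- 0:L
  pmin.int(cummin(val - idx) + idx, k + 1L)
}

run_edit_search <- function(index, pc, srch, psizes, k, sink) {
  segs <- search_segments(srch, psizes)
  bpos <- segs$bpos
  XL <- rev(pc[seq_len(bpos)])            # left side, consumed right-to-left
  XR <- if (bpos < length(pc)) pc[(bpos + 1L):length(pc)] else integer(0)
  parts <- length(segs$piece)

  recurse <- function(state, t, rowL, rowR, qdoneL, qdoneR) {
    side <- segs$side[t]
    qt <- segs$q[t]
    Ut <- segs$U[t]
    state <- switch_direction(index, state,
                              if (side == "L") "forward" else "reverse")
    arow <- if (side == "L") rowL else rowR
    d_other <- if (side == "L") rowR[qdoneR + 1L] else rowL[qdoneL + 1L]
    # branch 1: close this piece at the current text length
    dcut <- arow[qt + 1L] + d_other
    if (dcut <= Ut) {
      if (t == parts) {
        starts <- locate_for(index, state)
        sink(data.frame(start = starts, length = state$m, distance = dcut,
                        stringsAsFactors = FALSE))
      } else {
        if (side == "L") recurse(state, t + 1L, rowL, rowR, qt, qdoneR)
        else recurse(state, t + 1L, rowL, rowR, qdoneL, qt)
      }
    }
    # branch 2: extend the active side by one text character
    pat <- if (side == "L") XL else XR
    for (cc in 1:4) {
      st2 <- if (side == "L") add_char_left(index, state, cc)
             else add_char_right(index, state, cc)
      if (is.null(st2)) next
      nrow_ <- dp_extend(arow, pat, cc, k)
      if (min(nrow_) + d_other > Ut) next
      if (side == "L") recurse(st2, t, nrow_, rowR, qdoneL, qdoneR)
      else recurse(st2, t, rowL, nrow_, qdoneL, qdoneR)
    }
  }

  rowL0 <- pmin.int(0:length(XL), k + 1L)
  rowR0 <- pmin.int(0:length(XR), k + 1L)
  recurse(bistate_init(index), 1L, rowL0, rowR0, 0L, 0L)
}

## ---- top level -------------------------------------------------------------

#' Run a search scheme over the index
#'
#' Executes every search of the scheme against the bidirectional index:
#' pieces are matched in `pi` order via left/right character extensions
#' (switching direction as the order demands), errors are tracked per
#' extension for Hamming distance or with a banded dynamic-programming row
#' per side for edit distance, and every state that completes the final
#' piece within its bounds is located. Results from all searches are
#' pooled and reduced with [dedup_occurrences()]; the outcome equals the
#' exhaustive-scan oracle ([occurrences_oracle()]).
#'
#' @param index a `bmove_index`.
#' @param pattern string over `{A,C,G,T}`.
#' @param k maximum distance.
#' @param metric `"hamming"` or `"edit"`.
#' @param scheme a `search_scheme`, or `NULL` for the pigeonhole scheme.
#' @return occurrence data.frame (`start`, `length`, `distance`, `strand`),
#'   strand `"+"`.
#' @export
run_search_scheme <- function(index, pattern, k = 0L,
                              metric = c("hamming", "edit"), scheme = NULL) {
  metric <- match.arg(metric)
  k <- as.integer(k)
  pc <- bm_encode(strsplit(toupper(pattern), "", fixed = TRUE)[[1L]],
                  "pattern")
  if (any(pc == 0L)) stop("pattern may not contain the sentinel", call. = FALSE)
  if (is.null(scheme)) scheme <- pigeonhole_scheme(k)
  psizes <- partition_pattern(length(pc), scheme$parts)

  found <- new.env(parent = emptyenv())
  found$rows <- vector("list", 64L)
  found$i <- 0L
  sink <- function(df) {
    found$i <- found$i + 1L
    found$rows[[found$i]] <- df
  }
  for (srch in scheme$searches) {
    if (metric == "hamming") run_ham_search(index, pc, srch, psizes, sink)
    else run_edit_search(index, pc, srch, psizes, k, sink)
  }
  if (found$i == 0L) return(empty_occurrences())
  occ <- do.call(rbind, found$rows[seq_len(found$i)])
  occ$strand <- "+"
  dedup_occurrences(occ, metric)
}

#' Reduce raw occurrences to the canonical set
#'
#' Hamming distance: occurrences are unique by `(strand, start)` (a fixed
#' length makes duplicates identical). Edit distance: several substrings
#' with different lengths and distances can begin at the same position;
#' the minimum-distance one is kept, ties broken by shortest length. The
#' exhaustive oracle applies the identical rule, so set comparisons
#' between index and oracle are well defined.
#'
#' @param occ occurrence data.frame.
#' @param metric `"hamming"` or `"edit"`.
#' @return deduplicated occurrence data.frame, sorted by strand and start.
#' @export
dedup_occurrences <- function(occ, metric = c("hamming", "edit")) {
  metric <- match.arg(metric)
  if (nrow(occ) == 0L) return(occ)
  o <- order(occ$strand, occ$start, occ$distance, occ$length)
  occ <- occ[o, , drop = FALSE]
  occ <- occ[!duplicated(occ[c("strand", "start")]), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Align one read on both strands
#'
#' Runs the search scheme for the read and for its reverse complement and
#' pools the strand-tagged occurrences. Reads containing characters
#' outside `{A,C,G,T}` (e.g. `N`) are reported unmapped — the sentinel
#' never occurs in reads, and ambiguity codes are not indexed. Reads
#' shorter than `k + 1` cannot be partitioned for the scheme and are
#' likewise unmapped.
#'
#' @param index a `bmove_index`.
#' @param read read sequence.
#' @param k maximum distance.
#' @param metric `"hamming"` or `"edit"`.
#' @param scheme optional `search_scheme`.
#' @return occurrence data.frame with strand `"+"` or `"-"`; zero rows
#'   means unmapped.
#' @export
align_read <- function(index, read, k = 0L, metric = c("hamming", "edit"),
                       scheme = NULL) {
  metric <- match.arg(metric)
  read <- toupper(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T")) || length(chars) < k + 1L)
    return(empty_occurrences())
  fwd <- run_search_scheme(index, read, k, metric, scheme)
  rc <- run_search_scheme(index, revcomp(read), k, metric, scheme)
  if (nrow(rc) > 0L) rc$strand <- "-"
  out <- rbind(fwd, rc)
  out[order(out$strand, out$start), , drop = FALSE]
}

#' Align a set of reads
#'
#' @param index a `bmove_index`.
#' @param reads named character vector of read sequences.
#' @inheritParams align_read
#' @return data.frame with one row per occurrence (`read`, `start`,
#'   `length`, `distance`, `strand`); unmapped reads contribute a row with
#'   `NA` start.
#' @export
align_reads <- function(index, reads, k = 0L, metric = c("hamming", "edit"),
                        scheme = NULL) {
  metric <- match.arg(metric)
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  res <- lapply(seq_along(reads), function(i) {
    occ <- align_read(index, reads[[i]], k, metric, scheme)
    if (nrow(occ) == 0L)
      data.frame(read = names(reads)[i], start = NA_integer_,
                 length = NA_integer_, distance = NA_integer_,
                 strand = NA_character_, stringsAsFactors = FALSE)
    else
      cbind(read = names(reads)[i], occ, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## ---- SAM output ------------------------------------------------------------

# Resolve a concatenated-text span to a fragment; NA when it spans a
# fragment boundary (concatenation artifacts are not biological matches).
resolve_fragment <- function(frag, start, len) {
  k <- findInterval(start, frag$offset)
  if (k < 1L) return(NA_integer_)
  if (start + len > frag$offset[k] + frag$length[k]) return(NA_integer_)
  k
}

#' Write alignments as SAM
#'
#' One line per occurrence: `FLAG` 0/16 by strand (4 for unmapped reads),
#' `RNAME`/`POS` resolved from concatenated coordinates through the
#' fragment boundary table (occurrences spanning a fragment boundary are
#' discarded), `MAPQ` 255, `CIGAR` `*` (the index does not store the text,
#' so alignment paths are not reconstructed) and an `NM` tag carrying the
#' distance.
#'
#' @param index a `bmove_index`.
#' @param hits data.frame from [align_reads()].
#' @param reads the named read vector that produced `hits`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(index, hits, reads, path) {
  frag <- index$fragments
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", frag$name, frag$length),
           "@PG\tID:bimove\tPN:bimove")
  lines <- character(0)
  for (nm in names(reads)) {
    seq <- reads[[nm]]
    sub <- hits[hits$read == nm, , drop = FALSE]
    emitted <- 0L
    if (nrow(sub) > 0L && !all(is.na(sub$start))) {
      for (r in seq_len(nrow(sub))) {
        if (is.na(sub$start[r])) next
        fi <- resolve_fragment(frag, sub$start[r], sub$length[r])
        if (is.na(fi)) next
        rev <- identical(sub$strand[r], "-")
        lines <- c(lines, paste(
          nm, if (rev) 16L else 0L, frag$name[fi],
          sub$start[r] - frag$offset[fi] + 1L, 255L, "*", "*", 0L, 0L,
          if (rev) revcomp(seq) else seq, "*",
          sprintf("NM:i:%d", sub$distance[r]), sep = "\t"))
        emitted <- emitted + 1L
      }
    }
    if (emitted == 0L)
      lines <- c(lines, paste(nm, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                              seq, "*", sep = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
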