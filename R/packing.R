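# Bit-packed row encodings and whole-index serialization. Each packed row
# stores (c,) p, pi, xi in dedicated bit fields, byte-aligned per row so a
# row access touches a fixed byte range of one contiguous block.

#' Bit layout of a packed move-table row
#'
#' The `p` and `pi` fields are wide enough for every value up to `n`
#' inclusive (the sentinel row stores `p = n`, so the width is
#' `ceiling(log2(n + 1))`); `xi` needs `ceiling(log2(rows))` bits; run
#' characters take 3 bits when present. Every field width is floored at
#' one bit so degenerate tables still encode, and each row is padded to a
#' whole number of bytes.
#'
#' @param n domain size of the table.
#' @param rows total row count (including the sentinel row).
#' @param has_char whether rows carry a run character (LF tables).
#' @return list with `w_ch`, `w_pos`, `w_xi`, `bits_per_row`,
#'   `bytes_per_row`.
#' @export
row_layout <- function(n, rows, has_char) {
  stopifnot(n >= 2L, rows >= 1L)
  w_pos <- max(1L, as.integer(ceiling(log2(n + 1))))
  w_xi <- max(1L, as.integer(ceiling(log2(rows))))
  w_ch <- if (has_char) 3L else 0L
  bits <- 2L * w_pos + w_xi + w_ch
  if (bits > 52L)
    stop("table too large for the packed representation", call. = FALSE)
  list(w_ch = w_ch, w_pos = w_pos, w_xi = w_xi,
       bits_per_row = bits, bytes_per_row = as.integer(ceiling(bits / 8)))
}

# Field order, low bits first: [c] p pi xi. Values are assembled in a
# double (exact below 2^53) and emitted little-endian.
encode_row <- function(layout, ch, p, pi, xi) {
  lim_pos <- 2^layout$w_pos
  lim_xi <- 2^layout$w_xi
  if (p >= lim_pos || pi >= lim_pos || xi >= lim_xi ||
      (layout$w_ch > 0L && ch >= 8L))
    stop("encode_row: field overflow (layout bug)", call. = FALSE)
  val <- 0
  shift <- 0
  if (layout$w_ch > 0L) { val <- ch; shift <- layout$w_ch }
  val <- val + p * 2^shift; shift <- shift + layout$w_pos
  val <- val + pi * 2^shift; shift <- shift + layout$w_pos
  val <- val + xi * 2^shift
  bytes <- raw(layout$bytes_per_row)
  for (b in seq_len(layout$bytes_per_row)) {
    bytes[b] <- as.raw(val %% 256)
    val <- val %/% 256
  }
  bytes
}

decode_row <- function(layout, bytes) {
  val <- sum(as.integer(bytes) * 2^(8 * (seq_along(bytes) - 1)))
  out <- list(ch = NA_integer_)
  if (layout$w_ch > 0L) {
    out$ch <- as.integer(val %% 2^layout$w_ch)
    val <- val %/% 2^layout$w_ch
  }
  out$p <- as.integer(val %% 2^layout$w_pos)
  val <- val %/% 2^layout$w_pos
  out$pi <- as.integer(val %% 2^layout$w_pos)
  val <- val %/% 2^layout$w_pos
  out$xi <- as.integer(val %% 2^layout$w_xi)
  out
}

#' Pack / unpack a move table
#'
#' `pack_table` encodes every row of a full move table into a contiguous
#' byte block using [row_layout()]; `unpack_table` restores the full
#' table. The round trip is lossless, and all move-table primitives
#' ([move_step()], [fast_forward()], [update_run_indices()], the walking
#' functions) run directly on the packed representation through the shared
#' row accessors, yielding identical results.
#'
#' @param tab a `move_table`.
#' @return `pack_table`: a `packed_table`; `unpack_table`: a `move_table`.
#' @export
pack_table <- function(tab) {
  stopifnot(inherits(tab, "move_table"))
  rows <- length(tab$p)
  has_char <- !is.null(tab$ch)
  layout <- row_layout(tab$n, rows, has_char)
  block <- raw(layout$bytes_per_row * rows)
  for (j in seq_len(rows)) {
    ch <- if (has_char) tab$ch[j] else 0L
    if (is.na(ch)) ch <- 0L                       # sentinel row of LF tables
    enc <- encode_row(layout, ch, tab$p[j], tab$pi[j], tab$xi[j])
    block[(j - 1L) * layout$bytes_per_row + seq_len(layout$bytes_per_row)] <- enc
  }
  structure(list(kind = tab$kind, n = tab$n, rows = rows,
                 has_char = has_char, layout = layout, block = block,
                 balanced = tab$balanced),
            class = "packed_table")
}

#' @rdname pack_table
#' @param ptab a `packed_table`.
#' @export
unpack_table <- function(ptab) {
  stopifnot(inherits(ptab, "packed_table"))
  rows <- ptab$rows
  p <- integer(rows); pi <- integer(rows); xi <- integer(rows)
  ch <- if (ptab$has_char) integer(rows) else NULL
  for (j in seq_len(rows)) {
    r <- decode_packed_row(ptab, j - 1L)
    p[j] <- r$p; pi[j] <- r$pi; xi[j] <- r$xi
    if (ptab$has_char) ch[j] <- r$ch
  }
  if (ptab$has_char) ch[rows] <- NA_integer_      # sentinel row
  new_move_table(ptab$kind, ptab$n, p, pi, xi, ch = ch,
                 balanced = ptab$balanced)
}

decode_packed_row <- function(ptab, j) {
  bpr <- ptab$layout$bytes_per_row
  decode_row(ptab$layout, ptab$block[j * bpr + seq_len(bpr)])
}

#' @export
print.packed_table <- function(x, ...) {
  cat(sprintf("<packed_table %s: n = %d, rows = %d, %d bits/row, %d bytes/row>\n",
              x$kind, x$n, x$rows, x$layout$bits_per_row,
              x$layout$bytes_per_row))
  invisible(x)
}

# row accessors shared with the full representation
#' @export
mt_runs.packed_table <- function(tab) tab$rows - 1L
#' @export
mt_p.packed_table <- function(tab, j) decode_packed_row(tab, j)$p
#' @export
mt_pi.packed_table <- function(tab, j) decode_packed_row(tab, j)$pi
#' @export
mt_xi.packed_table <- function(tab, j) decode_packed_row(tab, j)$xi
#' @export
mt_ch.packed_table <- function(tab, j) {
  if (!tab$has_char || j == tab$rows - 1L) return(NA_integer_)
  decode_packed_row(tab, j)$ch
}

## ---- serialization ---------------------------------------------------------

BM_MAGIC <- "BMVIDX"
BM_VERSION <- 1L

write_int <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                       endian = "little")
read_int <- function(con, n = 1L) {
  out <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(out) != n) stop("index file truncated", call. = FALSE)
  out
}
write_str <- function(con, s) {
  b <- charToRaw(s)
  write_int(con, length(b))
  writeBin(b, con)
}
read_str <- function(con) {
  len <- read_int(con)
  b <- readBin(con, "raw", n = len)
  if (length(b) != len) stop("index file truncated", call. = FALSE)
  rawToChar(b)
}
write_ivec <- function(con, v) {
  write_int(con, length(v))
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}
read_ivec <- function(con) {
  len <- read_int(con)
  out <- readBin(con, "integer", n = len, size = 4L, endian = "little")
  if (length(out) != len) stop("index file truncated", call. = FALSE)
  out
}

write_packed <- function(con, ptab) {
  write_str(con, ptab$kind)
  write_int(con, c(ptab$n, ptab$rows, as.integer(ptab$has_char),
                   as.integer(ptab$balanced)))
  writeBin(ptab$block, con)
}
read_packed <- function(con, n_expect) {
  kind <- read_str(con)
  hdr <- read_int(con, 4L)
  if (hdr[1L] != n_expect)
    stop("index file corrupt: table domain does not match header n",
         call. = FALSE)
  layout <- row_layout(hdr[1L], hdr[2L], hdr[3L] == 1L)
  nbytes <- layout$bytes_per_row * hdr[2L]
  block <- readBin(con, "raw", n = nbytes)
  if (length(block) != nbytes) stop("index file truncated", call. = FALSE)
  structure(list(kind = kind, n = hdr[1L], rows = hdr[2L],
                 has_char = hdr[3L] == 1L, layout = layout, block = block,
                 balanced = hdr[4L] == 1L),
            class = "packed_table")
}

#' Save / load an index
#'
#' The on-disk container is a little-endian binary format: a magic string
#' and version, a header (n, balancing parameter, phi-table and fallback
#' flags), the fragment table, the bit-packed move tables, the per-run
#' suffix-array samples, the PLCP samples and, for indexes built without
#' phi tables, the dense fallback arrays. Loading restores an index whose
#' behavior is bit-identical to the saved one.
#'
#' @param index a `bmove_index`.
#' @param path file path.
#' @return `save_index`: `path` invisibly; `load_index`: a `bmove_index`.
#' @export
save_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(BM_MAGIC), con)
  write_int(con, c(BM_VERSION, index$n, index$d,
                   as.integer(index$with_phi),
                   as.integer(!is.null(index$fallback))))
  write_str(con, index$name)
  write_int(con, nrow(index$fragments))
  for (i in seq_len(nrow(index$fragments))) {
    write_str(con, index$fragments$name[i])
    write_int(con, c(index$fragments$offset[i], index$fragments$length[i]))
  }
  pk <- function(tab) if (inherits(tab, "packed_table")) tab else pack_table(tab)
  write_packed(con, pk(index$mlf))
  write_packed(con, pk(index$mlfrev))
  if (index$with_phi) {
    write_packed(con, pk(index$mphi))
    write_packed(con, pk(index$mphi_inv))
  }
  for (v in index$samples) write_ivec(con, v)
  write_ivec(con, index$plcp$pos)
  write_ivec(con, index$plcp$val)
  if (!is.null(index$fallback)) {
    write_ivec(con, index$fallback$sa)
    write_ivec(con, index$fallback$isa)
  }
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = nchar(BM_MAGIC))
  if (length(magic) != nchar(BM_MAGIC) || rawToChar(magic) != BM_MAGIC)
    stop("not an index file (magic mismatch)", call. = FALSE)
  hdr <- read_int(con, 5L)
  if (hdr[1L] != BM_VERSION)
    stop(sprintf("unsupported index version %d", hdr[1L]), call. = FALSE)
  n <- hdr[2L]
  name <- read_str(con)
  nfrag <- read_int(con)
  frag <- data.frame(name = character(nfrag), offset = integer(nfrag),
                     length = integer(nfrag), stringsAsFactors = FALSE)
  for (i in seq_len(nfrag)) {
    frag$name[i] <- read_str(con)
    ol <- read_int(con, 2L)
    frag$offset[i] <- ol[1L]; frag$length[i] <- ol[2L]
  }
  with_phi <- hdr[4L] == 1L
  mlf <- unpack_table(read_packed(con, n))
  mlfrev <- unpack_table(read_packed(con, n))
  mphi <- NULL; mphi_inv <- NULL
  if (with_phi) {
    mphi <- unpack_table(read_packed(con, n))
    mphi_inv <- unpack_table(read_packed(con, n))
  }
  samples <- list(fwd_start = read_ivec(con), fwd_end = read_ivec(con),
                  rev_start = read_ivec(con), rev_end = read_ivec(con))
  plcp <- list(pos = read_ivec(con), val = read_ivec(con))
  fallback <- NULL
  if (hdr[5L] == 1L)
    fallback <- list(sa = read_ivec(con), isa = read_ivec(con))
  structure(list(n = n, name = name, d = hdr[3L], with_phi = with_phi,
                 packed = FALSE, fragments = frag,
                 mlf = mlf, mlfrev = mlfrev,
                 mphi = mphi, mphi_inv = mphi_inv,
                 samples = samples, plcp = plcp, fallback = fallback),
            class = "bmove_index")
}
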