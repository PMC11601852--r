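# Whole-index construction: text ingestion, forward/reverse suffix
# structures, LF and phi move tables, suffix-array samples, sparse PLCP,
# and construction-time verification against the dense oracles.

#' Build a bidirectional move-structure index
#'
#' Constructs the full index for a sequence collection: the concatenated
#' sentinel-terminated text, the forward and reverse LF move tables, the
#' balanced phi and phi^-1 move tables (optional), per-run suffix-array
#' samples for toehold maintenance, and the sparse permuted LCP array for
#' the locate stopping rule. Construction is in-memory from dense suffix
#' structures, which suits desk-scale collections.
#'
#' With `with_phi_tables = FALSE` the phi tables are dropped and the dense
#' suffix array / inverse are retained instead, trading memory layout for
#' the table-free locate path ([locate_all_no_tables()]).
#'
#' @param x a FASTA file path, a character vector of fragments, or a
#'   `bm_text`.
#' @param with_phi_tables build balanced phi / phi^-1 move tables (default
#'   `TRUE`).
#' @param balance_d balancing threshold for the phi tables (>= 2; default 2,
#'   the tightest bound on fast-forward steps).
#' @param packed store the move tables bit-packed (default `FALSE`; see
#'   [pack_table()]).
#' @param verify run the full construction-time verification (every table
#'   row and the PLCP recovery rule checked against the dense oracles);
#'   default: enabled for texts up to 100 kb.
#' @param name label for the text.
#' @return an object of class `bmove_index`.
#' @export
move_index <- function(x, with_phi_tables = TRUE, balance_d = 2L,
                       packed = FALSE, verify = NULL, name = "index") {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("\\$$", x)) {
    frags <- read_fasta(x)
    text <- concat_with_sentinel(frags, name = name)
  } else if (inherits(x, "bm_text")) {
    text <- x
  } else if (is.character(x) && length(x) >= 1L && !grepl("\\$", x[1L])) {
    text <- concat_with_sentinel(x, name = name)
  } else {
    text <- bm_text(x, name = name)
  }
  n <- text$n
  if (is.null(verify)) verify <- n <= 100000L

  ss <- build_suffix_structures(text)
  ss_rev <- build_suffix_structures(reverse_text(text))

  mlf <- build_lf_table(ss, "LF")
  mlfrev <- build_lf_table(ss_rev, "LFrev")

  run_starts <- c(0L, which(ss$bwt[-1L] != ss$bwt[-n]))
  run_ends <- c(run_starts[-1L] - 1L, n - 1L)
  rev_starts <- c(0L, which(ss_rev$bwt[-1L] != ss_rev$bwt[-n]))
  rev_ends <- c(rev_starts[-1L] - 1L, n - 1L)
  samples <- list(
    fwd_start = ss$sa[run_starts + 1L],
    fwd_end = ss$sa[run_ends + 1L],
    rev_start = ss_rev$sa[rev_starts + 1L],
    rev_end = ss_rev$sa[rev_ends + 1L])

  # PLCP samples at the phi input-interval starts (irreducible positions)
  plcp_pos <- sort(ss$sa[run_starts + 1L])
  plcp_val <- ss$lcp[ss$isa[plcp_pos + 1L] + 1L]

  mphi <- NULL
  mphi_inv <- NULL
  fallback <- NULL
  if (with_phi_tables) {
    pt <- build_phi_tables(ss)
    mphi <- balance_table(pt$phi, balance_d)
    mphi_inv <- balance_table(pt$phi_inv, balance_d)
  } else {
    fallback <- list(sa = ss$sa, isa = ss$isa)
  }

  if (verify) {
    verify_index_build(ss, ss_rev, mlf, mlfrev, mphi, mphi_inv,
                       plcp_pos, plcp_val)
  }

  if (packed) {
    mlf <- pack_table(mlf)
    mlfrev <- pack_table(mlfrev)
    if (with_phi_tables) {
      mphi <- pack_table(mphi)
      mphi_inv <- pack_table(mphi_inv)
    }
  }

  frag <- text$fragments
  if (is.null(frag))
    frag <- data.frame(name = text$name, offset = 0L, length = n - 1L,
                       stringsAsFactors = FALSE)

  structure(list(
    n = n, name = text$name, d = as.integer(balance_d),
    with_phi = with_phi_tables, packed = packed,
    fragments = frag,
    mlf = mlf, mlfrev = mlfrev, mphi = mphi, mphi_inv = mphi_inv,
    samples = samples,
    plcp = list(pos = plcp_pos, val = plcp_val),
    fallback = fallback), class = "bmove_index")
}

# Full construction-time check: every table reproduces its dense oracle on
# the whole domain, and the PLCP recovery rule holds at every position.
verify_index_build <- function(ss, ss_rev, mlf, mlfrev, mphi, mphi_inv,
                               plcp_pos, plcp_val) {
  n <- ss$n
  stopifnot(identical(table_mapping(as_full_table(mlf)), lf_all(ss)),
            identical(table_mapping(as_full_table(mlfrev)), lf_all(ss_rev)))
  if (!is.null(mphi)) {
    stopifnot(identical(table_mapping(as_full_table(mphi)), phi_all(ss)),
              identical(table_mapping(as_full_table(mphi_inv)),
                        phi_inv_all(ss)))
  }
  plcp_full <- ss$lcp[ss$isa + 1L]
  k <- findInterval(0:(n - 1L), plcp_pos)
  if (!identical(plcp_val[k] - (0:(n - 1L) - plcp_pos[k]), plcp_full))
    stop("PLCP recovery rule failed construction-time verification")
  invisible(TRUE)
}

as_full_table <- function(tab) {
  if (inherits(tab, "packed_table")) unpack_table(tab) else tab
}

#' @export
print.bmove_index <- function(x, ...) {
  cat(sprintf("<bmove_index '%s': n = %d, r = %d, r_rev = %d%s%s>\n",
              x$name, x$n, mt_runs(x$mlf), mt_runs(x$mlfrev),
              if (x$with_phi)
                sprintf(", phi rows = %d/%d (balanced, d = %d)",
                        mt_runs(x$mphi), mt_runs(x$mphi_inv), x$d)
              else ", no phi tables",
              if (isTRUE(x$packed)) ", bit-packed" else ""))
  cat(sprintf("  fragments: %d\n", nrow(x$fragments)))
  invisible(x)
}

# Locate dispatch used by the aligner.
locate_for <- function(index, state) {
  if (index$with_phi) locate_all(index, state)
  else locate_all_no_tables(index, state)
}
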