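# Deterministic synthetic data: a pan-genome-like fragment collection
# (one base sequence plus mutated near-copies, so BWT run counts grow
# sublinearly with the number of copies) and reads with planted errors and
# truth annotations.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

mutate_seq <- function(chars, substitution_rate, indel_rate) {
  sigma <- c("A", "C", "G", "T")
  n <- length(chars)
  sub_at <- runif(n) < substitution_rate
  if (any(sub_at)) {
    repl <- vapply(chars[sub_at],
                   function(b) sample(setdiff(sigma, b), 1L), character(1))
    chars[sub_at] <- repl
  }
  if (indel_rate > 0) {
    del_at <- runif(length(chars)) < indel_rate / 2
    ins_at <- runif(length(chars)) < indel_rate / 2
    out <- character(0)
    ins_chars <- sample(sigma, sum(ins_at), replace = TRUE)
    ii <- 1L
    pieces <- lapply(seq_along(chars), function(i) {
      keep <- if (del_at[i]) character(0) else chars[i]
      if (ins_at[i]) {
        ic <- ins_chars[ii]; ii <<- ii + 1L
        c(keep, ic)
      } else keep
    })
    chars <- unlist(pieces)
  }
  chars
}

#' Synthetic pan-genome fragments
#'
#' Emulates a collection of closely related genomes: one random base
#' sequence and `copies - 1` independently mutated near-copies
#' (substitutions at `substitution_rate`, insertions/deletions at
#' `indel_rate`, each split evenly). Defaults reflect intra-species
#' diversity of a bacterial pan-genome: roughly 1% substitutions and 0.1%
#' indels between strains. Because the copies are near-identical, the BWT
#' run count of the concatenation grows sublinearly with `copies`.
#'
#' @param base_length length of the base sequence.
#' @param copies total number of fragments (>= 1).
#' @param substitution_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel probability in `[0, 1)`.
#' @param seed integer seed; the output is a deterministic function of it.
#' @return named character vector of fragments.
#' @export
synth_pangenome <- function(base_length = 20000L, copies = 8L,
                            substitution_rate = 0.01, indel_rate = 0.001,
                            seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1, copies >= 1L)
  with_seed(seed, {
    sigma <- c("A", "C", "G", "T")
    base <- sample(sigma, base_length, replace = TRUE)
    frags <- character(copies)
    frags[1L] <- paste(base, collapse = "")
    for (i in seq_len(copies - 1L)) {
      frags[i + 1L] <- paste(mutate_seq(base, substitution_rate, indel_rate),
                             collapse = "")
    }
    names(frags) <- sprintf("copy%d", seq_len(copies))
    frags
  })
}

#' Synthetic reads with truth annotations
#'
#' Samples reads of fixed length from both strands of a text and plants
#' errors (substitutions, and short indels when `indels = TRUE`). The
#' truth — origin position, strand, number of planted edits — rides in the
#' read names as colon-separated fields (`id:pos:strand:edits`), keeping
#' the records FASTQ-compliant.
#'
#' @param text a `bm_text` or string (sentinel-terminated).
#' @param count number of reads.
#' @param length read length; must fit in the text.
#' @param error_rate per-base error probability.
#' @param indels allow planted insertions/deletions (default substitutions
#'   only).
#' @param seed integer seed.
#' @return data.frame with columns `name`, `seq`, `origin`, `strand`,
#'   `edits`.
#' @export
synth_reads <- function(text, count = 100L, length = 100L, error_rate = 0.01,
                        indels = FALSE, seed = 1L) {
  text <- bm_text(text)
  usable <- text$n - 1L
  if (length > usable) stop("read length exceeds text length", call. = FALSE)
  with_seed(seed, {
    sigma <- c("A", "C", "G", "T")
    starts <- sample.int(usable - length + 1L, count, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), count, replace = TRUE)
    seqs <- character(count)
    edits <- integer(count)
    for (i in seq_len(count)) {
      chars <- BM_ALPHABET[text$codes[starts[i] + seq_len(length)] + 1L]
      if (strands[i] == "-")
        chars <- strsplit(revcomp(paste(chars, collapse = "")), "",
                          fixed = TRUE)[[1L]]
      err_at <- which(runif(length) < error_rate)
      for (p in err_at) {
        kind <- if (indels) sample(c("sub", "ins", "del"), 1L,
                                   prob = c(0.8, 0.1, 0.1)) else "sub"
        if (kind == "sub") {
          chars[p] <- sample(setdiff(sigma, chars[p]), 1L)
        } else if (kind == "ins") {
          chars <- append(chars, sample(sigma, 1L), after = p)
        } else {
          chars <- chars[-p]
        }
      }
      edits[i] <- length(err_at)
      seqs[i] <- paste(chars, collapse = "")
    }
    data.frame(
      name = sprintf("r%d:%d:%s:%d", seq_len(count), starts, strands, edits),
      seq = seqs, origin = starts, strand = strands, edits = edits,
      stringsAsFactors = FALSE)
  })
}

#' Write fragments as FASTA / reads as FASTQ
#'
#' @param frags named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(frags, path) {
  if (is.null(names(frags))) names(frags) <- sprintf("seq%d", seq_along(frags))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(frags), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param reads a data.frame from [synth_reads()] (columns `name`, `seq`).
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+",
                           strrep("I", nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}
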