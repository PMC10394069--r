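#' Generate a random circular reference genome
#'
#' Creates a synthetic stand-in for a mitochondrial reference: a circular
#' sequence over A/C/G/T with a target GC content.  Positions are 1-based and
#' inclusive; coordinate arithmetic elsewhere in the package wraps around the
#' origin.
#'
#' @param length Sequence length in bases (>= 1000).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same call with the same seed reproduces the
#'   same sequence.
#' @param name Sequence name used in FASTA/SAM headers.
#' @return A `ref_genome` object: list with `name`, `sequence` (uppercase
#'   character scalar), `circular` and `length`.
#' @examples
#' ref <- make_reference(2000, gc = 0.4, seed = 1)
#' nchar(ref$sequence)
#' @export
make_reference <- function(length, gc = 0.4, seed = 1, name = "synthetic_mito") {
  if (!is.numeric(length) || length(length) != 1L || length < 1000)
    stop("`length` must be a single number >= 1000", call. = FALSE)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("`gc` must be strictly between 0 and 1", call. = FALSE)
  length <- as.integer(length)
  withr_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  new_ref_genome(name, paste(bases, collapse = ""), circular = TRUE)
}

new_ref_genome <- function(name, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence restricted to A/C/G/T", call. = FALSE)
  structure(
    list(name = name, sequence = sequence, circular = circular,
         length = nchar(sequence)),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# 1-based circular position normalisation.
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

# Extract `len` bases starting at 1-based `start`, wrapping around the origin.
circ_substr <- function(sequence, start, len) {
  L <- nchar(sequence)
  start <- wrap_pos(start, L)
  end <- start + len - 1L
  if (end <= L) return(substr(sequence, start, end))
  paste0(substr(sequence, start, L), substr(sequence, 1L, end - L))
}

str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Read and write references as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that carry the circularity convention used
#' throughout this package.
#'
#' @param path FASTA file path.
#' @param circular Whether the (first) sequence is circular.
#' @param ref A `ref_genome`.
#' @return `read_reference()` returns a `ref_genome`; `write_reference()`
#'   returns `path` invisibly.
#' @export
read_reference <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path, call. = FALSE)
  new_ref_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]),
                 circular = circular)
}

#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a named set of sequences to FASTA
#'
#' @param seqs Named character vector of sequences (may contain N/-).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}
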