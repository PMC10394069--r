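#' Call a consensus sequence from a pileup
#'
#' At every reference position the winning allele (base or deletion) is
#' emitted when its count reaches `threshold` of the depth *and* the depth
#' reaches `min_depth`; otherwise the position is called N.  The threshold is
#' inclusive: a winner at exactly `threshold` of the depth is a call, not an
#' N.  Deletions compete as ordinary alleles and are tracked explicitly;
#' insertion alleles are emitted only when they meet the same support rule
#' against the flanking position's depth.
#'
#' @param pileup A `pileup`.
#' @param threshold Winning-allele fraction required, in (0.5, 1].
#' @param min_depth Minimum depth for any call (the proxy for a mapper's
#'   "highest quality" consensus setting; configurable).
#' @return A `consensus_seq` object: `calls` (character vector over
#'   A/C/G/T/N/`-`, one per reference position), `sequence` (calls collapsed
#'   with deletions removed), `depth`, `win_fraction`, `insertions` (the
#'   emitted ones), `low_conf` (mask of N positions) and `ref`.
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' sim <- simulate_reads(ref$sequence,
#'                       damage_params(delta_ss = 0, delta_ds = 0,
#'                                     seq_error = 0, coverage = 20),
#'                       seed = 5)
#' cons <- call_consensus(build_pileup(map_reads(sim, ref)))
#' sum(cons$calls == "N")
#' @export
call_consensus <- function(pileup, threshold = 0.75, min_depth = 3) {
  stopifnot(inherits(pileup, "pileup"))
  if (threshold <= 0.5 || threshold > 1)
    stop("`threshold` must lie in (0.5, 1]", call. = FALSE)
  counts <- pileup$counts
  depth <- pileup$depth
  if (all(depth == 0)) warning("empty pileup: all-N consensus", call. = FALSE)

  win_i <- apply(counts, 2, which.max)
  win_n <- counts[cbind(win_i, seq_len(ncol(counts)))]
  frac <- ifelse(depth > 0, win_n / depth, 0)
  ok <- depth >= min_depth & frac >= threshold
  calls <- ifelse(ok, rownames(counts)[win_i], "N")

  ins <- pileup$insertions
  if (nrow(ins)) {
    flank_depth <- depth[ins$pos]
    keep <- flank_depth >= min_depth & ins$count / flank_depth >= threshold
    ins <- ins[keep, , drop = FALSE]
  }

  structure(
    list(calls = calls,
         sequence = paste(calls[calls != "-"], collapse = ""),
         depth = depth, win_fraction = frac,
         insertions = ins, low_conf = calls == "N",
         threshold = threshold, min_depth = min_depth, ref = pileup$ref),
    class = "consensus_seq"
  )
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> %s: %d positions, %.2f%% N, %d deletions, %d insertions\n",
              x$ref$name, length(x$calls), 100 * mean(x$low_conf),
              sum(x$calls == "-"), nrow(x$insertions)))
  invisible(x)
}

#' Write a consensus as FASTA and per-position call table
#'
#' @param cons A `consensus_seq`.
#' @param path Output FASTA path.
#' @param name Sequence name (defaults to the reference name).
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(cons, path, name = cons$ref$name) {
  write_fasta(setNames(paste(cons$calls, collapse = ""), name), path)
  invisible(path)
}

#' @rdname write_consensus_fasta
#' @export
write_call_table <- function(cons, path) {
  df <- data.frame(pos = seq_along(cons$calls), call = cons$calls,
                   depth = cons$depth,
                   win_fraction = round(cons$win_fraction, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
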