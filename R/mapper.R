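#' Map reads to a circular reference
#'
#' Seed-and-extend mapping: exact k-mer seeds on both strands against the
#' doubled circular sequence, diagonal voting, then a fitting alignment of the
#' whole read inside a window of +/- `band` around each candidate diagonal
#' (match +1, mismatch -1, gap -2).  The best location is reported with a
#' mapping-quality proxy `mapq = min(60, 4 * (best - second_best))`, 60 when
#' no runner-up location exists.  Reads crossing the origin get wrapped
#' 1-based coordinates.
#'
#' @param reads Data frame with `read_id`, `sequence` (e.g. from
#'   [read_fastq()] or a `read_sim$reads`), or a `read_sim`.
#' @param ref A `ref_genome`.
#' @param k Seed length (>= 8).
#' @param band Half-width of the alignment window around a candidate diagonal.
#' @param max_candidates Candidate locations examined per read.
#' @return A `read_alignments` data frame: `read_id`, `ref_start`, `ref_end`
#'   (1-based, circular), `strand`, `map_score`, `mapq_proxy`, `n_mismatch`,
#'   `n_gap`, `aln_len`, `read_aln`, `ref_aln`.  Unmapped read ids are kept in
#'   attribute `unmapped`; the reference is carried in attribute `ref`.
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' reads <- data.frame(read_id = "r1",
#'                     sequence = substr(ref$sequence, 101, 160))
#' map_reads(reads, ref)[, 1:6]
#' @export
map_reads <- function(reads, ref, k = 13, band = 16, max_candidates = 6) {
  if (inherits(reads, "read_sim")) reads <- reads$reads
  stopifnot(inherits(ref, "ref_genome"))
  if (k < 8) stop("`k` must be >= 8", call. = FALSE)
  if (nrow(reads) == 0L) stop("`reads` must be nonempty", call. = FALSE)

  res <- cpp_map_reads(toupper(reads$sequence), ref$sequence,
                       k = as.integer(k), band = as.integer(band),
                       max_candidates = as.integer(max_candidates))
  mapped <- res$mapped
  mapq <- ifelse(is.na(res$second), 60L,
                 pmin(60L, pmax(0L, 4L * (res$score - res$second))))
  out <- data.frame(
    read_id = reads$read_id[mapped],
    ref_start = res$ref_start[mapped],
    ref_end = wrap_pos(res$ref_start[mapped] + res$ref_span[mapped] - 1L,
                       ref$length),
    strand = res$strand[mapped],
    map_score = res$score[mapped],
    mapq_proxy = mapq[mapped],
    n_mismatch = res$n_mismatch[mapped],
    n_gap = res$n_gap[mapped],
    aln_len = res$aln_len[mapped],
    read_aln = res$read_aln[mapped],
    ref_aln = res$ref_aln[mapped]
  )
  structure(out, class = c("read_alignments", "data.frame"),
            unmapped = reads$read_id[!mapped], ref = ref)
}

as_read_alignments <- function(df, ref, unmapped = character()) {
  structure(as.data.frame(df), class = c("read_alignments", "data.frame"),
            unmapped = unmapped, ref = ref)
}

#' Apply the mapping filters
#'
#' Retains alignments with mismatch fraction and gap-column fraction at or
#' below the caps and mapping quality at or above the floor.  The default
#' caps mirror standard degraded-DNA mapping practice: mapping quality >= 30,
#' at most 5\% mismatches and at most 5\% gap columns per mapped read; the 5\%
#' bounds are inclusive.  Order is preserved and filtering is idempotent.
#'
#' @param alns A `read_alignments` data frame.
#' @param max_mismatch_frac,max_gap_frac Caps in `[0, 1]`.
#' @param min_mapq Mapping-quality floor.
#' @return Filtered `read_alignments`.
#' @export
filter_alignments <- function(alns, max_mismatch_frac = 0.05,
                              max_gap_frac = 0.05, min_mapq = 30) {
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1 ||
      max_gap_frac < 0 || max_gap_frac > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (nrow(alns) == 0L) return(alns)
  keep <- alns$n_mismatch / alns$aln_len <= max_mismatch_frac &
          alns$n_gap / alns$aln_len <= max_gap_frac &
          alns$mapq_proxy >= min_mapq
  as_read_alignments(alns[keep, , drop = FALSE], attr(alns, "ref"),
                     attr(alns, "unmapped"))
}

#' Remove duplicate alignments
#'
#' Alignments sharing (`ref_start`, `ref_end`, `strand`) are treated as
#' optical/PCR duplicates; the one with the highest `map_score` survives
#' (ties broken by lexicographically smallest `read_id`).  Opposite strands
#' over the same span are distinct molecules and both kept.
#'
#' @param alns A `read_alignments` data frame.
#' @return Deduplicated `read_alignments` (input order preserved).
#' @export
deduplicate <- function(alns) {
  if (nrow(alns) <= 1L) return(alns)
  key <- paste(alns$ref_start, alns$ref_end, alns$strand, sep = "/")
  ord <- order(key, -alns$map_score, alns$read_id)
  best <- !duplicated(key[ord])
  keep_ids <- alns$read_id[ord][best]
  as_read_alignments(alns[alns$read_id %in% keep_ids, , drop = FALSE],
                     attr(alns, "ref"), attr(alns, "unmapped"))
}

#' Build a per-position pileup
#'
#' Counts A/C/G/T/deletion per reference position over the circle; insertions
#' are recorded separately, keyed by the flanking (preceding) reference
#' position.
#'
#' @param alns A `read_alignments` data frame (normally filtered and
#'   deduplicated).
#' @param ref A `ref_genome`; defaults to the reference carried by `alns`.
#' @return A `pileup` object: list with `counts` (5 x L integer matrix, rows
#'   A/C/G/T/del), `insertions` (data frame `pos`, `seq`, `count`), `depth`
#'   (vector of column sums) and `ref`.
#' @export
build_pileup <- function(alns, ref = attr(alns, "ref")) {
  stopifnot(inherits(ref, "ref_genome"))
  pl <- cpp_build_pileup(alns$ref_aln, alns$read_aln,
                         as.integer(alns$ref_start), ref$length)
  counts <- pl$counts
  rownames(counts) <- c("A", "C", "G", "T", "-")
  ins <- data.frame(pos = pl$ins_pos, seq = pl$ins_seq, count = pl$ins_count)
  ins <- ins[order(ins$pos, ins$seq), , drop = FALSE]
  rownames(ins) <- NULL
  structure(list(counts = counts, insertions = ins,
                 depth = colSums(counts), ref = ref),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d positions, mean depth %.2f\n",
              x$ref$name, ncol(x$counts), mean(x$depth)))
  invisible(x)
}

#' Export a pileup as TSV
#'
#' Columns: `pos`, `A`, `C`, `G`, `T`, `del`, `depth`.
#'
#' @param pileup A `pileup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.frame(pos = seq_len(ncol(pileup$counts)),
                   t(pileup$counts), depth = pileup$depth)
  names(df) <- c("pos", "A", "C", "G", "T", "del", "depth")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal SAM text output for alignments
#'
#' Writes mapped records with NM and MD tags derived from the stored aligned
#' pairs.  Alignments spanning the circular origin keep their wrapped POS.
#'
#' @param alns A `read_alignments`.
#' @param path Output SAM path.
#' @param reads Optional read table (`read_id`, `sequence`, `quality`) to
#'   recover original base qualities; fixed qualities are written otherwise.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, path, reads = NULL) {
  ref <- attr(alns, "ref")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
               "@PG\tID:paleobov\tPN:paleobov"), con)
  qual_of <- if (!is.null(reads)) setNames(reads$quality, reads$read_id) else NULL
  for (i in seq_len(nrow(alns))) {
    ra <- strsplit(alns$ref_aln[i], "")[[1]]
    qa <- strsplit(alns$read_aln[i], "")[[1]]
    cig <- cigar_from_pairs(ra, qa)
    md <- md_tag_gapped(ra, qa)
    seq_out <- paste(qa[qa != "-"], collapse = "")
    q <- qual_of[[alns$read_id[i]]] %||% strrep("I", nchar(seq_out))
    if (alns$strand[i] == "-") q <- str_rev(q)
    flag <- if (alns$strand[i] == "-") 16L else 0L
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                       alns$read_id[i], flag, ref$name, alns$ref_start[i],
                       alns$mapq_proxy[i], cig, seq_out, q,
                       alns$n_mismatch[i] + alns$n_gap[i], md), con)
  }
  invisible(path)
}

cigar_from_pairs <- function(ra, qa) {
  op <- ifelse(ra == "-", "I", ifelse(qa == "-", "D", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

md_tag_gapped <- function(ra, qa) {
  out <- character()
  run <- 0L
  in_del <- FALSE
  for (c in seq_along(ra)) {
    if (ra[c] == "-") next             # insertion: not represented in MD
    if (qa[c] == "-") {
      if (!in_del) { out <- c(out, as.character(run), "^"); run <- 0L }
      out <- c(out, ra[c])
      in_del <- TRUE
    } else if (ra[c] == qa[c]) {
      run <- run + 1L
      in_del <- FALSE
    } else {
      out <- c(out, as.character(run), ra[c])
      run <- 0L
      in_del <- FALSE
    }
  }
  paste(c(out, as.character(run)), collapse = "")
}

#' Read a SAM text file
#'
#' Parses the mandatory columns of mapped records into a data frame; header
#' lines are returned as an attribute.  Intended for the truth/alignment
#' files this package writes, not as a general-purpose SAM reader.
#'
#' @param path SAM path.
#' @return Data frame `read_id`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`, `qual` with attribute `header`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  f <- strsplit(rec, "\t")
  df <- data.frame(
    read_id = vapply(f, `[`, "", 1L), flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L), pos = as.integer(vapply(f, `[`, "", 4L)),
    mapq = as.integer(vapply(f, `[`, "", 5L)), cigar = vapply(f, `[`, "", 6L),
    seq = vapply(f, `[`, "", 10L), qual = vapply(f, `[`, "", 11L))
  attr(df, "header") <- hdr
  df
}
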