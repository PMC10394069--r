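#' Simulate damaged ancient reads from a haplotype
#'
#' Draws fragments from the circular haplotype with log-normal lengths and
#' uniform start/strand, attaches geometric single-stranded overhangs to both
#' termini, deaminates cytosines (probability `delta_ss` in the 5' overhang,
#' `delta_ds` in the core; the mirrored G->A at the 3' terminus comes from the
#' complementary strand), then applies uniform sequencing error.  Every
#' introduced change is recorded, so simulations are fully closed-loop: the
#' truth table reproduces each read-versus-haplotype mismatch exactly.
#'
#' The number of fragments is `round(coverage * L / E[len])` with `E[len]` the
#' log-normal mean, so realised mean depth concentrates tightly around the
#' target.  Fragments longer than the genome are resampled, never emitted.
#'
#' @param hap Haplotype sequence (character scalar, circular).
#' @param params A [damage_params()] object.
#' @param seed Integer seed.
#' @param read_prefix Prefix for read identifiers.
#' @return A `read_sim` object: list with `reads` (data frame `read_id`,
#'   `sequence`, `quality`), `truth` (per read: `read_id`, `ref_start` 1-based
#'   on the circle, `strand`, `length`, overhang lengths `l5`, `l3`) and
#'   `changes` (per introduced change: `read_id`, `read_pos`, `ref_pos`,
#'   `from`, `to`, `type` in ct_ss/ct_ds/ga_ss/ga_ds/error).
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' sim <- simulate_reads(ref$sequence, damage_params(coverage = 5), seed = 2)
#' nrow(sim$reads)
#' @export
simulate_reads <- function(hap, params, seed = 1, read_prefix = "read") {
  stopifnot(inherits(params, "damage_params"))
  hap <- as.character(hap)
  L <- nchar(hap)
  n <- max(1L, as.integer(round(params$coverage * L / lognormal_mean(params))))

  withr_seed(seed, {
    len <- as.integer(round(rlnorm(n, log(params$frag_mean), params$frag_sd)))
    len[len < 1L] <- 1L
    while (any(bad <- len > L)) {
      len[bad] <- as.integer(round(rlnorm(sum(bad), log(params$frag_mean),
                                          params$frag_sd)))
      len[len < 1L] <- 1L
    }
    start <- sample.int(L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    l5 <- rgeom(n, params$overhang_p)
    l3 <- rgeom(n, params$overhang_p)

    frags <- vapply(seq_len(n), function(i) circ_substr(hap, start[i], len[i]),
                    character(1))
    minus <- strand == "-"
    frags[minus] <- revcomp(frags[minus])

    out_seq <- character(n)
    chg <- vector("list", n)
    for (i in seq_len(n)) {
      b <- strsplit(frags[i], "")[[1]]
      m <- length(b)
      in5 <- seq_len(m) <= l5[i]
      in3 <- seq_len(m) > m - l3[i]
      orig <- b

      isC <- b == "C"
      isG <- b == "G"
      p_ct <- ifelse(in5, params$delta_ss, params$delta_ds)
      p_ga <- ifelse(in3, params$delta_ss, params$delta_ds)
      hit_ct <- isC & runif(m) < p_ct
      hit_ga <- isG & runif(m) < p_ga
      b[hit_ct] <- "T"
      b[hit_ga] <- "A"

      hit_err <- runif(m) < params$seq_error
      if (any(hit_err)) {
        b[hit_err] <- vapply(b[hit_err], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      }

      changed <- which(b != orig)
      if (length(changed)) {
        type <- ifelse(changed %in% which(hit_err), "error",
                ifelse(changed %in% which(hit_ct),
                       ifelse(in5[changed], "ct_ss", "ct_ds"),
                       ifelse(in3[changed], "ga_ss", "ga_ds")))
        # damage followed by an error on the same base is booked as error
        ref_pos <- if (strand[i] == "+") wrap_pos(start[i] + changed - 1L, L)
                   else wrap_pos(start[i] + (m - changed), L)
        chg[[i]] <- data.frame(read_id = i, read_pos = changed,
                               ref_pos = ref_pos, from = orig[changed],
                               to = b[changed], type = type)
      }
      out_seq[i] <- paste(b, collapse = "")
    }
  })

  ids <- sprintf("%s_%05d", read_prefix, seq_len(n))
  changes <- if (length(ch <- chg[!vapply(chg, is.null, logical(1))]))
    do.call(rbind, ch) else
    data.frame(read_id = integer(), read_pos = integer(), ref_pos = integer(),
               from = character(), to = character(), type = character())
  changes$read_id <- ids[changes$read_id]

  structure(
    list(
      reads = data.frame(read_id = ids, sequence = out_seq,
                         quality = strrep("I", nchar(out_seq))),
      truth = data.frame(read_id = ids, ref_start = start, strand = strand,
                         length = len, l5 = pmin(l5, len), l3 = pmin(l3, len)),
      changes = changes,
      params = params, genome_length = L
    ),
    class = "read_sim"
  )
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("<read_sim> %d reads, %.1fx mean depth, %d recorded changes\n",
              nrow(x$reads), sum(x$truth$length) / x$genome_length,
              nrow(x$changes)))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param sim A `read_sim` object (or any data frame with `read_id`,
#'   `sequence`, `quality`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "read_sim")) sim$reads else sim
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::PhredQuality(reads$quality)
  # pairing sequence and quality drops (empty) metadata columns; expected
  qsd <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(dna, qual))
  Biostrings::writeQualityScaledXStringSet(qsd, path)
  invisible(path)
}

#' Read a FASTQ file into the simulator's read table
#'
#' @param path FASTQ path (Phred+33).
#' @return Data frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # dropping the (empty) metadata columns during conversion is expected
  qsd <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(
    data.frame(read_id = sub("\\s.*$", "", names(qsd)),
               sequence = as.character(qsd),
               quality = as.character(Biostrings::quality(qsd))))
}

#' Export simulation truth as SAM
#'
#' Writes one mapped, soft-clip-free record per read with NM and MD tags
#' computed against the reference frame the reads were drawn from.  Reads
#' crossing the circular origin keep their wrapped 1-based start.
#'
#' @param sim A `read_sim`.
#' @param ref The `ref_genome` (or haplotype) the reads were simulated from;
#'   used for the header and MD tags.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, ref, path) {
  seqs <- if (inherits(ref, "ref_genome")) ref$sequence else as.character(ref)
  name <- if (inherits(ref, "ref_genome")) ref$name else "ref"
  L <- nchar(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", name, L)), con)
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    read <- sim$reads$sequence[i]
    refseg <- circ_substr(seqs, tr$ref_start, tr$length)
    aln_read <- if (tr$strand == "-") revcomp(read) else read
    nm <- sum(strsplit(aln_read, "")[[1]] != strsplit(refseg, "")[[1]])
    md <- md_tag(strsplit(refseg, "")[[1]], strsplit(aln_read, "")[[1]])
    flag <- if (tr$strand == "-") 16L else 0L
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                       sim$reads$read_id[i], flag, name, tr$ref_start,
                       tr$length, aln_read,
                       if (tr$strand == "-") str_rev(sim$reads$quality[i]) else sim$reads$quality[i],
                       nm, md), con)
  }
  invisible(path)
}

# MD tag for a gap-free alignment given reference and read character vectors.
md_tag <- function(ref_chars, read_chars) {
  runs <- character()
  match_run <- 0L
  for (j in seq_along(ref_chars)) {
    if (ref_chars[j] == read_chars[j]) {
      match_run <- match_run + 1L
    } else {
      runs <- c(runs, as.character(match_run), ref_chars[j])
      match_run <- 0L
    }
  }
  paste(c(runs, as.character(match_run)), collapse = "")
}
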