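#' Haplotype diversity (Nei's unbiased gene diversity)
#'
#' `H = n (1 - sum p_i^2) / (n - 1)` over haplotype frequencies
#' `p_i = k_i / n` — the probability that two sequences sampled without
#' replacement carry different haplotypes, with the small-sample correction
#' used by the standard polymorphism tools.  Monomorphic samples give exactly
#' 0; all-distinct samples give exactly 1.
#'
#' @param multiplicities Integer counts per haplotype (all >= 1, total >= 2).
#' @return `H` at full precision.
#' @examples
#' haplotype_diversity(c(3, 2, rep(1, 16)))   # 0.98095...
#' @export
haplotype_diversity <- function(multiplicities) {
  k <- as.numeric(multiplicities)
  if (any(k < 1)) stop("multiplicities must be >= 1", call. = FALSE)
  n <- sum(k)
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  n / (n - 1) * (1 - sum((k / n)^2))
}

#' Diversity summary of an alignment region
#'
#' Collapses the alignment (dropping any column with a gap/N in any sequence,
#' optionally restricted to a region such as the D-loop), then reports the
#' number of haplotypes `k`, haplotype diversity `H`, segregating sites `S`
#' (included columns with >= 2 observed alleles) and nucleotide diversity
#' `pi` (mean pairwise difference per included site).
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (>= 2).
#' @param region Optional 1-based interval (or interval list), as in
#'   [collapse_haplotypes()].
#' @return A `diversity_report`: list with `n`, `k`, `H`, `S`, `pi`,
#'   `region`, `included_sites`, `dropped_sites` and the underlying
#'   `haplotype_table`.
#' @export
summarize_diversity <- function(seqs, region = NULL) {
  if (length(seqs) < 2) stop("need >= 2 sequences", call. = FALSE)
  tab <- collapse_haplotypes(seqs, region = region)
  n <- sum(tab$multiplicity)
  k <- length(tab$haplotypes)
  H <- haplotype_diversity(tab$multiplicity)

  mat <- do.call(rbind, strsplit(tab$haplotypes, ""))
  expand <- mat[rep(seq_len(k), tab$multiplicity), , drop = FALSE]
  S <- sum(apply(expand, 2, function(col) length(unique(col))) >= 2)

  d <- hamming_matrix(tab$haplotypes)
  w <- outer(tab$multiplicity, tab$multiplicity)
  diag(w) <- tab$multiplicity * (tab$multiplicity - 1)
  n_sites <- length(tab$included_sites)
  pi <- sum(d * w) / (n * (n - 1)) / n_sites

  structure(
    list(n = n, k = k, H = H, S = S, pi = pi, region = region,
         included_sites = length(tab$included_sites),
         dropped_sites = length(tab$dropped_sites), table = tab),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "<diversity_report> n=%d  k=%d  H=%.3f  S=%d  pi=%.5f  (%d sites used, %d dropped)\n",
    x$n, x$k, x$H, x$S, x$pi, x$included_sites, x$dropped_sites))
  invisible(x)
}

#' Haplogroup frequency table
#'
#' Counts assigned haplogroup calls per reporting label, rolling sub-clades
#' up through a reporting map (by default T1a/T1b/T1d report as T1 and the
#' ancestral T123 node reports as T).  Non-assigned calls are counted under
#' `unassigned`.  Full-precision frequencies are retained; the report view
#' rounds to 2 decimals.
#'
#' @param calls A list of `mt_call` objects, or a data frame with columns
#'   `haplogroup` and `status`.
#' @param rollup Named character vector mapping sub-clade label to reporting
#'   label.
#' @return A `frequency_table` data frame: `label`, `count`, `frequency`
#'   (full precision), `frequency_report` (2 decimals).
#' @examples
#' calls <- data.frame(haplogroup = c("T3", "T3", "T1b"),
#'                     status = "assigned")
#' haplogroup_frequencies(calls)
#' @export
haplogroup_frequencies <- function(calls,
                                   rollup = c(T1a = "T1", T1b = "T1",
                                              T1d = "T1", T123 = "T")) {
  if (is.data.frame(calls)) {
    hg <- calls$haplogroup
    status <- calls$status
  } else {
    hg <- vapply(calls, function(x) x$haplogroup %||% NA_character_,
                 character(1))
    status <- vapply(calls, `[[`, character(1), "status")
  }
  if (!length(hg)) {
    out <- data.frame(label = character(), count = integer(),
                      frequency = numeric(), frequency_report = numeric())
    class(out) <- c("frequency_table", "data.frame")
    return(out)
  }
  label <- ifelse(status == "assigned",
                  ifelse(hg %in% names(rollup), rollup[hg], hg),
                  "unassigned")
  tab <- sort(tapply(rep(1L, length(label)), label, sum), decreasing = TRUE)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / length(label))
  stopifnot(abs(sum(out$frequency) - 1) < 1e-12)
  out$frequency_report <- round(out$frequency, 2)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Write a Table-style diversity report
#'
#' Mirrors the usual population-summary layout: sample size, haplotype count,
#' haplotype diversity (3 decimals), segregating sites, nucleotide diversity,
#' then one row per haplogroup reporting label with count and 2-decimal
#' frequency.
#'
#' @param report A `diversity_report`.
#' @param freqs A `frequency_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(report, freqs, path) {
  lines <- c(
    sprintf("n_specimens\t%d", report$n),
    sprintf("n_haplotypes\t%d", report$k),
    sprintf("haplotype_diversity\t%.3f", report$H),
    sprintf("segregating_sites\t%d", report$S),
    sprintf("nucleotide_diversity\t%.5f", report$pi),
    sprintf("freq_%s\t%.2f", freqs$label, freqs$frequency_report)
  )
  writeLines(lines, path)
  invisible(path)
}
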