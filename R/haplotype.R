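#' Build a haplotype carrying a diagnostic panel
#'
#' Starting from the reference, applies the derived alleles of `label`'s panel
#' and of every ancestral panel in the hierarchy, then adds `n_private` random
#' private mutations.  Private mutations never land on a panel position of
#' *any* loaded panel (so diagnostic sites stay clean for the whole cohort),
#' nor on positions listed in `exclude`, and are drawn transition:transversion
#' at 2:1 — the usual mitochondrial bias.
#'
#' If the reference does not carry the panels' ancestral alleles it is
#' rewritten first (see [apply_panel_refs()]); the edit is recorded in
#' attribute `panel_edits` of the result.
#'
#' @param ref A `ref_genome`.
#' @param panels A `diagnostic_panels` table (all loaded panels).
#' @param label Haplogroup whose panel (plus ancestors) to realise; `NULL`
#'   applies no panel variants.
#' @param n_private Number of random private mutations.
#' @param seed Integer seed for private-mutation placement.
#' @param extra_variants Optional data frame `(position, alt)` of forced,
#'   deterministic variants (applied after panel variants).
#' @param exclude Positions private mutations must avoid (in addition to all
#'   panel positions and `extra_variants` positions).
#' @return Character scalar: the haplotype sequence, with attributes `label`,
#'   `variants` (data frame of every difference from the reference:
#'   position, ref, alt, origin) and `panel_edits`.
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' pan <- diagnostic_panels(data.frame(
#'   haplogroup = "X", parent = NA, position = c(100, 200),
#'   ref = c("C", "A"), alt = c("T", "G"), class = "transition"))
#' hap <- make_haplotype(ref, pan, "X", n_private = 2, seed = 9)
#' attr(hap, "variants")
#' @export
make_haplotype <- function(ref, panels, label = NULL, n_private = 0, seed = 1,
                           extra_variants = NULL, exclude = integer()) {
  stopifnot(inherits(ref, "ref_genome"))
  ref <- apply_panel_refs(ref, panels)
  s <- strsplit(ref$sequence, "")[[1]]
  L <- length(s)

  vars <- data.frame(position = integer(), ref = character(),
                     alt = character(), origin = character())
  if (!is.null(label)) {
    pv <- panel_variants(panels, label, with_ancestors = TRUE)
    s[pv$position] <- pv$alt
    vars <- rbind(vars, data.frame(position = pv$position, ref = pv$ref,
                                   alt = pv$alt, origin = pv$haplogroup))
  }
  if (!is.null(extra_variants) && nrow(extra_variants)) {
    p <- as.integer(extra_variants$position)
    if (any(p < 1 | p > L)) stop("extra variant outside reference", call. = FALSE)
    vars <- rbind(vars, data.frame(position = p, ref = s[p],
                                   alt = toupper(extra_variants$alt),
                                   origin = "forced"))
    s[p] <- toupper(extra_variants$alt)
  }

  if (n_private > 0) {
    banned <- unique(c(panels$position, vars$position, as.integer(exclude)))
    avail <- setdiff(seq_len(L), banned)
    if (length(avail) < n_private)
      stop("cannot place ", n_private, " private mutations without collision",
           call. = FALSE)
    withr_seed(seed, {
      pos <- sort(sample(avail, n_private))
      alt <- vapply(s[pos], mutate_base, character(1))
    })
    vars <- rbind(vars, data.frame(position = pos, ref = s[pos], alt = alt,
                                   origin = "private"))
    s[pos] <- alt
  }

  structure(paste(s, collapse = ""), label = label %||% "reference",
            variants = vars[order(vars$position), ],
            panel_edits = attr(ref, "panel_edits"))
}

# Draw a substitute base: transition with prob 2/3, else one of the two
# transversions uniformly.
mutate_base <- function(base) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  if (runif(1) < 2 / 3) ti[[base]] else sample(tv[[base]], 1)
}
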