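#' Read diagnostic variant states off a consensus
#'
#' For each variant of one haplogroup's panel, reports the consensus state at
#' that position: `derived` (consensus equals the derived allele),
#' `ancestral` (equals the panel's reference allele), `uncallable` (N) or
#' `other` (some third base — never counted as derived).  The consensus must
#' share the reference coordinate frame.
#'
#' @param consensus A `consensus_seq`, or a character vector of per-position
#'   calls in reference coordinates.
#' @param ref A `ref_genome` (range checks).
#' @param panel Variant rows for one haplogroup (e.g.
#'   `panel_variants(panels, "T1b", with_ancestors = FALSE)`).
#' @return Data frame: the panel rows plus `observed` and `state`; attribute
#'   `n_derived` carries the derived count.
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' pan <- diagnostic_panels(data.frame(
#'   haplogroup = "X", parent = NA, position = c(100, 200),
#'   ref = c("C", "A"), alt = c("T", "G"), class = "transition"))
#' calls <- strsplit(apply_panel_refs(ref, pan)$sequence, "")[[1]]
#' calls[100] <- "T"
#' detect_diagnostics(calls, ref, pan)
#' @export
detect_diagnostics <- function(consensus, ref, panel) {
  calls <- if (inherits(consensus, "consensus_seq")) consensus$calls
           else as.character(consensus)
  if (any(panel$position < 1 | panel$position > ref$length))
    stop("panel position outside reference range", call. = FALSE)
  obs <- calls[panel$position]
  state <- ifelse(obs == "N", "uncallable",
           ifelse(obs == panel$alt, "derived",
           ifelse(obs == panel$ref, "ancestral", "other")))
  out <- cbind(panel, observed = obs, state = state)
  rownames(out) <- NULL
  attr(out, "n_derived") <- sum(state == "derived")
  out
}

#' Assign a mitochondrial haplogroup from hierarchical panels
#'
#' A clade matches when every *callable* variant of its own panel and of all
#' ancestral panels is in the derived state, and each panel in the chain has
#' at least `min_completeness` of its positions callable (uncallable never
#' counts for or against a panel).  The most-derived matching clade is
#' assigned; several maximal matching clades give status `ambiguous`, none
#' gives `unassigned`.
#'
#' @param consensus A `consensus_seq` or per-position call vector.
#' @param ref A `ref_genome`.
#' @param panels A `diagnostic_panels` table.
#' @param min_completeness Minimum callable fraction per panel (robustness
#'   floor for degraded consensi).
#' @param specimen_id Label carried into the result.
#' @return An `mt_call`: list with `specimen_id`, `haplogroup`, `status`
#'   (`assigned` / `ambiguous` / `unassigned`), `completeness` (over the
#'   assigned chain, or overall minimum), and `detail` (per-panel match
#'   table).
#' @export
assign_mt_haplogroup <- function(consensus, ref, panels,
                                 min_completeness = 0.8,
                                 specimen_id = NA_character_) {
  labs <- unique(panels$haplogroup)
  if (!length(labs)) stop("no panels loaded", call. = FALSE)

  per_panel <- lapply(labs, function(l) {
    d <- detect_diagnostics(consensus, ref,
                            panel_variants(panels, l, with_ancestors = FALSE))
    callable <- d$state != "uncallable"
    list(label = l,
         complete = mean(callable),
         all_derived = all(d$state[callable] == "derived") && any(callable))
  })
  names(per_panel) <- labs

  chain_matches <- function(l) {
    all(vapply(panel_chain(panels, l), function(a) {
      p <- per_panel[[a]]
      p$complete >= min_completeness && p$all_derived
    }, logical(1)))
  }
  matching <- labs[vapply(labs, chain_matches, logical(1))]

  # maximal = matching clades that are not an ancestor of another match
  is_ancestor_of_match <- vapply(matching, function(l)
    any(vapply(setdiff(matching, l), function(m)
      l %in% panel_chain(panels, m), logical(1))), logical(1))
  maximal <- matching[!is_ancestor_of_match]

  detail <- data.frame(
    haplogroup = labs,
    completeness = vapply(per_panel, `[[`, numeric(1), "complete"),
    all_derived = vapply(per_panel, `[[`, logical(1), "all_derived"))

  if (length(maximal) == 1L) {
    chain <- panel_chain(panels, maximal)
    # hierarchy soundness: every ancestor of the assignment must match too
    stopifnot(all(chain %in% matching))
    comp <- min(detail$completeness[detail$haplogroup %in% chain])
    status <- "assigned"
    label <- maximal
  } else {
    comp <- min(detail$completeness)
    status <- if (length(maximal) > 1L) "ambiguous" else "unassigned"
    label <- NA_character_
  }
  structure(list(specimen_id = specimen_id, haplogroup = label,
                 status = status, completeness = comp, detail = detail,
                 maximal = maximal),
            class = "mt_call")
}

#' @export
print.mt_call <- function(x, ...) {
  cat(sprintf("<mt_call> %s: %s (%s, completeness %.2f)\n",
              x$specimen_id %||% "?",
              if (is.na(x$haplogroup)) x$status else x$haplogroup,
              x$status, x$completeness))
  invisible(x)
}

#' Y-chromosome marker definitions and haplogroup table
#'
#' The main taurine/indicine Y lineages are typed from seven markers spread
#' over five intron regions (DDX3Y introns 1 and 7, UTY intron 19, ZFY
#' introns 9 and 10): five SNPs, one (AT)n microsatellite and one 2-base
#' indel.  `default_y_markers()` returns the marker anchor table used by both
#' the region simulator and the genotyper; `default_y_table()` returns the
#' three haplogroup allele rows (Y1/Y2 taurine, Y3 indicine):
#' Y1 = C/(AT)x10/C/C/C/C/absent, Y2 = C/(AT)x10/C/A/C/C/present,
#' Y3 = T/(AT)x8/T/A/T/T/present.
#'
#' Marker anchors are declared per region in that region's own 1-based
#' coordinate frame; `ref_len` is the uninserted region length the indel
#' caller compares against.  The published anchor sources name the two ZFY
#' introns inconsistently (9/10 in table headers versus 4/5 in a footnote);
#' the neutral ids `zfy9`/`zfy10` from the table headers are used here.
#'
#' @return Data frames, see Details.
#' @export
default_y_markers <- function() {
  data.frame(
    marker = c("ddx3y1_snp", "ddx3y1_at_repeat", "ddx3y7_snp", "uty19_snp",
               "zfy9_snp", "zfy10_snp", "zfy10_indel"),
    region = c("ddx3y1", "ddx3y1", "ddx3y7", "uty19",
               "zfy9", "zfy10", "zfy10"),
    type = c("snp", "microsat", "snp", "snp", "snp", "snp", "indel"),
    anchor = c(425L, 363L, 165L, 423L, 120L, 609L, 651L),
    ref_len = c(700L, 700L, 500L, 650L, 600L, 717L, 717L),
    motif = c(NA, "AT", NA, NA, NA, NA, "GT")
  )
}

#' @rdname default_y_markers
#' @export
default_y_table <- function() {
  data.frame(
    haplogroup = c("Y1", "Y2", "Y3"),
    ddx3y1_snp = c("C", "C", "T"),
    ddx3y1_at_repeat = c(10L, 10L, 8L),
    ddx3y7_snp = c("C", "C", "T"),
    uty19_snp = c("C", "A", "A"),
    zfy9_snp = c("C", "C", "T"),
    zfy10_snp = c("C", "C", "T"),
    zfy10_indel = c("absent", "present", "present")
  )
}

#' Genotype the Y markers from per-region consensus sequences
#'
#' SNP states are read at their anchors; the microsatellite state is the
#' length, in repeat units, of the maximal uninterrupted run of the motif
#' containing the anchor; the indel is `present` when the region is two bases
#' longer than its uninserted length and the motif sits at the anchor,
#' `absent` when the region has the uninserted length, otherwise uncallable.
#' Missing regions leave the affected markers uncallable; a vector is always
#' returned.
#'
#' @param regions Named list/vector of region consensus sequences (characters
#'   over A/C/G/T/N), named as in `markers$region`.
#' @param markers Marker definition table (see [default_y_markers()]).
#' @return A `y_allele_vector`: named list of marker states with a `callable`
#'   logical vector attached.
#' @examples
#' regs <- make_y_regions("Y2", seed = 1)
#' genotype_y_markers(regs)
#' @export
genotype_y_markers <- function(regions, markers = default_y_markers()) {
  regions <- lapply(regions, as.character)
  states <- setNames(vector("list", nrow(markers)), markers$marker)
  callable <- setNames(logical(nrow(markers)), markers$marker)
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    seqr <- regions[[m$region]]
    if (is.null(seqr) || !nzchar(seqr)) {
      states[[m$marker]] <- NA
      next
    }
    if (m$type == "snp") {
      b <- substr(seqr, m$anchor, m$anchor)
      states[[m$marker]] <- b
      callable[m$marker] <- b %in% c("A", "C", "G", "T")
    } else if (m$type == "microsat") {
      n <- motif_run_units(seqr, m$anchor, m$motif)
      states[[m$marker]] <- n
      callable[m$marker] <- !is.na(n) && n > 0
    } else {  # indel
      len <- nchar(seqr)
      at_anchor <- substr(seqr, m$anchor, m$anchor + nchar(m$motif) - 1L)
      if (len == m$ref_len + nchar(m$motif) && at_anchor == m$motif) {
        states[[m$marker]] <- "present"; callable[m$marker] <- TRUE
      } else if (len == m$ref_len) {
        states[[m$marker]] <- "absent"; callable[m$marker] <- TRUE
      } else {
        states[[m$marker]] <- NA
      }
    }
  }
  structure(states, callable = callable, class = "y_allele_vector")
}

# Length, in motif units, of the maximal uninterrupted motif run containing
# the anchor (anchor assumed on a unit boundary).
motif_run_units <- function(seqr, anchor, motif) {
  w <- nchar(motif)
  if (substr(seqr, anchor, anchor + w - 1L) != motif) return(0L)
  n <- 1L
  while (anchor + (n + 1L) * w - 1L <= nchar(seqr) &&
         substr(seqr, anchor + n * w, anchor + (n + 1L) * w - 1L) == motif)
    n <- n + 1L
  back <- 0L
  while (anchor - (back + 1L) * w >= 1L &&
         substr(seqr, anchor - (back + 1L) * w,
                anchor - back * w - 1L) == motif)
    back <- back + 1L
  n + back
}

#' Assign a Y haplogroup from a marker vector
#'
#' Callable markers are matched exactly against the three haplogroup rows; if
#' exactly one row is consistent with every callable marker and at least
#' `min_callable` markers are callable, that haplogroup is assigned.
#' Evaluation is independent of marker order.
#'
#' @param v A `y_allele_vector` (or named list of the seven marker states).
#' @param table Haplogroup allele rows (see [default_y_table()]).
#' @param min_callable Robustness floor on the number of callable markers.
#' @return Character scalar: `"Y1"`, `"Y2"`, `"Y3"` or `"unassigned"`.
#' @examples
#' assign_y_haplogroup(list(ddx3y1_snp = "C", ddx3y1_at_repeat = 10,
#'                          ddx3y7_snp = "C", uty19_snp = "A",
#'                          zfy9_snp = "C", zfy10_snp = "C",
#'                          zfy10_indel = "present"))
#' @export
assign_y_haplogroup <- function(v, table = default_y_table(),
                                min_callable = 4) {
  markers <- setdiff(names(table), "haplogroup")
  callable <- attr(v, "callable")
  if (is.null(callable)) {
    callable <- vapply(markers, function(m)
      !is.null(v[[m]]) && !is.na(v[[m]]) &&
        !(is.character(v[[m]]) && v[[m]] == "N"), logical(1))
    names(callable) <- markers
  }
  use <- markers[callable[markers]]
  if (length(use) < min_callable) return("unassigned")
  consistent <- vapply(seq_len(nrow(table)), function(r)
    all(vapply(use, function(m)
      as.character(v[[m]]) == as.character(table[r, m]), logical(1))),
    logical(1))
  if (sum(consistent) == 1L) table$haplogroup[consistent] else "unassigned"
}

#' Simulate the five Y intron regions for a haplogroup
#'
#' Generates the synthetic intron set (total 3167 uninserted bases; 3169 with
#' the 2-base indel present, as for Y2/Y3) carrying the marker states of the
#' requested haplogroup: SNP bases at their anchors, the (AT)n microsatellite
#' at its anchor with flanking run-breakers, and the optional GT insertion.
#'
#' @param haplogroup `"Y1"`, `"Y2"` or `"Y3"`.
#' @param seed Integer seed for the background sequence.
#' @param markers Marker definitions; `table` the allele rows.
#' @param table Haplogroup allele table.
#' @return Named list of region sequences.
#' @export
make_y_regions <- function(haplogroup, seed = 1,
                           markers = default_y_markers(),
                           table = default_y_table()) {
  row <- table[table$haplogroup == haplogroup, ]
  if (nrow(row) != 1L) stop("unknown Y haplogroup: ", haplogroup, call. = FALSE)
  lens <- tapply(markers$ref_len, markers$region, unique)
  regions <- lapply(names(lens), function(rn) {
    withr_seed(derive_seed(seed, rn), {
      paste(sample(c("A", "C", "G", "T"), lens[[rn]], replace = TRUE),
            collapse = "")
    })
  })
  names(regions) <- names(lens)

  set_at <- function(s, pos, val) {
    paste0(substr(s, 1, pos - 1), val, substr(s, pos + nchar(val), nchar(s)))
  }
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    st <- row[[m$marker]]
    if (m$type == "snp") {
      regions[[m$region]] <- set_at(regions[[m$region]], m$anchor, st)
    } else if (m$type == "microsat") {
      run <- strrep(m$motif, st)
      # run-breakers on both flanks so the maximal run is exactly st units
      block <- paste0("GC", run, "GC")
      regions[[m$region]] <- set_at(regions[[m$region]], m$anchor - 2L, block)
    } else if (m$type == "indel" && st == "present") {
      s <- regions[[m$region]]
      regions[[m$region]] <- paste0(substr(s, 1, m$anchor - 1), m$motif,
                                    substr(s, m$anchor, nchar(s)))
    }
  }
  # the insertion must not extend an adjacent identical 2-mer; the anchor
  # flanks are fixed to break any accidental run
  regions
}
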