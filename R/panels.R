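#' Diagnostic variant panels
#'
#' A panel set is the classifier's rule base: for each haplogroup, the
#' diagnostic variants (1-based position on the reference, ancestral and
#' derived allele, mutation class) plus an optional parent label giving the
#' clade hierarchy (e.g. T1a/T1b/T1d descend from T1, which descends from the
#' ancestral T123 node).  The generator and the classifier consume the same
#' panel table, so simulation tests are closed-loop.
#'
#' `diagnostic_panels()` validates a data frame with columns `haplogroup`,
#' `parent` (NA for a root), `position`, `ref`, `alt`, `class`
#' (`transition`, `transversion`, `insertion` or `deletion`).
#'
#' @param df Data frame as described above.
#' @param ref_length Optional reference length used to range-check positions.
#' @return A `diagnostic_panels` object (validated data frame).
#' @examples
#' p <- default_panels()
#' panel_chain(p, "T1b")
#' @export
diagnostic_panels <- function(df, ref_length = NULL) {
  need <- c("haplogroup", "parent", "position", "ref", "alt", "class")
  if (!all(need %in% names(df)))
    stop("panel table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, need]
  df$haplogroup <- as.character(df$haplogroup)
  df$parent <- as.character(df$parent)
  df$parent[df$parent %in% c("", "NA", ".")] <- NA_character_
  df$position <- as.integer(df$position)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$class <- as.character(df$class)

  if (any(df$ref == df$alt))
    stop("ref allele must differ from derived allele", call. = FALSE)
  if (!all(df$class %in% c("transition", "transversion", "insertion", "deletion")))
    stop("unknown variant class", call. = FALSE)
  ti <- df$class == "transition"
  pair <- paste0(pmin(df$ref[ti], df$alt[ti]), pmax(df$ref[ti], df$alt[ti]))
  if (!all(pair %in% c("AG", "CT")))
    stop("transitions are restricted to A<->G and C<->T", call. = FALSE)
  if (!is.null(ref_length) && any(df$position < 1 | df$position > ref_length))
    stop("panel position outside reference range", call. = FALSE)

  # parent labels must resolve and the hierarchy must be acyclic
  labs <- unique(df$haplogroup)
  parents <- setNames(df$parent[!duplicated(df$haplogroup)], labs)
  bad <- setdiff(stats::na.omit(unique(df$parent)), labs)
  if (length(bad))
    stop("unknown parent haplogroup(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (l in labs) {
    seen <- character()
    cur <- l
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic parent links in panel hierarchy", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  structure(df, class = c("diagnostic_panels", "data.frame"))
}

#' @rdname diagnostic_panels
#' @param path Tab-separated panel file with the schema columns.
#' @export
read_panels <- function(path, ref_length = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  diagnostic_panels(df, ref_length = ref_length)
}

#' @rdname diagnostic_panels
#' @param panels A `diagnostic_panels` object.
#' @export
write_panels <- function(panels, path) {
  utils::write.table(panels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname diagnostic_panels
#' @details `default_panels()` returns the panel set shipped with the package.
#'   Only the two T1b transitions at positions 7,542 and 16,022 are
#'   literature-derived coordinates on the bovine reference frame; every other
#'   panel is synthetic (clearly non-biological), chosen to exercise the
#'   T123/T1/T3 hierarchy with sub-clades T1a/T1b/T1d and an I outgroup.
#' @export
default_panels <- function() {
  path <- system.file("extdata", "panels_synthetic.tsv", package = "paleobov")
  read_panels(path)
}

#' @rdname diagnostic_panels
#' @param label Haplogroup label.
#' @return `panel_chain()`: labels from root to `label`; `panel_variants()`:
#'   the variant rows for `label`, optionally including all ancestors'.
#' @export
panel_chain <- function(panels, label) {
  parents <- setNames(panels$parent[!duplicated(panels$haplogroup)],
                      unique(panels$haplogroup))
  if (!label %in% names(parents))
    stop("unknown haplogroup label: ", label, call. = FALSE)
  chain <- character()
  cur <- label
  while (!is.na(cur)) {
    chain <- c(cur, chain)
    cur <- parents[[cur]]
  }
  chain
}

#' @rdname diagnostic_panels
#' @param with_ancestors Include ancestral panels' variants.
#' @export
panel_variants <- function(panels, label, with_ancestors = TRUE) {
  labs <- if (with_ancestors) panel_chain(panels, label) else label
  out <- panels[panels$haplogroup %in% labs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rewrite a reference so panel reference alleles hold
#'
#' The haplotype generator requires the reference base at every panel position
#' to equal the panel's stated ancestral allele.  On a random synthetic
#' reference that is not automatically true, so the positions are rewritten
#' first; the edited positions are recorded in attribute `panel_edits`.
#'
#' @param ref A `ref_genome`.
#' @param panels A `diagnostic_panels` object.
#' @return The (possibly edited) `ref_genome` with attribute `panel_edits`.
#' @export
apply_panel_refs <- function(ref, panels) {
  s <- strsplit(ref$sequence, "")[[1]]
  idx <- panels$position
  if (any(idx < 1 | idx > ref$length))
    stop("panel position outside reference range", call. = FALSE)
  edited <- idx[s[idx] != panels$ref]
  s[idx] <- panels$ref
  out <- new_ref_genome(ref$name, paste(s, collapse = ""), ref$circular)
  attr(out, "panel_edits") <- sort(unique(edited))
  out
}
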