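#' Build a cohort of haplotypes and read sets
#'
#' `make_cohort()` realises one haplotype and one damaged read set per row of
#' a cohort specification, with per-specimen seeds derived from the cohort
#' seed by stable string hashing so any row is reproducible in isolation.
#'
#' @param spec Data frame with columns `specimen_id`, `haplogroup`,
#'   `n_private` and optionally `seed` (absent seeds are derived).
#' @param ref A `ref_genome`.
#' @param panels A `diagnostic_panels` table; every `haplogroup` label in
#'   `spec` must resolve to a panel.
#' @param params A [damage_params()] object.
#' @param seed Cohort seed used to derive missing per-specimen seeds.
#' @param simulate Also simulate reads (set `FALSE` to build haplotypes only).
#' @return A `cohort` object: list with `specimens` (per specimen: `haplotype`,
#'   `sim`) and `manifest` (data frame `specimen_id`, `true_haplogroup`,
#'   `seed`).
#' @examples
#' ref <- make_reference(2000, 0.4, 1)
#' pan <- diagnostic_panels(data.frame(
#'   haplogroup = "X", parent = NA, position = 55,
#'   ref = "C", alt = "T", class = "transition"))
#' co <- make_cohort(data.frame(specimen_id = "s1", haplogroup = "X",
#'                              n_private = 1),
#'                   ref, pan, damage_params(coverage = 2), seed = 4)
#' co$manifest
#' @export
make_cohort <- function(spec, ref, panels, params, seed = 1, simulate = TRUE) {
  spec <- as.data.frame(spec)
  if (nrow(spec) == 0L) {
    return(structure(list(specimens = list(),
                          manifest = data.frame(specimen_id = character(),
                                                true_haplogroup = character(),
                                                seed = integer())),
                     class = "cohort"))
  }
  if (anyDuplicated(spec$specimen_id))
    stop("specimen ids must be unique", call. = FALSE)
  unknown <- setdiff(unique(spec$haplogroup), unique(panels$haplogroup))
  if (length(unknown))
    stop("unknown haplogroup label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(spec$seed)) spec$seed <- NA_integer_
  spec$seed <- ifelse(is.na(spec$seed),
                      vapply(spec$specimen_id, function(id)
                        derive_seed(seed, id), integer(1)),
                      as.integer(spec$seed))

  specimens <- lapply(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    extra <- attr(spec, "extra_variants")[[row$specimen_id]]
    excl <- attr(spec, "exclude_private") %||% integer()
    hap <- make_haplotype(ref, panels, row$haplogroup,
                          n_private = row$n_private, seed = row$seed,
                          extra_variants = extra, exclude = excl)
    sim <- if (simulate)
      simulate_reads(hap, params, seed = row$seed, read_prefix = row$specimen_id)
    list(haplotype = hap, sim = sim)
  })
  names(specimens) <- spec$specimen_id

  structure(
    list(specimens = specimens,
         manifest = data.frame(specimen_id = spec$specimen_id,
                               true_haplogroup = spec$haplogroup,
                               seed = spec$seed)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$true_haplogroup)
  cat(sprintf("<cohort> %d specimens (%s)\n", nrow(x$manifest),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' The 21-specimen colonial cohort roster
#'
#' A synthetic stand-in for the archaeological roster the pipeline is designed
#' around: 21 specimens with haplogroup composition 14 x T3, 6 x T1-family
#' (four T1, one T1b, one T1d) and 1 x T123, and a control-region (D-loop)
#' haplotype structure of 18 distinct haplotypes with multiplicities
#' {3, 2, 1 x 16}.  The D-loop structure is engineered deterministically: one
#' trio and one pair of T3 specimens share their D-loop sequence, every other
#' specimen carries a unique D-loop variant at a reserved position; random
#' private mutations are placed outside the D-loop so they cannot disturb the
#' multiplicity profile.
#'
#' @param ref A `ref_genome` (the D-loop is taken as its last `dloop_bp`
#'   bases).
#' @param panels Panel table (defaults to the shipped synthetic panels).
#' @param params [damage_params()] for read simulation.
#' @param seed Cohort seed.
#' @param n_private Random private mutations per specimen (outside the
#'   D-loop).
#' @param dloop_bp Control-region width in bases.
#' @param simulate Simulate reads as well.
#' @return `colonial_cohort_spec()`: the cohort specification data frame with
#'   the D-loop engineering attached as attributes; `make_colonial_cohort()`:
#'   the realised `cohort` with attribute `dloop` (c(start, end)).
#' @export
make_colonial_cohort <- function(ref, panels = default_panels(),
                                 params = damage_params(), seed = 1,
                                 n_private = 3, dloop_bp = 700,
                                 simulate = TRUE) {
  spec <- colonial_cohort_spec(ref, panels, seed = seed,
                               n_private = n_private, dloop_bp = dloop_bp)
  co <- make_cohort(spec, ref, panels, params, seed = seed, simulate = simulate)
  attr(co, "dloop") <- attr(spec, "dloop")
  co
}

#' @rdname make_colonial_cohort
#' @export
colonial_cohort_spec <- function(ref, panels = default_panels(), seed = 1,
                                 n_private = 3, dloop_bp = 700) {
  L <- ref$length
  ds <- L - dloop_bp + 1L
  dloop <- c(ds, L)

  ids <- c(sprintf("PuertoReal%02d", 1:5), sprintf("Xochimilco%02d", 6:9),
           "JustoSierra10", "BellasArtes11", "BellasArtes12",
           "Merida14", "Merida16",                      # 14 x T3
           "JustoSierra15", "Merida17", "Merida18", "Merida19",  # 4 x T1
           "BellasArtes24",                             # T1b
           "JustoSierra21",                             # T1d
           "Merida13")                                  # T123
  hg <- c(rep("T3", 14), rep("T1", 4), "T1b", "T1d", "T123")
  spec <- data.frame(specimen_id = ids, haplogroup = hg,
                     n_private = n_private)

  # D-loop engineering: trio and pair share their D-loop; the other 16 get a
  # unique deterministic transition each at reserved, panel-free positions.
  share3 <- ids[1:3]
  share2 <- ids[4:5]
  singles <- setdiff(ids, c(share3, share2))
  s <- strsplit(apply_panel_refs(ref, panels)$sequence, "")[[1]]
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  reserved <- ds + 40L + 20L * seq_len(30)
  reserved <- setdiff(reserved, panels$position)
  extra <- setNames(vector("list", length(ids)), ids)
  p2 <- ds + 13L
  stopifnot(!p2 %in% panels$position)
  for (id in share2)
    extra[[id]] <- data.frame(position = p2, alt = ti[[s[p2]]])
  for (i in seq_along(singles)) {
    p <- reserved[i]
    extra[[singles[i]]] <- data.frame(position = p, alt = ti[[s[p]]])
  }

  attr(spec, "extra_variants") <- extra
  attr(spec, "exclude_private") <- seq.int(ds, L)
  attr(spec, "dloop") <- dloop
  spec
}

#' Write a cohort to disk
#'
#' One FASTQ and one truth SAM per specimen plus a `manifest.tsv`
#' (`specimen_id`, `true_haplogroup`, `seed`) and a `haplotypes.fasta` of the
#' true haplotypes.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @param ref The `ref_genome` used (for SAM headers).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ref) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$specimens)) {
    sp <- cohort$specimens[[id]]
    if (!is.null(sp$sim)) {
      write_fastq(sp$sim, file.path(dir, paste0(id, ".fastq")))
      write_truth_sam(sp$sim, ref, file.path(dir, paste0(id, ".truth.sam")))
    }
  }
  haps <- vapply(cohort$specimens, function(sp) as.character(sp$haplotype),
                 character(1))
  if (length(haps)) write_fasta(haps, file.path(dir, "haplotypes.fasta"))
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
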