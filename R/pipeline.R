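config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("paleobov_config_error", "error")))
}

#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end pipeline.  The
#' defaults are the package's standard settings: mapping quality >= 30, at
#' most 5\% mismatches and 5\% gap columns per read, 75\% consensus threshold
#' with minimum depth 3, and a 700 bp control-region window at the end of the
#' circular reference for diversity summaries.  Invalid values or missing
#' referenced files raise a *config* error (condition class
#' `paleobov_config_error`), distinct from runtime failures.
#'
#' @param outdir Run directory (created by [run_pipeline()]).
#' @param seed Master seed for every stochastic stage.
#' @param reference Path to a reference FASTA, or `NULL` to generate a
#'   synthetic circular reference of `ref_length` bases.
#' @param ref_length,gc Synthetic-reference parameters (used when
#'   `reference` is `NULL`).
#' @param panels Path to a panel TSV, or `NULL` for the shipped synthetic
#'   panels.
#' @param cohort `"colonial"` for the built-in 21-specimen roster, or the
#'   path of a cohort spec TSV (`specimen_id`, `haplogroup`, `n_private`).
#' @param damage Named list of [damage_params()] overrides.
#' @param k,band Mapper seed length and window half-width.
#' @param min_mapq,max_mismatch_frac,max_gap_frac Alignment filters.
#' @param consensus_threshold,min_depth Consensus-calling rule.
#' @param dloop_bp Control-region width for diversity/network summaries.
#' @param damage_min_terminal,damage_decay_positions Authenticity rule.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, reference = NULL,
                            ref_length = 16338, gc = 0.4, panels = NULL,
                            cohort = "colonial", damage = list(),
                            k = 13, band = 16, min_mapq = 30,
                            max_mismatch_frac = 0.05, max_gap_frac = 0.05,
                            consensus_threshold = 0.75, min_depth = 3,
                            dloop_bp = 700, damage_min_terminal = 0.05,
                            damage_decay_positions = 5) {
  if (missing(outdir) || !nzchar(outdir)) config_error("`outdir` is required")
  if (!is.null(reference) && !file.exists(reference))
    config_error("reference file not found: ", reference)
  if (!is.null(panels) && !file.exists(panels))
    config_error("panel file not found: ", panels)
  if (!identical(cohort, "colonial") && !file.exists(cohort))
    config_error("cohort spec file not found: ", cohort)
  if (min_mapq < 0 || min_mapq > 60) config_error("min_mapq out of range")
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1 ||
      max_gap_frac < 0 || max_gap_frac > 1)
    config_error("filter fractions must lie in [0, 1]")
  if (consensus_threshold <= 0.5 || consensus_threshold > 1)
    config_error("consensus_threshold must lie in (0.5, 1]")
  dp <- tryCatch(do.call(damage_params, damage),
                 error = function(e) config_error("bad damage params: ",
                                                  conditionMessage(e)))
  structure(
    list(outdir = outdir, seed = as.integer(seed), reference = reference,
         ref_length = as.integer(ref_length), gc = gc, panels = panels,
         cohort = cohort, damage = dp, k = as.integer(k),
         band = as.integer(band), min_mapq = min_mapq,
         max_mismatch_frac = max_mismatch_frac, max_gap_frac = max_gap_frac,
         consensus_threshold = consensus_threshold, min_depth = min_depth,
         dloop_bp = as.integer(dloop_bp),
         damage_min_terminal = damage_min_terminal,
         damage_decay_positions = damage_decay_positions),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  args <- yaml::read_yaml(path)
  bad <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(bad)) config_error("unknown config keys: ",
                                paste(bad, collapse = ", "))
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the cohort, then per specimen: maps reads to the
#' circular reference, applies the alignment filters, removes duplicates,
#' builds the pileup, calls the consensus, profiles damage and assigns the
#' mitochondrial haplogroup.  Cohort-level outputs are the haplogroup
#' frequency table, the control-region diversity report and the
#' median-joining network of control-region haplotypes.  Every machine output
#' is deterministic given the config seed (no timestamps are written); a
#' failure in one specimen is recorded and does not abort the others.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, a list with the per-specimen results, cohort tables and
#'   the run directory.  Files written under `config$outdir`:
#'   `<specimen>.consensus.fasta`, `<specimen>.calls.tsv`,
#'   `<specimen>.profile.tsv`, `cohort_calls.tsv`, `frequencies.tsv`,
#'   `diversity.tsv`, `network.nodes.tsv`, `network.edges.tsv`,
#'   `manifest.tsv` and `run_log.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  ref <- if (is.null(config$reference))
    make_reference(config$ref_length, config$gc,
                   seed = derive_seed(config$seed, "reference"))
  else read_reference(config$reference)
  panels <- if (is.null(config$panels)) default_panels()
            else read_panels(config$panels, ref_length = ref$length)
  ref <- apply_panel_refs(ref, panels)

  if (identical(config$cohort, "colonial")) {
    cohort <- make_colonial_cohort(ref, panels, config$damage,
                                   seed = config$seed,
                                   dloop_bp = config$dloop_bp)
  } else {
    spec <- utils::read.table(config$cohort, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    cohort <- make_cohort(spec, ref, panels, config$damage,
                          seed = config$seed)
  }
  utils::write.table(cohort$manifest, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_rows <- list()
  results <- list()
  for (id in names(cohort$specimens)) {
    results[[id]] <- tryCatch({
      sim <- cohort$specimens[[id]]$sim
      alns <- map_reads(sim, ref, k = config$k, band = config$band)
      filt <- filter_alignments(alns, config$max_mismatch_frac,
                                config$max_gap_frac, config$min_mapq)
      dedup <- deduplicate(filt)
      cons <- call_consensus(build_pileup(dedup, ref),
                             threshold = config$consensus_threshold,
                             min_depth = config$min_depth)
      # damage is profiled before the mismatch-cap filter: the cap clips the
      # most-damaged reads and would bias terminal rates downward
      prof <- misincorporation_profile(alns)
      verdict <- authenticity_check(prof, config$damage_min_terminal,
                                    config$damage_decay_positions)
      call <- assign_mt_haplogroup(cons, ref, panels, specimen_id = id)

      write_consensus_fasta(cons, file.path(config$outdir,
                                            paste0(id, ".consensus.fasta")),
                            name = id)
      write_call_table(cons, file.path(config$outdir,
                                       paste0(id, ".calls.tsv")))
      write_profile_tsv(prof, file.path(config$outdir,
                                        paste0(id, ".profile.tsv")))
      log_rows[[id]] <- data.frame(
        specimen = id, status = "ok", reads_in = nrow(sim$reads),
        mapped = nrow(alns), filtered = nrow(filt), deduped = nrow(dedup),
        n_frac = round(mean(cons$low_conf), 4),
        damage_verdict = verdict$verdict,
        mt_haplogroup = call$haplogroup %||% NA_character_,
        mt_status = call$status)
      list(consensus = cons, profile = prof, verdict = verdict, call = call)
    }, error = function(e) {
      log_rows[[id]] <<- data.frame(
        specimen = id, status = paste0("failed: ", conditionMessage(e)),
        reads_in = NA, mapped = NA, filtered = NA, deduped = NA, n_frac = NA,
        damage_verdict = NA, mt_haplogroup = NA, mt_status = NA)
      NULL
    })
  }

  ok <- !vapply(results, is.null, logical(1))
  calls_df <- do.call(rbind, lapply(results[ok], function(r)
    data.frame(specimen_id = r$call$specimen_id,
               haplogroup = r$call$haplogroup %||% NA_character_,
               status = r$call$status,
               completeness = round(r$call$completeness, 3),
               damage_verdict = r$verdict$verdict)))
  utils::write.table(calls_df, file.path(config$outdir, "cohort_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  freqs <- haplogroup_frequencies(
    data.frame(haplogroup = calls_df$haplogroup, status = calls_df$status))
  utils::write.table(freqs, file.path(config$outdir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # control-region diversity and network over the per-specimen consensi
  dloop <- c(ref$length - config$dloop_bp + 1L, ref$length)
  cons_seqs <- vapply(results[ok], function(r)
    paste(r$consensus$calls, collapse = ""), character(1))
  names(cons_seqs) <- names(results)[ok]
  report <- NULL; net <- NULL
  if (length(cons_seqs) >= 2) {
    report <- summarize_diversity(cons_seqs, region = dloop)
    write_diversity_tsv(report, freqs,
                        file.path(config$outdir, "diversity.tsv"))
    if (length(report$table$haplotypes) >= 2) {
      net <- median_joining(report$table)
      write_network_tsv(net, file.path(config$outdir, "network.nodes.tsv"),
                        file.path(config$outdir, "network.edges.tsv"))
    }
  }

  log_df <- do.call(rbind, log_rows)
  # the hash fingerprints the analysis, not where it was written
  cfg_flat <- config[setdiff(names(config), "outdir")]
  cfg_flat <- cfg_flat[!vapply(cfg_flat, is.null, logical(1))]
  cfg_string <- paste(names(cfg_flat),
                      vapply(cfg_flat, function(x)
                        paste(format(unlist(x)), collapse = ","),
                        character(1)),
                      sep = "=", collapse = ";")
  attr(log_df, "config_hash") <- config_hash <- digest_string(cfg_string)
  hdr <- c(sprintf("# paleobov %s", as.character(utils::packageVersion("paleobov"))),
           sprintf("# config_hash %s", config_hash))
  writeLines(c(hdr, paste(names(log_df), collapse = "\t"),
               apply(log_df, 1, paste, collapse = "\t")),
             file.path(config$outdir, "run_log.tsv"))

  invisible(list(ref = ref, panels = panels, cohort = cohort,
                 results = results, calls = calls_df, frequencies = freqs,
                 diversity = report, network = net, log = log_df,
                 outdir = config$outdir))
}

# Tiny stable string digest (djb2-style over UTF-8 bytes, hex); enough to
# fingerprint a config in the run log without external dependencies.
digest_string <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  format(as.hexmode(as.integer(h)), width = 8)
}
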