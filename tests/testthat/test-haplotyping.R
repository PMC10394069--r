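test_that("diagnostic detection distinguishes derived, ancestral and uncallable", {
  ref <- make_reference(16338, 0.4, seed = 7)
  pan <- default_panels()
  base <- strsplit(apply_panel_refs(ref, pan)$sequence, "")[[1]]
  t1b <- pan[pan$haplogroup == "T1b", ]

  calls <- base
  calls[c(7542, 16022)] <- t1b$alt[match(c(7542, 16022), t1b$position)]
  d <- detect_diagnostics(calls, ref, t1b)
  expect_equal(attr(d, "n_derived"), 2)
  expect_true(all(d$state == "derived"))

  d0 <- detect_diagnostics(base, ref, t1b)
  expect_equal(attr(d0, "n_derived"), 0)
  expect_true(all(d0$state == "ancestral"))

  calls_n <- calls
  calls_n[7542] <- "N"
  dn <- detect_diagnostics(calls_n, ref, t1b)
  expect_setequal(dn$state, c("uncallable", "derived"))
  expect_false("ancestral" %in% dn$state)

  bad <- t1b
  bad$position[1] <- 99999L
  expect_error(detect_diagnostics(calls, ref, bad), "outside")
})

test_that("haplogroup assignment picks the most-derived matching clade", {
  ref <- small_ref()
  pan <- small_panels()
  base <- strsplit(apply_panel_refs(ref, pan)$sequence, "")[[1]]

  to_derived <- function(calls, labels) {
    pv <- pan[pan$haplogroup %in% labels, ]
    calls[pv$position] <- pv$alt
    calls
  }

  callB <- assign_mt_haplogroup(to_derived(base, c("A", "B")), ref, pan)
  expect_equal(callB$haplogroup, "B")
  expect_equal(callB$status, "assigned")

  callA <- assign_mt_haplogroup(to_derived(base, "A"), ref, pan)
  expect_equal(callA$haplogroup, "A")

  # a genome matching two unrelated clades fully is ambiguous
  both <- assign_mt_haplogroup(to_derived(base, c("A", "C")), ref, pan)
  expect_equal(both$status, "ambiguous")
  expect_true(is.na(both$haplogroup))

  # nothing derived -> unassigned
  none <- assign_mt_haplogroup(base, ref, pan)
  expect_equal(none$status, "unassigned")

  # uncallable positions never count as ancestral, but completeness gates
  masked <- to_derived(base, c("A", "B"))
  masked[pan$position[pan$haplogroup == "A"]] <- "N"   # A panel 0/2 callable
  gated <- assign_mt_haplogroup(masked, ref, pan)
  expect_false(identical(gated$haplogroup, "B"))
})

test_that("cyclic panel hierarchies are rejected", {
  expect_error(diagnostic_panels(data.frame(
    haplogroup = c("P", "Q"), parent = c("Q", "P"),
    position = c(10L, 20L), ref = "C", alt = "T", class = "transition")),
    "cyclic")
})

test_that("microsatellite repeat counting uses the maximal run at the anchor", {
  pad <- function(core) paste0(strrep("G", 9), core, strrep("G", 400))
  # anchor at position 10
  seq10 <- pad(paste0(strrep("AT", 10), "GG"))
  expect_equal(paleobov:::motif_run_units(seq10, 10L, "AT"), 10L)
  seq8 <- pad(paste0(strrep("AT", 8), "GG"))
  expect_equal(paleobov:::motif_run_units(seq8, 10L, "AT"), 8L)
  # interrupted after 6 units
  seq6 <- pad(paste0(strrep("AT", 5), "AC", strrep("AT", 4)))
  expect_equal(paleobov:::motif_run_units(paste0(strrep("G",9), strrep("AT",6), "AC", strrep("AT",4), strrep("G",400)), 10L, "AT"), 6L)
})

test_that("the three published marker rows classify to Y1, Y2 and Y3", {
  rows <- list(
    Y1 = list(ddx3y1_snp = "C", ddx3y1_at_repeat = 10L, ddx3y7_snp = "C",
              uty19_snp = "C", zfy9_snp = "C", zfy10_snp = "C",
              zfy10_indel = "absent"),
    Y2 = list(ddx3y1_snp = "C", ddx3y1_at_repeat = 10L, ddx3y7_snp = "C",
              uty19_snp = "A", zfy9_snp = "C", zfy10_snp = "C",
              zfy10_indel = "present"),
    Y3 = list(ddx3y1_snp = "T", ddx3y1_at_repeat = 8L, ddx3y7_snp = "T",
              uty19_snp = "A", zfy9_snp = "T", zfy10_snp = "T",
              zfy10_indel = "present"))
  for (hg in names(rows))
    expect_equal(assign_y_haplogroup(rows[[hg]]), hg)

  # a repeat count matching no row leaves the vector unassigned
  off <- rows$Y2
  off$ddx3y1_at_repeat <- 9L
  expect_equal(assign_y_haplogroup(off), "unassigned")

  # permutation invariance of marker evaluation order
  perm <- rows$Y3[sample(names(rows$Y3))]
  expect_equal(assign_y_haplogroup(perm), "Y3")

  # too few callable markers
  sparse <- rows$Y2
  sparse[c("ddx3y1_snp", "ddx3y7_snp", "zfy9_snp", "zfy10_snp")] <- NA
  expect_equal(assign_y_haplogroup(sparse), "unassigned")
})

test_that("Y regions genotype back to their generating haplogroup", {
  for (hg in c("Y1", "Y2", "Y3")) {
    regs <- make_y_regions(hg, seed = 5)
    expect_equal(sum(nchar(unlist(regs))),
                 if (hg == "Y1") 3167L else 3169L)
    v <- genotype_y_markers(regs)
    expect_equal(assign_y_haplogroup(v), hg)
  }
  # a missing region leaves its markers uncallable but still returns a vector
  regs <- make_y_regions("Y2", seed = 6)
  regs$uty19 <- NULL
  v <- genotype_y_markers(regs)
  expect_false(attr(v, "callable")[["uty19_snp"]])
  # Y1 and Y2 differ only at UTY19 and the indel; dropping UTY19 keeps the
  # indel informative, so Y2 is still the unique consistent row
  expect_equal(assign_y_haplogroup(v), "Y2")
})

test_that("generator-to-assignment closed loop recovers every shipped panel", {
  ref <- make_reference(16338, 0.4, seed = 7)
  pan <- default_panels()
  labels <- unique(pan$haplogroup)
  cases <- expand.grid(label = labels, seed = c(1, 2, 3),
                       stringsAsFactors = FALSE)
  hits <- vapply(seq_len(nrow(cases)), function(i) {
    hap <- make_haplotype(ref, pan, cases$label[i], n_private = 3,
                          seed = cases$seed[i])
    sim <- simulate_reads(hap, damage_params(coverage = 30),
                          seed = cases$seed[i] + 100)
    alns <- deduplicate(filter_alignments(map_reads(sim, ref)))
    cons <- call_consensus(build_pileup(alns, ref))
    call <- assign_mt_haplogroup(cons, ref, pan)
    # hierarchy soundness: an assignment implies the whole chain matches
    if (call$status == "assigned") {
      chain <- panel_chain(pan, call$haplogroup)
      expect_true(all(chain %in% call$maximal |
                        chain %in% panel_chain(pan, call$haplogroup)))
    }
    identical(call$haplogroup, cases$label[i])
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
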