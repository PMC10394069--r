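test_that("make_reference honours length, GC target and determinism", {
  ref <- make_reference(16338, 0.4, seed = 7)
  expect_equal(ref$length, 16338)
  expect_equal(nchar(ref$sequence), 16338)
  expect_true(ref$circular)

  gc <- mean(strsplit(ref$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.02)

  expect_identical(ref$sequence, make_reference(16338, 0.4, seed = 7)$sequence)
  expect_false(identical(ref$sequence,
                         make_reference(16338, 0.4, seed = 8)$sequence))

  expect_error(make_reference(500, 0.4, 1), "length")
  expect_error(make_reference(2000, 1.2, 1), "gc")
})

test_that("make_haplotype differs from the reference exactly as specified", {
  ref <- small_ref()
  pan <- small_panels()

  hap <- make_haplotype(ref, pan, "A", n_private = 0, seed = 1)
  refseq <- apply_panel_refs(ref, pan)$sequence
  diffs <- which(strsplit(hap, "")[[1]] != strsplit(refseq, "")[[1]])
  expect_identical(diffs, c(150L, 900L))

  hap5 <- make_haplotype(ref, pan, "A", n_private = 5, seed = 3)
  d5 <- which(strsplit(hap5, "")[[1]] != strsplit(refseq, "")[[1]])
  expect_length(d5, 7)  # 2 panel + 5 private
  expect_false(any(setdiff(d5, c(150, 900)) %in% pan$position))
  # reproducible placement
  hap5b <- make_haplotype(ref, pan, "A", n_private = 5, seed = 3)
  expect_identical(as.character(hap5), as.character(hap5b))

  # child haplogroup carries its ancestors' variants too
  hapB <- make_haplotype(ref, pan, "B", n_private = 0, seed = 1)
  dB <- which(strsplit(hapB, "")[[1]] != strsplit(refseq, "")[[1]])
  expect_identical(dB, c(150L, 400L, 900L))
})

test_that("the shipped T1b panel places derived transitions at 7542 and 16022", {
  ref <- make_reference(16338, 0.4, seed = 7)
  pan <- default_panels()
  hap <- make_haplotype(ref, pan, "T1b", n_private = 0, seed = 1)
  s <- strsplit(as.character(hap), "")[[1]]
  t1b <- pan[pan$haplogroup == "T1b", ]
  expect_setequal(t1b$position, c(7542L, 16022L))
  expect_identical(s[7542], t1b$alt[t1b$position == 7542])
  expect_identical(s[16022], t1b$alt[t1b$position == 16022])
  # both are transitions
  expect_true(all(t1b$class == "transition"))
})

test_that("noise-free reads are exact circular substrings and depth is on target", {
  ref <- small_ref()
  sim <- simulate_reads(ref$sequence, noiseless_params(coverage = 30), seed = 5)

  doubled <- paste0(ref$sequence, ref$sequence)
  hits <- vapply(seq_len(nrow(sim$reads)), function(i) {
    r <- sim$reads$sequence[i]
    grepl(r, doubled, fixed = TRUE) ||
      grepl(paleobov:::revcomp(r), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  expect_equal(nrow(sim$changes), 0)

  depth <- sum(nchar(sim$reads$sequence)) / ref$length
  expect_gte(depth, 27)
  expect_lte(depth, 33)
})

test_that("truth records reproduce every read-versus-haplotype mismatch", {
  ref <- small_ref()
  sim <- simulate_reads(ref$sequence, damage_params(coverage = 5), seed = 9)
  observed <- do.call(rbind, lapply(seq_len(nrow(sim$reads)), function(i) {
    frag <- true_fragment(ref$sequence, sim$truth[i, ])
    a <- strsplit(frag, "")[[1]]
    b <- strsplit(sim$reads$sequence[i], "")[[1]]
    pos <- which(a != b)
    if (!length(pos)) return(NULL)
    data.frame(read_id = sim$reads$read_id[i], read_pos = pos,
               from = a[pos], to = b[pos])
  }))
  recorded <- sim$changes[order(sim$changes$read_id, sim$changes$read_pos),
                          c("read_id", "read_pos", "from", "to")]
  observed <- observed[order(observed$read_id, observed$read_pos), ]
  rownames(recorded) <- rownames(observed) <- NULL
  expect_equal(recorded, observed)
})

test_that("fragment lengths follow the log-normal model", {
  p <- damage_params(frag_mean = 70, frag_sd = 0.3, coverage = 1)
  # ~>10k fragments on a long reference
  ref <- make_reference(50000, 0.4, seed = 2)
  p_many <- damage_params(frag_mean = 70, frag_sd = 0.3, coverage = 20)
  sim <- simulate_reads(ref$sequence, p_many, seed = 4)
  expect_gt(nrow(sim$truth), 10000)
  expected_mean <- exp(log(70) + 0.3^2 / 2)
  expect_lt(abs(mean(sim$truth$length) - expected_mean) / expected_mean, 0.05)
})

test_that("terminal C->T rate matches the closed-form overhang model", {
  ref <- small_ref(4000, seed = 11)
  p <- damage_params(overhang_p = 0.3, delta_ss = 0.5, delta_ds = 0,
                     seq_error = 0, coverage = 60)
  sim <- simulate_reads(ref$sequence, p, seed = 13)
  # tally damage at read position 1 among reads whose first base was C
  firstC <- vapply(seq_len(nrow(sim$truth)), function(i)
    substr(true_fragment(ref$sequence, sim$truth[i, ]), 1, 1) == "C",
    logical(1))
  den <- sum(firstC)
  num <- sum(sim$changes$read_pos == 1 & sim$changes$from == "C" &
             sim$changes$to == "T")
  expected <- 0.5 * (1 - 0.3)   # delta_ss * P(overhang covers position 1)
  se <- sqrt(expected * (1 - expected) / den)
  expect_lt(abs(num / den - expected), 1.96 * se + 1e-9)
})

test_that("cohorts resolve labels, are deterministic, and report true counts", {
  ref <- small_ref()
  pan <- small_panels()
  par <- noiseless_params(coverage = 3)

  empty <- make_cohort(data.frame(specimen_id = character(),
                                  haplogroup = character(),
                                  n_private = integer()),
                       ref, pan, par)
  expect_length(empty$specimens, 0)
  expect_equal(nrow(empty$manifest), 0)

  expect_error(
    make_cohort(data.frame(specimen_id = "s", haplogroup = "ZZZ",
                           n_private = 0), ref, pan, par),
    "unknown haplogroup")

  spec <- data.frame(specimen_id = c("s1", "s2"), haplogroup = "A",
                     n_private = 1, seed = 77L)
  co <- make_cohort(spec, ref, pan, par, seed = 1)
  expect_identical(co$specimens$s1$sim$reads$sequence,
                   co$specimens$s2$sim$reads$sequence)

  co2 <- make_cohort(spec, ref, pan, par, seed = 999)
  expect_identical(co$specimens$s1$sim$reads$sequence,
                   co2$specimens$s1$sim$reads$sequence)
})

test_that("the colonial roster has the published composition", {
  ref <- make_reference(16338, 0.4, seed = 7)
  spec <- colonial_cohort_spec(ref)
  tab <- table(spec$haplogroup)
  expect_equal(unname(tab[["T3"]]), 14)
  expect_equal(sum(spec$haplogroup %in% c("T1", "T1b", "T1d")), 6)
  expect_equal(unname(tab[["T123"]]), 1)
  expect_equal(nrow(spec), 21)
})
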