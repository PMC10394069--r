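test_that("exact substrings map perfectly, including across the origin", {
  ref <- small_ref()
  L <- ref$length

  reads <- data.frame(
    read_id = c("exact", "wrap", "rc"),
    sequence = c(substr(ref$sequence, 501, 560),
                 paleobov:::circ_substr(ref$sequence, L - 20, 60),
                 paleobov:::revcomp(substr(ref$sequence, 801, 860))))
  alns <- map_reads(reads, ref)

  ex <- alns[alns$read_id == "exact", ]
  expect_equal(ex$ref_start, 501)
  expect_equal(ex$n_mismatch, 0)
  expect_equal(ex$mapq_proxy, 60)
  expect_equal(ex$strand, "+")

  wr <- alns[alns$read_id == "wrap", ]
  expect_equal(wr$ref_start, L - 20)
  expect_equal(wr$ref_end, 39)       # wrapped 1-based end
  expect_equal(wr$n_mismatch, 0)

  rc <- alns[alns$read_id == "rc", ]
  expect_equal(rc$ref_start, 801)
  expect_equal(rc$strand, "-")
  expect_equal(rc$n_mismatch, 0)
})

test_that("best mapping score equals an exhaustive alignment oracle", {
  ref <- small_ref(1200, seed = 3)
  short <- paleobov:::new_ref_genome("oracle_ref",
                                     substr(ref$sequence, 1, 200))
  sim <- simulate_reads(short$sequence,
                        damage_params(coverage = 6, seq_error = 0.01),
                        seed = 21)
  reads <- head(sim$reads, 30)
  alns <- map_reads(reads, short, k = 8)

  doubled <- paste0(short$sequence, short$sequence)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in seq_len(nrow(alns))) {
    q <- reads$sequence[reads$read_id == alns$read_id[i]]
    oracle <- max(vapply(c(q, paleobov:::revcomp(q)), function(qq)
      Biostrings::pairwiseAlignment(
        qq, doubled, type = "global-local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2, scoreOnly = TRUE), numeric(1)))
    expect_equal(alns$map_score[i], oracle)
  }
})

test_that("mapping filters apply the documented inclusive caps", {
  ref <- small_ref()
  fake <- paleobov:::as_read_alignments(data.frame(
    read_id = c("over", "boundary", "lowmapq", "clean"),
    ref_start = 1L, ref_end = 100L, strand = "+",
    map_score = 90L,
    mapq_proxy = c(60L, 60L, 29L, 60L),
    n_mismatch = c(6L, 5L, 0L, 0L),
    n_gap = c(0L, 5L, 0L, 0L),
    aln_len = 100L,
    read_aln = "", ref_aln = ""), ref)

  kept <- filter_alignments(fake)
  expect_setequal(kept$read_id, c("boundary", "clean"))  # 0.05 inclusive
  expect_false("over" %in% kept$read_id)     # 0.06 > 0.05
  expect_false("lowmapq" %in% kept$read_id)  # 29 < 30

  # idempotent and order-independent
  expect_identical(filter_alignments(kept)$read_id, kept$read_id)
  shuffled <- paleobov:::as_read_alignments(fake[c(3, 1, 4, 2), ], ref)
  expect_setequal(filter_alignments(shuffled)$read_id, kept$read_id)

  expect_equal(nrow(filter_alignments(fake[0, ])), 0)
  expect_error(filter_alignments(fake, max_mismatch_frac = 1.5), "fractions")
})

test_that("deduplication keeps one alignment per start/end/strand", {
  ref <- small_ref()
  base <- data.frame(
    ref_start = 10L, ref_end = 70L, strand = "+", map_score = 50L,
    mapq_proxy = 60L, n_mismatch = 0L, n_gap = 0L, aln_len = 61L,
    read_aln = "", ref_aln = "")

  dup2 <- paleobov:::as_read_alignments(
    cbind(read_id = c("r1", "r2"), rbind(base, base)), ref)
  expect_equal(nrow(deduplicate(dup2)), 1)

  both <- rbind(base, base)
  both$strand <- c("+", "-")
  strands <- paleobov:::as_read_alignments(
    cbind(read_id = c("p", "m"), both), ref)
  expect_equal(nrow(deduplicate(strands)), 2)

  six <- rbind(base, base, base, base, base,
               transform(base, ref_start = 200L, ref_end = 260L))
  mixed <- paleobov:::as_read_alignments(
    cbind(read_id = paste0("r", 1:6), six), ref)
  # brute-force oracle: distinct (start, end, strand) keys
  expect_equal(nrow(deduplicate(mixed)),
               nrow(unique(six[c("ref_start", "ref_end", "strand")])))

  # highest score survives, ties to smallest read id
  scored <- rbind(base, base, base)
  scored$map_score <- c(40L, 55L, 55L)
  tie <- paleobov:::as_read_alignments(
    cbind(read_id = c("za", "zb", "aa"), scored), ref)
  expect_identical(deduplicate(tie)$read_id, "aa")
})

test_that("pileups conserve depth and expose allele splits", {
  ref <- small_ref()
  one <- map_reads(data.frame(read_id = "r1",
                              sequence = substr(ref$sequence, 1, 60)), ref)
  pl <- build_pileup(one, ref)
  expect_equal(unname(pl$depth[1:60]), rep(1, 60))
  expect_equal(sum(pl$depth), 60)

  # depth conservation against covered-position indicators
  sim <- simulate_reads(ref$sequence, noiseless_params(coverage = 8), seed = 31)
  alns <- map_reads(sim, ref)
  pl2 <- build_pileup(alns, ref)
  expect_equal(sum(pl2$depth), sum(alns$aln_len - alns$n_gap))
  expect_lt(abs(mean(pl2$depth) - 8) / 8, 0.1)

  # overlapping reads disagreeing at one position give a split count
  s <- substr(ref$sequence, 101, 160)
  s2 <- s
  substr(s2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 30, 30))[1]
  two <- map_reads(data.frame(read_id = c("a", "b"), sequence = c(s, s2)),
                   ref)
  pl3 <- build_pileup(two, ref)
  expect_equal(sum(pl3$counts[, 130] > 0), 2)
  expect_equal(unname(pl3$depth[130]), 2)
})

test_that("SAM round trip preserves coordinates and read sequences", {
  ref <- small_ref()
  sim <- simulate_reads(ref$sequence, noiseless_params(coverage = 2), seed = 41)
  alns <- map_reads(sim, ref)
  path <- tempfile(fileext = ".sam")
  on.exit(unlink(path))
  write_sam(alns, path, reads = sim$reads)
  back <- read_sam(path)
  expect_equal(nrow(back), nrow(alns))
  expect_equal(back$pos, alns$ref_start)
  expect_true(any(grepl("^@SQ", attr(back, "header"))))
  # plus-strand sequences survive unchanged
  plus <- alns$strand == "+"
  expect_identical(
    back$seq[plus],
    sim$reads$sequence[match(alns$read_id[plus], sim$reads$read_id)])
})
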