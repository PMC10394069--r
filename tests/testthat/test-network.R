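make_variants <- function(base, positions, alt = "T") {
  s <- strsplit(base, "")[[1]]
  s[positions] <- alt
  paste(s, collapse = "")
}

test_that("collapse groups identical sequences and masks gap/N columns", {
  base <- strrep("A", 100)

  expect_equal(length(collapse_haplotypes(rep(c(x = base), 5))$haplotypes), 1)
  expect_equal(collapse_haplotypes(rep(c(x = base), 5))$multiplicity, 5L)

  # engineered multiplicity profile {3, 2, 1 x 16} over 21 sequences
  seqs <- c(rep(base, 3),
            rep(make_variants(base, 10), 2),
            vapply(1:16, function(i) make_variants(base, 20 + i), character(1)))
  names(seqs) <- sprintf("s%02d", 1:21)
  tab <- collapse_haplotypes(seqs)
  expect_equal(length(tab$haplotypes), 18)
  expect_equal(sort(tab$multiplicity, decreasing = TRUE),
               c(3L, 2L, rep(1L, 16)))
  expect_equal(sum(tab$multiplicity), 21)

  # sequences differing only at an N-containing column collapse together
  a <- make_variants(base, 50, "G")
  b <- make_variants(base, 50, "N")
  tab2 <- collapse_haplotypes(c(a = a, b = b))
  expect_equal(length(tab2$haplotypes), 1)
  expect_equal(tab2$dropped_sites, 50L)

  # region restriction happens before masking
  tab3 <- collapse_haplotypes(c(a = a, b = b), region = c(1, 40))
  expect_equal(length(tab3$included_sites), 40)

  expect_error(collapse_haplotypes(c(a = "NN", b = "NN")), "dropped")
  expect_error(collapse_haplotypes(c(a = "ACGT", b = "ACG")), "equal length")
})

test_that("minimum spanning networks keep all tied connecting edges", {
  # two haplotypes at distance 3: a single edge of weight 3
  two <- haplotype_table(c(h1 = "AAATTT", h2 = "AAAGGG"))
  net2 <- minimum_spanning_network(two)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$weight, 3)

  # three pairwise-equidistant haplotypes: all tied edges kept -> 3-cycle
  tri <- haplotype_table(c("AAC", "ACA", "CAA"))
  net3 <- minimum_spanning_network(tri)
  expect_equal(nrow(net3$edges), 3)
  expect_true(all(net3$edges$weight == 2))

  # brute-force check of the tie rule: every pair is a valid MST edge here
  expect_equal(length(unique(net3$components)), 1)
})

test_that("on tie-free tree-like data the MSN equals a standard MST oracle", {
  # chain s0 -s1 -s2 -s3 with branch lengths 1, 2, 4 at disjoint sites:
  # all pairwise distances are distinct subset sums
  s0 <- strrep("A", 60)
  s1 <- make_variants(s0, 1)
  s2 <- make_variants(s1, 2:3)
  s3 <- make_variants(s2, 4:7)
  tab <- haplotype_table(c(s0 = s0, s1 = s1, s2 = s2, s3 = s3))
  net <- minimum_spanning_network(tab)

  d <- paleobov:::hamming_matrix(tab$haplotypes)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst_w <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(net$total_length, mst_w)
  expect_equal(nrow(net$edges), 3)
})

test_that("median joining solves the binary triple against a Steiner oracle", {
  tab <- haplotype_table(c(s1 = "000", s2 = "110", s3 = "101"))
  net <- median_joining(tab)

  medians <- net$nodes[net$nodes$inferred, ]
  expect_equal(nrow(medians), 1)
  expect_equal(medians$sequence, "100")
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(net$total_length, 3)

  # exhaustive Steiner search: try every set of <= 2 auxiliary binary vectors
  obs <- c("000", "110", "101")
  all_vec <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  net_len <- function(ss) {
    names(ss) <- paste0("n", seq_along(ss))
    sum(paleobov:::msn_edges(paleobov:::hamming_matrix(ss))$weight)
  }
  cand_sets <- c(list(character(0)), as.list(all_vec),
                 utils::combn(all_vec, 2, simplify = FALSE))
  oracle <- min(vapply(cand_sets, function(aux) net_len(c(obs, aux)),
                       numeric(1)))
  expect_equal(net$total_length, oracle)

  # adding the median beat the median-free network (length 4 as a tree)
  expect_lt(net$total_length, net_len(obs))
})

test_that("two haplotypes give a single edge and no medians", {
  tab <- haplotype_table(c(a = "AAAA", b = "AATT"))
  net <- median_joining(tab)
  expect_equal(nrow(net$nodes), 2)
  expect_false(any(net$nodes$inferred))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
})

test_that("clade structure separates families in the network", {
  ref <- make_reference(16338, 0.4, seed = 7)
  pan <- default_panels()
  labs <- c("T1", "T1a", "T1b", "T1d", "T3")
  haps <- vapply(labs, function(l)
    as.character(make_haplotype(ref, pan, l, n_private = 0, seed = 1)),
    character(1))
  d <- paleobov:::hamming_matrix(haps)
  t1fam <- labs != "T3"
  intra <- d[t1fam, t1fam][upper.tri(d[t1fam, t1fam])]
  inter <- d[t1fam, !t1fam]
  expect_lt(max(intra), min(inter))

  net <- median_joining(haplotype_table(haps))
  expect_equal(length(unique(net$components)), 1)
})

test_that("network exports carry multiplicities, flags and weights", {
  tab <- haplotype_table(c(s1 = "000", s2 = "110", s3 = "101", s4 = "000"))
  net <- median_joining(tab)
  nodes_path <- tempfile(); edges_path <- tempfile(); gml <- tempfile()
  on.exit(unlink(c(nodes_path, edges_path, gml)))
  write_network_tsv(net, nodes_path, edges_path)
  nodes <- read.table(nodes_path, header = TRUE, sep = "\t",
                      colClasses = c(sequence = "character"))
  expect_equal(sum(nodes$multiplicity), 4)
  expect_equal(sum(nodes$inferred), 1)
  write_network_graphml(net, gml)
  doc <- xml2::read_xml(gml)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")),
               nrow(net$edges))
})
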