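#' Collapse aligned sequences into haplotypes
#'
#' Restricts equal-length aligned sequences to an optional region, drops every
#' column containing a character outside the allowed alphabet (gaps, N) in
#' *any* sequence, and groups identical restricted sequences into haplotypes.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param region Optional 1-based inclusive interval `c(start, end)` (or a
#'   list of such intervals) selecting columns before filtering.
#' @param alphabet Characters a column may contain to be kept.
#' @return A `haplotype_table`: list with `haplotypes` (distinct collapsed
#'   sequences, in order of first appearance, named H01, H02, ...),
#'   `multiplicity`, `members` (specimen ids per haplotype), `included_sites`
#'   (original coordinates of the kept columns) and `dropped_sites`.
#' @examples
#' collapse_haplotypes(c(a = "ACGT", b = "ACGT", c = "ACTT"))
#' @export
collapse_haplotypes <- function(seqs, region = NULL,
                                alphabet = c("A", "C", "G", "T")) {
  seqs <- toupper(as.character(setNames(seqs, names(seqs))))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  n_col <- nchar(seqs[1])

  cols <- if (is.null(region)) seq_len(n_col) else {
    iv <- if (is.list(region)) region else list(region)
    unlist(lapply(iv, function(r) {
      if (r[1] < 1 || r[2] > n_col || r[1] > r[2])
        stop("region outside alignment bounds", call. = FALSE)
      seq.int(r[1], r[2])
    }))
  }

  mat <- do.call(rbind, strsplit(seqs, ""))[, cols, drop = FALSE]
  good <- apply(mat, 2, function(col) all(col %in% alphabet))
  dropped <- cols[!good]
  if (!any(good))
    stop("every column was dropped (gap/N in all columns); nothing to collapse",
         call. = FALSE)
  mat <- mat[, good, drop = FALSE]

  collapsed <- apply(mat, 1, paste, collapse = "")
  first <- !duplicated(collapsed)
  haps <- collapsed[first]
  idx <- match(collapsed, haps)
  names(haps) <- sprintf("H%02d", seq_along(haps))
  structure(
    list(haplotypes = haps,
         multiplicity = as.integer(tabulate(idx, nbins = length(haps))),
         members = split(names(seqs), names(haps)[idx]),
         included_sites = cols[good],
         dropped_sites = dropped),
    class = "haplotype_table"
  )
}

#' @rdname collapse_haplotypes
#' @details `haplotype_table()` builds a table directly from already-distinct
#'   (or not) sequences without any column filtering — useful for abstract
#'   site patterns such as binary encodings.
#' @export
haplotype_table <- function(seqs) {
  seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  first <- !duplicated(seqs)
  haps <- seqs[first]
  idx <- match(seqs, haps)
  names(haps) <- sprintf("H%02d", seq_along(haps))
  structure(
    list(haplotypes = haps,
         multiplicity = as.integer(tabulate(idx, nbins = length(haps))),
         members = split(names(seqs), names(haps)[idx]),
         included_sites = seq_len(nchar(haps[1])),
         dropped_sites = integer()),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes from %d sequences over %d sites\n",
              length(x$haplotypes), sum(x$multiplicity),
              length(x$included_sites)))
  invisible(x)
}

# Pairwise Hamming distances between equal-length strings.
hamming_matrix <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- sum(mat[i, ] != mat[j, ])
    d[i, j] <- h; d[j, i] <- h
  }
  d
}

# Minimum spanning network over a distance matrix: repeatedly find the
# minimum inter-component distance delta and admit ALL inter-component edges
# of weight <= delta + epsilon, so every tied minimum spanning tree is
# represented.  Returns an edge data frame (from, to, weight).
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n <= 1) return(data.frame(from = character(), to = character(),
                                weight = integer()))
  comp <- seq_len(n)
  edges <- data.frame(from = character(), to = character(), weight = integer())
  while (length(unique(comp)) > 1L) {
    inter <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    delta <- min(d[inter])
    take <- inter[d[inter] <= delta + epsilon, , drop = FALSE]
    for (r in seq_len(nrow(take))) {
      i <- take[r, 1]; j <- take[r, 2]
      edges <- rbind(edges, data.frame(from = rownames(d)[i],
                                       to = rownames(d)[j],
                                       weight = d[i, j]))
    }
    for (r in seq_len(nrow(take))) {
      ci <- comp[take[r, 1]]; cj <- comp[take[r, 2]]
      comp[comp == cj] <- ci
    }
  }
  edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

new_haplotype_network <- function(nodes, edges, converged = TRUE) {
  comp <- components_of(nodes$id, edges)
  structure(
    list(nodes = nodes, edges = edges, components = comp,
         total_length = sum(edges$weight), converged = converged),
    class = "haplotype_network"
  )
}

components_of <- function(ids, edges) {
  comp <- setNames(seq_along(ids), ids)
  for (r in seq_len(nrow(edges))) {
    a <- comp[[edges$from[r]]]; b <- comp[[edges$to[r]]]
    if (a != b) comp[comp == b] <- a
  }
  match(comp, unique(comp))
}

#' Minimum spanning network of a haplotype table
#'
#' Kruskal-style construction over pairwise Hamming distances that keeps
#' *all* edges of a weight class connecting distinct components at the moment
#' that class is processed — the union of all minimum spanning trees rather
#' than a single one.  With `epsilon > 0`, weight classes up to the minimum
#' connecting weight plus `epsilon` are also admitted.
#'
#' @param table A `haplotype_table`.
#' @param epsilon Relaxation parameter (0 keeps only tied-minimum classes).
#' @return A `haplotype_network`: `nodes` (id, sequence, multiplicity,
#'   inferred flag), `edges` (from, to, weight), `components`, `total_length`.
#' @examples
#' tab <- haplotype_table(c("AAA", "AAT", "ATT"))
#' minimum_spanning_network(tab)$edges
#' @export
minimum_spanning_network <- function(table, epsilon = 0) {
  stopifnot(inherits(table, "haplotype_table"))
  if (length(table$haplotypes) < 1) stop("need >= 1 haplotype", call. = FALSE)
  d <- hamming_matrix(table$haplotypes)
  edges <- msn_edges(d, epsilon)
  nodes <- data.frame(id = names(table$haplotypes),
                      sequence = unname(table$haplotypes),
                      multiplicity = table$multiplicity,
                      inferred = FALSE)
  new_haplotype_network(nodes, edges)
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes (%d inferred), %d edges, total length %d%s\n",
              nrow(x$nodes), sum(x$nodes$inferred), nrow(x$edges),
              x$total_length,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

# Per-site majority state of three sequences; a three-way split falls back to
# the state of the lexicographically smallest sequence (deterministic).
median_vector <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  first <- sort(c(a, b, c))[1]
  fb <- strsplit(first, "")[[1]]
  vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    if (max(tab) >= 2) names(tab)[which.max(tab)] else fb[j]
  }, character(1)) |> paste(collapse = "")
}

#' Median-joining network
#'
#' Iterates minimum-spanning-network construction with median-vector
#' insertion: candidate median vectors (per-site majority of three
#' haplotypes) are generated from triples in the current network — by default
#' triples forming a connected path in the MSN, or every triple in
#' `exhaustive` mode — and the novel vector whose insertion most reduces the
#' total network length is added, until no insertion helps or `max_iter` is
#' reached.  Inferred nodes of degree < 3 are pruned at the end.  All
#' tie-breaks are lexicographic on the sequence, so the result is
#' deterministic under a fixed input order.
#'
#' @param table A `haplotype_table` (>= 2 haplotypes).
#' @param epsilon MSN relaxation parameter, as in
#'   [minimum_spanning_network()].
#' @param max_iter Maximum number of medians added.
#' @param exhaustive Generate candidates from all triples instead of
#'   MSN-connected ones.
#' @return A `haplotype_network` with inferred median nodes flagged
#'   (`multiplicity` 0); `converged` is `FALSE` if `max_iter` stopped the
#'   iteration while insertions were still improving.
#' @examples
#' tab <- haplotype_table(c(s1 = "000", s2 = "110", s3 = "101"))
#' net <- median_joining(tab)
#' net$total_length   # 3: one inferred median joins all three
#' @export
median_joining <- function(table, epsilon = 0, max_iter = 25,
                           exhaustive = FALSE) {
  stopifnot(inherits(table, "haplotype_table"))
  if (length(table$haplotypes) < 2) stop("need >= 2 haplotypes", call. = FALSE)

  obs <- unname(table$haplotypes)
  seqs <- obs
  converged <- TRUE

  net_len <- function(ss) {
    names(ss) <- paste0("n", seq_along(ss))
    sum(msn_edges(hamming_matrix(ss), epsilon)$weight)
  }

  for (iter in seq_len(max_iter)) {
    names(seqs) <- paste0("n", seq_along(seqs))
    d <- hamming_matrix(seqs)
    edges <- msn_edges(d, epsilon)
    cur_len <- sum(edges$weight)

    cand <- candidate_medians(seqs, edges, exhaustive)
    cand <- setdiff(cand, seqs)
    if (!length(cand)) break
    trial <- vapply(cand, function(mv) net_len(c(seqs, mv)), numeric(1))
    best <- min(trial)
    if (best >= cur_len) break
    pick <- sort(cand[trial == best])[1]
    seqs <- c(seqs, pick)
    # invariant: adding a median never increases total network length
    stopifnot(best <= cur_len)
    if (iter == max_iter) converged <- FALSE
  }

  # prune inferred nodes of degree < 3 (repeat until stable)
  repeat {
    names(seqs) <- paste0("n", seq_along(seqs))
    edges <- msn_edges(hamming_matrix(seqs), epsilon)
    deg <- tabulate(match(c(edges$from, edges$to), names(seqs)),
                    nbins = length(seqs))
    inferred <- !(seqs %in% obs)
    drop <- inferred & deg < 3
    if (!any(drop)) break
    seqs <- seqs[!drop]
  }

  ids <- character(length(seqs))
  inferred <- !(seqs %in% obs)
  ids[!inferred] <- names(table$haplotypes)[match(seqs[!inferred], obs)]
  ids[inferred] <- sprintf("mv%02d", seq_len(sum(inferred)))
  names(seqs) <- ids
  edges <- msn_edges(hamming_matrix(seqs), epsilon)
  mult <- ifelse(inferred, 0L,
                 table$multiplicity[match(seqs, obs)])
  nodes <- data.frame(id = ids, sequence = unname(seqs),
                      multiplicity = mult, inferred = inferred)
  new_haplotype_network(nodes, edges, converged)
}

# Candidate median vectors from triples of current sequences.  Default mode
# uses triples connected through the MSN (sharing a path u-v-w); exhaustive
# mode enumerates every triple.
candidate_medians <- function(seqs, edges, exhaustive = FALSE) {
  n <- length(seqs)
  if (n < 3) return(character())
  triples <- if (exhaustive) {
    utils::combn(n, 3, simplify = FALSE)
  } else {
    adj <- matrix(FALSE, n, n, dimnames = list(names(seqs), names(seqs)))
    for (r in seq_len(nrow(edges))) {
      adj[edges$from[r], edges$to[r]] <- TRUE
      adj[edges$to[r], edges$from[r]] <- TRUE
    }
    out <- list()
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      n_adj <- sum(adj[tri[1], tri[2]], adj[tri[1], tri[3]],
                   adj[tri[2], tri[3]])
      if (n_adj >= 2) out <- c(out, list(tri))
    }
    out
  }
  unique(vapply(triples, function(tri)
    median_vector(seqs[tri[1]], seqs[tri[2]], seqs[tri[3]]), character(1)))
}

#' Export a haplotype network
#'
#' `write_network_tsv()` writes a node table and an edge list as TSV;
#' `write_network_graphml()` writes a minimal GraphML document with
#' multiplicity and inferred-flag attributes.
#'
#' @param net A `haplotype_network`.
#' @param nodes_path,edges_path,path Output paths.
#' @return The (last) path, invisibly.
#' @export
write_network_tsv <- function(net, nodes_path, edges_path) {
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="mult" for="node" attr.name="multiplicity" attr.type="int"/>',
    '  <key id="inf" for="node" attr.name="inferred" attr.type="boolean"/>',
    '  <key id="w" for="edge" attr.name="weight" attr.type="int"/>',
    '  <graph edgedefault="undirected">',
    vapply(seq_len(nrow(net$nodes)), function(i) sprintf(
      '    <node id="%s"><data key="mult">%d</data><data key="inf">%s</data></node>',
      esc(net$nodes$id[i]), net$nodes$multiplicity[i],
      tolower(net$nodes$inferred[i])), character(1)),
    vapply(seq_len(nrow(net$edges)), function(i) sprintf(
      '    <edge source="%s" target="%s"><data key="w">%d</data></edge>',
      esc(net$edges$from[i]), esc(net$edges$to[i]), net$edges$weight[i]),
      character(1)),
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path)
  invisible(path)
}
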