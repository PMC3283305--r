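# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force single-link clustering: repeated boolean matrix closure of the
# adjacency matrix; returns a partition as a named component index.
closure_membership <- function(genes, links) {
  n <- length(genes)
  A <- diag(1, n)
  rownames(A) <- colnames(A) <- genes
  if (nrow(links)) {
    A[cbind(links$gene1, links$gene2)] <- 1
    A[cbind(links$gene2, links$gene1)] <- 1
  }
  repeat {
    B <- ((A %*% A) > 0) * 1
    if (identical(B, A)) break
    A <- B
  }
  comp <- apply(A > 0, 1, function(row) min(which(row)))
  stats::setNames(comp, genes)
}

# Adjusted Rand index between two labelings of the same items.
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  ex <- b * cc / choose(n, 2)
  denom <- (b + cc) / 2 - ex
  if (denom == 0) {
    # degenerate partitions (all singletons / one block on both sides):
    # ARI is 1 iff the two partitions agree exactly
    return(as.numeric(a == b && b == cc))
  }
  (a - ex) / denom
}

# Random link table over a random manifest, for property tests.
random_graph_case <- function(n_genes, n_genomes = 4L, p_link = NULL) {
  genes <- sprintf("x%04d", seq_len(n_genes))
  manifest <- genome_manifest(genes,
                              sample(sprintf("G%d", seq_len(n_genomes)),
                                     n_genes, replace = TRUE),
                              sample(100:500, n_genes, replace = TRUE))
  if (is.null(p_link)) p_link <- runif(1, 0, 2 / n_genes)
  pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_link
  links <- data.table::data.table(gene1 = genes[pairs[keep, 1]],
                                  gene2 = genes[pairs[keep, 2]])
  list(manifest = manifest, links = links, genes = genes)
}

# Labeling of the package's cluster output as a named vector.
cluster_labels <- function(clusters) {
  stats::setNames(clusters$cluster_id, clusters$gene_id)
}
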