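#' Link criteria for direct homology links
#'
#' Two genes x and y are joined by a direct link when hits exist in both
#' directions (x as query of y and y as query of x), both E-values are
#' strictly below `e_cut`, and in each direction the retained alignment is
#' strictly longer than `f_min` times the full length of *both* sequences.
#'
#' @param e_cut E-value threshold (> 0); strict `<` comparison.
#' @param f_min minimum alignment-length fraction in (0, 1]; strict `>`
#'   comparison against `f_min * length` of each sequence.
#' @return a `link_criteria` object.
#' @export
link_criteria <- function(e_cut = 1e-20, f_min = 0.7) {
  stopifnot(is.numeric(e_cut), length(e_cut) == 1L, e_cut > 0,
            is.numeric(f_min), length(f_min) == 1L, f_min > 0, f_min <= 1)
  structure(list(e_cut = e_cut, f_min = f_min), class = "link_criteria")
}

#' @export
print.link_criteria <- function(x, ...) {
  cat(sprintf("link_criteria: E < %g, aligned fraction > %g of both sequences\n",
              x$e_cut, x$f_min))
  invisible(x)
}

#' Build direct links from a deduplicated hit table
#'
#' Applies the reciprocal link criterion of [link_criteria()] to a
#' [parse_hits()] table. Each unordered pair appears once.
#'
#' @param hits a `similarity_hits` table (one row per ordered pair).
#' @param manifest a [genome_manifest()] supplying full sequence lengths.
#' @param criteria a [link_criteria()].
#' @return a `data.table` with columns `gene1`, `gene2` (`gene1 < gene2`),
#'   sorted; zero rows when no pair qualifies.
#' @export
build_links <- function(hits, manifest, criteria = link_criteria()) {
  stopifnot(inherits(criteria, "link_criteria"))
  h <- data.table::as.data.table(hits)
  empty <- data.table::data.table(gene1 = character(), gene2 = character())
  if (nrow(h) == 0L) return(empty)
  missing_len <- setdiff(unique(c(h$query_id, h$subject_id)), manifest$gene_id)
  if (length(missing_len)) {
    stop("no manifest length for gene id(s): ",
         paste(utils::head(missing_len, 5L), collapse = ", "))
  }
  len <- stats::setNames(manifest$length, manifest$gene_id)
  lq <- len[h$query_id]
  ls <- len[h$subject_id]
  ok <- h$e_value < criteria$e_cut &
    h$aln_length > criteria$f_min * lq &
    h$aln_length > criteria$f_min * ls
  h <- h[ok]
  if (nrow(h) == 0L) return(empty)
  # reciprocal requirement: keep unordered pairs seen in both directions
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  fwd <- h$query_id == a
  pair <- paste(a, b, sep = "\r")
  both <- intersect(pair[fwd], pair[!fwd])
  if (length(both) == 0L) return(empty)
  keep <- !duplicated(pair) & pair %in% both
  links <- data.table::data.table(gene1 = a[keep], gene2 = b[keep])
  data.table::setorder(links, gene1, gene2)
  links[]
}

#' Single-link clusters (connected components of the link graph)
#'
#' Every gene in the manifest is assigned to exactly one cluster: the
#' connected component of the direct-link graph it belongs to. Genes with no
#' links become singleton clusters. Cluster ids are deterministic: clusters
#' are numbered in the sort order of their smallest member gene id.
#'
#' @param manifest a [genome_manifest()].
#' @param links link table from [build_links()].
#' @return a `data.table` of class `gene_clusters` with columns
#'   `cluster_id`, `gene_id`, `genome_id`, ordered by cluster then gene.
#' @export
single_link_clusters <- function(manifest, links) {
  bad <- setdiff(unique(c(links$gene1, links$gene2)), manifest$gene_id)
  if (length(bad)) {
    stop("links reference gene id(s) absent from the manifest: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  genes <- sort(manifest$gene_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = links$gene1, to = links$gene2),
    directed = FALSE, vertices = genes)
  comp <- igraph::components(g)$membership
  comp <- comp[genes]
  # renumber components by smallest member gene id (genes already sorted)
  first_seen <- !duplicated(comp)
  rank <- stats::setNames(seq_len(sum(first_seen)), comp[first_seen])
  idx <- rank[as.character(comp)]
  width <- max(6L, nchar(as.character(max(idx))))
  cl <- data.table::data.table(
    cluster_id = sprintf("C%0*d", width, idx),
    gene_id = genes)
  cl <- merge(cl, data.table::as.data.table(manifest)[, c("gene_id", "genome_id")],
              by = "gene_id", sort = FALSE)
  data.table::setcolorder(cl, c("cluster_id", "gene_id", "genome_id"))
  data.table::setorder(cl, cluster_id, gene_id)
  data.table::setattr(cl, "class", c("gene_clusters", class(cl)))
  cl[]
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("gene_clusters: %d genes in %d clusters\n",
              nrow(x), length(unique(x$cluster_id))))
  NextMethod()
}

#' Per-cluster summary: g, k and mean family size
#'
#' For each cluster, `g` is the total number of genes, `k` the number of
#' distinct genomes with at least one member, and `nbar = g / k` the mean
#' family size within the cluster.
#'
#' @param clusters a `gene_clusters` table.
#' @return a `data.table` with columns `cluster_id`, `g`, `k`, `nbar`.
#' @export
cluster_summary <- function(clusters) {
  cl <- data.table::as.data.table(clusters)
  s <- cl[, list(g = .N, k = data.table::uniqueN(genome_id)), by = "cluster_id"]
  s[, nbar := g / k]
  data.table::setorder(s, cluster_id)
  s[]
}

#' Write cluster membership as TSV
#' @param clusters a `gene_clusters` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  data.table::fwrite(data.table::as.data.table(clusters), path, sep = "\t")
  invisible(path)
}

#' Read cluster membership from TSV
#' @param path a file written by [write_clusters()].
#' @return a `gene_clusters` table.
#' @export
read_clusters <- function(path) {
  cl <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("cluster_id", "gene_id", "genome_id")
  if (!all(need %in% names(cl))) {
    stop("cluster TSV must have columns: ", paste(need, collapse = ", "))
  }
  data.table::setorder(cl, cluster_id, gene_id)
  data.table::setattr(cl, "class", c("gene_clusters", class(cl)))
  cl[]
}
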