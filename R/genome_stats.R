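#' Gene frequency spectrum G(k)
#'
#' G(k) is the number of clusters occupying exactly k genomes. Empirically
#' this spectrum is U-shaped: a large peak of clusters confined to a single
#' genome (ORFans, G(1)) and a smaller peak of core clusters present in
#' every genome (G_core = G(n_genomes)).
#'
#' @param clusters a `gene_clusters` table (or a [cluster_summary()] table).
#' @param n_genomes total number of genomes in the dataset.
#' @return a list of class `gene_frequency_spectrum` with elements `k`
#'   (1..n_genomes), `G` (counts), `G_tot`, `G1`, `G_core`, `k_bar` and
#'   `n_genomes`.
#' @export
cluster_spectrum <- function(clusters, n_genomes) {
  stopifnot(n_genomes >= 1L)
  s <- if (is.data.frame(clusters) && all(c("g", "k") %in% names(clusters))) {
    data.table::as.data.table(clusters)
  } else {
    cluster_summary(clusters)
  }
  if (nrow(s) && max(s$k) > n_genomes) {
    stop("cluster occupies more genomes (", max(s$k), ") than n_genomes (",
         n_genomes, ")")
  }
  G <- tabulate(s$k, nbins = n_genomes)
  G_tot <- sum(G)
  structure(list(k = seq_len(n_genomes), G = G, G_tot = G_tot,
                 G1 = G[1L], G_core = G[n_genomes],
                 k_bar = if (G_tot > 0) sum(seq_len(n_genomes) * G) / G_tot else NA_real_,
                 n_genomes = as.integer(n_genomes)),
            class = "gene_frequency_spectrum")
}

#' @export
print.gene_frequency_spectrum <- function(x, ...) {
  cat(sprintf(
    "gene_frequency_spectrum over %d genomes: G_tot=%d, G(1)=%d, G_core=%d, k_bar=%.3f\n",
    x$n_genomes, x$G_tot, x$G1, x$G_core, x$k_bar))
  invisible(x)
}

#' Family size distribution of one genome
#'
#' Each cluster containing at least one gene of the genome contributes one
#' family, whose size is the cluster's gene count within that genome.
#'
#' @param clusters a `gene_clusters` table.
#' @param genome_id genome to extract.
#' @return a [family_size_distribution()].
#' @export
family_distribution <- function(clusters, genome_id) {
  cl <- data.table::as.data.table(clusters)
  gid <- genome_id
  sub <- cl[cl$genome_id == gid]
  if (nrow(sub) == 0L) stop("unknown genome_id: ", gid)
  sizes <- sub[, list(size = .N), by = "cluster_id"]$size
  tab <- tabulate(sizes)
  family_size_distribution(seq_along(tab), tab, genome_id = gid)
}

#' Family size distributions for every genome
#' @param clusters a `gene_clusters` table.
#' @return named list of [family_size_distribution()], one per genome.
#' @export
family_distributions <- function(clusters) {
  gids <- sort(unique(clusters$genome_id))
  stats::setNames(lapply(gids, function(g) family_distribution(clusters, g)), gids)
}

#' Mean family size as a function of k
#'
#' Arithmetic mean of the per-cluster mean family size `nbar = g/k`, grouped
#' by the number of genomes k the cluster occupies. Empirically this rises
#' from just above 1 for ORFans to about 2 for core clusters.
#'
#' @param clusters a `gene_clusters` table or [cluster_summary()] table.
#' @return a `data.table` with columns `k`, `mean_nbar`, `n_clusters`,
#'   sorted by `k`; k values with no clusters are omitted.
#' @export
mean_family_size_by_k <- function(clusters) {
  s <- if (is.data.frame(clusters) && all(c("k", "nbar") %in% names(clusters))) {
    data.table::as.data.table(clusters)
  } else {
    cluster_summary(clusters)
  }
  if (nrow(s) == 0L) stop("no clusters")
  out <- s[, list(mean_nbar = mean(nbar), n_clusters = .N), by = "k"]
  data.table::setorder(out, k)
  out[]
}

#' Mean family size distribution over genomes
#'
#' Per size n, the arithmetic mean of F(n) across the given genomes, with
#' absent sizes counted as zero. Counts are real-valued; the result is
#' flagged so that AIC selection refuses it (families shared by related
#' genomes are not independent observations).
#'
#' @param fsds list of [family_size_distribution()] objects.
#' @return a [family_size_distribution()] with `mean = TRUE`.
#' @export
mean_distribution <- function(fsds) {
  stopifnot(length(fsds) >= 1L)
  nmax <- max(vapply(fsds, function(f) max(f$n), 0L))
  acc <- numeric(nmax)
  for (f in fsds) acc[f$n] <- acc[f$n] + f$count
  family_size_distribution(seq_len(nmax), acc / length(fsds),
                           genome_id = "mean", mean = TRUE)
}

#' Ordinary least-squares trend line
#'
#' Fits `y = intercept + slope * x` by least squares and reports the
#' x-intercept `-intercept/slope` (defined only for nonzero slope), used for
#' threshold-style readings such as the genome size below which large
#' families vanish.
#'
#' @param x,y numeric vectors of equal length with >= 2 distinct x values.
#' @return a list of class `trend_line`: `slope`, `intercept`,
#'   `x_intercept`, and the underlying `lm` fit.
#' @export
fit_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L) stop("need >= 2 distinct x values")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  structure(list(slope = slope, intercept = intercept,
                 x_intercept = if (slope != 0) -intercept / slope else NA_real_,
                 fit = fit),
            class = "trend_line")
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("trend_line: y = %.6g + %.6g x  (x-intercept %.6g)\n",
              x$intercept, x$slope, x$x_intercept))
  invisible(x)
}

#' Pool the tail of a family size distribution (display only)
#'
#' All mass at sizes `>= n_cap` is summed into the `n_cap` bin, as done when
#' plotting distributions whose tails are sparse. The pooled distribution
#' must never be used for likelihood computation.
#'
#' @param fsd a [family_size_distribution()].
#' @param n_cap pooling bin (>= 2).
#' @return a pooled [family_size_distribution()].
#' @export
aggregate_tail <- function(fsd, n_cap) {
  stopifnot(n_cap >= 2L)
  below <- fsd$n < n_cap
  tail_mass <- sum(fsd$count[!below])
  n <- fsd$n[below]; count <- fsd$count[below]
  if (tail_mass > 0) {
    n <- c(n, as.integer(n_cap)); count <- c(count, tail_mass)
  }
  family_size_distribution(n, count, genome_id = fsd$genome_id, mean = fsd$mean)
}

#' Per-genome summary table
#'
#' One row per genome: `N_genes`, `F_tot`, `F1`, `F_large` (families of
#' size >= 5), `nbar = N_genes/F_tot`, and `n_max`.
#'
#' @param clusters a `gene_clusters` table.
#' @param exclude optional genome ids to drop (e.g. an outlier genome that
#'   would distort dataset averages).
#' @return a `data.table`, one row per genome.
#' @export
genome_summaries <- function(clusters, exclude = NULL) {
  fsds <- family_distributions(clusters)
  fsds <- fsds[!names(fsds) %in% exclude]
  if (length(fsds) == 0L) stop("all genomes excluded")
  data.table::rbindlist(lapply(fsds, function(f) {
    data.table::data.table(genome_id = f$genome_id, N_genes = n_genes(f),
                           F_tot = f_tot(f), F1 = sum(f$count[f$n == 1L]),
                           F_large = f_large(f), nbar = nbar(f),
                           n_max = max(f$n))
  }))
}

#' Dataset-level clustering report
#'
#' One row in the style of a clustering-parameter sweep table: cluster-side
#' statistics (`G_tot`, `G1`, `G_core`, `k_bar`) plus family-side statistics
#' averaged over genomes (`F_tot`, `F1`, `F_large`, `nbar`) and the maximum
#' family size found in any one genome (`n_max`).
#'
#' @param clusters a `gene_clusters` table.
#' @param n_genomes number of genomes in the dataset (before exclusions).
#' @param exclude genomes excluded from the per-genome averages *and* the
#'   spectrum (their genes are dropped from the clustered universe).
#' @param e_cut,f_min optional clustering parameters echoed into the row.
#' @return a one-row `data.table`.
#' @export
clustering_report <- function(clusters, n_genomes = NULL, exclude = NULL,
                              e_cut = NA_real_, f_min = NA_real_) {
  cl <- data.table::as.data.table(clusters)
  if (!is.null(exclude)) cl <- cl[!cl$genome_id %in% exclude]
  if (nrow(cl) == 0L) stop("no genes left after exclusions")
  data.table::setattr(cl, "class", c("gene_clusters", class(cl)))
  if (is.null(n_genomes)) n_genomes <- length(unique(cl$genome_id))
  spec <- cluster_spectrum(cl, n_genomes)
  gs <- genome_summaries(cl)
  data.table::data.table(
    E_cut = e_cut, f_min = f_min,
    G_tot = spec$G_tot, G1 = spec$G1, G_core = spec$G_core, k_bar = spec$k_bar,
    F_tot = mean(gs$F_tot), F1 = mean(gs$F1), F_large = mean(gs$F_large),
    nbar = mean(gs$nbar), n_max = max(gs$n_max))
}
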