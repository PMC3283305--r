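#' Family size distribution F(n)
#'
#' The number of families of each size n within one genome (or, for a mean
#' distribution over genomes, real-valued average counts). This is the
#' sufficient statistic for all model likelihoods.
#'
#' @param n integer family sizes (>= 1).
#' @param count counts F(n); non-negative, real-valued allowed for mean
#'   distributions.
#' @param genome_id optional genome label.
#' @param mean logical; `TRUE` marks a distribution averaged over genomes.
#'   AIC-based model selection refuses such input because families shared
#'   across genomes are phylogenetically dependent.
#' @return an object of class `family_size_distribution`.
#' @export
family_size_distribution <- function(n, count, genome_id = NA_character_,
                                     mean = FALSE) {
  n <- as.integer(n)
  count <- as.numeric(count)
  stopifnot(length(n) == length(count))
  if (anyNA(n) || any(n < 1L)) stop("family sizes must be integers >= 1")
  if (anyNA(count) || any(count < 0)) stop("counts must be non-negative")
  keep <- count > 0
  n <- n[keep]; count <- count[keep]
  if (anyDuplicated(n)) {
    count <- vapply(split(count, n), sum, 0)
    n <- as.integer(names(count))
  }
  o <- order(n)
  structure(list(n = n[o], count = count[o],
                 genome_id = as.character(genome_id), mean = isTRUE(mean)),
            class = "family_size_distribution")
}

#' @export
print.family_size_distribution <- function(x, ...) {
  cat(sprintf("family_size_distribution%s%s: F_tot=%g, N_genes=%g, nbar=%.4g, n_max=%s\n",
              if (is.na(x$genome_id)) "" else paste0(" [", x$genome_id, "]"),
              if (x$mean) " (mean over genomes)" else "",
              f_tot(x), n_genes(x), nbar(x),
              if (length(x$n)) max(x$n) else "NA"))
  invisible(x)
}

#' @export
as.data.frame.family_size_distribution <- function(x, ...) {
  data.frame(n = x$n, count = x$count)
}

#' Total number of families, `F_tot`
#' @param fsd a [family_size_distribution()].
#' @return `sum(F(n))`.
#' @export
f_tot <- function(fsd) sum(fsd$count)

#' Total number of genes, `N_genes = sum(n * F(n))`
#' @inheritParams f_tot
#' @export
n_genes <- function(fsd) sum(fsd$n * fsd$count)

#' Mean family size `nbar = N_genes / F_tot`
#' @inheritParams f_tot
#' @export
nbar <- function(fsd) n_genes(fsd) / f_tot(fsd)

#' Number of large families (size >= `threshold`)
#' @inheritParams f_tot
#' @param threshold inclusive size threshold (default 5).
#' @export
f_large <- function(fsd, threshold = 5L) sum(fsd$count[fsd$n >= threshold])

#' Write / read a family size distribution as a two-column TSV
#' @param fsd a [family_size_distribution()].
#' @param path file path.
#' @return `path` (write) or a `family_size_distribution` (read).
#' @export
write_fsd <- function(fsd, path) {
  data.table::fwrite(data.table::data.table(n = fsd$n, count = fsd$count),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_fsd
#' @param genome_id,mean passed to [family_size_distribution()].
#' @export
read_fsd <- function(path, genome_id = NA_character_, mean = FALSE) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  family_size_distribution(d$n, d$count, genome_id = genome_id, mean = mean)
}
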