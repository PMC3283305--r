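# Truncated support for inverse-CDF sampling of a stationary law: grow the
# support until the captured mass is within 1e-12 of 1.
.qn_support <- function(params, tail_tol = 1e-12, n_max = 2^22) {
  N <- 256L
  repeat {
    q <- model_qn(params, seq_len(N))
    if (sum(q) >= 1 - tail_tol || N >= n_max) return(q)
    N <- N * 2L
  }
}

#' Sample family sizes from a stationary model
#'
#' Draws `f_tot` independent family sizes from the stationary law q_n of a
#' model (inverse CDF on a support truncated where the tail mass falls
#' below 1e-12) and tabulates them as a family size distribution.
#'
#' @param params a model parameter object ([bdi1_params()], [bdik_params()],
#'   [gbdi_params()] or [powerlaw_params()]).
#' @param f_tot number of families to draw (>= 1).
#' @param seed integer seed; draws are reproducible.
#' @param genome_id optional label for the resulting distribution.
#' @return a [family_size_distribution()] with `sum(count) == f_tot`.
#' @export
sample_family_sizes <- function(params, f_tot, seed = 1L,
                                genome_id = NA_character_) {
  stopifnot(f_tot >= 1)
  q <- .qn_support(params)
  set.seed(seed)
  draws <- sample.int(length(q), size = f_tot, replace = TRUE, prob = q)
  tab <- tabulate(draws)
  family_size_distribution(seq_along(tab), tab, genome_id = genome_id)
}

#' Event-driven simulation of the birth-death-innovation process
#'
#' Exact (Gillespie) stochastic simulation of family sizes in one genome:
#' new single-gene families appear at rate `u`; a family of n genes gains a
#' gene at rate `n * lam` and loses one at rate `n * delta`; a family whose
#' last gene is deleted is lost. The simulator reports time-weighted average
#' family counts after burn-in, which at stationarity converge to the
#' closed-form expected counts `f(n) = (u/delta) r^(n-1)/n`.
#'
#' @param u innovation rate (> 0).
#' @param lam per-gene duplication rate (> 0).
#' @param delta per-gene deletion rate (> 0); `lam/delta < 1` required for
#'   stationarity.
#' @param n_events number of post-burn-in events to average over.
#' @param burn_in fraction of the total event budget discarded from the
#'   start (in [0, 1)); the chain starts empty, so the burn-in carries it
#'   into the stationary regime.
#' @param seed integer seed.
#' @return a list of class `bdi_ctmc`: `f_hat` (time-averaged counts, index
#'   = family size), `f_tot_hat`, `final_counts`, `time_averaged` span, and
#'   the rates.
#' @export
simulate_bdi_ctmc <- function(u = 1, lam = 0.5, delta = 1,
                              n_events = 1e5, burn_in = 0.2, seed = 1L) {
  stopifnot(u > 0, lam >= 0, delta > 0, lam / delta < 1,
            burn_in >= 0, burn_in < 1, n_events >= 1)
  set.seed(seed)
  total_events <- ceiling(n_events / (1 - burn_in))
  n_burn <- total_events - n_events

  cap <- 64L
  cnt <- numeric(cap)      # cnt[n] = number of families of size n
  acc <- numeric(cap)      # time-weighted accumulator
  len <- 0L                # largest occupied size
  G <- 0                   # total genes
  t_acc <- 0

  for (ev in seq_len(total_events)) {
    tot_rate <- u + (lam + delta) * G
    dt <- stats::rexp(1, tot_rate)
    if (ev > n_burn) {
      if (len > 0L) acc[seq_len(len)] <- acc[seq_len(len)] + cnt[seq_len(len)] * dt
      t_acc <- t_acc + dt
    }
    x <- stats::runif(1) * tot_rate
    if (x < u) {
      cnt[1L] <- cnt[1L] + 1; G <- G + 1
      if (len < 1L) len <- 1L
    } else {
      sizes <- seq_len(len)
      n <- sizes[sample.int(len, 1L, prob = sizes * cnt[sizes])]
      if (x < u + lam * G) {                     # duplication: n -> n + 1
        cnt[n] <- cnt[n] - 1
        if (n + 1L > cap) {
          cap <- cap * 2L
          cnt <- c(cnt, numeric(cap / 2L)); acc <- c(acc, numeric(cap / 2L))
        }
        cnt[n + 1L] <- cnt[n + 1L] + 1; G <- G + 1
        if (n + 1L > len) len <- n + 1L
      } else {                                   # deletion: n -> n - 1
        cnt[n] <- cnt[n] - 1
        if (n > 1L) cnt[n - 1L] <- cnt[n - 1L] + 1
        G <- G - 1
      }
      while (len > 0L && cnt[len] == 0) len <- len - 1L
    }
  }

  f_hat <- if (t_acc > 0) acc / t_acc else acc
  keep <- seq_len(max(which(f_hat > 0), 1L))
  structure(list(f_hat = f_hat[keep], f_tot_hat = sum(f_hat),
                 final_counts = cnt[seq_len(max(len, 1L))],
                 time_averaged = t_acc, u = u, lam = lam, delta = delta,
                 r = lam / delta, n_events = n_events, burn_in = burn_in),
            class = "bdi_ctmc")
}

#' @export
print.bdi_ctmc <- function(x, ...) {
  cat(sprintf(
    "bdi_ctmc: u=%g lam=%g delta=%g (r=%g); f_tot_hat=%.4f over %.1f time units\n",
    x$u, x$lam, x$delta, x$r, x$f_tot_hat, x$time_averaged))
  invisible(x)
}

#' Generate a planted pan-genome with a known clustering truth
#'
#' Builds a synthetic dataset shaped like real input: a manifest of genes
#' across `n_genomes` genomes partitioned into `n_clusters` planted
#' clusters, and a hit table engineered so that clustering at the
#' generator's own thresholds recovers the planted partition exactly.
#' Cluster occupancy follows a crude U-shape: with probability `p_core` a
#' cluster spans every genome, otherwise its genome count is a truncated
#' geometric. Within-cluster family sizes are drawn from `size_model`.
#' Within-cluster hits (a chain of reciprocal pairs) get E-values
#' log-uniform below `e_cut` and full-length alignments; an optional
#' `noise_frac` of decoy hits (above-threshold E-values and one-directional
#' near hits) exercises the strictness of the link criterion without
#' altering the truth.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param n_clusters number of planted clusters (>= 1).
#' @param size_model stationary model for family sizes (default a BDI3-like
#'   mixture).
#' @param p_core probability a cluster spans all genomes.
#' @param occ_p success probability of the truncated geometric occupancy.
#' @param e_cut,f_min generator thresholds (`f_min < 1`).
#' @param noise_frac expected decoy hits per cluster.
#' @param k_values optional integer vector of length `n_clusters` fixing
#'   each cluster's genome count directly (overrides the occupancy model).
#' @param seed integer seed.
#' @return a list of class `planted_pangenome`: `manifest`, `hits`, `truth`
#'   (named cluster index per gene), and the generator settings.
#' @export
generate_planted_pangenome <- function(n_genomes, n_clusters,
                                       size_model = bdik_params(
                                         xi = c(0.75, 0.22, 0.03),
                                         r = c(0.10, 0.70, 0.97)),
                                       p_core = 0.1, occ_p = 0.5,
                                       e_cut = 1e-20, f_min = 0.7,
                                       noise_frac = 0, k_values = NULL,
                                       seed = 1L) {
  stopifnot(n_genomes >= 1L, n_clusters >= 1L, f_min > 0, f_min < 1,
            e_cut > 0, p_core >= 0, p_core <= 1)
  if (!is.null(k_values)) {
    stopifnot(length(k_values) == n_clusters, all(k_values >= 1L),
              all(k_values <= n_genomes))
  }
  q <- .qn_support(size_model)
  set.seed(seed)
  genomes <- sprintf("G%03d", seq_len(n_genomes))

  gene_id <- character(0); genome_id <- character(0); length_ <- integer(0)
  truth <- integer(0)
  counter <- 0L
  cluster_members <- vector("list", n_clusters)
  cluster_len <- integer(n_clusters)

  for (j in seq_len(n_clusters)) {
    k <- if (!is.null(k_values)) k_values[j] else
      if (stats::runif(1) < p_core) n_genomes else
        min(stats::rgeom(1, occ_p) + 1L, n_genomes)
    occ <- sort(sample(genomes, k))
    sizes <- sample.int(length(q), size = k, replace = TRUE, prob = q)
    L <- sample(100:1000, 1L)
    ids <- sprintf("g%07d", counter + seq_len(sum(sizes)))
    counter <- counter + sum(sizes)
    gene_id <- c(gene_id, ids)
    genome_id <- c(genome_id, rep(occ, sizes))
    length_ <- c(length_, rep(L, sum(sizes)))
    truth <- c(truth, rep(j, sum(sizes)))
    cluster_members[[j]] <- ids
    cluster_len[j] <- L
  }
  manifest <- genome_manifest(gene_id, genome_id, length_)
  names(truth) <- gene_id

  # within-cluster reciprocal chains, strictly below threshold
  qh <- character(0); sh <- character(0); ev <- numeric(0); al <- integer(0)
  for (j in seq_len(n_clusters)) {
    mem <- cluster_members[[j]]
    if (length(mem) < 2L) next
    a <- mem[-length(mem)]; b <- mem[-1L]
    n_pairs <- length(a)
    e_fwd <- 10^stats::runif(n_pairs, -180, log10(e_cut) - 1)
    e_rev <- 10^stats::runif(n_pairs, -180, log10(e_cut) - 1)
    qh <- c(qh, a, b); sh <- c(sh, b, a)
    ev <- c(ev, e_fwd, e_rev)
    al <- c(al, rep(cluster_len[j], 2L * n_pairs))
  }
  # decoy hits: cross-cluster pairs with E-values at/above the cutoff, and
  # one-directional below-threshold hits that must fail reciprocity
  n_noise <- round(noise_frac * n_clusters)
  if (n_noise > 0 && length(gene_id) >= 2L) {
    for (i in seq_len(n_noise)) {
      pair <- sort(sample(gene_id, 2L))  # one-directional decoys always min->max
      above <- stats::runif(1) < 0.5
      e <- if (above) 10^stats::runif(1, log10(e_cut), 2) else
        10^stats::runif(1, -180, log10(e_cut) - 1)
      qh <- c(qh, pair[1]); sh <- c(sh, pair[2]); ev <- c(ev, e)
      al <- c(al, max(manifest$length[manifest$gene_id %in% pair]))
      if (above) {  # reciprocal, but both E-values fail the strict cutoff
        qh <- c(qh, pair[2]); sh <- c(sh, pair[1])
        ev <- c(ev, 10^stats::runif(1, log10(e_cut), 2))
        al <- c(al, max(manifest$length[manifest$gene_id %in% pair]))
      }
    }
  }
  hits <- parse_hits(
    data.frame(query_id = qh, subject_id = sh, e_value = ev, aln_length = al),
    manifest)
  structure(list(manifest = manifest, hits = hits, truth = truth,
                 e_cut = e_cut, f_min = f_min, seed = seed,
                 n_genomes = n_genomes, n_clusters = n_clusters),
            class = "planted_pangenome")
}

#' @export
print.planted_pangenome <- function(x, ...) {
  cat(sprintf(
    "planted_pangenome: %d genes, %d planted clusters, %d genomes, %d hits\n",
    nrow(x$manifest), x$n_clusters, x$n_genomes, nrow(x$hits)))
  invisible(x)
}

#' Write a planted pan-genome to disk as plain-text fixtures
#'
#' Emits one protein FASTA per genome (placeholder sequences of the
#' recorded lengths: an initial M followed by A residues), a manifest TSV,
#' and a hit table in the BLAST outfmt-6 dialect. Output is byte-identical
#' across runs for the same pan-genome object.
#'
#' @param pan a [generate_planted_pangenome()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_fixtures <- function(pan, dir) {
  stopifnot(inherits(pan, "planted_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- data.table::as.data.table(pan$manifest)
  fasta_paths <- character(0)
  for (g in sort(unique(m$genome_id))) {
    sub <- m[m$genome_id == g][order(gene_id)]
    seqs <- Biostrings::AAStringSet(vapply(sub$length, function(L) {
      paste0("M", strrep("A", L - 1L))
    }, ""))
    names(seqs) <- sub$gene_id
    p <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(seqs, p, width = 70L)
    fasta_paths <- c(fasta_paths, p)
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(pan$manifest, manifest_path)
  hits_path <- file.path(dir, "hits.tsv")
  h <- data.table::as.data.table(pan$hits)
  data.table::setorder(h, query_id, subject_id)
  write_hits(h, hits_path)
  invisible(list(fasta = fasta_paths, manifest = manifest_path,
                 hits = hits_path))
}
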