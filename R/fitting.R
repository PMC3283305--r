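#' Model catalogue used by the fitting functions
#'
#' Canonical model names are `"bdi1"`, `"bdi2"`, `"bdi3"`, `"bdi4"` (K-class
#' mixtures with K = 1..4), `"gbdi"`, and `"powerlaw"`. Free-parameter
#' counts enter AIC as: BDIK -> 2K - 1, GBDI -> 3, power law -> 1. The
#' innovation scale u/delta never shapes q_n and is excluded from the count.
#'
#' @param model a model name.
#' @return a list with `name`, `K` (NA unless a BDIK model) and `n_free`.
#' @export
model_spec <- function(model) {
  model <- match.arg(model, c("bdi1", "bdi2", "bdi3", "bdi4",
                              "gbdi", "powerlaw"))
  if (grepl("^bdi[0-9]+$", model)) {
    K <- as.integer(sub("^bdi", "", model))
    list(name = model, K = K, n_free = 2L * K - 1L)
  } else if (model == "gbdi") {
    list(name = model, K = NA_integer_, n_free = 3L)
  } else {
    list(name = model, K = NA_integer_, n_free = 1L)
  }
}

#' Closed-form maximum-likelihood fit of BDI1
#'
#' At the ML optimum of the single-class model, the model mean family size
#' equals the empirical mean `m = N_genes / F_tot`. The fit therefore
#' reduces to inverting the (strictly increasing) mean function by
#' bisection. The scale u/delta is then calibrated so the expected total
#' family count matches the observed one.
#'
#' @param fsd a non-empty [family_size_distribution()].
#' @param tol bisection stops when the model mean is within `tol` of the
#'   empirical mean.
#' @return a list with `params` (a [bdi1_params()]), `lnL`, and `degenerate`
#'   (TRUE when the empirical mean is 1, i.e. all families are singletons,
#'   and r sits at the lower clamp).
#' @export
fit_bdi1_closed <- function(fsd, tol = 1e-10) {
  stopifnot(inherits(fsd, "family_size_distribution"), length(fsd$n) > 0L)
  m <- nbar(fsd)
  lo <- .r_eps; hi <- 1 - .r_eps
  if (m <= bdi1_mean(lo)) {
    r <- lo; degenerate <- TRUE
  } else if (m >= bdi1_mean(hi)) {
    r <- hi; degenerate <- TRUE
  } else {
    degenerate <- FALSE
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- bdi1_mean(mid)
      if (abs(fm - m) < tol) break
      if (fm < m) lo <- mid else hi <- mid
    }
    r <- mid
  }
  params <- bdi1_params(r, u_over_delta = calibrate_scale(r, f_tot(fsd)))
  list(params = params, lnL = log_likelihood(params, fsd),
       degenerate = degenerate)
}

# ---- unconstrained reparameterizations -------------------------------------
# BDIK: K logits map to strictly ordered ratios via stick-breaking in (0,1);
# K-1 reals map to the weight simplex by softmax (last coordinate pinned).
.theta_to_bdik <- function(theta, K) {
  z <- theta[seq_len(K)]
  r <- numeric(K)
  r[1] <- stats::plogis(z[1])
  if (K > 1L) for (j in 2:K) r[j] <- r[j - 1] + (1 - r[j - 1]) * stats::plogis(z[j])
  xi <- if (K == 1L) 1 else {
    w <- c(theta[(K + 1):(2L * K - 1L)], 0)
    ew <- exp(w - max(w)); ew / sum(ew)
  }
  list(xi = xi, r = pmin(pmax(r, .r_eps), 1 - .r_eps))
}

.bdik_to_theta <- function(xi, r) {
  K <- length(r)
  z <- numeric(K)
  z[1] <- stats::qlogis(r[1])
  if (K > 1L) for (j in 2:K) z[j] <- stats::qlogis((r[j] - r[j - 1]) / (1 - r[j - 1]))
  if (K == 1L) z else c(z, log(xi[-K] / xi[K]))
}

# GBDI: r via logit, a > 0 and b > -2 via exp.
.theta_to_gbdi <- function(theta) {
  list(r = stats::plogis(theta[1]), a = exp(theta[2]), b = -2 + exp(theta[3]))
}

# lnL closures that tolerate invalid parameter combinations (return -Inf)
# so Nelder-Mead can roam the unconstrained space.
.make_negll <- function(spec, fsd) {
  n <- fsd$n; cnt <- fsd$count
  logn <- log(n)
  if (!is.na(spec$K)) {
    K <- spec$K
    function(theta) {
      p <- .theta_to_bdik(theta, K)
      q <- 0
      for (k in seq_len(K)) {
        q <- q + p$xi[k] * exp(n * log(p$r[k]) - logn - log(-log1p(-p$r[k])))
      }
      if (any(q <= 0)) return(Inf)
      -sum(cnt * log(q))
    }
  } else if (spec$name == "gbdi") {
    Nsup <- max(1e5, 50 * max(n))
    function(theta) {
      p <- .theta_to_gbdi(theta)
      if (p$r >= 1 - .r_eps && p$b <= p$a) return(Inf)
      nz <- gbdi_normalizer(p, n_max_support = Nsup)
      if (!is.finite(nz$Z)) return(Inf)
      logq <- nz$logw[n] - nz$log_scale - log(nz$Z)
      if (anyNA(logq) || any(!is.finite(logq))) return(Inf)
      -sum(cnt * logq)
    }
  } else {
    function(theta) {
      gamma <- 1 + exp(theta[1])
      if (!is.finite(gamma) || gamma <= 1) return(Inf)
      -sum(cnt * (-gamma * logn - log(riemann_zeta(gamma))))
    }
  }
}

# Seeded multi-start initial points in the unconstrained space. The first
# start is deterministic and data-informed (BDI1 closed form spread across
# classes); the rest draw r components from a quantile-spread grid with
# jitter and weights from a near-uniform simplex.
.fit_starts <- function(spec, fsd, n_restarts) {
  if (!is.na(spec$K)) {
    K <- spec$K
    base_r <- stats::qlogis(seq(0.15, 0.92, length.out = max(K, 2L)))[seq_len(K)]
    starts <- list(.bdik_to_theta(rep(1 / K, K), stats::plogis(base_r)))
    for (i in seq_len(n_restarts - 1L)) {
      grid <- sort(stats::runif(K, min = 0.02, max = 0.985))
      xi <- stats::rexp(K) + 0.2; xi <- xi / sum(xi)
      starts[[i + 1L]] <- .bdik_to_theta(xi, grid)
    }
    starts
  } else if (spec$name == "gbdi") {
    starts <- list(c(stats::qlogis(0.8), log(1), log(2)))
    for (i in seq_len(n_restarts - 1L)) {
      starts[[i + 1L]] <- c(stats::qlogis(stats::runif(1, 0.3, 0.999)),
                            log(stats::rexp(1) + 0.05),
                            log(stats::runif(1, 0.5, 4)))
    }
    starts
  } else {
    starts <- list(log(2 - 1))  # gamma = 2
    for (i in seq_len(n_restarts - 1L)) {
      starts[[i + 1L]] <- log(stats::runif(1, 0.2, 3))
    }
    starts
  }
}

#' Maximum-likelihood fit of one model by Nelder-Mead
#'
#' Maximizes the log-likelihood over an unconstrained reparameterization of
#' the model's shape parameters (logit/stick-breaking for ordered ratios,
#' softmax for mixture weights, log for positive offsets) using Nelder-Mead
#' with seeded multi-start. The best restart is polished by a second
#' Nelder-Mead round from its own solution. BDIK ratios are reported in
#' ascending order by construction.
#'
#' @param fsd a non-empty [family_size_distribution()].
#' @param model a name accepted by [model_spec()].
#' @param seed integer seed for the multi-start initials.
#' @param n_restarts number of Nelder-Mead starts (default 10).
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 5e4, reltol = 1e-10)`.
#' @return an object of class `fit_result`: `model_name`, `params`, `lnL`,
#'   `n_free`, `aic`, `converged`, `n_restarts_used`, `degenerate`.
#' @export
fit_model <- function(fsd, model, seed = 1L, n_restarts = 10L,
                      control = list(maxit = 5e4, reltol = 1e-10)) {
  stopifnot(inherits(fsd, "family_size_distribution"), length(fsd$n) > 0L)
  spec <- model_spec(model)
  degenerate <- nbar(fsd) <= 1 + 1e-12

  if (spec$name == "bdi1" && degenerate) {
    cf <- fit_bdi1_closed(fsd)
    return(structure(list(model_name = "bdi1", params = cf$params,
                          lnL = cf$lnL, n_free = spec$n_free,
                          aic = 2 * (-cf$lnL + spec$n_free),
                          converged = TRUE, n_restarts_used = 0L,
                          degenerate = TRUE),
                     class = "fit_result"))
  }

  negll <- .make_negll(spec, fsd)
  set.seed(seed)
  starts <- .fit_starts(spec, fsd, n_restarts)

  best <- NULL
  for (theta0 in starts) {
    opt <- suppressWarnings(
      stats::optim(theta0, negll, method = "Nelder-Mead", control = control))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish from the incumbent
  opt <- suppressWarnings(
    stats::optim(best$par, negll, method = "Nelder-Mead", control = control))
  if (opt$value < best$value) best <- opt

  params <- if (!is.na(spec$K)) {
    p <- .theta_to_bdik(best$par, spec$K)
    if (spec$K == 1L) {
      bdi1_params(p$r[1], u_over_delta = calibrate_scale(p$r[1], f_tot(fsd)))
    } else {
      # enforce strict ordering at reporting time (ties can collapse under
      # the clamp when classes merge)
      r <- p$r
      for (j in seq_along(r)[-1]) if (r[j] <= r[j - 1]) r[j] <- min(r[j - 1] + 1e-12, 1 - .r_eps / 2)
      bdik_params(p$xi, r)
    }
  } else if (spec$name == "gbdi") {
    p <- .theta_to_gbdi(best$par)
    structure(list(r = p$r, a = p$a, b = p$b), class = "gbdi_params")
  } else {
    powerlaw_params(1 + exp(best$par[1]))
  }
  lnL <- -best$value
  structure(list(model_name = spec$name, params = params, lnL = lnL,
                 n_free = spec$n_free, aic = 2 * (-lnL + spec$n_free),
                 converged = best$convergence == 0L,
                 n_restarts_used = length(starts),
                 degenerate = degenerate),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: lnL = %.4f, n_free = %d, AIC = %.4f%s%s\n",
              x$model_name, x$lnL, x$n_free, x$aic,
              if (x$converged) "" else " (NOT converged)",
              if (isTRUE(x$degenerate)) " (degenerate data)" else ""))
  print(x$params)
  invisible(x)
}

#' Akaike's Information Criterion of a fit
#'
#' `AIC = 2 * (-lnL + n_free)`; smaller is preferred.
#'
#' @param fit a `fit_result`.
#' @return the AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!is.finite(fit$lnL)) stop("AIC undefined: log-likelihood is not finite")
  2 * (-fit$lnL + fit$n_free)
}

#' Pick the preferred model from an AIC table
#'
#' Minimal AIC wins; exact ties are broken toward fewer free parameters,
#' then toward earlier position in the candidate list.
#'
#' @param tab a data frame with columns `model`, `n_free`, `aic`.
#' @return the preferred model name.
#' @export
best_by_aic <- function(tab) {
  stopifnot(all(c("model", "n_free", "aic") %in% names(tab)))
  o <- order(tab$aic, tab$n_free, seq_len(nrow(tab)))
  tab$model[o[1L]]
}

#' Fit several models and select by AIC
#'
#' Fits every candidate model to one per-genome family size distribution
#' and selects the minimal-AIC model; ties are broken toward fewer free
#' parameters. Mean distributions are refused: families from the same
#' cluster observed in related genomes are not independent, so AIC is not
#' applicable there.
#'
#' @param fsd a per-genome [family_size_distribution()].
#' @param candidates model names (>= 2).
#' @param seed base seed; each model gets an independent derived seed.
#' @param n_restarts multi-start count per model.
#' @return an object of class `model_selection`: `fits` (named list of
#'   `fit_result`), `best` (model name), and an `aic` table.
#' @export
select_model <- function(fsd, candidates = c("bdi1", "bdi2", "bdi3", "bdi4",
                                             "gbdi", "powerlaw"),
                         seed = 1L, n_restarts = 10L) {
  stopifnot(length(candidates) >= 2L)
  if (isTRUE(fsd$mean)) {
    stop("AIC model selection is not applicable to a mean distribution ",
         "(families shared across genomes are not independent); ",
         "fit models to the mean with fit_model() instead")
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(candidates))
  fits <- stats::setNames(vector("list", length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    fits[[i]] <- fit_model(fsd, candidates[i], seed = sub_seeds[i],
                           n_restarts = n_restarts)
  }
  tab <- data.table::data.table(
    model = candidates,
    lnL = vapply(fits, function(f) f$lnL, 0),
    n_free = vapply(fits, function(f) f$n_free, 0L),
    aic = vapply(fits, function(f) f$aic, 0))
  structure(list(fits = fits, best = best_by_aic(tab), aic = tab),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model_selection (best:", x$best, ")\n")
  print(x$aic)
  invisible(x)
}

#' Fit and select models across many genomes
#'
#' Runs [select_model()] on each per-genome distribution and reports, for
#' each candidate, the fraction of genomes for which it was preferred. Also
#' fits every candidate to the mean distribution over the genomes (weights
#' only; no AIC), the way parameter tables for a whole dataset are built.
#'
#' @param fsds named list of per-genome [family_size_distribution()]s.
#' @param candidates model names.
#' @param seed base seed.
#' @param n_restarts multi-start count per model.
#' @return a list of class `genome_fit_table`: `per_genome` (data.table of
#'   genome_id, best model, AIC per model), `fractions` (named numeric),
#'   `mean_fits` (named list of `fit_result` on the mean distribution).
#' @export
fit_all_genomes <- function(fsds, candidates = c("bdi1", "bdi2", "bdi3",
                                                 "bdi4", "gbdi", "powerlaw"),
                            seed = 1L, n_restarts = 10L) {
  stopifnot(length(fsds) >= 1L)
  set.seed(seed)
  genome_seeds <- sample.int(.Machine$integer.max - 1L, length(fsds))
  rows <- vector("list", length(fsds))
  for (i in seq_along(fsds)) {
    sel <- select_model(fsds[[i]], candidates, seed = genome_seeds[i],
                        n_restarts = n_restarts)
    aics <- stats::setNames(as.list(sel$aic$aic), paste0("aic_", sel$aic$model))
    rows[[i]] <- data.table::as.data.table(
      c(list(genome_id = fsds[[i]]$genome_id, best = sel$best), aics))
  }
  per_genome <- data.table::rbindlist(rows)
  fractions <- vapply(candidates,
                      function(m) mean(per_genome$best == m), 0)
  mfsd <- mean_distribution(fsds)
  set.seed(seed + 1L)
  mean_seeds <- sample.int(.Machine$integer.max - 1L, length(candidates))
  mean_fits <- stats::setNames(vector("list", length(candidates)), candidates)
  for (i in seq_along(candidates)) {
    mean_fits[[i]] <- fit_model(mfsd, candidates[i], seed = mean_seeds[i],
                                n_restarts = n_restarts)
  }
  structure(list(per_genome = per_genome, fractions = fractions,
                 mean_fits = mean_fits),
            class = "genome_fit_table")
}

#' @export
print.genome_fit_table <- function(x, ...) {
  cat("fraction of genomes preferring each model:\n")
  print(round(x$fractions, 3))
  invisible(x)
}
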