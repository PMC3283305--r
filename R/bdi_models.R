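# Numerical guard band for the duplication/deletion ratio r: the stationary
# law is singular at r = 0 and r = 1, so evaluation clamps r into
# [1e-9, 1 - 1e-9] (clamping is reported via message()).
.r_eps <- 1e-9

clamp_r <- function(r, quiet = FALSE) {
  lo <- .r_eps; hi <- 1 - .r_eps
  out <- pmin(pmax(r, lo), hi)
  if (!quiet && any(out != r)) {
    message("r clamped into [", lo, ", ", hi, "] for numerical evaluation")
  }
  out
}

#' Single-class birth-death-innovation parameters (BDI1)
#'
#' The BDI1 model assumes per-gene duplication rate lambda and deletion rate
#' delta (so a family of n genes gains at rate n*lambda and shrinks at rate
#' n*delta) plus an innovation rate u creating new single-gene families.
#' The stationary family-size law depends only on the ratio r = lambda/delta;
#' `u/delta` sets the absolute number of families.
#'
#' @param r duplication/deletion ratio, in (0, 1) for a proper stationary
#'   distribution. Values inside (0,1) but within 1e-9 of a boundary are
#'   clamped (with a message).
#' @param u_over_delta optional positive scale `u/delta` (expected number of
#'   single-gene families); `NA` when only the shape is of interest.
#' @return an object of class `bdi1_params`.
#' @export
bdi1_params <- function(r, u_over_delta = NA_real_) {
  stopifnot(is.numeric(r), length(r) == 1L)
  if (!(r > 0 && r < 1)) stop("r must lie strictly in (0, 1)")
  if (!is.na(u_over_delta) && u_over_delta <= 0) {
    stop("u_over_delta must be positive")
  }
  structure(list(r = clamp_r(r), u_over_delta = u_over_delta),
            class = "bdi1_params")
}

#' K-class mixture parameters (BDIK)
#'
#' K gene classes, each evolving as an independent BDI1 process with its own
#' ratio `r[k]`; class k holds a fraction `xi[k]` of all families. The
#' ratios must be strictly increasing (the classes are identifiable only up
#' to relabelling, so the ordered labelling is canonical). The model has
#' 2K - 1 free shape parameters.
#'
#' @param xi positive class weights summing to 1.
#' @param r strictly increasing ratios, each in (0, 1).
#' @return an object of class `bdik_params`.
#' @export
bdik_params <- function(xi, r) {
  stopifnot(length(xi) == length(r), length(r) >= 1L)
  if (any(xi <= 0)) stop("all class weights xi must be positive")
  if (abs(sum(xi) - 1) > 1e-8) stop("class weights xi must sum to 1")
  if (any(r <= 0 | r >= 1)) stop("all ratios r must lie strictly in (0, 1)")
  if (length(r) > 1L && any(diff(r) <= 0)) {
    stop("ratios r must be strictly increasing (r1 < r2 < ... < rK)")
  }
  structure(list(K = length(r), xi = xi / sum(xi), r = clamp_r(r)),
            class = "bdik_params")
}

#' Generalized birth-death-innovation parameters (GBDI)
#'
#' Size-dependent rates `lambda_n = lambda (n + a)` and
#' `delta_n = delta (n + b)`; three shape parameters r = lambda/delta, a, b.
#' The stationary law converges for r < 1, or for r = 1 provided b > a
#' (the "second-order balanced" case), where it approaches a power law
#' `q_n ~ n^-(1 + b - a)` at large n.
#'
#' @param r ratio in (0, 1]; r = 1 requires `b > a`.
#' @param a birth offset, > 0.
#' @param b death offset, > -2 (so that delta_n > 0 for all n >= 2).
#' @return an object of class `gbdi_params`.
#' @export
gbdi_params <- function(r, a, b) {
  stopifnot(is.numeric(r), is.numeric(a), is.numeric(b))
  if (!(r > 0 && r <= 1)) stop("r must lie in (0, 1]")
  if (a <= 0) stop("a must be positive")
  if (b <= -2) stop("b must exceed -2")
  if (r >= 1 - .r_eps && b <= a) {
    stop("at r = 1 the distribution converges only for b > a")
  }
  structure(list(r = r, a = a, b = b), class = "gbdi_params")
}

#' Discrete power-law parameters
#'
#' `q_n = n^-gamma / zeta(gamma)` over n >= 1; one free parameter.
#'
#' @param gamma exponent, > 1 for normalizability.
#' @return an object of class `powerlaw_params`.
#' @export
powerlaw_params <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L)
  if (gamma <= 1) stop("gamma must exceed 1")
  structure(list(gamma = gamma), class = "powerlaw_params")
}

#' @export
print.bdi1_params <- function(x, ...) {
  cat(sprintf("BDI1: r = %.6g, u/delta = %.6g\n", x$r, x$u_over_delta))
  invisible(x)
}
#' @export
print.bdik_params <- function(x, ...) {
  cat(sprintf("BDI%d: xi = (%s), r = (%s)\n", x$K,
              paste(sprintf("%.4g", x$xi), collapse = ", "),
              paste(sprintf("%.4g", x$r), collapse = ", ")))
  invisible(x)
}
#' @export
print.gbdi_params <- function(x, ...) {
  cat(sprintf("GBDI: r = %.6g, a = %.6g, b = %.6g\n", x$r, x$a, x$b))
  invisible(x)
}
#' @export
print.powerlaw_params <- function(x, ...) {
  cat(sprintf("power law: gamma = %.6g\n", x$gamma))
  invisible(x)
}

#' Normalizing series Phi(r) = sum_{n>=1} r^(n-1)/n = -log(1-r)/r
#'
#' Links the family-count scale to the shape: the expected total number of
#' families is `f_tot = (u/delta) * Phi(r)`.
#'
#' @param r ratio in (0, 1).
#' @return Phi(r).
#' @export
bdi_phi <- function(r) {
  r <- clamp_r(r, quiet = TRUE)
  -log1p(-r) / r
}

#' Stationary family-size probabilities under BDI1
#'
#' `q_n = r^n / (n * (-log(1 - r)))`, the logarithmic-series distribution.
#'
#' @param params a [bdi1_params()] (or a bare numeric r).
#' @param n vector of family sizes (integers >= 1).
#' @return probabilities q_n.
#' @export
bdi1_qn <- function(params, n) {
  r <- if (inherits(params, "bdi1_params")) params$r else clamp_r(params)
  stopifnot(all(n >= 1))
  exp(n * log(r) - log(n) - log(-log1p(-r)))
}

#' Mean family size under BDI1
#'
#' `nbar(r) = r / ((1 - r) * (-log(1 - r)))`; strictly increasing, tending
#' to 1 as r -> 0 and diverging as r -> 1.
#'
#' @param r ratio(s) in (0, 1).
#' @return mean family size(s).
#' @export
bdi1_mean <- function(r) {
  stopifnot(all(r > 0 & r < 1))
  r <- clamp_r(r, quiet = TRUE)
  r / ((1 - r) * (-log1p(-r)))
}

#' Expected family counts f(n) under BDI1
#'
#' `f(n) = (u/delta) * r^(n-1) / n`. Satisfies detailed balance
#' `f(n) * n * delta = f(n-1) * (n-1) * lambda` and the innovation balance
#' `u = delta * f(1)`.
#'
#' @param params a [bdi1_params()] with `u_over_delta` set.
#' @param n family sizes (>= 1).
#' @return expected counts f(n).
#' @export
bdi1_fn <- function(params, n) {
  stopifnot(inherits(params, "bdi1_params"), !is.na(params$u_over_delta),
            all(n >= 1))
  params$u_over_delta * exp((n - 1) * log(params$r) - log(n))
}

#' Expected total number of families under BDI1
#' @inheritParams bdi1_fn
#' @return `f_tot = (u/delta) * Phi(r)`.
#' @export
bdi1_ftot <- function(params) {
  stopifnot(inherits(params, "bdi1_params"), !is.na(params$u_over_delta))
  params$u_over_delta * bdi_phi(params$r)
}

#' Calibrate the innovation scale to an observed family count
#'
#' Chooses `u/delta` so that the model's expected total number of families
#' equals the observed `F_tot` exactly: `u/delta = F_tot / Phi(r)`.
#'
#' @param r fitted ratio in (0, 1).
#' @param observed_f_tot observed total number of families (> 0).
#' @return the calibrated `u/delta`.
#' @export
calibrate_scale <- function(r, observed_f_tot) {
  stopifnot(r > 0, r < 1, observed_f_tot > 0)
  observed_f_tot / bdi_phi(r)
}

#' Stationary probabilities for a model
#'
#' Generic dispatching on the parameter class: BDI1, BDIK mixtures, GBDI
#' and the discrete power law all provide `model_qn`.
#'
#' @param params a parameter object.
#' @param n vector of family sizes (integers >= 1).
#' @param ... passed to methods.
#' @return probabilities q_n.
#' @export
model_qn <- function(params, n, ...) UseMethod("model_qn")

#' @export
model_qn.bdi1_params <- function(params, n, ...) bdi1_qn(params, n)

#' @rdname model_qn
#' @export
bdik_qn <- function(params, n) {
  stopifnot(inherits(params, "bdik_params"), all(n >= 1))
  comp <- vapply(seq_len(params$K),
                 function(k) params$xi[k] * bdi1_qn(params$r[k], n),
                 numeric(length(n)))
  if (length(n) == 1L) sum(comp) else rowSums(matrix(comp, nrow = length(n)))
}

#' @export
model_qn.bdik_params <- function(params, n, ...) bdik_qn(params, n)

# Unnormalized log-weights of the GBDI stationary law:
# w_1 = 1, w_n = prod_{m=2}^{n} r (m - 1 + a) / (m + b).
gbdi_log_weights <- function(params, N) {
  m <- seq(2L, N)
  c(0, cumsum(log(params$r) + log(m - 1 + params$a) - log(m + params$b)))
}

# Truncation point and additive tail estimate for the GBDI normalizer.
# For r < 1 the weights are eventually geometric with ratio -> r, so the
# support is truncated where a geometric bound certifies a negligible tail
# (capped at n_max_support); for r = 1 the weights fall off as
# n^-(1+b-a) and an integral tail estimate is added.
gbdi_normalizer <- function(params, n_max_support = 1e5) {
  r <- params$r; a <- params$a; b <- params$b
  if (r < 1 - .r_eps) {
    # smallest N with r^N roughly below machine tail, subject to the cap
    N <- min(n_max_support, max(1000, ceiling(log(1e-300) / log(r))))
  } else {
    N <- n_max_support
  }
  logw <- gbdi_log_weights(params, N)
  mx <- max(logw)
  Z_body <- sum(exp(logw - mx))
  wN <- exp(logw[N] - mx)
  if (r < 1 - .r_eps) {
    rho <- max(r, r * (N + a) / (N + 1 + b))
    tail <- if (rho < 1) wN * rho / (1 - rho) else Inf
  } else {
    tail <- wN * N / (b - a)
  }
  list(log_scale = mx, Z = Z_body + tail, N = N, logw = logw,
       tail_fraction = tail / (Z_body + tail))
}

#' @rdname model_qn
#' @param n_max_support truncation bound for the GBDI normalizing sum; the
#'   series is summed to `max(n_max_support, max(n))` with a certified tail
#'   estimate (geometric for r < 1, integral for r = 1).
#' @export
gbdi_qn <- function(params, n, n_max_support = 1e5) {
  stopifnot(inherits(params, "gbdi_params"), all(n >= 1))
  N <- max(n_max_support, max(n))
  nz <- gbdi_normalizer(params, n_max_support = N)
  out <- numeric(length(n))
  inb <- n <= nz$N  # sizes beyond the certified truncation have underflowed
  out[inb] <- exp(nz$logw[n[inb]] - nz$log_scale - log(nz$Z))
  out
}

#' @export
model_qn.gbdi_params <- function(params, n, ...) gbdi_qn(params, n, ...)

#' Riemann zeta function for real s > 1
#'
#' Euler-Maclaurin evaluation: direct summation of the first `N` terms plus
#' integral and Bernoulli corrections; absolute error is far below 1e-12
#' throughout s in (1.01, 50].
#'
#' @param s exponent, > 1.
#' @param N number of directly summed terms.
#' @return zeta(s).
#' @export
riemann_zeta <- function(s, N = 1e4) {
  stopifnot(s > 1)
  n <- seq_len(N)
  sum(n^(-s)) + N^(1 - s) / (s - 1) - N^(-s) / 2 +
    s * N^(-s - 1) / 12 - s * (s + 1) * (s + 2) * N^(-s - 3) / 720
}

#' @rdname model_qn
#' @export
powerlaw_qn <- function(params, n) {
  stopifnot(inherits(params, "powerlaw_params"), all(n >= 1))
  n^(-params$gamma) / riemann_zeta(params$gamma)
}

#' @export
model_qn.powerlaw_params <- function(params, n, ...) powerlaw_qn(params, n)

#' Log-likelihood of a family size distribution under a model
#'
#' `lnL = sum_n F(n) * log(q_n)`. Counts may be real-valued (mean
#' distributions used as weights). Returns `-Inf` when any size with
#' positive count has zero (underflowed) probability; an empty distribution
#' has log-likelihood 0.
#'
#' @param params a model parameter object ([bdi1_params()],
#'   [bdik_params()], [gbdi_params()] or [powerlaw_params()]).
#' @param fsd a [family_size_distribution()].
#' @param ... passed to [model_qn()].
#' @return the log-likelihood.
#' @export
log_likelihood <- function(params, fsd, ...) {
  stopifnot(inherits(fsd, "family_size_distribution"))
  if (length(fsd$n) == 0L) return(0)
  q <- model_qn(params, fsd$n, ...)
  if (any(q <= 0 & fsd$count > 0)) return(-Inf)
  sum(fsd$count * log(q))
}
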