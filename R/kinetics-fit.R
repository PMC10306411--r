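# Global exponential fitting of right singular vectors: all RSVs share one
# set of time constants; amplitudes are per-RSV linear parameters profiled
# out analytically (variable projection), so the nonlinear search runs only
# over log(tau).

# Scaled complementary error function exp(z^2) erfc(z); asymptotic series
# beyond the range where the library routine is stable.
.erfcx <- function(z) {
  out <- numeric(length(z))
  small <- z < 25
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    out[!small] <- (1 - 1 / (2 * zz^2) + 3 / (4 * zz^4) - 15 / (8 * zz^6)) /
      (zz * sqrt(pi))
  }
  out
}

#' Exponential decay convolved with a Gaussian instrument response
#'
#' Exact convolution of a causal exponential `exp(-(t - t0)/tau)` (zero before
#' `t0`) with a normalized Gaussian of full width at half maximum `irf_fwhm`
#' centered at `t0`:
#' `h(t) = 1/2 exp(s^2/(2 tau^2) - (t-t0)/tau) erfc(s/(tau sqrt(2)) - (t-t0)/(s sqrt(2)))`
#' with `s = irf_fwhm / sqrt(8 log 2)`. `tau = Inf` gives the IRF-broadened
#' step `1/2 erfc(-(t-t0)/(s sqrt 2))`; `irf_fwhm = 0` gives the sharp
#' exponential. Evaluated in the scaled-complementary-error-function form, so
#' it is overflow-safe for any `tau/s` ratio.
#'
#' @param t Time delays, ps.
#' @param tau Decay constant, ps; positive or `Inf` (step).
#' @param t0 Time zero, ps.
#' @param irf_fwhm Gaussian IRF full width at half maximum, ps (>= 0).
#' @return Numeric vector, same length as `t`.
#' @examples
#' irf_exp(10, tau = 10, t0 = 0, irf_fwhm = 0)  # exp(-1)
#' @export
irf_exp <- function(t, tau, t0 = 0, irf_fwhm = 0) {
  t <- as.numeric(t)
  if (irf_fwhm < 0) stop("irf_fwhm must be >= 0", call. = FALSE)
  if (!is.infinite(tau) && tau <= 0)
    stop("tau must be positive or Inf", call. = FALSE)
  x <- t - t0
  if (irf_fwhm == 0) {
    if (is.infinite(tau)) return(as.numeric(x >= 0))
    return(ifelse(x >= 0, exp(-x / tau), 0))
  }
  s <- irf_fwhm / sqrt(8 * log(2))
  if (is.infinite(tau)) return(0.5 * pracma::erfc(-x / (s * sqrt(2))))
  z <- s / (tau * sqrt(2)) - x / (s * sqrt(2))
  out <- numeric(length(x))
  pos <- z >= 0
  # exp(a) erfc(z) = erfcx(z) exp(a - z^2); here a - z^2 = -x^2 / (2 s^2)
  out[pos] <- 0.5 * .erfcx(z[pos]) * exp(-x[pos]^2 / (2 * s^2))
  out[!pos] <- 0.5 * exp(s^2 / (2 * tau^2) - x[!pos] / tau) *
    pracma::erfc(z[!pos])
  out
}

# Design matrix of IRF-convolved exponentials (+ optional constant column).
.irf_design <- function(t, taus, t0, irf_fwhm, offset) {
  X <- vapply(taus, function(tau) irf_exp(t, tau, t0, irf_fwhm),
              numeric(length(t)))
  if (offset) X <- cbind(X, 1)
  X
}

# Profiled SSE: given taus, solve amplitudes per RSV by linear least squares.
.profiled_sse <- function(taus, t, V, t0, irf_fwhm, offset) {
  X <- .irf_design(t, taus, t0, irf_fwhm, offset)
  fit <- tryCatch(lm.fit(X, V), error = function(e) NULL)
  if (is.null(fit)) return(list(sse = Inf))
  res <- V - X %*% fit$coefficients
  list(sse = sum(res^2), coef = fit$coefficients, X = X)
}

#' Global multi-exponential fit of right singular vectors
#'
#' Fits the first `k` RSVs simultaneously with a sum of `n_exp` IRF-convolved
#' exponentials sharing one set of time constants; amplitudes are free per
#' RSV. Time constants are optimized in log space with multiple deterministic
#' log-spaced starting points; the best final residual wins, ties broken by
#' the lexicographically smallest sorted tau vector.
#'
#' @param svd_res An [svd_decompose()] result.
#' @param k Number of RSVs to fit jointly.
#' @param n_exp Number of shared exponentials.
#' @param irf_fwhm Gaussian IRF FWHM in ps (fixed).
#' @param t0 Time zero in ps (fixed).
#' @param offset If `TRUE`, each RSV additionally gets a free constant
#'   (long-lived plateau).
#' @param sv_weighted If `TRUE`, RSV residuals are weighted by their singular
#'   values.
#' @param n_starts Number of multi-start tau grids.
#' @param tau_bounds Optional length-2 vector of tau bounds in ps; default
#'   `[0.1 * min spacing, 10 * max t]`.
#' @return Object of class `global_fit_result`: `taus` (ascending, ps),
#'   `tau_se` (standard errors from the Jacobian at the optimum),
#'   `amplitudes` (k x n_exp [+offset] matrix), `t0`, `irf_fwhm`,
#'   `residual_norm`, `covariance` (over log-tau), `fitted` (n_t x k matrix).
#' @export
global_fit_rsvs <- function(svd_res, k, n_exp, irf_fwhm = 0, t0 = 0,
                            offset = FALSE, sv_weighted = FALSE,
                            n_starts = 5, tau_bounds = NULL) {
  stopifnot(inherits(svd_res, "svd_result"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(svd_res$rsv))
    stop("k out of range", call. = FALSE)
  if (n_exp < 1L) stop("n_exp must be >= 1", call. = FALSE)
  t <- svd_res$t
  V <- svd_res$rsv[, 1:k, drop = FALSE]
  if (sv_weighted) V <- sweep(V, 2, svd_res$sv[1:k], `*`)

  tpos <- t[t > t0]
  if (length(tpos) < n_exp + 1L)
    stop("too few positive delays to constrain the fit", call. = FALSE)
  if (is.null(tau_bounds)) {
    dt_min <- min(diff(t))
    tau_bounds <- c(0.1 * dt_min, 10 * max(tpos))
  }
  lb <- log(tau_bounds[1]); ub <- log(tau_bounds[2])

  # Deterministic multi-start: n_exp-point log-spaced ladders sliding across
  # the admissible window, plus one maximally spread ladder.
  starts <- list(seq(lb + 0.05 * (ub - lb), ub - 0.05 * (ub - lb),
                     length.out = n_exp))
  span <- (ub - lb) / max(2, n_exp)
  for (i in seq_len(max(0, n_starts - 1))) {
    cen <- lb + (i / n_starts) * (ub - lb)
    starts[[i + 1L]] <- seq(cen - span / 2, cen + span / 2,
                            length.out = n_exp)
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, lb), ub))

  obj <- function(ltau) {
    if (any(ltau < lb - 20) || any(ltau > ub + 20)) return(1e30)
    .profiled_sse(exp(ltau), t, V, t0, irf_fwhm, offset)$sse
  }
  best <- NULL
  for (s0 in starts) {
    opt <- tryCatch(
      if (n_exp == 1L) {
        stats::optim(s0, obj, method = "Brent",
                     lower = lb - 5, upper = ub + 5,
                     control = list(maxit = 4000))
      } else {
        stats::optim(s0, obj, method = "Nelder-Mead",
                     control = list(maxit = 4000, reltol = 1e-14))
      },
      error = function(e) NULL)
    if (is.null(opt)) next
    # polish with BFGS (numeric gradient)
    opt2 <- tryCatch(
      stats::optim(opt$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) opt)
    cand <- if (!is.null(opt2) && opt2$value <= opt$value) opt2 else opt
    cand$par <- sort(cand$par)
    if (is.null(best) || cand$value < best$value - 1e-15 ||
        (abs(cand$value - best$value) <= 1e-15 &&
         isTRUE(all(cand$par < best$par)[1])))
      best <- cand
  }
  if (is.null(best) || !is.finite(best$value))
    stop("global RSV fit failed to converge from every start", call. = FALSE)

  taus <- exp(best$par)
  final <- .profiled_sse(taus, t, V, t0, irf_fwhm, offset)
  amps <- t(final$coef)                      # k x (n_exp [+1])
  colnames(amps) <- c(paste0("tau", seq_len(n_exp)),
                      if (offset) "offset" else NULL)

  # Covariance of log-tau from the Gauss-Newton approximation at the optimum.
  nobs <- length(t) * k
  npar <- n_exp + k * ncol(amps)
  dof <- max(1L, nobs - npar)
  s2 <- final$sse / dof
  J <- matrix(0, nobs, n_exp)
  h <- 1e-6
  r0 <- as.numeric(V - final$X %*% final$coef)
  for (j in seq_len(n_exp)) {
    lt <- log(taus); lt[j] <- lt[j] + h
    pj <- .profiled_sse(exp(lt), t, V, t0, irf_fwhm, offset)
    rj <- as.numeric(V - pj$X %*% pj$coef)
    J[, j] <- (rj - r0) / h
  }
  cov_ltau <- tryCatch(s2 * solve(crossprod(J)),
                       error = function(e) matrix(NA_real_, n_exp, n_exp))
  tau_se <- taus * sqrt(pmax(diag(cov_ltau), 0))

  structure(list(
    taus = taus, tau_se = tau_se, amplitudes = amps,
    t0 = t0, irf_fwhm = irf_fwhm, offset = offset,
    residual_norm = sqrt(final$sse),
    covariance = cov_ltau,
    fitted = final$X %*% final$coef,
    t = t), class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result>\n  tau (ps):",
      paste(sprintf("%.4g +/- %.2g", x$taus, x$tau_se), collapse = ", "),
      sprintf("\n  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}
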