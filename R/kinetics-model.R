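# Kinetic models and concentration profiles. Sequential chains use the
# Bateman closed form, each eigen-decay convolved exactly with the Gaussian
# IRF; general first-order rate matrices go through eigendecomposition with
# per-mode IRF convolution. Degenerate (repeated) rates fall back to dense
# ODE integration plus numerical convolution.

#' First-order kinetic model
#'
#' Either a sequential chain `A1 -> A2 -> ... -> An -> ground` with one time
#' constant per species, or a general first-order rate matrix `K` (ps^-1,
#' column j holds the rates out of species j; column sums <= 0, leakage to a
#' non-scattering ground state).
#'
#' @param species Character vector of species labels.
#' @param taus Time constants in ps (sequential scheme), one per species.
#' @param K Rate matrix in ps^-1 (rate-matrix scheme); supply `taus` or `K`,
#'   not both.
#' @param t0 Time zero, ps.
#' @param irf_fwhm Gaussian IRF FWHM, ps.
#' @param initial_fractions Simplex vector of excited-state populations at
#'   `t0`; defaults to everything in the first species.
#' @return Object of class `kinetic_model`.
#' @export
kinetic_model <- function(species, taus = NULL, K = NULL, t0 = 0,
                          irf_fwhm = 0, initial_fractions = NULL) {
  species <- as.character(species)
  n_s <- length(species)
  if (n_s < 1L) stop("at least one species required", call. = FALSE)
  if (is.null(initial_fractions)) {
    initial_fractions <- c(1, rep(0, n_s - 1))
  }
  if (length(initial_fractions) != n_s ||
      any(initial_fractions < 0) ||
      abs(sum(initial_fractions) - 1) > 1e-9)
    stop("initial_fractions must be a length-n_species simplex vector",
         call. = FALSE)
  if (!is.null(taus) && !is.null(K))
    stop("supply taus (sequential) or K (rate matrix), not both", call. = FALSE)
  if (!is.null(taus)) {
    taus <- as.numeric(taus)
    if (length(taus) != n_s || any(taus <= 0))
      stop("sequential scheme needs one positive tau per species", call. = FALSE)
    scheme <- "sequential"
  } else if (!is.null(K)) {
    K <- base::as.matrix(K)
    if (!all(dim(K) == n_s))
      stop("K must be n_species x n_species", call. = FALSE)
    if (any(colSums(K) > 1e-12))
      stop("columns of K must conserve mass (column sums <= 0)", call. = FALSE)
    scheme <- "rate_matrix"
  } else stop("supply taus or K", call. = FALSE)
  if (irf_fwhm < 0) stop("irf_fwhm must be >= 0", call. = FALSE)
  structure(list(species = species, scheme = scheme, taus = taus, K = K,
                 t0 = t0, irf_fwhm = irf_fwhm,
                 initial_fractions = initial_fractions),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %s, %d species (%s)\n", x$scheme,
              length(x$species), paste(x$species, collapse = " -> ")))
  if (x$scheme == "sequential")
    cat("  tau (ps):", paste(signif(x$taus, 4), collapse = ", "), "\n")
  cat(sprintf("  t0 = %g ps, IRF FWHM = %g ps\n", x$t0, x$irf_fwhm))
  invisible(x)
}

#' Species concentration profiles under a kinetic model
#'
#' Molar fractions `f_k(t)` of each solute species, IRF-broadened. The ground
#' state is implicit: row sums decay from 1 toward 0 as population leaks out
#' of the chain.
#'
#' @param model A [kinetic_model()].
#' @param t Time delays, ps.
#' @param R Solvent-to-solute number ratio carried along for scaling
#'   (default 1).
#' @return Object of class `concentration_matrix`: `t`, `C` (n_t x n_s),
#'   `species`, `R`.
#' @examples
#' m <- kinetic_model("A", taus = 10)
#' cp <- concentration_profiles(m, c(0, 10, 20))
#' cp$C[, 1]  # exp(-t/10)
#' @export
concentration_profiles <- function(model, t, R = 1) {
  stopifnot(inherits(model, "kinetic_model"))
  t <- as.numeric(t)
  if (R <= 0) stop("R must be positive", call. = FALSE)
  C <- if (model$scheme == "sequential") {
    .conc_sequential(model, t)
  } else {
    .conc_rate_matrix(model, t)
  }
  # clip tiny numerical excursions only
  lo <- C < 0 & C > -1e-9
  hi <- C > 1 & C < 1 + 1e-9
  C[lo] <- 0; C[hi] <- 1
  colnames(C) <- model$species
  structure(list(t = t, C = C, species = model$species, R = R),
            class = "concentration_matrix")
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat(sprintf("<concentration_matrix> %d delays x %d species (R = %g)\n",
              length(x$t), ncol(x$C), x$R))
  invisible(x)
}

.conc_sequential <- function(model, t) {
  n_s <- length(model$species)
  k <- 1 / model$taus
  # repeated rates make the Bateman denominators singular
  if (n_s > 1L) {
    gaps <- abs(outer(k, k, `-`)) / max(k)
    diag(gaps) <- Inf
    if (min(gaps) < 1e-9) return(.conc_ode(model, t))
  }
  decays <- vapply(seq_len(n_s), function(i)
    irf_exp(t, model$taus[i], model$t0, model$irf_fwhm),
    numeric(length(t)))
  C <- matrix(0, length(t), n_s)
  for (s in seq_len(n_s)) {                 # chain entered at species s
    p <- model$initial_fractions[s]
    if (p == 0) next
    for (j in s:n_s) {
      rate_prod <- if (j > s) prod(k[s:(j - 1)]) else 1
      for (i in s:j) {
        denom <- prod(k[setdiff(s:j, i)] - k[i])
        # j == s: empty product -> denom 1
        if (j == s) denom <- 1
        C[, j] <- C[, j] + p * rate_prod * decays[, i] / denom
      }
    }
  }
  C
}

.conc_rate_matrix <- function(model, t) {
  K <- model$K
  n_s <- nrow(K)
  eig <- eigen(K)
  if (any(abs(Im(eig$values)) > 1e-12 * max(abs(eig$values), 1)))
    return(.conc_ode(model, t))
  lam <- Re(eig$values)
  if (n_s > 1L) {
    gaps <- abs(outer(lam, lam, `-`)) / max(abs(lam), 1e-30)
    diag(gaps) <- Inf
    if (min(gaps) < 1e-9) return(.conc_ode(model, t))
  }
  V <- Re(eig$vectors)
  coef <- tryCatch(solve(V, model$initial_fractions),
                   error = function(e) NULL)
  if (is.null(coef)) return(.conc_ode(model, t))
  C <- matrix(0, length(t), n_s)
  for (i in seq_len(n_s)) {
    tau_i <- if (abs(lam[i]) < 1e-30) Inf else -1 / lam[i]
    if (is.finite(tau_i) && tau_i <= 0)
      stop("rate matrix has a growing mode (positive eigenvalue)",
           call. = FALSE)
    mode_t <- irf_exp(t, tau_i, model$t0, model$irf_fwhm)
    C <- C + outer(mode_t, coef[i] * V[, i])
  }
  C
}

# Dense fallback: integrate the rate equations, then convolve numerically
# with the Gaussian IRF on a fine uniform grid.
.conc_ode <- function(model, t) {
  n_s <- length(model$species)
  K <- if (model$scheme == "sequential") {
    k <- 1 / model$taus
    M <- diag(-k, n_s)
    if (n_s > 1L) for (j in seq_len(n_s - 1L)) M[j + 1L, j] <- k[j]
    M
  } else model$K
  s <- model$irf_fwhm / sqrt(8 * log(2))
  t_rel_max <- max(t - model$t0, 1e-6) + 6 * s
  n_grid <- 4000L
  tg <- seq(0, t_rel_max, length.out = n_grid)
  deriv <- function(tt, y, parms) list(as.numeric(K %*% y))
  sol <- deSolve::lsoda(y = model$initial_fractions, times = tg,
                        func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  Fg <- sol[, -1, drop = FALSE]             # delta-IRF response on tg
  C <- matrix(0, length(t), n_s)
  for (j in seq_len(n_s)) {
    fj <- stats::approxfun(tg, Fg[, j], yleft = Fg[1, j],
                           yright = Fg[n_grid, j])
    if (s == 0) {
      C[, j] <- ifelse(t >= model$t0, fj(t - model$t0), 0)
    } else {
      # h(t) = int g(u) f(t - u) du over the Gaussian support
      ug <- seq(-6 * s, 6 * s, length.out = 601L)
      g <- exp(-ug^2 / (2 * s^2)) / (s * sqrt(2 * pi))
      du <- ug[2] - ug[1]
      for (i in seq_along(t)) {
        x <- t[i] - model$t0 - ug
        fv <- ifelse(x >= 0, fj(x), 0)
        C[i, j] <- sum(g * fv) * du
      }
    }
  }
  C
}

#' Kinetics-constrained extraction of species-associated curves
#'
#' Given PEPC-treated data and fixed concentration profiles, solves
#' `dS_PEPC ~ (1/R) SADS C^T` for the per-species difference curves by linear
#' least squares. When `svd_rank` is supplied, the data are first replaced by
#' their rank-`svd_rank` truncation, so each recovered curve is exactly a
#' linear combination of the retained left singular vectors.
#'
#' @param ds_pepc A [trxl_dataset()] (typically PEPC-treated).
#' @param conc A [concentration_profiles()] result with full column rank over
#'   the dataset's delays.
#' @param svd_rank Optional truncation rank.
#' @param cond_max Condition-number ceiling for `C` beyond which the species
#'   kinetics are declared indistinguishable.
#' @return A [sads_set()] of kind `"pepc"` with per-species residual norms.
#' @export
extract_sads <- function(ds_pepc, conc, svd_rank = NULL, cond_max = 1e8) {
  stopifnot(inherits(ds_pepc, "trxl_dataset"),
            inherits(conc, "concentration_matrix"))
  if (length(conc$t) != length(ds_pepc$t) ||
      max(abs(conc$t - ds_pepc$t)) > 1e-9 * max(abs(ds_pepc$t)))
    stop("concentration profiles and dataset use different delays",
         call. = FALSE)
  ds_fit <- if (is.null(svd_rank)) ds_pepc else truncate_rank(ds_pepc, svd_rank)
  C <- conc$C
  sv <- svd(C)$d
  cond <- sv[1] / max(sv[length(sv)], .Machine$double.xmin)
  if (!is.finite(cond) || cond > cond_max)
    stop(sprintf("concentration matrix is ill-conditioned (condition number %.3g): species kinetics are indistinguishable",
                 cond), call. = FALSE)
  # dS^T ~ (1/R) C S^T  ->  S^T = R (C^T C)^-1 C^T dS^T
  St <- conc$R * solve(crossprod(C), crossprod(C, t(ds_fit$matrix)))
  S <- t(St)                                   # n_q x n_s
  resid <- ds_fit$matrix - (1 / conc$R) * S %*% t(C)
  res_norms <- vapply(seq_len(ncol(C)), function(k2) {
    ck <- C[, k2]
    sqrt(sum((resid %*% ck)^2)) / max(sqrt(sum(ck^2)), .Machine$double.xmin)
  }, numeric(1))
  curves <- lapply(seq_len(ncol(S)), function(k2)
    trxl_curve(ds_pepc$q, S[, k2], label = conc$species[k2]))
  sads_set(curves, kind = "pepc", species = conc$species,
           residual_norms = res_norms)
}
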