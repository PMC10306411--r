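# Forward simulation of complete TRXL datasets with full ground truth:
# solute term (1/R) sum_k f_k(t) SADS_k(q), solvent term
# dT(t) (dS/dT)_rho + drho(t) (dS/drho)_T, Gaussian IRF broadening, seeded
# additive noise. Every analysis stage in the package is tested against the
# stored truth.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic solvent differential basis
#'
#' Two smooth sum-of-Gaussian shapes in q standing in for `(dS/dT)_rho` and
#' `(dS/drho)_T`. Both are unit-normalized and the second is constructed with
#' an exact target cosine against the first: `water_like` uses cosine 0.98
#' (nearly collinear, as the two water differentials are), `distinct` uses
#' 0.15. Amplitude scalings are applied afterwards.
#'
#' @param q Momentum-transfer grid.
#' @param mode `"water_like"` or `"distinct"`.
#' @param amplitudes Length-2 scaling of the unit-norm curves.
#' @param cosine Optional override of the target cosine similarity.
#' @return A [trivial_set()] of two curves labelled `dSdT` and `dSdrho`.
#' @export
make_solvent_basis <- function(q, mode = c("water_like", "distinct"),
                               amplitudes = c(1, 1), cosine = NULL) {
  mode <- match.arg(mode)
  q <- as.numeric(q)
  target <- if (!is.null(cosine)) cosine else
    switch(mode, water_like = 0.98, distinct = 0.15)
  # two smooth, structurally different shapes
  g <- function(c0, w) exp(-((q - c0) / w)^2)
  s1 <- 1.0 * g(1.9, 0.55) - 0.85 * g(3.1, 0.75) + 0.25 * g(4.6, 0.9)
  s2 <- 0.7 * g(1.4, 0.45) - 0.5 * g(2.4, 0.5) + 0.9 * g(3.9, 0.8) -
    0.3 * g(6.0, 1.2)
  u1 <- s1 / sqrt(sum(s1^2))
  p2 <- s2 - sum(u1 * s2) * u1
  u2p <- p2 / sqrt(sum(p2^2))
  v2 <- target * u1 + sqrt(1 - target^2) * u2p
  trivial_set(
    trxl_curve(q, amplitudes[1] * u1, label = "dSdT"),
    trxl_curve(q, amplitudes[2] * v2, label = "dSdrho"))
}

#' Seeded additive Gaussian noise
#'
#' @param matrix Numeric matrix.
#' @param sigma Scalar standard deviation, or a per-row (per-q) vector.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @return Matrix of the same shape.
#' @export
add_noise <- function(matrix, sigma, seed) {
  matrix <- base::as.matrix(matrix)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (!(length(sigma) %in% c(1L, nrow(matrix))))
    stop("sigma must be scalar or one value per q point", call. = FALSE)
  .with_seed(seed, {
    noise <- matrix(stats::rnorm(length(matrix)), nrow(matrix))
    matrix + noise * sigma
  })
}

#' Simulation configuration
#'
#' Assembles every ingredient of the forward model. The solvent temperature
#' profile is an IRF-convolved step (prompt heating) plus a slower
#' exponential rise (vibrational-to-thermal relaxation); the density profile
#' is a delayed rise (thermal expansion lags heating).
#'
#' @param q Momentum-transfer grid, or `c(min, max, n)` spec (default
#'   `seq(0.3, 9, length.out = 300)`).
#' @param t Time delays in ps (include negative reference delays).
#' @param model A [kinetic_model()].
#' @param sads_real A [sads_set()] of kind `"real"`, one curve per species on
#'   the q-grid.
#' @param R Solvent:solute number ratio.
#' @param solvent_basis A [trivial_set()] of 2 solvent differentials (see
#'   [make_solvent_basis()]), or `NULL` for no solvent term.
#' @param dT_params List `amp_step`, `amp_slow`, `tau_slow_ps` for the
#'   temperature profile.
#' @param drho_params List `amp`, `tau_rise_ps` for the density profile.
#' @param noise `NULL` for noiseless, or a list with `sigma_rel` (fraction of
#'   the noiseless root-mean-square) or `sigma_abs` (absolute, scalar or
#'   per-q), optionally `one_over_q = TRUE` for a 1/q amplitude profile.
#' @param seed Integer seed; mandatory when noise is requested.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(q = NULL, t, model, sads_real, R = 1000,
                              solvent_basis = NULL,
                              dT_params = list(amp_step = 1, amp_slow = 1.5,
                                               tau_slow_ps = 100),
                              drho_params = list(amp = 1, tau_rise_ps = 1000),
                              noise = NULL, seed = NULL) {
  if (is.null(q)) q <- seq(0.3, 9, length.out = 300)
  if (length(q) == 3L && q[3] > 3 && q[3] == round(q[3]))
    q <- seq(q[1], q[2], length.out = q[3])
  stopifnot(inherits(model, "kinetic_model"), inherits(sads_real, "sads_set"))
  if (length(sads_real$curves) != length(model$species))
    stop("one SADS per model species required", call. = FALSE)
  .check_shared_grid(q, sads_real$q)
  if (!is.null(solvent_basis)) {
    stopifnot(inherits(solvent_basis, "trivial_set"))
    .check_shared_grid(q, solvent_basis$q)
  }
  if (!is.null(noise) && is.null(seed))
    stop("seed is mandatory when noise is requested", call. = FALSE)
  structure(list(q = q, t = as.numeric(t), model = model,
                 sads_real = sads_real, R = R,
                 solvent_basis = solvent_basis,
                 dT_params = dT_params, drho_params = drho_params,
                 noise = noise, seed = seed),
            class = "simulation_config")
}

# Solvent response profiles: prompt IRF-broadened step plus slow rise.
.dT_profile <- function(t, p, t0, irf_fwhm) {
  p$amp_step * irf_exp(t, Inf, t0, irf_fwhm) +
    p$amp_slow * (irf_exp(t, Inf, t0, irf_fwhm) -
                    irf_exp(t, p$tau_slow_ps, t0, irf_fwhm))
}

.drho_profile <- function(t, p, t0, irf_fwhm) {
  p$amp * (irf_exp(t, Inf, t0, irf_fwhm) -
             irf_exp(t, p$tau_rise_ps, t0, irf_fwhm))
}

#' Simulate a complete TRXL dataset with ground truth
#'
#' Builds concentration profiles from the kinetic model, assembles the
#' noiseless matrix
#' `(1/R) SADS C^T + (dS/dT)_rho dT^T + (dS/drho)_T drho^T`, and adds seeded
#' Gaussian noise if configured. All intermediate truth quantities are
#' stored, including the projection-distorted species curves and their d
#' coefficients against the solvent basis.
#'
#' @param config A [simulation_config()].
#' @return Object of class `simulation_output`: `dataset` (a
#'   [trxl_dataset()], with `sigma` populated when noise was added) and
#'   `truth` (list: `conc`, `sads_real`, `sads_perp`, `d_coeffs` (m x n_s),
#'   `solvent_basis`, `dT`, `drho`, `noiseless`, `noise_sigma`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  q <- config$q; t <- config$t; model <- config$model
  conc <- concentration_profiles(model, t, R = config$R)
  S <- vapply(config$sads_real$curves, function(cv) cv$values,
              numeric(length(q)))
  M <- (1 / config$R) * S %*% t(conc$C)
  dT <- rep(0, length(t)); drho <- rep(0, length(t))
  sads_perp <- config$sads_real
  d_coeffs <- NULL
  if (!is.null(config$solvent_basis)) {
    dT <- .dT_profile(t, config$dT_params, model$t0, model$irf_fwhm)
    drho <- .drho_profile(t, config$drho_params, model$t0, model$irf_fwhm)
    B <- config$solvent_basis$basis
    M <- M + B[, 1] %o% dT + B[, 2] %o% drho
    decs <- lapply(config$sads_real$curves, decompose_sads,
                   trivials = config$solvent_basis)
    d_coeffs <- vapply(decs, function(d) d$d_coeffs,
                       numeric(ncol(B)))
    colnames(d_coeffs) <- config$sads_real$species
    sads_perp <- sads_set(lapply(decs, function(d) d$perpendicular),
                          kind = "pepc", species = config$sads_real$species)
  }
  noisy <- M
  sigma_mat <- NULL
  sigma_used <- 0
  if (!is.null(config$noise)) {
    nz <- config$noise
    sigma_used <- if (!is.null(nz$sigma_abs)) nz$sigma_abs
                  else nz$sigma_rel * sqrt(mean(M^2))
    if (isTRUE(nz$one_over_q))
      sigma_used <- sigma_used * (min(q) / q) * length(q) /
        sum(min(q) / q)                     # mean-preserving 1/q profile
    noisy <- add_noise(M, sigma_used, config$seed)
    sigma_mat <- matrix(sigma_used, length(q), length(t))
  }
  structure(list(
    dataset = trxl_dataset(q, t, noisy, sigma = sigma_mat,
                           meta = list(R = config$R, provenance = "synthetic")),
    truth = list(conc = conc, sads_real = config$sads_real,
                 sads_perp = sads_perp, d_coeffs = d_coeffs,
                 solvent_basis = config$solvent_basis,
                 dT = dT, drho = drho, noiseless = M,
                 noise_sigma = sigma_used),
    config = config), class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat("<simulation_output>\n  ")
  print(x$dataset)
  invisible(x)
}

#' Canned three-species scenario with a water-like solvent basis
#'
#' A gold-trimer-like photocycle: three sequential species with fs-ns-us time
#' constants (1.7 ps, 1.0 ns, 114 ns), a 0.48 ps Gaussian IRF, log-spaced
#' delays spanning 0.1 ps to 1 us plus negative references, and a nearly
#' collinear (water-like) pair of solvent differentials. Species curves come
#' from toy metal-cluster structures with contracting and aggregating metal
#' cores plus cage terms.
#'
#' @param n_t Number of positive log-spaced delays.
#' @param noise_rel Relative noise level (`NULL` for noiseless).
#' @param seed Seed for the noise realization.
#' @param basis_mode `"water_like"` (default) or `"distinct"`.
#' @return A [simulation_config()].
#' @export
sim_config_gtc_like <- function(n_t = 60, noise_rel = NULL, seed = NULL,
                                basis_mode = "water_like") {
  q <- seq(0.3, 9, length.out = 300)
  t <- c(-20, -10, -5, 10^seq(log10(0.1), log10(1e6), length.out = n_t))
  model <- kinetic_model(c("T1prime", "T1", "tetramer"),
                         taus = c(1.7, 1000, 114000),
                         t0 = 0, irf_fwhm = 0.48)
  au <- 79
  ground <- toy_structure(rep("Au", 3), rep(au, 3),
                          rbind(c(0, 0, 0), c(3.3, 0, 0), c(6.6, 0.4, 0)))
  exc1 <- toy_structure(rep("Au", 3), rep(au, 3),
                        rbind(c(0, 0, 0), c(2.8, 0, 0), c(5.6, 0.2, 0)))
  exc2 <- toy_structure(rep("Au", 3), rep(au, 3),
                        rbind(c(0, 0, 0), c(2.7, 0, 0), c(5.4, 0, 0)))
  exc3 <- toy_structure(rep("Au", 4), rep(au, 4),
                        rbind(c(0, 0, 0), c(2.7, 0, 0), c(5.4, 0, 0),
                              c(8.1, 0, 0)))
  mk <- function(st, lab, r0)
    sads_from_structures(st, ground, q,
                         cage = cage_curve(q, amplitude = 0.1 * au^2, r0 = r0),
                         label = lab)
  sads <- sads_set(list(mk(exc1, "T1prime", 3.8), mk(exc2, "T1", 4.0),
                        mk(exc3, "tetramer", 4.2)),
                   kind = "real")
  # heating and expansion terms each within a factor ~2 of the solute-term
  # Frobenius norm, as in strongly heated solution data
  simulation_config(
    q = q, t = t, model = model, sads_real = sads, R = 1000,
    solvent_basis = make_solvent_basis(q, basis_mode, amplitudes = c(30, 60)),
    dT_params = list(amp_step = 0.6, amp_slow = 1.2, tau_slow_ps = 50),
    drho_params = list(amp = 0.8, tau_rise_ps = 2000),
    noise = if (is.null(noise_rel)) NULL else list(sigma_rel = noise_rel),
    seed = seed)
}

#' Canned null-hypothesis scenario with known-pathway components removed
#'
#' A haloform-photolysis-like setup: two known product pathways (their
#' difference curves treated as trivial components alongside the two distinct
#' solvent differentials) plus, optionally, one hidden isomer species whose
#' kinetics should survive projection. Used to exercise the residual
#' null-hypothesis test.
#'
#' @param hidden If `TRUE`, the hidden isomer pathway is active.
#' @param hidden_scale Multiplier on the hidden species amplitude. The
#'   default places the hidden pathway's projection residual at roughly ten
#'   times the noise floor when the default 5% relative noise is used.
#' @param noise_rel Relative noise level (`NULL` for noiseless).
#' @param seed Seed for the noise realization.
#' @return List with elements `config` (a [simulation_config()]), `trivials`
#'   (the 4-component [trivial_set()] to remove) and `hidden_f` (the hidden
#'   species' concentration profile, `NULL` when inactive).
#' @export
sim_config_chi3_like <- function(hidden = TRUE, hidden_scale = 7,
                                 noise_rel = NULL, seed = NULL) {
  q <- seq(0.3, 9, length.out = 300)
  t <- c(-50, -20, -10, 10^seq(log10(1), log10(1e6), length.out = 40))
  iodine <- 53; carbon <- 6
  chi3 <- toy_structure(c("C", "I", "I", "I"), c(carbon, rep(iodine, 3)),
                        rbind(c(0, 0, 0), c(2.15, 0, 0),
                              c(-1.0, 1.9, 0), c(-1.0, -1.9, 0)))
  chi2_rad <- toy_structure(c("C", "I", "I"), c(carbon, rep(iodine, 2)),
                            rbind(c(0, 0, 0), c(2.1, 0.2, 0),
                                  c(-1.0, 1.85, 0)))
  chi2_i2 <- toy_structure(c("C", "I", "I", "I", "I"),
                           c(carbon, rep(iodine, 4)),
                           rbind(c(0, 0, 0), c(2.1, 0.2, 0),
                                 c(-1.0, 1.85, 0), c(6, 0, 0), c(8.67, 0, 0)))
  iso <- toy_structure(c("C", "I", "I", "I"), c(carbon, rep(iodine, 3)),
                       rbind(c(0, 0, 0), c(2.12, 0, 0),
                             c(-1.0, 1.9, 0), c(-3.0, 2.6, 0)))
  s_known1 <- sads_from_structures(chi2_rad, chi3, q, label = "CHI2_plus_I")
  s_known2 <- sads_from_structures(chi2_i2, chi3, q, label = "CHI2_plus_halfI2")
  s_hidden <- sads_from_structures(iso, chi3, q, label = "iso_CHI2_I")
  s_hidden$values <- s_hidden$values * hidden_scale
  basis <- make_solvent_basis(q, "distinct", amplitudes = c(6, 6))
  species <- c("CHI2_plus_I", "CHI2_plus_halfI2", "iso_CHI2_I")
  # two parallel pathways: dissociation (species 1 feeds species 2, radical
  # -> molecular iodine) and, when active, isomerization (species 3 decays
  # to ground on its own)
  K <- matrix(0, 3, 3)
  K[1, 1] <- -1 / 100; K[2, 1] <- 1 / 100
  K[2, 2] <- -1 / 5e4
  K[3, 3] <- -1 / 2.5e4
  model <- kinetic_model(species, K = K, t0 = 0, irf_fwhm = 1,
                         initial_fractions = if (hidden) c(0.45, 0.2, 0.35)
                                             else c(0.6, 0.4, 0))
  sads <- sads_set(list(s_known1, s_known2, s_hidden), kind = "real")
  cfg <- simulation_config(
    q = q, t = t, model = model, sads_real = sads, R = 1000,
    solvent_basis = basis,
    dT_params = list(amp_step = 0.5, amp_slow = 1.0, tau_slow_ps = 30),
    drho_params = list(amp = 0.7, tau_rise_ps = 1500),
    noise = if (is.null(noise_rel)) NULL else list(sigma_rel = noise_rel),
    seed = seed)
  trivials <- trivial_set(basis$components[[1]], basis$components[[2]],
                          s_known1, s_known2)
  hidden_f <- if (hidden) {
    conc <- concentration_profiles(model, cfg$t)
    conc$C[, 3]
  } else NULL
  list(config = cfg, trivials = trivials, hidden_f = hidden_f)
}
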