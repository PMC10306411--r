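# End-to-end orchestration: projection -> SVD -> rank selection -> global
# exponential fit -> kinetics-constrained species extraction -> optional
# structural correction -> solvent hydrodynamics; plus dataset splitting and
# the null-hypothesis residual test.

#' Split a dataset at a time delay
#'
#' @param ds A [trxl_dataset()].
#' @param t_split Split point in ps, strictly inside the delay range; early
#'   holds `t < t_split`, late holds `t >= t_split`.
#' @return List with [trxl_dataset()] elements `early` and `late`.
#' @export
split_dataset <- function(ds, t_split) {
  stopifnot(inherits(ds, "trxl_dataset"))
  early_idx <- ds$t < t_split
  if (!any(early_idx) || all(early_idx))
    stop("t_split must leave delays on both sides", call. = FALSE)
  sub <- function(idx) trxl_dataset(
    ds$q, ds$t[idx], ds$matrix[, idx, drop = FALSE],
    sigma = if (is.null(ds$sigma)) NULL else ds$sigma[, idx, drop = FALSE],
    meta = ds$meta)
  list(early = sub(early_idx), late = sub(!early_idx))
}

#' Null-hypothesis residual test
#'
#' If every signal component is in the trivial span, projection leaves only
#' noise. The statistic is the Frobenius-norm fraction of the PEPC residual
#' over positive delays; the noise floor is the same statistic predicted from
#' the uncertainty matrix when present, otherwise from negative-delay
#' (noise-only) columns. `signal_remains` is declared when the residual
#' fraction exceeds `factor` times the noise floor.
#'
#' @param ds A [trxl_dataset()] with negative reference delays and/or a sigma
#'   matrix.
#' @param trivials The [trivial_set()] asserting the null-hypothesis signal
#'   content.
#' @param factor Decision multiplier on the noise floor.
#' @return Object of class `residual_test_report`: `residual_fraction`,
#'   `noise_floor`, `decision` (`"signal_remains"` or
#'   `"consistent_with_null"`), `factor`, `per_delay_norms` (data frame of
#'   delay, input norm, residual norm).
#' @export
residual_test <- function(ds, trivials, factor = 3.0) {
  stopifnot(inherits(ds, "trxl_dataset"), inherits(trivials, "trivial_set"))
  res <- pepc_multi(ds, trivials)
  pos <- ds$t > 0
  neg <- ds$t < 0
  if (!any(pos)) stop("no positive delays to test", call. = FALSE)
  norm_in_pos <- norm(ds$matrix[, pos, drop = FALSE], "F")
  norm_res_pos <- norm(res$pepc$matrix[, pos, drop = FALSE], "F")
  residual_fraction <- norm_res_pos / max(norm_in_pos, .Machine$double.xmin)
  if (!is.null(ds$sigma)) {
    noise_floor <- sqrt(sum(ds$sigma[, pos]^2)) /
      max(norm_in_pos, .Machine$double.xmin)
  } else if (any(neg)) {
    # noise-only columns, projected the same way, scaled to the number of
    # positive delays
    norm_res_neg <- norm(res$pepc$matrix[, neg, drop = FALSE], "F")
    noise_floor <- norm_res_neg * sqrt(sum(pos) / sum(neg)) /
      max(norm_in_pos, .Machine$double.xmin)
  } else {
    stop("need negative-delay columns or a sigma matrix for the noise floor",
         call. = FALSE)
  }
  per_delay <- data.frame(
    t = ds$t,
    input_norm = apply(ds$matrix, 2, function(v) sqrt(sum(v^2))),
    residual_norm = apply(res$pepc$matrix, 2, function(v) sqrt(sum(v^2))))
  structure(list(
    residual_fraction = residual_fraction, noise_floor = noise_floor,
    factor = factor,
    decision = if (residual_fraction > factor * noise_floor)
      "signal_remains" else "consistent_with_null",
    per_delay_norms = per_delay,
    pepc = res$pepc), class = "residual_test_report")
}

#' @export
print.residual_test_report <- function(x, ...) {
  cat(sprintf("<residual_test_report> %s\n  residual fraction %.4g vs %g x noise floor %.4g\n",
              x$decision, x$residual_fraction, x$factor, x$noise_floor))
  invisible(x)
}

#' Run the full projection-to-hydrodynamics analysis
#'
#' Executes the standard chain: projection against the trivial set, SVD, rank
#' selection, global multi-exponential fit of the significant RSVs, a
#' sequential kinetic model from the fitted time constants,
#' kinetics-constrained species extraction, optional per-species correction
#' against candidate curves, and (when corrected curves are available)
#' solute-term subtraction plus solvent decomposition. When `t_split` is
#' given, SVD + fitting is additionally run on the early/late subsets.
#'
#' @param config Named list (or path to a YAML/JSON file) with keys:
#'   `data` (a [trxl_dataset()] or matrix-file path), `trivials` (a
#'   [trivial_set()] or character vector of curve-file paths), fit settings
#'   `n_exp`, `irf_fwhm_ps`, `t0_ps`, `offset`, rank settings `ac_threshold`,
#'   `sv_ratio_floor`, `rank_override`, model settings `R`,
#'   `initial_fractions`, optional `taus_ps` (fixed time constants instead of
#'   the fitted ones), optional `t_split`, optional `candidates` (a
#'   [sads_set()] of kind real), optional `solvent_basis` (a [trivial_set()]
#'   of <= 2 curves for the hydrodynamics stage), `hydro_mode`, optional
#'   `out_dir` for writing every product.
#' @return Report bundle (list) with elements `pepc`, `svd`, `rank`, `fit`,
#'   `model`, `conc`, `sads_pepc`, `corrections`, `sads_corrected`, `hydro`,
#'   `splits`, `summary` (plain list mirrored to `summary.json` when
#'   `out_dir` is set).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  ds <- cfg$data
  if (is.character(ds)) ds <- read_matrix(ds)
  trivials <- cfg$trivials
  if (is.character(trivials))
    trivials <- trivial_set(lapply(trivials, read_curve))
  n_exp <- cfg$n_exp %||% 1L
  irf <- cfg$irf_fwhm_ps %||% 0
  t0 <- cfg$t0_ps %||% 0
  offset <- isTRUE(cfg$offset)
  ac_thr <- cfg$ac_threshold %||% 0.6
  sv_floor <- cfg$sv_ratio_floor %||% 1e-3
  R <- cfg$R %||% 1

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  pr <- stage("pepc", pepc_multi(ds, trivials))
  dec <- stage("svd", svd_decompose(pr$pepc))
  k <- stage("select_rank",
             select_rank(dec, ac_thr, sv_floor, override = cfg$rank_override))
  fit <- NULL; model <- NULL; conc <- NULL; sads_pepc <- NULL
  if (k >= 1L) {
    fit <- stage("global_fit_rsvs",
                 global_fit_rsvs(dec, k = k, n_exp = n_exp, irf_fwhm = irf,
                                 t0 = t0, offset = offset))
    taus <- cfg$taus_ps %||% fit$taus
    species <- cfg$species %||% paste0("S", seq_along(taus))
    model <- kinetic_model(species, taus = taus, t0 = t0, irf_fwhm = irf,
                           initial_fractions = cfg$initial_fractions)
    conc <- stage("concentration_profiles",
                  concentration_profiles(model, ds$t, R = R))
    sads_pepc <- stage("extract_sads",
                       extract_sads(pr$pepc, conc, svd_rank = k))
  }

  corrections <- NULL; sads_corr <- NULL; hydro <- NULL
  if (!is.null(cfg$candidates) && !is.null(sads_pepc)) {
    cand <- cfg$candidates
    corrections <- stage("correct_sads", lapply(
      seq_along(sads_pepc$curves), function(i)
        correct_sads(sads_pepc$curves[[i]], trivials, cand$curves[[i]])))
    sads_corr <- sads_set(lapply(corrections, function(cr) cr$corrected),
                          kind = "corrected", species = sads_pepc$species)
    sb <- cfg$solvent_basis
    if (!is.null(sb)) {
      solvent_only <- stage("subtract_solute_related",
                            subtract_solute_related(ds, sads_corr, conc))
      hydro <- stage("nod_solvent",
                     nod_solvent(solvent_only, sb,
                                 mode = cfg$hydro_mode %||% "two_term"))
    }
  }

  splits <- NULL
  if (!is.null(cfg$t_split)) {
    halves <- stage("split_dataset", split_dataset(pr$pepc, cfg$t_split))
    splits <- lapply(halves, function(h) {
      d2 <- svd_decompose(h)
      k2 <- select_rank(d2, ac_thr, sv_floor)
      f2 <- if (k2 >= 1L)
        tryCatch(global_fit_rsvs(d2, k = k2,
                                 n_exp = cfg$n_exp_split %||% max(1L, k2),
                                 irf_fwhm = irf, t0 = t0, offset = offset),
                 error = function(e) NULL)
      list(rank = k2, fit = f2)
    })
  }

  summary <- list(
    n_q = length(ds$q), n_t = length(ds$t),
    trivial_components = trivials$labels,
    trivial_rank = pr$trivial_rank,
    residual_fraction = norm(pr$pepc$matrix, "F") /
      max(norm(ds$matrix, "F"), .Machine$double.xmin),
    selected_rank = k,
    taus_ps = if (!is.null(fit)) fit$taus,
    tau_se_ps = if (!is.null(fit)) fit$tau_se,
    irf_fwhm_ps = irf, t0_ps = t0, n_exp = n_exp,
    ac_threshold = ac_thr, sv_ratio_floor = sv_floor, R = R,
    sads_residual_norms = if (!is.null(sads_pepc)) sads_pepc$residual_norms,
    correction_chi2 = if (!is.null(corrections))
      vapply(corrections, function(cr) cr$chi2, numeric(1)),
    hydro_condition_number = if (!is.null(hydro)) hydro$condition_number,
    split_ranks = if (!is.null(splits))
      vapply(splits, function(sp) sp$rank, integer(1)),
    split_taus_ps = if (!is.null(splits))
      lapply(splits, function(sp) if (!is.null(sp$fit)) sp$fit$taus))

  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(pr$pepc, file.path(out_dir, "pepc_matrix.tsv"))
    utils::write.table(
      cbind(t = ds$t, t(pr$weights)),
      file.path(out_dir, "pepc_weights.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sads_pepc))
      for (i in seq_along(sads_pepc$curves))
        write_curve(sads_pepc$curves[[i]],
                    file.path(out_dir, sprintf("sads_pepc_%d.tsv", i)))
    if (!is.null(sads_corr))
      for (i in seq_along(sads_corr$curves))
        write_curve(sads_corr$curves[[i]],
                    file.path(out_dir, sprintf("sads_corrected_%d.tsv", i)))
    if (!is.null(hydro))
      utils::write.table(
        data.frame(t = hydro$t, dT = .fmt_num(hydro$dT),
                   drho = .fmt_num(hydro$drho),
                   condition_number = hydro$condition_number),
        file.path(out_dir, "hydro.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  list(pepc = pr, svd = dec, rank = k, fit = fit, model = model, conc = conc,
       sads_pepc = sads_pepc, corrections = corrections,
       sads_corrected = sads_corr, hydro = hydro, splits = splits,
       summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
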