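# Species-associated difference scattering curves (SADS) and their relation
# to the trivial space. Projection removes from each true SADS its component
# inside the trivial space (coefficients d); the distortion is undone per
# candidate structure by an analytic linear solve for the correction weights
# alpha (the generalization of the g/h coefficients).

#' Set of species-associated difference scattering curves
#'
#' @param curves List of [trxl_curve()] on one shared q-grid, one per species.
#' @param kind One of `"real"` (true curves), `"pepc"` (projection-distorted)
#'   or `"corrected"`.
#' @param species Optional labels (default: curve labels).
#' @param residual_norms Optional per-species residual norms from extraction.
#' @return Object of class `sads_set`.
#' @export
sads_set <- function(curves, kind = c("real", "pepc", "corrected"),
                     species = NULL, residual_norms = NULL) {
  kind <- match.arg(kind)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "trxl_curve")))
    stop("curves must be a non-empty list of trxl_curve objects", call. = FALSE)
  q0 <- curves[[1]]$q
  for (cv in curves) .check_shared_grid(q0, cv$q)
  if (is.null(species))
    species <- vapply(curves, function(cv) cv$label, character(1))
  if (length(species) != length(curves))
    stop("species labels must match number of curves", call. = FALSE)
  structure(list(curves = curves, species = as.character(species),
                 kind = kind, q = q0, residual_norms = residual_norms),
            class = "sads_set")
}

#' @export
print.sads_set <- function(x, ...) {
  cat(sprintf("<sads_set> kind '%s', %d species: %s\n", x$kind,
              length(x$curves), paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Split a SADS into components inside and perpendicular to the trivial space
#'
#' The parallel part is the minimum-norm least-squares projection onto the
#' span of the trivial components (the same machinery as the dataset-level
#' projection, applied to a single curve); its weights are the d coefficients
#' quantifying how much of each trivial curve the projection removes from
#' this species.
#'
#' @param sads A [trxl_curve()].
#' @param trivials A [trivial_set()] on the same q-grid.
#' @param rank_tol Relative singular-value cutoff.
#' @return Object of class `sads_decomposition`: `parallel`, `perpendicular`
#'   (both [trxl_curve()]), `d_coeffs` (named numeric, one per component).
#' @export
decompose_sads <- function(sads, trivials, rank_tol = 1e-10) {
  stopifnot(inherits(sads, "trxl_curve"), inherits(trivials, "trivial_set"))
  .check_shared_grid(sads$q, trivials$q)
  sol <- .minnorm_ls(trivials$basis, sads$values, rank_tol)
  d <- drop(sol$coef)
  names(d) <- trivials$labels
  par_vals <- drop(trivials$basis %*% sol$coef)
  structure(list(
    parallel = trxl_curve(sads$q, par_vals,
                          label = paste0(sads$label, "_parallel")),
    perpendicular = trxl_curve(sads$q, sads$values - par_vals,
                               label = paste0(sads$label, "_perp")),
    d_coeffs = d), class = "sads_decomposition")
}

#' Correct a projection-distorted SADS against a candidate curve
#'
#' Projection removes too much of the trivial components from each species
#' curve; the corrected curve is
#' `sads_pepc + sum_i alpha_i trv_i`. The alpha weights are never free
#' nonlinear parameters: for a given candidate they are the analytic solution
#' of the linear least-squares problem
#' `min || sads_pepc + sum_i alpha_i trv_i - candidate ||`
#' (uncertainty-weighted when `sigma` is given).
#'
#' @param sads_pepc Distorted species curve ([trxl_curve()]).
#' @param trivials The [trivial_set()] used in the projection.
#' @param candidate Candidate true curve (e.g. from [sads_from_structures()]).
#' @param sigma Optional [trxl_curve()] of per-point uncertainties for
#'   chi-square weighting.
#' @return Object of class `correction_result`: `corrected` curve, `alpha`
#'   (named weights), `chi2` (weighted SSE / dof), `dof` (`n_q - m`).
#' @export
correct_sads <- function(sads_pepc, trivials, candidate, sigma = NULL) {
  stopifnot(inherits(sads_pepc, "trxl_curve"),
            inherits(trivials, "trivial_set"),
            inherits(candidate, "trxl_curve"))
  .check_shared_grid(sads_pepc$q, trivials$q)
  .check_shared_grid(sads_pepc$q, candidate$q)
  m <- ncol(trivials$basis)
  n_q <- length(sads_pepc$q)
  if (m >= n_q)
    stop("underdetermined: as many trivial components as q points",
         call. = FALSE)
  w <- rep(1, n_q)
  if (!is.null(sigma)) {
    .check_shared_grid(sads_pepc$q, sigma$q)
    w <- 1 / pmax(sigma$values, .Machine$double.eps)
  }
  rhs <- candidate$values - sads_pepc$values
  sol <- .minnorm_ls(trivials$basis * w, rhs * w)
  alpha <- drop(sol$coef)
  names(alpha) <- trivials$labels
  corr_vals <- sads_pepc$values + drop(trivials$basis %*% sol$coef)
  dof <- n_q - m
  chi2 <- sum((w * (corr_vals - candidate$values))^2) / dof
  structure(list(
    corrected = trxl_curve(sads_pepc$q, corr_vals,
                           label = paste0(sads_pepc$label, "_corr")),
    alpha = alpha, chi2 = chi2, dof = dof), class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> chi2 = %.4g (dof %d); alpha: %s\n",
              x$chi2, x$dof,
              paste(sprintf("%s=%.4g", names(x$alpha), x$alpha),
                    collapse = ", ")))
  invisible(x)
}

#' Rank candidate species curves by corrected-SADS misfit
#'
#' Runs [correct_sads()] against each candidate and sorts ascending by
#' chi-square: the generating structure should fit an order of magnitude
#' better than structurally perturbed alternatives. Ties are broken by label
#' order.
#'
#' @inheritParams correct_sads
#' @param candidates A [sads_set()] of candidate curves (>= 2).
#' @return `data.frame` with columns `species` and `chi2`, best first.
#' @export
rank_candidates <- function(sads_pepc, trivials, candidates, sigma = NULL) {
  stopifnot(inherits(candidates, "sads_set"))
  if (length(candidates$curves) < 2L)
    stop("need at least 2 candidates to rank", call. = FALSE)
  chi2 <- vapply(candidates$curves, function(cand)
    correct_sads(sads_pepc, trivials, cand, sigma)$chi2, numeric(1))
  ord <- order(chi2, seq_along(chi2))
  data.frame(species = candidates$species[ord], chi2 = chi2[ord],
             stringsAsFactors = FALSE)
}
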