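# Solvent hydrodynamics reconstruction: once the solute-related term is
# known, the remainder of the data is a per-delay linear combination of the
# two solvent differentials; solving that combination delay by delay gives
# the temperature and density time traces.

#' Subtract the solute-related term from experimental data
#'
#' Removes `(1/R) sum_k f_k(t) SADS_k(q)` columnwise, leaving the solvent-only
#' term.
#'
#' @param ds_exp Experimental [trxl_dataset()].
#' @param sads A [sads_set()] of kind `"real"` or `"corrected"` (true species
#'   curves).
#' @param conc Matching [concentration_profiles()] result (carries `R`).
#' @return A [trxl_dataset()] holding the solvent-only remainder.
#' @export
subtract_solute_related <- function(ds_exp, sads, conc) {
  stopifnot(inherits(ds_exp, "trxl_dataset"), inherits(sads, "sads_set"),
            inherits(conc, "concentration_matrix"))
  if (sads$kind == "pepc")
    stop("sads must be true (real/corrected) curves, not projection-distorted ones",
         call. = FALSE)
  if (!identical(sads$species, conc$species))
    stop("species mismatch between sads and concentration profiles",
         call. = FALSE)
  .check_shared_grid(ds_exp$q, sads$q)
  if (length(conc$t) != length(ds_exp$t) ||
      max(abs(conc$t - ds_exp$t)) > 1e-9 * max(abs(ds_exp$t)))
    stop("concentration profiles and dataset use different delays",
         call. = FALSE)
  S <- vapply(sads$curves, function(cv) cv$values, numeric(length(ds_exp$q)))
  sol_rel <- (1 / conc$R) * S %*% t(conc$C)
  trxl_dataset(ds_exp$q, ds_exp$t, ds_exp$matrix - sol_rel,
               sigma = ds_exp$sigma, meta = ds_exp$meta)
}

#' Decompose the solvent-only term into temperature and density traces
#'
#' Per time delay, a linear least-squares solve expresses the residual as
#' `dT(t) (dS/dT)_rho + drho(t) (dS/drho)_T` (or `dT(t)` alone in
#' `temperature_only` mode, the appropriate treatment when the two
#' differentials are nearly collinear, as for water). The condition number of
#' the basis matrix (ratio of its singular values) is reported; above
#' `cond_warn` the two-term solve is flagged as ill-conditioned. The default
#' threshold corresponds to a cosine similarity of 0.95 between two
#' normalized basis curves, the regime where the water differentials become
#' indistinguishable.
#'
#' @param residual Solvent-only [trxl_dataset()] (from
#'   [subtract_solute_related()]).
#' @param basis A [trivial_set()] of 1 or 2 solvent differential curves.
#' @param mode `"two_term"` or `"temperature_only"`.
#' @param sigma_weighted Whiten each per-delay solve by `residual$sigma`.
#' @param cond_warn Condition-number threshold for the ill-conditioning flag.
#' @return Object of class `hydro_trace`: `t`, `dT`, `drho` (zero in
#'   temperature-only mode), `condition_number`, `ill_conditioned`, `mode`,
#'   `units`.
#' @export
nod_solvent <- function(residual, basis, mode = c("two_term", "temperature_only"),
                        sigma_weighted = FALSE, cond_warn = 6.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(residual, "trxl_dataset"), inherits(basis, "trivial_set"))
  .check_shared_grid(residual$q, basis$q)
  m <- ncol(basis$basis)
  if (m > 2L) stop("solvent basis holds at most 2 differentials", call. = FALSE)
  B <- if (mode == "temperature_only") basis$basis[, 1, drop = FALSE]
       else basis$basis
  sv <- svd(B)$d
  cond <- sv[1] / max(sv[length(sv)], .Machine$double.xmin)
  ill <- is.finite(cond) && cond > cond_warn
  if (ill && mode == "two_term")
    warning(sprintf("solvent basis nearly collinear (condition number %.3g); consider temperature_only mode",
                    cond), call. = FALSE)
  n_t <- length(residual$t)
  coefs <- matrix(0, 2, n_t)
  for (j in seq_len(n_t)) {
    w <- if (sigma_weighted && !is.null(residual$sigma))
      1 / pmax(residual$sigma[, j], .Machine$double.eps) else 1
    cj <- .minnorm_ls(B * w, residual$matrix[, j] * w)$coef
    coefs[seq_len(ncol(B)), j] <- cj
  }
  structure(list(t = residual$t, dT = coefs[1, ], drho = coefs[2, ],
                 condition_number = cond, ill_conditioned = ill,
                 mode = mode,
                 units = c(dT = "K (per basis-curve scaling)",
                           drho = "kg m^-3 (per basis-curve scaling)")),
            class = "hydro_trace")
}

#' @export
print.hydro_trace <- function(x, ...) {
  cat(sprintf("<hydro_trace> mode '%s', %d delays; condition number %.3g%s\n",
              x$mode, length(x$t), x$condition_number,
              if (x$ill_conditioned) " [ILL-CONDITIONED]" else ""))
  invisible(x)
}
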