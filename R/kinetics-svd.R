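# SVD stage of the kinetic analysis: decompose the (PEPC-treated) matrix into
# q-space shapes (LSVs) and time profiles (RSVs), and pick the number of
# signal-bearing components from singular values and lag-1 autocorrelations.

#' Singular value decomposition of a scattering dataset
#'
#' Columns of `lsv` are q-space shapes, columns of `rsv` their time profiles;
#' `lsv %*% diag(sv) %*% t(rsv)` reconstructs the matrix. Sign convention:
#' each LSV is flipped so its largest-magnitude element is positive, with the
#' matching RSV flipped alongside, removing the inherent sign ambiguity.
#'
#' @param ds A [trxl_dataset()].
#' @return Object of class `svd_result` with `lsv` (n_q x r), `sv`
#'   (descending), `rsv` (n_t x r), `lsv_autocorr`, `rsv_autocorr`
#'   (lag-1 autocorrelations per component) and the dataset's `t` and `q`.
#' @export
svd_decompose <- function(ds) {
  stopifnot(inherits(ds, "trxl_dataset"))
  if (any(!is.finite(ds$matrix)))
    stop("non-finite entries in matrix", call. = FALSE)
  dec <- svd(ds$matrix)
  for (j in seq_along(dec$d)) {
    i_max <- which.max(abs(dec$u[, j]))
    if (dec$u[i_max, j] < 0) {
      dec$u[, j] <- -dec$u[, j]
      dec$v[, j] <- -dec$v[, j]
    }
  }
  structure(list(
    lsv = dec$u, sv = dec$d, rsv = dec$v,
    lsv_autocorr = apply(dec$u, 2, autocorrelation),
    rsv_autocorr = apply(dec$v, 2, autocorrelation),
    q = ds$q, t = ds$t), class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  k <- min(6L, length(x$sv))
  cat("<svd_result> leading components:\n")
  print(data.frame(sv = signif(x$sv[1:k], 4),
                   lsv_ac = round(x$lsv_autocorr[1:k], 3),
                   rsv_ac = round(x$rsv_autocorr[1:k], 3)))
  invisible(x)
}

#' Lag-1 autocorrelation of a singular vector
#'
#' `sum(v[i] v[i+1]) / sum(v[i]^2)`. Smooth, signal-bearing vectors score near
#' 1; white-noise vectors score near 0.
#'
#' @param v Numeric vector, length >= 2, nonzero norm.
#' @return Scalar in `[-1, 1]`.
#' @export
autocorrelation <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("need at least 2 elements", call. = FALSE)
  denom <- sum(v^2)
  if (denom == 0) stop("autocorrelation undefined for the zero vector",
                       call. = FALSE)
  sum(v[-length(v)] * v[-1]) / denom
}

#' Number of signal-bearing SVD components
#'
#' Returns the largest `k` such that components `1..k` all have LSV and RSV
#' autocorrelations above `ac_threshold` and singular value above
#' `sv_ratio_floor` relative to the first. `k = 0` means the matrix is
#' indistinguishable from noise.
#'
#' @param svd_res An [svd_decompose()] result.
#' @param ac_threshold Autocorrelation threshold in (0, 1).
#' @param sv_ratio_floor Relative singular-value floor in (0, 1).
#' @param override If supplied, returned as-is (manual rank choice).
#' @return Integer rank.
#' @export
select_rank <- function(svd_res, ac_threshold = 0.6, sv_ratio_floor = 1e-3,
                        override = NULL) {
  stopifnot(inherits(svd_res, "svd_result"))
  if (!is.null(override)) return(as.integer(override))
  if (ac_threshold <= 0 || ac_threshold >= 1 ||
      sv_ratio_floor <= 0 || sv_ratio_floor >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  ok <- svd_res$lsv_autocorr > ac_threshold &
    svd_res$rsv_autocorr > ac_threshold &
    svd_res$sv > sv_ratio_floor * svd_res$sv[1]
  k <- 0L
  while (k < length(ok) && ok[k + 1L]) k <- k + 1L
  k
}

#' Rank-k truncation of a dataset
#'
#' Reconstructs the matrix from its first `k` singular triplets, discarding
#' the noise-dominated remainder before kinetic fitting.
#'
#' @param ds A [trxl_dataset()].
#' @param k Number of components to keep (`k >= 1`).
#' @return A [trxl_dataset()] of rank at most `k`.
#' @export
truncate_rank <- function(ds, k) {
  stopifnot(inherits(ds, "trxl_dataset"), k >= 1)
  dec <- svd_decompose(ds)
  k <- min(as.integer(k), length(dec$sv))
  m <- dec$lsv[, 1:k, drop = FALSE] %*%
    (dec$sv[1:k] * t(dec$rsv[, 1:k, drop = FALSE]))
  trxl_dataset(ds$q, ds$t, m, meta = ds$meta)
}
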