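# PEPC: per time delay, split each difference curve into the component inside
# the trivial subspace (the least-squares linear combination of the trivial
# curves) and the perpendicular residual. The residual depends only on the
# span of the trivial set; the reported weights are the minimum-norm
# least-squares solution so they are deterministic even when the set is
# rank-deficient.

#' Component of each time-delay curve parallel to a single basis curve
#'
#' Projects every column of the dataset onto the unit vector of `basis`:
#' `(v . u_hat) u_hat`. This is the signal share carrying the basis curve's
#' kinetics.
#'
#' @param ds A [trxl_dataset()].
#' @param basis A [trxl_curve()] on the same q-grid.
#' @return A [trxl_dataset()] holding the parallel component (rank <= 1 in q).
#' @export
project_parallel_single <- function(ds, basis) {
  stopifnot(inherits(ds, "trxl_dataset"), inherits(basis, "trxl_curve"))
  .check_shared_grid(ds$q, basis$q)
  u <- basis$values
  nrm <- sqrt(sum(u^2))
  if (nrm == 0) stop("degenerate basis: zero norm", call. = FALSE)
  u <- u / nrm
  coeff <- drop(crossprod(u, ds$matrix))          # 1 x n_t dot products
  trxl_dataset(ds$q, ds$t, outer(u, coeff), meta = ds$meta)
}

#' PEPC with a single trivial component
#'
#' Removes, per time delay, the component parallel to one known curve
#' (typically the solvent temperature differential), leaving the perpendicular
#' residual whose time dependence carries only the remaining (solute)
#' kinetics.
#'
#' @inheritParams project_parallel_single
#' @return A `pepc_result`; see [pepc_multi()].
#' @export
pepc_single <- function(ds, basis) {
  pepc_multi(ds, trivial_set(basis))
}

#' PEPC with multiple trivial components
#'
#' For every time delay, finds the least-squares weights of the trivial
#' components and subtracts their combination, retaining the residual
#' perpendicular to the whole trivial space. Weights are the minimum-norm
#' solution (singular-value cutoff `rank_tol` relative to the largest singular
#' value), so rank-deficient trivial sets are handled deterministically and
#' the residual depends only on the span.
#'
#' @param ds A [trxl_dataset()].
#' @param trivials A [trivial_set()] on the same q-grid.
#' @param rank_tol Relative singular-value cutoff for the effective rank of
#'   the trivial set.
#' @param sigma_weighted If `TRUE` and `ds$sigma` is present, each per-delay
#'   solve is whitened by the column's uncertainties. Off by default: the
#'   projection geometry is the plain dot product.
#' @return Object of class `pepc_result` with elements `pepc` (residual
#'   dataset), `parallel` (projection onto the trivial space), `weights`
#'   (m x n_t matrix of least-squares weights, rows named by component),
#'   `trivial_rank` (effective rank).
#' @examples
#' q <- seq(0.5, 5, length.out = 40)
#' ts <- trivial_set(trxl_curve(q, exp(-q), "solvent"))
#' ds <- trxl_dataset(q, c(1, 10), cbind(exp(-q) + sin(q), 2 * sin(q)))
#' res <- pepc_multi(ds, ts)
#' max(abs(crossprod(ts$basis, res$pepc$matrix)))  # ~0: orthogonal
#' @export
pepc_multi <- function(ds, trivials, rank_tol = 1e-10, sigma_weighted = FALSE) {
  stopifnot(inherits(ds, "trxl_dataset"), inherits(trivials, "trivial_set"))
  .check_shared_grid(ds$q, trivials$q)
  B <- trivials$basis                              # n_q x m
  Y <- ds$matrix
  if (sigma_weighted && !is.null(ds$sigma)) {
    W <- matrix(NA_real_, ncol(B), ncol(Y))
    for (j in seq_len(ncol(Y))) {
      wj <- 1 / pmax(ds$sigma[, j], .Machine$double.eps)
      W[, j] <- .minnorm_ls(B * wj, Y[, j] * wj, rank_tol)$coef
    }
    rk <- .minnorm_ls(B, Y[, 1, drop = FALSE], rank_tol)$rank
  } else {
    sol <- .minnorm_ls(B, Y, rank_tol)
    W <- sol$coef
    rk <- sol$rank
  }
  par_mat <- B %*% W
  rownames(W) <- trivials$labels
  structure(list(
    pepc = trxl_dataset(ds$q, ds$t, Y - par_mat, meta = ds$meta),
    parallel = trxl_dataset(ds$q, ds$t, par_mat, meta = ds$meta),
    weights = W,
    trivial_rank = rk), class = "pepc_result")
}

#' @export
print.pepc_result <- function(x, ...) {
  cat(sprintf("<pepc_result> %d trivial component(s), effective rank %d\n",
              nrow(x$weights), x$trivial_rank))
  cat(sprintf("  residual Frobenius fraction: %.4g\n",
              norm(x$pepc$matrix, "F") /
                max(norm(x$pepc$matrix + x$parallel$matrix, "F"),
                    .Machine$double.xmin)))
  invisible(x)
}

# Minimum-norm least squares via SVD with relative singular-value cutoff.
.minnorm_ls <- function(A, b, rank_tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rank_tol * sv$d[1]
  r <- sum(keep)
  if (r == 0L) {
    coef <- matrix(0, ncol(A), NCOL(b))
  } else {
    Ut_b <- crossprod(sv$u[, keep, drop = FALSE], b)
    coef <- sv$v[, keep, drop = FALSE] %*% (Ut_b / sv$d[keep])
  }
  list(coef = coef, rank = r)
}

#' Brute-force projection residual by sequential Gram-Schmidt subtraction
#'
#' Independent cross-check for [pepc_multi()]: orthonormalizes the trivial set
#' by modified Gram-Schmidt with re-orthogonalization (dropping vectors whose
#' remaining norm falls below `rank_tol` relative to their original norm),
#' then subtracts from each column its projection onto each orthonormal
#' vector in turn.
#'
#' @inheritParams pepc_multi
#' @return A [trxl_dataset()] holding the residual.
#' @export
orthonormal_projection_oracle <- function(ds, trivials, rank_tol = 1e-10) {
  stopifnot(inherits(ds, "trxl_dataset"), inherits(trivials, "trivial_set"))
  .check_shared_grid(ds$q, trivials$q)
  basis <- list()
  for (j in seq_len(ncol(trivials$basis))) {
    v <- trivials$basis[, j]
    v0 <- sqrt(sum(v^2))
    for (pass in 1:2)                               # re-orthogonalize
      for (u in basis) v <- v - sum(u * v) * u
    if (sqrt(sum(v^2)) > rank_tol * v0)
      basis[[length(basis) + 1L]] <- v / sqrt(sum(v^2))
  }
  R <- ds$matrix
  for (u in basis) R <- R - outer(u, drop(crossprod(u, R)))
  trxl_dataset(ds$q, ds$t, R, meta = ds$meta)
}

.check_shared_grid <- function(q1, q2) {
  if (length(q1) != length(q2) || max(abs(q1 - q2)) > 1e-9 * max(abs(q1)))
    stop("objects are not on a shared q-grid; see align_to_grid()",
         call. = FALSE)
  invisible(TRUE)
}
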