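#' Difference scattering curve
#'
#' A single scattering curve on a momentum-transfer grid: the basic carrier for
#' solvent differentials ((dS/dT)_rho, (dS/drho)_T), species-associated
#' difference scattering curves (SADS) and any other "trivial" component used
#' in projection.
#'
#' @param q Numeric vector of momentum-transfer magnitudes in inverse Angstrom;
#'   strictly increasing, all positive, length >= 2.
#' @param values Numeric vector of scattering intensities (electron units per
#'   molecule convention), same length as `q`.
#' @param label Character label for the curve.
#' @param sigma Optional numeric vector of per-point uncertainties
#'   (non-negative, same length as `q`).
#' @return An object of class `trxl_curve`: a list with elements `q`, `values`,
#'   `label` and (possibly `NULL`) `sigma`.
#' @examples
#' crv <- trxl_curve(q = c(0.5, 1, 2), values = c(1, -2, 0.5), label = "demo")
#' crv
#' @export
trxl_curve <- function(q, values, label = "", sigma = NULL) {
  q <- as.numeric(q); values <- as.numeric(values)
  if (length(q) < 2L) stop("curve needs at least 2 q points", call. = FALSE)
  if (length(values) != length(q))
    stop("q and values must have equal length", call. = FALSE)
  if (!all(is.finite(q)) || !all(is.finite(values)))
    stop("non-finite entries in curve", call. = FALSE)
  if (any(q <= 0)) stop("all q must be positive", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must match q length", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop("sigma must be finite and non-negative", call. = FALSE)
  }
  structure(list(q = q, values = values, label = as.character(label)[1],
                 sigma = sigma),
            class = "trxl_curve")
}

#' @export
print.trxl_curve <- function(x, ...) {
  cat(sprintf("<trxl_curve> '%s': %d q-points in [%.4g, %.4g] A^-1%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' Time-resolved difference scattering dataset
#'
#' A matrix of difference scattering intensities Delta-S(q, t) on a shared
#' q-grid across time delays. Negative delays (pre-excitation references) are
#' allowed and typically carry noise only.
#'
#' @param q Numeric vector, strictly increasing, positive; inverse Angstrom.
#' @param t Numeric vector of time delays in picoseconds, strictly increasing
#'   (log-spacing typical, negative reference delays allowed).
#' @param matrix Numeric matrix of dimension `length(q) x length(t)`.
#' @param sigma Optional uncertainty matrix of the same dimension.
#' @param meta Named list of metadata (solvent name, solvent:solute ratio R,
#'   provenance).
#' @return An object of class `trxl_dataset`.
#' @examples
#' ds <- trxl_dataset(q = c(1, 2, 3), t = c(-5, 1, 10),
#'                    matrix = matrix(rnorm(9), 3, 3))
#' ds
#' @export
trxl_dataset <- function(q, t, matrix, sigma = NULL, meta = list()) {
  q <- as.numeric(q); t <- as.numeric(t)
  matrix <- base::as.matrix(matrix)
  if (any(!is.finite(q)) || any(q <= 0) || any(diff(q) <= 0))
    stop("q must be finite, positive, strictly increasing", call. = FALSE)
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("t must be finite and strictly increasing", call. = FALSE)
  if (!all(dim(matrix) == c(length(q), length(t))))
    stop(sprintf("matrix must be %d x %d (n_q x n_t), got %d x %d",
                 length(q), length(t), nrow(matrix), ncol(matrix)),
         call. = FALSE)
  if (any(!is.finite(matrix)))
    stop("non-finite entries in scattering matrix", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- base::as.matrix(sigma)
    if (!all(dim(sigma) == dim(matrix)))
      stop("sigma must match matrix dimensions", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop("sigma must be finite and non-negative", call. = FALSE)
  }
  structure(list(q = q, t = t, matrix = unname(matrix),
                 sigma = if (is.null(sigma)) NULL else unname(sigma),
                 meta = meta),
            class = "trxl_dataset")
}

#' @export
print.trxl_dataset <- function(x, ...) {
  cat(sprintf("<trxl_dataset> %d q-points x %d delays; q in [%.4g, %.4g] A^-1, t in [%.4g, %.4g] ps\n",
              length(x$q), length(x$t), min(x$q), max(x$q), min(x$t), max(x$t)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ordered set of trivial components spanning the trivial space
#'
#' The basis curves whose kinetic contributions are to be removed by
#' projection: solvent heating differentials and/or difference curves of known
#' species. All components must share one q-grid and none may be the zero
#' vector.
#'
#' @param ... `trxl_curve` objects, or a single list of them.
#' @param labels Optional character vector overriding the curve labels.
#' @return Object of class `trivial_set` with elements `components` (list of
#'   curves), `labels`, `q` (shared grid) and `basis` (the n_q x m matrix of
#'   component values).
#' @examples
#' q <- seq(0.5, 5, length.out = 20)
#' ts <- trivial_set(trxl_curve(q, sin(q), "a"), trxl_curve(q, cos(q), "b"))
#' ts
#' @export
trivial_set <- function(..., labels = NULL) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1]], "trxl_curve"))
    comps <- comps[[1]]
  if (length(comps) < 1L) stop("at least one trivial component required", call. = FALSE)
  if (!all(vapply(comps, inherits, logical(1), "trxl_curve")))
    stop("all components must be trxl_curve objects", call. = FALSE)
  q0 <- comps[[1]]$q
  for (i in seq_along(comps)) {
    if (length(comps[[i]]$q) != length(q0) ||
        max(abs(comps[[i]]$q - q0)) > 1e-9 * max(abs(q0)))
      stop("all trivial components must share one q-grid", call. = FALSE)
    if (all(comps[[i]]$values == 0))
      stop(sprintf("trivial component %d is the zero vector", i), call. = FALSE)
  }
  lbl <- if (is.null(labels)) {
    raw <- vapply(comps, function(cv) cv$label, character(1))
    ifelse(nzchar(raw), raw, paste0("trv", seq_along(comps)))
  } else {
    if (length(labels) != length(comps))
      stop("labels length must match number of components", call. = FALSE)
    as.character(labels)
  }
  structure(list(components = comps, labels = lbl, q = q0,
                 basis = vapply(comps, function(cv) cv$values,
                                numeric(length(q0)))),
            class = "trivial_set")
}

#' @export
print.trivial_set <- function(x, ...) {
  cat(sprintf("<trivial_set> %d component(s) on %d q-points: %s\n",
              length(x$components), length(x$q),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Number of components in a trivial set
#' @param x A `trivial_set`.
#' @return Integer count of components.
#' @export
n_components <- function(x) {
  stopifnot(inherits(x, "trivial_set"))
  length(x$components)
}
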