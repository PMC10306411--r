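# Toy Debye scattering for candidate and synthetic species. Atomic form
# factors are treated as q-independent constants (f ~ Z), which preserves the
# interference structure that drives species discrimination while keeping the
# forward model exactly invertible in tests.

#' Toy molecular structure for Debye scattering
#'
#' @param labels Character atom labels.
#' @param f Positive scattering factors (q-independent; roughly atomic
#'   number).
#' @param xyz Numeric matrix `n_atoms x 3` of coordinates in Angstrom.
#' @return Object of class `toy_structure`.
#' @examples
#' di <- toy_structure(c("I", "I"), f = c(53, 53),
#'                     xyz = rbind(c(0, 0, 0), c(2.7, 0, 0)))
#' @export
toy_structure <- function(labels, f, xyz) {
  labels <- as.character(labels)
  f <- as.numeric(f)
  xyz <- base::as.matrix(xyz)
  if (length(labels) < 1L) stop("at least one atom required", call. = FALSE)
  if (length(f) != length(labels) || any(!is.finite(f)) || any(f <= 0))
    stop("f must be positive and finite, one per atom", call. = FALSE)
  if (!all(dim(xyz) == c(length(labels), 3L)) || any(!is.finite(xyz)))
    stop("xyz must be a finite n_atoms x 3 matrix", call. = FALSE)
  structure(list(labels = labels, f = f, xyz = unname(xyz)),
            class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("<toy_structure> %d atoms: %s\n", length(x$labels),
              paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Debye scattering intensity of a rigid structure
#'
#' `S(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij)` with the `r = 0` and
#' `q -> 0` limits taken as 1, so `S(0+) = (sum_i f_i)^2`.
#'
#' @param structure A [toy_structure()].
#' @param q Positive momentum-transfer grid, inverse Angstrom.
#' @return A [trxl_curve()] of the scattering intensity.
#' @export
debye_scattering <- function(structure, q) {
  stopifnot(inherits(structure, "toy_structure"))
  q <- as.numeric(q)
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  n <- length(structure$f)
  d <- as.matrix(stats::dist(structure$xyz))
  s <- numeric(length(q))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- d[i, j]
      ff <- structure$f[i] * structure$f[j]
      s <- s + if (r == 0) rep(ff, length(q)) else ff * sin(q * r) / (q * r)
    }
  }
  trxl_curve(q, s, label = "debye")
}

#' Species-associated difference curve from a pair of structures
#'
#' Difference of Debye intensities, excited minus ground, optionally plus a
#' solvent-cage term supplied as a curve (see [cage_curve()] for a
#' parameterized stand-in).
#'
#' @param excited,ground [toy_structure()] objects.
#' @param q Momentum-transfer grid.
#' @param cage Optional [trxl_curve()] cage contribution on the same grid.
#' @param label Curve label.
#' @return A [trxl_curve()].
#' @export
sads_from_structures <- function(excited, ground, q, cage = NULL,
                                 label = "sads") {
  exc <- debye_scattering(excited, q)
  grd <- debye_scattering(ground, q)
  v <- exc$values - grd$values
  if (!is.null(cage)) {
    .check_shared_grid(exc$q, cage$q)
    v <- v + cage$values
  }
  trxl_curve(q, v, label = label)
}

#' Parameterized solute-cage difference term
#'
#' Damped sinusoid `A exp(-q^2 w^2) sin(q r0) / (q r0)` standing in for the
#' solute-solvent cross term that a pair-distribution-function calculation
#' would provide.
#'
#' @param q Momentum-transfer grid.
#' @param amplitude `A`.
#' @param r0 Dominant solute-solvent distance, Angstrom.
#' @param width Gaussian damping width `w`, Angstrom.
#' @return A [trxl_curve()].
#' @export
cage_curve <- function(q, amplitude = 1, r0 = 4, width = 0.35) {
  q <- as.numeric(q)
  trxl_curve(q, amplitude * exp(-q^2 * width^2) * sin(q * r0) / (q * r0),
             label = "cage")
}
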