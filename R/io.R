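# Delimited-text interchange formats. Matrix files carry '#' comment headers,
# a "# t: ..." delay line, then one row per q point; curve files are 2-3
# numeric columns (q, value[, sigma]). 15 significant digits on output so
# write/read round-trips are lossless at double precision.

.fmt_num <- function(x) formatC(x, digits = 15, format = "g", width = -1)

#' Read a difference scattering matrix from a delimited-text file
#'
#' Expected layout: optional `# key: value` comment lines (collected into
#' `meta`), a mandatory `# t: <t1> <t2> ...` line holding the time delays in
#' ps, then rows `<q> <dS(q,t1)> <dS(q,t2)> ...`. Fields are separated by
#' whitespace or tabs.
#'
#' @param path Path to the matrix file.
#' @param sigma_path Optional companion file with identical layout holding
#'   per-point uncertainties.
#' @return A [trxl_dataset()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, sigma_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  comments <- trimws(sub("^\\s*#\\s?", "", lines[is_comment]))
  t_line <- grep("^t:", comments, value = TRUE)
  if (length(t_line) != 1L)
    stop("matrix file must contain exactly one '# t: ...' delay line", call. = FALSE)
  t <- .parse_row(sub("^t:", "", t_line), path, "t-header")
  meta_lines <- grep("^t:", comments, invert = TRUE, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    if (grepl(":", ml, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", ml))
      val <- trimws(sub("^[^:]*:", "", ml))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_comment]
  if (length(body) < 2L) stop("matrix file has fewer than 2 data rows", call. = FALSE)
  rows <- lapply(seq_along(body), function(i) {
    r <- .parse_row(body[i], path, sprintf("row %d", i))
    if (length(r) != length(t) + 1L)
      stop(sprintf("parse error in %s, row %d: expected %d fields, got %d",
                   path, i, length(t) + 1L, length(r)), call. = FALSE)
    r
  })
  m <- do.call(rbind, rows)
  sigma <- NULL
  if (!is.null(sigma_path)) {
    sds <- read_matrix(sigma_path)
    if (!isTRUE(all.equal(sds$q, m[, 1])) || !isTRUE(all.equal(sds$t, t)))
      stop("sigma file grids do not match data file", call. = FALSE)
    sigma <- sds$matrix
  }
  trxl_dataset(q = m[, 1], t = t, matrix = m[, -1, drop = FALSE],
               sigma = sigma, meta = meta)
}

.parse_row <- function(line, path, where) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("parse error in %s (%s, field %d): '%s' is not numeric",
                 path, where, bad, fields[bad]), call. = FALSE)
  }
  vals
}

#' Write a difference scattering matrix to a delimited-text file
#'
#' @param ds A [trxl_dataset()].
#' @param path Output path.
#' @param sigma_path Optional path for the companion uncertainty matrix.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(ds, path, sigma_path = NULL) {
  stopifnot(inherits(ds, "trxl_dataset"))
  .write_one <- function(mat, p) {
    con <- file(p, "w"); on.exit(close(con))
    for (key in names(ds$meta))
      writeLines(sprintf("# %s: %s", key, format(ds$meta[[key]])), con)
    writeLines(paste("# t:", paste(.fmt_num(ds$t), collapse = " ")), con)
    body <- vapply(seq_along(ds$q), function(i)
      paste(c(.fmt_num(ds$q[i]), .fmt_num(mat[i, ])), collapse = "\t"),
      character(1))
    writeLines(body, con)
  }
  .write_one(ds$matrix, path)
  if (!is.null(sigma_path)) {
    if (is.null(ds$sigma)) stop("dataset carries no sigma matrix", call. = FALSE)
    .write_one(ds$sigma, sigma_path)
  }
  invisible(path)
}

#' Read a scattering curve from a two- or three-column text file
#'
#' Columns are `q value [sigma]`; `#` lines are comments. The file name (sans
#' extension) becomes the curve label unless a `# label: ...` comment is
#' present.
#'
#' @param path Path to the curve file.
#' @return A [trxl_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  label <- sub("\\.[^.]*$", "", basename(path))
  lab_line <- grep("^label:", trimws(sub("^\\s*#\\s?", "", lines[is_comment])),
                   value = TRUE)
  if (length(lab_line)) label <- trimws(sub("^label:", "", lab_line[1]))
  body <- lines[!is_comment]
  rows <- lapply(seq_along(body), function(i)
    .parse_row(body[i], path, sprintf("row %d", i)))
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("inconsistent column counts in ", path, call. = FALSE)
  if (ncols < 2L || ncols > 3L)
    stop(sprintf("curve file %s must have 2 or 3 columns, found %d",
                 path, ncols), call. = FALSE)
  m <- do.call(rbind, rows)
  trxl_curve(q = m[, 1], values = m[, 2], label = label,
             sigma = if (ncols == 3L) m[, 3] else NULL)
}

#' Write a scattering curve to a text file
#'
#' @param curve A [trxl_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "trxl_curve"))
  con <- file(path, "w"); on.exit(close(con))
  if (nzchar(curve$label)) writeLines(sprintf("# label: %s", curve$label), con)
  cols <- cbind(curve$q, curve$values)
  if (!is.null(curve$sigma)) cols <- cbind(cols, curve$sigma)
  writeLines(apply(cols, 1, function(r)
    paste(.fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' Bring curves and datasets onto one shared q-grid
#'
#' Projection requires every object to live on the same q sampling. In
#' `strict` mode the grids must already agree (to 1e-9 relative); in
#' `interpolate` mode every item is linearly interpolated onto the points of
#' the first item's grid that fall inside the common overlap of all ranges.
#'
#' @param items List of [trxl_curve()] and/or [trxl_dataset()] objects.
#' @param policy `"strict"` or `"interpolate"`.
#' @return List of the same items on one shared grid (idempotent).
#' @export
align_to_grid <- function(items, policy = c("strict", "interpolate")) {
  policy <- match.arg(policy)
  if (!length(items)) return(items)
  grids <- lapply(items, function(x) x$q)
  q0 <- grids[[1]]
  if (policy == "strict") {
    for (g in grids) {
      if (length(g) != length(q0) || max(abs(g - q0)) > 1e-9 * max(abs(q0)))
        stop("grids differ; use policy = 'interpolate'", call. = FALSE)
    }
    return(items)
  }
  lo <- max(vapply(grids, min, numeric(1)))
  hi <- min(vapply(grids, max, numeric(1)))
  if (lo >= hi) stop("q ranges are disjoint; cannot align", call. = FALSE)
  target <- q0[q0 >= lo & q0 <= hi]
  if (length(target) < 2L)
    stop("q overlap contains fewer than 2 points of the reference grid",
         call. = FALSE)
  lapply(items, function(x) {
    interp <- function(v) stats::approx(x$q, v, xout = target)$y
    if (inherits(x, "trxl_curve")) {
      trxl_curve(target, interp(x$values), x$label,
                 sigma = if (is.null(x$sigma)) NULL else interp(x$sigma))
    } else if (inherits(x, "trxl_dataset")) {
      m <- apply(x$matrix, 2, interp)
      s <- if (is.null(x$sigma)) NULL else apply(x$sigma, 2, interp)
      trxl_dataset(target, x$t, m, sigma = s, meta = x$meta)
    } else stop("align_to_grid handles trxl_curve / trxl_dataset only",
                call. = FALSE)
  })
}
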