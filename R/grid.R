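# ScalarGrid: uniform rectilinear volumetric field, plus Gaussian cube IO.
# Internally: origin and axis step vectors in angstrom; ESP values in
# kcal/mol/e, density values in e/bohr^3.

#' Construct a scalar volumetric grid
#'
#' A rectilinear 3D field.  `axes` holds the three step vectors as rows;
#' they must be mutually orthogonal (the common cube-file dialect).  ESP
#' grids (`kind = "esp_kcalmol"`) store kcal mol^-1 e^-1; density grids
#' (`kind = "density_au"`) store e bohr^-3.  Lengths are angstrom.
#'
#' @param origin numeric length-3 origin (A).
#' @param axes 3 x 3 matrix, rows = step vectors (A).
#' @param shape integer length-3 voxel counts (>= 2 each).
#' @param values numeric array of dim `shape` (index order x, y, z).
#' @param kind `"esp_kcalmol"` or `"density_au"`.
#' @return An object of class `"scalar_grid"`.
#' @export
scalar_grid <- function(origin, axes, shape, values,
                        kind = c("esp_kcalmol", "density_au")) {
  kind <- match.arg(kind)
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)),
            length(shape) == 3L)
  if (any(shape < 2L)) stop("grid shape must be >= 2 per axis", call. = FALSE)
  # orthogonality of the rectilinear dialect
  g <- axes %*% t(axes)
  scale <- sqrt(diag(g))
  offdiag <- abs(g[upper.tri(g)]) / (scale[c(1, 1, 2)] * scale[c(2, 3, 3)])
  if (any(offdiag > 1e-8))
    stop("grid axes are not orthogonal within tolerance", call. = FALSE)
  values <- array(as.numeric(values), dim = shape)
  if (!all(is.finite(values)))
    stop("grid values must be finite everywhere", call. = FALSE)
  structure(list(origin = origin, axes = axes, shape = shape,
                 values = values, kind = kind),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid [%s]: %d x %d x %d, spacing %.5f A>\n",
              x$kind, x$shape[1], x$shape[2], x$shape[3],
              sqrt(sum(x$axes[1, ]^2))))
  invisible(x)
}

#' Grid spacings along each axis (A)
#' @param grid a [scalar_grid()].
#' @return Numeric length-3 vector of step lengths.
#' @export
grid_spacing <- function(grid) sqrt(rowSums(grid$axes^2))

#' Cartesian coordinates of every voxel (A)
#'
#' @param grid a [scalar_grid()].
#' @return An N x 3 matrix in the R array linear order of the value
#'   array (first index, x, fastest).
#' @export
grid_points <- function(grid) {
  idx <- as.matrix(expand.grid(seq_len(grid$shape[1]) - 1L,
                               seq_len(grid$shape[2]) - 1L,
                               seq_len(grid$shape[3]) - 1L))
  sweep(idx %*% grid$axes, 2, grid$origin, "+")
}

#' Read and write Gaussian cube volumetric files
#'
#' Reads the standard scalar-field cube dialect: two comment lines, an
#' atom-count/origin line, three axis lines (voxel counts plus step
#' vectors, bohr), an atom block, then the value stream with z fastest.
#' Lengths are converted bohr to angstrom on read; for
#' `kind = "esp_kcalmol"` values are converted hartree/e to kcal/mol/e
#' (unless `values_in_hartree = FALSE`), while density grids keep their
#' native e/bohr^3.  [write_cube()] inverts both conversions.
#'
#' The "negative NAtoms means molecular-orbital cube" convention is
#' rejected: only scalar-field cubes are supported.
#'
#' @param path file path.
#' @param kind field kind, `"esp_kcalmol"` (default) or `"density_au"`.
#' @param values_in_hartree for ESP cubes, whether file values are in
#'   hartree/e (the Multiwfn/ORCA convention; default `TRUE`).  Set to
#'   `FALSE` for cubes already in kcal/mol/e.
#' @return [read_cube()] returns a list with elements `grid` (a
#'   [scalar_grid()]) and `mol` (a [molecule()], or `NULL` when the cube
#'   carries no atoms); [write_cube()] returns `path` invisibly.
#' @export
read_cube <- function(path, kind = c("esp_kcalmol", "density_au"),
                      values_in_hartree = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("cube format error: truncated header",
                               call. = FALSE)
  num <- function(line, k) {
    v <- suppressWarnings(as.numeric(
      strsplit(trimws(line), "[[:space:]]+")[[1L]]))
    if (length(v) < k || anyNA(v[seq_len(k)]))
      stop("cube format error: bad header line '", line, "'", call. = FALSE)
    v
  }
  h <- num(lines[3L], 4L)
  natm <- as.integer(h[1L])
  if (natm < 0L)
    stop("cube format error: negative atom count (molecular-orbital cubes ",
         "are not supported)", call. = FALSE)
  origin <- h[2:4] * .BOHR
  shape <- integer(3L)
  axes <- matrix(0, 3L, 3L)
  for (a in 1:3) {
    v <- num(lines[3L + a], 4L)
    shape[a] <- as.integer(v[1L])
    if (shape[a] <= 0L)
      stop("cube format error: non-positive voxel count on axis ", a,
           call. = FALSE)
    axes[a, ] <- v[2:4] * .BOHR
  }
  atom_lines <- lines[6L + seq_len(natm)]
  mol <- NULL
  if (natm > 0L) {
    z <- integer(natm); xyz <- matrix(0, natm, 3L)
    for (i in seq_len(natm)) {
      v <- num(atom_lines[i], 5L)
      z[i] <- as.integer(v[1L])
      xyz[i, ] <- v[3:5] * .BOHR
    }
    mol <- molecule(.element_symbol(z), xyz)
  }
  value_txt <- lines[-(seq_len(6L + natm))]
  vals <- suppressWarnings(as.numeric(
    unlist(strsplit(trimws(value_txt[nzchar(trimws(value_txt))]),
                    "[[:space:]]+"), use.names = FALSE)))
  nexp <- prod(shape)
  if (length(vals) != nexp || anyNA(vals))
    stop("cube format error: expected ", nexp, " values, found ",
         length(vals), call. = FALSE)
  # cube stream: first index slowest, last (z) fastest -> fill reversed dims
  arr <- aperm(array(vals, dim = rev(shape)), c(3L, 2L, 1L))
  if (kind == "esp_kcalmol" && values_in_hartree)
    arr <- arr * .HARTREE_KCAL
  list(grid = scalar_grid(origin, axes, shape, arr, kind), mol = mol)
}

#' @rdname read_cube
#' @param grid a [scalar_grid()].
#' @param mol a [molecule()] for the atom block, or `NULL`.
#' @param values_in_hartree see [read_cube()]; the writer mirrors it.
#' @export
write_cube <- function(grid, mol = NULL, path,
                       values_in_hartree = TRUE) {
  stopifnot(inherits(grid, "scalar_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("esphole cube file",
               sprintf("kind=%s", grid$kind)), con)
  natm <- if (is.null(mol)) 0L else natoms(mol)
  fmt <- function(i, v) sprintf("%5d %12.6f %12.6f %12.6f", i, v[1], v[2], v[3])
  writeLines(fmt(natm, grid$origin / .BOHR), con)
  for (a in 1:3) writeLines(fmt(grid$shape[a], grid$axes[a, ] / .BOHR), con)
  if (natm > 0L) {
    z <- .element_number(mol$elements)
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, as.numeric(z),
                       mol$coords[, 1] / .BOHR, mol$coords[, 2] / .BOHR,
                       mol$coords[, 3] / .BOHR), con)
  }
  vals <- grid$values
  if (grid$kind == "esp_kcalmol" && values_in_hartree)
    vals <- vals / .HARTREE_KCAL
  stream <- as.vector(aperm(vals, c(3L, 2L, 1L)))
  # 6 values per line, %.10e keeps round trips bit-consistent at 1e-9 rel
  n <- length(stream)
  full <- n %/% 6L
  if (full > 0L) {
    m <- matrix(sprintf("% .10e", stream[seq_len(full * 6L)]), ncol = 6L,
                byrow = TRUE)
    writeLines(apply(m, 1L, paste, collapse = " "), con)
  }
  if (n > full * 6L)
    writeLines(paste(sprintf("% .10e", stream[(full * 6L + 1L):n]),
                     collapse = " "), con)
  invisible(path)
}

#' Trilinear interpolation on a scalar grid
#'
#' Samples the field at arbitrary Cartesian points by trilinear
#' interpolation of the eight surrounding voxel values.  Exact at voxel
#' corners and for fields linear in the coordinates.
#'
#' @param grid a [scalar_grid()].
#' @param points numeric M x 3 matrix (or length-3 vector) of positions (A).
#' @param on_oob `"error"` to fail on any out-of-bounds point (the error
#'   carries the offending point), `"na"` to return `NA` there and let the
#'   caller decide.
#' @return Numeric vector of M interpolated values.
#' @export
sample_grid <- function(grid, points, on_oob = c("error", "na")) {
  on_oob <- match.arg(on_oob)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  len2 <- rowSums(grid$axes^2)
  # fractional voxel coordinates along each (orthogonal) axis
  u <- sweep(points, 2, grid$origin) %*% t(grid$axes / len2)
  nmax <- grid$shape - 1L
  eps <- 1e-9
  oob <- u[, 1] < -eps | u[, 2] < -eps | u[, 3] < -eps |
    u[, 1] > nmax[1] + eps | u[, 2] > nmax[2] + eps | u[, 3] > nmax[3] + eps
  if (any(oob) && on_oob == "error") {
    p <- points[which(oob)[1L], ]
    stop(sprintf(paste0("sampling error: point (%.4f, %.4f, %.4f) outside",
                        " grid bounds"), p[1], p[2], p[3]), call. = FALSE)
  }
  u <- pmin(pmax(u, 0), matrix(nmax, nrow(u), 3L, byrow = TRUE))
  i0 <- pmin(floor(u), matrix(nmax - 1L, nrow(u), 3L, byrow = TRUE))
  f <- u - i0
  v <- grid$values
  lin <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)]
  }
  out <-
    lin(0L, 0L, 0L) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(1L, 0L, 0L) * f[, 1]       * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(0L, 1L, 0L) * (1 - f[, 1]) * f[, 2]       * (1 - f[, 3]) +
    lin(0L, 0L, 1L) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    lin(1L, 1L, 0L) * f[, 1]       * f[, 2]       * (1 - f[, 3]) +
    lin(1L, 0L, 1L) * f[, 1]       * (1 - f[, 2]) * f[, 3] +
    lin(0L, 1L, 1L) * (1 - f[, 1]) * f[, 2]       * f[, 3] +
    lin(1L, 1L, 1L) * f[, 1]       * f[, 2]       * f[, 3]
  if (any(oob)) out[oob] <- NA_real_
  out
}
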