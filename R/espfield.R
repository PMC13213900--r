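# Synthetic volumetric fields (point-charge Coulomb ESP, Gaussian ESP
# features, model Gaussian densities), isodensity surface extraction and
# the global surface maximum Vs_max.  These fields stand in for
# QM-derived cubes in tests and end-to-end runs.

#' Specify a synthetic field
#'
#' A field spec combines point charges and Gaussian features for the ESP
#' with Gaussian terms for a model electron density, plus the grid to
#' evaluate them on.  All generators are deterministic given the spec.
#'
#' @param charges data.frame with columns `q` (e), `x`, `y`, `z` (A), or
#'   `NULL`.
#' @param gaussians data.frame with columns `A` (kcal/mol), `x`, `y`, `z`
#'   (A), `w` (width, A), or `NULL`.  Each contributes
#'   `A * exp(-d^2 / (2 w^2))` to the ESP.
#' @param density_gaussians data.frame with columns `A` (e/bohr^3), `x`,
#'   `y`, `z` (A), `w` (width, bohr), or `NULL`.
#' @param grid list with `origin` (A), `shape` (3 ints) and `spacing`
#'   (scalar, A); see [grid_request()].
#' @return An object of class `"field_spec"`.
#' @export
field_spec <- function(charges = NULL, gaussians = NULL,
                       density_gaussians = NULL, grid) {
  chk <- function(df, cols, name) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop(name, " needs columns ", paste(cols, collapse = ", "),
           call. = FALSE)
    if ("w" %in% cols && any(df$w <= 0))
      stop(name, " widths must be positive", call. = FALSE)
    df
  }
  stopifnot(is.list(grid), all(c("origin", "shape", "spacing") %in%
                                 names(grid)))
  if (any(grid$shape < 2L)) stop("grid shape must be >= 2 per axis",
                                 call. = FALSE)
  structure(list(
    charges = chk(charges, c("q", "x", "y", "z"), "charges"),
    gaussians = chk(gaussians, c("A", "x", "y", "z", "w"), "gaussians"),
    density_gaussians = chk(density_gaussians, c("A", "x", "y", "z", "w"),
                            "density_gaussians"),
    grid = grid), class = "field_spec")
}

#' Request a grid around a set of points
#'
#' Builds the grid geometry the field generators evaluate on: cubic
#' voxels of `spacing_bohr` (default 0.25 bohr, the conventional ESP grid
#' resolution) padded `padding` angstrom beyond the given centers.
#'
#' @param centers M x 3 matrix of positions to cover (A).
#' @param spacing_bohr voxel edge in bohr.
#' @param padding margin beyond the centers (A).
#' @return A list with `origin`, `shape`, `spacing` (A) for [field_spec()].
#' @export
grid_request <- function(centers, spacing_bohr = 0.25, padding = 4) {
  centers <- as.matrix(centers)
  spacing <- bohr_to_ang(spacing_bohr)
  lo <- apply(centers, 2, min) - padding
  hi <- apply(centers, 2, max) + padding
  shape <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(origin = lo, shape = shape, spacing = spacing)
}

.empty_grid <- function(g, kind) {
  scalar_grid(g$origin, diag(3) * g$spacing, g$shape,
              array(0, g$shape), kind)
}

# analytic ESP of a spec at arbitrary points (A); used by the generators
.eval_esp <- function(spec, points, clamp = 0.1) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  v <- numeric(nrow(points))
  ch <- spec$charges
  if (!is.null(ch)) for (i in seq_len(nrow(ch))) {
    r <- sqrt((points[, 1] - ch$x[i])^2 + (points[, 2] - ch$y[i])^2 +
                (points[, 3] - ch$z[i])^2)
    v <- v + .KCOUL * ch$q[i] / pmax(r, clamp)
  }
  ga <- spec$gaussians
  if (!is.null(ga)) for (i in seq_len(nrow(ga))) {
    d2 <- (points[, 1] - ga$x[i])^2 + (points[, 2] - ga$y[i])^2 +
      (points[, 3] - ga$z[i])^2
    v <- v + ga$A[i] * exp(-d2 / (2 * ga$w[i]^2))
  }
  v
}

#' Generate the ESP grid of a synthetic field spec
#'
#' Point charges contribute `332.0637 * q / r` kcal/mol/e; to keep fixture
#' voxels finite, distances below 0.1 A are clamped to 0.1 A (a region no
#' detector samples).  Gaussian ESP features add
#' `A * exp(-d^2 / (2 w^2))`.  Superposition holds exactly: the field of
#' a combined spec is the sum of the parts.
#'
#' @param spec a [field_spec()].
#' @return An ESP [scalar_grid()] (kcal/mol/e).
#' @export
point_charge_field <- function(spec) {
  grid <- .empty_grid(spec$grid, "esp_kcalmol")
  grid$values <- array(.eval_esp(spec, grid_points(grid)), dim = grid$shape)
  grid
}

#' Generate a model Gaussian electron density grid
#'
#' Each term contributes `A * exp(-d^2 / (2 w^2))` e/bohr^3 with the
#' width `w` in bohr and `d` the distance from its center.
#'
#' @param spec a [field_spec()] with `density_gaussians`.
#' @return A density [scalar_grid()] (e/bohr^3).
#' @export
gaussian_density <- function(spec) {
  if (is.null(spec$density_gaussians))
    stop("spec has no density_gaussians", call. = FALSE)
  grid <- .empty_grid(spec$grid, "density_au")
  pts <- grid_points(grid)
  v <- numeric(nrow(pts))
  dg <- spec$density_gaussians
  for (i in seq_len(nrow(dg))) {
    d2 <- (pts[, 1] - dg$x[i])^2 + (pts[, 2] - dg$y[i])^2 +
      (pts[, 3] - dg$z[i])^2
    v <- v + dg$A[i] * exp(-ang_to_bohr(sqrt(d2))^2 / (2 * dg$w[i]^2))
  }
  grid$values <- array(v, dim = grid$shape)
  grid
}

#' Extract an isodensity point set
#'
#' Marching-edge extraction: every grid edge (along x, y and z) whose end
#' values bracket `iso` contributes one linearly interpolated crossing
#' point.  The returned points sample the rho = `iso` isosurface; each has
#' interpolated density within 2 percent of `iso` on smooth fields.
#'
#' @param density a density [scalar_grid()].
#' @param iso isodensity threshold (e/bohr^3), default 0.001, the
#'   conventional molecular-surface definition.
#' @return M x 3 matrix of surface points (A).
#' @export
isosurface_points <- function(density, iso = 0.001) {
  v <- density$values
  if (iso >= max(v) || iso <= min(v))
    stop("empty-surface error: iso level ", iso,
         " outside the grid value range", call. = FALSE)
  sh <- density$shape
  pts <- list()
  shift <- function(arr, ax, drop_first) {
    ind <- lapply(sh, seq_len)
    ind[[ax]] <- if (drop_first) 2:sh[ax] else 1:(sh[ax] - 1L)
    do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
  }
  for (axis in 1:3) {
    a <- shift(v, axis, FALSE)
    b <- shift(v, axis, TRUE)
    cross <- (a - iso) * (b - iso) < 0
    if (!any(cross)) next
    w <- which(cross, arr.ind = TRUE)
    t <- (iso - a[cross]) / (b[cross] - a[cross])
    base <- sweep((w - 1) %*% density$axes, 2, density$origin, "+")
    pts[[axis]] <- base + outer(t, density$axes[axis, ])
  }
  out <- do.call(rbind, pts)
  if (is.null(out))
    stop("empty-surface error: no grid edge brackets iso level ", iso,
         call. = FALSE)
  out
}

#' Maximum ESP over a surface point set
#'
#' Samples the ESP grid at every surface point (trilinear) and returns the
#' maximum and its location -- the conventional Vs_max on the 0.001
#' e/bohr^3 isodensity surface when `surface` comes from
#' [isosurface_points()].
#'
#' @param esp an ESP [scalar_grid()].
#' @param surface M x 3 matrix of surface points (A).
#' @return A list with `value` (kcal/mol/e) and `location` (length-3, A).
#' @export
vs_max <- function(esp, surface) {
  surface <- as.matrix(surface)
  if (!nrow(surface)) stop("coverage error: empty surface", call. = FALSE)
  v <- sample_grid(esp, surface, on_oob = "na")
  bad <- sum(is.na(v))
  if (bad > 0.01 * length(v))
    stop(sprintf(
      "coverage error: %d of %d surface points unsampleable on the ESP grid",
      bad, length(v)), call. = FALSE)
  k <- which.max(v)
  list(value = v[k], location = surface[k, ])
}

#' Synthetic axial-depletion fixture
#'
#' Builds the package's reference synthetic system: a +2 e charge at the
#' origin (the metal), four -0.4 e charges at the donor-nitrogen positions
#' in the z = 0 plane, and a positive axial ESP Gaussian whose center is
#' solved (by root finding on the analytic on-axis derivative) so that the
#' analytic on-axis maximum sits exactly at `z_hole`.  A spherical model
#' density centered at the origin is included so the 0.001 e/bohr^3
#' surface and Vs_max can be exercised.
#'
#' @param z_hole height of the on-axis ESP maximum above the plane (A);
#'   default 2.1, the middle of the 1.8-2.4 A band where metal-centered
#'   pi-holes sit.
#' @param amplitude,width Gaussian feature amplitude (kcal/mol) and width
#'   (A).
#' @param donor_radius in-plane distance of the four -0.4 e charges (A).
#' @param spacing_bohr grid spacing (bohr).
#' @param compact when `TRUE`, use a tight grid box (just covering the
#'   axial search cylinder and the background sectors) and a 1-bohr model
#'   density, for fast file-based or multi-spacing runs; the default
#'   box pads 4 A beyond all features.
#' @return A [field_spec()]; the solved Gaussian center is in attribute
#'   `"gaussian_center"`.
#' @export
axial_depletion_spec <- function(z_hole = 2.1, amplitude = 80, width = 0.3,
                                 donor_radius = 1.45, spacing_bohr = 0.25,
                                 compact = FALSE) {
  charges <- data.frame(
    q = c(2, rep(-0.4, 4)),
    x = c(0, donor_radius, -donor_radius, 0, 0),
    y = c(0, 0, 0, donor_radius, -donor_radius),
    z = 0)
  # on-axis background slope at z_hole (kcal/mol/A)
  slope <- .KCOUL * (-2 / z_hole^2 +
                       4 * 0.4 * z_hole / (z_hole^2 + donor_radius^2)^1.5)
  # Gaussian centered at zc > z_hole cancels it:
  # d/dz A exp(-(z-zc)^2/(2w^2)) |_{z_hole} = -slope
  f <- function(zc) {
    dz <- z_hole - zc
    -amplitude * dz / width^2 * exp(-dz^2 / (2 * width^2)) + slope
  }
  # near branch (|zc - z_hole| < width) so the stationary point is a
  # maximum: the Gaussian curvature there dominates the Coulomb curvature
  if (f(z_hole + width) <= 0)
    stop("amplitude too weak to place an on-axis maximum at z_hole: need ",
         "amplitude > ", sprintf("%.1f", -slope * width * exp(0.5)),
         " kcal/mol for width ", width, call. = FALSE)
  zc <- stats::uniroot(f, c(z_hole, z_hole + width), tol = 1e-12)$root
  if (compact) {
    centers <- rbind(c(-2.8, -2.8, -2.4), c(2.8, 2.8, 3.4))
    padding <- 0.8
    density_w <- 1   # 0.001 e/bohr^3 surface at ~1.97 A, inside the box
  } else {
    centers <- rbind(as.matrix(charges[, c("x", "y", "z")]),
                     c(0, 0, zc), c(0, 0, -3.5), c(0, 0, 3.5),
                     c(3, 3, 0), c(-3, -3, 0))
    padding <- 4
    density_w <- 2
  }
  spec <- field_spec(
    charges = charges,
    gaussians = data.frame(A = amplitude, x = 0, y = 0, z = zc, w = width),
    density_gaussians = data.frame(A = 1, x = 0, y = 0, z = 0,
                                   w = density_w),
    grid = grid_request(centers, spacing_bohr = spacing_bohr,
                        padding = padding))
  attr(spec, "gaussian_center") <- zc
  spec
}

#' Molecule matching the axial-depletion fixture
#'
#' A synthetic square-planar complex whose metal and donor positions
#' coincide with the fixture charges of [axial_depletion_spec()]: role
#' tags only, no hydrogens.
#'
#' @param metal element symbol for the central atom.
#' @param donor_radius donor distance from the center (A).
#' @return A [molecule()] with `metal` and `donor_N` roles.
#' @export
axial_depletion_molecule <- function(metal = "Zn", donor_radius = 1.45) {
  molecule(c(metal, "N", "N", "N", "N"),
           rbind(c(0, 0, 0),
                 c(donor_radius, 0, 0), c(-donor_radius, 0, 0),
                 c(0, donor_radius, 0), c(0, -donor_radius, 0)),
           roles = c("metal", rep("donor_N", 4)),
           charge = 2L, multiplicity = 1L,
           comment = sprintf("metal=%s conformer=SYN pattern=H,H,H,H", metal))
}
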