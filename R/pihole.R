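# Axial pi-hole candidate search, eight-sector background validation and
# the relative descriptor set V_hole_mean / V_hole_max / V_hole_min,
# dV_hole, dV_angle.

#' Detection parameters
#'
#' Registry of every tunable constant of the detection algorithm, with
#' the conventional defaults: axial search to 3.0 A within a 1.0 A
#' cylinder sampled every 0.05 A; background cylinder of radius 2.5 A and
#' half-height 0.25 A split into 8 azimuthal sectors of 1000 samples
#' each; validation threshold 5 kcal/mol.
#'
#' @param zmax axial search bound (A).
#' @param zmin axial search start (A); 0 starts at the N4 centroid.
#' @param step axial step (A).
#' @param radius candidate-cylinder radius used for lateral confirmation
#'   (A).
#' @param lateral logical: require the on-axis value to dominate 8 probe
#'   points at `radius` (flag to disable).
#' @param sector_radius background cylinder radius (A).
#' @param sector_halfheight background cylinder half-height (A).
#' @param n_sectors number of azimuthal sectors.
#' @param n_samples target ESP samples per sector.
#' @param inner_radius optional inner exclusion radius of the background
#'   cylinder (A); 0 spans the full radius as literally defined.
#' @param thr validation threshold Delta_thr (kcal/mol).
#' @param sampler `"stratified"` (deterministic, default) or `"random"`
#'   (seeded uniform sampling, for robustness checks).
#' @param seed integer seed for the random sampler.
#' @return A list of parameters.
#' @export
detect_params <- function(zmax = 3.0, zmin = 0.0, step = 0.05,
                          radius = 1.0, lateral = TRUE,
                          sector_radius = 2.5, sector_halfheight = 0.25,
                          n_sectors = 8L, n_samples = 1000L,
                          inner_radius = 0.0, thr = 5.0,
                          sampler = c("stratified", "random"), seed = 1L) {
  stopifnot(zmax > zmin, step > 0, radius > 0, sector_radius > 0,
            sector_halfheight > 0, n_sectors >= 2L, n_samples >= 8L,
            thr >= 0, inner_radius >= 0, inner_radius < sector_radius)
  list(zmax = zmax, zmin = zmin, step = step, radius = radius,
       lateral = lateral, sector_radius = sector_radius,
       sector_halfheight = sector_halfheight,
       n_sectors = as.integer(n_sectors),
       n_samples = as.integer(n_samples), inner_radius = inner_radius,
       thr = thr, sampler = match.arg(sampler), seed = as.integer(seed))
}

#' Axial pi-hole candidate search
#'
#' Samples the ESP by trilinear interpolation along the pi-axis from the
#' N4 centroid out to `zmax` in one hemisphere, and flags points where the
#' discrete first derivative changes sign from + to - and the central
#' second difference is negative (a local maximum: dV/dr = 0,
#' d2V/dr2 < 0).  Each flagged point is laterally confirmed: its on-axis
#' value must be >= the ESP at 8 probe points on the candidate-cylinder
#' wall (radius 1.0 A, same z).  Candidates are returned sorted by ESP
#' descending.
#'
#' @param esp an ESP [scalar_grid()] in lab coordinates.
#' @param frame an [fit_plane()] frame mapping the molecule into the
#'   aligned frame.
#' @param hemisphere `"+z"` or `"-z"`.
#' @param params a [detect_params()] list.
#' @return A list of candidates; each is a list with `z` (signed distance
#'   from the N4-plane, A), `position` (aligned frame), `V` (kcal/mol),
#'   `curvature` (kcal/mol/A^2, negative) and `hemisphere`.
#' @export
scan_axis <- function(esp, frame, hemisphere = c("+z", "-z"),
                      params = detect_params()) {
  hemisphere <- match.arg(hemisphere)
  sgn <- if (hemisphere == "+z") 1 else -1
  z <- seq(params$zmin, params$zmax, by = params$step)
  axis_pts <- unalign(cbind(0, 0, sgn * z), frame)
  v <- sample_grid(esp, axis_pts, on_oob = "na")
  if (anyNA(v))
    stop("coverage error: ESP grid does not cover the axial search cylinder",
         call. = FALSE)
  n <- length(v)
  if (n < 3L) return(list())
  d <- diff(v)
  cand_idx <- which(d[-(n - 1L)] > 0 & d[-1L] < 0) + 1L
  out <- list()
  for (i in cand_idx) {
    curv <- (v[i - 1L] - 2 * v[i] + v[i + 1L]) / params$step^2
    if (curv >= 0) next
    if (params$lateral) {
      th <- (0:7) * pi / 4
      probes <- unalign(cbind(params$radius * cos(th),
                              params$radius * sin(th),
                              sgn * z[i]), frame)
      pv <- sample_grid(esp, probes, on_oob = "na")
      if (anyNA(pv))
        stop("coverage error: lateral probes fall outside the ESP grid",
             call. = FALSE)
      if (any(pv > v[i])) next
    }
    out[[length(out) + 1L]] <- list(
      z = sgn * z[i], position = c(0, 0, sgn * z[i]), V = v[i],
      curvature = curv, hemisphere = hemisphere)
  }
  if (length(out) > 1L)
    out <- out[order(vapply(out, `[[`, numeric(1), "V"),
                     decreasing = TRUE)]
  out
}

# sample points of one sector wedge, aligned-frame coordinates
.sector_points <- function(candidate_z, sector, params) {
  R2o <- params$sector_radius^2
  R2i <- params$inner_radius^2
  h <- params$sector_halfheight
  width <- 2 * pi / params$n_sectors
  center <- (sector - 1L) * width
  if (params$sampler == "stratified") {
    m <- max(2L, floor((params$n_samples + 0.5)^(1 / 3)))
    u <- (seq_len(m) - 0.5) / m
    gr <- expand.grid(ur = u, ut = u, uz = u)
    r <- sqrt(R2i + gr$ur * (R2o - R2i))   # uniform in r^2: uniform in volume
    t <- center + (gr$ut - 0.5) * width
    zz <- candidate_z + (2 * gr$uz - 1) * h
  } else {
    r <- sqrt(R2i + stats::runif(params$n_samples) * (R2o - R2i))
    t <- center + (stats::runif(params$n_samples) - 0.5) * width
    zz <- candidate_z + (2 * stats::runif(params$n_samples) - 1) * h
  }
  cbind(r * cos(t), r * sin(t), zz)
}

#' Eight-sector background profile around a candidate
#'
#' Constructs a cylindrical region of radius 2.5 A and height +-0.25 A
#' centered on the candidate, splits it into eight 45-degree azimuthal
#' sectors in the aligned xy-plane (sector i centered at (i-1)*45
#' degrees), draws 1000 evenly distributed samples per sector
#' (deterministic stratified, uniform in r^2, theta, z) and averages the
#' interpolated ESP to the mean sectoral potentials.
#'
#' @param esp an ESP [scalar_grid()].
#' @param candidate one element of [scan_axis()] output (or any list with
#'   a `z` field).
#' @param frame the aligned frame.
#' @param params a [detect_params()] list.
#' @return A list with `sector_means` (length `n_sectors`),
#'   `sector_centers_deg`, `samples_per_sector` and `skipped` (points
#'   outside the grid, at most 1 percent per sector).
#' @export
sector_profile <- function(esp, candidate, frame,
                           params = detect_params()) {
  if (params$sampler == "random") set.seed(params$seed)
  means <- numeric(params$n_sectors)
  used <- integer(params$n_sectors)
  skipped <- integer(params$n_sectors)
  for (s in seq_len(params$n_sectors)) {
    pts <- .sector_points(candidate$z, s, params)
    v <- sample_grid(esp, unalign(pts, frame), on_oob = "na")
    bad <- sum(is.na(v))
    if (bad > 0.01 * length(v))
      stop(sprintf(
        "coverage error: %d of %d samples in sector %d fall outside the grid",
        bad, length(v), s), call. = FALSE)
    means[s] <- mean(v, na.rm = TRUE)
    used[s] <- length(v) - bad
    skipped[s] <- bad
  }
  list(sector_means = means,
       sector_centers_deg = (seq_len(params$n_sectors) - 1L) *
         360 / params$n_sectors,
       samples_per_sector = used, skipped = skipped)
}

#' Sector validation and relative pi-hole descriptors
#'
#' From the candidate's local-maximum ESP `V` and the sector means
#' `Vbar_i`:
#' \itemize{
#'   \item `V_hole_mean = V - mean(Vbar_i)` -- must exceed `Delta_thr`
#'     (5 kcal/mol) for a genuine pi-hole;
#'   \item `V_hole_max = V - min(Vbar_i)`, `V_hole_min = V - max(Vbar_i)`
#'     -- maximum and minimum relative depth of electron depletion;
#'   \item `dV_hole = V_hole_max - V_hole_min = max(Vbar_i) - min(Vbar_i)`
#'     -- angular anisotropy of the depletion;
#'   \item `dV_angle` -- minimal circular separation of the sector center
#'     angles holding the extreme means (0, 45, ..., 180 degrees).
#' }
#'
#' @param candidate a [scan_axis()] candidate.
#' @param profile a [sector_profile()].
#' @param thr validation threshold Delta_thr (kcal/mol).
#' @return An object of class `"pihole_result"`: a list with the
#'   candidate, profile, descriptors, `valid` flag and `status`
#'   (`"valid"` or `"failed_validation"`).
#' @export
validate_candidate <- function(candidate, profile, thr = 5) {
  vb <- profile$sector_means
  vmean <- candidate$V - mean(vb)
  vmax <- candidate$V - min(vb)
  vmin <- candidate$V - max(vb)
  imax <- which.max(vb)[1L]
  imin <- which.min(vb)[1L]
  sep <- abs(profile$sector_centers_deg[imax] -
               profile$sector_centers_deg[imin])
  sep <- min(sep, 360 - sep)
  valid <- vmean > thr
  structure(list(
    candidate = candidate, profile = profile,
    V_hole_mean = vmean, V_hole_max = vmax, V_hole_min = vmin,
    dV_hole = vmax - vmin, dV_angle = sep,
    valid = valid, thr = thr, Vs_max = NA_real_,
    status = if (valid) "valid" else "failed_validation"),
    class = "pihole_result")
}

#' @export
print.pihole_result <- function(x, ...) {
  if (x$status == "no_candidate") {
    cat(sprintf("<pihole_result %s: no candidate>\n",
                x$candidate$hemisphere))
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<pihole_result %s: z = %.2f A, V = %.2f, V_hole_mean = %.2f,",
           " dV_hole = %.2f kcal/mol, %s>\n"),
    x$candidate$hemisphere, x$candidate$z, x$candidate$V, x$V_hole_mean,
    x$dV_hole, x$status))
  invisible(x)
}

#' Full pi-hole analysis of one complex
#'
#' Builds the aligned frame from the molecule's donor nitrogens, scans
#' both hemispheres for axial candidates, validates the highest-ESP
#' candidate of each hemisphere against its eight-sector background, and
#' (when a density grid is supplied) attaches the global surface maximum
#' Vs_max on the 0.001 e/bohr^3 isosurface.  Hemispheres with no
#' derivative-criterion candidate yield a result with status
#' `"no_candidate"`, distinct from `"failed_validation"`.
#'
#' @param mol a [molecule()] with `donor_N` (and usually `metal`) roles.
#' @param esp an ESP [scalar_grid()].
#' @param density optional density [scalar_grid()] for Vs_max.
#' @param params a [detect_params()] list.
#' @param iso isodensity level for Vs_max.
#' @return A list with one `"pihole_result"` per hemisphere (`+z` first;
#'   secondary unvalidated candidates in attribute `"secondary"`), the
#'   frame in attribute `"frame"`.
#' @export
analyze_complex <- function(mol, esp, density = NULL,
                            params = detect_params(), iso = 0.001) {
  frame <- frame_from_molecule(mol)
  vsm <- NA_real_
  if (!is.null(density))
    vsm <- vs_max(esp, isosurface_points(density, iso))$value
  out <- list()
  secondary <- list()
  for (hemi in c("+z", "-z")) {
    cands <- scan_axis(esp, frame, hemi, params)
    if (!length(cands)) {
      out[[hemi]] <- structure(list(
        candidate = list(z = NA_real_, V = NA_real_,
                         curvature = NA_real_, hemisphere = hemi),
        profile = NULL, V_hole_mean = NA_real_, V_hole_max = NA_real_,
        V_hole_min = NA_real_, dV_hole = NA_real_, dV_angle = NA_real_,
        valid = FALSE, thr = params$thr, Vs_max = vsm,
        status = "no_candidate"), class = "pihole_result")
      next
    }
    prof <- sector_profile(esp, cands[[1L]], frame, params)
    res <- validate_candidate(cands[[1L]], prof, params$thr)
    res$Vs_max <- vsm
    out[[hemi]] <- res
    if (length(cands) > 1L) secondary[[hemi]] <- cands[-1L]
  }
  structure(out, frame = frame, secondary = secondary)
}
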