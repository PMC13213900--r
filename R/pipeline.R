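# Batch orchestration: configuration, dataset generation, per-complex
# analysis to a descriptor CSV, grid-sensitivity comparison and aggregate
# reporting.

.MANIFEST_HEADER <- "# esphole manifest schema v1"
.DESCRIPTOR_HEADER <- "# esphole descriptors schema v1"

#' Run configuration
#'
#' Collects every tunable of the pipeline with the conventional defaults
#' (N-C 1.47 A, clash 0.8 A, rotation 10 deg, RMSD 1.5 A, detection
#' parameters of [detect_params()], 0.25 bohr grids, iso 0.001 e/bohr^3).
#'
#' @param metals,conformers,alphabet structure-space definition; see
#'   [enumerate_dataset()].
#' @param nc_dist,clash,rot_step substitution constants, see
#'   [substitute_site()].
#' @param detect a [detect_params()] list.
#' @param rmsd_threshold dedup threshold (A).
#' @param grid_spacing_bohr,grid_padding grid geometry for synthetic
#'   fields.
#' @param iso isodensity level for Vs_max.
#' @param verbose print per-structure status lines.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(metals = c("Co", "Ni", "Cu", "Zn"),
                       conformers = enumerate_conformers(),
                       alphabet = c("H", "Me", "Et"),
                       nc_dist = 1.47, clash = 0.8, rot_step = 10,
                       detect = detect_params(),
                       rmsd_threshold = 1.5,
                       grid_spacing_bohr = 0.25, grid_padding = 4,
                       iso = 0.001, verbose = FALSE) {
  if (!length(metals) || !length(conformers) || !length(alphabet))
    stop("config validation error: metals, conformers and alphabet must be non-empty",
         call. = FALSE)
  if (detect$thr < 0)
    stop("config validation error: thr must be >= 0", call. = FALSE)
  structure(list(metals = metals, conformers = conformers,
                 alphabet = alphabet, nc_dist = nc_dist, clash = clash,
                 rot_step = rot_step, detect = detect,
                 rmsd_threshold = rmsd_threshold,
                 grid_spacing_bohr = grid_spacing_bohr,
                 grid_padding = grid_padding, iso = iso,
                 verbose = verbose),
            class = "run_config")
}

.log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Generate the structure dataset
#'
#' Runs [enumerate_dataset()] followed by [dedup()], optionally writing
#' one XYZ per generated structure plus a manifest CSV, and logs counts
#' per status.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory for XYZ files and
#'   `manifest.csv`.
#' @return The manifest data.frame (molecules in attribute
#'   `"molecules"`).
#' @export
cmd_generate <- function(config = run_config(), outdir = NULL) {
  if (!is.null(outdir) && !dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("io error: cannot create output directory ", outdir, call. = FALSE)
  manifest <- enumerate_dataset(config$metals, config$conformers,
                                config$alphabet, outdir = outdir,
                                clash = config$clash,
                                rot_step = config$rot_step,
                                nc_dist = config$nc_dist)
  manifest <- dedup(manifest, config$rmsd_threshold)
  counts <- table(manifest$status)
  .log(config, "generated dataset: %s",
       paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  if (!is.null(outdir)) {
    path <- file.path(outdir, "manifest.csv")
    writeLines(.MANIFEST_HEADER, path)
    suppressWarnings(utils::write.table(
      manifest, path, sep = ",", row.names = FALSE, append = TRUE,
      qmethod = "double"))
  }
  manifest
}

# one descriptor row per hemisphere result
.result_rows <- function(meta, results, geom) {
  do.call(rbind, lapply(names(results), function(hemi) {
    r <- results[[hemi]]
    data.frame(metal = meta$metal, conformer = meta$conformer,
               pattern = meta$pattern, hemisphere = hemi,
               z = r$candidate$z, V_candidate = r$candidate$V,
               Vs_max = r$Vs_max, V_hole_mean = r$V_hole_mean,
               V_hole_max = r$V_hole_max, V_hole_min = r$V_hole_min,
               dV_hole = r$dV_hole, dV_angle = r$dV_angle,
               valid = r$valid, status = r$status,
               tau4 = geom$tau4, mn_mean = geom$mn_mean,
               stringsAsFactors = FALSE)
  }))
}

.meta_from_comment <- function(comment) {
  get <- function(key) {
    m <- regmatches(comment, regexec(paste0(key, "=([^ ]+)"), comment))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  list(metal = get("metal"), conformer = get("conformer"),
       pattern = get("pattern"))
}

#' Analyze XYZ + cube pairs into a descriptor table
#'
#' For every input pair, reads the geometry and ESP cube (plus optional
#' density cube), runs [analyze_complex()] and [geometry_descriptors()],
#' and appends one row per hemisphere.  Per-file failures are logged and
#' skipped; the run fails only if no pair succeeds.
#'
#' @param config a [run_config()].
#' @param inputs data.frame with columns `xyz`, `esp` and optionally
#'   `density` (file paths), or a list of in-memory triples
#'   `list(mol=, esp=, density=)`.
#' @param out_csv optional path for the descriptor CSV (schema-versioned
#'   header comment line).
#' @return The descriptor data.frame; failures in attribute
#'   `"failures"`.
#' @export
cmd_analyze <- function(config = run_config(), inputs, out_csv = NULL) {
  items <- if (is.data.frame(inputs)) {
    lapply(seq_len(nrow(inputs)), function(i) as.list(inputs[i, ]))
  } else inputs
  rows <- list()
  failures <- character(0)
  for (i in seq_along(items)) {
    it <- items[[i]]
    label <- if (!is.null(it$xyz)) it$xyz else sprintf("input %d", i)
    res <- tryCatch({
      mol <- if (!is.null(it$mol)) it$mol else read_xyz(it$xyz)
      esp <- if (inherits(it$esp, "scalar_grid")) it$esp else
        read_cube(it$esp, kind = "esp_kcalmol")$grid
      density <- NULL
      if (!is.null(it$density) && !(is.atomic(it$density) &&
                                    is.na(it$density))) {
        density <- if (inherits(it$density, "scalar_grid")) it$density else
          read_cube(it$density, kind = "density_au")$grid
      }
      ana <- analyze_complex(mol, esp, density, config$detect, config$iso)
      geom <- tryCatch(geometry_descriptors(mol),
                       error = function(e) list(tau4 = NA_real_,
                                                mn_mean = NA_real_))
      .result_rows(.meta_from_comment(mol$comment), ana, geom)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", label, conditionMessage(res)))
      .log(config, "FAILED %s: %s", label, conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
      .log(config, "analyzed %s: %s", label,
           paste(res$status, collapse = "/"))
    }
  }
  if (!length(rows))
    stop("empty-run error: no input pair analyzed successfully",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) {
    writeLines(.DESCRIPTOR_HEADER, out_csv)
    suppressWarnings(utils::write.table(
      out, out_csv, sep = ",", row.names = FALSE, append = TRUE,
      qmethod = "double"))
  }
  attr(out, "failures") <- failures
  out
}

#' Grid-sensitivity comparison on synthetic fixtures
#'
#' Regenerates each fixture's ESP (and density, when specified) at every
#' requested spacing, re-runs the full detection, and reports the mean
#' absolute percent deviation of each V-descriptor between the first
#' spacing and each other one -- the synthetic analogue of recomputing a
#' structure subset at 0.25 versus 0.20 bohr.
#'
#' @param config a [run_config()].
#' @param fixtures list of `list(mol =, spec =)` pairs; `spec` must be
#'   regenerable at any spacing (a [field_spec()]).
#' @param spacings numeric vector of at least two grid spacings (bohr).
#' @return A data.frame with one row per (spacing pair, descriptor):
#'   columns `spacing_ref`, `spacing`, `descriptor`,
#'   `mean_abs_pct_deviation` and `n_lost` (fixtures whose candidate
#'   disappeared at one of the two resolutions).
#' @export
cmd_grid_sensitivity <- function(config = run_config(), fixtures,
                                 spacings = c(0.25, 0.20)) {
  if (length(spacings) < 2L)
    stop("config error: need at least two grid spacings", call. = FALSE)
  descriptors <- c("Vs_max", "V_hole_mean", "V_hole_max", "V_hole_min",
                   "dV_hole")
  per_spacing <- lapply(spacings, function(sp) {
    rows <- lapply(fixtures, function(fx) {
      spec <- fx$spec
      spec$grid$spacing <- bohr_to_ang(sp)
      # keep coverage identical: same origin/extent, rescaled shape
      extent <- (fx$spec$grid$shape - 1L) * fx$spec$grid$spacing
      spec$grid$shape <- as.integer(ceiling(extent / spec$grid$spacing)) + 1L
      esp <- point_charge_field(spec)
      density <- if (!is.null(spec$density_gaussians))
        gaussian_density(spec) else NULL
      ana <- analyze_complex(fx$mol, esp, density, config$detect,
                             config$iso)
      ok <- Filter(function(r) r$status != "no_candidate", ana)
      if (!length(ok))   # candidate lost at this resolution
        return(data.frame(Vs_max = NA_real_, V_hole_mean = NA_real_,
                          V_hole_max = NA_real_, V_hole_min = NA_real_,
                          dV_hole = NA_real_))
      r <- ok[[which.max(vapply(ok, `[[`, numeric(1), "V_hole_mean"))]]
      data.frame(Vs_max = r$Vs_max, V_hole_mean = r$V_hole_mean,
                 V_hole_max = r$V_hole_max, V_hole_min = r$V_hole_min,
                 dV_hole = r$dV_hole)
    })
    do.call(rbind, rows)
  })
  ref <- per_spacing[[1L]]
  out <- list()
  for (k in seq_along(spacings)[-1L]) {
    cur <- per_spacing[[k]]
    for (d in descriptors) {
      dev <- abs(cur[[d]] - ref[[d]]) / pmax(abs(ref[[d]]), 1e-12) * 100
      out[[length(out) + 1L]] <- data.frame(
        spacing_ref = spacings[1L], spacing = spacings[k], descriptor = d,
        mean_abs_pct_deviation = mean(dev, na.rm = TRUE),
        n_lost = sum(is.na(dev)))
    }
  }
  do.call(rbind, out)
}

#' Aggregate a descriptor table per metal and conformer
#'
#' Computes, per (metal, conformer) group: the percentage of complexes
#' showing at least one validated pi-hole (occurrence), mean and sd of
#' the hole height z and of V_hole_mean over valid rows, and the mean
#' tau4 and mean M-N distance -- the machine-readable summary of the
#' dataset-level trends.  Empty groups (no analyzable rows) are omitted
#' with a warning.
#'
#' @param descriptors a descriptor data.frame from [cmd_analyze()], or
#'   the path of a descriptor CSV.
#' @return A summary data.frame.
#' @export
cmd_report <- function(descriptors) {
  if (is.character(descriptors))
    descriptors <- utils::read.csv(descriptors, comment.char = "#",
                                   stringsAsFactors = FALSE)
  req <- c("metal", "conformer", "valid", "z", "V_hole_mean", "tau4",
           "mn_mean")
  if (!all(req %in% names(descriptors)))
    stop("schema error: descriptor table lacks column(s) ",
         paste(setdiff(req, names(descriptors)), collapse = ", "),
         call. = FALSE)
  if (!nrow(descriptors))
    stop("schema error: empty descriptor table", call. = FALSE)
  groups <- split(descriptors,
                  list(descriptors$metal, descriptors$conformer),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    # a group where no hemisphere ever produced a candidate has nothing
    # to aggregate
    if (!is.null(g$status) && all(g$status == "no_candidate"))
      return(NULL)
    val <- g[which(g$valid), ]
    cx <- if ("pattern" %in% names(g)) g$pattern else
      rep("all", nrow(g))
    data.frame(metal = g$metal[1L], conformer = g$conformer[1L],
               n = length(unique(cx)),
               occurrence_pct = 100 * length(unique(cx[which(g$valid)])) /
                 length(unique(cx)),
               z_mean = mean(val$z), z_sd = stats::sd(val$z),
               V_hole_mean_mean = mean(val$V_hole_mean),
               V_hole_mean_sd = stats::sd(val$V_hole_mean),
               tau4_mean = mean(g$tau4, na.rm = TRUE),
               mn_mean = mean(g$mn_mean, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning("omitting empty group(s): ",
            paste(names(rows)[empty], collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  out[order(out$metal, out$conformer), ]
}

#' Export a synthetic fixture as cube files
#'
#' Writes the ESP (and, when the spec defines a model density, the
#' density) of a [field_spec()] as Gaussian cube files, plus the matching
#' XYZ, enabling end-to-end file-based runs.
#'
#' @param spec a [field_spec()].
#' @param mol the matching [molecule()].
#' @param dir output directory.
#' @param name base file name.
#' @return Named character vector of the written paths.
#' @export
export_fixture_cubes <- function(spec, mol, dir, name = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  esp <- point_charge_field(spec)
  paths <- c(xyz = file.path(dir, paste0(name, ".xyz")),
             esp = file.path(dir, paste0(name, "_esp.cube")))
  write_xyz(mol, paths[["xyz"]])
  write_cube(esp, mol, paths[["esp"]])
  if (!is.null(spec$density_gaussians)) {
    paths[["density"]] <- file.path(dir, paste0(name, "_rho.cube"))
    write_cube(gaussian_density(spec), mol, paths[["density"]])
  }
  paths
}
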