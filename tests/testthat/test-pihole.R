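# Axial candidate search, sector profiles, validation descriptors and the
# full per-complex analysis.

test_that("a bare monopole produces no axial candidate", {
  spec <- field_spec(charges = data.frame(q = 2, x = 0, y = 0, z = 0),
                     grid = list(origin = rep(-5, 3), shape = rep(41L, 3),
                                 spacing = 0.25))
  esp <- point_charge_field(spec)
  cands <- scan_axis(esp, identity_frame(), "+z", fixture_params())
  expect_length(cands, 0)
})

test_that("an axial Gaussian bump is located within one step of the dense oracle", {
  spec <- field_spec(
    charges = data.frame(q = 2, x = 0, y = 0, z = 0),
    gaussians = data.frame(A = 120, x = 0, y = 0, z = 2.0, w = 0.3),
    grid = list(origin = rep(-4.5, 3), shape = rep(61L, 3), spacing = 0.15))
  esp <- point_charge_field(spec)
  cands <- scan_axis(esp, identity_frame(), "+z", fixture_params())
  expect_length(cands, 1)
  z_oracle <- oracle_axis_max(spec)
  expect_false(is.na(z_oracle))
  expect_lte(abs(cands[[1]]$z - z_oracle), 0.05 + 1e-9)
  expect_lt(cands[[1]]$curvature, 0)
})

test_that("mirror-symmetric bumps give one candidate per hemisphere at symmetric z", {
  spec <- field_spec(
    gaussians = data.frame(A = c(25, 25), x = 0, y = 0, z = c(2, -2),
                           w = 0.4),
    grid = list(origin = rep(-4.5, 3), shape = rep(61L, 3), spacing = 0.15))
  esp <- point_charge_field(spec)
  up <- scan_axis(esp, identity_frame(), "+z", detect_params())
  dn <- scan_axis(esp, identity_frame(), "-z", detect_params())
  expect_length(up, 1)
  expect_length(dn, 1)
  expect_lt(abs(up[[1]]$z + dn[[1]]$z), 1e-6)
  expect_identical(up[[1]]$hemisphere, "+z")
  expect_identical(dn[[1]]$hemisphere, "-z")
})

test_that("scan errors when the grid misses the search cylinder", {
  spec <- field_spec(charges = data.frame(q = 1, x = 0, y = 0, z = 0),
                     grid = list(origin = rep(-1, 3), shape = rep(9L, 3),
                                 spacing = 0.25))
  esp <- point_charge_field(spec)
  expect_error(scan_axis(esp, identity_frame(), "+z", detect_params()),
               "coverage error")
})

test_that("sector means are exact on constant and antisymmetric on linear fields", {
  gr <- scalar_grid(rep(-4, 3), diag(3) * 0.25, rep(33L, 3),
                    array(4.2, rep(33L, 3)), "esp_kcalmol")
  cand <- list(z = 0, V = 4.2, hemisphere = "+z")
  prof <- sector_profile(gr, cand, identity_frame(), detect_params())
  expect_equal(prof$sector_means, rep(4.2, 8), tolerance = 1e-12)
  expect_identical(prof$sector_centers_deg, seq(0, 315, by = 45))
  expect_true(all(prof$samples_per_sector == 1000))

  lin <- gr
  lin$values <- array(3 * grid_points(gr)[, 1], dim = gr$shape)
  pl <- sector_profile(lin, cand, identity_frame(), detect_params())
  # odd symmetry: opposite sectors cancel pairwise
  for (i in 1:4)
    expect_lt(abs(pl$sector_means[i] + pl$sector_means[i + 4]), 1e-6)
})

test_that("stratified sector means match a 1e6-sample Monte-Carlo oracle within 0.5%", {
  # point-charge field: the background the sectors are meant to measure
  fx <- fx_axial()
  spec <- fx$spec
  spec$gaussians <- NULL
  esp <- point_charge_field(spec)
  cand <- list(z = 2.1, V = NA, hemisphere = "+z")
  prof <- sector_profile(esp, cand, identity_frame(), detect_params())
  set.seed(1234)
  for (s in 1:8) {
    mc <- oracle_sector_mean(spec, s, 2.1)
    expect_lt(abs(prof$sector_means[s] - mc) / abs(mc), 0.005)
  }
})

test_that("sector profile errors when samples leave the grid", {
  gr <- scalar_grid(rep(-1.5, 3), diag(3) * 0.25, rep(13L, 3),
                    array(1, rep(13L, 3)), "esp_kcalmol")
  cand <- list(z = 0, V = 1, hemisphere = "+z")
  expect_error(sector_profile(gr, cand, identity_frame(), detect_params()),
               "coverage error")
})

test_that("validation reproduces the printed descriptor arithmetic", {
  centers <- seq(0, 315, by = 45)
  # profile engineered to the printed Zn relative descriptors:
  # V_hole_mean 30.30, V_hole_max 41.83, V_hole_min 19.76
  V0 <- 100
  vb <- rep(V0 - (242.40 - 61.59) / 6, 8)
  vb[3] <- V0 - 41.83   # lowest sector mean
  vb[7] <- V0 - 19.76   # highest sector mean
  prof <- list(sector_means = vb, sector_centers_deg = centers)
  res <- validate_candidate(list(V = V0, z = 2.0, hemisphere = "+z"), prof)
  expect_equal(res$V_hole_mean, 30.30, tolerance = 1e-9)
  expect_equal(res$V_hole_max, 41.83, tolerance = 1e-9)
  expect_equal(res$V_hole_min, 19.76, tolerance = 1e-9)
  expect_equal(res$dV_hole, 41.83 - 19.76, tolerance = 1e-9)  # 22.07
  expect_true(res$V_hole_min <= res$V_hole_mean &
                res$V_hole_mean <= res$V_hole_max)
  expect_true(res$valid)
  expect_equal(res$dV_angle, 180)  # sectors 3 and 7 are opposite

  # flat background: nothing to validate
  flat <- list(sector_means = rep(10, 8), sector_centers_deg = centers)
  r0 <- validate_candidate(list(V = 10, z = 1, hemisphere = "+z"), flat)
  expect_equal(r0$V_hole_mean, 0)
  expect_equal(r0$dV_hole, 0)
  expect_false(r0$valid)

  # a negative relative depth fails the 5 kcal/mol threshold
  neg <- list(sector_means = rep(197.94, 8), sector_centers_deg = centers)
  rn <- validate_candidate(list(V = 197.04, z = 1, hemisphere = "+z"), neg)
  expect_equal(rn$V_hole_mean, -0.90, tolerance = 1e-9)
  expect_false(rn$valid)
  expect_identical(rn$status, "failed_validation")

  # adjacent extreme sectors
  adj <- list(sector_means = c(1, 9, rep(5, 6)), sector_centers_deg = centers)
  expect_equal(validate_candidate(list(V = 20), adj)$dV_angle, 45)
})

test_that("dV_hole identity and descriptor ordering hold on analyzed fixtures", {
  fx <- fx_axial()
  ana <- analyze_complex(fx$mol, fx$esp, fx$density, fixture_params())
  r <- ana[["+z"]]
  expect_identical(r$status, "valid")
  vb <- r$profile$sector_means
  expect_equal(r$dV_hole, max(vb) - min(vb), tolerance = 1e-12)
  expect_true(r$V_hole_min <= r$V_hole_mean & r$V_hole_mean <= r$V_hole_max)
  expect_true(r$dV_hole >= 0)
  expect_true(is.finite(r$Vs_max))
})

test_that("relative descriptors are invariant to a constant ESP shift; Vs_max shifts", {
  fx <- fx_axial()
  shifted <- fx$esp
  shifted$values <- shifted$values + 50
  a1 <- analyze_complex(fx$mol, fx$esp, fx$density, fixture_params())
  a2 <- analyze_complex(fx$mol, shifted, fx$density, fixture_params())
  r1 <- a1[["+z"]]; r2 <- a2[["+z"]]
  for (d in c("V_hole_mean", "V_hole_max", "V_hole_min", "dV_hole",
              "dV_angle"))
    expect_equal(r2[[d]], r1[[d]], tolerance = 1e-9)
  expect_equal(r2$Vs_max - r1$Vs_max, 50, tolerance = 1e-9)
  expect_equal(r2$candidate$z, r1$candidate$z)
})

test_that("the axial-depletion fixture yields one valid +z hole in the 1.8-2.4 A band", {
  fx <- fx_axial()
  ana <- analyze_complex(fx$mol, fx$esp, fx$density, fixture_params())
  r <- ana[["+z"]]
  expect_true(r$valid)
  expect_gte(r$candidate$z, 1.8)
  expect_lte(r$candidate$z, 2.4)
  # ground truth: the analytic on-axis maximum was placed at 2.1 A
  z_oracle <- oracle_axis_max(fx$spec)
  expect_equal(z_oracle, 2.1, tolerance = 1e-3)
  expect_lte(abs(r$candidate$z - z_oracle), 0.05 + 1e-9)
  expect_identical(ana[["-z"]]$status, "no_candidate")
  expect_false(ana[["-z"]]$valid)
})

test_that("a saddle field with only off-axis structure reports no candidate", {
  spec <- field_spec(
    charges = data.frame(q = c(2, rep(-0.4, 4)),
                         x = c(0, 1.45, -1.45, 0, 0),
                         y = c(0, 0, 0, 1.45, -1.45), z = 0),
    gaussians = data.frame(A = 40, x = 1.5, y = 0, z = 2.0, w = 0.4),
    grid = grid_request(rbind(c(0, 0, 0), c(0, 0, 3.5), c(0, 0, -3.5),
                              c(3, 3, 0), c(-3, -3, 0)),
                        spacing_bohr = 0.25, padding = 4))
  esp <- point_charge_field(spec)
  ana <- analyze_complex(axial_depletion_molecule(), esp, NULL,
                         fixture_params())
  expect_identical(ana[["+z"]]$status, "no_candidate")
  expect_identical(ana[["-z"]]$status, "no_candidate")
})

test_that("descriptors are equivariant under rigid motion of molecule and field", {
  # lattice-preserving rigid motion (90-degree rotation about z plus a
  # whole-voxel translation) keeps the regenerated grid strictly
  # comparable, so any descriptor change is an algorithmic artifact
  h <- bohr_to_ang(0.25)
  gr <- list(origin = rep(-42 * h, 3), shape = rep(85L, 3), spacing = h)
  spec <- axial_depletion_spec()
  spec$grid <- gr
  R <- rotation_matrix(c(0, 0, 1), 90)
  shift <- h * c(3, -5, 2)
  spec_r <- spec
  for (f in c("charges", "gaussians", "density_gaussians")) {
    xyz <- as.matrix(spec[[f]][, c("x", "y", "z")]) %*% t(R)
    spec_r[[f]]$x <- xyz[, 1] + shift[1]
    spec_r[[f]]$y <- xyz[, 2] + shift[2]
    spec_r[[f]]$z <- xyz[, 3] + shift[3]
  }
  spec_r$grid$origin <- gr$origin + shift
  mol_r <- transform_molecule(axial_depletion_molecule(), R, shift)

  a1 <- analyze_complex(axial_depletion_molecule(),
                        point_charge_field(spec), NULL, fixture_params())
  a2 <- analyze_complex(mol_r, point_charge_field(spec_r), NULL,
                        fixture_params())
  v1 <- Filter(function(r) isTRUE(r$valid), a1)
  v2 <- Filter(function(r) isTRUE(r$valid), a2)
  expect_length(v1, 1)
  expect_length(v2, 1)
  r1 <- v1[[1]]; r2 <- v2[[1]]
  expect_equal(abs(r2$candidate$z), abs(r1$candidate$z), tolerance = 1e-6)
  for (d in c("V_hole_mean", "V_hole_max", "V_hole_min", "dV_hole"))
    expect_lt(abs(r2[[d]] - r1[[d]]), 1e-3)
})

test_that("halving the grid spacing changes descriptors by less than 5%", {
  fx1 <- fx_axial(0.25)
  fx2 <- fx_axial(0.125)
  p <- fixture_params()
  r1 <- analyze_complex(fx1$mol, fx1$esp, fx1$density, p)[["+z"]]
  r2 <- analyze_complex(fx2$mol, fx2$esp, fx2$density, p)[["+z"]]
  for (d in c("Vs_max", "V_hole_mean", "V_hole_max", "V_hole_min"))
    expect_lt(abs(r2[[d]] - r1[[d]]) / abs(r1[[d]]), 0.05)
})
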