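# Conformer enumeration, template construction, metalation, substitution
# and RMSD deduplication.

test_that("conformer enumeration matches the brute-force orbit partition", {
  reps <- enumerate_conformers()
  expect_length(reps, 4)
  expect_setequal(reps, c("UUUU", "DUUU", "DDUU", "DUDU"))

  classes <- oracle_conformer_classes(4)
  expect_length(classes, 4)
  # each representative sits in exactly one orbit, and all orbits are hit
  hits <- vapply(reps, function(r)
    which(vapply(classes, function(cl) r %in% cl, logical(1))), integer(1))
  expect_setequal(hits, seq_along(classes))
  # orbits partition all 16 strings
  expect_identical(sum(lengths(classes)), 16L)

  # single-site analogue: U and D collapse under inversion
  expect_identical(enumerate_conformers(1), "U")
  expect_length(oracle_conformer_classes(1), 1)
})

test_that("templates are planar C8H20N4 rings with pattern-matched N-H vectors", {
  for (pat in enumerate_conformers()) {
    t <- build_template(pat)
    expect_identical(as.vector(table(t$elements)[c("C", "H", "N")]),
                     c(8L, 20L, 4L))
    ring <- t$coords[1:12, ]
    expect_lte(max(abs(ring[, 3])), 0.3)
    donors <- role_indices(t, "donor_N")
    hs <- role_indices(t, "NH_hydrogen")
    expect_length(donors, 4)
    expect_length(hs, 4)
    letters <- strsplit(pat, "")[[1]]
    for (i in 1:4) {
      nh <- t$coords[hs[i], ] - t$coords[donors[i], ]
      expect_equal(sqrt(sum(nh^2)), 1.02, tolerance = 1e-9)
      expect_identical(sign(nh[3]), if (letters[i] == "U") 1 else -1)
    }
  }
  # DUDU: N-H z signs alternate in ring order
  t <- build_template("DUDU")
  zsign <- sign(t$coords[role_indices(t, "NH_hydrogen"), 3])
  expect_identical(zsign, c(-1, 1, -1, 1))
})

test_that("metalation places the metal at the donor centroid, charge +2", {
  sq <- molecule(rep("N", 4),
                 rbind(c(1.4, 1.4, 0), c(-1.4, 1.4, 0),
                       c(-1.4, -1.4, 0), c(1.4, -1.4, 0)),
                 roles = rep("donor_N", 4))
  m <- metalate(sq, "Ni")
  expect_equal(m$coords[role_indices(m, "metal"), ], c(0, 0, 0),
               tolerance = 1e-12)
  expect_identical(m$charge, 2L)
  expect_identical(m$multiplicity, 1L)  # d8 low spin

  # translation equivariance
  sq2 <- sq; sq2$coords <- sweep(sq2$coords, 2, c(3, -2, 7), "+")
  m2 <- metalate(sq2, "Ni")
  expect_equal(m2$coords[role_indices(m2, "metal"), ], c(3, -2, 7),
               tolerance = 1e-12)

  # role errors
  bad <- sq; bad$roles[1] <- NA
  expect_error(metalate(bad, "Ni"), "role error")
})

test_that("metal multiplicities follow the lowest-spin d-electron count", {
  t <- build_template("UUUU")
  mult <- vapply(c("Co", "Ni", "Cu", "Zn"),
                 function(m) metalate(t, m)$multiplicity, integer(1))
  expect_identical(unname(mult), c(2L, 1L, 2L, 1L))
})

test_that("substitution places the root carbon 1.47 A along the former N-H vector", {
  cx <- metalate(build_template("UUUU"), "Zn")
  donors <- role_indices(cx, "donor_N")
  npos <- cx$coords[donors[1], ]
  hidx <- role_indices(cx, "NH_hydrogen")
  hpos <- cx$coords[hidx[which.min(
    sqrt(colSums((t(cx$coords[hidx, , drop = FALSE]) - npos)^2)))], ]
  vref <- (hpos - npos) / sqrt(sum((hpos - npos)^2))

  for (grp in c("Me", "Et")) {
    s <- substitute_site(cx, donors[1], grp)
    root <- s$coords[role_indices(s, "substituent_root")[1], ]
    expect_equal(sqrt(sum((root - npos)^2)), 1.47, tolerance = 1e-6)
    expect_equal((root - npos) / 1.47, vref, tolerance = 1e-6)
    expect_gte(min(stats::dist(s$coords)), 0.8)
    expect_identical(attr(s, "rotation_deg") %% 10, 0)
    expect_identical(natoms(s), natoms(cx) - 1L +
                       if (grp == "Me") 4L else 7L)
  }

  # a truly isolated N-H: placement succeeds with zero rotations tried
  lone <- molecule(c("N", "H"), rbind(c(0, 0, 0), c(0, 0, 1.02)),
                   roles = c("donor_N", "NH_hydrogen"))
  s <- substitute_site(lone, 1, "Me")
  expect_identical(attr(s, "rotation_deg"), 0)
  expect_equal(s$coords[role_indices(s, "substituent_root"), ],
               c(0, 0, 1.47), tolerance = 1e-9)
})

test_that("clash resolution picks the first passing 10-degree angle (dense oracle)", {
  # contrived clash: a blocking atom near where the rot = 0 ethyl tail lands
  cx <- metalate(build_template("UUUU"), "Zn")
  donors <- role_indices(cx, "donor_N")
  npos <- cx$coords[donors[1], ]
  hidx <- role_indices(cx, "NH_hydrogen")
  hpos <- cx$coords[hidx[which.min(
    sqrt(colSums((t(cx$coords[hidx, , drop = FALSE]) - npos)^2)))], ]
  v <- (hpos - npos) / sqrt(sum((hpos - npos)^2))
  probe <- substitute_site(cx, donors[1], "Et")
  tail_c <- probe$coords[natoms(cx) - 1L + 2L, ]   # second substituent carbon
  blocker <- molecule(c(cx$elements, "He"), rbind(cx$coords, tail_c + 0.1),
                      roles = c(cx$roles, NA), charge = cx$charge,
                      multiplicity = cx$multiplicity)

  s <- substitute_site(blocker, donors[1], "Et")
  rot <- attr(s, "rotation_deg")
  expect_identical(rot %% 10, 0)
  expect_gte(min(stats::dist(s$coords)), 0.8)

  # dense 1-degree replay: an independent Rodrigues rotation of the
  # accepted substituent about the N->C axis, checking min distance
  base_idx <- seq_len(natoms(blocker))[-which(
    blocker$roles == "NH_hydrogen" &
      sqrt(rowSums(sweep(blocker$coords, 2, npos)^2)) < 1.3)]
  base <- blocker$coords[base_idx, ]
  sub0 <- s$coords[(nrow(base) + 1):natoms(s), ]
  # un-rotate the accepted geometry back to the 0-degree reference
  R_acc <- rotation_matrix(v, -rot)
  sub_ref <- sweep(sweep(sub0, 2, npos) %*% t(R_acc), 2, npos, "+")
  clear <- function(theta) {
    R <- rotation_matrix(v, theta)
    subr <- sweep(sweep(sub_ref, 2, npos) %*% t(R), 2, npos, "+")
    min(stats::dist(rbind(base, subr))) >= 0.8
  }
  dense_ok <- vapply(0:359, clear, logical(1))
  first_grid_pass <- (0:35 * 10)[which(dense_ok[0:35 * 10 + 1])[1]]
  expect_identical(rot, first_grid_pass)
  expect_gt(first_grid_pass, 0)  # the blocker really forced a scan
})

test_that("substitution rejects structures no rotation can fix", {
  cx <- metalate(build_template("UUUU"), "Zn")
  donors <- role_indices(cx, "donor_N")
  npos <- cx$coords[donors[1], ]
  hidx <- role_indices(cx, "NH_hydrogen")
  hpos <- cx$coords[hidx[which.min(
    sqrt(colSums((t(cx$coords[hidx, , drop = FALSE]) - npos)^2)))], ]
  v <- (hpos - npos) / sqrt(sum((hpos - npos)^2))
  # blocker sitting right on the root-carbon site: rotation cannot move it
  blocked <- molecule(c(cx$elements, "He"),
                      rbind(cx$coords, npos + 1.47 * v + c(0.1, 0, 0)),
                      roles = c(cx$roles, NA), charge = cx$charge,
                      multiplicity = cx$multiplicity)
  expect_error(substitute_site(blocked, donors[1], "Me"),
               class = "esphole_overlap_error")
})

test_that("dataset enumeration follows the product formula", {
  m <- enumerate_dataset(metals = c("Co", "Zn"),
                         conformers = enumerate_conformers(),
                         alphabet = c("H", "Me"))
  expect_identical(nrow(m), 128L)  # 2 metals x 4 conformers x 2^4
  expect_true(all(m$status == "generated"))
  expect_identical(anyDuplicated(m[c("metal", "conformer", "pattern")]), 0L)

  single <- enumerate_dataset(metals = "Ni", conformers = "UUUU",
                              alphabet = "H")
  expect_identical(nrow(single), 1L)
  expect_identical(single$pattern, "H,H,H,H")

  expect_error(enumerate_dataset(metals = character(0)),
               "config validation error")
})

test_that("every generated geometry clears the 0.8 A overlap threshold", {
  m <- enumerate_dataset(metals = "Cu", conformers = c("DUDU", "UUUU"),
                         alphabet = c("H", "Et"))
  mols <- attr(m, "molecules")
  mind <- vapply(mols, function(x) min(stats::dist(x$coords)), numeric(1))
  expect_true(all(mind >= 0.8))
})

test_that("rmsd is zero under rigid motion and errors on element mismatch", {
  cx <- metalate(build_template("DDUU"), "Co")
  expect_lt(rmsd(cx, cx), 1e-12)
  R <- rotation_matrix(c(1, 2, 3), 37)
  moved <- cx
  moved$coords <- sweep(cx$coords %*% t(R), 2, c(5, -1, 2), "+")
  expect_lt(rmsd(cx, moved), 1e-9)
  other <- metalate(build_template("DDUU"), "Ni")
  expect_error(rmsd(cx, other), "comparability error")
})

test_that("dedup flags re-generated copies, is idempotent, and keeps the combinatorial set", {
  m <- enumerate_dataset(metals = "Zn", conformers = c("UUUU", "DUUU"),
                         alphabet = c("H", "Me"))
  d1 <- dedup(m)
  expect_true(all(d1$status == "generated"))  # deliberate variation kept
  # a doubled manifest: every second copy is a true duplicate
  both <- rbind(m, m)
  attr(both, "molecules") <- c(attr(m, "molecules"), attr(m, "molecules"))
  d2 <- dedup(both)
  expect_identical(sum(d2$status == "duplicate"), nrow(m))
  expect_true(all(d2$status[seq_len(nrow(m))] == "generated"))
  # idempotent
  expect_identical(dedup(d2)$status, d2$status)
})

test_that("generation is equivariant under rigid motion of the template", {
  t <- build_template("DUUU")
  R <- rotation_matrix(c(0, 1, 1), 63)
  shift <- c(-2, 4, 1)
  t2 <- t
  t2$coords <- sweep(t$coords %*% t(R), 2, shift, "+")
  m1 <- substitute_site(metalate(t, "Cu"), role_indices(t, "donor_N")[2], "Me")
  m2 <- substitute_site(metalate(t2, "Cu"), role_indices(t2, "donor_N")[2], "Me")
  expect_lt(max(abs(sweep(m1$coords %*% t(R), 2, shift, "+") - m2$coords)),
            1e-8)
})
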