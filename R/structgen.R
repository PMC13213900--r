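# Combinatorial {TM(cyclen)}2+ structure generation: U/D conformer
# enumeration, planar template construction, metalation at the N4 centroid,
# N-substitution with steric-clash resolution, and RMSD uniqueness
# filtering.

.TETRA_HALF <- 54.7356103172  # half of 109.4712 deg, sp3 construction
.NC_DIST <- 1.47   # N-C bond on substitution (A)
.CC_DIST <- 1.54
.CH_DIST <- 1.09
.NH_DIST <- 1.02

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# ---------------------------------------------------------------- conformers

.conformer_orbit <- function(pattern) {
  ch <- strsplit(pattern, "")[[1L]]
  n <- length(ch)
  rots <- lapply(seq_len(n) - 1L, function(k)
    ch[((seq_len(n) - 1L + k) %% n) + 1L])
  out <- character(0)
  inv <- c(U = "D", D = "U")
  for (r in rots) {
    for (s in list(r, rev(r))) {               # ring rotation x reflection
      out <- c(out, paste(s, collapse = ""),
               paste(inv[s], collapse = ""))   # global U<->D inversion
    }
  }
  unique(out)
}

.canonical_conformer <- function(pattern) {
  orb <- .conformer_orbit(pattern)
  nd <- nchar(gsub("[^D]", "", orb))
  cand <- orb[nd == min(nd)]
  sort(cand)[1L]
}

#' Enumerate unique macrocycle U/D conformers
#'
#' Each ring nitrogen's N-H (or N-R) vector points up (`U`) or down (`D`)
#' relative to the N4-plane.  Patterns related by ring rotation, ring
#' reflection, or a global up/down flip describe the same conformer; this
#' returns one canonical representative per equivalence class (fewest `D`
#' letters, then lexicographic), in lexicographic order.
#'
#' For the four-nitrogen ring there are exactly four classes:
#' `UUUU`, `DUUU`, `DDUU` and `DUDU`.
#'
#' @param n ring size (number of substitutable nitrogens); default 4.
#' @return Character vector of canonical patterns.
#' @examples
#' enumerate_conformers()      # "DDUU" "DUDU" "DUUU" "UUUU"
#' enumerate_conformers(1)     # "U": a single site has one class
#' @export
enumerate_conformers <- function(n = 4L) {
  all <- do.call(expand.grid,
                 c(rep(list(c("D", "U")), n),
                   stringsAsFactors = FALSE))
  pats <- apply(as.matrix(all), 1L, paste, collapse = "")
  sort(unique(vapply(pats, .canonical_conformer, character(1))))
}

# ------------------------------------------------------------------ template

# the two remaining sp3 directions at a ring atom bonded to prev/next,
# symmetric about the in-plane exocyclic bisector, tilted +-z
.sp3_directions <- function(pos, prev, nxt) {
  u1 <- .unit(prev - pos)
  u2 <- .unit(nxt - pos)
  bis <- -(u1 + u2)
  bis <- .unit(bis - c(0, 0, bis[3]))  # keep the bisector in-plane
  th <- .TETRA_HALF * pi / 180
  list(up = cos(th) * bis + sin(th) * c(0, 0, 1),
       down = cos(th) * bis + sin(th) * c(0, 0, -1))
}

#' Build a planar cyclen template for a U/D conformer
#'
#' Constructs the 12-membered tetraaza ring (4 N + 8 C, sequence N-C-C
#' repeated) on a circle in the z = 0 plane with bond lengths N-C 1.47 A
#' and C-C 1.54 A, then adds CH2 hydrogens (C-H 1.09 A) and one N-H per
#' nitrogen (N-H 1.02 A) by local tetrahedral construction.  The N-H of
#' ring nitrogen i points along +z when the i-th pattern letter is `U` and
#' along -z for `D`; non-UUUU conformers are obtained by mirroring the
#' corresponding hydrogens across the N4-plane.
#'
#' @param conformer length-4 string over `{U, D}`.
#' @return A [molecule()] with 32 atoms (C8H20N4), `donor_N` and
#'   `NH_hydrogen` roles set, and the conformer recorded on the comment
#'   line.
#' @examples
#' t <- build_template("DUDU")
#' natoms(t)  # 32
#' @export
build_template <- function(conformer) {
  ch <- strsplit(conformer, "")[[1L]]
  if (length(ch) != 4L || !all(ch %in% c("U", "D")))
    stop("conformer must be a length-4 string over {U, D}", call. = FALSE)
  ring_elem <- rep(c("N", "C", "C"), 4L)
  bonds <- rep(c(.NC_DIST, .CC_DIST, .NC_DIST), 4L)  # bond j: atom j -> j+1
  radius <- stats::uniroot(
    function(R) sum(2 * asin(bonds / (2 * R))) - 2 * pi,
    lower = max(bonds) / 2 + 1e-6, upper = 10, tol = 1e-12)$root
  ang <- cumsum(c(0, 2 * asin(bonds[-12L] / (2 * radius))))
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)

  elements <- ring_elem
  coords <- ring
  roles <- ifelse(ring_elem == "N", "donor_N", NA_character_)
  n_letter <- 0L
  for (j in seq_len(12L)) {
    prev <- ring[if (j == 1L) 12L else j - 1L, ]
    nxt <- ring[if (j == 12L) 1L else j + 1L, ]
    d <- .sp3_directions(ring[j, ], prev, nxt)
    if (ring_elem[j] == "N") {
      n_letter <- n_letter + 1L
      dir <- if (ch[n_letter] == "U") d$up else d$down
      elements <- c(elements, "H")
      coords <- rbind(coords, ring[j, ] + .NH_DIST * dir)
      roles <- c(roles, "NH_hydrogen")
    } else {
      elements <- c(elements, "H", "H")
      coords <- rbind(coords, ring[j, ] + .CH_DIST * d$up,
                      ring[j, ] + .CH_DIST * d$down)
      roles <- c(roles, NA_character_, NA_character_)
    }
  }
  molecule(elements, coords, roles = roles, charge = 0L, multiplicity = 1L,
           comment = sprintf("conformer=%s", conformer))
}

# ---------------------------------------------------------------- metalation

# lowest accessible spin multiplicity for the +2 ions handled by default;
# other elements fall back to electron-count parity of the full complex
.METAL_MULT <- c(Co = 2L, Ni = 1L, Cu = 2L, Zn = 1L)

#' Place a metal at the centroid of the four nitrogen donors
#'
#' Appends one metal atom at the arithmetic centroid of the `donor_N`
#' atoms, tags it `metal`, sets the complex charge to +2 and records the
#' lowest accessible spin multiplicity as metadata (doublet for Co(II) and
#' Cu(II), singlet for Ni(II) and Zn(II); electron-parity fallback for
#' other elements).
#'
#' @param mol a [molecule()] with exactly four `donor_N` atoms and no
#'   metal.
#' @param metal element symbol, one of `Co`, `Ni`, `Cu`, `Zn` by default
#'   (any known element is accepted).
#' @return The metalated [molecule()].
#' @export
metalate <- function(mol, metal) {
  donors <- role_indices(mol, "donor_N")
  if (length(donors) != 4L)
    stop("role error: metalation needs exactly 4 donor_N atoms, found ",
         length(donors), call. = FALSE)
  if (length(role_indices(mol, "metal")) > 0L)
    stop("role error: molecule already carries a metal", call. = FALSE)
  .element_number(metal)
  centroid <- colMeans(mol$coords[donors, , drop = FALSE])
  mult <- .METAL_MULT[metal]
  if (is.na(mult)) {
    nelec <- sum(.element_number(c(mol$elements, metal))) - 2L
    mult <- if (nelec %% 2L == 0L) 1L else 2L
  }
  molecule(c(mol$elements, metal), rbind(mol$coords, centroid),
           roles = c(mol$roles, "metal"), charge = 2L,
           multiplicity = as.integer(mult),
           comment = trimws(paste(mol$comment,
                                  sprintf("metal=%s", metal))))
}

# -------------------------------------------------------------- substitution

# perpendicular pair for axis v; ref (when given) anchors e1 to molecular
# geometry so substitution is equivariant under rigid motion
.perp_basis <- function(v, ref = NULL) {
  e1 <- NULL
  if (!is.null(ref)) {
    p <- ref - sum(ref * v) * v
    if (sqrt(sum(p^2)) > 1e-6) e1 <- .unit(p)
  }
  if (is.null(e1)) {
    a <- diag(3)[, which.min(abs(v))]
    e1 <- .unit(.cross(v, a))
  }
  list(e1 = e1, e2 = .cross(v, e1))
}

# rigid substituent template: atoms of a methyl or ethyl group attached at
# npos along unit vector v, rotated by rot degrees about the N->C axis
.substituent_atoms <- function(npos, v, group, rot_deg, ref = NULL,
                               nc_dist = .NC_DIST) {
  b <- .perp_basis(v, ref)
  th <- (180 - 109.4712) * pi / 180   # C-X bonds at 109.47 deg from C-N
  dir <- function(phi_deg) {
    phi <- (rot_deg + phi_deg) * pi / 180
    cos(th) * v + sin(th) * (cos(phi) * b$e1 + sin(phi) * b$e2)
  }
  c1 <- npos + nc_dist * v
  if (group == "Me") {
    list(elements = c("C", "H", "H", "H"),
         coords = rbind(c1,
                        c1 + .CH_DIST * dir(0),
                        c1 + .CH_DIST * dir(120),
                        c1 + .CH_DIST * dir(240)),
         roles = c("substituent_root", NA, NA, NA))
  } else if (group == "Et") {
    d0 <- dir(0)
    c2 <- c1 + .CC_DIST * d0
    # staggered anti: methyl H frame referenced to the N seen from the
    # C1->C2 axis, one H trans to N
    refp <- .unit(-v - sum(-v * d0) * d0)
    e2p <- .cross(d0, refp)
    dir2 <- function(phi_deg) {
      phi <- phi_deg * pi / 180
      cos(th) * d0 + sin(th) * (cos(phi) * refp + sin(phi) * e2p)
    }
    list(elements = c("C", "C", "H", "H", "H", "H", "H"),
         coords = rbind(c1, c2,
                        c1 + .CH_DIST * dir(120),
                        c1 + .CH_DIST * dir(240),
                        c2 + .CH_DIST * dir2(0),
                        c2 + .CH_DIST * dir2(120),
                        c2 + .CH_DIST * dir2(240)),
         roles = c("substituent_root", rep(NA_character_, 6L)))
  } else stop("unknown substituent group '", group, "'", call. = FALSE)
}

#' Replace an N-H hydrogen by a methyl or ethyl group
#'
#' The N-H hydrogen at `site` is removed and the substituent's root carbon
#' is placed 1.47 A from the nitrogen along the former N-H unit vector
#' (the reference vector).  After placement all interatomic distances are
#' checked; if any falls below `clash` (0.8 A), the rigid substituent is
#' rotated about the N-to-root-carbon axis in `rot_step` (10 degree)
#' increments, 0 to 350, and the first clash-free angle is kept.  If no
#' angle passes, an error of class `esphole_overlap_error` is signalled
#' (the structure is unphysical).
#'
#' @param mol a [molecule()].
#' @param site atom index of a donor nitrogen that still carries an
#'   `NH_hydrogen`.
#' @param group `"Me"` or `"Et"`.
#' @param clash minimum allowed interatomic distance (A).
#' @param rot_step rotation increment (degrees).
#' @param nc_dist N to root-carbon bond length (A).
#' @return The substituted [molecule()], with the accepted rotation angle
#'   (degrees) in attribute `"rotation_deg"`.
#' @export
substitute_site <- function(mol, site, group, clash = 0.8, rot_step = 10,
                            nc_dist = 1.47) {
  if (is.na(mol$roles[site]) || mol$roles[site] != "donor_N")
    stop("role error: site ", site, " is not a donor_N atom", call. = FALSE)
  hcand <- role_indices(mol, "NH_hydrogen")
  if (!length(hcand))
    stop("role error: no NH_hydrogen atoms available", call. = FALSE)
  npos <- mol$coords[site, ]
  dists <- sqrt(colSums((t(mol$coords[hcand, , drop = FALSE]) - npos)^2))
  if (min(dists) > 1.3)
    stop("role error: site ", site, " carries no N-H hydrogen", call. = FALSE)
  hidx <- hcand[which.min(dists)]
  v <- .unit(mol$coords[hidx, ] - npos)

  keep <- setdiff(seq_len(natoms(mol)), hidx)
  base_elem <- mol$elements[keep]
  base_coords <- mol$coords[keep, , drop = FALSE]
  base_roles <- mol$roles[keep]

  # anchor the rotation-zero reference to the nearest ring carbon so the
  # construction is equivariant under rigid motion of the input
  cidx <- which(mol$elements == "C")
  ref <- NULL
  if (length(cidx)) {
    dc <- sqrt(colSums((t(mol$coords[cidx, , drop = FALSE]) - npos)^2))
    # rotation-zero reference points away from the nearest ring carbon, so
    # the unrotated tail leans off the ring; near-ties (both ring
    # neighbours sit at the same bond length) break to the lowest atom
    # index, which is stable under rigid motion of the input
    near <- which(dc <= min(dc) + 1e-6)
    ref <- npos - mol$coords[cidx[near[1L]], ]
  }

  angles <- seq(0, 350, by = rot_step)
  for (rot in angles) {
    sub <- .substituent_atoms(npos, v, group, rot, ref, nc_dist)
    coords <- rbind(base_coords, sub$coords)
    if (min(stats::dist(coords)) >= clash) {
      out <- molecule(c(base_elem, sub$elements), coords,
                      roles = c(base_roles, sub$roles),
                      charge = mol$charge, multiplicity = mol$multiplicity,
                      comment = mol$comment)
      attr(out, "rotation_deg") <- rot
      return(out)
    }
  }
  stop(structure(class = c("esphole_overlap_error", "error", "condition"),
                 list(message = sprintf(
                   "substitution at site %d (%s): no rotation angle clears the %.2f A overlap threshold",
                   site, group, clash),
                   call = NULL)))
}

# --------------------------------------------------------------- enumeration

.pattern_string <- function(groups) paste(groups, collapse = ",")

#' Enumerate the combinatorial complex dataset
#'
#' Builds one structure per (metal, conformer, substitution pattern)
#' triple: planar template, metalation at the N4 centroid, then
#' substitution of each non-H site via [substitute_site()].  Substitution
#' patterns run over `alphabet^4` indexed by ring nitrogen; structures
#' whose clash scan fails are kept in the manifest with status
#' `rejected_overlap` rather than raising.
#'
#' With the defaults (4 metals, 4 conformers, alphabet H/Me/Et) this
#' yields 16 unsubstituted and 1280 substituted structures, 1296 in total.
#'
#' @param metals character vector of metal symbols.
#' @param conformers character vector of U/D patterns.
#' @param alphabet substituent alphabet; must contain `"H"`.
#' @param outdir optional directory; when given, one XYZ file is written
#'   per generated row and its path recorded.
#' @param clash,rot_step,nc_dist steric-resolution constants, see
#'   [substitute_site()].
#' @return A `data.frame` manifest (columns `metal`, `conformer`,
#'   `pattern`, `status`, `path`) with the built molecules in attribute
#'   `"molecules"` (a list, `NULL` entries for rejected rows).
#' @examples
#' m <- enumerate_dataset(metals = "Zn", conformers = "UUUU",
#'                        alphabet = "H")
#' nrow(m)  # 1
#' @export
enumerate_dataset <- function(metals = c("Co", "Ni", "Cu", "Zn"),
                              conformers = enumerate_conformers(),
                              alphabet = c("H", "Me", "Et"),
                              outdir = NULL, clash = 0.8, rot_step = 10,
                              nc_dist = 1.47) {
  if (!length(metals)) stop("config validation error: empty metal list",
                            call. = FALSE)
  if (!length(conformers)) stop("config validation error: empty conformer list",
                                call. = FALSE)
  if (!"H" %in% alphabet)
    stop("config validation error: alphabet must contain 'H'", call. = FALSE)
  # site 4 varies fastest: patterns in alphabet order, ring site 1 slowest
  g <- expand.grid(s4 = alphabet, s3 = alphabet, s2 = alphabet,
                   s1 = alphabet, stringsAsFactors = FALSE)
  g <- unname(as.matrix(g[, c("s1", "s2", "s3", "s4")]))

  templates <- lapply(stats::setNames(conformers, conformers), build_template)
  rows <- list(); mols <- list(); k <- 0L
  for (metal in metals) {
    for (conf in conformers) {
      base <- metalate(templates[[conf]], metal)
      donors <- role_indices(base, "donor_N")
      for (p in seq_len(nrow(g))) {
        groups <- g[p, ]
        k <- k + 1L
        mol <- base
        status <- "generated"
        res <- tryCatch({
          for (s in seq_len(4L)) {
            if (groups[s] != "H")
              mol <- substitute_site(mol, donors[s], groups[s],
                                     clash = clash, rot_step = rot_step,
                                     nc_dist = nc_dist)
          }
          mol
        }, esphole_overlap_error = function(e) e)
        path <- NA_character_
        if (inherits(res, "esphole_overlap_error")) {
          status <- "rejected_overlap"
          mols[[k]] <- list(NULL)
        } else {
          res$comment <- sprintf("metal=%s conformer=%s pattern=%s",
                                 metal, conf, .pattern_string(groups))
          mols[[k]] <- list(res)
          if (!is.null(outdir)) {
            path <- file.path(outdir, sprintf("%s_%s_%s.xyz", metal, conf,
                                              paste(groups, collapse = "")))
            write_xyz(res, path)
          }
        }
        rows[[k]] <- data.frame(metal = metal, conformer = conf,
                                pattern = .pattern_string(groups),
                                status = status, path = path,
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "molecules") <- lapply(mols, `[[`, 1L)
  manifest
}

# ---------------------------------------------------------------------- rmsd

#' Minimum RMSD after optimal rigid superposition
#'
#' Kabsch superposition in the canonical generated atom order (no
#' atom-matching search): both molecules are centered, the optimal proper
#' rotation is found from the SVD of the covariance matrix, and the
#' root-mean-square coordinate deviation of the superposed pair is
#' returned.
#'
#' @param a,b [molecule()]s with identical element multisets.
#' @return RMSD in angstrom.
#' @export
rmsd <- function(a, b) {
  if (natoms(a) != natoms(b) ||
      !identical(sort(a$elements), sort(b$elements)))
    stop("comparability error: element multisets differ", call. = FALSE)
  A <- sweep(a$coords, 2, colMeans(a$coords))
  B <- sweep(b$coords, 2, colMeans(b$coords))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Mark near-duplicate structures in a manifest
#'
#' Compares generated rows with identical atom counts (and element
#' multisets) pairwise by [rmsd()]; when a pair falls below `threshold`
#' the later row is marked `duplicate`.  Idempotent.
#'
#' Two scoping rules make the index-paired RMSD meaningful.  First,
#' comparisons require identical canonical element sequences, not just
#' equal multisets: with fixed atom ordering, superposing rows whose
#' sequences differ would pair carbons onto hydrogens.  Second,
#' comparisons stay within a (metal, conformer) identity group: the U/D
#' label, like the metal, is part of a dataset entry's identity, and two
#' conformers of one planar template differ only by mirrored N-H/N-R
#' hydrogens -- a sub-threshold RMSD that does not make them the same
#' entry.  The filter thus catches true redundancies (the same labeled
#' structure generated twice) without collapsing deliberate conformer or
#' substitution variation.
#'
#' @param manifest output of [enumerate_dataset()].
#' @param threshold RMSD threshold (A), default 1.5.
#' @return The manifest with updated `status` column.
#' @export
dedup <- function(manifest, threshold = 1.5) {
  mols <- attr(manifest, "molecules")
  gen <- which(manifest$status == "generated")
  key <- vapply(gen, function(i)
    paste(manifest$metal[i], manifest$conformer[i],
          paste(mols[[i]]$elements, collapse = "")), character(1))
  status <- manifest$status
  for (grp in split(gen, key)) {
    if (length(grp) < 2L) next
    coords <- lapply(grp, function(i) mols[[i]])
    for (jj in seq_along(grp)[-1L]) {
      if (status[grp[jj]] == "duplicate") next
      for (ii in seq_len(jj - 1L)) {
        if (status[grp[ii]] == "duplicate") next
        if (rmsd(coords[[ii]], coords[[jj]]) < threshold) {
          status[grp[jj]] <- "duplicate"
          break
        }
      }
    }
  }
  manifest$status <- status
  manifest
}
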