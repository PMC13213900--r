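# Aligned molecular reference frame from the four nitrogen donors, and
# geometric descriptors (tau4, M-N distances).

#' Least-squares N4-plane frame
#'
#' Fits the best least-squares plane through the four donor nitrogens.
#' The centroid becomes the frame origin; the plane normal (the direction
#' of smallest variance of the centered points) becomes the pseudo-z
#' pi-axis.  The in-plane x-axis is the projection of the shortest N-N
#' difference vector (ties broken by lowest donor-index pair); y completes
#' a right-handed triad, so the rotation uses the two shortest
#' noncollinear N-N vectors to fix the in-plane orientation.  The normal
#' sign makes the donors wind counterclockwise in input (ring) order when
#' viewed from +z, a convention that is intrinsic to the molecule and
#' hence stable under rigid motion; [frame_from_molecule()] can override
#' it from substituent role tags.
#'
#' Points are mapped into the frame as `(r - centroid) %*% rotation`; the
#' rotation matrix columns are the x, y and normal axes.
#'
#' @param nitrogens 4 x 3 matrix of donor positions (A).
#' @return An object of class `"esp_frame"` with elements `centroid`,
#'   `rotation` (orthonormal, det +1) and `normal` (its third column).
#' @export
fit_plane <- function(nitrogens) {
  nitrogens <- as.matrix(nitrogens)
  stopifnot(nrow(nitrogens) == 4L, ncol(nitrogens) == 3L)
  centroid <- colMeans(nitrogens)
  X <- sweep(nitrogens, 2, centroid)
  s <- svd(X)
  if (s$d[2L] < 1e-8 * max(s$d[1L], 1e-300))
    stop("fit error: donor nitrogens are collinear or degenerate",
         call. = FALSE)
  normal <- s$v[, 3L]
  # deterministic, rotation-equivariant sign: donors in input (ring) order
  # wind counterclockwise when viewed from the +normal side
  wind <- sum(vapply(1:4, function(i) {
    j <- if (i == 4L) 1L else i + 1L
    sum(.cross(X[i, ], X[j, ]) * normal)
  }, numeric(1)))
  if (wind < 0) normal <- -normal

  pairs <- utils::combn(4L, 2L)
  dvec <- apply(pairs, 2L, function(p) nitrogens[p[2L], ] - nitrogens[p[1L], ])
  lens <- sqrt(colSums(dvec^2))
  # near-equal lengths (1e-6 A) tie-break by lowest donor-index pair, so
  # the in-plane axes are stable under rigid motion
  ord <- order(round(lens / 1e-6), pairs[1L, ], pairs[2L, ])
  xaxis <- NULL
  for (k in ord) {
    v <- dvec[, k]
    v <- v - sum(v * normal) * normal
    if (sqrt(sum(v^2)) > 1e-8) { xaxis <- .unit(v); break }
  }
  if (is.null(xaxis))
    stop("fit error: no in-plane N-N direction found", call. = FALSE)
  yaxis <- .cross(normal, xaxis)
  rotation <- cbind(xaxis, yaxis, normal, deparse.level = 0)
  structure(list(centroid = centroid, rotation = rotation, normal = normal),
            class = "esp_frame")
}

#' @export
print.esp_frame <- function(x, ...) {
  cat(sprintf("<esp_frame: centroid (%.3f, %.3f, %.3f), normal (%.3f, %.3f, %.3f)>\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# flip the pi-axis (and y, preserving handedness)
.flip_frame <- function(frame) {
  frame$normal <- -frame$normal
  frame$rotation[, 2L] <- -frame$rotation[, 2L]
  frame$rotation[, 3L] <- -frame$rotation[, 3L]
  frame
}

#' Map points between the lab and aligned frames
#'
#' [align()] applies `(r - centroid) %*% rotation`; [unalign()] is its
#' exact inverse.
#'
#' @param points M x 3 matrix (or length-3 vector) of positions (A).
#' @param frame an [fit_plane()] frame.
#' @return M x 3 matrix of mapped positions.
#' @export
align <- function(points, frame) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  sweep(points, 2, frame$centroid) %*% frame$rotation
}

#' @rdname align
#' @export
unalign <- function(points, frame) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  sweep(points %*% t(frame$rotation), 2, frame$centroid, "+")
}

#' Frame of a complex, oriented by its substituent vectors
#'
#' Builds the N4-plane frame from a molecule's `donor_N` atoms and, when
#' N-H / N-R role tags are available, orients the normal so that the
#' majority of substituent vectors point along +z (the `U` side).  With a
#' tie, or without tags, the deterministic [fit_plane()] sign is kept;
#' both hemispheres are analyzed downstream either way, so the choice
#' affects labels only.
#'
#' @param mol a [molecule()] with four `donor_N` atoms.
#' @return An `"esp_frame"`.
#' @export
frame_from_molecule <- function(mol) {
  donors <- role_indices(mol, "donor_N")
  if (length(donors) != 4L)
    stop("role error: need exactly 4 donor_N atoms, found ",
         length(donors), call. = FALSE)
  frame <- fit_plane(mol$coords[donors, , drop = FALSE])
  subs <- c(role_indices(mol, "NH_hydrogen"),
            role_indices(mol, "substituent_root"))
  if (length(subs)) {
    score <- 0
    for (s in subs) {
      dn <- sqrt(colSums((t(mol$coords[donors, , drop = FALSE]) -
                            mol$coords[s, ])^2))
      v <- mol$coords[s, ] - mol$coords[donors[which.min(dn)], ]
      score <- score + sign(sum(v * frame$normal))
    }
    if (score < 0) frame <- .flip_frame(frame)
  }
  frame
}

#' Four-coordinate geometry index tau4
#'
#' `tau4 = (360 - (alpha + beta)) / 141` where `alpha >= beta` are the two
#' largest of the six donor-metal-donor angles (degrees).  0 for an ideal
#' square-planar arrangement (two trans angles of 180), 1 for an ideal
#' tetrahedron (all angles 109.47).
#'
#' @param metal length-3 metal position (A).
#' @param donors 4 x 3 matrix of donor positions (A).
#' @return A list with `tau4`, `alpha`, `beta` (degrees).
#' @examples
#' sq <- rbind(c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0), c(0, -2, 0))
#' tau4(c(0, 0, 0), sq)$tau4  # 0
#' @export
tau4 <- function(metal, donors) {
  donors <- as.matrix(donors)
  stopifnot(nrow(donors) == 4L, ncol(donors) == 3L)
  v <- sweep(donors, 2, as.numeric(metal))
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12))
    stop("geometry error: zero-length metal-donor vector", call. = FALSE)
  v <- v / len
  pairs <- utils::combn(4L, 2L)
  # atan2 form stays well conditioned at the 180-degree trans angles
  ang <- apply(pairs, 2L, function(p) {
    cr <- .cross(v[p[1L], ], v[p[2L], ])
    atan2(sqrt(sum(cr^2)), sum(v[p[1L], ] * v[p[2L], ])) * 180 / pi
  })
  ang <- sort(ang, decreasing = TRUE)
  list(tau4 = (360 - (ang[1L] + ang[2L])) / 141,
       alpha = ang[1L], beta = ang[2L])
}

#' Geometric descriptors of a four-coordinate complex
#'
#' @param mol a [molecule()] with `metal` and four `donor_N` roles.
#' @return A list with `mn_distances` (four M-N bond lengths, A),
#'   `mn_mean`, `tau4`, `alpha`, `beta`.
#' @export
geometry_descriptors <- function(mol) {
  metal <- role_indices(mol, "metal")
  donors <- role_indices(mol, "donor_N")
  if (length(metal) != 1L || length(donors) != 4L)
    stop("role error: need one metal and four donor_N atoms", call. = FALSE)
  m <- mol$coords[metal, ]
  d <- mol$coords[donors, , drop = FALSE]
  dist <- sqrt(rowSums(sweep(d, 2, m)^2))
  t4 <- tau4(m, d)
  list(mn_distances = dist, mn_mean = mean(dist),
       tau4 = t4$tau4, alpha = t4$alpha, beta = t4$beta)
}
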