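SHAPE_NAMES <- c(
  "Volume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity", "Compactness1",
  "Compactness2", "SphericalDisproportion", "Maximum3DDiameter",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxis", "MinorAxis",
  "LeastAxis", "Elongation", "Flatness"
)

# Triangulated 0.5-iso-surface of a binary mask: one quad (two triangles) per
# voxel face separating foreground from background, vertices at voxel corners
# in physical (mm) coordinates. Watertight by construction.
surface_mesh <- function(mask_values, spacing) {
  d <- dim(mask_values)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask_values
  quads <- vector("list", 3L)
  for (axis in 1:3) {
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(m, perm)
    da <- a[-1, , , drop = FALSE] != a[-dim(a)[1], , , drop = FALSE]
    idx <- which(da, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    # boundary face between (i, j, k) and (i + 1, j, k) along permuted axis 1:
    # face plane at i + 0.5, spanning [j - .5, j + .5] x [k - .5, k + .5]
    un <- idx[, 1] + 0.5
    v0 <- idx[, 2] - 0.5; v1 <- idx[, 2] + 0.5
    w0 <- idx[, 3] - 0.5; w1 <- idx[, 3] + 0.5
    corner <- function(vv, ww) {
      p <- cbind(un, vv, ww)
      p[, order(perm), drop = FALSE]   # undo axis permutation
    }
    quads[[axis]] <- list(corner(v0, w0), corner(v1, w0),
                          corner(v1, w1), corner(v0, w1))
  }
  quads <- quads[!vapply(quads, is.null, logical(1))]
  c1 <- do.call(rbind, lapply(quads, `[[`, 1))
  c2 <- do.call(rbind, lapply(quads, `[[`, 2))
  c3 <- do.call(rbind, lapply(quads, `[[`, 3))
  c4 <- do.call(rbind, lapply(quads, `[[`, 4))
  nq <- nrow(c1)
  verts_all <- rbind(c1, c2, c3, c4)
  # merge duplicate corners; coordinates are half-integers so 2x is exact
  key <- paste(verts_all[, 1] * 2, verts_all[, 2] * 2, verts_all[, 3] * 2)
  uid <- match(key, unique(key))
  verts <- verts_all[!duplicated(key), , drop = FALSE]
  i1 <- uid[seq_len(nq)]
  i2 <- uid[nq + seq_len(nq)]
  i3 <- uid[2 * nq + seq_len(nq)]
  i4 <- uid[3 * nq + seq_len(nq)]
  faces <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
  # shift back for padding and scale to physical coordinates
  verts <- sweep(verts - 1, 2, spacing, `*`)
  list(vertices = verts, faces = faces)
}

# Taubin lambda|mu smoothing: alternating shrink/inflate Laplacian steps that
# reduce staircase artifacts without the net shrinkage of plain Laplacian
# smoothing. Connectivity (faces) is unchanged.
taubin_smooth <- function(mesh, iterations = 20, lambda = 0.5, mu = -0.53) {
  V <- mesh$vertices
  f <- mesh$faces
  n <- nrow(V)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    for (w in c(lambda, mu)) {
      mean_nb <- as.matrix(A %*% V) / deg
      V <- V + w * (mean_nb - V)
    }
  }
  mesh$vertices <- V
  mesh
}

mesh_area <- function(mesh) {
  V <- mesh$vertices; f <- mesh$faces
  a <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  b <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

# max pairwise Euclidean distance, chunked to bound memory
max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[s:e, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

boundary_voxels <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  interior <- p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(m & !interior, arr.ind = TRUE)
}

#' Shape features of a lesion mask
#'
#' The 15 morphological descriptors. `Volume` is voxel count times physical
#' voxel volume. `SurfaceArea` is the area of the triangulated 0.5
#' iso-surface of the mask; for masks of at least 27 voxels the mesh is
#' Taubin-smoothed (20 iterations) before measuring so that staircase
#' artifacts do not inflate the area (a digital ball then reports area within
#' a few percent of the analytic sphere); tiny masks keep the raw voxel-face
#' mesh, so a single voxel reports the unit voxel cube. Sphericity and its
#' algebraic relatives compare the mask with a ball of equal volume. Diameters
#' are largest pairwise distances between boundary-voxel centers in 3-D and in
#' the plane orthogonal to the column (dim 2) or row (dim 1) axis. Axis
#' lengths are `4 * sqrt(lambda)` from the eigenvalues of the
#' physical-coordinate covariance of mask voxels; `Elongation =
#' sqrt(lambda2/lambda1)` and `Flatness = sqrt(lambda3/lambda1)` are 1 for a
#' ball and 0 for a single point or line/plane respectively.
#'
#' @param mask a [lesion_mask()] (spacing is taken from it) or a logical/0-1
#'   3-D array combined with `spacing`.
#' @param spacing per-axis voxel spacing in mm; ignored when `mask` is a
#'   `lesion_mask`.
#' @param smooth_iterations Taubin iterations for the surface mesh.
#' @return Named numeric vector of 15 features.
#' @export
shape_features <- function(mask, spacing = NULL, smooth_iterations = 20) {
  if (inherits(mask, "lesion_mask")) {
    m <- mask$values
    spacing <- mask$spacing
  } else {
    m <- mask > 0.5
    if (is.null(spacing)) stop("spacing required for a raw mask array")
  }
  spacing <- as.numeric(spacing)
  n <- sum(m)
  vv <- voxel_volume(spacing)
  V <- n * vv

  mesh <- surface_mesh(m, spacing)
  if (n >= 27L && smooth_iterations > 0)
    mesh <- taubin_smooth(mesh, iterations = smooth_iterations)
  A <- mesh_area(mesh)

  R <- (3 * V / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A

  bnd <- boundary_voxels(m)
  pts <- sweep(bnd, 2, spacing, `*`)
  d3 <- max_pairwise_dist(pts)
  d_col <- max_pairwise_dist(pts[, c(1, 3), drop = FALSE])  # ignore column axis
  d_row <- max_pairwise_dist(pts[, c(2, 3), drop = FALSE])  # ignore row axis

  coords <- sweep(which(m, arr.ind = TRUE), 2, spacing, `*`)
  if (n > 1L) {
    cc <- sweep(coords, 2, colMeans(coords))
    covm <- crossprod(cc) / n     # population covariance
    lam <- sort(pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0),
                decreasing = TRUE)
  } else {
    lam <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(lam)
  elong <- if (lam[1] > 0) sqrt(lam[2] / lam[1]) else 0
  flat <- if (lam[1] > 0) sqrt(lam[3] / lam[1]) else 0

  out <- c(V, A, A / V, sphericity,
           V / (sqrt(pi) * A^1.5),
           36 * pi * V^2 / A^3,
           A / (4 * pi * R^2),
           d3, d_col, d_row,
           axes[1], axes[2], axes[3], elong, flat)
  names(out) <- SHAPE_NAMES
  out
}
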