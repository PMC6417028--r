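#' The 13 unique directions of the 3-D 26-neighbourhood (modulo sign)
#'
#' Row `k` is the integer offset of direction `k`; texture features average
#' over these directions, a set closed under 90-degree grid rotations.
#'
#' @return A 13 x 3 integer matrix.
#' @export
texture_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

check_offset <- function(offset) {
  offset <- as.integer(offset)
  if (length(offset) != 3L || all(offset == 0L))
    stop("offset must be a non-zero integer 3-vector")
  if (any(abs(offset) > 1L))
    stop("offset components must be in {-1, 0, 1}")
  offset
}

new_texture_matrix <- function(kind, counts, Ng, offset = NULL) {
  total <- sum(counts)
  structure(list(kind = kind, counts = counts, Ng = Ng, offset = offset,
                 normalized = if (total > 0) counts / total else counts,
                 n_observations = total, degenerate = total == 0),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<%s matrix: %dx%d, %g observations%s>\n", x$kind,
              nrow(x$counts), ncol(x$counts), x$n_observations,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# aligned in-mask voxel pairs separated by `offset * distance`
shifted_pairs <- function(lev, offset, distance = 1L) {
  d <- dim(lev)
  o <- offset * distance
  if (any(abs(o) >= d)) return(list(a = lev[0], b = lev[0]))
  src <- lapply(1:3, function(a) {
    if (o[a] >= 0) seq_len(d[a] - o[a]) else seq(1L - o[a], d[a])
  })
  dst <- lapply(1:3, function(a) src[[a]] + o[a])
  a <- lev[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- lev[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' Grey-level co-occurrence matrix
#'
#' Counts of in-mask voxel pairs `(i, j)` separated by `offset * distance`
#' where both voxels lie in the mask. The matrix is symmetrized (`A + t(A)`),
#' so each unordered pair is counted in both orders; the `normalized` copy
#' sums to 1.
#'
#' @param d a [discretize()]d ROI.
#' @param offset integer 3-vector with entries in `{-1, 0, 1}`, not all zero.
#' @param distance positive integer step multiplier.
#' @return A `texture_matrix` of kind `"GLCM"`.
#' @export
glcm_matrix <- function(d, offset, distance = 1L) {
  stopifnot(inherits(d, "discretized_roi"))
  offset <- check_offset(offset)
  Ng <- d$n_levels
  pr <- shifted_pairs(d$levels, offset, as.integer(distance))
  counts <- matrix(0, Ng, Ng)
  if (length(pr$a)) {
    tab <- tabulate((pr$a - 1L) * Ng + pr$b, nbins = Ng * Ng)
    counts <- matrix(tab, Ng, Ng, byrow = TRUE)
    counts <- counts + t(counts)
  }
  new_texture_matrix("GLCM", counts, Ng, offset)
}

#' Grey-level run-length matrix
#'
#' Counts of maximal runs of equal grey level along `offset`, restricted to
#' in-mask voxels (a gap in the mask breaks a run). Entry `(i, l)` counts
#' runs of level `i` and length `l`.
#'
#' @inheritParams glcm_matrix
#' @return A `texture_matrix` of kind `"GLRLM"` (`Ng` rows, `max run` cols).
#' @export
glrlm_matrix <- function(d, offset) {
  stopifnot(inherits(d, "discretized_roi"))
  offset <- check_offset(offset)
  Ng <- d$n_levels
  idx <- which(!is.na(d$levels), arr.ind = TRUE)
  lv <- d$levels[!is.na(d$levels)]
  step2 <- sum(offset^2)
  t_par <- as.vector(idx %*% offset)
  line <- idx * step2 - outer(t_par, offset)   # integer line identifier
  dm <- dim(d$levels)
  span <- (max(dm) + 2L) * step2 * 2L
  key <- (line[, 1] + span) + (line[, 2] + span) * (2 * span + 1) +
    (line[, 3] + span) * (2 * span + 1)^2
  o <- order(key, t_par)
  key <- key[o]; tp <- t_par[o]; lvo <- lv[o]
  n <- length(lvo)
  if (n == 0L) return(new_texture_matrix("GLRLM", matrix(0, Ng, 1), Ng, offset))
  new_run <- c(TRUE, key[-1] != key[-n] | tp[-1] != tp[-n] + step2 |
                 lvo[-1] != lvo[-n])
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_lev <- lvo[new_run]
  Lmax <- max(run_len)
  tab <- tabulate((run_lev - 1L) * Lmax + run_len, nbins = Ng * Lmax)
  counts <- matrix(tab, Ng, Lmax, byrow = TRUE)
  new_texture_matrix("GLRLM", counts, Ng, offset)
}

#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of equal grey level within the mask;
#' there is a single matrix (no directions). Entry `(i, s)` counts zones of
#' level `i` and size `s` voxels.
#'
#' @inheritParams glcm_matrix
#' @return A `texture_matrix` of kind `"GLSZM"`.
#' @export
glszm_matrix <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  Ng <- d$n_levels
  lev <- d$levels
  vox_id <- array(NA_integer_, dim(lev))
  in_mask <- which(!is.na(lev))
  vox_id[in_mask] <- seq_along(in_mask)
  edges <- list()
  dirs <- texture_directions()
  for (k in seq_len(nrow(dirs))) {
    pr <- shifted_pairs(lev, dirs[k, ], 1L)
    ia <- shifted_pairs(vox_id, dirs[k, ], 1L)
    same <- pr$a == pr$b
    if (any(same)) edges[[length(edges) + 1L]] <- cbind(ia$a[same], ia$b[same])
  }
  nv <- length(in_mask)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(nv, directed = FALSE)
  }
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_lev <- lev[in_mask][match(seq_len(comp$no), comp$membership)]
  Smax <- max(zone_size)
  tab <- tabulate((zone_lev - 1L) * Smax + zone_size, nbins = Ng * Smax)
  counts <- matrix(tab, Ng, Smax, byrow = TRUE)
  new_texture_matrix("GLSZM", counts, Ng)
}
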