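# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain voxel loops and pair/run/zone enumeration.

oracle_glcm <- function(d, offset, distance = 1L) {
  lev <- d$levels
  Ng <- d$n_levels
  dm <- dim(lev)
  counts <- matrix(0, Ng, Ng)
  o <- offset * distance
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    p <- c(i, j, k) + o
    if (any(p < 1) || any(p > dm)) next
    b <- lev[p[1], p[2], p[3]]
    if (is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1  # symmetrization
  }
  counts
}

oracle_glrlm <- function(d, offset) {
  lev <- d$levels
  dm <- dim(lev)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= dm)
  val <- function(p) lev[p[1], p[2], p[3]]
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k)
    a <- val(p)
    if (is.na(a)) next
    prev <- p - offset
    # run starts where the predecessor is outside the grid/mask or differs
    if (inb(prev) && !is.na(val(prev)) && val(prev) == a) next
    len <- 1L
    nxt <- p + offset
    while (inb(nxt) && !is.na(val(nxt)) && val(nxt) == a) {
      len <- len + 1L
      nxt <- nxt + offset
    }
    runs[[length(runs) + 1L]] <- c(a, len)
  }
  runs <- do.call(rbind, runs)
  Lmax <- max(runs[, 2])
  counts <- matrix(0, d$n_levels, Lmax)
  for (r in seq_len(nrow(runs)))
    counts[runs[r, 1], runs[r, 2]] <- counts[runs[r, 1], runs[r, 2]] + 1
  counts
}

oracle_glszm <- function(d) {
  lev <- d$levels
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  zones <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (seen[i, j, k] || is.na(lev[i, j, k])) next
    a <- lev[i, j, k]
    # flood fill
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (q in seq_len(nrow(nbrs))) {
        np <- p + nbrs[q, ]
        if (any(np < 1) || any(np > dm)) next
        if (seen[np[1], np[2], np[3]]) next
        b <- lev[np[1], np[2], np[3]]
        if (is.na(b) || b != a) next
        seen[np[1], np[2], np[3]] <- TRUE
        stack[[length(stack) + 1L]] <- np
      }
    }
    zones[[length(zones) + 1L]] <- c(a, size)
  }
  zones <- do.call(rbind, zones)
  Smax <- max(zones[, 2])
  counts <- matrix(0, d$n_levels, Smax)
  for (r in seq_len(nrow(zones)))
    counts[zones[r, 1], zones[r, 2]] <- counts[zones[r, 1], zones[r, 2]] + 1
  counts
}

# AUC by explicit concordant-pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# 90-degree rotation of a 3-D array about an axis (right-hand rule on the
# remaining two axes): transpose those axes, then reverse one of them
rotate90 <- function(arr, axis) {
  d <- dim(arr)
  if (axis == 3L) {
    out <- aperm(arr, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE]
  } else if (axis == 1L) {
    out <- aperm(arr, c(1, 3, 2))[, rev(seq_len(d[3])), , drop = FALSE]
  } else {
    out <- aperm(arr, c(3, 2, 1))[, , rev(seq_len(d[1])), drop = FALSE]
  }
  out
}
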