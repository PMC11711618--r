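# Independent brute-force oracles. These deliberately share no code
# with the package: plain loops and first-principles formulas only.

# max over mask_t of the min Euclidean distance to the t=0 outline
# point set, with distances inside the t=0 body clipped to zero.
oracle_tc_distance <- function(mask_t, mask_0, pixel_size = 1) {
  nr <- nrow(mask_0); nc <- ncol(mask_0)
  outline <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask_0[r, c]) next
    on_border <- r == 1 || r == nr || c == 1 || c == nc
    if (on_border || !mask_0[r - 1, c] || !mask_0[r + 1, c] ||
        !mask_0[r, c - 1] || !mask_0[r, c + 1])
      outline <- rbind(outline, c(r, c))
  }
  best <- 0
  pts <- which(mask_t, arr.ind = TRUE)
  for (i in seq_len(nrow(pts))) {
    if (mask_0[pts[i, 1], pts[i, 2]]) next # interior clipping
    d <- sqrt(min((outline[, 1] - pts[i, 1])^2 + (outline[, 2] - pts[i, 2])^2))
    best <- max(best, d)
  }
  best * pixel_size
}

# O(N * M) shell membership: distance from each point to the nearest
# boundary voxel centre of the mask (points in mask voxels excluded).
oracle_shell_members <- function(points, mask, voxel_size, d_min, d_max) {
  dm <- dim(mask)
  surf <- NULL
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    bare <- i == 1 || i == dm[1] || j == 1 || j == dm[2] || k == 1 || k == dm[3]
    if (bare || !mask[i - 1, j, k] || !mask[i + 1, j, k] ||
        !mask[i, j - 1, k] || !mask[i, j + 1, k] ||
        !mask[i, j, k - 1] || !mask[i, j, k + 1])
      surf <- rbind(surf, (c(i, j, k) - 1) * voxel_size)
  }
  keep <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    vox <- round(points[p, ] / voxel_size) + 1
    inside <- all(vox >= 1) && all(vox <= dm) && mask[vox[1], vox[2], vox[3]]
    if (inside) next
    d <- sqrt(min(colSums((t(surf) - points[p, ])^2)))
    keep[p] <- d >= d_min && d <= d_max
  }
  which(keep)
}

# O(V^2) Dijkstra over 26-connected voxels with physical edge weights.
oracle_geodesic_length <- function(voxels, voxel_size, from, to) {
  n <- nrow(voxels)
  dist <- rep(Inf, n)
  done <- logical(n)
  dist[from] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    if (u == to) break
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (done[v]) next
      step <- abs(voxels[v, ] - voxels[u, ])
      if (max(step) == 1) {
        w <- sqrt(sum((step * voxel_size)^2))
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
  }
  dist[to]
}

# Convex hull area by gift wrapping plus an explicit per-pixel
# point-in-polygon loop (pixel count of the filled hull).
oracle_hull_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(nrow(pts))
  # gift wrapping (Jarvis march)
  start <- which.min(pts[, 1] + pts[, 2] / 1e6)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(nrow(pts)), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > nrow(pts)) stop("gift wrapping failed")
  }
  verts <- pts[hull, , drop = FALSE]
  if (nrow(verts) < 3) return(length(unique(paste(pts[, 1], pts[, 2]))))
  nv <- nrow(verts)
  nxt <- c(2:nv, 1)
  if (sum(verts[, 1] * verts[nxt, 2] - verts[nxt, 1] * verts[, 2]) < 0)
    verts <- verts[nv:1, , drop = FALSE] # orient counterclockwise
  area <- 0L
  for (r in min(verts[, 1]):max(verts[, 1])) {
    for (c in min(verts[, 2]):max(verts[, 2])) {
      inside <- TRUE
      for (i in seq_len(nv)) {
        a <- verts[i, ]; b <- verts[if (i == nv) 1 else i + 1, ]
        cr <- (b[1] - a[1]) * (c - a[2]) - (b[2] - a[2]) * (r - a[1])
        if (cr < -1e-9) { inside <- FALSE; break }
      }
      if (inside) area <- area + 1L
    }
  }
  area
}

# Welch statistic, degrees of freedom and two-sided p from the
# closed-form definitions.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# filled disk / rectangle rasterizers used to build small fixtures
disk_mask <- function(n, r, ctr = (n + 1) / 2) {
  xs <- matrix(seq_len(n) - ctr, n, n)
  ys <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  xs^2 + ys^2 <= r^2
}

ellipse_mask <- function(nr, nc, a, b) {
  xs <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  ys <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
  (xs / a)^2 + (ys / b)^2 <= 1
}
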