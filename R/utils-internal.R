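# Internal numerical primitives shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# FNV-1a 32-bit hash of a deparsed object; used to stamp CSV outputs
# so that results can be traced back to the configuration that made them.
.fnv1a <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  # double-precision arithmetic with 16-bit split products, since the
  # 32-bit state exceeds R's integer range
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- ((h %/% 65536 * p) %% 65536 * 65536 + (h %% 65536) * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ---- exact Euclidean distance transform (separable lower-envelope) ----

# Squared 1D distance transform of sampled function f at spacing `step`.
# f holds squared distances (0 at sources, .EDT_BIG elsewhere).
.EDT_BIG <- 1e12

.edt1d_sq <- function(f, step = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- (seq_len(n) - 1) * step
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2L:n) {
    s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * (x[q] - x[v[k]]))
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * (x[q] - x[v[k]]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1L:n) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean distance (in physical units) from every grid element to
# the nearest TRUE element of `src`, with per-axis sampling `spacing`.
# Works for 2D matrices and 3D arrays.
.edt <- function(src, spacing = rep(1, length(dim(src)))) {
  dm <- dim(src)
  nd <- length(dm)
  stopifnot(nd %in% c(2L, 3L), length(spacing) == nd, all(spacing > 0))
  if (!any(src)) stop("distance transform: no source elements")
  f <- array(.EDT_BIG, dm)
  f[src] <- 0
  for (ax in seq_len(nd)) {
    f <- .apply_lines(f, ax, spacing[ax])
  }
  sqrt(f)
}

# Apply the 1D transform along axis `ax` of array `f`.
.apply_lines <- function(f, ax, step) {
  dm <- dim(f)
  nd <- length(dm)
  perm <- c(ax, setdiff(seq_len(nd), ax))
  g <- aperm(f, perm)
  gm <- matrix(g, nrow = dm[ax])
  for (j in seq_len(ncol(gm))) {
    col <- gm[, j]
    if (any(col < .EDT_BIG)) gm[, j] <- .edt1d_sq(col, step)
  }
  g <- array(gm, dim(g))
  aperm(g, order(perm))
}

# ---- exact nearest-neighbour search via uniform grid buckets ----

# For each row of `query`, index of the nearest row of `ref` (Euclidean),
# plus the distance. Exact: bucket rings are expanded until no closer
# point can exist. Both inputs are n x d numeric matrices (d = 2 or 3).
# With a finite `max_dist`, queries whose nearest neighbour is farther
# than that report NA/Inf (the search stops early, which keeps far-away
# queries cheap); matches within max_dist are still exact.
.nn_search <- function(query, ref, cell = NULL, max_dist = Inf) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  d <- ncol(ref)
  stopifnot(ncol(query) == d, nrow(ref) >= 1L)
  if (is.null(cell)) {
    # robust to degenerate reference sets (single point, collinear):
    # never shrink the bucket below the largest extent divided by
    # n^(1/d), nor below 1/64 of the combined query+ref bounding box
    span <- apply(ref, 2, function(v) diff(range(v)))
    span_all <- apply(rbind(ref, query), 2, function(v) diff(range(v)))
    vol <- prod(pmax(span, 1e-9))
    cell <- max((vol / nrow(ref))^(1 / d),
                max(span) / max(ceiling(nrow(ref)^(1 / d)), 1),
                max(span_all) / 64,
                1e-6)
  }
  rcell <- floor(sweep(ref, 2, rep(cell, d), "/"))
  lo <- apply(rcell, 2, min)
  rcell <- sweep(rcell, 2, lo - 1) # 1-based grid coordinates
  G <- apply(rcell, 2, max)
  mult <- cumprod(c(1, G[-d]))
  lin <- as.integer(rcell %*% mult - sum(mult) + 1)
  buckets <- vector("list", prod(G))
  filled <- split(seq_len(nrow(ref)), lin)
  buckets[as.integer(names(filled))] <- filled
  qcell <- sweep(floor(query / cell), 2, lo - 1)

  offsets_for_ring <- function(r) {
    if (r == 0L) return(matrix(0L, 1L, d))
    g <- as.matrix(expand.grid(rep(list((-r):r), d)))
    g[apply(abs(g), 1, max) == r, , drop = FALSE]
  }
  off_cache <- list()

  n <- nrow(query)
  idx <- integer(n)
  dist <- numeric(n)
  tref <- t(ref)
  max_ring <- max(G) + max(abs(range(qcell))) + 2L
  for (i in seq_len(n)) {
    best <- Inf
    best_i <- NA_integer_
    r <- 0L
    repeat {
      kr <- r + 1L
      if (kr > length(off_cache) || is.null(off_cache[[kr]]))
        off_cache[[kr]] <- offsets_for_ring(r)
      cells <- sweep(off_cache[[kr]], 2, as.numeric(qcell[i, ]), "+")
      ok <- rowSums(cells >= 1 & cells <= rep(G, each = nrow(cells))) == d
      if (any(ok)) {
        cl <- as.integer(cells[ok, , drop = FALSE] %*% mult - sum(mult) + 1)
        cand <- unlist(buckets[cl], use.names = FALSE)
        if (length(cand)) {
          dd <- sqrt(colSums((tref[, cand, drop = FALSE] - query[i, ])^2))
          j <- which.min(dd)
          if (dd[j] < best) {
            best <- dd[j]
            best_i <- cand[j]
          }
        }
      }
      # a point in ring r+1 is at least r*cell away from anywhere in the
      # query's own cell, so stop once that bound exceeds the best match
      # (or the caller's search radius)
      if ((is.finite(best) && r * cell >= best) || r > max_ring ||
          r * cell > max_dist) break
      r <- r + 1L
    }
    idx[i] <- best_i
    dist[i] <- best
  }
  list(index = idx, dist = dist)
}

# ---- 3D voxel utilities ----

# Linear-index offsets of the 26-neighbourhood for an array of dim `dm`.
.offsets26 <- function(dm) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  list(steps = g, lin = g[, 1] + g[, 2] * dm[1] + g[, 3] * dm[1] * dm[2])
}

# Label 26-connected components of a 3D logical array; returns an integer
# array (0 = background) and the component count.
.label3d <- function(mask) {
  dm <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dm)
  if (!length(fg)) return(list(labels = lab, n = 0L))
  pos <- arrayInd(fg, dm)
  id_of <- array(0L, dm)
  id_of[fg] <- seq_along(fg)
  off <- .offsets26(dm)$steps
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(off))) {
    s <- off[r, ]
    if (s[1] < 0 || (s[1] == 0 && (s[2] < 0 || (s[2] == 0 && s[3] < 0)))) next # half the offsets
    nb <- sweep(pos, 2, s, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    keep <- mask[nl]
    if (!any(keep)) next
    edges_from <- c(edges_from, which(ok)[keep])
    edges_to <- c(edges_to, id_of[nl[keep]])
  }
  g <- igraph::make_graph(rbind(edges_from, edges_to), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  list(labels = lab, n = comp$no)
}

# Voxels of a 3D mask with at least one of their 6 face-neighbours outside
# the mask (array borders count as background).
.surface_voxels <- function(mask) {
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  all_nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  core & !all_nb
}

# Physical coordinates (micrometres, 0-based voxel-centre convention) of
# voxel indices given per-axis voxel size.
.voxel_um <- function(ind, voxel_size) {
  sweep(ind - 1, 2, voxel_size, "*")
}
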