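# 3D curve thinning via sequential deletion of simple points.
#
# A border voxel is deletable when removing it preserves both the local
# foreground 26-connectivity and the local background 6-connectivity
# (the classical simple-point characterization: exactly one 26-connected
# foreground component in the 26-neighbourhood, and exactly one
# 6-connected background component in the 18-neighbourhood touching a
# face). Deleting voxels in order of increasing distance to the
# background, while protecting curve endpoints, reduces a tubular mask
# to a centred 1-voxel-wide curve.

.cube27 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  centre <- which(rowSums(abs(g)) == 0)
  n26 <- setdiff(seq_len(27), centre)
  n18 <- which(rowSums(abs(g)) > 0 & rowSums(abs(g)) <= 2)
  faces <- which(rowSums(abs(g)) == 1)
  cheb <- function(a, b) max(abs(g[a, ] - g[b, ]))
  manh <- function(a, b) sum(abs(g[a, ] - g[b, ]))
  adj26 <- lapply(seq_len(27), function(a)
    Filter(function(b) b != a && cheb(a, b) == 1, n26))
  adj6 <- lapply(seq_len(27), function(a)
    Filter(function(b) b != a && manh(a, b) == 1, n18))
  list(offsets = g, centre = centre, n26 = n26, n18 = n18, faces = faces,
       adj26 = adj26, adj6 = adj6)
})

# Count connected components of `cells` (27-cube positions) under the
# adjacency lists `adj`; optionally only components containing a cell of
# `must_touch` are counted.
.cube_components <- function(cells, adj, must_touch = NULL) {
  if (!length(cells)) return(0L)
  seen <- logical(27)
  in_set <- logical(27)
  in_set[cells] <- TRUE
  n <- 0L
  for (s in cells) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    touched <- FALSE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.null(must_touch) && v %in% must_touch) touched <- TRUE
      for (w in adj[[v]]) {
        if (in_set[w] && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    if (is.null(must_touch) || touched) n <- n + 1L
  }
  n
}

# nb27: logical foreground configuration of the 3x3x3 neighbourhood in
# .cube27$offsets order (centre value ignored).
.is_simple_point <- function(nb27) {
  fg <- intersect(.cube27$n26, which(nb27))
  if (.cube_components(fg, .cube27$adj26) != 1L) return(FALSE)
  bg18 <- intersect(.cube27$n18, which(!nb27))
  .cube_components(bg18, .cube27$adj6, must_touch = .cube27$faces) == 1L
}

# Thin a 3D logical array to a curve skeleton. Returns voxel indices
# (n x 3, 1-based) of the retained curve.
.thin3d <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  pd <- dm + 2L
  pad <- array(FALSE, pd)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  # deletion order: distance to background (borders count as background)
  dt <- array(0, pd)
  dt_core <- .edt(!pad, spacing)
  dt <- dt_core
  lin27 <- .cube27$offsets[, 1] + .cube27$offsets[, 2] * pd[1] +
    .cube27$offsets[, 3] * pd[1] * pd[2]
  lin26 <- lin27[-.cube27$centre]
  # six directional sub-iterations per pass (symmetric peeling: a ball
  # collapses to its centre instead of leaving a one-sided spur)
  dir_off <- c(-1L, 1L, -pd[1], pd[1], -pd[1] * pd[2], pd[1] * pd[2])
  repeat {
    changed <- FALSE
    for (dl in dir_off) {
      border <- which(.surface_voxels_padded(pad))
      if (!length(border)) break
      border <- border[!pad[border + dl]] # open towards this direction
      border <- border[order(dt[border])]
      for (v in border) {
        if (!pad[v]) next
        nb27 <- pad[v + lin27]
        if (sum(nb27[-.cube27$centre]) <= 1L) next # endpoint: keep
        if (.is_simple_point(nb27)) {
          pad[v] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  idx <- which(pad)
  pos <- arrayInd(idx, pd)
  pos - 1L # un-pad
}

# surface test on an already padded array (margin voxels are FALSE)
.surface_voxels_padded <- function(pad) {
  pd <- dim(pad)
  res <- array(FALSE, pd)
  i <- 2:(pd[1] - 1); j <- 2:(pd[2] - 1); k <- 2:(pd[3] - 1)
  core <- pad[i, j, k, drop = FALSE]
  all_nb <- pad[i - 1, j, k, drop = FALSE] & pad[i + 1, j, k, drop = FALSE] &
    pad[i, j - 1, k, drop = FALSE] & pad[i, j + 1, k, drop = FALSE] &
    pad[i, j, k - 1, drop = FALSE] & pad[i, j, k + 1, drop = FALSE]
  res[i, j, k] <- core & !all_nb
  res
}

# Weighted 26-neighbour graph over skeleton voxels; edge weights are
# physical step lengths so paths are anisotropy-aware.
.skeleton_graph <- function(voxels, voxel_size) {
  n <- nrow(voxels)
  if (n == 1L) {
    return(igraph::make_empty_graph(n = 1, directed = FALSE))
  }
  key <- paste(voxels[, 1], voxels[, 2], voxels[, 3], sep = ",")
  id <- seq_len(n)
  names(id) <- key
  off <- .cube27$offsets[-.cube27$centre, , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(off))) {
    s <- off[r, ]
    if (s[1] < 0 || (s[1] == 0 && (s[2] < 0 || (s[2] == 0 && s[3] < 0)))) next
    nb <- sweep(voxels, 2, s, "+")
    nbkey <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
    hit <- !is.na(id[nbkey])
    if (!any(hit)) next
    from <- c(from, id[key[hit]])
    to <- c(to, id[nbkey[hit]])
    w <- c(w, rep(sqrt(sum((s * voxel_size)^2)), sum(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}
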