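# small axis-aligned tube helper (voxel indices are 1-based)
tube_mask <- function(dm, from, to, r) {
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                             z = seq_len(dm[3])))
  seg <- to - from
  len2 <- sum(seg^2)
  t <- pmin(pmax(((g[, 1] - from[1]) * seg[1] + (g[, 2] - from[2]) * seg[2] +
                    (g[, 3] - from[3]) * seg[3]) / len2, 0), 1)
  d2 <- (g[, 1] - from[1] - t * seg[1])^2 + (g[, 2] - from[2] - t * seg[2])^2 +
    (g[, 3] - from[3] - t * seg[3])^2
  array(d2 <= r^2, dm)
}

test_that("skeleton of a straight cylinder stays on the axis", {
  mask <- tube_mask(c(40, 15, 15), c(5, 8, 8), c(35, 8, 8), 4)
  sk <- skeletonize_sprout(mask)
  # distance of every skeleton voxel to the analytic axis line y=z=8
  off_axis <- sqrt((sk$voxels[, 2] - 8)^2 + (sk$voxels[, 3] - 8)^2)
  expect_lte(max(off_axis), 1)
  expect_gt(nrow(sk$voxels), 15)
})

ball_mask <- function(dm, ctr, r) {
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                             z = seq_len(dm[3])))
  array(rowSums(sweep(g, 2, ctr)^2) <= r^2, dm)
}

test_that("skeleton of a sphere collapses to a small central cluster", {
  mask <- ball_mask(c(21, 21, 21), c(11, 11, 11), 7)
  sk <- skeletonize_sprout(mask)
  expect_lte(nrow(sk$voxels), 5)
  ctr_dist <- sqrt(rowSums(sweep(sk$voxels, 2, c(11, 11, 11))^2))
  expect_lte(max(ctr_dist), 2)
})

test_that("L-shaped tube skeleton has the geodesic length of its arms", {
  mask <- tube_mask(c(40, 40, 9), c(5, 6, 5), c(35, 6, 5), 3) |
    tube_mask(c(40, 40, 9), c(35, 6, 5), c(35, 34, 5), 3)
  sk <- skeletonize_sprout(mask)
  ep <- select_endpoints(sk, reference_point = c(4, 5, 4))
  path <- geodesic_path(sk, ep$base, ep$tip)
  # arms: 30 + 28 voxel steps, corners and rounding give a few voxels slack
  expect_lt(abs(attr(path, "arc_length") - 58), 5)
})

test_that("endpoint selection follows the reference point and manual override", {
  mask <- tube_mask(c(40, 15, 15), c(5, 8, 8), c(35, 8, 8), 4)
  sk <- skeletonize_sprout(mask)
  ep <- select_endpoints(sk, reference_point = c(0, 7, 7))
  expect_lt(ep$base_um[1], ep$tip_um[1])
  ep2 <- select_endpoints(sk, reference_point = c(100, 7, 7))
  expect_gt(ep2$base_um[1], ep2$tip_um[1]) # reference at the far end flips roles
  epm <- select_endpoints(sk, base = c(30, 7, 7), tip = c(10, 7, 7))
  expect_equal(unname(epm$base_um[1] > epm$tip_um[1]), TRUE)
})

test_that("geodesic paths carry physical weights and match Dijkstra", {
  # hand-built straight skeleton of 50 voxels
  vox <- cbind(1:50, 1, 1)
  sk <- structure(list(voxels = vox, dim = c(50, 3, 3),
                       voxel_size = c(1, 1, 1)), class = "sprout_skeleton")
  p <- geodesic_path(sk, 1, 50)
  expect_equal(attr(p, "arc_length"), 49)
  # anisotropic z steps
  skz <- structure(list(voxels = cbind(1, 1, 1:11), dim = c(3, 3, 11),
                        voxel_size = c(1, 1, 2)), class = "sprout_skeleton")
  expect_equal(attr(geodesic_path(skz, 1, 11), "arc_length"), 20)
  # branched: path must avoid the side branch; compare with Dijkstra oracle
  for (seed in 1:6) {
    set.seed(seed)
    main <- cbind(1:20, 10, 5)
    joint <- sample(5:15, 1)
    side <- cbind(joint, 10 + seq_len(6), 5)
    vox <- rbind(main, side)
    skb <- structure(list(voxels = vox, dim = c(25, 20, 9),
                          voxel_size = c(1, 1, 1)), class = "sprout_skeleton")
    pb <- geodesic_path(skb, 1, 20)
    expect_equal(attr(pb, "arc_length"),
                 oracle_geodesic_length(vox, c(1, 1, 1), 1, 20))
    expect_true(all(unclass(pb)[, 2] == 9)) # stays on the main branch
  }
})

test_that("growth direction is the oriented principal axis", {
  straight <- cbind(seq(0, 30), 0, 0)
  g <- growth_direction(straight)
  expect_equal(as.numeric(g), c(1, 0, 0), tolerance = 0.05)
  # reversal leaves the direction unchanged (orientation convention)
  expect_equal(growth_direction(straight[nrow(straight):1, ]),
               -g, tolerance = 1e-9)
  # gently curved path still points broadly base to tip
  t <- seq(0, 1, length.out = 40)
  curved <- cbind(30 * t, 5 * sin(pi * t), 0)
  gc <- growth_direction(curved)
  chord <- curved[40, ] - curved[1, ]
  expect_gt(sum(gc * chord) / sqrt(sum(chord^2)), 0.9)
  expect_error(growth_direction(matrix(1, 5, 3)), "degenerate")
})

test_that("surface shell membership matches the brute-force oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    vs <- sample(c(1, 1, 2), 3, replace = TRUE) * 0.5
    dm <- c(18, 14, 12)
    mask <- tube_mask(dm, c(4, 7, 6), c(14, 7, 6), 3)
    pts <- cbind(runif(150, 0, (dm[1] - 1) * vs[1]),
                 runif(150, 0, (dm[2] - 1) * vs[2]),
                 runif(150, 0, (dm[3] - 1) * vs[3]))
    fld <- displacement_field(pts, matrix(0.1, 150, 3))
    members <- tryCatch(surface_shell(mask, fld, vs, 0.5, 3)$index,
                        error = function(e) integer(0))
    expect_identical(members,
                     oracle_shell_members(pts, mask, vs, 0.5, 3))
  }
})

test_that("shell means and maxima reduce the field as specified", {
  dm <- c(20, 13, 13)
  mask <- tube_mask(dm, c(4, 7, 7), c(16, 7, 7), 3)
  set.seed(1)
  pts <- cbind(runif(300, 0, 19), runif(300, 0, 12), runif(300, 0, 12))
  uni <- displacement_field(pts, cbind(rep(2, 300), 0, 0))
  sh <- surface_shell(mask, uni, c(1, 1, 1), 0, 5)
  expect_equal(mean_shell_displacement(uni, sh), 2)
  zero <- displacement_field(pts, matrix(0, 300, 3))
  expect_equal(mean_shell_displacement(zero, surface_shell(mask, zero,
                                                           c(1, 1, 1), 0, 5)), 0)
  # beads inside the mask or beyond the band are excluded
  one <- displacement_field(rbind(c(10, 6, 6), c(10, 6 + 3 + 3, 6),
                                  c(10, 6 + 3 + 7, 6)),
                            matrix(1, 3, 3))
  sh1 <- surface_shell(mask, one, c(1, 1, 1), 0, 5)
  expect_identical(sh1$index, 2L)
})

test_that("signed profiles carry the base-to-tip sign convention", {
  ph <- make_sprout_phantom(seed = 2)
  geom <- sprout_geometry(ph$mask, ph$voxel_size,
                          reference_point = ph$true_base)
  expect_equal(sum(geom$growth_dir * ph$true_axis), 1, tolerance = 2e-2)
  prof <- signed_profile(ph$field, geom)
  vals <- prof$signed_disp_um[!is.na(prof$signed_disp_um)]
  expect_true(all(vals <= 1e-9)) # contraction towards the origin is negative
  expect_equal(prof$lambda[1], 0)
  expect_equal(prof$lambda[nrow(prof)], 1)
  # uniform tip-ward field gives +0.5 at every populated station
  upts <- ph$field$points
  uplus <- displacement_field(upts,
                              matrix(rep(0.5 * ph$true_axis, each = nrow(upts)),
                                     ncol = 3))
  prof2 <- signed_profile(uplus, geom)
  vals2 <- prof2$signed_disp_um[!is.na(prof2$signed_disp_um)]
  expect_equal(vals2, rep(0.5, length(vals2)))
  # reversing the geometry (base and tip swapped) flips every sign
  geom_r <- sprout_geometry(ph$mask, ph$voxel_size,
                            base = ph$true_tip, tip = ph$true_base)
  prof_r <- signed_profile(ph$field, geom_r)
  vals_r <- prof_r$signed_disp_um[!is.na(prof_r$signed_disp_um)]
  expect_true(all(vals_r >= -1e-9))
})

test_that("profile averaging resamples onto a common normalized axis", {
  mk <- function(vals) {
    n <- length(vals)
    structure(data.frame(arc_length_um = seq(0, n - 1),
                         lambda = seq(0, 1, length.out = n),
                         signed_disp_um = vals, n_points = 1L),
              class = c("displacement_profile", "data.frame"))
  }
  p <- mk(c(-1, -2, -3, -2, -1))
  avg <- normalize_and_average(list(p, p, p, p, p), n_out = 9)
  expect_equal(avg$sd_disp_um, rep(0, 9))
  expect_equal(min(avg$mean_disp_um), -3)
  # two constant profiles of opposite sign cancel
  avg2 <- normalize_and_average(list(mk(rep(1, 4)), mk(rep(-1, 4))))
  expect_equal(avg2$mean_disp_um, rep(0, 51))
  # linear profiles resample exactly
  lin <- mk(seq(-2, 0, length.out = 5))
  avg3 <- normalize_and_average(list(lin), n_out = 11)
  expect_equal(avg3$mean_disp_um, seq(-2, 0, length.out = 11))
  expect_warning(normalize_and_average(list(mk(c(-1, NA, NA, NA, NA)), p)),
                 "excluded")
})

test_that("bead matching recovers the generating field and is order-invariant", {
  ph <- make_sprout_phantom(peak_magnitude_um = 0.8, n_beads = 250, seed = 9)
  rec <- match_beads(ph$bead_positions_stressed, ph$bead_positions_relaxed,
                     max_match_um = 3)
  si <- attr(rec, "stressed_index")
  expect_equal(attr(rec, "relaxed_index"), si) # correct correspondence
  expect_equal(rec$vectors, ph$field$vectors[si, , drop = FALSE],
               tolerance = 1e-12)
  # permuted relaxed input yields the identical pairing
  set.seed(3)
  perm <- sample(nrow(ph$bead_positions_relaxed))
  rec2 <- match_beads(ph$bead_positions_stressed,
                      ph$bead_positions_relaxed[perm, ], max_match_um = 3)
  expect_equal(rec2$points, rec$points)
  expect_equal(rec2$vectors, rec$vectors)
  # displacements beyond the matching radius stay unmatched
  far <- rbind(c(0, 0, 0), c(50, 50, 50))
  near <- far + 0.1
  expect_message(match_beads(rbind(near, c(200, 200, 200)), far,
                             max_match_um = 1), "unmatched")
  expect_error(match_beads(matrix(0, 1, 3), matrix(100, 1, 3),
                           max_match_um = 1), "no bead pairs")
})
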