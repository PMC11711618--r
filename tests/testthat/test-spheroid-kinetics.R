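test_that("std-filter segmentation recovers the generating mask", {
  sc <- make_spheroid_timelapse(radius_px = 50, n_frames = 3,
                                growth_rate_px_per_frame = 3, seed = 21)
  seg <- segment_spheroid(sc$stack$frames[[3]])
  expect_gte(jaccard(seg, sc$true_masks[[3]]), 0.90)

  # noise-free render: recovered mask within a small boundary band
  sc0 <- make_spheroid_timelapse(radius_px = 50, n_frames = 2,
                                 growth_rate_px_per_frame = 3,
                                 noise_level = 0, seed = 22)
  seg0 <- segment_spheroid(sc0$stack$frames[[2]], std_window_px = 3,
                           morph_radius_px = 2)
  truth <- sc0$true_masks[[2]]
  grow <- function(m, r) EBImage::dilate(m + 0,
                                         EBImage::makeBrush(2 * r + 1, "disc")) > 0
  expect_true(all(!(seg0 & !grow(truth, 2))))
  expect_true(all(!(truth & !grow(seg0, 2))))

  expect_error(segment_spheroid(matrix(0.5, 64, 64)), "no spheroid")
})

test_that("full-pipeline tip distance tracks the programmed growth to a few px", {
  # segmentation adds a halo (~half the std window) that cancels between
  # the t=0 outline and the tip, plus speckle roughness of the outline;
  # the net accuracy of tc through segmentation is ~3 px
  for (seed in c(2, 8)) { # the worst of the generator seeds
    sc <- make_spheroid_timelapse(n_frames = 6, seed = seed)
    segs <- lapply(sc$stack$frames, segment_spheroid)
    kin <- kinetics_from_masks(segs, sc$pixel_size)
    expect_lt(max(abs(kin$tc_distance_um - sc$true_tc_distance)),
              3.5 * sc$pixel_size)
    expect_true(all(diff(kin$tc_distance_um) > -2 * sc$pixel_size))
  }
})

test_that("tc_distance measures outgrowth beyond the initial outline", {
  m0 <- disk_mask(101, 30)
  expect_equal(tc_distance(m0, m0, pixel_size = 2), 0)

  # single-pixel-wide sprout protruding 10 px beyond the disk
  mt <- m0
  mt[51, 81:91] <- TRUE # disk edge at col 81 on the midline
  d <- tc_distance(mt, m0, pixel_size = 1)
  expect_lt(abs(d - 10), 1)
  expect_equal(tc_distance(mt, m0, pixel_size = 0.5), d * 0.5)
  expect_error(tc_distance(m0 & FALSE, m0), "empty")
})

test_that("tc_distance matches the brute-force outline-distance oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    m0 <- disk_mask(48, runif(1, 8, 14))
    mt <- m0
    for (k in 1:3) { # poke random sprouts
      ang <- runif(1, 0, 2 * pi)
      len <- sample(3:12, 1)
      r0 <- 24.5 + cos(ang) * seq(0, 24, by = 0.5)
      c0 <- 24.5 + sin(ang) * seq(0, 24, by = 0.5)
      keep <- r0 >= 1 & r0 <= 48 & c0 >= 1 & c0 <= 48
      pix <- unique(cbind(round(r0[keep]), round(c0[keep])))
      pix <- pix[seq_len(min(nrow(pix), len + 10)), , drop = FALSE]
      mt[pix] <- TRUE
    }
    expect_equal(tc_distance(mt, m0), oracle_tc_distance(mt, m0),
                 tolerance = 1e-9)
  }
})

test_that("invasion area counts added pixels and is additive", {
  m0 <- disk_mask(201, 50)
  expect_equal(invasion_area(m0, m0, 1), 0)
  mt <- m0
  mt[1:20, 1:4] <- TRUE    # 80 px^2
  mt[180:199, 10:13] <- TRUE # 80 px^2
  mt[1:20, 190:193] <- TRUE  # 80 px^2
  expect_equal(invasion_area(mt, m0, 1), 240)
  expect_equal(invasion_area(mt, m0, 0.65), 240 * 0.65^2)
  # additivity over disjoint regions
  m1 <- m0; m1[1:20, 1:4] <- TRUE
  m2 <- m0; m2[180:199, 10:13] <- TRUE
  expect_equal(invasion_area(mt, m0),
               invasion_area(m1, m0) + invasion_area(m2, m0) + 80)
})

test_that("kinetics curves aggregate replicates with SD bands", {
  sc <- make_spheroid_timelapse(radius_px = 45, n_frames = 4, seed = 31)
  ks <- kinetics_curves(list(sc$stack, sc$stack, sc$stack))
  expect_equal(ks$summary$tc_sd, rep(0, 4))
  expect_equal(ks$summary$area_sd, rep(0, 4))
  expect_equal(ks$summary$tc_distance_um[1], 0)
  expect_true(all(diff(ks$summary$tc_distance_um) >= 0))

  # mean curve of two growth rates lies between the two
  fast <- make_spheroid_timelapse(radius_px = 45, n_frames = 4,
                                  growth_rate_px_per_frame = 2, seed = 32)
  slow <- make_spheroid_timelapse(radius_px = 45, n_frames = 4,
                                  growth_rate_px_per_frame = 1, seed = 33)
  kf <- kinetics_from_masks(fast$true_masks, 1)
  ksl <- kinetics_from_masks(slow$true_masks, 1)
  km <- kinetics_curves(list(
    timelapse_stack(lapply(fast$true_masks, function(m) m + 0), 1),
    timelapse_stack(lapply(slow$true_masks, function(m) m + 0), 1)))
  mid <- km$summary$tc_distance_um[4]
  expect_lte(mid, max(kf$tc_distance_um[4], ksl$tc_distance_um[4]))
  expect_gte(mid, min(kf$tc_distance_um[4], ksl$tc_distance_um[4]))

  short <- timelapse_stack(sc$stack$frames[1:3], sc$pixel_size)
  expect_error(kinetics_curves(list(sc$stack, short)), "different numbers")
})

test_that("outline overlay labels each timepoint", {
  masks <- lapply(c(10, 15, 20), function(r) disk_mask(61, r))
  ov <- outline_overlay(masks)
  expect_setequal(setdiff(unique(as.vector(ov)), 0L), 1:3)
  ov1 <- outline_overlay(masks[1])
  expect_setequal(setdiff(unique(as.vector(ov1)), 0L), 1L)
  expect_error(outline_overlay(list()), "empty")
})
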