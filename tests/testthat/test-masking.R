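test_that("dilation and border operations equal exhaustive scans", {
  set.seed(808)
  for (conn in list(26, 6, "2d8")) {
    offs <- neighborhood_offsets(conn)
    for (rep in 1:3) {
      m <- array(runif(20^3) < 0.1, c(20, 20, 20))
      expect_identical(dilate_mask(m, conn), oracle_dilate(m, offs))
      b <- array(runif(20^3) < 0.1, c(20, 20, 20))
      expect_identical(border_voxels(m, b, conn), oracle_border(m, b,
                                                                offs))
    }
  }
  expect_error(neighborhood_offsets(5), "connectivity")
})

test_that("band segmentation recovers ground truth on a clean phantom", {
  # disjoint intensity bands: GM 0.05, mixed 0.5, WM 1.0 of max
  cls <- array(0L, c(10, 10, 3))
  cls[3:8, 3:8, ] <- 1L          # GM block
  cls[4:7, 4:7, ] <- 4L          # mixed ring
  cls[5:6, 5:6, ] <- 2L          # WM core
  sir <- array(0, dim(cls))
  sir[cls == 1L] <- 0.06; sir[cls == 4L] <- 0.5; sir[cls == 2L] <- 1
  wm <- segment_wm(sir, mask_config(wm_threshold = 0.8))
  expect_identical(wm, cls == 2L)
  gm <- segment_gm(sir)
  expect_identical(gm, cls == 1L)
  expect_warning(segment_wm(array(0, c(4, 4, 2))), "empty")
})

test_that("noisy SIR segmentation overlaps truth with Dice >= 0.95", {
  tm <- sample_tissue_map(seed = 17)
  sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 2),
                         noise = noise_config(sir_noise_sd = 0.05),
                         seed = 18)
  wm <- segment_wm(sim$sir)
  truth <- tm$tissue_class == TISSUE_CODES[["WM"]]
  dice <- 2 * sum(wm & truth) / (sum(wm) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("periventricular mask is the WM shell around the ventricle", {
  # constructed geometry: CSF block enclosed by WM, GM frame outside
  sir <- array(0, c(12, 12, 3))
  sir[2:11, 2:11, ] <- 0.1       # GM frame
  sir[4:9, 4:9, ] <- 1           # WM
  sir[6:7, 6:7, ] <- 0.02        # ventricle
  cfg <- mask_config()
  wm <- segment_wm(sir, cfg)
  pv <- periventricular_mask(sir, wm, cfg)
  shell <- array(FALSE, dim(sir))
  shell[5:8, 5:8, ] <- TRUE; shell[6:7, 6:7, ] <- FALSE
  expect_identical(pv, shell)
  # externally supplied ventricle mask takes precedence
  vent <- array(FALSE, dim(sir)); vent[6:7, 6:7, ] <- TRUE
  expect_identical(periventricular_mask(sir, wm, cfg, ventricles = vent),
                   shell)
  # no ventricle: empty sub-mask with a warning
  sir2 <- sir; sir2[6:7, 6:7, ] <- 1
  expect_warning(pv2 <- periventricular_mask(sir2, segment_wm(sir2, cfg),
                                             cfg), "ventricle")
  expect_equal(sum(pv2), 0)
})

test_that("peripheral mask picks exactly the WM voxels touching GM", {
  # WM block inside an in-plane GM shell: outer WM layer only
  gm <- array(FALSE, c(10, 10, 3)); wm <- array(FALSE, c(10, 10, 3))
  gm[2:9, 2:9, 2] <- TRUE
  wm[4:7, 4:7, 2] <- TRUE
  gm[wm] <- FALSE
  per <- peripheral_mask(wm, gm, mask_config(connectivity = 26))
  outer <- wm
  outer[5:6, 5:6, 2] <- FALSE
  expect_identical(per, outer)
  # WM with no GM contact: empty
  no_gm <- array(FALSE, dim(gm))
  expect_equal(sum(peripheral_mask(wm, no_gm, mask_config())), 0)
})

test_that("sub-masks partition the full WM mask on phantoms", {
  for (seed in c(19, 23, 29)) {
    tm <- sample_tissue_map(seed = seed)
    sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 2),
                           seed = seed + 1)
    ms <- build_masks(sim$sir)
    expect_gt(sum(ms$periventricular), 0)
    expect_gt(sum(ms$peripheral), 0)
    expect_gt(sum(ms$deep), 0)
    # pairwise disjoint and exhaustive
    expect_equal(sum(ms$periventricular) + sum(ms$peripheral) +
                   sum(ms$deep), sum(ms$full_wm))
    expect_false(any(ms$periventricular & ms$peripheral))
    expect_false(any(ms$periventricular & ms$deep))
    expect_false(any(ms$peripheral & ms$deep))
    expect_identical(ms$periventricular | ms$peripheral | ms$deep,
                     ms$full_wm)
    # deterministic
    ms2 <- build_masks(sim$sir)
    expect_identical(ms, ms2)
  }
})
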