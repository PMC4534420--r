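test_that("tissue map generation is deterministic and validates config", {
  tm1 <- sample_tissue_map(shape = c(16, 16, 4), seed = 7)
  tm2 <- sample_tissue_map(shape = c(16, 16, 4), seed = 7)
  expect_identical(tm1$cbf, tm2$cbf)
  expect_identical(tm1$responder, tm2$responder)
  tm3 <- sample_tissue_map(shape = c(16, 16, 4), seed = 8)
  expect_false(identical(tm1$cbf, tm3$cbf))
  expect_error(tissue_config(nonresponder_fraction = 1.2), "fraction")
  expect_warning(tissue_config(wm_cbf_mean = 55, gm_cbf_mean = 60),
                 "2-4x")
})

test_that("phantom honors configured non-responder count and CBF gap", {
  cfg0 <- tissue_config(nonresponder_fraction = 0)
  tm0 <- sample_tissue_map(config = cfg0, seed = 3)
  expect_true(all(tm0$responder))

  cfg <- tissue_config(nonresponder_fraction = 0.1)
  tm <- sample_tissue_map(config = cfg, seed = 3)
  wm <- tm$tissue_class == TISSUE_CODES[["WM"]]
  expect_equal(sum(!tm$responder[wm]), round(0.1 * sum(wm)))
  expect_true(all(tm$responder[!wm]))

  # WM mean CBF within [GM/4, GM/2]; draws near configured means
  big <- sample_tissue_map(shape = c(64, 64, 8), seed = 4)
  gm <- big$tissue_class == TISSUE_CODES[["GM"]]
  wmb <- big$tissue_class == TISSUE_CODES[["WM"]]
  gm_mean <- mean(big$cbf[gm]); wm_mean <- mean(big$cbf[wmb])
  expect_gte(wm_mean, gm_mean / 4)
  expect_lte(wm_mean, gm_mean / 2)
  # Monte-Carlo: sample WM mean within 3 standard errors of 20
  se <- sd(big$cbf[wmb]) / sqrt(sum(wmb))
  expect_lt(abs(wm_mean - 20), 3 * se + 0.2)  # +0.2 for pmax(0,) bias
})

test_that("noiseless simulation reproduces the kinetic signal exactly", {
  tissue <- tissue_config(nonresponder_fraction = 0)
  tm <- sample_tissue_map(shape = c(12, 12, 2), config = tissue, seed = 5)
  p <- protocol_preset("exp3", n_pairs = 6)
  sim <- simulate_series(tm, p, noise = noise_config(sd = 0,
                                                     sir_noise_sd = 0),
                         seed = 9)
  d <- split_and_subtract(sim$series)
  for (i in seq_len(6))
    expect_equal(d$data[, , , i], sim$expected_dm, tolerance = 1e-12)
})

test_that("non-responder voxels never show positive noiseless signal", {
  tissue <- tissue_config(nonresponder_fraction = 0.5,
                          nonresponder_mean = 0.1)
  tm <- sample_tissue_map(shape = c(12, 12, 2), config = tissue, seed = 6)
  sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 4),
                         noise = noise_config(sd = 0, sir_noise_sd = 0),
                         seed = 2)
  d <- split_and_subtract(sim$series)
  nr <- !tm$responder
  expect_true(any(nr))
  for (i in seq_len(4)) {
    slice <- d$data[, , , i]
    expect_true(all(slice[nr] <= 0))
  }
})

test_that("empirical difference noise matches sigma * sqrt(2)", {
  # one voxel, many pairs: var(control - label) = 2 sigma^2
  tm <- sample_tissue_map(shape = c(3, 3, 1),
                          config = tissue_config(nonresponder_fraction = 0),
                          seed = 1)
  sigma <- 0.25
  sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 10000),
                         noise = noise_config(sd = sigma), seed = 42)
  d <- split_and_subtract(sim$series)
  v <- d$data[2, 2, 1, ]
  expect_lt(abs(sd(v) - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.05)
})

test_that("simulation is deterministic and SIR separates tissues", {
  s <- small_sim(n_pairs = 4, seed = 21)
  s2 <- small_sim(n_pairs = 4, seed = 21)
  expect_identical(s$sim$series$data, s2$sim$series$data)
  expect_identical(s$sim$sir$data, s2$sim$sir$data)
  cls <- s$tmap$tissue_class
  sir <- s$sim$sir$data
  wm_med <- median(sir[cls == TISSUE_CODES[["WM"]]])
  mx_med <- median(sir[cls == TISSUE_CODES[["mixed"]]])
  gm_med <- median(sir[cls == TISSUE_CODES[["GM"]]])
  expect_gt(wm_med, mx_med)
  expect_gt(mx_med, gm_med)
  # WM intensities stochastically dominate GM
  expect_gt(min(sir[cls == TISSUE_CODES[["WM"]]]),
            max(sir[cls == TISSUE_CODES[["GM"]]]))
  # static residual grows with slice index (noiseless control volumes)
  s0 <- small_sim(n_pairs = 2, seed = 22,
                  noise = noise_config(sd = 0, sir_noise_sd = 0))
  ctrl <- s0$sim$series$data[, , , 2]
  m_by_slice <- sapply(seq_len(dim(ctrl)[3]), function(z)
    mean(ctrl[, , z][s0$tmap$tissue_class[, , z] ==
                       TISSUE_CODES[["background"]]]))
  expect_true(all(diff(m_by_slice) > 0))
})
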