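test_that("paired_t matches hand values and the formula oracle", {
  r <- paired_t(c(1, -1))
  expect_equal(r$u, 0); expect_equal(r$t, 0); expect_equal(r$p, 0.5)

  r <- paired_t(c(2, 3))
  expect_equal(r$u, 2.5)
  expect_equal(r$sd, sqrt(0.5))
  expect_equal(r$t, 5.0)

  set.seed(101)
  for (i in 1:20) {
    d <- rnorm(5)
    r <- paired_t(d)
    expect_equal(r$t, mean(d) * sqrt(5) / sd(d), tolerance = 1e-12)
    # consistency with n, u, sd stored on the object
    expect_equal(r$t, r$u * sqrt(r$n) / r$sd, tolerance = 1e-10)
    # and with R's own t.test
    expect_equal(r$p, t.test(d, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  expect_error(paired_t(1), "at least 2")
})

test_that("zero-variance differences get limiting sentinels", {
  expect_identical(paired_t(c(2, 2, 2))$t, Inf)
  expect_identical(paired_t(c(2, 2, 2))$p, 0)
  expect_identical(paired_t(c(-1, -1))$t, -Inf)
  expect_identical(paired_t(c(-1, -1))$p, 1)
  expect_identical(paired_t(c(0, 0))$t, 0)
})

test_that("prefix t engine equals naive per-prefix recomputation", {
  set.seed(202)
  grid <- c(2, 3, 5, 10, 37, 100, 250, 400)
  dm <- matrix(rnorm(20 * 400, mean = 0.1), 20, 400)
  tc <- t_curves(dm, grid)
  for (v in 1:20)
    expect_equal(tc$t[v, ], oracle_prefix_t(dm[v, ], grid),
                 tolerance = 1e-9)
  # constant positive differences: +Inf at every grid point
  cst <- matrix(0.5, 1, 50)
  expect_true(all(t_curves(cst, c(2, 10, 50))$t == Inf))
  # grid validation
  expect_error(t_curves(dm, c(2, 500)), "n_pairs")
  expect_error(t_curves(dm, c(10, 5)), "increasing")
})

test_that("t from population moments follows the sqrt-N law exactly", {
  for (r in c(0.05, 0.2, 1)) {
    for (n in c(5, 25, 100)) {
      expect_identical(t_from_moments(r, 1, 4 * n),
                       2 * t_from_moments(r, 1, n))
    }
  }
  # empirical prefix curves track u * sqrt(N) / sd within sampling error
  set.seed(303)
  u <- 0.2; nrep <- 400
  dm <- matrix(rnorm(nrep * 400, mean = u, sd = 1), nrep, 400)
  grid <- c(25, 100, 400)
  tc <- t_curves(dm, grid)
  mean_t <- colMeans(tc$t)
  expected <- t_from_moments(u, 1, grid)
  # se of the mean of t across voxels ~ 1/sqrt(nrep)
  expect_true(all(abs(mean_t - expected) < 4 / sqrt(nrep) + 0.05))
})

test_that("significant_fraction applies thresholds and Bonferroni", {
  # noiseless responders-only: fraction 1 everywhere
  cst <- matrix(0.5, 10, 20) ; tc <- t_curves(cst, c(2, 10, 20))
  expect_equal(significant_fraction(tc)$fraction, rep(1, 3))
  # Bonferroni threshold is alpha / m
  set.seed(404)
  dm <- matrix(rnorm(100 * 50), 100, 50)
  tc <- t_curves(dm, c(10, 50))
  sfb <- significant_fraction(tc, alpha = 0.05, "bonferroni")
  expect_equal(sfb$m, rep(100, 2))
  manual <- colMeans(tc$p < 0.05 / 100)
  expect_equal(sfb$fraction, unname(manual))
  expect_error(significant_fraction(tc, alpha = 1.5), "alpha")
})

test_that("null simulation is calibrated at alpha (small-scale)", {
  set.seed(505)
  nv <- 4000
  dm <- matrix(rnorm(nv * 100), nv, 100)
  tc <- t_curves(dm, c(100))
  for (a in c(0.05, 0.01)) {
    frac <- significant_fraction(tc, alpha = a)$fraction
    se <- sqrt(a * (1 - a) / nv)
    expect_lt(abs(frac - a), 3 * se)
  }
})

test_that("time_to_significance finds the first crossing", {
  set.seed(606)
  grid <- seq(2, 400, by = 2)
  dm <- matrix(rnorm(30 * 400, mean = 0.2), 30, 400)
  tc <- t_curves(dm, grid)
  tts <- time_to_significance(tc, alpha = 0.05, "none")
  # brute-force scan of per-prefix p-values
  for (v in 1:30) {
    ps <- vapply(grid, function(k)
      t.test(dm[v, 1:k], alternative = "greater")$p.value, numeric(1))
    w <- which(ps < 0.05)
    expect_equal(tts$nsa[v], if (length(w)) grid[w[1]] else NA_integer_)
  }
  # noiseless responder crosses at the first grid value
  cst <- t_curves(matrix(1, 2, 10), c(2, 5, 10))
  expect_equal(time_to_significance(cst)$nsa, c(2, 2))
  # strict non-responder never crosses
  neg <- t_curves(matrix(-1, 2, 10), c(2, 5, 10))
  expect_true(all(is.na(time_to_significance(neg)$nsa)))
})

test_that("find_nonresponders equals an all(t<0) scan", {
  set.seed(707)
  dm <- matrix(rnorm(1000 * 60, mean = rep(c(-0.5, 0, 0.3),
                                           length.out = 1000)),
               1000, 60)
  grid <- seq(2, 60, by = 2)
  tc <- t_curves(dm, grid)
  got <- find_nonresponders(tc)
  want <- which(vapply(seq_len(1000), function(v)
    all(oracle_prefix_t(dm[v, ], grid) < 0), logical(1)))
  expect_identical(got, want)
  # all-positive noiseless voxels: empty set
  expect_length(find_nonresponders(t_curves(matrix(1, 3, 10),
                                            c(2, 10))), 0)
})
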