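test_that("neighbors agrees with the brute-force search", {
  withr::local_seed(101)
  for (i in 1:40) {
    n <- sample(25:60, 1)
    E <- sample(2:4, 1)
    excl <- sample(0:2, 1)
    k <- sample(3:6, 1)
    x <- rnorm(n + (E - 1))
    m <- delay_embed(x, E, 1)
    fv <- attr(m, "first_valid")
    q <- sample(seq_len(nrow(m)), 1)
    got <- neighbors(m, t = q + fv - 1, k = k, exclusion = excl)
    ref <- oracle_knn(as.matrix(m[, -1]), q, k, excl)
    expect_equal(got$time, ref$index + fv - 1)
    expect_equal(got$distance, ref$distance, tolerance = 1e-12)
  }
})

test_that("neighbors returns exact duplicates first and defaults to E + 1", {
  x <- c(1, 5, 2, 8, 1, 7, 3, 9, 4, 6)
  m <- delay_embed(x, dim = 2, lag = 1)
  # rows at times 5 and 9 (values 1,8 / 4,9)... construct explicit duplicate:
  x2 <- c(0.3, 0.7, 0.1, 0.3, 0.7, 0.5, 0.9, 0.2, 0.6, 0.8)
  m2 <- delay_embed(x2, dim = 2, lag = 1)  # rows (x_t, x_{t-1}); t=2 and t=5 identical
  nb <- neighbors(m2, t = 5, k = 3)
  expect_equal(nb$time[1], 2)
  expect_equal(nb$distance[1], 0)
  expect_true(all(diff(nb$distance) >= 0))

  m4 <- delay_embed(rnorm(50), dim = 4, lag = 1)
  expect_equal(nrow(neighbors(m4, t = 20)), 5)  # k defaults to E + 1

  expect_error(neighbors(m2, t = 1), "outside")
  expect_error(neighbors(delay_embed(rnorm(5), 2, 1), t = 3, k = 4), "need at least")
})

test_that("simplex weights follow the exponential-decay rule", {
  expect_equal(simplex_weights(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(simplex_weights(c(0, 1, 2)), c(1, 0, 0))
  # direct evaluation of w_i = exp(-d_i/d_min) / sum
  w <- exp(-c(1, 2) / 1)
  expect_equal(simplex_weights(c(1, 2)), w / sum(w))
  expect_error(simplex_weights(c(1, -1)), "non-negative")

  withr::local_seed(22)
  for (i in 1:50) {
    d <- sort(abs(rnorm(sample(2:8, 1))))
    w <- simplex_weights(d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_true(all(diff(w) <= 1e-15))  # non-increasing in distance
  }
})

test_that("cross map recovers a self-map and is affine-invariant", {
  orbit <- logistic_orbit(400)
  dat <- tibble::tibble(u = orbit, v = orbit)
  res <- cross_map(dat, "u", "v", dim = 2, lag = 1)
  expect_gt(res$rho, 0.99)

  # rho is invariant to affine rescaling of either series
  sim <- simulate_three_species("chain", length = 500, seed = 2)
  base <- cross_map(sim, "x", "z", dim = 4, lag = 1)$rho
  resc <- dplyr::mutate(sim, x = 3.2 * x - 1, z = -0.5 * z + 4)
  expect_equal(cross_map(resc, "x", "z", dim = 4, lag = 1)$rho, base,
               tolerance = 1e-10)
})

test_that("independent white noise shows no significant cross-map skill", {
  withr::local_seed(33)
  dat <- tibble::tibble(a = rnorm(1000), b = rnorm(1000))
  st <- surrogate_test(dat, "a", "b",
                       config = pcm_config(dim = 4, delays = 0,
                                           surrogates = 99, seed = 77))
  expect_gt(st$p_value, 0.05)
})

test_that("delay scan recovers a known shift and reduces to cross_map at 0", {
  sim <- simulate_three_species("chain", length = 800, seed = 5)
  single <- cross_map(sim, "x", "z", dim = 4, lag = 1)
  scanned <- cross_map_delay_scan(sim, "x", "z", delays = 0, dim = 4, lag = 1)
  expect_equal(single$rho, scanned$rho)
  expect_equal(single$estimate, scanned$estimate)

  # v a copy of u shifted by 3 steps: scanning recovers the shift exactly
  # with a scalar embedding, and within the embedding window otherwise
  orbit <- logistic_orbit(500)
  shifted <- tibble::tibble(u = orbit[1:490], v = dplyr::lead(orbit, 3)[1:490])
  res1 <- cross_map_delay_scan(shifted, "u", "v", delays = -5:5, dim = 1)
  expect_equal(res1$best_delay, -3)
  expect_gt(res1$rho, 0.99)
  res2 <- cross_map_delay_scan(shifted, "u", "v", delays = -5:5, dim = 2)
  expect_true(res2$best_delay %in% c(-3, -2))
  # argmax agrees with exhaustive evaluation of the per-delay curve
  expect_equal(res2$rho, max(res2$rho_by_delay$rho, na.rm = TRUE))

  # benchmark chain pair (z, y): the per-delay curve has an interior maximum
  res_zy <- cross_map_delay_scan(sim, "z", "y", delays = -5:5, dim = 4)
  expect_true(res_zy$best_delay > -5 && res_zy$best_delay < 5)
})

test_that("cross-map skill for a true causal pair converges with length", {
  lengths <- c(200, 500, 1000, 3000)
  ok <- vapply(1:10, function(s) {
    sim <- simulate_chain_noise_free(length = 3000, seed = s)
    rho <- vapply(lengths, function(L)
      cross_map(sim[1:L, ], "x", "z", dim = 4, lag = 1)$rho, numeric(1))
    all(diff(rho) >= -1e-6)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("degenerate cross-map inputs raise informative errors", {
  dat <- tibble::tibble(a = rep(1, 100), b = rnorm(100))
  expect_error(cross_map(dat, "a", "b", dim = 2), "zero.variance|zero variance")
  short <- tibble::tibble(a = rnorm(12), b = rnorm(12))
  expect_error(cross_map(short, "a", "b", dim = 4), "support too small",
               class = "pcmap_support_error")
})
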