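test_that("three-species presets encode the stated interaction modes", {
  sim <- simulate_three_species("chain", length = 300, seed = 1)
  expect_equal(attr(sim, "alpha"), c(x = 3.6, y = 3.72, z = 3.68))
  expect_equal(attr(sim, "noise_sd"), 0.005)
  tg <- truth_graph(sim)
  expect_equal(tg[, c("source", "target")],
               tibble::tibble(source = c("x", "z"), target = c("z", "y")))

  expect_equal(truth_graph(simulate_three_species("direct", length = 50,
                                                  seed = 1))$source, "x")
  loop_tg <- truth_graph(simulate_three_species("loop", length = 50, seed = 1))
  expect_equal(paste(loop_tg$source, loop_tg$target),
               c("x z", "y x", "z y"))
  expect_error(simulate_three_species("custom"), "beta")
  expect_error(simulate_three_species("chain", beta = diag(3)), "custom")
})

test_that("the iteration follows the printed map (hand-checked steps)", {
  x0 <- c(x = 0.31, y = 0.47, z = 0.62)
  sim <- simulate_chain_noise_free(length = 5, x0 = x0, burn_in = 0)
  a <- c(3.6, 3.72, 3.68); bzx <- 0.4; byz <- 0.4
  x <- x0[["x"]]; y <- x0[["y"]]; z <- x0[["z"]]
  for (t in 1:5) {
    xn <- x * (a[1] - a[1] * x)
    zn <- z * (a[3] - a[3] * z - bzx * x)
    yn <- y * (a[2] - a[2] * y - byz * z)
    x <- xn; y <- yn; z <- zn
    expect_equal(sim$x[t], x, tolerance = 1e-14)
    expect_equal(sim$y[t], y, tolerance = 1e-14)
    expect_equal(sim$z[t], z, tolerance = 1e-14)
  }
})

test_that("noise-free runs are deterministic; noisy runs are seed-reproducible", {
  x0 <- c(0.4, 0.5, 0.6)
  a <- simulate_three_species("chain", length = 200, noise_sd = 0, x0 = x0,
                              seed = 1)
  b <- simulate_three_species("chain", length = 200, noise_sd = 0, x0 = x0,
                              seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))

  n1 <- simulate_three_species("loop", length = 200, seed = 7)
  n2 <- simulate_three_species("loop", length = 200, seed = 7)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
})

test_that("the n-node generator specialises to the three-species system", {
  beta <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  beta["z", "x"] <- 0.4; beta["y", "z"] <- 0.4
  g <- simulate_network(alpha = c(x = 3.6, y = 3.72, z = 3.68), beta = beta,
                        length = 400, seed = 21)
  s <- simulate_three_species("chain", length = 400, seed = 21)
  expect_identical(as.data.frame(g), as.data.frame(s))
})

test_that("default eight-node network stays bounded with correct truth graph", {
  p <- default_network_params()
  sim <- simulate_network(p$alpha, p$beta, length = 2000, seed = 3)
  vals <- as.matrix(sim[, -1])
  expect_true(all(vals > 0 & vals < 1))
  tg <- truth_graph(sim)
  expect_equal(nrow(tg), 10)
  expect_true(all(paste0("x", c(1, 4)) %in% tg$source))
})

test_that("decoupled nodes show no significant cross-map association", {
  sim <- simulate_three_species("custom", beta = matrix(0, 3, 3),
                                length = 800, seed = 31)
  cfgq <- pcm_config(dim = 4, delays = 0, surrogates = 49, seed = 5)
  expect_gt(surrogate_test(sim, "x", "y", config = cfgq)$p_value, 0.05)
  expect_gt(surrogate_test(sim, "z", "x", config = cfgq)$p_value, 0.05)
})

test_that("divergent parameter sets are rejected with the failing step", {
  expect_error(
    simulate_three_species("custom", alpha = c(5, 5, 5),
                           beta = matrix(0, 3, 3), length = 100,
                           x0 = c(0.5, 0.5, 0.5), noise_sd = 0),
    "diverged at step", class = "pcmap_divergence_error")
})

test_that("sample_trials draws aligned, reproducible segments", {
  sim <- simulate_three_species("chain", length = 500, seed = 2)
  tr <- sample_trials(sim, n_trials = 10, segment_length = 100, seed = 8)
  expect_length(tr, 10)
  offs <- attr(tr, "offsets")
  for (i in seq_along(tr)) {
    expect_equal(nrow(tr[[i]]), 100)
    expect_equal(tr[[i]]$time, offs[i]:(offs[i] + 99))
  }
  # same seed, same offsets
  expect_identical(offs,
                   attr(sample_trials(sim, 10, 100, seed = 8), "offsets"))
  # degenerate: segment as long as the series leaves one possible offset
  tr_full <- sample_trials(sim, n_trials = 3, segment_length = 500, seed = 1)
  expect_true(all(attr(tr_full, "offsets") == 1))
  expect_error(sample_trials(sim, 2, 501), "exceeds")
})

test_that("transitivity demo: pairwise mapping flags the chain's end pair, PCM does not", {
  sim <- simulate_chain_noise_free(length = 1200, seed = 17)
  cfg <- pcm_config(dim = 4, lag = 1, delays = -5:5, threshold = 0.5)
  res <- pcm_pair(sim, "x", "y", "z", cfg)
  expect_gt(res$rho_C, 0.5)   # MCM sees a (spurious) x -> y link
  expect_lt(min(res$rho_D), 0.5) # PCM rejects it
  expect_equal(res$decision, "indirect")
})
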