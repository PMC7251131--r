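cfg <- pcm_config(dim = 4, lag = 1, delays = -5:5, threshold = 0.5)

test_that("classify_link implements the three-case rule", {
  expect_equal(classify_link(0.8, 0.7, 0.5), "direct")
  expect_equal(classify_link(0.8, 0.1, 0.5), "indirect")
  expect_equal(classify_link(0.3, 0.2, 0.5), "none")
  # vectorised
  expect_equal(classify_link(c(0.8, 0.8, 0.3), c(0.7, 0.1, 0.2), 0.5),
               c("direct", "indirect", "none"))
  expect_error(classify_link(1.2, 0.5, 0.5))
})

test_that("gamma_index evaluates the proximity ratio", {
  expect_equal(gamma_index(0.7, 0.7), 1)
  expect_equal(gamma_index(0.7, 0), 0)
  expect_equal(gamma_index(0.8, c(0.6, 0.4)), (0.6 * 0.4) / 0.8^2)
  expect_error(gamma_index(0, 0.5), "undefined")
})

test_that("pcm_pair separates direct, indirect, and absent links", {
  # chain: the pairwise index is fooled, the partial index is not
  sim <- simulate_three_species("chain", length = 1000, seed = 4)
  res <- pcm_pair(sim, "x", "y", "z", cfg)
  expect_gt(res$rho_C, 0.5)
  expect_lt(min(res$rho_D), 0.5)
  expect_equal(res$decision, "indirect")
  expect_true(all(c(res$rho_C, res$rho_D, res$gamma) >= 0))
  expect_true(all(c(res$rho_C, res$rho_D) <= 1))

  # direct coupling with a fully decoupled third variable: conditioning on it
  # changes almost nothing
  sim_d <- simulate_three_species("direct", length = 1000, seed = 4)
  res_d <- pcm_pair(sim_d, "x", "y", "z", cfg)
  expect_equal(res_d$decision, "direct")
  expect_lt(abs(res_d$rho_C - min(res_d$rho_D)) / res_d$rho_C, 0.2)

  # mutually uncoupled noise-driven maps: no link at all
  sim_0 <- simulate_three_species("custom", beta = matrix(0, 3, 3),
                                  length = 1000, seed = 4)
  res_0 <- pcm_pair(sim_0, "x", "y", "z", cfg)
  expect_lt(res_0$rho_C, 0.5)
  expect_equal(res_0$decision, "none")
})

test_that("pcm_pair is deterministic and consistent with classify_link", {
  sim <- simulate_three_species("chain", length = 800, seed = 9)
  c2 <- pcm_config(dim = 4, delays = -5:5, surrogates = 19, seed = 123)
  r1 <- pcm_pair(sim, "x", "y", "z", c2)
  r2 <- pcm_pair(sim, "x", "y", "z", c2)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$surrogate, r2$surrogate)
  expect_identical(r1$decision,
                   classify_link(r1$rho_C, min(r1$rho_D), c2$threshold))
})

test_that("a pure-noise conditioner barely moves the partial index", {
  res <- purrr::map_dbl(1:8, function(s) {
    sim <- simulate_three_species("direct", length = 1000, seed = s)
    sim$noise <- withr::with_seed(s + 500, rnorm(nrow(sim)))
    r <- pcm_pair(sim, "x", "y", "noise", cfg)
    abs(r$rho_C - min(r$rho_D))
  })
  expect_lt(mean(res), 0.1)
})

test_that("higher-order conditioning reduces to order one and enumerates chains", {
  sim <- simulate_three_species("chain", length = 700, seed = 6)
  r_pair <- pcm_pair(sim, "x", "y", "z", cfg)
  r_ho <- pcm_higher_order(sim, "x", "y", "z", order = 1, cfg)
  expect_equal(r_ho, unname(r_pair$rho_D["1"]))

  # ordered chains: s = 2, n = 2 has exactly the two ordered pairs
  expect_equal(length(pcmap:::ordered_chains(2, 2)), 2)
  expect_equal(length(pcmap:::ordered_chains(3, 2)), 6)
  expect_error(pcm_higher_order(sim, "x", "y", "z", order = 2, cfg),
               "exceeds the number of conditioners")

  cap <- pcm_config(dim = 4, max_chains = 1)
  sim4 <- simulate_network(
    alpha = c(x = 3.6, y = 3.72, z1 = 3.68, z2 = 3.65),
    beta = {
      b <- matrix(0, 4, 4,
                  dimnames = rep(list(c("x", "y", "z1", "z2")), 2))
      b["z1", "x"] <- 0.4; b["z2", "z1"] <- 0.4; b["y", "z2"] <- 0.4
      b
    }, length = 700, seed = 2)
  expect_error(
    pcm_higher_order(sim4, "x", "y", c("z1", "z2"), order = 2, cap),
    "max_chains")
})

test_that("second-order conditioning suppresses a two-mediator route", {
  # path x -> z1 -> z2 -> y: conditioning on nested two-step chains removes
  # the flow that single-mediator conditioning only partly captures
  mk <- function(seed) {
    b <- matrix(0, 4, 4, dimnames = rep(list(c("x", "y", "z1", "z2")), 2))
    b["z1", "x"] <- 0.4; b["z2", "z1"] <- 0.4; b["y", "z2"] <- 0.4
    simulate_network(alpha = c(x = 3.6, y = 3.72, z1 = 3.68, z2 = 3.65),
                     beta = b, length = 800, seed = seed)
  }
  res <- purrr::map_dfr(1:20, function(s) {
    sim <- mk(s)
    rC <- cross_map_delay_scan(sim, "x", "y", delays = -5:5, dim = 4)$rho
    rD2 <- pcm_higher_order(sim, "x", "y", c("z1", "z2"), order = 2, cfg)
    tibble::tibble(rho_C = rC, rho_D2 = rD2)
  })
  expect_lt(mean(res$rho_D2), mean(res$rho_C))
})

test_that("surrogate test is floored for a perfect copy and errors unconfigured", {
  orbit <- logistic_orbit(600)
  dat <- tibble::tibble(x = orbit, y = orbit)
  st <- surrogate_test(dat, "x", "y",
                       config = pcm_config(dim = 2, delays = 0,
                                           surrogates = 19, seed = 42))
  expect_equal(st$p_value, 1 / 20)
  expect_error(surrogate_test(dat, "x", "y", config = pcm_config()),
               "surrogates")
})

test_that("infer_network recovers the chain and tolerates per-pair failure", {
  sim <- simulate_three_species("chain", length = 1000, seed = 13)
  net <- infer_network(sim, cfg)
  expect_equal(nrow(net), 6)
  adj <- decision_adjacency(net)
  expect_true(adj["x", "z"] && adj["z", "y"])
  expect_false(adj["x", "y"])
  # the spurious x -> y edge appears under the pairwise rule
  adj_mcm <- decision_adjacency(net, rule = "mcm")
  expect_true(adj_mcm["x", "y"])

  # sparse_min equals all when there is a single mediator
  net_sparse <- infer_network(sim, pcm_config(dim = 4,
                                              conditioning = "sparse_min"))
  expect_equal(tidy(net_sparse), tidy(net))

  # a degenerate column fails its pairs without aborting the matrix
  bad <- sim
  bad$z <- rep(1, nrow(bad))
  net_bad <- infer_network(bad, cfg)
  expect_true(any(net_bad$decision == "error"))
  expect_equal(nrow(net_bad), 6)
})
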