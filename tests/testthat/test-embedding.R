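manifold_cols <- function(m) unname(as.matrix(m[, -1]))

test_that("delay_embed reproduces the delay-coordinate definition", {
  # length-10 series, E = 3, tau = 2: L - (E-1)tau = 6 points, r = 5
  m <- delay_embed(seq_len(10), dim = 3, lag = 2)
  expect_equal(nrow(m), 6)
  expect_equal(attr(m, "first_valid"), 5L)
  expect_equal(m$time, 5:10)

  # E = 1 is the identity embedding
  x <- rnorm(20)
  m1 <- delay_embed(x, dim = 1)
  expect_equal(m1$d1, x)
  expect_equal(attr(m1, "first_valid"), 1L)

  # row for time t is (x_t, x_{t-tau}, ...)
  m2 <- delay_embed(c(1, 2, 3, 4, 5), dim = 2, lag = 1)
  expect_equal(unname(as.matrix(m2[, c("d1", "d2")])),
               rbind(c(2, 1), c(3, 2), c(4, 3), c(5, 4)))

  expect_error(delay_embed(1:4, dim = 3, lag = 2),
               "minimum length 5")
})

test_that("delay_embed round-trips the series and is affine-equivariant", {
  withr::local_seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(30:80, 1))
    E <- sample(2:5, 1); tau <- sample(1:3, 1)
    if (length(x) < 1 + (E - 1) * tau + 5) next
    m <- delay_embed(x, E, tau)
    fv <- attr(m, "first_valid")
    expect_identical(m$d1, x[fv:length(x)])
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    m2 <- delay_embed(a * x + b, E, tau)
    expect_equal(manifold_cols(m2), a * manifold_cols(m) + b,
                 tolerance = 1e-12)
  }
})

test_that("FNN dimension selection matches the loop-based reference", {
  x <- logistic_orbit(300)
  got <- select_dim_fnn(x, lag = 1, max_dim = 6)
  expect_lte(as.integer(got), 3)
  # fractions agree with the reference implementation dimension by dimension
  fr <- attr(got, "fnn_fraction")
  for (E in seq_along(fr))
    expect_equal(unname(fr[E]), oracle_fnn_fraction(x, E, lag = 1),
                 tolerance = 1e-12)
  # the reference picks the same dimension
  ref <- which(vapply(1:6, oracle_fnn_fraction, numeric(1), x = x,
                      lag = 1) < 0.01)[1]
  expect_equal(as.integer(got), ref)
})

test_that("FNN handles periodic, noisy, and degenerate series", {
  s <- sin(2 * pi * (1:400) / 40)
  expect_equal(as.integer(select_dim_fnn(s, lag = 10, max_dim = 6)), 2L)

  withr::local_seed(7)
  noise <- rnorm(400)
  expect_warning(got <- select_dim_fnn(noise, lag = 1, max_dim = 6),
                 "never dropped")
  expect_equal(as.integer(got), 6L)

  expect_error(select_dim_fnn(rep(1, 100), lag = 1), "zero variance")
})

test_that("DMI lag selection finds the first interior minimum", {
  # a touch of observation noise keeps the sine from collapsing onto a
  # 20-state deterministic orbit (where every lag carries full information)
  withr::local_seed(5)
  s <- sin(2 * pi * (1:500) / 20) + rnorm(500, sd = 0.1)
  got <- select_lag_dmi(s, max_lag = 15)
  expect_true(as.integer(got) %in% 4:6)
  expect_equal(unname(attr(got, "dmi")), oracle_dmi_curve(s, 15),
               tolerance = 1e-12)

  # i.i.d. noise: no dependence at any lag, fallback lag 1
  withr::local_seed(11)
  expect_equal(as.integer(select_lag_dmi(rnorm(500), max_lag = 15)), 1L)

  # strongly autocorrelated AR(1): dependence decays slowly, minimum beyond 1
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 800))
  expect_gt(as.integer(select_lag_dmi(ar, max_lag = 30)), 1L)

  expect_error(select_lag_dmi(rep(2, 100)), "zero variance")

  # deterministic for fixed input
  expect_identical(select_lag_dmi(s, max_lag = 15),
                   select_lag_dmi(s, max_lag = 15))
})
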