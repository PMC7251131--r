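#' Delay-coordinate embedding of a scalar time series
#'
#' Reconstructs the shadow manifold of a scalar observable by the
#' Takens--Mañé delay-coordinate map. Row `t` of the manifold is the vector
#' \eqn{(x_t, x_{t-\tau}, \dots, x_{t-(E-1)\tau})}, so the first valid time is
#' \eqn{r = 1 + (E-1)\tau} and a series of length `L` yields
#' \eqn{L - (E-1)\tau} points.
#'
#' @param x Numeric vector, the time series (unit sampling, no missing values).
#' @param dim Embedding dimension `E` (positive integer).
#' @param lag Embedding lag `tau` (positive integer).
#' @return A tibble of class `shadow_manifold` with a `time` column (1-based
#'   original time index of each point) and columns `d1 ... dE` holding the
#'   delay coordinates (`d1` is the undelayed coordinate). Attributes `dim`,
#'   `lag` and `first_valid` record the embedding.
#' @examples
#' m <- delay_embed(sin(1:50), dim = 3, lag = 2)
#' attr(m, "first_valid") # 5
#' @export
delay_embed <- function(x, dim, lag = 1) {
  check_series(x, "x")
  stopifnot(length(dim) == 1, dim >= 1, dim == as.integer(dim),
            length(lag) == 1, lag >= 1, lag == as.integer(lag))
  min_len <- 1 + (dim - 1) * lag
  if (length(x) < min_len)
    abort(sprintf(
      "series too short for embedding: length %d < minimum length %d required by dim = %d, lag = %d",
      length(x), min_len, dim, lag))
  pts <- embed_matrix(x, dim, lag)
  out <- as_tibble(as.data.frame(pts))
  names(out) <- paste0("d", seq_len(dim))
  out <- dplyr::bind_cols(tibble(time = min_len:length(x)), out)
  structure(out, dim_embed = as.integer(dim), lag_embed = as.integer(lag),
            first_valid = as.integer(min_len),
            class = c("shadow_manifold", class(out)))
}

# Plain-matrix embedding used on hot paths: rows are times r..L, column j
# holds x_{t-(j-1)lag}.
embed_matrix <- function(x, dim, lag) {
  n <- length(x)
  r <- 1 + (dim - 1) * lag
  m <- vapply(0:(dim - 1), function(j) x[(r - j * lag):(n - j * lag)],
              numeric(n - r + 1))
  if (is.null(base::dim(m))) m <- matrix(m, nrow = 1)
  m
}

manifold_matrix <- function(manifold) {
  stopifnot(inherits(manifold, "shadow_manifold"))
  as.matrix(manifold[, -1, drop = FALSE])
}

#' Select an embedding dimension by false nearest neighbours
#'
#' Classical Kennel-style false-nearest-neighbour (FNN) search: for each
#' candidate dimension `E`, the nearest neighbour of every manifold point is
#' tested for being "false" — either the extra coordinate revealed at
#' dimension `E + 1` blows up their distance by more than `rtol`, or the
#' inflated distance exceeds `atol` standard deviations of the series. The
#' smallest `E` whose false-neighbour fraction drops below `threshold` is
#' returned.
#'
#' @param x Numeric series.
#' @param lag Embedding lag used throughout the search.
#' @param max_dim Largest dimension tried; if the fraction never drops below
#'   `threshold`, `max_dim` is returned with a warning (typical for noise).
#' @param rtol Ratio test tolerance (default 10).
#' @param atol Absolute test tolerance in units of the series standard
#'   deviation (default 2).
#' @param threshold False-neighbour fraction below which a dimension is
#'   accepted (default 0.01).
#' @return An integer dimension, with attribute `fnn_fraction` holding the
#'   false-neighbour fraction per candidate dimension.
#' @export
select_dim_fnn <- function(x, lag = 1, max_dim = 10, rtol = 10, atol = 2,
                           threshold = 0.01) {
  check_series(x, "x", min_len = 1 + max_dim * lag + 1)
  check_nonconstant(x, "x")
  stopifnot(max_dim >= 2, lag >= 1)
  sigma <- sd(x)
  n <- length(x)
  fracs <- setNames(numeric(max_dim), paste0("E", seq_len(max_dim)))
  chosen <- NA_integer_
  for (E in seq_len(max_dim)) {
    # forward (predictive) convention: vectors (x_t, x_{t+lag}, ...,
    # x_{t+(E-1)lag}) and revealed coordinate x_{t+E*lag}. The backward
    # convention would test a preimage coordinate, which never resolves for
    # non-invertible maps; the forward test asks the question that matters
    # for cross mapping — do neighbours stay predictive one lag further out?
    n_pts <- n - E * lag
    m <- vapply(0:(E - 1), function(j) x[(1 + j * lag):(n_pts + j * lag)],
                numeric(n_pts))
    if (is.null(base::dim(m))) m <- matrix(m, nrow = 1)
    nn <- cpp_nn1_all(m, 0L)
    extra_t <- x[(1:n_pts) + E * lag]
    extra_n <- extra_t[nn$index]
    dE <- nn$distance
    gap <- abs(extra_t - extra_n)
    d_next <- sqrt(dE^2 + gap^2)
    false_nb <- ifelse(dE == 0, gap > 0, gap / dE > rtol) | (d_next / sigma > atol)
    # machine-precision recurrences (exactly periodic orbits) are true
    # neighbours; the ratio of two ~1e-16 distances is noise
    false_nb[d_next / sigma < 1e-8] <- FALSE
    fracs[E] <- mean(false_nb)
    if (is.na(chosen) && fracs[E] < threshold) {
      chosen <- E
      fracs <- fracs[seq_len(E)]
      break
    }
  }
  if (is.na(chosen)) {
    warn(sprintf(
      "false-neighbour fraction never dropped below %.3g up to dim %d; returning max_dim (series may be noise-dominated)",
      threshold, max_dim))
    chosen <- max_dim
  }
  structure(as.integer(chosen), fnn_fraction = fracs)
}

#' Select an embedding lag by delayed mutual information
#'
#' Computes the mutual information between \eqn{x_t} and \eqn{x_{t+\ell}} for
#' lags \eqn{\ell = 1, \dots,} `max_lag` with an equiprobable histogram
#' estimator (\eqn{\lceil\sqrt{L}\rceil} bins) and returns the lag of the
#' first interior local minimum of the curve. When the series carries no
#' detectable lag-1 dependence (the estimate is consistent with the
#' independence null at the 1% level) or no interior minimum exists, the
#' conventional fallback lag 1 is returned.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag scanned (default 20).
#' @return Integer lag with attribute `dmi` holding the mutual-information
#'   curve (nats) per lag.
#' @export
select_lag_dmi <- function(x, max_lag = 20) {
  check_series(x, "x", min_len = max_lag + 10)
  check_nonconstant(x, "x")
  stopifnot(max_lag >= 1)
  n <- length(x)
  nbins <- ceiling(sqrt(n))
  bins <- equiprobable_bins(x, nbins)
  mi <- vapply(seq_len(max_lag), function(lag) {
    a <- bins[seq_len(n - lag)]
    b <- bins[(1 + lag):n]
    mutual_information(a, b, nbins)
  }, numeric(1))
  # independence gate: the histogram estimator is biased upward, so the lag-1
  # value is compared against a permutation null (internally seeded, so the
  # selection stays deterministic for fixed input); a series with no
  # detectable lag-1 dependence falls back to lag 1
  null_mi <- withr::with_seed(271828L, vapply(seq_len(20), function(b) {
    sh <- sample(bins)
    mutual_information(sh[seq_len(n - 1)], sh[2:n], nbins)
  }, numeric(1)))
  crit <- mean(null_mi) + 4 * sd(null_mi)
  lag_sel <- 1L
  if (mi[1] >= crit && max_lag >= 3) {
    for (l in 2:(max_lag - 1)) {
      if (mi[l] < mi[l - 1] && mi[l] <= mi[l + 1]) { lag_sel <- l; break }
    }
  }
  structure(as.integer(lag_sel), dmi = setNames(mi, seq_len(max_lag)))
}

equiprobable_bins <- function(x, nbins) {
  ceiling(rank(x, ties.method = "first") * nbins / length(x))
}

mutual_information <- function(a, b, nbins) {
  joint <- table(factor(a, levels = seq_len(nbins)),
                 factor(b, levels = seq_len(nbins)))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Select both embedding parameters automatically
#'
#' Convenience wrapper: the lag comes from [select_lag_dmi()], the dimension
#' from [select_dim_fnn()] at that lag.
#'
#' @inheritParams select_dim_fnn
#' @inheritParams select_lag_dmi
#' @return A list with elements `dim` and `lag`.
#' @export
select_embedding <- function(x, max_dim = 10, max_lag = 20, rtol = 10,
                             atol = 2, threshold = 0.01) {
  lag <- select_lag_dmi(x, max_lag = max_lag)
  dim <- select_dim_fnn(x, lag = as.integer(lag), max_dim = max_dim,
                        rtol = rtol, atol = atol, threshold = threshold)
  list(dim = as.integer(dim), lag = as.integer(lag))
}
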