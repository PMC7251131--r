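# Independent reference implementations used as oracles. These are direct,
# loop-based transcriptions of the defining formulas, deliberately kept apart
# from the package's (vectorised / compiled) code paths.

# Partial correlation by the textbook recursion: peel conditioners one at a
# time, Pcc(x,y|S) from the three Pcc's with the last conditioner removed.
oracle_pcc_recursive <- function(x, y, conds) {
  if (length(conds) == 0) return(cor(x, y))
  z <- conds[[length(conds)]]
  rest <- conds[-length(conds)]
  rxy <- oracle_pcc_recursive(x, y, rest)
  rxz <- oracle_pcc_recursive(x, z, rest)
  ryz <- oracle_pcc_recursive(y, z, rest)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Brute-force k nearest neighbours of row i (times are row indices here).
oracle_knn <- function(points, i, k, exclusion = 0) {
  n <- nrow(points)
  d <- sqrt(rowSums((points - matrix(points[i, ], n, ncol(points),
                                     byrow = TRUE))^2))
  elig <- which(abs(seq_len(n) - i) > exclusion)
  ord <- elig[order(d[elig], elig)]
  list(index = ord[seq_len(k)], distance = d[ord[seq_len(k)]])
}

# AUROC as the midrank Mann-Whitney statistic.
oracle_auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kennel false-nearest-neighbour fraction at dimension E (forward
# convention), written as plain loops over points.
oracle_fnn_fraction <- function(x, E, lag, rtol = 10, atol = 2) {
  n <- length(x)
  times <- 1:(n - E * lag)
  emb <- function(t, dim) x[t + (0:(dim - 1)) * lag]
  sigma <- sd(x)
  n_false <- 0
  for (t in times) {
    best_d <- Inf; best_s <- NA
    for (s in times) {
      if (s == t) next
      d <- sqrt(sum((emb(t, E) - emb(s, E))^2))
      if (d < best_d) { best_d <- d; best_s <- s }
    }
    gap <- abs(x[t + E * lag] - x[best_s + E * lag])
    is_false <- if (best_d == 0) gap > 0 else gap / best_d > rtol
    if (sqrt(best_d^2 + gap^2) / sigma > atol) is_false <- TRUE
    if (sqrt(best_d^2 + gap^2) / sigma < 1e-8) is_false <- FALSE
    if (is_false) n_false <- n_false + 1
  }
  n_false / length(times)
}

# Delayed mutual information curve via the entropy identity
# I = H(a) + H(b) - H(a, b), with the package's equiprobable binning.
oracle_dmi_curve <- function(x, max_lag) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  bins <- ceiling(rank(x, ties.method = "first") * nb / n)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  vapply(seq_len(max_lag), function(lag) {
    a <- bins[seq_len(n - lag)]
    b <- bins[(1 + lag):n]
    ent(table(a)) + ent(table(b)) - ent(table(paste(a, b)))
  }, numeric(1))
}

# Chaotic logistic-map orbit (x_{t+1} = r x_t (1 - x_t)), for fixtures.
logistic_orbit <- function(n, r = 3.99, x0 = 0.3141, burn = 100) {
  x <- x0
  out <- numeric(n + burn)
  for (t in seq_len(n + burn)) {
    x <- r * x * (1 - x)
    out[t] <- x
  }
  out[(burn + 1):(n + burn)]
}
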