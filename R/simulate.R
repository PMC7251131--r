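#' Simulate a network of coupled noisy logistic maps
#'
#' Iterates the coupled logistic system
#' \deqn{x^j_t = x^j_{t-1}\bigl(\alpha_j - \alpha_j x^j_{t-1} -
#'   \textstyle\sum_i \beta_{ji}\, x^i_{t-1}\bigr) + \epsilon_{j,t}}
#' with independent Gaussian noise \eqn{\epsilon_{j,t} \sim N(0,
#' \mathrm{noise\_sd}^2)} drawn fresh per node per step. The ground-truth
#' causal graph is exactly the support of the coupling matrix: an edge
#' \eqn{i \to j} exists iff `beta[j, i] != 0`; recover it with
#' [truth_graph()].
#'
#' @param alpha Numeric vector of per-node growth rates; its names (or
#'   `x1 ... xn`) become the column names.
#' @param beta Square coupling matrix, `beta[j, i]` = strength of node `i`'s
#'   influence on node `j`.
#' @param length Number of retained time steps after burn-in.
#' @param noise_sd Standard deviation of the dynamical noise (0 for a
#'   deterministic run).
#' @param burn_in Transient steps discarded before recording.
#' @param x0 Initial state in `(0, 1)^n`; drawn uniformly from `(0.2, 0.8)`
#'   (seeded) when `NULL`.
#' @param seed Integer seed for the initial state and the noise; `NULL` uses
#'   the current RNG state.
#' @return A tibble with a `time` column and one column per node, of class
#'   `pcm_sim`. The coupling matrix, growth rates and noise level are attached
#'   as attributes. Trajectories leaving the guard band `(-0.5, 1.5)` or
#'   becoming non-finite raise a divergence error naming the step.
#' @export
simulate_network <- function(alpha, beta, length = 5000, noise_sd = 0.005,
                             burn_in = 1000, x0 = NULL, seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) >= 2,
            is.matrix(beta), nrow(beta) == length(alpha),
            ncol(beta) == length(alpha),
            length >= 1, burn_in >= 0, noise_sd >= 0)
  run <- function() {
    p <- base::length(alpha)
    x <- x0 %||% runif(p, 0.2, 0.8)
    stopifnot(base::length(x) == p, all(x > 0), all(x < 1))
    n_total <- length + burn_in
    out <- matrix(NA_real_, n_total, p)
    for (t in seq_len(n_total)) {
      eps <- if (noise_sd > 0) rnorm(p, 0, noise_sd) else numeric(p)
      x <- x * (alpha - alpha * x - as.vector(beta %*% x)) + eps
      if (!all(is.finite(x)) || any(x <= -0.5) || any(x >= 1.5))
        abort(sprintf(
          "trajectory diverged at step %d (state left the (-0.5, 1.5) guard band); the parameter set is rejected",
          t), class = "pcmap_divergence_error")
      out[t, ] <- x
    }
    out[(burn_in + 1):n_total, , drop = FALSE]
  }
  m <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  nms <- names(alpha) %||% paste0("x", seq_along(alpha))
  dimnames(beta) <- list(nms, nms)
  out <- as_tibble(as.data.frame(m))
  names(out) <- nms
  out <- dplyr::bind_cols(tibble(time = seq_len(nrow(out))), out)
  structure(out, alpha = setNames(alpha, nms), beta = beta,
            noise_sd = noise_sd,
            class = c("pcm_sim", class(out)))
}

#' Simulate the three-species logistic benchmark
#'
#' The benchmark system of three interacting species
#' \deqn{x_t = x_{t-1}(\alpha_x - \alpha_x x_{t-1} - \beta_{xy} y_{t-1}) + \epsilon_{x,t}}
#' \deqn{y_t = y_{t-1}(\alpha_y - \alpha_y y_{t-1} - \beta_{yx} x_{t-1} - \beta_{yz} z_{t-1}) + \epsilon_{y,t}}
#' \deqn{z_t = z_{t-1}(\alpha_z - \alpha_z z_{t-1} - \beta_{zx} x_{t-1}) + \epsilon_{z,t}}
#' with growth rates \eqn{\alpha = (3.6, 3.72, 3.68)} and white noise of sd
#' 0.005. The interaction mode presets set the active couplings (all at
#' `coupling`):
#' \describe{
#'   \item{`direct`}{\eqn{\beta_{yx}} active: X → Y, Z isolated.}
#'   \item{`chain`}{\eqn{\beta_{zx}, \beta_{yz}} active: the unidirectional
#'     chain X → Z → Y, so X → Y is indirect only.}
#'   \item{`loop`}{\eqn{\beta_{xy}, \beta_{yz}, \beta_{zx}} active: the causal
#'     loop X → Z → Y → X; every neighbouring pair has a direct link one way
#'     and an indirect link the other way.}
#'   \item{`custom`}{supply a full 3x3 `beta` (rows = target, columns =
#'     source, order x, y, z).}
#' }
#'
#' @param mode One of `"direct"`, `"chain"`, `"loop"`, `"custom"`.
#' @param coupling Common magnitude for the active couplings (default 0.4).
#' @param beta Full coupling matrix, only for `mode = "custom"`.
#' @param alpha Growth rates, order (x, y, z).
#' @inheritParams simulate_network
#' @return A `pcm_sim` tibble with columns `time`, `x`, `y`, `z`; see
#'   [simulate_network()] and [truth_graph()].
#' @examples
#' sim <- simulate_three_species("chain", length = 500, seed = 7)
#' truth_graph(sim)
#' @export
simulate_three_species <- function(mode = c("direct", "chain", "loop", "custom"),
                                   length = 5000, coupling = 0.4, beta = NULL,
                                   alpha = c(x = 3.6, y = 3.72, z = 3.68),
                                   noise_sd = 0.005, burn_in = 1000,
                                   x0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(alpha) == 3)
  names(alpha) <- c("x", "y", "z")
  if (mode == "custom") {
    if (is.null(beta) || !is.matrix(beta) || any(dim(beta) != 3))
      abort("mode = \"custom\" requires a 3x3 `beta` matrix (rows = target, cols = source)")
  } else {
    if (!is.null(beta))
      abort("supply `beta` only with mode = \"custom\"; presets use `coupling`")
    beta <- matrix(0, 3, 3)
    active <- switch(mode,
      direct = list(c("y", "x")),                         # beta_yx
      chain  = list(c("z", "x"), c("y", "z")),            # beta_zx, beta_yz
      loop   = list(c("x", "y"), c("y", "z"), c("z", "x"))# beta_xy, beta_yz, beta_zx
    )
    dimnames(beta) <- list(c("x", "y", "z"), c("x", "y", "z"))
    for (e in active) beta[e[1], e[2]] <- coupling
  }
  simulate_network(alpha, beta, length = length, noise_sd = noise_sd,
                   burn_in = burn_in, x0 = x0, seed = seed)
}

#' Simulate the noise-free causal chain
#'
#' The deterministic three-species chain X → Z → Y,
#' \deqn{x_t = x_{t-1}(\alpha_x - \alpha_x x_{t-1})}
#' \deqn{z_t = z_{t-1}(\alpha_z - \alpha_z z_{t-1} - \beta_{zx} x_{t-1})}
#' \deqn{y_t = y_{t-1}(\alpha_y - \alpha_y y_{t-1} - \beta_{yz} z_{t-1})}
#' used to demonstrate causation transitivity: algebraic substitution shows
#' that Y depends on X two steps back even though no direct X → Y coupling
#' exists, so pairwise cross mapping flags a (spurious) X → Y link that
#' partial cross mapping removes. With a fixed `x0` the trajectory is a
#' deterministic function of the parameters; `seed` only affects the initial
#' state draw when `x0` is `NULL`.
#'
#' @param beta_zx,beta_yz Nonzero chain couplings.
#' @inheritParams simulate_three_species
#' @return A `pcm_sim` tibble; truth graph is exactly \{X → Z, Z → Y\}.
#' @export
simulate_chain_noise_free <- function(length = 5000, beta_zx = 0.4,
                                      beta_yz = 0.4,
                                      alpha = c(x = 3.6, y = 3.72, z = 3.68),
                                      burn_in = 1000, x0 = NULL, seed = NULL) {
  b <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  b["z", "x"] <- beta_zx
  b["y", "z"] <- beta_yz
  simulate_three_species("custom", length = length, beta = b, alpha = alpha,
                         noise_sd = 0, burn_in = burn_in, x0 = x0, seed = seed)
}

#' Default eight-node benchmark topology (synthetic stand-in)
#'
#' A documented sparse eight-node directed topology — a ring
#' `x1 -> x2 -> ... -> x8 -> x1` plus two chords (`x1 -> x5`, `x4 -> x7`), ten
#' edges in all — used as the default network benchmark. It is a synthetic
#' stand-in chosen for sparsity and for mixing short and long indirect paths;
#' it does not reproduce any published network. The default coupling 0.2 keeps
#' nodes with two incoming edges inside the stable band of the logistic maps.
#'
#' @param coupling Common coupling strength (default 0.2).
#' @return A list with elements `alpha` (named growth rates, cycling through
#'   3.55–3.78) and `beta` (8x8 coupling matrix).
#' @export
default_network_params <- function(coupling = 0.2) {
  nms <- paste0("x", 1:8)
  alpha <- setNames(c(3.60, 3.72, 3.68, 3.62, 3.76, 3.58, 3.70, 3.66), nms)
  beta <- matrix(0, 8, 8, dimnames = list(nms, nms))
  ring <- cbind(1:8, c(2:8, 1))                   # i -> i+1
  for (i in seq_len(nrow(ring))) beta[ring[i, 2], ring[i, 1]] <- coupling
  beta["x5", "x1"] <- coupling
  beta["x7", "x4"] <- coupling
  list(alpha = alpha, beta = beta)
}

#' Ground-truth causal graph of a simulation
#'
#' Derives the directed edge list from the coupling matrix attached to a
#' [simulate_network()] / [simulate_three_species()] result: `i -> j` iff
#' `beta[j, i] != 0`. The graph is always derived from the matrix, never
#' stored separately, so it cannot drift from the dynamics.
#'
#' @param sim A `pcm_sim` tibble.
#' @return A tibble with columns `source`, `target`, `strength`, sorted by
#'   source then target.
#' @export
truth_graph <- function(sim) {
  beta <- attr(sim, "beta")
  if (is.null(beta)) abort("`sim` carries no coupling matrix; not a pcm_sim?")
  idx <- which(beta != 0, arr.ind = TRUE)
  out <- tibble(source = colnames(beta)[idx[, "col"]],
                target = rownames(beta)[idx[, "row"]],
                strength = beta[idx])
  dplyr::arrange(out, .data$source, .data$target)
}

#' Draw aligned random trials from a long simulation
#'
#' Samples `n_trials` segments of `segment_length` consecutive steps, each at
#' a uniformly random start offset shared across all variables of the trial
#' (the benchmark protocol: 100 random length-1000 segments of a length-5000
#' run).
#'
#' @param data A data frame of aligned series (a `time` column, if present,
#'   is carried along).
#' @param n_trials Number of segments to draw.
#' @param segment_length Length of each segment; at most `nrow(data)`.
#' @param seed Integer seed for the offset draw.
#' @return A list of `n_trials` tibbles; the start offsets are attached as
#'   attribute `offsets`.
#' @export
sample_trials <- function(data, n_trials = 100, segment_length = 1000,
                          seed = NULL) {
  stopifnot(is.data.frame(data), n_trials >= 1)
  L <- nrow(data)
  if (segment_length > L)
    abort(sprintf("segment_length %d exceeds series length %d",
                  segment_length, L))
  draw <- function() sample.int(L - segment_length + 1, n_trials,
                                replace = TRUE)
  offs <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  trials <- lapply(offs, function(o) data[o:(o + segment_length - 1), ])
  structure(trials, offsets = offs)
}
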