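#' Nearest neighbours of a shadow-manifold point
#'
#' Returns the `k` nearest manifold points to the point at original time `t`
#' under Euclidean distance. Points within `exclusion` time steps of `t` are
#' barred (a Theiler window); with the default `exclusion = 0` only the query
#' point itself is excluded. Distance ties break toward the smaller time
#' index.
#'
#' @param manifold A `shadow_manifold` from [delay_embed()].
#' @param t Original (1-based) time index of the query point; must be at or
#'   after the manifold's `first_valid` time.
#' @param k Number of neighbours (the simplex default is `E + 1`).
#' @param exclusion Half-width of the temporal exclusion window.
#' @return A tibble with columns `time` and `distance`, sorted by distance.
#' @export
neighbors <- function(manifold, t, k = NULL, exclusion = 0) {
  stopifnot(inherits(manifold, "shadow_manifold"))
  E <- attr(manifold, "dim_embed")
  k <- k %||% (E + 1L)
  fv <- attr(manifold, "first_valid")
  n <- nrow(manifold)
  if (t < fv || t > fv + n - 1)
    abort(sprintf("query time %d outside manifold support [%d, %d]", t, fv, fv + n - 1))
  if (n < k + 1)
    abort(sprintf("manifold has %d points; need at least k + 1 = %d", n, k + 1))
  res <- cpp_neighbors(manifold_matrix(manifold), t - fv + 1L, as.integer(k),
                       as.integer(exclusion))
  tibble(time = res$index + fv - 1L, distance = res$distance)
}

#' Simplex weights from neighbour distances
#'
#' Exponentially decaying weights over a neighbour set:
#' \eqn{w_i \propto \exp(-d_i / d_{\min})} with \eqn{d_{\min}} the smallest
#' nonzero distance, normalised to sum to one. If any distance is exactly
#' zero, the weight mass is spread uniformly over the zero-distance entries
#' only (an exact match dominates).
#'
#' @param distances Non-negative numeric vector of neighbour distances.
#' @return Numeric weights, non-negative, summing to 1, non-increasing in
#'   distance.
#' @examples
#' simplex_weights(c(1, 2))
#' simplex_weights(c(0, 1, 2)) # exact match takes all the mass
#' @export
simplex_weights <- function(distances) {
  if (!is.numeric(distances) || length(distances) < 1)
    abort("`distances` must be a non-empty numeric vector")
  if (any(!is.finite(distances)) || any(distances < 0))
    abort("`distances` must be finite and non-negative")
  if (any(distances == 0)) {
    w <- as.numeric(distances == 0)
  } else {
    w <- exp(-distances / min(distances))
  }
  w / sum(w)
}

# ---- internal cross-map engine ------------------------------------------
# Series are carried as (values, start) pairs: values[i] sits at time
# start + i - 1 on the shared 1-based time axis.

# Cross map `u` from the shadow manifold of `v` on their common support.
# The support starts at max of both manifolds' first-valid times (r_u covers
# the cause side, whose manifold must also exist at every support time).
# Returns the estimate series, its start time, and rho = |cor(u, u_hat)|.
cm_core <- function(u, u_start, v, v_start, dim_v, lag_v, r_u, k, exclusion,
                    min_support, stage = "cross_map") {
  t0 <- max(u_start, v_start)
  t1 <- min(u_start + length(u) - 1, v_start + length(v) - 1)
  r_v <- 1 + (dim_v - 1) * lag_v
  r <- max(r_v, r_u)
  n_pts <- t1 - t0 + 1 - r + 1
  if (n_pts < max(min_support, k + 2))
    abort(sprintf(
      "[%s] support too small: %d usable points (need >= %d); series overlap [%d, %d], embedding needs %d leading points",
      stage, max(n_pts, 0), max(min_support, k + 2), t0, t1, r - 1),
      class = "pcmap_support_error")
  ua <- u[(t0 - u_start + 1):(t1 - u_start + 1)]
  va <- v[(t0 - v_start + 1):(t1 - v_start + 1)]
  mv <- embed_matrix(va, dim_v, lag_v)
  if (r > r_v) mv <- mv[(r - r_v + 1):nrow(mv), , drop = FALSE]
  uu <- ua[r:length(ua)]
  if (sd(uu) == 0 || sd(va) == 0)
    abort(sprintf("[%s] zero-variance series; correlation undefined", stage),
          class = "pcmap_degenerate_error")
  est <- cpp_cross_map_estimate(mv, uu, as.integer(k), as.integer(exclusion))
  if (sd(est) == 0)
    abort(sprintf("[%s] cross-map estimate has zero variance; correlation undefined", stage),
          class = "pcmap_degenerate_error")
  list(est = est, est_start = t0 + r - 1, rho = abs(cor(uu, est)),
       support = c(t0 + r - 1, t1))
}

# Delay-scanned cross map: the library-side series v is translated by each
# candidate delay d (v'_t = v_{t+d}, i.e. start shifts to v_start - d) and the
# best |cor| wins. Ties break toward the smallest |d|, then the negative one.
cm_scan <- function(u, u_start, v, v_start, dim_v, lag_v, r_u, k, exclusion,
                    delays, min_support, stage = "cross_map") {
  stopifnot(length(delays) >= 1)
  delays <- sort(unique(as.integer(delays)))
  rho_by_delay <- setNames(rep(NA_real_, length(delays)), delays)
  best <- NULL
  first_err <- NULL
  for (d in delays) {
    res <- tryCatch(
      cm_core(u, u_start, v, v_start - d, dim_v, lag_v, r_u, k, exclusion,
              min_support, stage),
      pcmap_support_error = function(e) {
        if (is.null(first_err)) first_err <<- conditionMessage(e)
        NULL
      })
    if (is.null(res)) next
    rho_by_delay[as.character(d)] <- res$rho
    take <- is.null(best) || res$rho > best$rho ||
      (res$rho == best$rho &&
         (abs(d) < abs(best$delay) || (abs(d) == abs(best$delay) && d < best$delay)))
    if (take) best <- c(res, list(delay = d))
  }
  if (is.null(best))
    abort(sprintf("[%s] no candidate delay leaves enough overlapping support (%s)",
                  stage, first_err %||% "no feasible delay"),
          class = "pcmap_support_error")
  best$rho_by_delay <- rho_by_delay
  best
}

new_cross_map_result <- function(best, cause, effect, dim, lag, k, exclusion) {
  structure(list(
    cause = cause, effect = effect,
    rho = best$rho, best_delay = best$delay,
    rho_by_delay = tibble(delay = as.integer(names(best$rho_by_delay)),
                          rho = unname(best$rho_by_delay)),
    estimate = tibble(time = seq(best$est_start, by = 1,
                                 length.out = length(best$est)),
                      value = best$est),
    support = best$support,
    params = list(dim = dim, lag = lag, k = k, exclusion = exclusion)
  ), class = "cross_map_result")
}

#' Cross map one variable from another's shadow manifold
#'
#' Mutual cross mapping (MCM): for each point of the effect variable's shadow
#' manifold, the simplex-weighted average of the cause variable's values at
#' the neighbour times yields an estimate \eqn{\hat u_t}; the causal index is
#' \eqn{\varrho_C = |\mathrm{Corr}(u_t, \hat u_t)|} over the common support.
#' High skill in recovering the cause from the effect's manifold indicates a
#' causal influence cause → effect.
#'
#' `cross_map()` evaluates a single (zero-delay) map; [cross_map_delay_scan()]
#' scans candidate delays and keeps the strongest.
#'
#' @param data Data frame with one numeric column per variable.
#' @param cause,effect Column names (strings) of the putative cause and effect.
#' @param dim,lag Embedding dimension and lag applied to both variables
#'   (scalars, or length-2 vectors `c(cause, effect)`).
#' @param k Number of neighbours; default `E + 1` (minimal bounding simplex).
#' @param exclusion Theiler exclusion half-width (default 0: only the query
#'   point is excluded).
#' @param min_support Minimum number of overlapping support points required.
#' @return A `cross_map_result`: the estimate series, `rho`, the per-delay
#'   curve, and the selected delay. Use [tidy()] / [glance()] to extract
#'   tibbles.
#' @examples
#' sim <- simulate_three_species("chain", length = 400, seed = 1)
#' cross_map(sim, "x", "y", dim = 4, lag = 1)$rho
#' @export
cross_map <- function(data, cause, effect, dim = 4, lag = 1, k = NULL,
                      exclusion = 0, min_support = 20) {
  cross_map_delay_scan(data, cause, effect, delays = 0L, dim = dim, lag = lag,
                       k = k, exclusion = exclusion, min_support = min_support)
}

#' Delay-scanned cross mapping
#'
#' Runs [cross_map()] against each translated effect series
#' \eqn{\{v_{t+\tau_i}\}} for every candidate delay and retains the delay
#' maximising \eqn{|\mathrm{Corr}|}; causal influence manifests at a
#' characteristic delay, so scanning strengthens detection. Ties break toward
#' the smallest absolute delay, preferring the negative one.
#'
#' @inheritParams cross_map
#' @param delays Integer vector of candidate delays (default `-5:5`).
#' @return A `cross_map_result`; `rho` equals the maximum of `rho_by_delay`.
#' @export
cross_map_delay_scan <- function(data, cause, effect, delays = -5:5, dim = 4,
                                 lag = 1, k = NULL, exclusion = 0,
                                 min_support = 20) {
  cols <- get_columns(data, c(cause, effect))
  dim <- rep_len(as.integer(dim), 2)
  lag <- rep_len(as.integer(lag), 2)
  k <- as.integer(k %||% (dim[2] + 1L))
  r_u <- 1L + (dim[1] - 1L) * lag[1]
  best <- cm_scan(cols[[cause]], 1L, cols[[effect]], 1L, dim[2], lag[2], r_u,
                  k, exclusion, delays, min_support,
                  stage = sprintf("%s<-M(%s)", cause, effect))
  new_cross_map_result(best, cause, effect, dim[2], lag[2], k, exclusion)
}

#' @export
print.cross_map_result <- function(x, ...) {
  cat(sprintf("<cross_map_result> %s -> %s\n", x$cause, x$effect))
  cat(sprintf("  rho = %.4f at delay %d (scanned %d delays)\n",
              x$rho, x$best_delay, nrow(x$rho_by_delay)))
  cat(sprintf("  support: [%d, %d] (%d points), E = %d, tau = %d, k = %d\n",
              x$support[1], x$support[2], nrow(x$estimate),
              x$params$dim, x$params$lag, x$params$k))
  invisible(x)
}

#' @rdname cross_map
#' @param x A `cross_map_result`.
#' @param ... Unused.
#' @method tidy cross_map_result
#' @export
tidy.cross_map_result <- function(x, ...) x$rho_by_delay

#' @rdname cross_map
#' @method glance cross_map_result
#' @export
glance.cross_map_result <- function(x, ...) {
  tibble(cause = x$cause, effect = x$effect, rho = x$rho,
         best_delay = x$best_delay, n_support = nrow(x$estimate))
}
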