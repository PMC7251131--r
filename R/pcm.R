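#' Configuration for partial cross mapping
#'
#' Collects every tunable of the PCM pipeline in one validated object.
#'
#' @param dim Embedding dimension `E`; a scalar, or a named vector giving a
#'   dimension per variable (benchmark default 4).
#' @param lag Embedding lag `tau`, scalar or named per variable (default 1).
#' @param delays Integer candidate delays scanned in every cross-map stage
#'   (default `-5:5`).
#' @param k Neighbours per simplex; `NULL` means `E + 1` of the library-side
#'   variable (the minimal bounding simplex).
#' @param exclusion Theiler exclusion half-width (default 0: only the query
#'   point excluded).
#' @param threshold Decision threshold `T` in (0, 1) (default 0.5).
#' @param order Highest conditioning order computed; 1 conditions on single
#'   mediators (default), higher orders add nested mediator chains.
#' @param surrogates Number of circular time-shift surrogates for significance
#'   (0 disables testing).
#' @param seed Integer seed; child seeds for each stochastic stage are derived
#'   from it so runs are reproducible end to end.
#' @param conditioning Strategy for network inference: `"all"` conditions on
#'   every other variable jointly; `"top_score"` on the `top_q` mediators with
#'   the largest \eqn{\varrho_C^{X\to Z} + \varrho_C^{Z\to Y}};
#'   `"sparse_min"` conditions on each mediator singly and keeps the minimum
#'   \eqn{\varrho_D}.
#' @param top_q Number of mediators kept by `"top_score"` (default 3).
#' @param min_support Minimum overlapping support for any correlation
#'   (default 20).
#' @param max_chains Refusal cap on the number of nested mediator chains a
#'   higher-order computation may build (default 60).
#' @return A list of class `pcm_config`.
#' @export
pcm_config <- function(dim = 4, lag = 1, delays = -5:5, k = NULL,
                       exclusion = 0, threshold = 0.5, order = 1,
                       surrogates = 0, seed = NULL,
                       conditioning = c("all", "top_score", "sparse_min"),
                       top_q = 3, min_support = 20, max_chains = 60) {
  conditioning <- match.arg(conditioning)
  stopifnot(all(dim >= 1), all(lag >= 1), length(delays) >= 1,
            threshold > 0, threshold < 1, order >= 1, surrogates >= 0,
            min_support >= 3, max_chains >= 1, top_q >= 1)
  structure(list(dim = setNames(as.integer(dim), names(dim)),
                 lag = setNames(as.integer(lag), names(lag)),
                 delays = as.integer(delays),
                 k = if (is.null(k)) NULL else as.integer(k),
                 exclusion = as.integer(exclusion),
                 threshold = as.numeric(threshold), order = as.integer(order),
                 surrogates = as.integer(surrogates),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 conditioning = conditioning, top_q = as.integer(top_q),
                 min_support = as.integer(min_support),
                 max_chains = as.integer(max_chains)),
            class = "pcm_config")
}

cfg_dim <- function(config, var) {
  d <- config$dim
  as.integer(if (!is.null(names(d)) && var %in% names(d)) d[[var]] else d[[1]])
}
cfg_lag <- function(config, var) {
  l <- config$lag
  as.integer(if (!is.null(names(l)) && var %in% names(l)) l[[var]] else l[[1]])
}
cfg_k <- function(config, lib_var) {
  as.integer(config$k %||% (cfg_dim(config, lib_var) + 1L))
}

# Delay-scanned cross map of `u` (cause side, values only) from the manifold
# of `v`; spec_var names the variable whose embedding describes v's manifold.
scan_stage <- function(u, u_start, v, v_start, u_var, v_var, config, stage) {
  cm_scan(u, u_start, v, v_start,
          dim_v = cfg_dim(config, v_var), lag_v = cfg_lag(config, v_var),
          r_u = 1L + (cfg_dim(config, u_var) - 1L) * cfg_lag(config, u_var),
          k = cfg_k(config, v_var), exclusion = config$exclusion,
          delays = config$delays, min_support = config$min_support,
          stage = stage)
}

# Core of Procedure B for one ordered pair, returning indices and
# intermediates. `s1_cache` lets callers (surrogate testing, network loops)
# reuse the mediator stages that do not involve the cause series.
pcm_engine <- function(x, y, zs, cause, effect, config,
                       s1_cache = NULL, s3 = NULL) {
  s1 <- s1_cache %||% lapply(names(zs), function(znm)
    scan_stage(zs[[znm]], 1L, y, 1L, znm, effect, config,
               stage = sprintf("Zhat^Y (%s from %s)", znm, effect)))
  names(s1) <- names(zs)
  s2 <- lapply(names(zs), function(znm)
    scan_stage(x, 1L, s1[[znm]]$est, s1[[znm]]$est_start, cause, znm, config,
               stage = sprintf("Xhat^(Zhat^Y) via %s", znm)))
  names(s2) <- names(zs)
  s3 <- s3 %||% scan_stage(x, 1L, y, 1L, cause, effect, config,
                           stage = sprintf("Xhat^Y (%s from %s)", cause, effect))
  t0 <- max(c(1L, s3$est_start, vapply(s2, `[[`, 1, "est_start")))
  t1 <- min(c(length(x), s3$est_start + length(s3$est) - 1L,
              vapply(s2, function(s) s$est_start + length(s$est) - 1L, 1)))
  if (t1 - t0 + 1 < config$min_support)
    abort(sprintf(
      "[alignment] common support of X, Xhat^Y and conditioning estimates is %d points (need >= %d)",
      t1 - t0 + 1, config$min_support), class = "pcmap_support_error")
  xa <- x[t0:t1]
  e3 <- s3$est[(t0 - s3$est_start + 1):(t1 - s3$est_start + 1)]
  conds <- lapply(s2, function(s)
    s$est[(t0 - s$est_start + 1):(t1 - s$est_start + 1)])
  rho_C <- abs(cor(xa, e3))
  rho_D1 <- abs(partial_corr(xa, e3, conds))
  list(rho_C = rho_C, rho_D1 = rho_D1, s1 = s1, s2 = s2, s3 = s3,
       align = c(t0, t1), xa = xa, e3 = e3, conds = conds)
}

#' Partial cross mapping for one ordered pair
#'
#' The PCM estimator of direct causation cause → effect, conditioning on one
#' or more candidate mediators. Three delay-optimised cross maps are built:
#' the mediator estimate \eqn{\hat Z^Y} (mediator from the effect's
#' manifold), the routed estimate \eqn{\hat X^{\hat Z^Y}} (cause from the
#' manifold of \eqn{\hat Z^Y}, carrying only the information that flows
#' through the mediator), and the full estimate \eqn{\hat X^Y}. On their
#' common support,
#' \deqn{\varrho_C = |\mathrm{Corr}(X, \hat X^Y)|, \qquad
#'       \varrho_D = |\mathrm{Pcc}(X, \hat X^Y \mid \hat X^{\hat Z^Y})|,}
#' with multiple mediators conditioned jointly. A direct link keeps
#' \eqn{\varrho_D} high; a purely indirect link collapses it. The decision
#' compares \eqn{\varrho_C} and the smallest computed \eqn{\varrho_D} against
#' the threshold `T` (see [classify_link()]).
#'
#' @param data Data frame with one numeric column per variable.
#' @param cause,effect Column names of the ordered pair under test.
#' @param conditioners Character vector of mediator column names; defaults to
#'   every other numeric column (at least one is required).
#' @param config A [pcm_config()].
#' @return A `pcm_result`: indices `rho_C`, `rho_D` (one value per computed
#'   order), `gamma`, the `decision`, per-stage best delays, intermediate
#'   estimate series, and (when `config$surrogates > 0`) surrogate p-values.
#'   Use [tidy()] / [glance()] for tibble views.
#' @examples
#' sim <- simulate_three_species("chain", length = 600, seed = 3)
#' res <- pcm_pair(sim, "x", "y", "z", pcm_config(dim = 4, lag = 1))
#' glance(res)
#' @export
pcm_pair <- function(data, cause, effect, conditioners = NULL,
                     config = pcm_config()) {
  stopifnot(inherits(config, "pcm_config"))
  conditioners <- conditioners %||%
    setdiff(names(data)[vapply(data, is.numeric, TRUE)],
            c(cause, effect, "time"))
  if (length(conditioners) < 1)
    abort("at least one conditioning variable is required")
  cols <- get_columns(data, unique(c(cause, effect, conditioners)))
  x <- cols[[cause]]; y <- cols[[effect]]
  zs <- cols[conditioners]
  if (config$order > length(zs))
    abort(sprintf("order %d exceeds the number of conditioners (%d)",
                  config$order, length(zs)))
  eng <- pcm_engine(x, y, zs, cause, effect, config)
  rho_D <- c(`1` = eng$rho_D1)
  if (config$order > 1) {
    for (n in 2:config$order)
      rho_D[as.character(n)] <- higher_order_rho(x, y, zs, cause, effect,
                                                 config, n, eng)
  }
  gamma <- gamma_index(eng$rho_C, rho_D)
  decision <- classify_link(eng$rho_C, min(rho_D), config$threshold)
  surrogate <- NULL
  if (config$surrogates > 0)
    surrogate <- surrogate_pvalues(x, y, zs, cause, effect, config, eng)
  best_delays <- dplyr::bind_rows(
    tibble(stage = "Zhat^Y", conditioner = names(eng$s1),
           delay = vapply(eng$s1, `[[`, 1L, "delay")),
    tibble(stage = "Xhat^ZhatY", conditioner = names(eng$s2),
           delay = vapply(eng$s2, `[[`, 1L, "delay")),
    tibble(stage = "Xhat^Y", conditioner = NA_character_,
           delay = eng$s3$delay))
  intermediates <- c(
    setNames(lapply(names(eng$s1), function(z) est_tibble(eng$s1[[z]])),
             paste0("Zhat^Y.", names(eng$s1))),
    setNames(lapply(names(eng$s2), function(z) est_tibble(eng$s2[[z]])),
             paste0("Xhat^ZhatY.", names(eng$s2))),
    list("Xhat^Y" = est_tibble(eng$s3)))
  structure(list(
    cause = cause, effect = effect, conditioners = conditioners,
    rho_C = eng$rho_C, rho_D = rho_D, gamma = gamma, decision = decision,
    best_delays = best_delays, surrogate = surrogate,
    p_value = if (!is.null(surrogate)) surrogate$p_value[surrogate$index == "rho_D"] else NA_real_,
    intermediates = intermediates, align = eng$align, config = config
  ), class = "pcm_result")
}

est_tibble <- function(s) {
  tibble(time = seq(s$est_start, by = 1, length.out = length(s$est)),
         value = s$est)
}

# All ordered chains of `n` distinct mediators, as a list of index vectors.
ordered_chains <- function(s, n) {
  if (n == 1) return(as.list(seq_len(s)))
  sub <- ordered_chains(s, n - 1)
  out <- list()
  for (ch in sub)
    for (i in setdiff(seq_len(s), ch)) out[[length(out) + 1]] <- c(ch, i)
  out
}

higher_order_rho <- function(x, y, zs, cause, effect, config, n, eng) {
  s <- length(zs)
  chains <- ordered_chains(s, n)
  if (length(chains) > config$max_chains)
    abort(sprintf(
      "order-%d conditioning needs %d mediator chains, exceeding max_chains = %d; raise the cap explicitly or lower the order",
      n, length(chains), config$max_chains))
  scans <- lapply(chains, function(ch) {
    # chain (i_1, ..., i_n): innermost mediator is cross mapped from the
    # effect, each further mediator from the previous estimate, the cause last
    znm <- names(zs)[ch[n]]
    cur <- scan_stage(zs[[znm]], 1L, y, 1L, znm, effect, config,
                      stage = sprintf("chain Zhat^Y (%s)", znm))
    if (n >= 2) for (j in (n - 1):1) {
      znm_j <- names(zs)[ch[j]]
      cur <- scan_stage(zs[[znm_j]], 1L, cur$est, cur$est_start, znm_j, znm,
                        config, stage = sprintf("chain link %s", znm_j))
      znm <- znm_j
    }
    scan_stage(x, 1L, cur$est, cur$est_start, cause, znm, config,
               stage = sprintf("chain Xhat (%s)",
                               paste(names(zs)[ch], collapse = ">")))
  })
  # nested estimates have narrower supports than the first-order window;
  # align everything on the common intersection
  t0 <- max(c(eng$align[1], vapply(scans, `[[`, 1, "est_start")))
  t1 <- min(c(eng$align[2], vapply(scans, function(s)
    s$est_start + length(s$est) - 1, 1)))
  if (t1 - t0 + 1 < config$min_support)
    abort(sprintf(
      "[higher order] common support of chain estimates is %d points (need >= %d)",
      t1 - t0 + 1, config$min_support), class = "pcmap_support_error")
  ests <- lapply(scans, function(s)
    s$est[(t0 - s$est_start + 1):(t1 - s$est_start + 1)])
  off <- (t0 - eng$align[1] + 1):(t1 - eng$align[1] + 1)
  abs(partial_corr(eng$xa[off], eng$e3[off], ests))
}

#' Higher-order PCM index
#'
#' The order-`n` index \eqn{\varrho_{D_n}}: for every ordered chain of `n`
#' distinct mediators, the nested, delay-optimised cross-map estimate of the
#' cause routed through that chain is built, and the partial correlation of
#' the cause with its full estimate \eqn{\hat X^Y} is taken conditioning on
#' all chain estimates jointly. Order 1 coincides with the `rho_D` of
#' [pcm_pair()].
#'
#' @inheritParams pcm_pair
#' @param order Chain length `n`; at most the number of conditioners.
#' @return The scalar \eqn{\varrho_{D_n}} in \eqn{[0, 1]}.
#' @export
pcm_higher_order <- function(data, cause, effect, conditioners, order,
                             config = pcm_config()) {
  stopifnot(inherits(config, "pcm_config"), order >= 1)
  cols <- get_columns(data, unique(c(cause, effect, conditioners)))
  x <- cols[[cause]]; y <- cols[[effect]]
  zs <- cols[conditioners]
  if (order > length(zs))
    abort(sprintf("order %d exceeds the number of conditioners (%d)",
                  order, length(zs)))
  eng <- pcm_engine(x, y, zs, cause, effect, config)
  if (order == 1) return(eng$rho_D1)
  higher_order_rho(x, y, zs, cause, effect, config, order, eng)
}

#' Proximity index gamma
#'
#' \eqn{\gamma = \bigl(\prod_{n=1}^{s} \varrho_{D_n}\bigr) / \varrho_C^{\,s}}
#' over the `s` computed orders; with a single order this is the plain ratio
#' \eqn{\varrho_D / \varrho_C}. Values near 1 support a direct link when both
#' indices hover near the decision threshold.
#'
#' @param rho_C The cross-map index \eqn{\varrho_C > 0}.
#' @param rho_D Numeric vector of \eqn{\varrho_{D_n}}, one entry per computed
#'   order.
#' @return The scalar proximity ratio.
#' @examples
#' gamma_index(0.8, c(0.6, 0.4)) # (0.6 * 0.4) / 0.8^2
#' @export
gamma_index <- function(rho_C, rho_D) {
  stopifnot(is.numeric(rho_C), length(rho_C) == 1, is.numeric(rho_D),
            length(rho_D) >= 1)
  if (rho_C == 0)
    abort("gamma is undefined for rho_C = 0", class = "pcmap_degenerate_error")
  prod(rho_D) / rho_C^length(rho_D)
}

#' Three-case causal decision
#'
#' Implements the threshold rule on the index pair: with
#' \eqn{\varrho_C \ge \varrho_D} holding in general,
#' \eqn{\varrho_D \ge T} calls a **direct** link,
#' \eqn{\varrho_C \ge T > \varrho_D} a sole **indirect** link, and
#' \eqn{\varrho_C < T} **none**.
#'
#' @param rho_C,rho_D Indices in \eqn{[0, 1]} (vectorised).
#' @param threshold Decision threshold `T` in (0, 1).
#' @return Character vector over `c("direct", "indirect", "none")`.
#' @examples
#' classify_link(0.8, 0.7, 0.5) # direct
#' classify_link(0.8, 0.1, 0.5) # indirect
#' classify_link(0.3, 0.2, 0.5) # none
#' @export
classify_link <- function(rho_C, rho_D, threshold = 0.5) {
  stopifnot(all(rho_C >= 0 & rho_C <= 1), all(rho_D >= 0 & rho_D <= 1),
            threshold > 0, threshold < 1)
  dplyr::case_when(rho_D >= threshold ~ "direct",
                   rho_C >= threshold ~ "indirect",
                   TRUE ~ "none")
}

# Surrogate significance: circular time-shift surrogates of the cause series,
# re-scored through the identical pipeline. Mediator stages s1 do not involve
# the cause and are reused.
surrogate_pvalues <- function(x, y, zs, cause, effect, config, eng) {
  N <- config$surrogates
  L <- length(x)
  draw <- function() sample.int(L - 1, N, replace = TRUE)
  offs <- if (is.null(config$seed)) draw() else
    withr::with_seed(derive_seed(config$seed, paste0("surrogate.", cause, ".", effect)), draw())
  surr <- vapply(offs, function(o) {
    xs <- c(x[(o + 1):L], x[1:o])
    res <- tryCatch(
      pcm_engine(xs, y, zs, cause, effect, config, s1_cache = eng$s1),
      error = function(e) NULL)
    if (is.null(res)) c(NA_real_, NA_real_) else c(res$rho_C, res$rho_D1)
  }, numeric(2))
  ok <- colSums(is.na(surr)) == 0
  surr <- surr[, ok, drop = FALSE]
  n_ok <- ncol(surr)
  tibble(index = c("rho_C", "rho_D"),
         observed = c(eng$rho_C, eng$rho_D1),
         n_surrogates = n_ok,
         p_value = c((1 + sum(surr[1, ] >= eng$rho_C)) / (1 + n_ok),
                     (1 + sum(surr[2, ] >= eng$rho_D1)) / (1 + n_ok)))
}

#' Surrogate significance test for a PCM pair
#'
#' Scores the observed \eqn{\varrho_C} (and, with conditioners,
#' \eqn{\varrho_D}) against circular time-shift surrogates of the cause
#' series: random rotations preserve the autocorrelation of the series while
#' destroying its cross-dependence, and each surrogate is pushed through the
#' identical pipeline. The p-value is
#' \eqn{(1 + \#\{\varrho^{surr} \ge \varrho^{obs}\}) / (1 + N)}; at least 19
#' surrogates are needed for a 0.05-level test.
#'
#' @inheritParams pcm_pair
#' @return A tibble with columns `index`, `observed`, `n_surrogates`,
#'   `p_value` (one row per index).
#' @export
surrogate_test <- function(data, cause, effect, conditioners = NULL,
                           config = pcm_config()) {
  stopifnot(inherits(config, "pcm_config"))
  if (config$surrogates < 1)
    abort("config$surrogates must be >= 1 for a surrogate test (>= 19 for a 0.05-level test)")
  if (!is.null(conditioners) && length(conditioners) > 0) {
    res <- pcm_pair(data, cause, effect, conditioners, config)
    return(res$surrogate)
  }
  # MCM-only test: statistic is the delay-scanned rho_C
  cols <- get_columns(data, c(cause, effect))
  x <- cols[[cause]]; y <- cols[[effect]]
  obs <- scan_stage(x, 1L, y, 1L, cause, effect, config, stage = "Xhat^Y")
  N <- config$surrogates
  L <- length(x)
  draw <- function() sample.int(L - 1, N, replace = TRUE)
  offs <- if (is.null(config$seed)) draw() else
    withr::with_seed(derive_seed(config$seed, paste0("surrogate.", cause, ".", effect)), draw())
  surr <- vapply(offs, function(o) {
    xs <- c(x[(o + 1):L], x[1:o])
    res <- tryCatch(scan_stage(xs, 1L, y, 1L, cause, effect, config, "surr"),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$rho
  }, numeric(1))
  surr <- surr[!is.na(surr)]
  tibble(index = "rho_C", observed = obs$rho, n_surrogates = length(surr),
         p_value = (1 + sum(surr >= obs$rho)) / (1 + length(surr)))
}

#' @export
print.pcm_result <- function(x, ...) {
  cat(sprintf("<pcm_result> %s -> %s | {%s}\n", x$cause, x$effect,
              paste(x$conditioners, collapse = ", ")))
  cat(sprintf("  rho_C = %.4f, rho_D = %s, gamma = %.4f\n", x$rho_C,
              paste(sprintf("%.4f", x$rho_D), collapse = "/"), x$gamma))
  cat(sprintf("  decision: %s (T = %.2f)", x$decision, x$config$threshold))
  if (!is.na(x$p_value)) cat(sprintf(", p[rho_D] = %.4f", x$p_value))
  cat("\n")
  invisible(x)
}

#' @rdname pcm_pair
#' @param x A `pcm_result`.
#' @param ... Unused.
#' @method tidy pcm_result
#' @export
tidy.pcm_result <- function(x, ...) {
  tibble(index = c("rho_C", paste0("rho_D", names(x$rho_D)), "gamma"),
         value = c(x$rho_C, unname(x$rho_D), x$gamma))
}

#' @rdname pcm_pair
#' @method glance pcm_result
#' @export
glance.pcm_result <- function(x, ...) {
  tibble(cause = x$cause, effect = x$effect, rho_C = x$rho_C,
         rho_D = min(x$rho_D), gamma = x$gamma, decision = x$decision,
         p_value = x$p_value, n_support = x$align[2] - x$align[1] + 1)
}
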