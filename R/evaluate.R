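#' Build an edge score table from an inferred network and ground truth
#'
#' Joins a [infer_network()] result (or any tibble of ordered pairs with
#' scores) against a ground-truth edge list, yielding one row per ordered
#' pair with a numeric score and a boolean truth label — the input for
#' [roc_curve()] and [threshold_sweep()].
#'
#' @param network A `pcm_network` or tibble with `source`, `target` and the
#'   score column.
#' @param truth Tibble of true edges with columns `source`, `target` (e.g.
#'   [truth_graph()]).
#' @param score Which column to use as the score (default `"rho_D"`).
#' @return Tibble with columns `source`, `target`, `score`, `truth` (and
#'   `decision` if present); self-pairs excluded.
#' @export
edge_score_table <- function(network, truth, score = "rho_D") {
  stopifnot(is.data.frame(network), is.data.frame(truth),
            all(c("source", "target") %in% names(network)),
            all(c("source", "target") %in% names(truth)),
            score %in% names(network))
  out <- tibble(source = network$source, target = network$target,
                score = network[[score]])
  if ("decision" %in% names(network)) out$decision <- network$decision
  out <- dplyr::filter(out, .data$source != .data$target)
  key <- paste(truth$source, truth$target)
  out$truth <- paste(out$source, out$target) %in% key
  out
}

#' ROC curve and AUROC of an edge score table
#'
#' Sweeps a decision threshold over the unique scores (ties included
#' simultaneously), accumulating true- and false-positive rates, and
#' integrates the curve by the trapezoid rule. With midrank tie handling the
#' area equals the Mann–Whitney statistic
#' \eqn{P(S_{\mathrm{edge}} > S_{\mathrm{non-edge}}) + \frac12 P(=)}.
#'
#' @param table Tibble with numeric `score` and logical `truth` (e.g. from
#'   [edge_score_table()]); both classes must be present.
#' @return Object of class `roc_curve`: a tibble of curve points
#'   (`threshold`, `tpr`, `fpr`) with the area in attribute `auroc`
#'   (also via [auroc()]).
#' @export
roc_curve <- function(table) {
  stopifnot(is.data.frame(table), all(c("score", "truth") %in% names(table)))
  score <- table$score
  truth <- as.logical(table$truth)
  if (anyNA(score) || anyNA(truth))
    abort("scores and truth labels must be complete (no NA)")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    abort("ROC needs both classes present in `truth`")
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- vapply(thr, function(s) {
    pred <- score >= s
    c(tpr = sum(pred & truth) / n_pos, fpr = sum(pred & !truth) / n_neg)
  }, numeric(2))
  curve <- tibble(threshold = c(Inf, thr),
                  tpr = c(0, pts["tpr", ]), fpr = c(0, pts["fpr", ]))
  au <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                 utils::tail(curve$tpr, -1)) / 2)
  structure(curve, auroc = au, class = c("roc_curve", class(curve)))
}

#' @rdname roc_curve
#' @param ... Passed to [roc_curve()] when `table` is not already a curve.
#' @export
auroc <- function(table, ...) {
  if (inherits(table, "roc_curve")) return(attr(table, "auroc"))
  attr(roc_curve(table, ...), "auroc")
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) as_tibble(unclass(x))

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) tibble(auroc = attr(x, "auroc"))

#' Decision-threshold robustness sweep
#'
#' For each threshold `T` in the grid, applies both decision rules to every
#' trial's edge table — the pairwise rule (`mcm`: predict an edge iff
#' \eqn{\varrho_C \ge T}) and the partial rule (`pcm`: predict iff
#' \eqn{\varrho_D \ge T}) — and summarises precision, recall, and accuracy
#' across trials. A method whose accuracy varies little over the grid is
#' robust to the choice of `T`. When a rule predicts no edges at a
#' threshold, precision is undefined and reported as `NA`.
#'
#' @param tables A list of edge tables (one per trial), each with columns
#'   `source`, `target`, `rho_C`, `rho_D`, `truth`.
#' @param thresholds Numeric grid of thresholds (non-empty).
#' @return Tibble with one row per (threshold, method): mean and sd of
#'   precision, recall, accuracy over trials.
#' @export
threshold_sweep <- function(tables, thresholds = seq(0.3, 0.7, by = 0.1)) {
  if (length(thresholds) < 1) abort("threshold grid must be non-empty")
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  metrics_one <- function(tab, T_, col) {
    pred <- !is.na(tab[[col]]) & tab[[col]] >= T_
    truth <- as.logical(tab$truth)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
      recall = tp / (tp + fn),
      accuracy = (tp + tn) / length(truth))
  }
  grid <- tidyr::expand_grid(threshold = thresholds,
                             method = c("mcm", "pcm"))
  purrr::pmap_dfr(grid, function(threshold, method) {
    col <- if (method == "mcm") "rho_C" else "rho_D"
    m <- vapply(tables, metrics_one, numeric(3), T_ = threshold, col = col)
    tibble(threshold = threshold, method = method,
           precision = mean(m["precision", ], na.rm = TRUE),
           precision_sd = sd(m["precision", ], na.rm = TRUE),
           recall = mean(m["recall", ]), recall_sd = sd(m["recall", ]),
           accuracy = mean(m["accuracy", ]), accuracy_sd = sd(m["accuracy", ]))
  })
}
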