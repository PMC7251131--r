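#' Partial correlation with an arbitrary conditioning set
#'
#' The partial correlation \eqn{\mathrm{Pcc}(x, y \mid Z)} measures the
#' association between `x` and `y` after the linear information carried by the
#' conditioning series has been removed. With an empty conditioning set it is
#' the plain Pearson correlation; with one conditioner it equals
#' \deqn{\frac{\mathrm{Corr}(x,y) - \mathrm{Corr}(x,z)\,\mathrm{Corr}(y,z)}
#'            {\sqrt{(1-\mathrm{Corr}(x,z)^2)(1-\mathrm{Corr}(y,z)^2)}}}
#' and larger sets follow by the standard recursion. Internally the value is
#' computed as the correlation of least-squares residuals of `x` and `y` on
#' the conditioners (numerically stabler and order-free); the recursion is the
#' defining contract and the two agree to near machine precision.
#'
#' @param x,y Numeric vectors of equal length (at least 3), nonzero variance.
#' @param conditioners A numeric vector, a list of numeric vectors, a matrix
#'   (columns are conditioners), or `NULL` for the plain correlation.
#' @return A single correlation in \eqn{[-1, 1]}.
#' @examples
#' set.seed(1)
#' z <- rnorm(100); x <- z + rnorm(100); y <- z + rnorm(100)
#' cor(x, y)
#' partial_corr(x, y, z) # association largely explained by z
#' @export
partial_corr <- function(x, y, conditioners = NULL) {
  check_series(x, "x", min_len = 3)
  check_series(y, "y", min_len = 3)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  check_nonconstant(x, "x"); check_nonconstant(y, "y")
  Z <- conditioner_matrix(conditioners, length(x))
  if (is.null(Z)) return(cor(x, y))
  for (j in seq_len(ncol(Z))) {
    zj <- Z[, j]
    check_nonconstant(zj, paste0("conditioner ", j))
    for (nm in c("x", "y")) {
      v <- if (nm == "x") x else y
      if (abs(cor(v, zj)) > 1 - 1e-10)
        abort(sprintf(
          "zero denominator: conditioner %d is (near-)perfectly correlated with `%s`",
          j, nm), class = "pcmap_collinear_error")
    }
  }
  Q <- cbind(1, Z)
  rx <- stats::lm.fit(Q, x)$residuals
  ry <- stats::lm.fit(Q, y)$residuals
  if (sd(rx) == 0 || sd(ry) == 0)
    abort("residual variance is zero after conditioning; partial correlation undefined",
          class = "pcmap_collinear_error")
  out <- cor(rx, ry)
  max(-1, min(1, out))
}

conditioner_matrix <- function(conditioners, n) {
  if (is.null(conditioners) || (is.list(conditioners) && length(conditioners) == 0))
    return(NULL)
  if (is.matrix(conditioners)) {
    Z <- conditioners
  } else if (is.data.frame(conditioners)) {
    Z <- as.matrix(conditioners)
  } else if (is.list(conditioners)) {
    Z <- do.call(cbind, conditioners)
  } else {
    Z <- matrix(conditioners, ncol = 1)
  }
  if (!is.numeric(Z) || nrow(Z) != n)
    abort("conditioners must be numeric and aligned with `x`/`y` (same length)")
  if (anyNA(Z) || !all(is.finite(Z)))
    abort("conditioners contain missing or non-finite values")
  Z
}
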