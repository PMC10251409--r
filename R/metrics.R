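#' Determination coefficient of predictions
#'
#' `R2 = 1 - sum((y - x)^2) / sum((x - mean(x))^2)` with `x` measured and
#' `y` predicted. Unlike a squared correlation this penalizes bias and
#' scale errors, and can be negative for models worse than the mean.
#'
#' @param measured measured trait values
#' @param predicted predicted values, same length (>= 2)
#' @return determination coefficient
#' @export
#' @examples
#' r2_metric(c(1, 2, 3), c(1, 2, 5))  # -1
r2_metric <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2) {
    stop("precondition error: equal lengths >= 2 required")
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) stop("degeneracy error: measured values are constant")
  1 - sum((predicted - measured)^2) / ss_tot
}

#' Root mean square error of predictions
#'
#' `RMSE = sqrt(mean((y - x)^2))`, in the trait's units (mg g-1 for LPC).
#'
#' @inheritParams r2_metric
#' @return non-negative error
#' @export
#' @examples
#' rmse_metric(c(0, 0), c(3, 4))  # sqrt(12.5)
rmse_metric <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1) {
    stop("precondition error: equal non-zero lengths required")
  }
  sqrt(mean((predicted - measured)^2))
}

#' Akaike information criterion for a least-squares model
#'
#' `AIC = 2k + n * ln(RSS / n)` with `RSS = sum((y - x)^2)`, `k` the
#' feature count and `n` the sample count; lower is better. The
#' `"printed"` variant replaces residuals by deviations of the predictions
#' from the measured mean, `sum((y - mean(x))^2)` -- a form that appears
#' in some applied papers but does not measure fit; it is provided for
#' comparability only.
#'
#' @inheritParams r2_metric
#' @param k number of model input features
#' @param variant `"rss"` (residual-based, default) or `"printed"`
#' @return criterion value
#' @export
#' @examples
#' aic_metric(rep(0, 10) + 1:10 * 0, 1:10 * 0 + sqrt(1), k = 2)  # residual-based
aic_metric <- function(measured, predicted, k, variant = c("rss", "printed")) {
  variant <- match.arg(variant)
  if (length(measured) != length(predicted) || length(measured) < 2) {
    stop("precondition error: equal lengths >= 2 required")
  }
  n <- length(measured)
  rss <- if (variant == "rss") sum((predicted - measured)^2)
         else sum((predicted - mean(measured))^2)
  if (rss <= 0) stop("degeneracy error: zero residual sum of squares (AIC is -Inf)")
  2 * k + n * log(rss / n)
}
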