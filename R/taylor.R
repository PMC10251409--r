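#' Taylor-diagram statistics of a prediction series
#'
#' Summarizes model skill by three linked quantities: the Pearson
#' correlation `r` between predicted and observed, the standard-deviation
#' ratio `sigma_pred / sigma_obs`, and the centered (bias-removed) pattern
#' RMS difference. Population (divide-by-n) standard deviations are used
#' throughout so the law-of-cosines identity
#' `cRMSD^2 = sigma_p^2 + sigma_o^2 - 2 sigma_p sigma_o r`
#' holds exactly; the ratio form is reported because diagrams are read
#' against a unit-reference observation point.
#'
#' @param observed observed trait values (not constant, length >= 3)
#' @param predicted predicted values, same length
#' @param label optional model identifier
#' @return object of class `taylor_point`: list with `label`, `pearson_r`,
#'   `std_ratio`, `centered_rmsd`, `sd_obs`, `sd_pred`
#' @export
#' @examples
#' taylor_statistics(1:5, 1:5)  # the reference point: r = 1, ratio 1, cRMSD 0
taylor_statistics <- function(observed, predicted, label = NULL) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop("precondition error: equal lengths >= 3 required")
  }
  n <- length(observed)
  sd_o <- sqrt(mean((observed - mean(observed))^2))
  if (sd_o <= 0) stop("degeneracy error: observed values are constant")
  sd_p <- sqrt(mean((predicted - mean(predicted))^2))
  r <- if (sd_p > 0) stats::cor(observed, predicted) else 0
  crmsd <- sqrt(mean(((predicted - mean(predicted)) - (observed - mean(observed)))^2))
  structure(list(label = label, pearson_r = r, std_ratio = sd_p / sd_o,
                 centered_rmsd = crmsd, sd_obs = sd_o, sd_pred = sd_p),
            class = "taylor_point")
}

#' @export
print.taylor_point <- function(x, ...) {
  cat(sprintf("taylor_point%s: r = %.3f, sd ratio = %.3f, centered RMSD = %.4f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$pearson_r, x$std_ratio, x$centered_rmsd))
  invisible(x)
}

#' Polar coordinates of a Taylor point
#'
#' Pure geometry for rendering: radius is the (normalized) standard
#' deviation ratio, angle is `acos(r)` from the horizontal axis. The
#' reference observation sits at (1, 0).
#'
#' @param point a `taylor_point`
#' @return named numeric vector `c(radius, angle)` (angle in radians)
#' @export
taylor_coordinates <- function(point) {
  stopifnot(inherits(point, "taylor_point"))
  c(radius = point$std_ratio, angle = acos(min(1, max(-1, point$pearson_r))))
}
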