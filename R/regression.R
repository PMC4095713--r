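#' Construct a perimeter-versus-area regression fit
#'
#' Container for a linear relation `P = slope * A + intercept` with its
#' Pearson correlation; produced by [fit_linear()] or filled in directly
#' from published coefficients.
#'
#' @param slope Slope (um per um^2).
#' @param intercept Intercept (um).
#' @param correlation Pearson r in `[-1, 1]`.
#' @param n Number of points behind the fit (>= 3).
#' @param model Optional underlying [stats::lm] object.
#' @return Object of class `pa_fit`.
#' @export
regression_fit <- function(slope, intercept, correlation = NA_real_, n = 3L,
                           model = NULL) {
  if (!is.na(correlation) && abs(correlation) > 1) {
    stop("'correlation' must lie in [-1, 1]", call. = FALSE)
  }
  if (n < 3L) stop("a regression fit needs n >= 3", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 correlation = correlation, n = as.integer(n), model = model),
            class = "pa_fit")
}

#' Least-squares regression of perimeter on area
#'
#' Ordinary least squares of P on A (minimising squared perimeter
#' residuals) with the Pearson correlation of the two vectors. Within a
#' developmental stage the relation is quasilinear because larger cells are
#' the more elongated ones.
#'
#' @param areas,perimeters Equal-length numeric vectors, n >= 3; the areas
#'   must not be constant.
#' @return A [regression_fit()] (class `pa_fit`) carrying the underlying
#'   `lm` model.
#' @export
fit_linear <- function(areas, perimeters) {
  if (length(areas) != length(perimeters)) {
    stop("'areas' and 'perimeters' must have the same length", call. = FALSE)
  }
  if (length(areas) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(areas) == 0) {
    stop("undefined fit: zero variance in areas", call. = FALSE)
  }
  d <- data.frame(A = areas, P = perimeters)
  m <- stats::lm(P ~ A, data = d)
  cf <- stats::coef(m)
  regression_fit(slope = unname(cf[2]), intercept = unname(cf[1]),
                 correlation = stats::cor(areas, perimeters),
                 n = length(areas), model = m)
}

#' Evaluate a regression line
#'
#' @param fit A `pa_fit`.
#' @param a Area value(s) (um^2).
#' @return Predicted perimeter(s) `slope * a + intercept` (um).
#' @export
evaluate_line <- function(fit, a) {
  stopifnot(inherits(fit, "pa_fit"))
  fit$slope * a + fit$intercept
}

#' Regression-line proximity ratio
#'
#' Compares the three stage regression lines at a single area value
#' (default 30 um^2, a region dense with measurements in all stages):
#' the ratio of the distance between the group I and II lines to the
#' distance between the group II and III lines. Large values mean the early
#' bell stage is much closer to late bell than to cap.
#'
#' @param fit_I,fit_II,fit_III `pa_fit` objects for groups I, II, III.
#' @param a Evaluation area (um^2).
#' @return `|P_II(a) - P_I(a)| / |P_III(a) - P_II(a)|`.
#' @export
line_proximity_ratio <- function(fit_I, fit_II, fit_III, a = 30) {
  p1 <- evaluate_line(fit_I, a)
  p2 <- evaluate_line(fit_II, a)
  p3 <- evaluate_line(fit_III, a)
  if (p3 == p2) stop("coincident group II and III lines at a", call. = FALSE)
  abs(p2 - p1) / abs(p3 - p2)
}

#' @export
print.pa_fit <- function(x, ...) {
  cat(sprintf("P = %.4f * A + %.4f  (r = %.4f, n = %d)\n",
              x$slope, x$intercept, x$correlation, x$n))
  invisible(x)
}

#' @export
coef.pa_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.pa_fit <- function(object, a, ...) {
  evaluate_line(object, a)
}

#' Scattergram of perimeter versus area with the fitted line
#'
#' @param x A `pa_fit` with an underlying model (from [fit_linear()]).
#' @param xlim,ylim Axis ranges (use common ranges to compare stages).
#' @param main Title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pa_fit <- function(x, xlim = NULL, ylim = NULL, main = NULL, ...) {
  if (is.null(x$model)) stop("no underlying data to plot", call. = FALSE)
  d <- x$model$model
  graphics::plot(d$A, d$P, xlab = expression(A ~ (mu * m^2)),
                 ylab = expression(P ~ (mu * m)), xlim = xlim, ylim = ylim,
                 main = main, pch = 20, cex = 0.5, col = "grey30", ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}
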