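#' Random case sample
#'
#' Draws `n` records (default 100) uniformly without replacement from a case
#' database, keeping the area, perimeter and form-factor vectors row-aligned
#' (the same cells). This mirrors the case-level sampling that equalises the
#' statistical weight of all cases before group pooling.
#'
#' @param db Case database: data frame with columns `area_um2`,
#'   `perimeter_um`, `form_factor` (see [measure_image()]).
#' @param n Sample size.
#' @param seed Optional integer seed; recorded on the result.
#' @return Data frame of `n` sampled records with attribute `seed`.
#' @export
sample_records <- function(db, n = 100L, seed = NULL) {
  need <- c("area_um2", "perimeter_um", "form_factor")
  if (!all(need %in% names(db))) {
    stop("case database must have columns area_um2, perimeter_um, form_factor",
         call. = FALSE)
  }
  if (nrow(db) < n) {
    id <- if ("case_id" %in% names(db)) unique(db$case_id)[1] else "?"
    stop(sprintf("case '%s' has only %d records, cannot sample %d without replacement",
                 id, nrow(db), n), call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(db), n))
  out <- db[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Descriptive statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and extreme values.
#'
#' @param values Non-empty numeric vector.
#' @return List of class `descriptive_stats`: `mean`, `sd`, `min`, `max`, `n`.
#' @export
describe <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  structure(list(mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0,
                 min = min(values), max = max(values),
                 n = length(values)),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("n = %d: %.3f +/- %.3f (min %.3f, max %.3f)\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

hist_class_width <- function(parameter) {
  switch(parameter, A = 3.5, P = 7, FF = 0.05,
         stop("parameter must be 'A', 'P' or 'FF'", call. = FALSE))
}

#' Fixed-width 20-class histogram
#'
#' Bins start at 0 with the conventional class width of the parameter
#' (A: 3.5 um^2, P: 7 um, FF: 0.05) and are half-open `[edge, edge + w)`;
#' the final bin's upper edge is closed. Values beyond the last bin are
#' counted as out-of-range, so in-range counts always sum to `n` minus the
#' out-of-range count.
#'
#' @param values Numeric vector (non-negative morphometric values).
#' @param parameter `"A"`, `"P"` or `"FF"` (selects the class width), or
#'   supply `class_width` directly.
#' @param class_width Bin width; defaults to the parameter's conventional
#'   width.
#' @param n_classes Number of bins (20).
#' @return List of class `morpho_histogram`: `parameter`, `class_width`,
#'   `left_edges`, `counts`, `n`, `out_of_range`.
#' @export
build_histogram <- function(values, parameter = c("A", "P", "FF"),
                            class_width = NULL, n_classes = 20L) {
  parameter <- match.arg(parameter)
  if (is.null(class_width)) class_width <- hist_class_width(parameter)
  stopifnot_scalar_pos(class_width, "class_width")
  edges <- seq(0, by = class_width, length.out = n_classes + 1L)
  bin <- findInterval(values, edges)           # [edge_i, edge_{i+1})
  bin[values == edges[n_classes + 1L]] <- n_classes  # top edge closed
  counts <- tabulate(bin[bin >= 1L & bin <= n_classes], nbins = n_classes)
  structure(list(parameter = parameter, class_width = class_width,
                 left_edges = edges[-(n_classes + 1L)], counts = counts,
                 n = length(values),
                 out_of_range = sum(bin < 1L | bin > n_classes)),
            class = "morpho_histogram")
}

#' Gaussian overlay for a histogram
#'
#' Normal density with the sample mean and standard deviation, evaluated at
#' the bin centres and scaled to the count scale (`n * class_width`), as
#' conventionally drawn over morphometric histograms.
#'
#' @param stats A [describe()] result.
#' @param hist A [build_histogram()] result.
#' @return List with `centers`, `heights` and `flat_spike` (`TRUE`, with no
#'   curve, when `sd = 0`).
#' @export
gaussian_overlay <- function(stats, hist) {
  stopifnot(inherits(stats, "descriptive_stats"),
            inherits(hist, "morpho_histogram"))
  centers <- hist$left_edges + hist$class_width / 2
  if (stats$sd == 0) {
    return(list(centers = centers, heights = NULL, flat_spike = TRUE))
  }
  list(centers = centers,
       heights = stats::dnorm(centers, stats$mean, stats$sd) *
         stats$n * hist$class_width,
       flat_spike = FALSE)
}

#' One-way analysis of variance
#'
#' Classical (equal-variance) one-way ANOVA across two or more groups.
#' Degenerate input in which every observation is identical yields
#' `F = 0, p = 1`.
#'
#' @param groups List of numeric vectors, each with at least 2 values.
#' @return List of class `morpho_test`: `statistic`, `p_value`, `df`
#'   (numerator, denominator), `test`, `equal_variance`.
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 groups with at least 2 values each", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    res <- list(statistic = 0, p_value = 1,
                df = c(length(groups) - 1L, length(y) - length(groups)))
  } else {
    ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
    res <- list(statistic = unname(ow$statistic), p_value = ow$p.value,
                df = unname(ow$parameter))
  }
  structure(c(res, list(test = "one-way ANOVA", equal_variance = TRUE)),
            class = "morpho_test")
}

#' Two-sample t test
#'
#' Welch's t test by default (the equal-variance assumption is usually
#' slightly violated in these data); set `equal_variance = TRUE` for the
#' pooled-variance Student test. Two constant samples with equal means give
#' `t = 0, p = 1`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param equal_variance Pool the variances?
#' @return A `morpho_test` (see [anova_one_way()]).
#' @export
t_test_two_sample <- function(x, y, equal_variance = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (eq) 1 else 0,
                df = length(x) + length(y) - 2L)
  } else {
    tt <- stats::t.test(x, y, var.equal = equal_variance)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter))
  }
  structure(c(res, list(test = if (equal_variance) "Student t (pooled)"
                        else "Welch t",
                        equal_variance = equal_variance)),
            class = "morpho_test")
}

#' @export
print.morpho_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g  [%s]\n",
              x$test, x$statistic, paste(signif(x$df, 5), collapse = ", "),
              x$p_value, p_tier(x$p_value)))
  invisible(x)
}
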