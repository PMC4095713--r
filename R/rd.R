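#' Element set for relative-distance analysis
#'
#' A set E = {e_1, ..., e_n} of positive values (typically per-case or
#' per-group mean values of one morphometric parameter) together with its
#' arithmetic mean M(E). All relative distances are scaled by M(E), which
#' makes them invariant to the overall size of the measured cells.
#'
#' @param elements Numeric vector, n >= 2, all positive.
#' @param label Optional label for reports.
#' @return Object of class `element_set` with fields `elements`, `M`,
#'   `label`.
#' @export
element_set <- function(elements, label = NULL) {
  if (length(elements) < 2L) stop("an element set needs n >= 2", call. = FALSE)
  if (any(!is.finite(elements)) || any(elements <= 0)) {
    stop("all elements must be positive and finite", call. = FALSE)
  }
  M <- mean(elements)
  structure(list(elements = as.numeric(elements), M = M, label = label),
            class = "element_set")
}

as_element_set <- function(x, label = NULL) {
  if (inherits(x, "element_set")) x else element_set(x, label)
}

#' Mean-value scaling
#'
#' The transformation e_i -> (e_i - M(E)) / M(E). The scaled values sum to
#' zero; their absolute values are the relative distances to the mean.
#'
#' @param E An [element_set()] (or numeric vector).
#' @return Numeric vector of scaled values.
#' @export
mean_scale <- function(E) {
  E <- as_element_set(E)
  (E$elements - E$M) / E$M
}

#' Relative distance between an element and the set mean
#'
#' `RD_E(e_i) = |e_i - M(E)| / M(E)`, the intragroup similarity statistic:
#' how far one case's mean value sits from its group mean, as a fraction of
#' the group mean.
#'
#' @param E An [element_set()] (or numeric vector).
#' @param i Element index.
#' @return Relative distance as a fraction.
#' @export
rd_to_mean <- function(E, i) {
  E <- as_element_set(E)
  if (i < 1L || i > length(E$elements)) stop("index out of range", call. = FALSE)
  abs(E$elements[i] - E$M) / E$M
}

#' Relative distance between two elements
#'
#' `RD(e_i, e_j) = |e_i - e_j| / M(E)`, the intergroup statistic: the
#' distance between two group means scaled by the global mean of all groups.
#' Symmetric in `i` and `j`.
#'
#' @param E An [element_set()] (or numeric vector).
#' @param i,j Element indices.
#' @return Relative distance as a fraction.
#' @export
rd_between <- function(E, i, j) {
  E <- as_element_set(E)
  n <- length(E$elements)
  if (i < 1L || i > n || j < 1L || j > n) stop("index out of range", call. = FALSE)
  abs(E$elements[i] - E$elements[j]) / E$M
}

#' Ratio of two relative distances
#'
#' Used to compare stage separations, e.g. how many times farther the cap
#' stage is from early bell than early bell is from late bell.
#'
#' @param rd_a,rd_b Relative distances (fractions or percentages, as long as
#'   both use the same scale); `rd_b` must be non-zero.
#' @return `rd_a / rd_b`.
#' @examples
#' rd_ratio(0.8829, 0.1657)
#' @export
rd_ratio <- function(rd_a, rd_b) {
  if (rd_b == 0) stop("undefined ratio: rd_b is zero", call. = FALSE)
  rd_a / rd_b
}

#' Intragroup relative-distance report
#'
#' Relative distances of the five case means of one group from the group
#' mean, compared against a similarity threshold (default 10%; a case passes
#' when its RD is strictly below the threshold).
#'
#' @param case_means Positive case mean values (typically 5).
#' @param parameter Label of the parameter (`"A"`, `"P"`, `"FF"`).
#' @param group Optional group label.
#' @param threshold Similarity threshold as a fraction (default 0.10).
#' @return Object of class `rd_intragroup`: per-case `rd` (fractions),
#'   `pass` flags, `max_rd`, `max_case`, `n_pass`, plus inputs.
#' @export
rd_intragroup <- function(case_means, parameter = "", group = "",
                          threshold = 0.10) {
  E <- element_set(case_means)
  rd <- abs(E$elements - E$M) / E$M
  structure(list(group = group, parameter = parameter,
                 case_means = E$elements, group_mean = E$M,
                 rd = rd, threshold = threshold, pass = rd < threshold,
                 n_pass = sum(rd < threshold),
                 max_rd = max(rd), max_case = which.max(rd)),
            class = "rd_intragroup")
}

#' @export
print.rd_intragroup <- function(x, ...) {
  cat(sprintf("Intragroup RD%s%s: group mean %.3f, threshold %.0f%%\n",
              if (nzchar(x$group)) paste0(" group ", x$group) else "",
              if (nzchar(x$parameter)) paste0(" [", x$parameter, "]") else "",
              x$group_mean, 100 * x$threshold))
  for (i in seq_along(x$rd)) {
    cat(sprintf("  case %d: mean %.3f, RD = %.2f%% %s\n", i, x$case_means[i],
                100 * x$rd[i], if (x$pass[i]) "(similar)" else "(above threshold)"))
  }
  cat(sprintf("  %d of %d cases below threshold; max RD %.2f%% (case %d)\n",
              x$n_pass, length(x$rd), 100 * x$max_rd, x$max_case))
  invisible(x)
}

#' Intergroup relative-distance report
#'
#' Relative distances between consecutive stage means (group I vs II, group
#' II vs III), scaled by the global mean of the three group means, plus the
#' ratio RD(I,II) / RD(II,III) quantifying which stages are closer.
#'
#' @param group_means Three positive group means, ordered I, II, III.
#' @param parameter Label of the parameter.
#' @return Object of class `rd_intergroup`: `global_mean`, `rd_I_II`,
#'   `rd_II_III` (fractions), `percent` (named, in %), `ratio`.
#' @export
rd_intergroup <- function(group_means, parameter = "") {
  if (length(group_means) != 3L) {
    stop("'group_means' must contain exactly three group means (I, II, III)",
         call. = FALSE)
  }
  E <- element_set(group_means)
  rd12 <- rd_between(E, 1, 2)
  rd23 <- rd_between(E, 2, 3)
  structure(list(parameter = parameter, group_means = E$elements,
                 global_mean = E$M, rd_I_II = rd12, rd_II_III = rd23,
                 percent = c(rd_I_II = 100 * rd12, rd_II_III = 100 * rd23),
                 ratio = if (rd23 > 0) rd12 / rd23 else NA_real_),
            class = "rd_intergroup")
}

#' @export
print.rd_intergroup <- function(x, ...) {
  cat(sprintf("Intergroup RD%s: global mean %.4g\n",
              if (nzchar(x$parameter)) paste0(" [", x$parameter, "]") else "",
              x$global_mean))
  cat(sprintf("  RD(gI, gII)   = %.2f%%\n", x$percent["rd_I_II"]))
  cat(sprintf("  RD(gII, gIII) = %.2f%%\n", x$percent["rd_II_III"]))
  if (is.finite(x$ratio)) {
    cat(sprintf("  ratio RD(gI,gII)/RD(gII,gIII) = %.4f\n", x$ratio))
  }
  invisible(x)
}
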