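#' Reference group-level morphometric summaries
#'
#' Group-level means, standard deviations and extreme values of cell area
#' (um^2), perimeter (um) and form factor for pulp fibroblasts in the three
#' tooth-development stages (group I = cap, group II = early bell, group
#' III = late bell), as reported in the reference study of 15 tooth germs
#' (500 sampled cells per group). These values parameterise the synthetic
#' generator defaults and drive the tables-only analysis mode.
#'
#' @return A data frame with one row per group and columns `group`, `stage`,
#'   `mean_A`, `sd_A`, `min_A`, `max_A`, `mean_P`, `sd_P`, `min_P`, `max_P`,
#'   `mean_FF`, `sd_FF`, `min_FF`, `max_FF`.
#' @seealso [reference_cases()], [stage_params()], [tables_report()]
#' @export
reference_groups <- function() {
  data.frame(
    group = c("I", "II", "III"),
    stage = c("cap", "early_bell", "late_bell"),
    mean_A = c(17.733, 25.187, 32.788),
    sd_A   = c(7.328, 10.351, 11.115),
    min_A  = c(5.078, 7.351, 10.719),
    max_A  = c(43.034, 58.368, 68.401),
    mean_P = c(29.980, 51.788, 67.021),
    sd_P   = c(11.585, 19.055, 22.198),
    min_P  = c(10.568, 18.370, 26.432),
    max_P  = c(73.705, 117.308, 125.166),
    mean_FF = c(0.289, 0.134, 0.104),
    sd_FF   = c(0.130, 0.056, 0.043),
    min_FF  = c(0.082, 0.032, 0.038),
    max_FF  = c(0.891, 0.371, 0.289),
    stringsAsFactors = FALSE
  )
}

#' Reference case-level mean values
#'
#' Per-case (five tooth germs per group) mean area, perimeter and form
#' factor from the reference study; the inputs of the intragroup
#' relative-distance analysis.
#'
#' @return A data frame with columns `group`, `case`, `mean_A`, `mean_P`,
#'   `mean_FF`, one row per case (15 rows).
#' @seealso [reference_groups()], [rd_intragroup()]
#' @export
reference_cases <- function() {
  data.frame(
    group = rep(c("I", "II", "III"), each = 5),
    case = rep(1:5, 3),
    mean_A = c(18.755, 14.635, 16.356, 20.335, 18.558,
               26.058, 24.212, 25.629, 24.499, 25.538,
               32.847, 31.520, 30.783, 34.730, 34.060),
    mean_P = c(31.582, 27.712, 29.281, 31.170, 30.154,
               51.903, 51.065, 52.892, 53.228, 49.854,
               67.560, 69.061, 64.058, 69.336, 65.089),
    mean_FF = c(0.272, 0.271, 0.273, 0.328, 0.303,
                0.143, 0.129, 0.129, 0.120, 0.147,
                0.105, 0.095, 0.106, 0.103, 0.114),
    stringsAsFactors = FALSE
  )
}

#' Reference perimeter-versus-area regression fits
#'
#' The per-group ordinary least-squares coefficients of perimeter on area
#' and Pearson correlations reported by the reference study, usable directly
#' by [evaluate_line()] and [line_proximity_ratio()].
#'
#' @return A list of three [regression_fit()] objects named `I`, `II`, `III`.
#' @export
reference_fits <- function() {
  list(I   = regression_fit(slope = 1.4263, intercept = 4.6868,
                            correlation = 0.9023, n = 500L),
       II  = regression_fit(slope = 1.6758, intercept = 9.5794,
                            correlation = 0.9104, n = 500L),
       III = regression_fit(slope = 1.7626, intercept = 9.2303,
                            correlation = 0.8825, n = 500L))
}
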