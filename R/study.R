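#' Study configuration
#'
#' Collects every tunable of the pipeline: study layout, calibration,
#' segmentation settings, sample size, seeds and analysis constants.
#' Defaults reproduce the reference study design (3 stages x 5 cases x
#' 5 images) at a synthetic scale of 24 cells per image.
#'
#' @param mode `"synthetic"` (generate images) or `"images"` (read an
#'   existing study tree).
#' @param stages Named list of three [stage_params()] (`I`, `II`, `III`).
#' @param n_cases Cases per group.
#' @param images_per_case Images per case.
#' @param dim_px Image size `c(rows, cols)` in pixels.
#' @param microns_per_pixel Calibration (um per pixel).
#' @param magnification Informational tag.
#' @param threshold A [threshold_spec()] for segmentation.
#' @param min_area_px Scrap-removal threshold in pixels.
#' @param stretch Apply [enhance_contrast()] before thresholding? Off by
#'   default for synthetic images, whose dynamic range is already fixed and
#'   whose threshold bounds are calibrated to the unstretched colours.
#' @param n_sample Records sampled per case (without replacement).
#' @param seed Master seed; fully determines a synthetic study.
#' @param rd_threshold Intragroup similarity threshold (fraction).
#' @param eval_area Area (um^2) at which regression lines are compared.
#' @return Object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "images"),
                         stages = list(I = stage_params("cap"),
                                       II = stage_params("early_bell"),
                                       III = stage_params("late_bell")),
                         n_cases = 5L, images_per_case = 5L,
                         dim_px = c(448L, 448L),
                         microns_per_pixel = 0.25,
                         magnification = "x200",
                         threshold = default_threshold_spec(),
                         min_area_px = 20L,
                         stretch = FALSE,
                         n_sample = 100L,
                         seed = 1L,
                         rd_threshold = 0.10,
                         eval_area = 30) {
  mode <- match.arg(mode)
  stopifnot(length(stages) == 3L, all(vapply(stages, inherits, TRUE, "stage_params")))
  stopifnot_scalar_pos(microns_per_pixel, "microns_per_pixel")
  stopifnot_scalar_pos(n_sample, "n_sample")
  stopifnot_scalar_pos(rd_threshold, "rd_threshold")
  stopifnot_scalar_pos(eval_area, "eval_area")
  if (is.null(names(stages))) names(stages) <- c("I", "II", "III")
  structure(list(mode = mode, stages = stages,
                 n_cases = as.integer(n_cases),
                 images_per_case = as.integer(images_per_case),
                 dim_px = as.integer(dim_px),
                 microns_per_pixel = microns_per_pixel,
                 magnification = magnification,
                 threshold = threshold, min_area_px = as.integer(min_area_px),
                 stretch = isTRUE(stretch),
                 n_sample = as.integer(n_sample), seed = as.integer(seed),
                 rd_threshold = rd_threshold, eval_area = eval_area),
            class = "study_config")
}

#' Read / write a case database
#'
#' The interchange format of the pipeline: one CSV per case with columns
#' `case_id,image_id,region_id,area_um2,perimeter_um,form_factor`.
#' Malformed files are rejected with the offending column or line.
#'
#' @param path CSV path.
#' @return `read_case_database()`: the validated data frame.
#' @export
read_case_database <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(db) == 0L) stop(sprintf("empty case database: '%s'", path), call. = FALSE)
  need <- c("case_id", "image_id", "region_id", "area_um2", "perimeter_um",
            "form_factor")
  missing_cols <- setdiff(need, names(db))
  if (length(missing_cols) > 0L) {
    stop(sprintf("case database '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("area_um2", "perimeter_um", "form_factor")) {
    v <- db[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric '%s' in '%s' at data line %d", col, path,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  db
}

#' @rdname read_case_database
#' @param db Data frame in the case-database schema.
#' @export
write_case_database <- function(db, path) {
  need <- c("case_id", "image_id", "region_id", "area_um2", "perimeter_um",
            "form_factor")
  if (!all(need %in% names(db))) {
    stop("case database must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  utils::write.csv(db[, need], path, row.names = FALSE)
  invisible(path)
}

read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  a[, , 1:3, drop = FALSE] * 255
}

# Segment + measure one image file.
process_image <- function(path, config, cal, case_id, image_id) {
  img <- read_image_png(path)
  if (config$stretch) img <- enhance_contrast(img)
  mask <- threshold_rgb(img, config$threshold)
  mask <- remove_scrap(mask, config$min_area_px)
  lab <- label_regions(mask, 8L)
  measure_image(lab, cal, case_id = case_id, image_id = image_id)
}

#' Run the full morphometric study
#'
#' End-to-end pipeline: (synthetic mode) generate and render the study,
#' then for every image segment by colour thresholding, remove scrap,
#' label and measure regions; accumulate per-case databases; draw the
#' per-case random samples; compute case and group descriptive statistics,
#' histograms, one-way ANOVA and pairwise Welch tests between groups;
#' evaluate intragroup and intergroup relative distances; and fit the
#' per-group perimeter-versus-area regressions with the line-proximity
#' ratio. All tabular artifacts are written to `dir` as CSV.
#'
#' @param config A [study_config()].
#' @param dir Study directory: written (synthetic mode) or read (images
#'   mode). Defaults to a fresh temporary directory in synthetic mode.
#' @param verbose Log per-stage progress via [message()].
#' @return Object of class `pulp_study`; see [print.pulp_study()],
#'   [summary.pulp_study()] and [plot.pulp_study()].
#' @export
run_study <- function(config = study_config(), dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(config$seed, 2L)
  if (config$mode == "synthetic") {
    if (is.null(dir)) dir <- file.path(tempfile("pulp_study_"))
    gen_cfg <- config
    gen_cfg$seed <- seeds[1]
    say("generating synthetic study under %s", dir)
    generate_study(gen_cfg, dir)
  } else {
    if (is.null(dir) || !dir.exists(dir)) {
      stop("images mode requires an existing study directory", call. = FALSE)
    }
  }
  groups <- names(config$stages)
  cal <- calibration(config$microns_per_pixel, config$magnification)
  samp_seeds <- derive_seeds(seeds[2], length(groups) * config$n_cases)
  params <- c("A", "P", "FF")
  col_of <- c(A = "area_um2", P = "perimeter_um", FF = "form_factor")

  case_dbs <- list(); samples <- list()
  case_stats <- list(); record_counts <- list()
  ci <- 0L
  for (g in groups) {
    for (cs in seq_len(config$n_cases)) {
      ci <- ci + 1L
      case_id <- sprintf("%s_%d", g, cs)
      case_dir <- file.path(dir, sprintf("group_%s", g), sprintf("case_%d", cs))
      paths <- file.path(case_dir, sprintf("image_%d.png", seq_len(config$images_per_case)))
      if (!all(file.exists(paths))) {
        stop(sprintf("stage segmentation, case %s: missing image file(s) under %s",
                     case_id, case_dir), call. = FALSE)
      }
      db <- do.call(rbind, lapply(seq_along(paths), function(j) {
        process_image(paths[j], config, cal, case_id, j)
      }))
      say("case %s: %d records from %d images", case_id, nrow(db), length(paths))
      write_case_database(db, file.path(dir, sprintf("records_%s.csv", case_id)))
      if (nrow(db) < config$n_sample) {
        warning(sprintf("case %s has only %d records (< sample size %d)",
                        case_id, nrow(db), config$n_sample), call. = FALSE)
      }
      smp <- sample_records(db, config$n_sample, seed = samp_seeds[ci])
      case_dbs[[case_id]] <- db
      samples[[case_id]] <- smp
      record_counts[[case_id]] <- data.frame(group = g, case_id = case_id,
                                             n_records = nrow(db),
                                             sample_seed = samp_seeds[ci])
      for (p in params) {
        st <- describe(smp[[col_of[p]]])
        case_stats[[paste(case_id, p)]] <- data.frame(
          group = g, case = cs, parameter = p, mean = st$mean, sd = st$sd,
          min = st$min, max = st$max, n = st$n)
      }
    }
  }
  case_stats <- do.call(rbind, case_stats)
  record_counts <- do.call(rbind, record_counts)
  rownames(case_stats) <- rownames(record_counts) <- NULL

  # group-level vectors: concatenation of the case samples
  group_vectors <- lapply(groups, function(g) {
    ids <- sprintf("%s_%d", g, seq_len(config$n_cases))
    d <- do.call(rbind, samples[ids])
    rownames(d) <- NULL
    d
  })
  names(group_vectors) <- groups

  group_stats <- list(); histograms <- list()
  for (g in groups) for (p in params) {
    v <- group_vectors[[g]][[col_of[p]]]
    st <- describe(v)
    group_stats[[paste(g, p)]] <- data.frame(
      group = g, parameter = p, mean = st$mean, sd = st$sd, min = st$min,
      max = st$max, n = st$n)
    h <- build_histogram(v, p)
    histograms[[paste(g, p)]] <- list(histogram = h,
                                      overlay = gaussian_overlay(st, h))
  }
  group_stats <- do.call(rbind, group_stats)
  rownames(group_stats) <- NULL

  say("hypothesis tests")
  tests <- list()
  for (p in params) {
    vecs <- lapply(group_vectors, `[[`, col_of[p])
    aw <- anova_one_way(vecs)
    tests[[paste("anova", p)]] <- data.frame(
      parameter = p, test = aw$test, comparison = "I vs II vs III",
      statistic = aw$statistic, df1 = aw$df[1], df2 = aw$df[2],
      p_value = aw$p_value)
    prs <- list(c("I", "II"), c("II", "III"), c("I", "III"))
    for (pr in prs) {
      tt <- t_test_two_sample(vecs[[pr[1]]], vecs[[pr[2]]])
      tests[[paste("t", p, pr[1], pr[2])]] <- data.frame(
        parameter = p, test = tt$test,
        comparison = sprintf("%s vs %s", pr[1], pr[2]),
        statistic = tt$statistic, df1 = tt$df, df2 = NA_real_,
        p_value = tt$p_value)
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL

  say("relative distances")
  rd_intra <- list(); rd_inter <- list()
  for (p in params) {
    for (g in groups) {
      cm <- case_stats$mean[case_stats$group == g & case_stats$parameter == p]
      rd_intra[[paste(g, p)]] <- rd_intragroup(cm, parameter = p, group = g,
                                               threshold = config$rd_threshold)
    }
    gm <- vapply(groups, function(g)
      group_stats$mean[group_stats$group == g & group_stats$parameter == p], 0)
    rd_inter[[p]] <- rd_intergroup(gm, parameter = p)
  }

  say("regression")
  fits <- lapply(group_vectors, function(d) fit_linear(d$area_um2, d$perimeter_um))
  proximity <- line_proximity_ratio(fits[[1]], fits[[2]], fits[[3]],
                                    a = config$eval_area)

  # tabular artifacts
  utils::write.csv(case_stats, file.path(dir, "case_stats.csv"), row.names = FALSE)
  utils::write.csv(group_stats, file.path(dir, "group_stats.csv"), row.names = FALSE)
  utils::write.csv(tests, file.path(dir, "tests.csv"), row.names = FALSE)
  intra_df <- do.call(rbind, lapply(rd_intra, function(r) data.frame(
    group = r$group, parameter = r$parameter, case = seq_along(r$rd),
    rd_percent = 100 * r$rd, pass = r$pass)))
  inter_df <- do.call(rbind, lapply(rd_inter, function(r) data.frame(
    parameter = r$parameter, global_mean = r$global_mean,
    rd_I_II_percent = r$percent[["rd_I_II"]],
    rd_II_III_percent = r$percent[["rd_II_III"]], ratio = r$ratio)))
  fit_df <- data.frame(group = groups,
                       slope = vapply(fits, `[[`, 0, "slope"),
                       intercept = vapply(fits, `[[`, 0, "intercept"),
                       correlation = vapply(fits, `[[`, 0, "correlation"),
                       n = vapply(fits, `[[`, 0L, "n"))
  rownames(intra_df) <- rownames(inter_df) <- rownames(fit_df) <- NULL
  utils::write.csv(intra_df, file.path(dir, "rd_intragroup.csv"), row.names = FALSE)
  utils::write.csv(inter_df, file.path(dir, "rd_intergroup.csv"), row.names = FALSE)
  utils::write.csv(fit_df, file.path(dir, "regression.csv"), row.names = FALSE)

  structure(list(config = config, dir = dir,
                 record_counts = record_counts,
                 case_stats = case_stats, group_stats = group_stats,
                 group_vectors = group_vectors,
                 histograms = histograms, tests = tests,
                 rd_intragroup = rd_intra, rd_intergroup = rd_inter,
                 fits = fits, proximity_ratio = proximity,
                 provenance = list(seed = config$seed,
                                   package_version = as.character(utils::packageVersion("pulpmorph")))),
            class = "pulp_study")
}

#' Tables-only analysis mode
#'
#' Runs the relative-distance framework directly on supplied case and group
#' mean values (no images), e.g. the published summary tables, so the RD
#' analyses can be reproduced from printed inputs alone.
#'
#' @param cases Data frame like [reference_cases()] (columns `group`,
#'   `case`, `mean_A`, `mean_P`, `mean_FF`).
#' @param groups Data frame like [reference_groups()] (columns `group`,
#'   `mean_A`, `mean_P`, `mean_FF`).
#' @param rd_threshold Intragroup similarity threshold (fraction).
#' @return List of class `tables_report` with `rd_intragroup` (list by
#'   group/parameter) and `rd_intergroup` (list by parameter).
#' @export
tables_report <- function(cases = reference_cases(),
                          groups = reference_groups(),
                          rd_threshold = 0.10) {
  params <- c("A", "P", "FF")
  rd_intra <- list(); rd_inter <- list()
  for (p in params) {
    col <- paste0("mean_", p)
    for (g in unique(cases$group)) {
      cm <- cases[[col]][cases$group == g]
      rd_intra[[paste(g, p)]] <- rd_intragroup(cm, parameter = p, group = g,
                                               threshold = rd_threshold)
    }
    rd_inter[[p]] <- rd_intergroup(groups[[col]], parameter = p)
  }
  structure(list(rd_intragroup = rd_intra, rd_intergroup = rd_inter),
            class = "tables_report")
}

#' @export
print.tables_report <- function(x, ...) {
  for (r in x$rd_intergroup) print(r)
  for (r in x$rd_intragroup) {
    cat(sprintf("group %s [%s]: %d/%d cases below %.0f%%, max RD %.2f%% (case %d)\n",
                r$group, r$parameter, r$n_pass, length(r$rd),
                100 * r$threshold, 100 * r$max_rd, r$max_case))
  }
  invisible(x)
}

#' @export
print.pulp_study <- function(x, ...) {
  cat("Pulp fibroblast morphometric study\n")
  cat(sprintf("  %d groups x %d cases x %d images; %d records total, %d sampled/case\n",
              length(x$config$stages), x$config$n_cases,
              x$config$images_per_case, sum(x$record_counts$n_records),
              x$config$n_sample))
  ffm <- x$group_stats[x$group_stats$parameter == "FF", ]
  cat(sprintf("  group FF means: %s\n",
              paste(sprintf("%s %.3f", ffm$group, ffm$mean), collapse = ", ")))
  cat(sprintf("  FF RD ratio (gI,gII)/(gII,gIII): %.3f; line proximity ratio at A=%g: %.3f\n",
              x$rd_intergroup$FF$ratio, x$config$eval_area, x$proximity_ratio))
  invisible(x)
}

#' @export
summary.pulp_study <- function(object, ...) {
  cat("Group statistics (sampled vectors):\n")
  print(object$group_stats, digits = 4)
  cat("\nHypothesis tests:\n")
  print(object$tests, digits = 4)
  cat("\nIntergroup relative distances:\n")
  for (r in object$rd_intergroup) print(r)
  cat("\nRegression P ~ A per group:\n")
  for (g in names(object$fits)) { cat(sprintf("  %s: ", g)); print(object$fits[[g]]) }
  cat(sprintf("\nLine proximity ratio at A = %g um^2: %.4f\n",
              object$config$eval_area, object$proximity_ratio))
  invisible(object)
}

#' Plot a study
#'
#' `"histogram"`: 20-class histograms of one parameter for the three groups
#' with their Gaussian overlays; `"scattergram"`: per-group P-versus-A
#' scattergrams with regression lines on common axes; `"lines"`: the three
#' regression lines on one comparative panel.
#'
#' @param x A `pulp_study`.
#' @param type Plot type.
#' @param parameter Parameter for `type = "histogram"`.
#' @param ... Unused.
#' @export
plot.pulp_study <- function(x, type = c("histogram", "scattergram", "lines"),
                            parameter = c("A", "P", "FF"), ...) {
  type <- match.arg(type)
  groups <- names(x$config$stages)
  if (type == "histogram") {
    parameter <- match.arg(parameter)
    old <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(old))
    for (g in groups) {
      hh <- x$histograms[[paste(g, parameter)]]
      h <- hh$histogram
      graphics::barplot(h$counts, width = h$class_width, space = 0,
                        col = "grey80", main = sprintf("group %s: %s", g, parameter),
                        xlab = parameter, ylab = "count")
      if (!hh$overlay$flat_spike) {
        graphics::lines((hh$overlay$centers) / h$class_width * h$class_width,
                        hh$overlay$heights, col = "red3", lwd = 2)
      }
      graphics::axis(1, at = seq(0, 20 * h$class_width, by = 5 * h$class_width))
    }
  } else if (type == "scattergram") {
    old <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(old))
    all_a <- unlist(lapply(x$group_vectors, `[[`, "area_um2"))
    all_p <- unlist(lapply(x$group_vectors, `[[`, "perimeter_um"))
    for (g in groups) {
      plot(x$fits[[g]], xlim = range(all_a), ylim = range(all_p),
           main = sprintf("group %s", g))
    }
  } else {
    a <- range(unlist(lapply(x$group_vectors, `[[`, "area_um2")))
    graphics::plot(NA, xlim = a,
                   ylim = range(vapply(x$fits, evaluate_line, numeric(2), a)),
                   xlab = expression(A ~ (mu * m^2)), ylab = expression(P ~ (mu * m)),
                   main = "Regression lines by stage")
    lt <- c(2, 1, 4)
    for (i in seq_along(groups)) {
      graphics::abline(x$fits[[i]]$intercept, x$fits[[i]]$slope, lty = lt[i], lwd = 2)
    }
    graphics::legend("topleft", legend = paste("group", groups), lty = lt, lwd = 2)
  }
  invisible(x)
}
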