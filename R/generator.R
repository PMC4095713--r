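#' Stage parameters for the synthetic-study generator
#'
#' Bundles the statistical and rendering parameters of one developmental
#' stage. Defaults for the three stages are the group-level means and
#' standard deviations of [reference_groups()]; cap-stage cells are rendered
#' as star-like contours, bell-stage cells as fusiform (elliptical) ones.
#'
#' Cell area `A` (um^2) and form factor `FF` are drawn from a bivariate
#' normal truncated to `A > 0`, `0 < FF <= 1`, with correlation `rho_A_FF`
#' (negative by default: within a stage, larger cells are the more elongated
#' ones, which is what makes the perimeter-area relation quasilinear).
#' Perimeter follows exactly as `P = sqrt(4 * pi * A / FF)`.
#'
#' Draws are truncated to the stage's observed ranges (`range_A`,
#' `range_FF`); without the form-factor floor, the `FF^(-1/2)` dependence
#' of the perimeter would produce extreme outliers never seen in real
#' measurements. The pre-truncation centres are adjusted (closed-form
#' truncated-normal moment matching) so the truncated means still equal
#' `mean_A` and `mean_FF`.
#'
#' @param stage `"cap"`, `"early_bell"` or `"late_bell"`.
#' @param mean_A,sd_A Mean and SD of cell area (um^2).
#' @param mean_FF,sd_FF Mean and SD of the form factor (dimensionless).
#' @param range_A,range_FF Truncation bounds `c(lo, hi)`; defaults are the
#'   stage's observed extremes from [reference_groups()].
#' @param cells_per_image Number of cells rendered per image.
#' @param rho_A_FF Correlation between the area and form-factor draws.
#' @param noise List with elements `bg_mean`, `bg_sd`, `fg_mean`, `fg_sd`
#'   (RGB means length 3 and per-channel SDs for background/foreground
#'   colour) and `additive_sd` (additive pixel noise, grey levels).
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(stage = c("cap", "early_bell", "late_bell"),
                         mean_A = NULL, sd_A = NULL,
                         mean_FF = NULL, sd_FF = NULL,
                         range_A = NULL, range_FF = NULL,
                         cells_per_image = 24L,
                         rho_A_FF = -0.75,
                         noise = NULL) {
  stage <- match.arg(stage)
  ref <- reference_groups()
  row <- ref[ref$stage == stage, ]
  if (is.null(mean_A)) mean_A <- row$mean_A
  if (is.null(sd_A)) sd_A <- row$sd_A
  if (is.null(mean_FF)) mean_FF <- row$mean_FF
  if (is.null(sd_FF)) sd_FF <- row$sd_FF
  if (is.null(range_A)) range_A <- c(row$min_A, row$max_A)
  if (is.null(range_FF)) range_FF <- c(row$min_FF, row$max_FF)
  stopifnot_scalar_pos(mean_A, "mean_A")
  if (sd_A < 0 || sd_FF < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (mean_FF <= 0 || mean_FF > 1) stop("'mean_FF' must lie in (0, 1]", call. = FALSE)
  if (abs(rho_A_FF) >= 1) stop("'rho_A_FF' must lie in (-1, 1)", call. = FALSE)
  if (cells_per_image < 0) stop("'cells_per_image' must be >= 0", call. = FALSE)
  if (is.null(noise)) {
    noise <- list(bg_mean = c(231, 190, 205), bg_sd = 4,
                  fg_mean = c(122, 64, 142), fg_sd = 5,
                  additive_sd = 4)
  }
  range_A <- c(max(0, range_A[1]), range_A[2])
  range_FF <- c(max(0, range_FF[1]), min(1, range_FF[2]))
  if (mean_A <= range_A[1] || mean_A >= range_A[2] ||
      mean_FF <= range_FF[1] || mean_FF >= range_FF[2]) {
    stop("target means must lie strictly inside their truncation ranges",
         call. = FALSE)
  }
  ctr <- joint_centers(mean_A, sd_A, range_A, mean_FF, sd_FF, range_FF, rho_A_FF)
  structure(list(stage = stage,
                 family = if (stage == "cap") "star" else "fusiform",
                 mean_A = mean_A, sd_A = sd_A,
                 mean_FF = mean_FF, sd_FF = sd_FF,
                 range_A = range_A, range_FF = range_FF,
                 mu_A = ctr[1], mu_FF = ctr[2],
                 cells_per_image = as.integer(cells_per_image),
                 rho_A_FF = rho_A_FF, noise = noise),
            class = "stage_params")
}

# Means of a bivariate normal truncated to the rectangle [lox,hix] x
# [loy,hiy]: E[X] computed by 1-D quadrature of x * f(x) * P(Y in range | x)
# (and symmetrically for Y).
rect_trunc_means <- function(mux, sdx, rx, muy, sdy, ry, rho) {
  cmean <- function(x, mu_self, sd_self, mu_oth, sd_oth, r_oth) {
    z <- (x - mu_self) / sd_self
    s <- sd_oth * sqrt(1 - rho^2)
    w <- stats::pnorm((r_oth[2] - mu_oth - rho * sd_oth * z) / s) -
      stats::pnorm((r_oth[1] - mu_oth - rho * sd_oth * z) / s)
    stats::dnorm(x, mu_self, sd_self) * w
  }
  ex <- function(mu_self, sd_self, r_self, mu_oth, sd_oth, r_oth) {
    z0 <- stats::integrate(cmean, r_self[1], r_self[2], mu_self = mu_self,
                           sd_self = sd_self, mu_oth = mu_oth, sd_oth = sd_oth,
                           r_oth = r_oth, rel.tol = 1e-9)$value
    z1 <- stats::integrate(function(x) x * cmean(x, mu_self, sd_self, mu_oth,
                                                 sd_oth, r_oth),
                           r_self[1], r_self[2], rel.tol = 1e-9)$value
    z1 / z0
  }
  c(ex(mux, sdx, rx, muy, sdy, ry), ex(muy, sdy, ry, mux, sdx, rx))
}

# Centre of a 1-D normal whose [lo, hi]-truncated mean equals the target.
truncnorm_center <- function(target, sd, range) {
  if (sd == 0) return(target)
  tmean <- function(mu) {
    a <- (range[1] - mu) / sd; b <- (range[2] - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 interval = target + c(-4, 4) * sd, extendInt = "yes",
                 tol = 1e-10)$root
}

# Pre-truncation centres whose rectangle-truncated means equal the targets
# (fixed-point iteration; a zero-sd axis degenerates to the 1-D problem).
joint_centers <- function(mean_A, sd_A, range_A, mean_FF, sd_FF, range_FF, rho) {
  if (sd_A == 0 || sd_FF == 0) {
    return(c(truncnorm_center(mean_A, sd_A, range_A),
             truncnorm_center(mean_FF, sd_FF, range_FF)))
  }
  mu <- c(mean_A, mean_FF)
  for (i in 1:60) {
    m <- rect_trunc_means(mu[1], sd_A, range_A, mu[2], sd_FF, range_FF, rho)
    delta <- c(mean_A, mean_FF) - m
    mu <- mu + delta
    if (max(abs(delta / c(sd_A, sd_FF))) < 1e-8) break
  }
  mu
}

# Correlated truncated-normal draws of (A, FF); redraws rejected rows.
draw_a_ff <- function(params, n) {
  rho <- params$rho_A_FF
  A <- numeric(n); FF <- numeric(n)
  need <- rep(TRUE, n)
  for (it in 1:1000) {
    m <- sum(need)
    if (m == 0L) break
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    a <- params$mu_A + params$sd_A * z1
    f <- params$mu_FF + params$sd_FF * z2
    ok <- a >= params$range_A[1] & a <= params$range_A[2] &
      f >= params$range_FF[1] & f <= params$range_FF[2]
    idx <- which(need)[ok]
    A[idx] <- a[ok]; FF[idx] <- f[ok]
    need[idx] <- FALSE
  }
  if (any(need)) stop("truncated-normal rejection sampling did not converge",
                      call. = FALSE)
  data.frame(area_um2 = A, form_factor = FF)
}

#' Draw cell records directly from a stage distribution
#'
#' Bypasses imaging: samples (A, FF) from the stage's truncated bivariate
#' normal and derives the perimeter as `P = sqrt(4 * pi * A / FF)` (the
#' relation implied by `FF = 4 * pi * A / P^2`). Useful for fast statistical
#' tests of the downstream analysis.
#'
#' @param params A [stage_params()] object.
#' @param n Number of records (>= 1).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Data frame with columns `area_um2`, `perimeter_um`, `form_factor`.
#' @export
generate_stage_records <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "stage_params"))
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  with_seed(seed, {
    if (params$sd_A == 0 && params$sd_FF == 0) {
      d <- data.frame(area_um2 = rep(params$mean_A, n),
                      form_factor = rep(params$mean_FF, n))
    } else {
      d <- draw_a_ff(params, n)
    }
    d$perimeter_um <- sqrt(4 * pi * d$area_um2 / d$form_factor)
    d[, c("area_um2", "perimeter_um", "form_factor")]
  })
}

# Rasterise a star-convex polygon: pixel centre (col - 0.5, row - 0.5) * cal
# is inside iff it lies on the centre side of the chord of its angular
# sector. Exact with respect to the polygon. Returns linear indices into an
# nrow x ncol matrix.
rasterize_polygon <- function(polygon, center, dim_px, microns_per_pixel) {
  cal <- microns_per_pixel
  vx <- polygon[, 1] / cal; vy <- polygon[, 2] / cal
  cx <- center[1] / cal; cy <- center[2] / cal
  cols <- max(1L, ceiling(min(vx) + 0.5)):min(dim_px[2], floor(max(vx) + 0.5))
  rows <- max(1L, ceiling(min(vy) + 0.5)):min(dim_px[1], floor(max(vy) + 0.5))
  if (length(cols) == 0L || length(rows) == 0L) return(integer(0))
  px <- rep(cols, each = length(rows)) - 0.5
  py <- rep(rows, times = length(cols)) - 0.5
  va <- atan2(vy - cy, vx - cx)
  o <- order(va)
  va <- va[o]; sx <- vx[o]; sy <- vy[o]
  nvert <- length(va)
  i1 <- findInterval(atan2(py - cy, px - cx), va)
  i1[i1 == 0L] <- nvert
  i2 <- i1 %% nvert + 1L
  cross <- (sx[i2] - sx[i1]) * (py - sy[i1]) - (sy[i2] - sy[i1]) * (px - sx[i1])
  inside <- cross >= 0
  ri <- rep(rows, times = length(cols))[inside]
  ci <- rep(cols, each = length(rows))[inside]
  ri + (ci - 1L) * dim_px[1]
}

#' Render a synthetic study image
#'
#' Paints ground-truth cells over a noisy background. Background and
#' foreground pixels are drawn from the stage's colour distributions, then
#' additive Gaussian noise is applied and values are clipped to `[0, 255]`.
#' The painted pixel set of every cell is returned as segmentation truth.
#'
#' @param records List of ground-truth records as produced by
#'   [place_cells()]: each has elements `polygon` (um), `center` (um) and
#'   identifiers.
#' @param params A [stage_params()] (colour/noise model).
#' @param dim_px Image size `c(rows, cols)` in pixels.
#' @param microns_per_pixel Calibration (um per pixel).
#' @param seed Optional seed for the pixel noise.
#' @return List with `image` (rows x cols x 3 array, 0-255), `truth_labels`
#'   (integer matrix, 0 = background, k = cell k) and `pixels` (list of
#'   linear pixel indices per cell). Errors if two cells overlap.
#' @export
render_study_image <- function(records, params, dim_px, microns_per_pixel,
                               seed = NULL) {
  stopifnot(inherits(params, "stage_params"))
  dim_px <- as.integer(dim_px)
  nz <- params$noise
  with_seed(seed, {
    npx <- prod(dim_px)
    img <- array(0, dim = c(dim_px[1], dim_px[2], 3))
    for (ch in 1:3) {
      img[, , ch] <- stats::rnorm(npx, nz$bg_mean[ch], nz$bg_sd)
    }
    truth <- matrix(0L, dim_px[1], dim_px[2])
    pixels <- vector("list", length(records))
    for (k in seq_along(records)) {
      rec <- records[[k]]
      idx <- rasterize_polygon(rec$polygon, rec$center, dim_px, microns_per_pixel)
      if (any(truth[idx] != 0L)) {
        stop(sprintf("cell %d overlaps cell %d in rendered image", k,
                     truth[idx][truth[idx] != 0L][1]), call. = FALSE)
      }
      truth[idx] <- k
      for (ch in 1:3) {
        img[idx + (ch - 1L) * npx] <- stats::rnorm(length(idx), nz$fg_mean[ch], nz$fg_sd)
      }
      pixels[[k]] <- idx
    }
    img <- img + stats::rnorm(3 * npx, 0, nz$additive_sd)
    img[img < 0] <- 0; img[img > 255] <- 255
    list(image = img, truth_labels = truth, pixels = pixels)
  })
}

#' Draw and place non-overlapping ground-truth cells for one image
#'
#' Samples `(A, FF)` for each cell from the stage distribution, solves the
#' matching contour (star lobe amplitude or fusiform aspect ratio), and
#' places cells by rejection sampling of centre and orientation: a candidate
#' is accepted when its rasterised footprint, dilated by one pixel, is
#' disjoint from all previously placed cells (so segmented regions stay
#' separate under 8-connectivity).
#'
#' @param params A [stage_params()].
#' @param n_cells Number of cells to place.
#' @param dim_px Image size `c(rows, cols)` in pixels.
#' @param microns_per_pixel Calibration (um per pixel).
#' Cells are placed in decreasing order of spatial extent (elongated cells
#' first, while the field is still empty), which keeps rejection sampling
#' reliable even for the long fusiform cells of the late bell stage;
#' `cell_id` still numbers the records in draw order.
#'
#' @param seed Optional seed.
#' @param max_retries Placement attempts per cell before failing.
#' @return List of records, each with `cell_id`, `polygon`, `center`,
#'   `area_true`, `perimeter_true`, `ff_true`.
#' @export
place_cells <- function(params, n_cells, dim_px, microns_per_pixel,
                        seed = NULL, max_retries = 200L) {
  stopifnot(inherits(params, "stage_params"))
  dim_px <- as.integer(dim_px)
  cal <- microns_per_pixel
  with_seed(seed, {
    if (n_cells == 0L) return(list())
    draws <- generate_stage_records(params, n_cells)
    occ <- matrix(FALSE, dim_px[1], dim_px[2])
    out <- vector("list", n_cells)
    max_extent <- 0.45 * min(dim_px) * cal
    shapes <- vector("list", n_cells)
    extents <- numeric(n_cells)
    for (k in seq_len(n_cells)) {
      lobe_k <- if (params$family == "star") sample(5:7, 1L) else 5L
      spec0 <- solve_shape(params$family, draws$area_um2[k],
                           draws$form_factor[k], lobe_count = lobe_k,
                           min_halfwidth_um = 1.3 * cal,
                           max_extent_um = max_extent)
      shapes[[k]] <- generate_contour(spec0)
      extents[k] <- max(sqrt(shapes[[k]][, 1]^2 + shapes[[k]][, 2]^2))
    }
    for (k in order(extents, decreasing = TRUE)) {
      poly0 <- shapes[[k]]
      ext <- extents[k]
      lo <- ext + 2 * cal
      hi_x <- dim_px[2] * cal - ext - 2 * cal
      hi_y <- dim_px[1] * cal - ext - 2 * cal
      if (hi_x <= lo || hi_y <= lo) {
        stop(sprintf("cell %d (extent %.1f um) does not fit the %dx%d px image",
                     k, ext, dim_px[1], dim_px[2]), call. = FALSE)
      }
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        rot <- stats::runif(1, 0, pi)
        ctr <- c(stats::runif(1, lo, hi_x), stats::runif(1, lo, hi_y))
        co <- cos(rot); si <- sin(rot)
        poly <- cbind(x = co * poly0[, 1] - si * poly0[, 2] + ctr[1],
                      y = si * poly0[, 1] + co * poly0[, 2] + ctr[2])
        idx <- rasterize_polygon(poly, ctr, dim_px, cal)
        if (length(idx) == 0L) next
        ri <- (idx - 1L) %% dim_px[1] + 1L
        ci <- (idx - 1L) %/% dim_px[1] + 1L
        hit <- FALSE
        for (dr in -1:1) {
          for (dc in -1:1) {
            r2 <- pmin(pmax(ri + dr, 1L), dim_px[1])
            c2 <- pmin(pmax(ci + dc, 1L), dim_px[2])
            if (any(occ[r2 + (c2 - 1L) * dim_px[1]])) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (!hit) {
          occ[idx] <- TRUE
          ap <- polygon_area_perimeter(poly)
          out[[k]] <- list(cell_id = k, polygon = poly, center = ctr,
                           area_true = ap$area, perimeter_true = ap$perimeter,
                           ff_true = 4 * pi * ap$area / ap$perimeter^2)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place cell %d without overlap after %d retries",
                     k, max_retries), call. = FALSE)
      }
    }
    out[order(vapply(out, `[[`, 0, "cell_id"))]
  })
}

polygon_to_wkt <- function(polygon) {
  pts <- rbind(polygon, polygon[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", pts[, 1], pts[, 2]), collapse = ", "))
}

#' Generate a complete synthetic study on disk
#'
#' Builds the full study layout (3 groups x `n_cases` cases x
#' `images_per_case` images) under `dir`: one PNG per image, a ground-truth
#' CSV with the analytic area, perimeter and form factor of every rendered
#' cell (plus its polygon in WKT), and a `config.json` provenance file. The
#' whole tree is reproducible from the master seed.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a manifest data frame with one row per image (`group`,
#'   `case_id`, `image_id`, `path`, `n_cells`).
#' @export
generate_study <- function(config = study_config(), dir) {
  if (missing(dir)) stop("'dir' is required", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create study directory '%s'", dir),
                             call. = FALSE)
  groups <- names(config$stages)
  n_img <- length(groups) * config$n_cases * config$images_per_case
  seeds <- derive_seeds(config$seed, 2L * n_img)
  manifest <- vector("list", n_img)
  truth <- vector("list", n_img)
  i <- 0L
  for (g in groups) {
    sp <- config$stages[[g]]
    for (cs in seq_len(config$n_cases)) {
      case_dir <- file.path(dir, sprintf("group_%s", g), sprintf("case_%d", cs))
      dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
      for (im in seq_len(config$images_per_case)) {
        i <- i + 1L
        recs <- place_cells(sp, sp$cells_per_image, config$dim_px,
                            config$microns_per_pixel, seed = seeds[2L * i - 1L])
        rendered <- render_study_image(recs, sp, config$dim_px,
                                       config$microns_per_pixel,
                                       seed = seeds[2L * i])
        path <- file.path(case_dir, sprintf("image_%d.png", im))
        png::writePNG(rendered$image / 255, target = path)
        manifest[[i]] <- data.frame(group = g, case_id = cs, image_id = im,
                                    path = path, n_cells = length(recs),
                                    stringsAsFactors = FALSE)
        if (length(recs) > 0L) {
          truth[[i]] <- data.frame(
            group = g, case_id = cs, image_id = im,
            cell_id = vapply(recs, `[[`, 0, "cell_id"),
            area_true = vapply(recs, `[[`, 0, "area_true"),
            perimeter_true = vapply(recs, `[[`, 0, "perimeter_true"),
            ff_true = vapply(recs, `[[`, 0, "ff_true"),
            polygon_wkt = vapply(recs, function(r) polygon_to_wkt(r$polygon), ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- unclass(config)
  cfg$stages <- lapply(cfg$stages, unclass)
  cfg$threshold <- unclass(cfg$threshold)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
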