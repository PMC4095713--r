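#' Spatial calibration
#'
#' @param microns_per_pixel Pixel size in micrometres (> 0).
#' @param magnification Informational tag, e.g. `"x200"`.
#' @return An object of class `calibration`.
#' @export
calibration <- function(microns_per_pixel = 0.25, magnification = "x200") {
  stopifnot_scalar_pos(microns_per_pixel, "microns_per_pixel")
  structure(list(microns_per_pixel = microns_per_pixel,
                 magnification = magnification),
            class = "calibration")
}

# Trace the crack (inter-pixel) boundary of a single 8-connected region.
# Vertices are pixel corners: pixel (r, c) occupies [c-1, c] x [r-1, r].
# The walk keeps foreground on its right; at saddle corners the left turn is
# preferred, which keeps diagonally-touching pixels on one boundary
# (8-connected foreground). Returns the closed polygon as an n x 2 matrix
# (x, y) in pixel units; interior holes are not traced (cells here are
# solid).
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  px <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  idx <- which(t(mask))[1]  # first foreground pixel in row-major order
  if (is.na(idx)) stop("empty mask", call. = FALSE)
  r0 <- (idx - 1L) %/% nc + 1L; c0 <- (idx - 1L) %% nc + 1L
  sx <- c0 - 1L; sy <- r0 - 1L
  step <- list(R = c(1L, 0L), D = c(0L, 1L), L = c(-1L, 0L), U = c(0L, -1L))
  leftturn  <- c(R = "U", U = "L", L = "D", D = "R")
  rightturn <- c(R = "D", D = "L", L = "U", U = "R")
  valid <- function(x, y, o) {
    switch(o,
           R = px(y + 1L, x + 1L) && !px(y,      x + 1L),
           L = px(y,      x)      && !px(y + 1L, x),
           D = px(y + 1L, x)      && !px(y + 1L, x + 1L),
           U = px(y,      x + 1L) && !px(y,      x))
  }
  cap <- 4L * sum(mask) + 8L
  vx <- integer(cap); vy <- integer(cap)
  x <- sx; y <- sy; d <- "R"
  k <- 0L
  repeat {
    k <- k + 1L
    if (k > cap) stop("boundary trace failed to close", call. = FALSE)
    vx[k] <- x; vy[k] <- y
    x <- x + step[[d]][1]; y <- y + step[[d]][2]
    nd <- NA_character_
    for (o in c(leftturn[[d]], d, rightturn[[d]])) {
      if (valid(x, y, o)) { nd <- o; break }
    }
    if (is.na(nd)) stop("boundary trace stuck", call. = FALSE)
    d <- nd
    if (x == sx && y == sy && d == "R") break
  }
  cbind(x = vx[1:k], y = vy[1:k])
}

# Ramer-Douglas-Peucker simplification of an open polyline (keeps endpoints).
rdp_open <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  L <- sqrt(sum(ab^2))
  d <- if (L == 0) {
    sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
  } else {
    abs(ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1])) / L
  }
  i <- which.max(d)
  if (d[i] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- rdp_open(pts[1:i, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], rdp_open(pts[i:n, , drop = FALSE], tol))
}

closed_length <- function(pts) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Perimeter estimators for pixel regions
#'
#' `perimeter_simplified()` (the default used by [measure_region()]) traces
#' the crack boundary of the region and simplifies it with the
#' Ramer-Douglas-Peucker algorithm at a 1.3-pixel tolerance before summing
#' edge lengths; this removes the quantisation staircase, is exact on
#' axis-aligned rectangles and biased by only about 1-3% on discs down to an
#' 8-pixel radius. `perimeter_crack()` returns the raw crack length (the
#' count of exposed pixel edges), which is exact for axis-aligned shapes but
#' overestimates smooth contours by up to 4/pi.
#'
#' @param mask Logical matrix containing a single 8-connected region.
#' @param tol Simplification tolerance in pixels.
#' @return Perimeter in pixel units.
#' @export
perimeter_simplified <- function(mask, tol = 1.3) {
  poly <- trace_boundary(mask)
  n <- nrow(poly)
  if (n <= 4L) return(closed_length(poly))
  far <- which.max((poly[, 1] - poly[1, 1])^2 + (poly[, 2] - poly[1, 2])^2)
  arc1 <- rdp_open(poly[1:far, , drop = FALSE], tol)
  arc2 <- rdp_open(rbind(poly[far:n, , drop = FALSE], poly[1, , drop = FALSE]), tol)
  pts <- rbind(arc1[-nrow(arc1), , drop = FALSE], arc2)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' @rdname perimeter_simplified
#' @export
perimeter_crack <- function(mask) {
  nrow(trace_boundary(mask))  # unit steps on the crack polygon
}

#' Measure one labelled region
#'
#' Area is pure pixel counting scaled by the squared calibration; perimeter
#' is estimated on the region's crack boundary (see
#' [perimeter_simplified()]) and scaled by the calibration.
#'
#' @param pixels Integer vector of linear pixel indices of the region.
#' @param dim_px Dimensions `c(rows, cols)` of the source mask.
#' @param cal A [calibration()].
#' @param estimator Perimeter estimator: a function of a logical region
#'   mask returning pixels (default [perimeter_simplified()]).
#' @return List with `area` (um^2) and `perimeter` (um).
#' @export
measure_region <- function(pixels, dim_px, cal = calibration(),
                           estimator = perimeter_simplified) {
  if (length(pixels) == 0L) stop("empty region", call. = FALSE)
  stopifnot(inherits(cal, "calibration"))
  mpp <- cal$microns_per_pixel
  ri <- (pixels - 1L) %% dim_px[1] + 1L
  ci <- (pixels - 1L) %/% dim_px[1] + 1L
  # region sub-mask with a 1-pixel pad for boundary tracing
  sub <- matrix(FALSE, max(ri) - min(ri) + 3L, max(ci) - min(ci) + 3L)
  sub[cbind(ri - min(ri) + 2L, ci - min(ci) + 2L)] <- TRUE
  list(area = length(pixels) * mpp^2,
       perimeter = estimator(sub) * mpp)
}

#' Form factor
#'
#' Circularity descriptor `FF = 4 * pi * A / P^2`: 1 for a perfect circle
#' and decreasing with elongation or boundary complexity. Values above 1
#' can arise for tiny regions from digital perimeter underestimation; they
#' are returned as-is with attribute `flag = TRUE` rather than clipped.
#'
#' @param area Area (> 0).
#' @param perimeter Perimeter (> 0), same length unit.
#' @return Numeric; attribute `flag` is `TRUE` where the value exceeds 1.
#' @examples
#' form_factor(25, 40)  # pi/16
#' @export
form_factor <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("'area' and 'perimeter' must be positive", call. = FALSE)
  }
  ff <- 4 * pi * area / perimeter^2
  attr(ff, "flag") <- ff > 1
  ff
}

#' Measure all regions of a labelled image
#'
#' One record per region, in label order (labels are deterministic,
#' row-major by first pixel).
#'
#' @param labeled A `labeled_regions` object from [label_regions()].
#' @param cal A [calibration()].
#' @param case_id,image_id Identifiers copied into the records.
#' @param estimator Perimeter estimator passed to [measure_region()].
#' @return Data frame with columns `case_id`, `image_id`, `region_id`,
#'   `area_um2`, `perimeter_um`, `form_factor`, `ff_flag`.
#' @export
measure_image <- function(labeled, cal = calibration(), case_id = 1L,
                          image_id = 1L, estimator = perimeter_simplified) {
  stopifnot(inherits(labeled, "labeled_regions"))
  n <- labeled$n
  if (n == 0L) {
    return(data.frame(case_id = character(0), image_id = integer(0),
                      region_id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), form_factor = numeric(0),
                      ff_flag = logical(0)))
  }
  dim_px <- dim(labeled$labels)
  area <- numeric(n); per <- numeric(n)
  for (k in seq_len(n)) {
    m <- tryCatch(measure_region(labeled$pixels[[k]], dim_px, cal, estimator),
                  error = function(e) {
                    stop(sprintf("region %d: %s", k, conditionMessage(e)),
                         call. = FALSE)
                  })
    area[k] <- m$area; per[k] <- m$perimeter
  }
  ff <- form_factor(area, per)
  data.frame(case_id = rep(case_id, n), image_id = rep(image_id, n),
             region_id = seq_len(n), area_um2 = area, perimeter_um = per,
             form_factor = as.numeric(ff), ff_flag = attr(ff, "flag"))
}
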