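#' Parametric cell-contour specification
#'
#' Describes one ground-truth cell outline. Two families are supported:
#' `"star"` cells with radial profile r(theta) = base_radius * (1 +
#' lobe_amplitude * cos(lobe_count * theta)), emulating the star-like
#' fibroblasts of the cap stage, and `"fusiform"` cells (ellipses of a given
#' aspect ratio) emulating the near-fusiform cells of the bell stages.
#'
#' @param family `"star"` or `"fusiform"`.
#' @param base_radius Base radius in micrometres (star: mean radius;
#'   fusiform: semi-minor axis).
#' @param lobe_amplitude Star only; lobe depth as a fraction in `[0, 1)`.
#'   Values `>= 1` are rejected because the radial profile would touch or
#'   cross zero and the contour could self-intersect.
#' @param lobe_count Star only; integer number of lobes, at least 3.
#' @param aspect_ratio Fusiform only; semi-major / semi-minor, at least 1.
#' @param rotation Rotation of the contour in radians.
#' @param center Numeric length-2, contour centre (x, y) in micrometres.
#' @param vertex_count Number of polygon vertices (>= 32; default 128 keeps
#'   the polygonal discretisation error of the form factor below 0.5%).
#' @return An object of class `shape_spec`.
#' @seealso [generate_contour()]
#' @export
shape_spec <- function(family = c("star", "fusiform"),
                       base_radius,
                       lobe_amplitude = 0,
                       lobe_count = 5L,
                       aspect_ratio = 1,
                       rotation = 0,
                       center = c(0, 0),
                       vertex_count = 128L) {
  family <- match.arg(family)
  stopifnot_scalar_pos(base_radius, "base_radius")
  if (family == "star") {
    if (!is.numeric(lobe_amplitude) || lobe_amplitude < 0 || lobe_amplitude >= 1) {
      stop("'lobe_amplitude' must lie in [0, 1)", call. = FALSE)
    }
    if (lobe_count < 3) stop("'lobe_count' must be at least 3", call. = FALSE)
  } else {
    if (!is.numeric(aspect_ratio) || aspect_ratio < 1) {
      stop("'aspect_ratio' must be >= 1", call. = FALSE)
    }
  }
  if (vertex_count < 32) stop("'vertex_count' must be at least 32", call. = FALSE)
  structure(list(family = family, base_radius = base_radius,
                 lobe_amplitude = lobe_amplitude,
                 lobe_count = as.integer(lobe_count),
                 aspect_ratio = aspect_ratio, rotation = rotation,
                 center = as.numeric(center),
                 vertex_count = as.integer(vertex_count)),
            class = "shape_spec")
}

#' Generate a closed polygonal cell contour
#'
#' Samples the parametric outline of a [shape_spec()] at `vertex_count`
#' uniformly spaced parameter values, applies rotation and translation, and
#' returns the vertices. The resulting polygon is simple (star-convex about
#' its centre) by construction.
#'
#' @param spec A [shape_spec()].
#' @return Numeric matrix with columns `x`, `y` (micrometres), one row per
#'   vertex, in counter-clockwise order; the closing edge is implicit.
#' @examples
#' poly <- generate_contour(shape_spec("star", 10, lobe_amplitude = 0.5))
#' polygon_area_perimeter(poly)
#' @export
generate_contour <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  theta <- seq(0, 2 * pi, length.out = spec$vertex_count + 1L)[-(spec$vertex_count + 1L)]
  if (spec$family == "star") {
    r <- spec$base_radius * (1 + spec$lobe_amplitude * cos(spec$lobe_count * theta))
    x <- r * cos(theta)
    y <- r * sin(theta)
  } else {
    x <- spec$base_radius * spec$aspect_ratio * cos(theta)
    y <- spec$base_radius * sin(theta)
  }
  co <- cos(spec$rotation); si <- sin(spec$rotation)
  out <- cbind(x = co * x - si * y + spec$center[1],
               y = si * x + co * y + spec$center[2])
  out
}

#' Polygon area and perimeter
#'
#' Area by the shoelace formula (absolute value, so vertex orientation does
#' not matter) and perimeter as the summed edge lengths of the closed
#' polygon. This is the analytic oracle against which pixel-level
#' measurements are compared.
#'
#' @param polygon Numeric matrix with columns `x`, `y`; at least 3 rows.
#' @return Named list with `area` and `perimeter` (in the units of the
#'   input coordinates, squared for the area).
#' @examples
#' sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' polygon_area_perimeter(sq)  # area 1, perimeter 4
#' @export
polygon_area_perimeter <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area == 0) stop("degenerate polygon with zero area", call. = FALSE)
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area, perimeter = perimeter)
}

# Form factor of a polygon: 4*pi*A/P^2.
polygon_ff <- function(polygon) {
  ap <- polygon_area_perimeter(polygon)
  4 * pi * ap$area / ap$perimeter^2
}

# Analytic form factor of a shape spec family at unit scale (FF is
# scale-invariant, so base_radius is irrelevant).
shape_ff <- function(family, lobe_amplitude = 0, lobe_count = 5L,
                     aspect_ratio = 1, vertex_count = 128L) {
  spec <- shape_spec(family, base_radius = 1,
                     lobe_amplitude = lobe_amplitude, lobe_count = lobe_count,
                     aspect_ratio = aspect_ratio, vertex_count = vertex_count)
  polygon_ff(generate_contour(spec))
}

# Invert FF -> shape parameters for one cell. Returns a shape_spec at the
# requested area (um^2). Star cells solve the lobe amplitude (escalating the
# lobe count when the target is below the family's reach); fusiform cells
# solve the aspect ratio, capped for rasterisation stability by
# max_aspect and, through min_halfwidth_um, by a minimum physical width.
solve_shape <- function(family, area_um2, ff_target, lobe_count = 5L,
                        rotation = 0, center = c(0, 0), vertex_count = 128L,
                        max_aspect = 60, min_halfwidth_um = 0,
                        max_extent_um = Inf) {
  stopifnot_scalar_pos(area_um2, "area_um2")
  stopifnot_scalar_pos(ff_target, "ff_target")
  nv <- as.integer(vertex_count)
  if (family == "star") {
    k <- as.integer(lobe_count)
    amp <- NA_real_
    repeat {
      ff_hi <- shape_ff("star", 0, k, vertex_count = nv)        # ~1
      ff_lo <- shape_ff("star", 0.95, k, vertex_count = max(nv, 32L * k))
      if (ff_target >= ff_hi) { amp <- 0; break }
      if (ff_target <= ff_lo) {
        if (k < 11L) { k <- k + 2L; next }
        amp <- 0.95; break
      }
      amp <- stats::uniroot(function(a)
        shape_ff("star", a, k, vertex_count = max(nv, 32L * k)) - ff_target,
        c(0, 0.95), tol = 1e-6)$root
      break
    }
    nv_k <- max(nv, 32L * k)
    unit <- shape_spec("star", 1, lobe_amplitude = amp, lobe_count = k,
                       vertex_count = nv_k)
    a1 <- polygon_area_perimeter(generate_contour(unit))$area
    R <- sqrt(area_um2 / a1)
    shape_spec("star", R, lobe_amplitude = amp, lobe_count = k,
               rotation = rotation, center = center, vertex_count = nv_k)
  } else {
    # joint caps: aspect, minimum half-width, maximum tip-to-tip extent
    q_hi <- max_aspect
    if (min_halfwidth_um > 0) {
      q_hi <- min(q_hi, max(1, area_um2 / (pi * min_halfwidth_um^2)))
    }
    if (is.finite(max_extent_um)) {
      q_hi <- min(q_hi, max(1, pi * max_extent_um^2 / (4 * area_um2)))
    }
    ff_lo <- shape_ff("fusiform", aspect_ratio = q_hi, vertex_count = nv)
    q <- if (ff_target <= ff_lo) q_hi
    else if (ff_target >= shape_ff("fusiform", aspect_ratio = 1, vertex_count = nv)) 1
    else stats::uniroot(function(q)
      shape_ff("fusiform", aspect_ratio = q, vertex_count = nv) - ff_target,
      c(1, q_hi), tol = 1e-6)$root
    unit <- shape_spec("fusiform", 1, aspect_ratio = q, vertex_count = nv)
    a1 <- polygon_area_perimeter(generate_contour(unit))$area
    b <- sqrt(area_um2 / a1)
    shape_spec("fusiform", b, aspect_ratio = q, rotation = rotation,
               center = center, vertex_count = nv)
  }
}
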