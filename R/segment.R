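#' Per-channel RGB threshold specification
#'
#' Inclusive low/high bounds per colour channel, on the 0-255 scale. A pixel
#' is classified as foreground (candidate fibroblast) when all three channel
#' values lie within their bounds.
#'
#' @param r,g,b Numeric length-2 vectors `c(low, high)`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(r = c(0, 255), g = c(0, 255), b = c(0, 255)) {
  for (ch in list(r = r, g = g, b = b)) {
    if (length(ch) != 2L || any(ch < 0) || any(ch > 255) || ch[1] > ch[2]) {
      stop("channel bounds must be c(low, high) within [0, 255], low <= high",
           call. = FALSE)
    }
  }
  structure(list(r = as.numeric(r), g = as.numeric(g), b = as.numeric(b)),
            class = "threshold_spec")
}

# Default bounds matching the synthetic foreground colour (see stage_params):
# each bound sits ~6 combined-noise SDs from the foreground mean and >= 10
# SDs from the background, so classification of noise-free structure is
# essentially exact.
default_threshold_spec <- function() {
  threshold_spec(r = c(82, 162), g = c(24, 104), b = c(102, 182))
}

#' Linear percentile contrast stretch
#'
#' Per-channel preprocessing used on real micrographs before thresholding:
#' the `p_low` and `p_high` quantiles are mapped linearly to 0 and 255 and
#' the result is clipped. A constant channel (stretch undefined) is returned
#' unchanged.
#'
#' @param image rows x cols x 3 numeric array, values 0-255.
#' @param p_low,p_high Stretch percentiles (defaults 0.01 and 0.99).
#' @return Array of the same dimensions, values in `[0, 255]`.
#' @export
enhance_contrast <- function(image, p_low = 0.01, p_high = 0.99) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L || length(image) == 0L) {
    stop("'image' must be a non-empty rows x cols x 3 array", call. = FALSE)
  }
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    q <- stats::quantile(v, c(p_low, p_high), names = FALSE)
    if (q[2] <= q[1]) next  # constant (or degenerate) channel: identity
    s <- (v - q[1]) * (255 / (q[2] - q[1]))
    s[s < 0] <- 0; s[s > 255] <- 255
    out[, , ch] <- s
  }
  out
}

#' RGB threshold segmentation
#'
#' Classifies each pixel as foreground when all three channel values lie
#' within the inclusive bounds of `spec`; the result is a binary mask of
#' candidate fibroblast pixels.
#'
#' @param image rows x cols x 3 array (0-255).
#' @param spec A [threshold_spec()].
#' @return Logical matrix of the image dimensions.
#' @export
threshold_rgb <- function(image, spec = default_threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("'image' must be a rows x cols x 3 array", call. = FALSE)
  }
  image[, , 1] >= spec$r[1] & image[, , 1] <= spec$r[2] &
    image[, , 2] >= spec$g[1] & image[, , 2] <= spec$g[2] &
    image[, , 3] >= spec$b[1] & image[, , 3] <= spec$b[2]
}

#' Remove scrap regions from a binary mask
#'
#' Deletes connected components (8-connectivity) whose pixel count is below
#' `min_area_px`; components of exactly `min_area_px` pixels are retained.
#' Idempotent by construction.
#'
#' @param mask Logical matrix.
#' @param min_area_px Minimum component size in pixels (default 20, i.e.
#'   1.25 um^2 at the default 0.25 um/px calibration).
#' @return Logical matrix with small components removed.
#' @export
remove_scrap <- function(mask, min_area_px = 20L) {
  if (min_area_px < 0) stop("'min_area_px' must be >= 0", call. = FALSE)
  if (!any(mask)) return(mask)
  lab <- label_matrix(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  mask & (lab %in% keep)
}

#' Label connected foreground regions
#'
#' Connected-component labelling of a binary mask with deterministic label
#' order: regions are numbered 1..k by the position of their first pixel in
#' a row-major scan (left to right within each row, top row first).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default; background then 4-connected) or 4.
#' @return List of class `labeled_regions` with `labels` (integer matrix),
#'   `n` (region count) and `pixels` (list of linear pixel indices per
#'   region).
#' @export
label_regions <- function(mask, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- label_matrix(mask, connectivity)
  n <- max(lab, 0L)
  if (n == 0L) {
    return(structure(list(labels = lab, n = 0L, pixels = list()),
                     class = "labeled_regions"))
  }
  # relabel by first pixel in row-major order
  idx <- which(lab > 0L)
  rowmajor <- ((idx - 1L) %% nr) * nc + ((idx - 1L) %/% nr)  # scan position
  first <- tapply(rowmajor, lab[idx], min)
  new_of_old <- integer(n)
  new_of_old[as.integer(names(first))[order(first)]] <- seq_len(n)
  lab[idx] <- new_of_old[lab[idx]]
  pixels <- split(idx, factor(lab[idx], levels = seq_len(n)))
  names(pixels) <- NULL
  structure(list(labels = lab, n = n, pixels = pixels),
            class = "labeled_regions")
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, 4-components touching diagonally are merged (union-find).
label_matrix <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1L)), nr, nc)
  n <- max(lab, 0L)
  if (connectivity == 4L || n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  # diagonal neighbour pairs (two offsets cover both diagonals)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, 0L)
    compact <- match(root, sort(unique(root)))
    lab[lab > 0L] <- compact[lab[lab > 0L]]
  }
  lab
}
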