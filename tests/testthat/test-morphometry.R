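test_that("pixel measurement matches closed forms on rectangles and single pixels", {
  cal05 <- calibration(0.5)
  m <- rect_mask(10, 10)
  res <- measure_region(which(m), dim(m), cal05)
  expect_equal(res$area, 25)       # 100 px * 0.25 um^2
  expect_equal(res$perimeter, 20)  # 40 unit steps * 0.5 um
  cal1 <- calibration(1)
  px <- rect_mask(1, 1)
  res1 <- measure_region(which(px), dim(px), cal1)
  expect_equal(res1$area, 1)
  expect_equal(res1$perimeter, 4)
  expect_error(measure_region(integer(0), c(4, 4), cal1), "empty")
})

test_that("disc perimeter is within the estimator's stated bias of the analytic value", {
  for (r in c(40, 60)) {
    m <- disc_mask(r)
    res <- measure_region(which(m), dim(m), calibration(1))
    expect_equal(res$perimeter, 2 * pi * r, tolerance = 0.03)
    expect_equal(res$area, pi * r^2, tolerance = 0.02)
  }
  # raw crack length overestimates a disc by ~4/pi; sanity-check the alternative
  m <- disc_mask(40)
  crack <- measure_region(which(m), dim(m), calibration(1),
                          estimator = perimeter_crack)$perimeter
  expect_gt(crack / (2 * pi * 40), 1.2)
})

test_that("form factor evaluates, flags impossible values, and rejects bad input", {
  expect_equal(as.numeric(form_factor(pi, 2 * pi)), 1)
  expect_equal(as.numeric(form_factor(25, 40)), pi / 16)
  expect_false(attr(form_factor(25, 40), "flag"))
  expect_true(attr(form_factor(10, 1), "flag"))   # FF > 1 flagged, not clipped
  expect_gt(as.numeric(form_factor(10, 1)), 1)
  expect_error(form_factor(0, 5), "positive")
  expect_error(form_factor(5, -1), "positive")
})

test_that("calibration scaling: doubling the pixel size quadruples area, doubles perimeter", {
  m <- disc_mask(15)
  r1 <- measure_region(which(m), dim(m), calibration(0.25))
  r2 <- measure_region(which(m), dim(m), calibration(0.5))
  expect_equal(r2$area, 4 * r1$area, tolerance = 1e-12)
  expect_equal(r2$perimeter, 2 * r1$perimeter, tolerance = 1e-12)
  # FF is calibration invariant
  expect_equal(as.numeric(form_factor(r1$area, r1$perimeter)),
               as.numeric(form_factor(r2$area, r2$perimeter)),
               tolerance = 1e-12)
})

test_that("measurements are invariant under translation and 90-degree rotation", {
  base <- disc_mask(9)                # asymmetric compound region
  base[16:19, 5:35] <- TRUE
  res <- measure_region(which(base), dim(base), calibration(1))
  # translation: embed at an offset inside a larger mask
  big <- matrix(FALSE, 80, 90)
  big[20 + seq_len(nrow(base)) - 1L, 30 + seq_len(ncol(base)) - 1L] <- base
  res_t <- measure_region(which(big), dim(big), calibration(1))
  expect_equal(res_t$area, res$area, tolerance = 1e-12)
  expect_equal(res_t$perimeter, res$perimeter, tolerance = 1e-12)
  # 90-degree rotation of the pixel grid
  rot <- t(base)[ncol(base):1, ]
  res_r <- measure_region(which(rot), dim(rot), calibration(1))
  expect_equal(res_r$area, res$area, tolerance = 1e-12)
  # the boundary simplification is deterministic but anchor placement can
  # differ after rotation; lengths agree closely, not bitwise
  expect_equal(res_r$perimeter, res$perimeter, tolerance = 0.01)
})

test_that("measure_image returns one record per region in label order", {
  expect_equal(nrow(measure_image(label_regions(matrix(FALSE, 5, 5)))), 0L)
  sp <- noise_free_params("cap", cells_per_image = 10L)
  recs <- place_cells(sp, 10L, c(300L, 300L), 0.25, seed = 15)
  out <- render_study_image(recs, sp, c(300L, 300L), 0.25, seed = 16)
  lab <- label_regions(remove_scrap(threshold_rgb(out$image), 20))
  m <- measure_image(lab, calibration(0.25), case_id = "I_1", image_id = 2L)
  expect_equal(nrow(m), 10L)
  expect_equal(m$region_id, 1:10)
  expect_true(all(m$case_id == "I_1" & m$image_id == 2L))
  # mean measured area within 5% of mean analytic area
  expect_equal(mean(m$area_um2), mean(vapply(recs, `[[`, 0, "area_true")),
               tolerance = 0.05)
})

test_that("pixel measurement agrees with the polygon oracle on large rendered shapes", {
  sp <- noise_free_params()
  cal <- calibration(0.25)
  mk <- function(spec) {
    poly <- generate_contour(spec)
    rec <- list(list(cell_id = 1L, polygon = poly, center = spec$center))
    out <- render_study_image(rec, sp, c(560L, 560L), 0.25)
    lab <- label_regions(threshold_rgb(out$image))
    stopifnot(lab$n == 1L)
    meas <- measure_region(lab$pixels[[1]], dim(lab$labels), cal)
    truth <- polygon_area_perimeter(poly)
    list(meas = meas, truth = truth)
  }
  shapes <- list(
    shape_spec("fusiform", 11, aspect_ratio = 1, center = c(70, 70),
               vertex_count = 256L),                       # disc r = 44 px
    shape_spec("star", 11, lobe_amplitude = 0.4, lobe_count = 5,
               rotation = 0.3, center = c(70, 70), vertex_count = 256L),
    shape_spec("fusiform", 5, aspect_ratio = 6, rotation = 1.0,
               center = c(70, 70), vertex_count = 256L))
  for (s in shapes) {
    x <- mk(s)
    expect_equal(x$meas$area, x$truth$area, tolerance = 0.05)
    expect_equal(x$meas$perimeter, x$truth$perimeter, tolerance = 0.03)
    ff_m <- 4 * pi * x$meas$area / x$meas$perimeter^2
    ff_t <- 4 * pi * x$truth$area / x$truth$perimeter^2
    expect_equal(ff_m, ff_t, tolerance = 0.10)
  }
})
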