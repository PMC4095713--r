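test_that("polygon area and perimeter match closed forms on simple shapes", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  ap <- polygon_area_perimeter(sq)
  expect_equal(ap$area, 1)
  expect_equal(ap$perimeter, 4)
  # orientation invariance
  ap_rev <- polygon_area_perimeter(sq[4:1, ])
  expect_equal(ap_rev$area, ap$area)
  expect_equal(ap_rev$perimeter, ap$perimeter)
  expect_error(polygon_area_perimeter(sq[1:2, ]), "3 vertices")
  expect_error(polygon_area_perimeter(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("shoelace area equals fan-triangulation brute force on random polygons", {
  set.seed(401)
  for (rep in 1:20) {
    # random star-convex 20-gon about the origin: fan triangulation is exact
    theta <- sort(stats::runif(20, 0, 2 * pi))
    r <- stats::runif(20, 0.5, 3)
    poly <- cbind(r * cos(theta), r * sin(theta))
    fan <- sum(vapply(1:20, function(i) {
      j <- i %% 20 + 1
      abs(poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]) / 2
    }, 0))
    expect_equal(polygon_area_perimeter(poly)$area, fan, tolerance = 1e-9)
  }
})

test_that("degenerate star is a circle and fusiform aspect 1 recovers pi R^2", {
  circ <- generate_contour(shape_spec("star", 5, lobe_amplitude = 0,
                                      vertex_count = 1024L))
  ap <- polygon_area_perimeter(circ)
  expect_equal(4 * pi * ap$area / ap$perimeter^2, 1, tolerance = 1e-4)
  fus <- generate_contour(shape_spec("fusiform", 7, aspect_ratio = 1,
                                     vertex_count = 128L))
  expect_equal(polygon_area_perimeter(fus)$area, pi * 49, tolerance = 0.005)
})

test_that("star contour measurements agree with independent quadrature oracle", {
  # r(theta) = R (1 + a cos k theta): A = 1/2 int r^2, P = int sqrt(r^2 + r'^2)
  R <- 10; a <- 0.5; k <- 5
  r_f <- function(th) R * (1 + a * cos(k * th))
  dr_f <- function(th) -R * a * k * sin(k * th)
  area_o <- stats::integrate(function(th) r_f(th)^2 / 2, 0, 2 * pi,
                             rel.tol = 1e-10)$value
  per_o <- stats::integrate(function(th) sqrt(r_f(th)^2 + dr_f(th)^2), 0, 2 * pi,
                            rel.tol = 1e-10, subdivisions = 400L)$value
  ff_o <- 4 * pi * area_o / per_o^2
  poly <- generate_contour(shape_spec("star", R, lobe_amplitude = a,
                                      lobe_count = k, vertex_count = 2048L))
  ap <- polygon_area_perimeter(poly)
  expect_equal(ap$area, area_o, tolerance = 1e-4)
  expect_equal(ap$perimeter, per_o, tolerance = 1e-4)
  expect_equal(4 * pi * ap$area / ap$perimeter^2, ff_o, tolerance = 1e-3)
  # default vertex count keeps FF discretisation error below 0.5%
  poly128 <- generate_contour(shape_spec("star", R, lobe_amplitude = a,
                                         lobe_count = k, vertex_count = 160L))
  ap128 <- polygon_area_perimeter(poly128)
  expect_equal(4 * pi * ap128$area / ap128$perimeter^2, ff_o, tolerance = 5e-3)
})

test_that("contour invariants hold: simplicity surrogate, FF bounds, monotonicity", {
  # analytic FF <= 1 for convex shapes, < 1 strictly with lobes
  expect_lt(pulpmorph:::shape_ff("star", 0.3, 5), 1)
  expect_lte(pulpmorph:::shape_ff("fusiform", aspect_ratio = 2), 1)
  # fixed area, increasing aspect ratio strictly decreases FF
  ffs <- vapply(c(1, 2, 4, 8, 16, 32), function(q)
    pulpmorph:::shape_ff("fusiform", aspect_ratio = q), 0)
  expect_true(all(diff(ffs) < 0))
  # strongly fusiform cells have FF < 0.2
  expect_lt(pulpmorph:::shape_ff("fusiform", aspect_ratio = 16), 0.2)
  # rotation and translation leave A, P unchanged
  s1 <- shape_spec("star", 8, lobe_amplitude = 0.4, lobe_count = 6)
  s2 <- shape_spec("star", 8, lobe_amplitude = 0.4, lobe_count = 6,
                   rotation = 1.1, center = c(40, -13))
  ap1 <- polygon_area_perimeter(generate_contour(s1))
  ap2 <- polygon_area_perimeter(generate_contour(s2))
  expect_equal(ap1$area, ap2$area, tolerance = 1e-12)
  expect_equal(ap1$perimeter, ap2$perimeter, tolerance = 1e-12)
})

test_that("invalid shape specifications are rejected", {
  expect_error(shape_spec("star", 5, lobe_amplitude = 1), "lobe_amplitude")
  expect_error(shape_spec("star", 5, lobe_count = 2), "lobe_count")
  expect_error(shape_spec("fusiform", 5, aspect_ratio = 0.5), "aspect_ratio")
  expect_error(shape_spec("star", -1), "base_radius")
  expect_error(shape_spec("star", 5, vertex_count = 8), "vertex_count")
})

test_that("solve_shape returns contours at the requested area and form factor", {
  for (ff in c(0.1, 0.3, 0.7)) {
    sp <- pulpmorph:::solve_shape("star", 20, ff)
    ap <- polygon_area_perimeter(generate_contour(sp))
    expect_equal(ap$area, 20, tolerance = 1e-3)
    expect_equal(4 * pi * ap$area / ap$perimeter^2, ff, tolerance = 1e-3)
  }
  for (ff in c(0.08, 0.2, 0.5)) {
    sp <- pulpmorph:::solve_shape("fusiform", 30, ff)
    ap <- polygon_area_perimeter(generate_contour(sp))
    expect_equal(ap$area, 30, tolerance = 1e-3)
    expect_equal(4 * pi * ap$area / ap$perimeter^2, ff, tolerance = 1e-3)
  }
})
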