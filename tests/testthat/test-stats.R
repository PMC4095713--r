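fake_db <- function(n, case_id = "I_1") {
  data.frame(case_id = case_id, image_id = rep_len(1:5, n), region_id = seq_len(n),
             area_um2 = stats::runif(n, 5, 40),
             perimeter_um = stats::runif(n, 10, 70),
             form_factor = stats::runif(n, 0.05, 0.9))
}

test_that("case sampling is exhaustive at n records, deterministic, and row-aligned", {
  set.seed(51)
  db <- fake_db(100)
  s <- sample_records(db, 100, seed = 1)
  expect_setequal(s$region_id, db$region_id)
  db6 <- fake_db(600)
  s1 <- sample_records(db6, 100, seed = 42)
  s2 <- sample_records(db6, 100, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100L)
  expect_false(any(duplicated(s1$region_id)))
  # row alignment: the A, P, FF triplets come from the same records
  orig <- db6[match(s1$region_id, db6$region_id), ]
  expect_equal(s1$area_um2, orig$area_um2)
  expect_equal(s1$form_factor, orig$form_factor)
  expect_error(sample_records(fake_db(80), 100), "only 80 records")
})

test_that("sampling without replacement is uniform across records", {
  set.seed(52)
  db <- fake_db(600)
  reps <- 10000L
  counts <- integer(600)
  for (i in seq_len(reps)) {
    idx <- sample_records(db, 100)$region_id
    counts[idx] <- counts[idx] + 1L
  }
  p <- 100 / 600
  se <- sqrt(p * (1 - p) / reps)
  freq <- counts / reps
  # each record's inclusion frequency within ~4 SE of 1/6 (600 simultaneous checks)
  expect_true(all(abs(freq - p) < 4.5 * se))
  expect_lt(abs(mean(freq) - p), 1e-12)
})

test_that("descriptive statistics use the sample standard deviation", {
  d <- describe(c(5, 5, 5))
  expect_equal(d$mean, 5); expect_equal(d$sd, 0)
  expect_equal(d$min, 5); expect_equal(d$max, 5)
  d2 <- describe(c(1, 2, 3))
  expect_equal(d2$mean, 2); expect_equal(d2$sd, 1)
  expect_equal(d2$min, 1); expect_equal(d2$max, 3)
  expect_error(describe(numeric(0)), "empty")
  # 500 draws from the cap stage recover the designed mean within 3 SE
  sp <- stage_params("cap")
  r <- generate_stage_records(sp, 500, seed = 77)
  d3 <- describe(r$area_um2)
  expect_lt(abs(d3$mean - sp$mean_A), 3 * sp$sd_A / sqrt(500))
})

test_that("histograms use half-open bins from zero and conserve counts", {
  h0 <- build_histogram(numeric(0), "A")
  expect_equal(h0$counts, rep(0L, 20))
  expect_equal(h0$out_of_range, 0L)
  # interior edge value goes to the right bin (half-open rule)
  h <- build_histogram(c(3.5, 3.49999, 7.0), "A")
  expect_equal(h$counts[1], 1L)  # 3.49999 in [0, 3.5)
  expect_equal(h$counts[2], 1L)  # 3.5 in [3.5, 7)
  expect_equal(h$counts[3], 1L)  # 7.0 in [7, 10.5)
  # final bin's upper edge is closed; beyond it is out of range
  hf <- build_histogram(c(70, 69.9999, 70.0001), "A")
  expect_equal(hf$counts[20], 2L)
  expect_equal(hf$out_of_range, 1L)
  # conventional class widths
  expect_equal(build_histogram(1, "A")$class_width, 3.5)
  expect_equal(build_histogram(1, "P")$class_width, 7)
  expect_equal(build_histogram(1, "FF")$class_width, 0.05)
  # conservation on a synthetic stage sample
  r <- generate_stage_records(stage_params("late_bell"), 500, seed = 3)
  hA <- build_histogram(r$area_um2, "A")
  expect_equal(sum(hA$counts) + hA$out_of_range, 500L)
  expect_equal(sum(hA$counts), 500L - hA$out_of_range)
})

test_that("gaussian overlay is count-scaled, peaks at the mean, and obeys the scaling law", {
  r <- generate_stage_records(stage_params("early_bell"), 500, seed = 9)
  st <- describe(r$area_um2)
  h <- build_histogram(r$area_um2, "A")
  ov <- gaussian_overlay(st, h)
  expect_false(ov$flat_spike)
  # numerical integral over the bins approximates n within 2%
  expect_equal(sum(ov$heights), st$n, tolerance = 0.02)
  # maximum at the bin containing the mean
  expect_equal(which.max(ov$heights), findInterval(st$mean, h$left_edges))
  # doubling the class width doubles the overlay height at a fixed abscissa
  h2 <- build_histogram(r$area_um2, "A", class_width = 7)
  ov2 <- gaussian_overlay(st, h2)
  at <- ov2$centers[3]
  h_w1 <- stats::approx(ov$centers, ov$heights, xout = at)$y
  expect_equal(ov2$heights[3] / h_w1, 2, tolerance = 0.01)
  # sd = 0 yields a flat-spike flag and no curve
  ov0 <- gaussian_overlay(describe(rep(2, 5)), h)
  expect_true(ov0$flat_spike)
  expect_null(ov0$heights)
})

test_that("one-way ANOVA matches the definitional sum-of-squares oracle", {
  set.seed(61)
  for (rep in 1:10) {
    gs <- lapply(1:3, function(i) stats::rnorm(sample(5:30, 1), mean = i * 0.3))
    res <- anova_one_way(gs)
    orc <- anova_oracle(gs)
    expect_equal(res$statistic, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
  # degenerate: identical values everywhere
  res0 <- anova_one_way(list(rep(2, 4), rep(2, 5)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(anova_one_way(list(1:5)), "at least 2 groups")
})

test_that("for two groups the ANOVA F equals the squared pooled t statistic", {
  set.seed(62)
  for (rep in 1:8) {
    x <- stats::rnorm(12); y <- stats::rnorm(17, 0.4)
    f <- anova_one_way(list(x, y))$statistic
    t <- t_test_two_sample(x, y, equal_variance = TRUE)$statistic
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("t tests match the definitional formulas and behave symmetrically", {
  set.seed(63)
  x <- stats::rnorm(20, 1, 1); y <- stats::rnorm(15, 0.2, 2)
  for (ev in c(TRUE, FALSE)) {
    res <- t_test_two_sample(x, y, equal_variance = ev)
    orc <- t_oracle(x, y, equal_variance = ev)
    expect_equal(res$statistic, orc$t, tolerance = 1e-10)
    expect_equal(res$df, orc$df, tolerance = 1e-8)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
  # identical samples: t = 0, p = 1
  res0 <- t_test_two_sample(x, x)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # mirroring both samples flips the sign but not |t| or p
  rp <- t_test_two_sample(x, y)
  rm <- t_test_two_sample(-x, -y)
  expect_equal(rm$statistic, -rp$statistic, tolerance = 1e-12)
  expect_equal(rm$p_value, rp$p_value, tolerance = 1e-12)
  # constant equal samples
  rc <- t_test_two_sample(rep(1, 3), rep(1, 4))
  expect_equal(rc$statistic, 0); expect_equal(rc$p_value, 1)
})

test_that("the F statistic is location invariant and scale consistent", {
  set.seed(64)
  gs <- lapply(1:3, function(i) stats::rnorm(10, i))
  f0 <- anova_one_way(gs)$statistic
  expect_equal(anova_one_way(lapply(gs, `+`, 100))$statistic, f0,
               tolerance = 1e-9)
  expect_equal(anova_one_way(lapply(gs, `*`, 3.7))$statistic, f0,
               tolerance = 1e-9)
})
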