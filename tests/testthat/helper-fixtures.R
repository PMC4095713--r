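# Shared fixtures: all synthetic, built in code at test time.

# Logical matrix with a digitised disc of radius r (pixel-centre rule).
disc_mask <- function(r, pad = 10L) {
  sz <- 2L * ceiling(r) + 2L * pad + 1L
  ctr <- (sz + 1) / 2
  xy <- expand.grid(c = 1:sz, rr = 1:sz)
  matrix((xy$c - ctr)^2 + (xy$rr - ctr)^2 <= r^2, sz, sz, byrow = TRUE)
}

# Axis-aligned rectangular blob inside a padded mask.
rect_mask <- function(h, w, pad = 2L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Noise-free stage parameters: flat colours, so thresholding is exact.
noise_free_params <- function(stage = "cap", ...) {
  stage_params(stage,
               noise = list(bg_mean = c(231, 190, 205), bg_sd = 0,
                            fg_mean = c(122, 64, 142), fg_sd = 0,
                            additive_sd = 0),
               ...)
}

# Small study configuration for structural / determinism tests.
tiny_config <- function(seed = 11L) {
  mk <- function(st) stage_params(st, cells_per_image = 8L)
  study_config(stages = list(I = mk("cap"), II = mk("early_bell"),
                             III = mk("late_bell")),
               n_cases = 2L, images_per_case = 2L,
               dim_px = c(320L, 320L), n_sample = 12L, seed = seed)
}

# Definitional one-way ANOVA from sums of squares (independent oracle).
anova_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gm <- mean(y)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Definitional Welch / pooled t statistic (independent oracle).
t_oracle <- function(x, y, equal_variance = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (equal_variance) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
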