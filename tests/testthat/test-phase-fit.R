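test_that("the three-knot fit tracks a noiseless cosine closely", {
  t <- seq(0, 24, length.out = 25)[-25]
  fit <- fit_periodic_spline(t, cos(2 * pi * (t - 8) / 24))
  grid <- seq(0, 23.99, by = 0.01)
  dev <- abs(predict(fit, grid) - cos(2 * pi * (grid - 8) / 24))
  # three free coefficients cannot represent a pure harmonic exactly:
  # the measured waveform distortion is ~0.07 at the worst point
  expect_lt(max(dev), 0.1)
  expect_lt(fit$rmse, 0.05)
  expect_equal(as.numeric(peak_time(fit)), 8, tolerance = 0.02)
  expect_equal(as.numeric(trough_time(fit)), 20, tolerance = 0.02)
})

test_that("periodicity: the curve is 24h-periodic and smooth at the seam", {
  set.seed(1)
  fit <- random_fit()
  t <- runif(20, 0, 24)
  expect_equal(predict(fit, t), predict(fit, t + 24), tolerance = 1e-10)
  eps <- 1e-5
  d_left <- (predict(fit, 24 - eps) - predict(fit, 24 - 2 * eps)) / eps
  d_right <- (predict(fit, eps) - predict(fit, 0)) / eps
  expect_equal(d_left, d_right, tolerance = 1e-2)
})

test_that("constant input gives a flat fit, zero rmse and flagged outputs", {
  t <- seq(0, 23, by = 2)
  fit <- fit_periodic_spline(t, rep(5, length(t)))
  expect_equal(predict(fit, seq(0, 23.9, by = 0.1)),
               rep(5, 240), tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  expect_warning(pk <- peak_time(fit), "flat")
  expect_equal(as.numeric(pk), 0)
  expect_true(attr(pk, "flat"))
  s <- snr(fit)
  expect_true(is.infinite(s) && attr(s, "noiseless"))
})

test_that("degenerate designs are rejected", {
  expect_error(fit_periodic_spline(rep(3, 10), rnorm(10)),
               "less than 12 h")
  expect_error(fit_periodic_spline(runif(5, 0, 24), rnorm(5)),
               "at least 6 observations")
  expect_error(fit_periodic_spline(runif(10, 0, 5), rnorm(10)),
               "less than 12 h")
  expect_error(fit_periodic_spline(c(1, 2), c(1, NA, 3)[1:2] * NA),
               "finite")
})

test_that("zero-residual fits get a flagged infinite snr; pure noise snr is tiny", {
  t <- seq(0.5, 23.5, length.out = 48)
  # a signal inside the spline span is fitted with zero residual
  f0 <- fit_periodic_spline(t, cos(2 * pi * t / 24))
  fit <- fit_periodic_spline(t, predict(f0, t))
  s <- snr(fit)
  expect_true(is.infinite(s))
  expect_true(attr(s, "noiseless"))
  set.seed(2)
  fit2 <- fit_periodic_spline(runif(200, 0, 24), rnorm(200))
  expect_lt(as.numeric(snr(fit2)), 1)
})

test_that("snr estimates peak-to-trough range over noise SD", {
  set.seed(3)
  for (a in c(1, 2)) {
    t <- runif(500, 0, 24)
    y <- a * cos(2 * pi * (t - 5) / 24) + rnorm(500)
    s <- as.numeric(snr(fit_periodic_spline(t, y)))
    expect_equal(s, 2 * a, tolerance = 0.15 * 2 * a)
  }
})

test_that("grid-plus-golden-section argmax matches the brute-force oracle", {
  set.seed(4)
  for (i in 1:30) {
    fit <- random_fit()
    expect_lt(abs_circ_diff(as.numeric(peak_time(fit)),
                            grid_extremum(fit, TRUE)), 0.005)
    expect_lt(abs_circ_diff(as.numeric(trough_time(fit)),
                            grid_extremum(fit, FALSE)), 0.005)
  }
})

test_that("phases and snr are exactly invariant under positive affine maps", {
  set.seed(5)
  t <- runif(60, 0, 24)
  for (i in 1:10) {
    y <- runif(1, 0.5, 2) * cos(2 * pi * (t - runif(1, 0, 24)) / 24) +
      rnorm(60, 0, 0.5)
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
    f1 <- fit_periodic_spline(t, y)
    f2 <- fit_periodic_spline(t, a * y + b)
    # golden-section refinement uses comparisons only, so the argmax is
    # bitwise identical under order-preserving maps
    expect_equal(as.numeric(peak_time(f1)), as.numeric(peak_time(f2)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(trough_time(f1)), as.numeric(trough_time(f2)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(snr(f1)), as.numeric(snr(f2)),
                 tolerance = 1e-9)
    # negative scale swaps peak and trough
    f3 <- fit_periodic_spline(t, -y)
    expect_equal(as.numeric(peak_time(f3)), as.numeric(trough_time(f1)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(trough_time(f3)), as.numeric(peak_time(f1)),
                 tolerance = 1e-9)
  }
})

test_that("time shifts by a knot spacing translate the peak exactly", {
  set.seed(6)
  t <- runif(80, 0, 24)
  y <- 1.5 * cos(2 * pi * (t - 10) / 24) + rnorm(80, 0, 0.4)
  base <- as.numeric(peak_time(fit_periodic_spline(t, y)))
  for (delta in c(8, 16)) {
    shifted <- as.numeric(peak_time(fit_periodic_spline(t + delta, y)))
    expect_lt(abs_circ_diff(shifted, (base + delta) %% 24), 1e-6)
  }
})

test_that("generic time shifts translate the peak within the distortion bound", {
  # the three-knot basis is only invariant under 8-h shifts; for generic
  # shifts the waveform distortion moves the argmax by up to ~1.1 h
  set.seed(7)
  t <- runif(200, 0, 24)
  y <- cos(2 * pi * (t - 4) / 24) + rnorm(200, 0, 0.3)
  base <- as.numeric(peak_time(fit_periodic_spline(t, y)))
  for (delta in c(2.5, 5, 11, 17.25)) {
    shifted <- as.numeric(peak_time(fit_periodic_spline(t + delta, y)))
    expect_lt(abs_circ_diff(shifted, (base + delta) %% 24), 1.2)
  }
})

test_that("estimate_phases keeps rhythmic genes and excludes noise", {
  cfg <- study_config(
    datasets = list(list(dataset_id = "d", organ = "blood",
                         n_subjects = 20, n_samples = 200)),
    subject_effect_sd = 0, subject_scale_sd = 0, seed = 11)
  st <- generate_study(cfg)
  ph <- estimate_phases(st$expression, st$samples,
                        genes = default_clock_panel()$gene_id)
  expect_equal(nrow(ph$estimates), 7)
  expect_equal(nrow(ph$excluded), 0)
  expect_true(all(ph$estimates$snr > 1))
  # estimated peaks near the generator truth (waveform bias < 0.7 h)
  err <- abs_circ_diff(
    ph$estimates$peak_time,
    st$truth$peaks$true_peak[match(ph$estimates$gene_id,
                                   st$truth$peaks$gene_id)])
  expect_lt(max(err), 1.0)
})

test_that("pure-noise genes fall below the snr threshold", {
  excluded <- vapply(1:5, function(seed) {
    set.seed(seed)
    t <- runif(200, 0, 24)
    x <- matrix(rnorm(200), 1, dimnames = list("NOISE", paste0("s", 1:200)))
    s <- data.frame(sample_id = colnames(x), circadian_time = t)
    ph <- estimate_phases(x, s, genes = "NOISE")
    nrow(ph$excluded) == 1L
  }, logical(1))
  expect_true(all(excluded))
})

test_that("absent genes are reported as not measured; empty panel is empty", {
  x <- make_matrix(c("ARNTL", "PER1"), n_samples = 48, seed = 8)
  s <- data.frame(sample_id = colnames(x),
                  circadian_time = seq(0, 23.5, length.out = 48))
  ph <- estimate_phases(x, s, genes = c("ARNTL", "PER1", "MISSING"))
  expect_identical(ph$not_measured, "MISSING")
  ph0 <- estimate_phases(x, s, genes = character(0))
  expect_equal(nrow(ph0$estimates) + nrow(ph0$excluded), 0)
})
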