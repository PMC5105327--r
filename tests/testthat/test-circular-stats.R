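test_that("circular mean handles wraparound, identity and degenerate input", {
  expect_equal(circular_mean(c(23, 1)), 0)
  expect_equal(circular_mean(c(8, 8, 8)), 8)
  expect_error(circular_mean(numeric(0)), "undefined circular mean")
  expect_error(circular_mean(c(0, 12)), "undefined circular mean")
})

test_that("circular mean matches the brute-force squared-distance minimizer", {
  set.seed(1)
  for (i in 1:20) {
    times <- runif(sample(3:12, 1), 0, 24)
    expect_lt(abs_circ_diff(circular_mean(times), grid_circular_mean(times)),
              0.002)
  }
})

test_that("circular mean is rotation-equivariant", {
  set.seed(2)
  for (i in 1:20) {
    times <- rnorm(8, mean = runif(1, 0, 24), sd = 2)
    delta <- runif(1, 0, 24)
    expect_equal(circular_mean(times + delta),
                 (circular_mean(times) + delta) %% 24, tolerance = 1e-9)
  }
})

test_that("signed circular difference follows the CT convention", {
  expect_identical(signed_circ_diff(2, 20), 6)  # CT2 is 6 h ahead of CT20
  expect_identical(signed_circ_diff(7.25, 7.25), 0)
  expect_identical(signed_circ_diff(0, 12), 12) # antipode convention: +12
  expect_equal(signed_circ_diff(c(2, 0), c(20, 12)), c(6, 12))
  # antisymmetry away from the antipode
  set.seed(3)
  a <- runif(50, 0, 24); b <- runif(50, 0, 24)
  expect_equal(signed_circ_diff(a, b), -signed_circ_diff(b, a),
               tolerance = 1e-12)
})

test_that("absolute circular difference is a metric on the circle", {
  expect_equal(abs_circ_diff(2, 20), 6)
  expect_equal(abs_circ_diff(23, 1), 2)
  expect_equal(abs_circ_diff(0, 12), 12)
  set.seed(4)
  for (i in 1:50) {
    x <- runif(3, 0, 24)
    expect_equal(abs_circ_diff(x[1], x[2]), abs_circ_diff(x[2], x[1]))
    expect_equal(abs_circ_diff(x[1], x[1]), 0)
    expect_lte(abs_circ_diff(x[1], x[3]),
               abs_circ_diff(x[1], x[2]) + abs_circ_diff(x[2], x[3]) + 1e-12)
    expect_lte(abs_circ_diff(x[1], x[2]), 12)
  }
})

make_estimates <- function(peaks, dataset_id) {
  data.frame(gene_id = names(peaks), dataset_id = dataset_id,
             peak_time = unname(peaks), stringsAsFactors = FALSE)
}

test_that("relative peak times cancel constant dataset shifts", {
  peaks <- c(ARNTL = 23, PER1 = 10, PER2 = 12.5)
  e1 <- make_estimates(peaks, "d1")
  e2 <- make_estimates((peaks + 5.5) %% 24, "d2")  # shifted dataset
  rel <- relative_peak_times(rbind(e1, e2), "ARNTL")
  expect_equal(rel$relative_peak_time[rel$dataset_id == "d1"],
               rel$relative_peak_time[rel$dataset_id == "d2"],
               tolerance = 1e-12)
  expect_equal(rel$relative_peak_time[rel$gene_id == "ARNTL"], c(0, 0))
  # missing reference: dataset skipped with warning
  e3 <- make_estimates(c(PER1 = 4), "d3")
  expect_warning(rel2 <- relative_peak_times(rbind(e1, e3), "ARNTL"), "d3")
  expect_false("d3" %in% rel2$dataset_id)
})

test_that("relative peaks recover configured gene-phase offsets", {
  cfg <- study_config(
    datasets = list(list(dataset_id = "d", organ = "blood",
                         n_subjects = 20, n_samples = 300)),
    subject_effect_sd = 0, subject_scale_sd = 0, noise_sd = 0.5, seed = 9)
  st <- generate_study(cfg)
  ph <- estimate_phases(st$expression, st$samples,
                        genes = default_clock_panel()$gene_id)
  rel <- relative_peak_times(ph$estimates, "ARNTL")
  panel <- default_clock_panel()
  truth <- signed_circ_diff(panel$phase, panel$phase[panel$gene_id == "ARNTL"])
  got <- rel$relative_peak_time[match(panel$gene_id, rel$gene_id)]
  expect_lt(max(abs(got - truth)), 1.0)
})

test_that("group comparisons summarize pooled pairwise differences", {
  a <- rbind(make_estimates(c(ARNTL = 23, PER1 = 10), "a1"),
             make_estimates(c(ARNTL = 23.4, PER1 = 10.2), "a2"))
  a1 <- a[a$dataset_id == "a1", ]
  id <- compare_groups(a1, a1)  # identical single-dataset groups
  expect_equal(id$mean_abs_diff, 0)
  expect_equal(id$median_abs_diff, 0)

  b <- a; b$peak_time <- (b$peak_time + 6) %% 24
  b$dataset_id <- paste0("b", b$dataset_id)
  cmp <- compare_groups(a, b, "A", "B")
  # pairs within a group differ by up to 0.4, so diffs are 6 +/- 0.4
  expect_equal(cmp$mean_abs_diff, 6, tolerance = 0.11)
  expect_equal(nrow(cmp$pairs), 8)  # 2 genes x 2 x 2 datasets

  # relabeling the groups leaves the summary unchanged
  rev <- compare_groups(b, a, "B", "A")
  expect_equal(rev$mean_abs_diff, cmp$mean_abs_diff)
  expect_equal(sort(rev$pairs$abs_diff), sort(cmp$pairs$abs_diff))

  # per-gene-first averaging weights genes equally
  pg <- compare_groups(a, b, per_gene_first = TRUE)
  expect_equal(pg$mean_abs_diff, cmp$mean_abs_diff, tolerance = 0.2)

  expect_error(compare_groups(a, make_estimates(c(NR1D1 = 2), "c1")),
               "no genes shared")
})

test_that("trough-based comparisons use the trough column", {
  a <- data.frame(gene_id = "PER1", dataset_id = "a1",
                  peak_time = 10, trough_time = 22)
  b <- data.frame(gene_id = "PER1", dataset_id = "b1",
                  peak_time = 10, trough_time = 2)
  cmp <- compare_groups(a, b, time_col = "trough_time")
  expect_equal(cmp$mean_abs_diff, 4)
})

test_that("group circular means average datasets within a class", {
  est <- rbind(make_estimates(c(PER1 = 23), "d1"),
               make_estimates(c(PER1 = 1), "d2"),
               make_estimates(c(PER1 = 7), "d3"))
  g <- group_circular_mean_peaks(est, c(d1 = "noct", d2 = "noct",
                                        d3 = "diur"))
  expect_equal(abs_circ_diff(g$mean_peak_time[g$group == "noct"], 0), 0,
               tolerance = 1e-9)
  expect_equal(g$mean_peak_time[g$group == "diur"], 7)  # singleton identity
  expect_error(group_circular_mean_peaks(est, c(d1 = "noct")), "d2")
})

test_that("group circular means recover a common phase from noisy datasets", {
  set.seed(5)
  peaks <- (10 + rnorm(3, 0, 1)) %% 24
  est <- do.call(rbind, lapply(1:3, function(i)
    make_estimates(c(PER2 = peaks[i]), paste0("d", i))))
  g <- group_circular_mean_peaks(est, c(d1 = "c", d2 = "c", d3 = "c"))
  expect_lt(abs_circ_diff(g$mean_peak_time, 10), 1.5)
})
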