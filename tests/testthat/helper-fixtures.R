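# Shared fixture builders: tiny expression matrices, random spline fits
# and compact synthetic studies used across the test files.

make_matrix <- function(genes = c("PER1", "ARNTL", "DBP"), n_samples = 4,
                        seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(length(genes) * n_samples), nrow = length(genes),
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  x
}

# A random (but valid) periodic spline fit: noisy sinusoid with random
# phase, amplitude and noise level.
random_fit <- function() {
  t <- runif(40, 0, 24)
  y <- runif(1, 0.5, 3) * cos(2 * pi * (t - runif(1, 0, 24)) / 24) +
    rnorm(40, 0, runif(1, 0.1, 1))
  fit_periodic_spline(t, y)
}

# Exhaustive arg-extremum over a fine grid: the brute-force oracle for
# peak_time()/trough_time().
grid_extremum <- function(fit, maximum = TRUE, resolution = 0.001) {
  grid <- seq(0, 24, by = resolution)
  grid <- grid[grid < 24]
  vals <- predict(fit, grid)
  grid[if (maximum) which.max(vals) else which.min(vals)]
}

# Brute-force circular mean: minimizer over a fine grid of the summed
# squared circular (chord) distances, i.e. squared Euclidean distances
# between the points on the unit circle -- the defining variational
# property of the vector-resultant circular mean.
grid_circular_mean <- function(times, resolution = 0.001) {
  cand <- seq(0, 24, by = resolution)
  cand <- cand[cand < 24]
  ss <- vapply(cand, function(cc) {
    d <- 2 * sin(pi * abs_circ_diff(times, cc) / 24)
    sum(d^2)
  }, numeric(1))
  cand[which.min(ss)]
}

# Two-organ study (blood-like dense + brain-like one-per-subject) with a
# known organ offset; small enough for unit tests.
small_two_organ_config <- function(seed = 1, n_blood = 100, n_brain = 100,
                                   offset = 8.5, advance = 0) {
  study_config(
    organs = data.frame(organ = c("blood", "brain"),
                        phase_offset = c(0, offset)),
    datasets = list(
      list(dataset_id = "blood1", organ = "blood", n_subjects = 10,
           n_samples = n_blood),
      list(dataset_id = "brain1", organ = "brain", n_subjects = 30,
           n_samples = n_brain, sampling = "one_per_subject",
           age_mean = 52, age_sd = 15)),
    age_phase_advance = advance,
    seed = seed)
}

# Adjust one dataset of a generated study by its natural batch variable
# (subject for dense designs, area for one-per-subject) and estimate the
# clock-panel phases.
fit_dataset_phases <- function(study, dataset_id, batch_col = NULL,
                               genes = default_clock_panel()$gene_id) {
  sel <- study$samples$dataset_id == dataset_id
  samples <- study$samples[sel, , drop = FALSE]
  if (is.null(batch_col)) {
    design <- Filter(function(d) d$dataset_id == dataset_id,
                     study$truth$config$datasets)[[1]]
    batch_col <- if (design$sampling == "dense_within_subject")
      "subject_id" else "batch_id"
  }
  x <- batch_adjust(study$expression[, sel, drop = FALSE],
                    samples[[batch_col]])
  estimate_phases(x, samples, genes = genes)
}
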