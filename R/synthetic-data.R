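# Synthetic multi-organ, multi-dataset circadian expression studies with
# known ground truth. The generator emulates the statistical structure of
# public human circadian datasets: per-gene sinusoidal expression with
# gene-specific phases, organ-specific phase offsets, per-subject additive
# and scale effects, per-dataset offsets, an age-dependent phase advance,
# Gaussian noise, and both dense within-subject sampling (blood-style)
# and one-time-per-subject designs (postmortem-brain-style, several
# anatomical areas sharing one circadian time per subject).

#' The seven-gene core clock panel
#'
#' Core clock genes with clear rhythmicity in human blood and brain:
#' ARNTL, DBP, NR1D1, NR1D2, PER1, PER2 and PER3. ARNTL is anchored at
#' phase 0 (it peaks near CT0 in nocturnal organs); the other six are
#' spread evenly over 8-14 h.
#'
#' @return data.frame `gene_id`, `phase` (hours), `amplitude` (log-units).
#' @export
default_clock_panel <- function() {
  data.frame(
    gene_id = c("ARNTL", "DBP", "NR1D1", "NR1D2", "PER1", "PER2", "PER3"),
    phase = c(0, seq(8, 14, length.out = 6)),
    amplitude = 1,
    stringsAsFactors = FALSE)
}

#' @noRd
.default_dataset <- function(d, i) {
  defaults <- list(sampling = "dense_within_subject", offset = 0,
                   age_mean = 30, age_sd = 8)
  for (f in names(defaults)) if (is.null(d[[f]])) d[[f]] <- defaults[[f]]
  required <- c("dataset_id", "organ", "n_subjects", "n_samples")
  for (f in required) if (is.null(d[[f]]))
    stop(sprintf("dataset %d: missing field '%s'", i, f))
  if (!d$sampling %in% c("dense_within_subject", "one_per_subject"))
    stop(sprintf("dataset %d: invalid field 'sampling'", i))
  if (d$n_subjects < 2) stop(sprintf("dataset %d: field 'n_subjects' must be >= 2", i))
  if (d$n_samples < d$n_subjects)
    stop(sprintf("dataset %d: field 'n_samples' must be >= n_subjects", i))
  d
}

#' Configure a synthetic circadian study
#'
#' Defaults describe a typical human circadian expression study: unit
#' gene amplitudes with unit noise SD (true-curve SNR 2, typical for
#' human data), moderate subject-level additive effects, and a 7-gene
#' clock panel.
#'
#' @param organs data.frame `organ`, `phase_offset` (hours added to every
#'   gene phase in that organ).
#' @param genes data.frame `gene_id`, `phase`, `amplitude` (default
#'   [default_clock_panel()]).
#' @param datasets list of dataset designs; each a list with
#'   `dataset_id`, `organ`, `n_subjects`, `n_samples`, and optionally
#'   `sampling` (`"dense_within_subject"`, the default, draws an evenly
#'   spaced time grid with a random subject-specific offset;
#'   `"one_per_subject"` draws a single circadian time per subject and
#'   spreads that subject's samples over anatomical-area batches),
#'   `offset` (additive dataset effect, log-units), `age_mean`, `age_sd`.
#' @param subject_effect_sd SD of per-subject additive offsets
#'   (log-units).
#' @param subject_scale_sd SD of per-subject log scale factors applied to
#'   the rhythmic signal.
#' @param noise_sd SD of i.i.d. Gaussian measurement noise (log-units).
#' @param age_phase_advance hours by which the older age group
#'   (`age > age_threshold`) is phase-advanced (peaks earlier).
#' @param age_threshold age split, years (default 40, inclusive on the
#'   young side).
#' @param sex_marker_effect log-units added to the sex marker gene in
#'   males; a non-rhythmic `RPS4Y1` row is included whenever this is > 0.
#' @param sex_marker_gene marker gene ID.
#' @param seed integer master seed; generation is fully reproducible.
#' @return validated list of class `study_config`.
#' @export
study_config <- function(organs = data.frame(organ = "blood",
                                             phase_offset = 0),
                         genes = default_clock_panel(),
                         datasets = list(list(dataset_id = "ds1",
                                              organ = "blood",
                                              n_subjects = 20,
                                              n_samples = 160)),
                         subject_effect_sd = 0.3,
                         subject_scale_sd = 0.1,
                         noise_sd = 1,
                         age_phase_advance = 0,
                         age_threshold = 40,
                         sex_marker_effect = 5,
                         sex_marker_gene = "RPS4Y1",
                         seed = 1L) {
  if (any(genes$phase < 0 | genes$phase >= 24))
    stop("invalid field 'genes$phase': phases must be in [0,24)")
  if (any(genes$amplitude <= 0))
    stop("invalid field 'genes$amplitude': amplitudes must be > 0")
  if (noise_sd < 0) stop("invalid field 'noise_sd'")
  if (subject_effect_sd < 0) stop("invalid field 'subject_effect_sd'")
  if (subject_scale_sd < 0) stop("invalid field 'subject_scale_sd'")
  datasets <- lapply(seq_along(datasets),
                     function(i) .default_dataset(datasets[[i]], i))
  for (d in datasets)
    if (!d$organ %in% organs$organ)
      stop("dataset organ not listed in organs table: ", d$organ)
  structure(
    list(organs = organs, genes = genes, datasets = datasets,
         subject_effect_sd = subject_effect_sd,
         subject_scale_sd = subject_scale_sd,
         noise_sd = noise_sd,
         age_phase_advance = age_phase_advance,
         age_threshold = age_threshold,
         sex_marker_effect = sex_marker_effect,
         sex_marker_gene = sex_marker_gene,
         seed = as.integer(seed)),
    class = "study_config")
}

#' The bundled published-design study configuration
#'
#' Five datasets mirroring the sample counts of the five public human
#' studies (three blood datasets with dense within-subject sampling:
#' 24/221, 22/147, 14/130 subjects/samples; two postmortem brain datasets
#' with one circadian time per subject spread over anatomical areas:
#' 55/269, 146/292), a brain phase offset of 8.5 h, a 2-h age phase
#' advance, and young blood donors versus older brain donors.
#'
#' @param seed master seed (default as shipped in the config file).
#' @return a [study_config()].
#' @export
human_study_config <- function(seed = NULL) {
  path <- system.file("extdata", "human_study_designs.yaml",
                      package = "circaphase")
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  study_config(
    organs = do.call(rbind, lapply(cfg$organs, as.data.frame)),
    genes = default_clock_panel(),
    datasets = cfg$datasets,
    subject_effect_sd = cfg$subject_effect_sd,
    subject_scale_sd = cfg$subject_scale_sd,
    noise_sd = cfg$noise_sd,
    age_phase_advance = cfg$age_phase_advance,
    sex_marker_effect = cfg$sex_marker_effect,
    seed = cfg$seed)
}

# Allocate n samples across k subjects as evenly as possible.
#' @noRd
.allocate <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Generate a synthetic circadian expression study
#'
#' Expression of gene g in sample s is
#' `subject_offset + dataset_offset +
#'  scale * amplitude_g * cos(2pi (t_s - phase_g - organ_offset - advance) / 24)
#'  + noise`,
#' where `advance` is `-age_phase_advance` applied as a phase advance
#' (earlier peak) to subjects older than the age threshold. Dense designs
#' give each subject an evenly spaced circadian-time grid with a random
#' offset and batch = subject; one-per-subject designs give each subject a
#' single uniform circadian time shared by all of its samples, with batch =
#' anatomical area and a postmortem-interval column.
#'
#' @param config a [study_config()].
#' @return list with `expression` (genes x samples matrix over all
#'   datasets), `samples` (sample table with `circadian_time`,
#'   `subject_id`, `batch_id`, `organ`, `dataset_id`, `age`, `sex`,
#'   `pmi`), and `truth`: list with `peaks` (data.frame `gene_id`,
#'   `dataset_id`, `true_peak` for the young/reference group),
#'   `organ_offsets`, `subjects` (per-subject offsets, scales, ages,
#'   sexes) and the echoed `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  genes <- config$genes
  organ_offset <- stats::setNames(config$organs$phase_offset,
                                  config$organs$organ)
  sample_rows <- list(); subject_rows <- list(); truth_peaks <- list()
  cols <- list()
  for (d in config$datasets) {
    subj_ids <- sprintf("%s_subj%02d", d$dataset_id, seq_len(d$n_subjects))
    ages <- round(pmax(18, stats::rnorm(d$n_subjects, d$age_mean, d$age_sd)))
    sexes <- sample(c("female", "male"), d$n_subjects, replace = TRUE)
    offs <- stats::rnorm(d$n_subjects, 0, config$subject_effect_sd)
    scales <- exp(stats::rnorm(d$n_subjects, 0, config$subject_scale_sd))
    alloc <- .allocate(d$n_samples, d$n_subjects)
    subject_rows[[d$dataset_id]] <- data.frame(
      subject_id = subj_ids, dataset_id = d$dataset_id, age = ages,
      sex = sexes, offset = offs, scale = scales,
      stringsAsFactors = FALSE)
    s_idx <- 0L
    for (j in seq_len(d$n_subjects)) {
      k <- alloc[j]
      if (d$sampling == "dense_within_subject") {
        t_subj <- (stats::runif(1, 0, 24) + 24 * (seq_len(k) - 1) / k) %% 24
        batch <- rep(subj_ids[j], k)
        pmi <- rep(NA_real_, k)
      } else {
        t_subj <- rep(stats::runif(1, 0, 24), k)
        batch <- sprintf("area%02d", seq_len(k))
        pmi <- rep(round(stats::runif(1, 2, 20), 1), k)
      }
      for (q in seq_len(k)) {
        s_idx <- s_idx + 1L
        sample_rows[[length(sample_rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_s%03d", d$dataset_id, s_idx),
          circadian_time = t_subj[q], subject_id = subj_ids[j],
          batch_id = batch[q], organ = d$organ, dataset_id = d$dataset_id,
          age = ages[j], sex = sexes[j], pmi = pmi[q],
          stringsAsFactors = FALSE)
        advance <- if (ages[j] > config$age_threshold)
          config$age_phase_advance else 0
        phase_eff <- genes$phase + organ_offset[[d$organ]] - advance
        expr <- offs[j] + d$offset +
          scales[j] * genes$amplitude *
            cos(2 * pi * (t_subj[q] - phase_eff) / 24) +
          stats::rnorm(nrow(genes), 0, config$noise_sd)
        if (config$sex_marker_effect > 0) {
          marker <- 1 + config$sex_marker_effect * (sexes[j] == "male") +
            stats::rnorm(1, 0, config$noise_sd)
          expr <- c(expr, marker)
        }
        cols[[length(cols) + 1L]] <- expr
      }
    }
    truth_peaks[[d$dataset_id]] <- data.frame(
      gene_id = genes$gene_id, dataset_id = d$dataset_id,
      true_peak = (genes$phase + organ_offset[[d$organ]]) %% 24,
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, c(sample_rows, list(make.row.names = FALSE)))
  x <- do.call(cbind, cols)
  rownames(x) <- if (config$sex_marker_effect > 0)
    c(genes$gene_id, config$sex_marker_gene) else genes$gene_id
  colnames(x) <- samples$sample_id
  validate_expression_matrix(x)
  validate_sample_table(samples)
  list(expression = x, samples = samples,
       truth = list(
         peaks = do.call(rbind, c(truth_peaks, list(make.row.names = FALSE))),
         organ_offsets = organ_offset,
         subjects = do.call(rbind, c(subject_rows,
                                     list(make.row.names = FALSE))),
         config = config))
}
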