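# End-to-end orchestration: per-dataset batch adjustment and phase fits,
# combined phase tables, pairwise group comparisons, relative phases and
# group circular means, written as TSV plus a JSON run manifest. The
# pipeline is deterministic given its inputs: rerunning a config
# reproduces every output byte-for-byte.

#' @noRd
.validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("pipeline config must be a list or a YAML path")
  if (is.null(config$datasets) || length(config$datasets) == 0L)
    stop("pipeline config lists no datasets")
  for (i in seq_along(config$datasets)) {
    d <- config$datasets[[i]]
    for (f in c("dataset_id", "expression", "samples"))
      if (is.null(d[[f]]))
        stop(sprintf("dataset %d: missing field '%s'", i, f))
    for (f in c("expression", "samples"))
      if (!file.exists(d[[f]]))
        stop(sprintf("dataset %s: file not found: %s", d$dataset_id, d[[f]]))
  }
  if (is.null(config$snr_threshold)) config$snr_threshold <- 1
  if (is.null(config$reference_gene)) config$reference_gene <- "ARNTL"
  if (is.null(config$genes)) config$genes <- default_clock_panel()$gene_id
  config
}

#' Run the end-to-end circadian phasing analysis
#'
#' For each configured dataset: read the expression matrix and sample
#' table, optionally batch-adjust (by the dataset's `batch_var` column),
#' and estimate peak/trough phases for the gene panel. Then combine the
#' per-dataset estimates, compute peak times relative to the reference
#' gene, compare every pair of dataset groups (pooled pairwise absolute
#' circular differences), and compute per-gene group circular mean peaks.
#'
#' All configuration is validated before any computation starts. Outputs
#' are written under `out_dir`: `phases.tsv`, `excluded.tsv`,
#' `relative_peaks.tsv`, `comparison_pairs.tsv`, `comparison_summary.tsv`,
#' `group_means.tsv` and `manifest.json` (the echoed config plus every
#' decision: gene panel, SNR threshold, batch variables, reference gene).
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{datasets}{list of `dataset_id`, `expression` (path),
#'       `samples` (path), optional `batch_var` (column of the sample
#'       table to use as batch) and `group` (comparison group label;
#'       defaults to the dataset's organ).}
#'     \item{genes}{gene panel (default: the seven-gene clock panel).}
#'     \item{snr_threshold}{rhythmicity threshold (default 1).}
#'     \item{reference_gene}{for relative peak times (default ARNTL).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `phases`, `excluded`, `relative`,
#'   `comparisons` (list of `phase_comparison`), `group_means`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- .validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phase_tabs <- list(); excl_tabs <- list(); groups <- character(0)
  for (d in config$datasets) {
    x <- read_expression_matrix(d$expression)
    samples <- read_sample_table(d$samples)
    samples <- align_samples(x, samples)
    if (!is.null(d$batch_var)) {
      if (is.null(samples[[d$batch_var]]))
        stop(sprintf("dataset %s: batch_var '%s' not in sample table",
                     d$dataset_id, d$batch_var))
      x <- batch_adjust(x, samples[[d$batch_var]])
    }
    samples$dataset_id <- d$dataset_id
    ph <- estimate_phases(x, samples, genes = config$genes,
                          snr_threshold = config$snr_threshold)
    phase_tabs[[d$dataset_id]] <- ph$estimates
    if (nrow(ph$excluded)) {
      e <- ph$excluded; e$dataset_id <- d$dataset_id
      excl_tabs[[d$dataset_id]] <- e
    }
    grp <- if (!is.null(d$group)) d$group else
      unique(stats::na.omit(samples$organ))[1]
    groups[d$dataset_id] <- grp
  }
  phases <- do.call(rbind, c(phase_tabs, list(make.row.names = FALSE)))
  excluded <- if (length(excl_tabs))
    do.call(rbind, c(excl_tabs, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(), snr = numeric(),
                  dataset_id = character())
  relative <- suppressWarnings(
    relative_peak_times(phases, config$reference_gene))
  comparisons <- list(); pair_tabs <- list(); summ <- list()
  group_levels <- unique(unname(groups))
  group_pairs <- if (length(group_levels) >= 2L)
    utils::combn(group_levels, 2, simplify = FALSE) else list()
  for (pair in group_pairs) {
    a <- phases[groups[phases$dataset_id] == pair[1], , drop = FALSE]
    b <- phases[groups[phases$dataset_id] == pair[2], , drop = FALSE]
    key <- paste(pair, collapse = "_vs_")
    cmp <- compare_groups(a, b, label_a = pair[1], label_b = pair[2])
    comparisons[[key]] <- cmp
    p <- cmp$pairs; p$comparison <- key
    pair_tabs[[key]] <- p
    summ[[key]] <- data.frame(
      comparison = key, group_a = pair[1], group_b = pair[2],
      n_pairs = nrow(cmp$pairs), mean_abs_diff = cmp$mean_abs_diff,
      sd_abs_diff = cmp$sd_abs_diff, median_abs_diff = cmp$median_abs_diff,
      stringsAsFactors = FALSE)
  }
  group_means <- group_circular_mean_peaks(phases, groups)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(phases, "phases.tsv")
  tsv(excluded, "excluded.tsv")
  tsv(relative, "relative_peaks.tsv")
  tsv(if (length(pair_tabs))
        do.call(rbind, c(pair_tabs, list(make.row.names = FALSE)))
      else data.frame(), "comparison_pairs.tsv")
  tsv(if (length(summ)) do.call(rbind, c(summ, list(make.row.names = FALSE)))
      else data.frame(), "comparison_summary.tsv")
  tsv(group_means, "group_means.tsv")
  manifest <- list(
    package = "circaphase",
    version = as.character(utils::packageVersion("circaphase")),
    config = config,
    dataset_groups = as.list(groups),
    outputs = c("phases.tsv", "excluded.tsv", "relative_peaks.tsv",
                "comparison_pairs.tsv", "comparison_summary.tsv",
                "group_means.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(phases = phases, excluded = excluded, relative = relative,
                 comparisons = comparisons, group_means = group_means,
                 out_dir = out_dir))
}

#' Split a sample table into young and old age groups
#'
#' Partition at `age <= threshold` versus `age > threshold`. Samples with
#' missing age are dropped with a warning; if no sample has a recorded
#' age, an error is raised.
#'
#' @param samples sample table with an `age` column.
#' @param threshold age boundary in years (default 40; the boundary value
#'   itself falls in the young group).
#' @return list with sample tables `young` and `old`.
#' @export
split_by_age <- function(samples, threshold = 40) {
  validate_sample_table(samples)
  if (is.null(samples$age) || all(is.na(samples$age)))
    stop("no sample has a recorded age")
  n_missing <- sum(is.na(samples$age))
  if (n_missing > 0) {
    warning(n_missing, " samples with missing age excluded")
    samples <- samples[!is.na(samples$age), , drop = FALSE]
  }
  list(young = samples[samples$age <= threshold, , drop = FALSE],
       old = samples[samples$age > threshold, , drop = FALSE])
}

#' Shift circadian times by a capped postmortem progression
#'
#' Sensitivity utility for postmortem designs: if the clock keeps running
#' after death, the tissue's circadian state corresponds to the time of
#' death plus (part of) the postmortem interval. Replaces each sample's
#' circadian time with `(circadian_time + min(pmi, progression)) mod 24`;
#' downstream phases can then be re-estimated under the shifted times.
#' This is a simplified what-if shift, not a model of postmortem
#' transcriptional dynamics.
#'
#' @param samples sample table with complete `circadian_time` and `pmi`
#'   (postmortem interval, hours) columns.
#' @param progression assumed maximum hours of postmortem clock
#'   progression.
#' @return sample table with shifted `circadian_time`.
#' @export
postmortem_shift_sensitivity <- function(samples, progression) {
  validate_sample_table(samples)
  if (is.null(samples$pmi) || anyNA(samples$pmi))
    stop("pmi column missing or incomplete")
  if (is.null(samples$circadian_time) || anyNA(samples$circadian_time))
    stop("circadian_time must be present for all samples")
  if (progression < 0) stop("progression must be >= 0")
  samples$circadian_time <-
    (samples$circadian_time + pmin(samples$pmi, progression)) %% 24
  samples
}
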