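# Circular arithmetic on circadian phases (hours on a 24-h circle):
# circular means, signed/absolute differences, phases relative to a
# reference gene, and pairwise group comparisons.

#' Circular mean of times on the 24-hour circle
#'
#' Each time is mapped to an angle, the unit vectors are summed, and the
#' angle of the resultant is mapped back to hours:
#' `t_bar = (24 / 2pi) * atan2(sum sin(t_i 2pi/24), sum cos(t_i 2pi/24))`.
#'
#' @param times hours (any real; interpreted modulo 24). Must be nonempty
#'   and not perfectly antipodal: if the resultant vector has length below
#'   1e-9 the mean is undefined and an error is raised.
#' @return circular mean, hours in `[0, 24)`.
#' @examples
#' circular_mean(c(23, 1))  # 0, not 12
#' @export
circular_mean <- function(times) {
  if (length(times) == 0L) stop("undefined circular mean: empty input")
  rad <- times * 2 * pi / 24
  S <- sum(sin(rad)); C <- sum(cos(rad))
  if (sqrt(S^2 + C^2) < 1e-9)
    stop("undefined circular mean: antipodal input")
  out <- (atan2(S, C) * 24 / (2 * pi)) %% 24
  if (24 - out < 1e-9) out <- 0  # keep the half-open [0,24) invariant
  out
}

#' Signed circular difference between two times
#'
#' How far `t1` is ahead of `t2` on the 24-h circle, in `(-12, 12]`:
#' `((t1 - t2 + 12) mod 24) - 12`, e.g. CT2 is 6 h ahead of CT20. Exact
#' antipodes return +12 by convention. Vectorized with recycling.
#'
#' @param t1,t2 hours.
#' @return signed difference in `(-12, 12]`.
#' @examples
#' signed_circ_diff(2, 20)  # +6
#' @export
signed_circ_diff <- function(t1, t2) {
  d <- ((t1 - t2 + 12) %% 24) - 12
  d[d == -12] <- 12
  d
}

#' Absolute circular difference between two times
#'
#' `|signed_circ_diff(t1, t2)|`, in `[0, 12]`.
#'
#' @inheritParams signed_circ_diff
#' @return absolute difference in `[0, 12]`.
#' @export
abs_circ_diff <- function(t1, t2) {
  abs(signed_circ_diff(t1, t2))
}

#' Peak times relative to a reference gene
#'
#' Within each dataset, circularly subtracts the reference gene's peak time
#' from every gene's peak time. Constant between-dataset phase shifts
#' cancel, so datasets that keep the same gene-to-gene phase relationships
#' produce identical relative tables. Datasets lacking the reference gene
#' are skipped with a warning.
#'
#' @param estimates data.frame of phase estimates with columns `gene_id`,
#'   `dataset_id` and `peak_time` (e.g. `$estimates` from
#'   [estimate_phases()]).
#' @param reference_gene gene ID used as phase zero.
#' @return data.frame `gene_id`, `dataset_id`, `relative_peak_time`
#'   (signed hours in `(-12, 12]`; the reference gene maps to 0).
#' @export
relative_peak_times <- function(estimates, reference_gene) {
  out <- list()
  for (ds in unique(estimates$dataset_id)) {
    sub <- estimates[estimates$dataset_id == ds, , drop = FALSE]
    ref <- sub$peak_time[sub$gene_id == reference_gene]
    if (length(ref) != 1L) {
      warning("reference gene ", reference_gene,
              " missing in dataset ", ds, "; dataset skipped")
      next
    }
    out[[ds]] <- data.frame(
      gene_id = sub$gene_id, dataset_id = ds,
      relative_peak_time = signed_circ_diff(sub$peak_time, ref),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), dataset_id = character(),
                      relative_peak_time = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Pairwise circular phase comparison between two groups of datasets
#'
#' For every gene shared between the two groups and every dataset pair
#' (one dataset from each group), computes the absolute circular
#' difference of peak times, then summarizes the pooled differences with
#' their arithmetic mean, SD (n-1 denominator) and median. Absolute
#' differences live on the line segment `[0, 12]`, so linear summaries
#' apply.
#'
#' With `per_gene_first = TRUE` the pairwise differences are averaged
#' within gene before the summary, weighting each gene equally regardless
#' of how many dataset pairs it appears in.
#'
#' @param estimates_a,estimates_b data.frames of phase estimates (columns
#'   `gene_id`, `dataset_id` and the time column).
#' @param label_a,label_b group labels used in printing.
#' @param time_col which phase to compare: `"peak_time"` (default) or
#'   `"trough_time"`.
#' @param per_gene_first average within gene before summarizing (default
#'   `FALSE`: pooled pairwise).
#' @return object of class `phase_comparison`: list with `group_a`,
#'   `group_b`, `pairs` (data.frame `gene_id`, `dataset_a`, `dataset_b`,
#'   `abs_diff`), `mean_abs_diff`, `sd_abs_diff`, `median_abs_diff`,
#'   `per_gene_first`.
#' @export
compare_groups <- function(estimates_a, estimates_b,
                           label_a = "group_a", label_b = "group_b",
                           time_col = c("peak_time", "trough_time"),
                           per_gene_first = FALSE) {
  time_col <- match.arg(time_col)
  shared <- intersect(estimates_a$gene_id, estimates_b$gene_id)
  if (length(shared) == 0L) stop("no genes shared between the groups")
  pairs <- list()
  for (g in shared) {
    a <- estimates_a[estimates_a$gene_id == g, , drop = FALSE]
    b <- estimates_b[estimates_b$gene_id == g, , drop = FALSE]
    grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
    pairs[[g]] <- data.frame(
      gene_id = g,
      dataset_a = a$dataset_id[grid$ia],
      dataset_b = b$dataset_id[grid$ib],
      abs_diff = abs_circ_diff(a[[time_col]][grid$ia],
                               b[[time_col]][grid$ib]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  diffs <- if (per_gene_first)
    tapply(pairs$abs_diff, pairs$gene_id, mean) else pairs$abs_diff
  structure(
    list(group_a = label_a, group_b = label_b, pairs = pairs,
         mean_abs_diff = mean(diffs),
         sd_abs_diff = stats::sd(diffs),
         median_abs_diff = stats::median(diffs),
         per_gene_first = per_gene_first),
    class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf(
    "Phase comparison %s vs %s: |dpeak| = %.2f +/- %.2f h (M +/- SD; median %.2f h; %d pairs%s)\n",
    x$group_a, x$group_b, x$mean_abs_diff, x$sd_abs_diff,
    x$median_abs_diff, nrow(x$pairs),
    if (x$per_gene_first) ", per-gene first" else ""))
  invisible(x)
}

#' Circular mean peak time per gene and organ class
#'
#' Groups datasets into classes (e.g. diurnal vs nocturnal, or organ) and
#' computes, per gene and class, the circular mean of the per-dataset peak
#' times.
#'
#' @param estimates data.frame of phase estimates (columns `gene_id`,
#'   `dataset_id`, `peak_time`).
#' @param grouping named character vector mapping `dataset_id` to a class
#'   label.
#' @return data.frame `gene_id`, `group`, `mean_peak_time`, `n_datasets`.
#' @export
group_circular_mean_peaks <- function(estimates, grouping) {
  missing_ds <- setdiff(unique(estimates$dataset_id), names(grouping))
  if (length(missing_ds))
    stop("datasets without a group label: ",
         paste(missing_ds, collapse = ", "))
  grp <- unname(grouping[as.character(estimates$dataset_id)])
  keys <- unique(data.frame(gene_id = estimates$gene_id, group = grp,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$gene_id, keys$group), , drop = FALSE]
  keys$mean_peak_time <- NA_real_
  keys$n_datasets <- NA_integer_
  for (i in seq_len(nrow(keys))) {
    sel <- estimates$gene_id == keys$gene_id[i] & grp == keys$group[i]
    keys$mean_peak_time[i] <- circular_mean(estimates$peak_time[sel])
    keys$n_datasets[i] <- sum(sel)
  }
  rownames(keys) <- NULL
  keys
}
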