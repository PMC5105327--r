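# Expression-matrix transformations applied upstream of phase fitting:
# tpm aggregation and log transform, location-scale batch adjustment,
# per-gene scaling and dataset merging. Phase estimation consumes adjusted,
# unscaled values; peak/trough times and SNR are invariant to per-gene
# affine maps, so scale_genes() is for display only.

#' Sum transcript-level tpm into gene-level abundances
#'
#' @param transcript_tpm numeric matrix, transcripts x samples, tpm scale
#'   (all values >= 0), with transcript rownames.
#' @param mapping data.frame whose first two columns are transcript ID and
#'   gene ID.
#' @return numeric matrix, genes x samples, gene value = sum of tpm over
#'   that gene's transcripts. Unmapped transcripts are dropped and their
#'   count reported via [message()].
#' @export
aggregate_transcripts_to_genes <- function(transcript_tpm, mapping) {
  if (!is.matrix(transcript_tpm) || !is.numeric(transcript_tpm))
    stop("transcript_tpm must be a numeric matrix")
  if (any(transcript_tpm < 0)) stop("tpm values must be >= 0")
  tx <- as.character(mapping[[1L]])
  gene <- as.character(mapping[[2L]])
  idx <- match(rownames(transcript_tpm), tx)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no transcripts in common with the mapping")
  n_drop <- sum(!keep)
  if (n_drop > 0) message(n_drop, " unmapped transcripts dropped")
  m <- transcript_tpm[keep, , drop = FALSE]
  g <- factor(gene[idx[keep]])
  out <- rowsum(m, g)
  rownames(out) <- levels(g)
  out
}

#' Natural-log transform of tpm values
#'
#' Applies `log(tpm + 1)`, mapping zero abundance to zero.
#'
#' @param value tpm values, all >= 0 (vector or matrix).
#' @return values on the natural-log scale.
#' @export
log_tpm <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("tpm values must be >= 0")
  log(value + 1)
}

# Pooled within-batch sample SD: sqrt of the (n_b - 1)-weighted mean of the
# within-batch variances. Using this (rather than the total SD) makes the
# adjustment exactly idempotent, because after one pass the between-batch
# variance is zero.
#' @noRd
.pooled_within_sd <- function(values, batch) {
  n_b <- tapply(values, batch, length)
  v_b <- tapply(values, batch, stats::var)
  sqrt(sum((n_b - 1) * v_b) / (sum(n_b) - length(n_b)))
}

#' Location-scale batch adjustment of an expression matrix
#'
#' For each gene, the values in every batch are standardized (batch mean
#' subtracted, batch SD divided out) and restored to the gene's overall
#' mean and pooled within-batch SD. After adjustment every batch has the
#' same per-gene mean and SD, which removes additive and multiplicative
#' batch effects while leaving the within-batch ordering of samples
#' untouched. The map is idempotent.
#'
#' Genes for which some batch has (numerically) zero variance are adjusted
#' in location only, with a warning; their within-batch scales are left
#' as-is. Sample SDs use the n-1 denominator throughout.
#'
#' @param x expression matrix.
#' @param batch character or factor of batch labels, one per column of `x`
#'   (typically `subject_id` for dense within-subject designs,
#'   anatomical area for one-time-per-subject designs, or `dataset_id`
#'   when merging datasets). Every batch needs at least 2 samples.
#' @return adjusted expression matrix of the same shape.
#' @export
batch_adjust <- function(x, batch) {
  validate_expression_matrix(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x))
    stop("need one batch label per sample")
  if (anyNA(batch)) stop("batch labels contain NA")
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("batches with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (length(sizes) == 1L) return(x)
  f <- factor(batch)
  out <- x
  degenerate <- character(0)
  for (g in seq_len(nrow(x))) {
    vals <- x[g, ]
    m_b <- tapply(vals, f, mean)[f]
    s_b <- tapply(vals, f, stats::sd)[f]
    m_pool <- mean(vals)
    if (any(s_b < 1e-12)) {
      # location-only shift; scale untouched
      out[g, ] <- vals - m_b + m_pool
      degenerate <- c(degenerate, rownames(x)[g])
    } else {
      s_pool <- .pooled_within_sd(vals, f)
      out[g, ] <- (vals - m_b) / s_b * s_pool + m_pool
    }
  }
  if (length(degenerate))
    warning("zero within-batch variance, location-only adjustment for: ",
            paste(degenerate, collapse = ", "))
  out
}

#' Scale each gene to mean zero and SD one
#'
#' Per-gene standardization for display and heatmaps (sample SD, n-1
#' denominator). Phase estimates and SNR are invariant to this map.
#'
#' @param x expression matrix; every gene needs at least two distinct
#'   values.
#' @return matrix with per-gene mean 0 and SD 1.
#' @export
scale_genes <- function(x) {
  validate_expression_matrix(x)
  s <- apply(x, 1L, stats::sd)
  constant <- rownames(x)[s < 1e-12]
  if (length(constant))
    stop("constant gene rows cannot be scaled: ",
         paste(constant, collapse = ", "))
  (x - rowMeans(x)) / s
}

#' Merge expression datasets on their shared genes
#'
#' Column-concatenates the matrices on the intersection of their gene sets,
#' row-binds the sample tables (missing columns filled with NA), then
#' applies [batch_adjust()] with `dataset_id` as the batch so that
#' between-dataset location and scale differences are removed.
#'
#' @param matrices list of >= 2 expression matrices.
#' @param samples list of matching sample tables; each must carry
#'   `dataset_id` (a single value per table).
#' @return list with elements `expression` (merged, adjusted matrix) and
#'   `samples` (combined sample table).
#' @export
merge_datasets <- function(matrices, samples) {
  if (length(matrices) < 2L) stop("need at least two datasets to merge")
  if (length(samples) != length(matrices))
    stop("need one sample table per matrix")
  for (i in seq_along(matrices)) {
    validate_expression_matrix(matrices[[i]])
    samples[[i]] <- align_samples(matrices[[i]], samples[[i]])
    if (is.null(samples[[i]]$dataset_id) ||
        length(unique(samples[[i]]$dataset_id)) != 1L)
      stop("each sample table must carry a single dataset_id")
  }
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0L) stop("no genes shared between the datasets")
  merged <- do.call(cbind, lapply(matrices, function(m)
    m[shared, , drop = FALSE]))
  all_cols <- Reduce(union, lapply(samples, names))
  samples <- lapply(samples, function(s) {
    s[setdiff(all_cols, names(s))] <- NA
    s[all_cols]
  })
  combined <- do.call(rbind, samples)
  rownames(combined) <- NULL
  validate_sample_table(combined)
  adjusted <- batch_adjust(merged, combined$dataset_id)
  list(expression = adjusted, samples = combined)
}
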