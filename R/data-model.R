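# Core tabular containers: an expression matrix is a plain numeric matrix
# (genes x samples, log scale) with unique dimnames; a sample table is a
# data.frame keyed by sample_id. Validators enforce the invariants at every
# entry point so downstream code can assume them.

#' Validate a genes-by-samples expression matrix
#'
#' @param x numeric matrix, genes in rows, samples in columns, log-scale
#'   values; `rownames` are gene IDs, `colnames` are sample IDs.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @keywords internal
#' @noRd
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' @noRd
validate_sample_table <- function(samples) {
  if (!is.data.frame(samples)) stop("sample table must be a data.frame")
  if (is.null(samples$sample_id)) stop("sample table lacks a sample_id column")
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup))
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if (!is.null(samples$circadian_time)) {
    ct <- samples$circadian_time
    if (any(!is.na(ct) & (ct < 0 | ct >= 24)))
      stop("circadian_time outside [0,24) after normalization")
  }
  invisible(samples)
}

# Align a sample table to the columns of an expression matrix; every column
# must have a metadata row.
#' @noRd
align_samples <- function(x, samples) {
  idx <- match(colnames(x), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample table: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  samples[idx, , drop = FALSE]
}

#' Read a genes-by-samples expression matrix from delimited text
#'
#' The first column holds gene IDs, the header row holds sample IDs and the
#' body is numeric log-scale expression.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect `"tsv"` or `"csv"`; by default inferred from the file
#'   extension (`.csv` means comma-separated, anything else tab-separated).
#' @return numeric matrix with gene rownames and sample colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "PER1\t0.5\t1.5", "ARNTL\t2\t0"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        stop("no data rows in ", path, call. = FALSE)
      stop(e)
    })
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (ncol(df) < 2L) stop("expression matrix needs gene IDs plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value %s at row %d, column %s",
                     dQuote(col[bad[1L]]), bad[1L], names(body)[j]))
      body[[j]] <- num
    }
  }
  x <- as.matrix(body)
  rownames(x) <- gene_ids
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, header of
#' sample IDs.
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Columns coerced to numeric hours/years when present.
.numeric_sample_cols <- c("circadian_time", "clock_time", "sunrise_time",
                          "age", "pmi")

#' Read a per-sample metadata table
#'
#' Requires a `sample_id` column; recognizes `circadian_time`, `clock_time`,
#' `sunrise_time`, `subject_id`, `batch_id`, `organ`, `dataset_id`, `age`,
#' `sex` and `pmi`, and preserves any other columns untouched.
#' `circadian_time` is normalized modulo 24 into `[0, 24)`; missing values
#' stay missing (they can be derived later with
#' [clock_time_to_circadian()]).
#'
#' @param path path to a TSV or CSV file with a header row.
#' @param dialect as in [read_expression_matrix()].
#' @return data.frame, one row per sample.
#' @export
read_sample_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (is.null(df$sample_id)) stop("sample table lacks a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  for (col in intersect(.numeric_sample_cols, names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if (!is.null(df$circadian_time))
    df$circadian_time <- wrap24(df$circadian_time)
  if (!is.null(df$sex)) {
    sex <- tolower(as.character(df$sex))
    sex[!sex %in% c("female", "male")] <- "unknown"
    df$sex <- sex
  }
  validate_sample_table(df)
  df
}

#' Write a sample table as delimited text
#'
#' @param samples sample table (data.frame with `sample_id`).
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_sample_table(samples)
  utils::write.table(samples, path, sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a two-column ortholog mapping table
#'
#' Columns: source gene ID, target (human) gene ID. Each source may map to
#' at most one target.
#'
#' @param path path to a headered two-column TSV.
#' @return data.frame with columns `source_gene_id`, `target_gene_id`.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns")
  out <- data.frame(source_gene_id = as.character(df[[1L]]),
                    target_gene_id = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  dup <- unique(out$source_gene_id[duplicated(out$source_gene_id)])
  if (length(dup))
    stop("source genes mapped to more than one target: ",
         paste(dup, collapse = ", "))
  out
}

#' Convert clock time to circadian time
#'
#' Circadian time zero corresponds to sunrise, so
#' `CT = (clock_time - sunrise_time) mod 24`. Both arguments are hours and
#' are vectorized with the usual recycling.
#'
#' @param clock_time time of day, hours.
#' @param sunrise_time local sunrise, hours.
#' @return circadian time, hours in `[0, 24)`.
#' @examples
#' clock_time_to_circadian(8, 6)  # CT2
#' clock_time_to_circadian(5, 6)  # CT23, wrapping past midnight
#' @export
clock_time_to_circadian <- function(clock_time, sunrise_time) {
  if (!all(is.finite(clock_time)) || !all(is.finite(sunrise_time)))
    stop("clock_time and sunrise_time must be finite")
  wrap24(clock_time - sunrise_time)
}

#' Infer biological sex from a Y-linked marker gene
#'
#' Computes, per subject, the median expression of a marker gene (RPS4Y1 by
#' default) across that subject's samples, then splits subjects into a low
#' and a high group at the largest gap in the sorted medians. Subjects in
#' the low group are called female, the high group male. Expression should
#' be taken prior to batch correction, since subject-level correction
#' removes exactly the between-subject signal used here.
#'
#' If the largest gap is less than twice the second-largest, the split is
#' not clearly bimodal: sex is still assigned but the result carries the
#' attribute `sex_ambiguous = TRUE` and a warning is raised. With a single
#' subject no split exists; sex is set to `"unknown"` with a warning.
#'
#' @param x expression matrix (before batch adjustment).
#' @param samples sample table covering the columns of `x`, with
#'   `subject_id`.
#' @param marker_gene gene ID of the marker; must be a row of `x`.
#' @return `samples` with the `sex` column filled in.
#' @export
infer_sex_from_marker <- function(x, samples, marker_gene = "RPS4Y1") {
  validate_expression_matrix(x)
  samples <- align_samples(x, samples)
  if (is.null(samples$subject_id)) stop("sample table lacks subject_id")
  if (!marker_gene %in% rownames(x))
    stop("marker gene ", marker_gene, " absent from expression matrix")
  med <- tapply(x[marker_gene, ], samples$subject_id, stats::median)
  ambiguous <- FALSE
  if (length(med) < 2L) {
    warning("single subject: cannot split marker medians, sex set to unknown")
    sex_by_subject <- stats::setNames("unknown", names(med))
    ambiguous <- TRUE
  } else {
    ord <- order(med)
    gaps <- diff(med[ord])
    split_at <- which.max(gaps)
    if (length(gaps) > 1L) {
      second <- max(gaps[-split_at])
      if (max(gaps) < 2 * second) {
        warning("marker medians not clearly bimodal (largest gap < 2x next)")
        ambiguous <- TRUE
      }
    }
    sex_sorted <- rep(c("female", "male"),
                      c(split_at, length(med) - split_at))
    sex_by_subject <- stats::setNames(sex_sorted, names(med)[ord])
  }
  samples$sex <- unname(sex_by_subject[as.character(samples$subject_id)])
  attr(samples, "sex_ambiguous") <- ambiguous
  samples
}

#' Map gene rows to (human) ortholog IDs
#'
#' Renames the rows of an expression matrix according to an ortholog table.
#' Source genes without a mapping are dropped. When two or more source
#' genes map to the same target, the row with the highest variance is kept
#' and the drop is reported via [message()].
#'
#' @param x expression matrix with source-species gene IDs as rownames.
#' @param table ortholog table as from [read_ortholog_table()].
#' @return expression matrix with target gene IDs as rownames.
#' @export
map_orthologs <- function(x, table) {
  validate_expression_matrix(x)
  idx <- match(rownames(x), table$source_gene_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no genes in common between matrix and ortholog table")
  x <- x[keep, , drop = FALSE]
  targets <- table$target_gene_id[idx[keep]]
  if (anyDuplicated(targets)) {
    v <- apply(x, 1L, stats::var)
    ord <- order(v, decreasing = TRUE)  # highest-variance row wins
    keep_rows <- ord[!duplicated(targets[ord])]
    dropped <- rownames(x)[setdiff(seq_len(nrow(x)), keep_rows)]
    message("ortholog collisions: dropped lower-variance rows ",
            paste(dropped, collapse = ", "))
    keep_rows <- sort(keep_rows)
    x <- x[keep_rows, , drop = FALSE]
    targets <- targets[keep_rows]
  }
  rownames(x) <- targets
  validate_expression_matrix(x)
  x
}
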