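#' Construct a feature table
#'
#' A feature table holds a samples x metabolites matrix of non-negative peak
#' areas together with per-sample batch and group labels. Groups are the
#' three botanical origins (`"CP"`, `"CM"`, `"CT"`) plus pooled `"QC"` runs;
#' every non-QC sample must carry a batch, and all replicates of a batch must
#' share its group.
#'
#' @param areas numeric matrix (samples x metabolites), row names are sample
#'   ids, column names are metabolite names.
#' @param group character vector of per-sample group labels.
#' @param batch character vector of per-sample batch ids (`NA` allowed for QC
#'   rows).
#' @return An object of class `feature_table` with elements `areas`,
#'   `sample_id`, `batch_id`, `group`, `metabolite_names`.
#' @export
feature_table <- function(areas, group, batch = NULL) {
  stopifnot(is.matrix(areas), is.numeric(areas))
  n <- nrow(areas)
  if (n > 0 && is.null(rownames(areas)))
    rownames(areas) <- paste0("S", seq_len(n))
  if (is.null(colnames(areas)))
    colnames(areas) <- paste0("M", seq_len(ncol(areas)))
  if (is.null(batch)) batch <- rep(NA_character_, n)
  group <- as.character(group)
  batch <- as.character(batch)
  stopifnot(length(group) == n, length(batch) == n)
  if (anyDuplicated(rownames(areas)))
    stop("duplicate sample ids in feature table")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("feature table areas must be finite and non-negative")
  if (any(is.na(group)))
    stop("every sample must carry a group label")
  non_qc <- group != "QC"
  if (any(non_qc & is.na(batch)))
    stop("every non-QC sample must carry a batch id")
  for (b in unique(batch[non_qc])) {
    g <- unique(group[!is.na(batch) & batch == b])
    if (length(g) > 1L)
      stop("replicates of batch '", b, "' carry conflicting group labels")
  }
  structure(list(areas = areas, sample_id = rownames(areas),
                 batch_id = batch, group = group,
                 metabolite_names = colnames(areas)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$group)
  cat("<feature_table> ", nrow(x$areas), " samples x ", ncol(x$areas),
      " metabolites (", paste(names(tab), tab, sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Drop QC rows from a feature table
#'
#' @param table a `feature_table`.
#' @return The table restricted to non-QC samples.
#' @export
drop_qc <- function(table) {
  subset_samples(table, table$group != "QC")
}

#' Restrict a feature table to a sample or metabolite subset
#'
#' @param table a [feature_table()].
#' @param idx logical or integer sample index.
#' @return The restricted `feature_table`.
#' @export
subset_samples <- function(table, idx) {
  feature_table(table$areas[idx, , drop = FALSE],
                group = table$group[idx], batch = table$batch_id[idx])
}

#' @rdname subset_samples
#' @param cols metabolite names or column indices (order preserved).
#' @export
subset_metabolites <- function(table, cols) {
  feature_table(table$areas[, cols, drop = FALSE],
                group = table$group, batch = table$batch_id)
}

#' Write a feature table to CSV
#'
#' The layout is one row per sample: `sample_id`, `batch_id`, `group`, then
#' one column per metabolite. [read_feature_table()] inverts it losslessly.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_id, batch_id = table$batch_id,
                   group = table$group, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$areas, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_feature_table()] (columns `sample_id`,
#'   `batch_id`, `group`, then metabolite areas).
#' @return A `feature_table`. Errors on missing schema columns, duplicate
#'   sample ids, or negative areas.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "batch_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table file is missing column(s): ",
         paste(miss, collapse = ", "))
  met <- setdiff(names(df), need)
  if (!length(met)) stop("feature table file has no metabolite columns")
  areas <- as.matrix(df[, met, drop = FALSE])
  if (!is.numeric(areas)) stop("non-numeric metabolite areas in file")
  rownames(areas) <- df$sample_id
  batch <- df$batch_id
  batch[batch %in% c("", "NA")] <- NA_character_
  feature_table(areas, group = df$group, batch = batch)
}
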