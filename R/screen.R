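#' Screening configuration
#'
#' @param p_threshold ANOVA p-value threshold (default 0.05, raw p).
#' @param fc_threshold linear fold-change threshold vs the central group
#'   (default 2).
#' @param central_group the origin fold changes are taken against (default
#'   `"CT"`).
#' @param adjust `"none"` (default, raw p-values) or `"BH"`
#'   (Benjamini-Hochberg).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.05, fc_threshold = 2,
                          central_group = "CT",
                          adjust = c("none", "BH")) {
  stopifnot(p_threshold > 0, p_threshold < 1, fc_threshold >= 1)
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 central_group = central_group,
                 adjust = match.arg(adjust)),
            class = "screen_config")
}

#' ANOVA + fold-change differential screen
#'
#' Per metabolite: a classical one-way fixed-effects ANOVA F-test across the
#' origin groups on log2 areas, and linear fold changes of each group mean
#' against the central group. A metabolite passes when `p < p_threshold` and
#' the largest group-vs-central fold change (taken as `max(fc, 1/fc)` over
#' groups) is at least `fc_threshold`.
#'
#' @param table a normalized [feature_table()] on the linear area scale
#'   (QC rows are ignored). The F-test is computed on `log2` areas
#'   internally; fold changes use the linear group means.
#' @param config a [screen_config()].
#' @return A data frame with one row per metabolite: `metabolite`,
#'   `p_value`, one `fc_<group>` column per non-central group, `max_abs_fc`,
#'   `passed`.
#' @export
anova_screen <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "feature_table"))
  tab <- drop_qc(table)
  grp <- factor(tab$group)
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  if (any(table(grp) < 2)) stop("every group needs at least 2 samples")
  if (!config$central_group %in% levels(grp))
    stop("central group '", config$central_group, "' absent from table")
  la <- log_areas(tab)
  others <- setdiff(levels(grp), config$central_group)
  res <- lapply(seq_len(ncol(la)), function(j) {
    x <- la[, j]
    p <- if (stats::sd(x) == 0) 1 else
      stats::oneway.test(x ~ grp, var.equal = TRUE)$p.value
    if (is.nan(p)) p <- 1  # identical values within every group
    lin_means <- tapply(tab$areas[, j], grp, mean)
    fc <- lin_means[others] / lin_means[[config$central_group]]
    out <- data.frame(metabolite = colnames(la)[j], p_value = p)
    for (g in others) out[[paste0("fc_", g)]] <- fc[[g]]
    out$max_abs_fc <- max(pmax(fc, 1 / fc))
    out
  })
  res <- do.call(rbind, res)
  if (config$adjust == "BH")
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  res$passed <- res$p_value < config$p_threshold &
    res$max_abs_fc >= config$fc_threshold
  rownames(res) <- NULL
  res
}

#' Per-group mean and SD of areas
#'
#' @param table a [feature_table()] (QC rows ignored).
#' @return A data frame: `metabolite`, `group`, `mean`, `sd` (sample SD) on
#'   the table's area scale.
#' @export
group_stats <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  tab <- drop_qc(table)
  grp <- factor(tab$group)
  out <- expand.grid(metabolite = colnames(tab$areas), group = levels(grp),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- mapply(function(m, g) mean(tab$areas[grp == g, m]),
                     out$metabolite, out$group)
  out$sd <- mapply(function(m, g) stats::sd(tab$areas[grp == g, m]),
                   out$metabolite, out$group)
  out
}

#' Select the reference metabolite
#'
#' Returns the candidate with the smallest overall sample SD of (normalized)
#' area across all non-QC samples — the compound whose content is most
#' similar and stable across every group, suitable as the denominator of the
#' peak-area ratio method. Ties break to the earliest candidate in table
#' column order.
#'
#' @param table a normalized [feature_table()].
#' @param candidates metabolite names or column indices to consider
#'   (default: all metabolites).
#' @return The selected metabolite name.
#' @export
select_reference <- function(table, candidates = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(candidates)) candidates <- colnames(table$areas)
  if (!length(candidates)) stop("empty candidate set")
  if (is.numeric(candidates)) candidates <- colnames(table$areas)[candidates]
  missing <- setdiff(candidates, colnames(table$areas))
  if (length(missing))
    stop("candidate metabolite(s) absent from table: ",
         paste(missing, collapse = ", "))
  areas <- table$areas[table$group != "QC", , drop = FALSE]
  # preserve table column order for deterministic tie-breaking
  candidates <- colnames(table$areas)[colnames(table$areas) %in% candidates]
  sds <- apply(areas[, candidates, drop = FALSE], 2, stats::sd)
  candidates[which.min(sds)]
}

#' Hierarchical cluster analysis for the heat map
#'
#' Clusters samples (columns of the heat map) and metabolites (rows) on
#' z-scored log2 areas with Euclidean distance and Ward linkage
#' (`ward.D2`), returning the leaf orders, merge trees and the sample
#' partition at `k` clusters.
#'
#' @param table a [feature_table()] restricted to the metabolites of
#'   interest (QC rows ignored).
#' @param k number of sample clusters to cut (default 3, one per origin).
#' @param scale z-score each metabolite across samples before clustering
#'   (default `TRUE`).
#' @return A list with `sample_tree`, `metabolite_tree` (class `hclust`),
#'   `sample_order`, `metabolite_order`, `sample_cluster` (named integer
#'   vector of cluster ids at `k`), and the `scaled` matrix.
#' @export
hca <- function(table, k = 3, scale = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  tab <- drop_qc(table)
  if (nrow(tab$areas) < 2 || ncol(tab$areas) < 2)
    stop("need at least 2 samples and 2 metabolites")
  la <- log_areas(tab)
  if (scale) {
    sds <- apply(la, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance metabolite(s); rerun with scale = FALSE")
    la <- base::scale(la)
  }
  st <- stats::hclust(stats::dist(la), method = "ward.D2")
  mt <- stats::hclust(stats::dist(t(la)), method = "ward.D2")
  cl <- stats::cutree(st, k = min(k, nrow(la)))
  list(sample_tree = st, metabolite_tree = mt,
       sample_order = st$order, metabolite_order = mt$order,
       sample_cluster = cl, scaled = la)
}

#' Purity of a sample partition against known labels
#'
#' Fraction of samples whose cluster's majority label matches their own —
#' 1 when every cluster is pure by origin.
#'
#' @param cluster integer vector of cluster ids.
#' @param labels true group labels, same length.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(cluster, labels) {
  stopifnot(length(cluster) == length(labels))
  tab <- table(cluster, labels)
  sum(apply(tab, 1, max)) / length(cluster)
}
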