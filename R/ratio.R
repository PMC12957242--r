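#' Decision thresholds of the peak-area ratio cascade
#'
#' The documented decision intervals for the four marker/reference area
#' ratios. Stage 1 (CT vs non-CT): a sample is on the CT side of the
#' codonopyrrolidium A ratio above `ct_A_low` (4.5) and on the non-CT side
#' below `other_A_high` (1.2); the codonopyrrolidium D ratio is CT-side
#' below `ct_D_high` (0.21) and non-CT-side above `other_D_low` (0.45).
#' Stage 2 (CP vs CM): tryptophan ratio above `cp_trp_low` (0.17) votes CP,
#' below `cm_trp_high` (0.14) votes CM; codonopsinol A analogously with
#' `cp_cod_low` (0.15) / `cm_cod_high` (0.13). All comparisons are strict;
#' values inside the unclaimed gaps yield a GAP vote.
#'
#' @param ct_A_low,other_A_high,ct_D_high,other_D_low stage-1 interval
#'   bounds.
#' @param cp_trp_low,cm_trp_high,cp_cod_low,cm_cod_high stage-2 interval
#'   bounds.
#' @return A list of class `ratio_thresholds`.
#' @export
ratio_thresholds <- function(ct_A_low = 4.5, other_A_high = 1.2,
                             ct_D_high = 0.21, other_D_low = 0.45,
                             cp_trp_low = 0.17, cm_trp_high = 0.14,
                             cp_cod_low = 0.15, cm_cod_high = 0.13) {
  th <- structure(as.list(environment()), class = "ratio_thresholds")
  if (!(th$other_A_high < th$ct_A_low))
    stop("invalid thresholds: other_A_high must be below ct_A_low")
  if (!(th$ct_D_high < th$other_D_low))
    stop("invalid thresholds: ct_D_high must be below other_D_low")
  if (!(th$cm_trp_high < th$cp_trp_low))
    stop("invalid thresholds: cm_trp_high must be below cp_trp_low")
  if (!(th$cm_cod_high < th$cp_cod_low))
    stop("invalid thresholds: cm_cod_high must be below cp_cod_low")
  th
}

#' Marker/reference peak-area ratios of one sample
#'
#' `ratio_m = area(m) / area(reference)` for the four markers. Ratios are
#' scale-free, so raw or normalized areas give identical results under
#' per-sample scaling.
#'
#' @param areas named numeric vector of one sample's peak areas.
#' @param marker_ids named vector (`A`, `D`, `trp`, `cod`) of marker names
#'   or indices into `areas`.
#' @param reference_id reference metabolite name or index.
#' @return Named numeric vector `c(A=, D=, trp=, cod=)`.
#' @export
compute_ratios <- function(areas, marker_ids, reference_id) {
  ref <- areas[[reference_id]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference metabolite area is zero or absent; ",
         "sample is unclassifiable by the ratio method")
  vapply(c("A", "D", "trp", "cod"),
         function(m) areas[[marker_ids[[m]]]] / ref, numeric(1))
}

.vote1 <- function(rA, rD, th) {
  c(A = if (rA > th$ct_A_low) "CT" else if (rA < th$other_A_high) "NON_CT"
        else "GAP",
    D = if (rD < th$ct_D_high) "CT" else if (rD > th$other_D_low) "NON_CT"
        else "GAP")
}

.vote2 <- function(rT, rC, th) {
  c(trp = if (rT > th$cp_trp_low) "CP" else if (rT < th$cm_trp_high) "CM"
          else "GAP",
    cod = if (rC > th$cp_cod_low) "CP" else if (rC < th$cm_cod_high) "CM"
          else "GAP")
}

#' Classify a sample from its marker ratios
#'
#' Two-stage cascade with mutual confirmation. Stage 1: the A and D ratios
#' each vote CT / NON_CT / GAP; both CT gives a final CT call, both NON_CT
#' proceeds to stage 2, any GAP is INDETERMINATE, and one CT against one
#' NON_CT is a CONFLICT. Stage 2: the tryptophan and codonopsinol A ratios
#' each vote CP / CM / GAP and must agree; disagreement is CONFLICT, any GAP
#' INDETERMINATE. Non-confirmation is surfaced, never guessed over.
#'
#' @param ratios named vector from [compute_ratios()].
#' @param thresholds a [ratio_thresholds()].
#' @return A list of class `ratio_decision`: `ratios`, `stage1_votes`,
#'   `stage2_votes` (NA when stage 2 is not reached), `final` (one of
#'   `"CP"`, `"CM"`, `"CT"`, `"INDETERMINATE"`, `"CONFLICT"`).
#' @examples
#' classify_ratios(c(A = 5.0, D = 0.15, trp = 0.2, cod = 0.2))$final  # CT
#' @export
classify_ratios <- function(ratios, thresholds = ratio_thresholds()) {
  stopifnot(all(c("A", "D", "trp", "cod") %in% names(ratios)),
            all(is.finite(ratios)), all(ratios >= 0))
  s1 <- .vote1(ratios[["A"]], ratios[["D"]], thresholds)
  s2 <- c(trp = NA_character_, cod = NA_character_)
  final <-
    if (all(s1 == "CT")) "CT"
    else if (any(s1 == "GAP")) "INDETERMINATE"
    else if (all(s1 == "NON_CT")) {
      s2 <- .vote2(ratios[["trp"]], ratios[["cod"]], thresholds)
      if (any(s2 == "GAP")) "INDETERMINATE"
      else if (s2[["trp"]] == s2[["cod"]]) s2[["trp"]]
      else "CONFLICT"
    } else "CONFLICT"
  structure(list(ratios = ratios, stage1_votes = s1, stage2_votes = s2,
                 final = final), class = "ratio_decision")
}

#' @export
print.ratio_decision <- function(x, ...) {
  cat("<ratio_decision>", x$final, "  ratios:",
      paste(names(x$ratios), round(x$ratios, 3), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Apply the ratio cascade to every sample of a labeled table
#'
#' @param table a [feature_table()] with origin labels (QC rows ignored).
#' @param marker_ids,reference_id as in [compute_ratios()].
#' @param thresholds a [ratio_thresholds()].
#' @return A list of class `ratio_report`: `decisions` (data frame with
#'   `sample_id`, `true_group`, `call`, the four ratios), `accuracy_pct`
#'   (over decided samples; `NA` if none decided), `n_decided`,
#'   `n_indeterminate`, `n_conflict`.
#' @export
evaluate_ratios <- function(table, marker_ids, reference_id,
                            thresholds = ratio_thresholds()) {
  stopifnot(inherits(table, "feature_table"))
  tab <- drop_qc(table)
  n <- nrow(tab$areas)
  dec <- lapply(seq_len(n), function(i) {
    r <- compute_ratios(tab$areas[i, ], marker_ids, reference_id)
    d <- classify_ratios(r, thresholds)
    data.frame(sample_id = tab$sample_id[i], true_group = tab$group[i],
               call = d$final, t(r))
  })
  dec <- if (n) do.call(rbind, dec) else
    data.frame(sample_id = character(0), true_group = character(0),
               call = character(0))
  decided <- dec$call %in% c("CP", "CM", "CT")
  structure(list(
    decisions = dec,
    accuracy_pct = if (any(decided))
      100 * mean(dec$call[decided] == dec$true_group[decided]) else NA_real_,
    n_decided = sum(decided),
    n_indeterminate = sum(dec$call == "INDETERMINATE"),
    n_conflict = sum(dec$call == "CONFLICT")), class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat("<ratio_report> decided ", x$n_decided, "/", nrow(x$decisions),
      " samples, accuracy ", round(x$accuracy_pct, 2), "% (",
      x$n_indeterminate, " indeterminate, ", x$n_conflict, " conflict)\n",
      sep = "")
  invisible(x)
}
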