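# Default planted structure for the synthetic cohort, in log2 peak-area
# units. Group columns are CP, CM, CT. The reference metabolite is flat
# across groups with a very small SD; the four ratio markers are placed so
# that every per-sample marker/reference ratio satisfies its decision
# interval with a wide margin; the remaining differential metabolites cycle
# through three effect patterns (origin-specific up/down shifts of >= 4-fold
# or a CP-vs-CM split), and null metabolites are flat.

.CR_GROUPS <- c("CP", "CM", "CT")

.DEFAULT_DIFFERENTIAL_IDS <- c(1, 2, 4, 7, 9, 10, 12, 14, 16, 18, 22, 24, 26,
                               28, 31, 33, 35, 36, 37, 38, 39, 40, 41, 43,
                               45, 47, 50, 53, 55)

.RATIO_MARGIN <- 1.25  # construction margin on the decision thresholds

default_group_log_means <- function(n_metabolites = 56,
                                    differential_ids = .DEFAULT_DIFFERENTIAL_IDS,
                                    reference_id = 5,
                                    marker_ids = c(A = 35, D = 40,
                                                   trp = 14, cod = 4)) {
  mu <- matrix(0, n_metabolites, 3,
               dimnames = list(NULL, .CR_GROUPS))
  # Null metabolites sit in a tight high-abundance band so the per-sample
  # 75th-percentile normalization factor is a stable order statistic drawn
  # from origin-invariant compounds; differential metabolites live below it.
  for (m in seq_len(n_metabolites)) {
    b <- 18.3 + (m %% 6) * 0.08           # null band, ~3.2e5..4.3e5 area
    mu[m, ] <- b
  }
  plain <- setdiff(differential_ids, c(marker_ids, reference_id))
  for (k in seq_along(plain)) {
    m <- plain[k]
    b <- 15 + (m %% 4) * 0.5              # differential baseline
    mu[m, ] <- b
    pat <- k %% 3
    if (pat == 1L) {                      # CT-high, 4-fold
      mu[m, "CT"] <- b + 2
    } else if (pat == 2L) {               # CT-low, 4-fold
      mu[m, "CT"] <- b - 2
    } else {                              # CP/CM split (CP 2.83x CT, 4x CM)
      mu[m, "CP"] <- b + 1.5
      mu[m, "CM"] <- b - 0.5
    }
  }
  # stable reference, modest abundance
  mu[reference_id, ] <- 13
  # markers placed relative to the reference (log2 ratio offsets)
  mu[marker_ids[["A"]], ]   <- 13 + c(-1.0, -1.0,  3.5)
  mu[marker_ids[["D"]], ]   <- 13 + c( 0.0,  0.0, -3.3)
  mu[marker_ids[["trp"]], ] <- 13 + c(-1.5, -3.9, -3.0)
  mu[marker_ids[["cod"]], ] <- 13 + c(-1.7, -4.1, -3.2)
  mu
}

#' Configuration of the synthetic Codonopsis Radix cohort
#'
#' Defines the statistical structure the downstream analysis assumes: three
#' origin groups sampled batch-wise with technical replicates, a planted set
#' of differential metabolites, a low-variance reference metabolite, and four
#' ratio markers whose per-sample peak-area ratios to the reference fall in
#' the documented decision intervals. Defaults emulate the 38-batch study
#' design (13 CP, 16 CM, 9 CT batches, 3 replicates each; 56 metabolites of
#' which 29 are differential).
#'
#' Peak areas are log-normal: `area = 2^N(mu, sd)` with `mu` from
#' `group_log_means` and `sd` from `log_sd` (split into a batch-level latent
#' component and replicate noise of SD `replicate_log_sd`). The default
#' within-group log2 SD of 0.216 corresponds to a ~15% CV, consistent with
#' pooled-QC repeatability in the single-digit RSD range.
#'
#' @param n_batches named integer vector of batches per origin.
#' @param replicates_per_batch technical replicates per batch.
#' @param n_metabolites number of metabolites.
#' @param differential_ids indices of planted differential metabolites.
#' @param reference_id index of the stable reference metabolite.
#' @param marker_ids named indices of the four ratio markers (`A`, `D`,
#'   `trp`, `cod` = codonopyrrolidium A, codonopyrrolidium D, tryptophan,
#'   codonopsinol A).
#' @param group_log_means metabolite x group matrix of log2 mean areas.
#' @param log_sd per-metabolite within-group log2 SD.
#' @param replicate_log_sd replicate-level log2 SD (within batch).
#' @param qc_noise_sd log2 SD of pooled-QC runs.
#' @param n_qc number of QC runs appended by [generate_qc()].
#' @param metabolite_names metabolite names (default: the 56 reference
#'   compounds of [cr_compounds()]).
#' @param seed integer seed; generation is deterministic given it.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = c(CP = 13, CM = 16, CT = 9),
                             replicates_per_batch = 3,
                             n_metabolites = 56,
                             differential_ids = .DEFAULT_DIFFERENTIAL_IDS,
                             reference_id = 5,
                             marker_ids = c(A = 35, D = 40, trp = 14, cod = 4),
                             group_log_means = NULL,
                             log_sd = NULL,
                             replicate_log_sd = 0.05,
                             qc_noise_sd = 0.06,
                             n_qc = 25,
                             metabolite_names = NULL,
                             seed = 20260218) {
  if (is.null(group_log_means))
    group_log_means <- default_group_log_means(n_metabolites,
                                               differential_ids,
                                               reference_id, marker_ids)
  if (is.null(log_sd)) {
    log_sd <- rep(0.216, n_metabolites)
    log_sd[reference_id] <- 0.02
  }
  if (is.null(metabolite_names)) {
    metabolite_names <- if (n_metabolites == 56) cr_compounds()$name
                        else paste0("M", seq_len(n_metabolites))
  }
  config <- structure(list(
    n_batches = n_batches, replicates_per_batch = replicates_per_batch,
    n_metabolites = n_metabolites, differential_ids = differential_ids,
    reference_id = reference_id, marker_ids = marker_ids,
    group_log_means = group_log_means, log_sd = log_sd,
    replicate_log_sd = replicate_log_sd, qc_noise_sd = qc_noise_sd,
    n_qc = n_qc, metabolite_names = metabolite_names, seed = seed,
    rng = "Mersenne-Twister"), class = "synthetic_config")
  validate_synthetic_config(config)
  config
}

#' Validate a synthetic cohort configuration
#'
#' Checks the structural invariants the generator relies on: the reference
#' metabolite has the strictly smallest log SD; every differential metabolite
#' separates at least one group pair by >= 2-fold in the mean; every
#' non-differential metabolite has all pairwise mean ratios < 1.3; and the
#' four marker/reference mean ratios satisfy their decision inequalities with
#' at least a 25% margin. Violations are errors naming the first failed
#' inequality.
#'
#' @param config a `synthetic_config`.
#' @return `config`, invisibly.
#' @export
validate_synthetic_config <- function(config) {
  mu <- config$group_log_means
  p <- config$n_metabolites
  stopifnot(nrow(mu) == p, length(config$log_sd) == p,
            all(.CR_GROUPS %in% colnames(mu)),
            all(names(config$n_batches) %in% .CR_GROUPS),
            config$replicates_per_batch >= 1)
  if (any(config$log_sd[-config$reference_id] <=
          config$log_sd[config$reference_id]))
    stop("invalid config: reference metabolite must have the smallest log_sd")
  spread <- apply(mu[, .CR_GROUPS], 1, function(x) max(x) - min(x))
  for (m in config$differential_ids)
    if (spread[m] < 1)
      stop("invalid config: differential metabolite ", m,
           " lacks a 2-fold mean separation between any group pair")
  nulls <- setdiff(seq_len(p), config$differential_ids)
  nulls <- setdiff(nulls, config$reference_id)
  for (m in nulls)
    if (spread[m] >= log2(1.3))
      stop("invalid config: non-differential metabolite ", m,
           " has a pairwise mean ratio >= 1.3")
  r <- function(marker, grp)
    2^(mu[config$marker_ids[[marker]], grp] - mu[config$reference_id, grp])
  marg <- .RATIO_MARGIN
  checks <- list(
    list("CT A/ref > 4.5",    r("A", "CT") > 4.5 * marg),
    list("CT D/ref < 0.21",   r("D", "CT") < 0.21 / marg),
    list("CP A/ref < 1.2",    r("A", "CP") < 1.2 / marg),
    list("CM A/ref < 1.2",    r("A", "CM") < 1.2 / marg),
    list("CP D/ref > 0.45",   r("D", "CP") > 0.45 * marg),
    list("CM D/ref > 0.45",   r("D", "CM") > 0.45 * marg),
    list("CP trp/ref > 0.17", r("trp", "CP") > 0.17 * marg),
    list("CM trp/ref < 0.14", r("trp", "CM") < 0.14 / marg),
    list("CP cod/ref > 0.15", r("cod", "CP") > 0.15 * marg),
    list("CM cod/ref < 0.13", r("cod", "CM") < 0.13 / marg))
  for (ck in checks)
    if (!ck[[2]])
      stop("infeasible config: marker mean ratio fails '", ck[[1]],
           "' with a 25% margin")
  invisible(config)
}

# The strict per-sample decision inequalities a generated sample of each
# origin must satisfy (no construction margin here: these are the actual
# classification thresholds).
.sample_rule_ok <- function(areas_row, group, marker_ids, reference_id) {
  ref <- areas_row[reference_id]
  if (ref <= 0) return(FALSE)
  rA <- areas_row[marker_ids[["A"]]] / ref
  rD <- areas_row[marker_ids[["D"]]] / ref
  rT <- areas_row[marker_ids[["trp"]]] / ref
  rC <- areas_row[marker_ids[["cod"]]] / ref
  switch(group,
         CT = rA > 4.5 && rD < 0.21,
         CP = rA < 1.2 && rD > 0.45 && rT > 0.17 && rC > 0.15,
         CM = rA < 1.2 && rD > 0.45 && rT < 0.14 && rC < 0.13,
         TRUE)
}

#' Generate a synthetic cohort feature table
#'
#' Draws peak areas as `2^N(group_log_mean, log_sd)` with a batch-level
#' latent mean shared by the technical replicates of a batch and independent
#' replicate noise. After drawing a batch, the per-sample marker/reference
#' ratio inequalities of its origin are verified; a violating batch is
#' redrawn (at most 100 times) so the planted ratio structure holds for every
#' sample. Deterministic for a fixed `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A [feature_table()] with `sum(n_batches) * replicates_per_batch`
#'   samples and no QC rows.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  p <- config$n_metabolites
  batch_sd <- sqrt(pmax(config$log_sd^2 - config$replicate_log_sd^2, 0))
  rows <- list(); groups <- character(0); batches <- character(0)
  for (g in .CR_GROUPS) {
    nb <- config$n_batches[[g]]
    mu <- config$group_log_means[, g]
    for (b in seq_len(nb)) {
      bid <- sprintf("%s%02d", g, b)
      for (try in seq_len(100L)) {
        latent <- mu + stats::rnorm(p, 0, batch_sd)
        reps <- vapply(seq_len(config$replicates_per_batch), function(r)
          2^(latent + stats::rnorm(p, 0, config$replicate_log_sd)),
          numeric(p))
        ok <- all(vapply(seq_len(ncol(reps)), function(r)
          .sample_rule_ok(reps[, r], g, config$marker_ids,
                          config$reference_id), logical(1)))
        if (ok) break
        if (try == 100L)
          stop("failed to draw batch ", bid,
               " satisfying the marker ratio inequalities after 100 tries")
      }
      for (r in seq_len(config$replicates_per_batch)) {
        rows[[length(rows) + 1L]] <- reps[, r]
        groups <- c(groups, g)
        batches <- c(batches, bid)
      }
    }
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- paste0(batches, "_r",
                            sequence(rep(config$replicates_per_batch,
                                         length(rows) /
                                           config$replicates_per_batch)))
  colnames(areas) <- config$metabolite_names
  feature_table(areas, group = groups, batch = batches)
}

#' Append pooled QC runs to a cohort
#'
#' Emulates pooled quality-control injections: each QC run is the
#' per-metabolite linear mean over all non-QC samples, perturbed by
#' log-normal noise of log2 SD `qc_noise_sd`. With `qc_noise_sd = 0` every
#' QC run equals the column means exactly.
#'
#' @param table a non-empty [feature_table()].
#' @param config a [synthetic_config()]; uses `n_qc`, `qc_noise_sd`, `seed`.
#' @return The table with `n_qc` QC rows appended (group `"QC"`, no batch).
#' @export
generate_qc <- function(table, config) {
  stopifnot(inherits(table, "feature_table"), nrow(table$areas) > 0)
  set.seed(config$seed + 1L)
  base <- colMeans(table$areas[table$group != "QC", , drop = FALSE])
  qc <- t(vapply(seq_len(config$n_qc), function(i)
    base * 2^stats::rnorm(length(base), 0, config$qc_noise_sd),
    numeric(length(base))))
  rownames(qc) <- sprintf("QC%02d", seq_len(config$n_qc))
  colnames(qc) <- colnames(table$areas)
  feature_table(rbind(table$areas, qc),
                group = c(table$group, rep("QC", config$n_qc)),
                batch = c(table$batch_id, rep(NA_character_, config$n_qc)))
}
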