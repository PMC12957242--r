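# Shared fixtures, built in code. The default cohort and the end-to-end study
# report are expensive enough to cache across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_config <- function() cached("config", synthetic_config())

default_cohort <- function() {
  cached("cohort", {
    cfg <- default_config()
    generate_qc(generate_cohort(cfg), cfg)
  })
}

default_study_report <- function() {
  cached("report", run_study(study_config(synthetic = default_config()),
                             models = "NN"))
}

# a small, fast cohort for structural tests
small_config <- function(seed = 42) {
  synthetic_config(n_batches = c(CP = 4, CM = 4, CT = 3),
                   replicates_per_batch = 2, n_qc = 5, seed = seed)
}

reference_name <- "3'-hydroxy codonopyrrolidium B"

# batch-mean profiles (38 x screened metabolites) of an independent cohort,
# for the multivariate-model tests
batch_level_data <- function(seed = 7) {
  cached(paste0("batch_data_", seed), {
    cfg <- synthetic_config(seed = seed)
    norm <- percentile_normalize(generate_cohort(cfg))
    sc <- anova_screen(norm)
    X <- log_areas(subset_metabolites(drop_qc(norm),
                                      sc$metabolite[sc$passed]))
    b <- drop_qc(norm)$batch_id
    list(X = apply(X, 2, function(col) tapply(col, b, mean)),
         y = unname(tapply(drop_qc(norm)$group, b, function(g) g[1])))
  })
}

planted_names <- function(cfg = default_config())
  cfg$metabolite_names[cfg$differential_ids]
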