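# Small cohort specs shared across test files. Group parameter centers are
# the package defaults; only the sizes are reduced where a test does not
# need the full 25/25/10 design.

tiny_spec <- function(seed = 1L, ...) {
  cohort_spec(n_control = 4, n_prodromal = 4, n_prevalent = 3,
              global_seed = seed, ...)
}

# Exchangeable null cohort: all groups share the control parameter
# distribution and carry no signature.
null_spec <- function(seed = 1L, n_per = 25, n_ref = 10) {
  cohort_spec(n_control = n_per, n_prodromal = n_per, n_prevalent = n_ref,
              global_seed = seed,
              hr_mean = 65.30, hr_sd = 2.65, morph_delta = 0)
}

# Feature table for a cohort: PSPR features against the prevalent
# references plus HR characteristics, control/prodromal rows only.
cohort_feature_table <- function(spec) {
  run <- run_pipeline(pipeline_config(cohort = spec, cv_k = NULL))
  run$feature_table
}

feature_formula <- function(feature_table) {
  cols <- setdiff(colnames(feature_table), c("subject_id", "label"))
  stats::as.formula(paste("label ~", paste(sprintf("`%s`", cols), collapse = " + ")))
}
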