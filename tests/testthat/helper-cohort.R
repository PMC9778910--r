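# The default-cohort pipeline run is expensive (~2 min: t-SNE on ~2200
# windows dominates); several test files share one cached run.
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (!exists("res", envir = .run_cache)) {
    cfg <- run_config(seed = 1L)
    assign("res", run_all(cfg), envir = .run_cache)
  }
  get("res", envir = .run_cache)
}

default_cohort_raw <- function() {
  if (!exists("cohort", envir = .run_cache)) {
    assign("cohort", generate_cohort(cohort_spec(seed = 1L)), envir = .run_cache)
  }
  get("cohort", envir = .run_cache)
}

small_cohort_spec <- function(seed = 5L) {
  cohort_spec(n_hc = 3, n_pd = 3, trials_per_subject = 2, trial_s = 8,
              seed = seed)
}
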