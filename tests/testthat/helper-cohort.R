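# Memoised standard-cohort pipeline run shared by the heavier tests, so the
# 12-sample simulation + screen is executed once per test session.
.cohort_cache <- new.env(parent = emptyenv())

standard_cohort_run <- function() {
  if (!is.null(.cohort_cache$run)) return(.cohort_cache$run)
  cohort <- cohort_preset(seed = 42)
  simdir <- file.path(tempdir(), "cohort42_sim")
  rundir <- file.path(tempdir(), "cohort42_run")
  sim <- simulate_cohort(cohort, simdir)
  res <- run_pipeline(cohort_pipeline_config(cohort, sim, rundir))
  .cohort_cache$run <- list(cohort = cohort, sim = sim, res = res,
                            simdir = simdir, rundir = rundir)
  .cohort_cache$run
}
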