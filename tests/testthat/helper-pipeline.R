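# Shared end-to-end pipeline fixture for the acceptance tests. The full
# desk-scale run (synthetic cohort -> AE training -> per-fold MLP heads) is
# expensive, so it is computed once per test session and reused by every test
# that needs trained models.

.pipeline_cache <- new.env(parent = emptyenv())

acceptance_pipeline <- function() {
  if (!is.null(.pipeline_cache$run)) return(.pipeline_cache$run)
  spec <- cohort_spec(seed = 11)
  cohort <- sample_cohort(spec)
  dataset <- build_cohort_dataset(cohort, spec)
  plan <- training_plan_desk(seed = 11)
  models <- run_algorithm1(dataset, plan)
  .pipeline_cache$run <- list(spec = spec, cohort = cohort,
                              dataset = dataset, plan = plan,
                              models = models)
  .pipeline_cache$run
}

# small, quickly-trainable autoencoder fixture for unit tests
tiny_ae_fixture <- function(n = 12, seed = 3) {
  cfg <- ae_config(input_shape = c(16, 16, 5),
                   encoder_filters = c(1, 8, 16),
                   decoder_filters = c(8, 5))
  vols <- withr::with_seed(seed, array(stats::runif(16 * 16 * 5 * n),
                                       c(16, 16, 5, n)))
  list(config = cfg, volumes = vols)
}
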