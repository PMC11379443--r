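# Closed-loop protocol mechanics: contact snapping, bound clipping, forced
# termination traces, and reproducibility. (End-to-end success-rate runs with
# trained models live in the acceptance tests.)

# a model set whose regressors predict fixed values and whose AE is tiny
stub_models <- function(pred = c(voltage = 3, frequency = 130, x = 0, y = 0,
                                 z = 1.4)) {
  fx <- tiny_ae_fixture(n = 2)
  ae <- ae_init(fx$config, seed = 50)
  latent_dim <- prod(fx$config$latent_shape)
  make_reg <- function(value) {
    h <- build_head(mlp_config(c(latent_dim, 32, 16, 1),
                               head = "regressor"), seed = 51)
    for (i in seq_along(h$net)) {
      if (h$net[[i]]$type == "linear") {
        h$net[[i]]$params$w[] <- 0
        h$net[[i]]$params$b[] <- 0
      }
    }
    h$normalization <- list(mean = value, sd = 1)
    h
  }
  regs <- lapply(1:2, function(i) lapply(as.list(pred), make_reg))
  list(ae = ae, classifiers = list(), regressors = regs,
       latent_scaling = NULL, target_names = names(pred))
}

test_that("proposed settings snap to the nearest contact with a lower-index tie-break", {
  grid <- cbind(x = rep(0, 4), y = rep(0, 4), z = c(0, 3, 6, 9))
  models <- stub_models(c(voltage = 3, frequency = 130, x = 0, y = 0,
                          z = 1.4))
  latent <- matrix(0, 1, prod(models$ae$config$latent_shape))
  s <- propose_next_setting(latent, models, grid)
  expect_equal(s$contact[3], 0)            # 1.4 is nearest to z = 0
  # exactly on a centroid
  models2 <- stub_models(c(voltage = 3, frequency = 130, x = 0, y = 0,
                           z = 6))
  expect_equal(propose_next_setting(latent, models2, grid)$contact[3], 6)
  # equidistant between z = 0 and z = 3: lower-index centroid wins
  models3 <- stub_models(c(voltage = 3, frequency = 130, x = 0, y = 0,
                           z = 1.5))
  expect_equal(propose_next_setting(latent, models3, grid)$contact[3], 0)
})

test_that("voltage and frequency proposals are clipped to the safety bounds", {
  grid <- cbind(x = 0, y = 0, z = 0)
  models <- stub_models(c(voltage = 40, frequency = 300, x = 0, y = 0,
                          z = 0))
  latent <- matrix(0, 1, prod(models$ae$config$latent_shape))
  s <- propose_next_setting(latent, models, grid,
                            setting_bounds(voltage = c(0.5, 8),
                                           frequency = c(80, 160)))
  expect_equal(s$voltage, 8)
  expect_equal(s$frequency, 160)
})

test_that("stub classifiers force the single-iteration and budget-exhausted traces", {
  spec <- cohort_spec(n_patients = 1, grid_shape = c(16, 16, 5),
                      voxel_size = c(12, 12, 36), blob_sigma = 14,
                      seed = 52)
  patient <- sample_cohort(spec)[[1]]
  sim <- make_patient_simulator(patient, spec, seed = 53)
  models <- stub_models()

  tr1 <- run_loop(sim, models, max_iterations = 5,
                  classify_fn = function(latent) 1.0)
  expect_length(tr1, 1)
  expect_equal(loop_outcome(tr1), "optimal-found")

  tr0 <- run_loop(sim, models, max_iterations = 4,
                  classify_fn = function(latent) 0.0)
  expect_length(tr0, 4)
  expect_equal(loop_outcome(tr0), "budget-exhausted")
  expect_true(tr0[[4]]$terminated)
  # every visited setting lies inside bounds and on the contact grid
  for (st in tr0) {
    expect_gte(st$setting$voltage, 0)
    expect_true(any(apply(sim$contact_grid, 1, function(g) {
      all(abs(g - st$setting$contact) < 1e-9)
    })))
  }

  # traces are reproducible
  tr0b <- run_loop(sim, models, max_iterations = 4,
                   classify_fn = function(latent) 0.0)
  expect_identical(tr0, tr0b)
})

test_that("the simulator's initial probe is sub-therapeutic at the planned contact", {
  spec <- cohort_spec(n_patients = 1, grid_shape = c(16, 16, 5),
                      voxel_size = c(12, 12, 36), blob_sigma = 14,
                      seed = 54)
  patient <- sample_cohort(spec)[[1]]
  sim <- make_patient_simulator(patient, spec, seed = 55)
  init <- sim$initial_setting
  expect_lt(init$voltage, patient$optimal$voltage)
  expect_equal(init$contact, patient$optimal$contact)
  expect_false(init$is_optimal)
})
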