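# Synthetic cohort generator: paradigm arithmetic, cohort structure and
# determinism, the voltage-amplitude law, and the left-right flip.

test_that("paradigm arithmetic gives the expected volume and block counts", {
  par <- make_paradigm(360, 30, 3)
  expect_equal(par$n_volumes, 120L)
  box <- paradigm_boxcar(par)
  runs <- rle(box)
  expect_equal(sum(runs$values == 1), 6)           # 6 ON blocks
  expect_true(all(runs$lengths[runs$values == 1] == 10))
  expect_equal(box[1], 0)                          # OFF-first start phase

  par1 <- make_paradigm(60, 30, 3)
  expect_equal(par1$n_volumes, 20L)
  expect_equal(sum(rle(paradigm_boxcar(par1))$values == 1), 1)

  expect_error(make_paradigm(360, 25, 3), "cycles")
  expect_error(make_paradigm(360, 30, 7), "repetition times")
})

test_that("cohort sampling respects the per-patient setting range and is deterministic", {
  spec <- cohort_spec(n_patients = 39, seed = 7)
  coh <- sample_cohort(spec)
  expect_length(coh, 39)
  counts <- vapply(coh, function(p) length(p$settings), 0L)
  expect_true(all(counts >= 1 & counts <= 5))
  expect_true(sum(counts) >= 39 && sum(counts) <= 195)
  n_opt <- vapply(coh, function(p) {
    sum(vapply(p$settings, function(s) s$is_optimal, TRUE))
  }, 0L)
  expect_true(all(n_opt == 1))
  # invariants on every setting
  for (p in coh) for (s in p$settings) {
    expect_gte(s$voltage, 0)
    expect_gte(s$frequency, spec$freq_band[1])
    expect_lte(s$frequency, spec$freq_band[2])
    expect_gt(s$pulse_width, 0)
    expect_true(all(is.finite(s$contact)))
  }
  expect_identical(coh, sample_cohort(spec))       # pure function of seed

  solo <- sample_cohort(cohort_spec(n_patients = 1,
                                    maps_per_patient = c(1, 1), seed = 2))
  expect_length(solo[[1]]$settings, 1)
  expect_true(solo[[1]]$settings[[1]]$is_optimal)
})

test_that("rendered maps follow the voltage-amplitude law", {
  spec <- cohort_spec(n_patients = 2, seed = 5)
  p <- sample_cohort(spec)[[1]]
  opt <- p$optimal
  m_opt <- render_response_map(p, opt, spec, noise_sd = 0)
  # optimal, noiseless: motor peak magnitude equals the patient's base
  # amplitude exactly
  expect_equal(max(abs(m_opt$data)), p$topography$base_amplitude,
               tolerance = 1e-6)

  sub_of <- function(f) {
    stim_setting(f * opt$voltage, opt$frequency, spec$pulse_width,
                 opt$contact)
  }
  m50 <- render_response_map(p, sub_of(0.5), spec, noise_sd = 0)
  m80 <- render_response_map(p, sub_of(0.8), spec, noise_sd = 0)
  expect_lt(max(abs(m50$data)), max(abs(m80$data)))  # monotone below v_opt
  expect_lt(max(abs(m80$data)), max(abs(m_opt$data)))
  # preserved topography: sign pattern at the motor peaks unchanged
  peak <- which.min(m_opt$data)
  expect_lt(m50$data[peak], 0)

  # non-motor recruitment only above the optimal voltage
  nm <- p$topography$nonmotor[1, ]
  axes <- dbsfmri:::grid_axes(spec$grid_shape, spec$voxel_size)
  vidx <- vapply(1:3, function(a) {
    which.min(abs(axes[[a]] - as.numeric(nm[c("x", "y", "z")])[a]))
  }, 0L)
  expect_equal(m50$data[vidx[1], vidx[2], vidx[3]], 0, tolerance = 1e-6)
  m150 <- render_response_map(p, sub_of(1.5), spec, noise_sd = 0)
  expect_gt(m150$data[vidx[1], vidx[2], vidx[3]], 1)
})

test_that("left-right flip is an involution and an isometry", {
  spec <- cohort_spec(n_patients = 1, seed = 9)
  p <- sample_cohort(spec)[[1]]
  m <- render_response_map(p, p$optimal, spec, seed = 1)
  f <- flip_lr(m)
  expect_true(f$flipped)
  expect_equal(flip_lr(f)$data, m$data)                     # involution
  expect_equal(sort(as.numeric(f$data)), sort(as.numeric(m$data)))  # isometry
  # delta volume at LR index j moves to W - 1 - j (0-based)
  W <- 8
  delta <- response_map(array(0, c(W, 4, 4)))
  delta$data[3, 2, 2] <- 1
  fd <- flip_lr(delta)
  idx <- which(fd$data != 0, arr.ind = TRUE)
  expect_equal(unname(idx[1, 1]), W - 3 + 1)
  # a symmetric map is unchanged
  sym <- response_map(array(1, c(6, 4, 4)))
  expect_equal(flip_lr(sym)$data, sym$data)
})

test_that("BOLD forward model round-trips through the GLM exactly", {
  par <- make_paradigm(120, 30, 3)
  m <- response_map(array(c(2.5, rep(0, 7)), c(2, 2, 2)))
  bs <- render_bold_series(m, par, noise_sd = 0)
  # constant baseline when the map is empty
  bs0 <- render_bold_series(response_map(array(0, c(2, 2, 2))), par,
                            noise_sd = 0)
  expect_equal(max(bs0$data), min(bs0$data))
  # noiseless single-voxel effect: OLS recovers beta to machine precision
  design <- build_design_matrix(par)
  X <- design$matrix
  y <- bs$data[1, 1, 1, ]
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(beta[1], 2.5, tolerance = 1e-8)
})

test_that("an injected 3 mm motion spike is censored exactly", {
  par <- make_paradigm(180, 30, 3)
  m <- response_map(array(1, c(2, 2, 2)))
  mot <- make_motion_trace(par$n_volumes, spike_volumes = 40, spike_mm = 3)
  bs <- render_bold_series(m, par, noise_sd = 0, motion = mot)
  cen <- censor_volumes(bs)
  expect_equal(cen$removed, 40L)
  expect_equal(dim(cen$series$data)[4], par$n_volumes - 1)
})
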