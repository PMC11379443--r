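# GLM mapping: HRF shape, design construction, censoring, smoothing,
# voxelwise OLS against the normal-equations oracle, and preprocessing.

test_that("double-gamma HRF has the canonical shape", {
  tg <- seq(0, 32, by = 0.1)
  h <- double_gamma_hrf(tg)
  expect_equal(h[1], 0)
  peak_t <- tg[which.max(h)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 6)
  # undershoot vanishes as the ratio grows
  h_nound <- double_gamma_hrf(tg, hrf_params(ratio = 1e9))
  expect_true(all(h_nound >= 0))
  expect_error(hrf_params(peak_dispersion = -1))
})

test_that("design matrix has the documented layout and degeneracy handling", {
  par <- make_paradigm(360, 30, 3)
  mot <- make_motion_trace(120, jitter_sd = 0.05, seed = 1)
  des <- build_design_matrix(par, mot)
  expect_equal(dim(des$matrix), c(120, 8))   # task + 6 motion + intercept
  expect_equal(des$column_labels[1], "task")
  expect_equal(des$column_labels[8], "intercept")
  expect_equal(des$contrast, c(1, rep(0, 7)))
  # regressor is causal: zero throughout the first OFF block
  expect_true(all(abs(des$matrix[1:10, "task"]) < 1e-12))

  # all-zero motion columns are dropped to preserve rank
  des0 <- build_design_matrix(par, matrix(0, 120, 6))
  expect_equal(ncol(des0$matrix), 2)
  expect_length(des0$dropped_columns, 6)

  # collinear columns are named in the error
  dup <- cbind(mot[, 1], mot[, 1], mot[, 2:5])
  colnames(dup) <- c("a", "b", "c", "d", "e", "f")
  expect_error(build_design_matrix(par, dup), "collinear")
  expect_error(build_design_matrix(par, mot[1:50, ]), "rows")
})

test_that("voxelwise t values match the normal-equations oracle", {
  par <- make_paradigm(60, 30, 3)
  withr::with_seed(20, {
    for (rep in 1:25) {
      m <- response_map(array(rnorm(8), c(2, 2, 2)))
      mot <- make_motion_trace(20, jitter_sd = 0.05)
      bs <- render_bold_series(m, par, noise_sd = 1, motion = mot)
      des <- build_design_matrix(par, mot)
      tm <- fit_glm_tmap(bs, des)
      v <- sample(8, 1)
      vi <- arrayInd(v, c(2, 2, 2))
      y <- bs$data[vi[1], vi[2], vi[3], ]
      expect_equal(tm$data[v], oracle_glm_t(y, des$matrix, des$contrast),
                   tolerance = 1e-8)
      expect_equal(tm$dof, 20 - ncol(des$matrix))
    }
  })
})

test_that("t statistics are invariant to affine rescaling of the signal", {
  par <- make_paradigm(240, 30, 3)
  withr::with_seed(21, {
    m <- response_map(array(rnorm(8), c(2, 2, 2)))
    bs <- render_bold_series(m, par, noise_sd = 1, seed = 5)
  })
  des <- build_design_matrix(par)
  t1 <- fit_glm_tmap(bs, des)$data
  bs$data <- 3.7 * bs$data + 11
  t2 <- fit_glm_tmap(bs, des)$data
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("noiseless signal takes the capped-t path with the correct sign", {
  par <- make_paradigm(60, 30, 3)
  m <- response_map(array(2, c(2, 2, 1)))
  bs <- render_bold_series(m, par, noise_sd = 0)
  expect_warning(tm <- fit_glm_tmap(bs, cap = 1e6), "zero residual")
  expect_true(all(tm$data == 1e6))
})

test_that("null simulation holds the nominal type-I rate", {
  par <- make_paradigm(360, 30, 3)
  des <- build_design_matrix(par)
  n_vox <- 4000
  nv <- par$n_volumes
  bs <- withr::with_seed(22, {
    bold_series(array(rnorm(n_vox * nv), c(n_vox, 1, 1, nv)), par)
  })
  tm <- fit_glm_tmap(bs, des)
  crit <- qt(0.975, tm$dof)
  rate <- mean(abs(tm$data) > crit)
  # mean t within 3 standard errors of zero
  expect_lt(abs(mean(tm$data)), 3 * sd(tm$data) / sqrt(n_vox))
  expect_lt(abs(rate - 0.05), 0.012)
})

test_that("motion-design correlation flags degenerate columns", {
  par <- make_paradigm(360, 30, 3)
  task <- task_regressor(par)
  mot <- cbind(2 * task, matrix(0, 120, 5))
  res <- motion_design_correlation(mot, task)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_true(all(res$r[-1] == 0))
  expect_true(all(res$degenerate[-1]))
  withr::with_seed(23, {
    rand <- matrix(rnorm(120 * 6), 120, 6)
  })
  res2 <- motion_design_correlation(rand, task)
  expect_true(all(abs(res2$r) < 0.35))
})

test_that("censoring commutes with design-row deletion", {
  par <- make_paradigm(360, 30, 3)
  mot <- make_motion_trace(120, jitter_sd = 0.1, spike_volumes = c(17, 63),
                           seed = 2)
  m <- response_map(array(1, c(2, 2, 1)))
  bs <- render_bold_series(m, par, noise_sd = 0.3, motion = mot, seed = 3)
  cen <- censor_volumes(bs)
  expect_equal(cen$removed, c(17L, 63L))
  full <- build_design_matrix(par, mot)
  kept <- build_design_matrix(par, cen$series$motion,
                              keep_volumes = cen$series$keep_volumes)
  expect_equal(kept$matrix, full$matrix[-c(17, 63), ], tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants and matches the kernel peak", {
  const <- array(3, c(9, 9, 9))
  expect_equal(smooth_gaussian(const, 6, c(2, 2, 2)), const,
               tolerance = 1e-10)
  v <- array(0, c(11, 11, 11))
  v[6, 6, 6] <- 1
  expect_equal(smooth_gaussian(v, 0, c(2, 2, 2)), v)   # fwhm 0 is identity
  sv <- smooth_gaussian(v, 6, c(2, 2, 2))
  # closed-form peak of the normalised separable kernel
  sigma <- 6 / (2 * 2 * sqrt(2 * log(2)))
  taps <- exp(-(-ceiling(4 * sigma):ceiling(4 * sigma))^2 / (2 * sigma^2))
  expect_equal(sv[6, 6, 6], (max(taps) / sum(taps))^3, tolerance = 1e-12)
})

test_that("autoencoder preprocessing resizes and min-max normalizes", {
  withr::with_seed(24, {
    m <- response_map(array(runif(20 * 22 * 24, -5, 5), c(20, 22, 24)))
  })
  out <- preprocess_for_ae(m, c(16, 16, 12))
  expect_equal(dim(out), c(16, 16, 12))
  expect_equal(range(out), c(0, 1))
  # already at target: extremes map to 0/1 exactly
  m2 <- response_map(array(seq(-5, 5, length.out = 8 * 8 * 4), c(8, 8, 4)))
  out2 <- preprocess_for_ae(m2, c(8, 8, 4))
  expect_equal(min(out2), 0)
  expect_equal(max(out2), 1)
  # constant maps take the declared midpoint value
  expect_equal(preprocess_for_ae(response_map(array(2, c(4, 4, 4))),
                                 c(4, 4, 4)),
               array(0.5, c(4, 4, 4)))
  # full-size grid contract
  big <- array(0, c(91, 91, 109))
  big[40, 40, 50] <- 1
  expect_equal(dim(preprocess_for_ae(response_map(big), c(96, 96, 91))),
               c(96, 96, 91))
})
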