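# Block-design GLM t-statistic mapping: paradigm, double-gamma HRF, design
# matrix with motion regressors, motion censoring, Gaussian smoothing,
# voxelwise OLS t-maps, and the motion/design correlation check.

#' DBS ON/OFF block paradigm
#'
#' @param total_s total scan duration in seconds; must be a whole number of
#'   ON+OFF cycles and of repetition times.
#' @param cycle_s duration in seconds of one ON (and one OFF) block.
#' @param tr repetition time in seconds.
#' @param start_on if `TRUE` the first block is stimulation-ON (default OFF).
#' @return object of class `dbs_paradigm` with the volume count and schedule.
#' @export
make_paradigm <- function(total_s = 360, cycle_s = 30, tr = 3,
                          start_on = FALSE) {
  stopifnot(total_s > 0, cycle_s > 0, tr > 0)
  if (total_s %% (2 * cycle_s) != 0) {
    stop("total duration (", total_s, " s) is not a whole number of ",
         2 * cycle_s, " s ON/OFF cycles")
  }
  if (abs(total_s / tr - round(total_s / tr)) > 1e-9) {
    stop("total duration (", total_s, " s) is not a whole number of ",
         "repetition times (tr = ", tr, " s)")
  }
  structure(list(total_s = total_s, cycle_on = cycle_s, cycle_off = cycle_s,
                 tr = tr, start_on = start_on,
                 n_volumes = as.integer(round(total_s / tr))),
            class = "dbs_paradigm")
}

#' Stimulation boxcar of a paradigm
#'
#' @param paradigm a [make_paradigm()] object.
#' @param times time points (s) to evaluate at; defaults to volume onsets.
#' @return 0/1 vector, 1 during stimulation-ON blocks.
#' @export
paradigm_boxcar <- function(paradigm, times = NULL) {
  if (is.null(times)) times <- (seq_len(paradigm$n_volumes) - 1) * paradigm$tr
  phase <- floor(times / paradigm$cycle_on) %% 2
  as.numeric(if (paradigm$start_on) phase == 0 else phase == 1)
}

#' Canonical double-gamma HRF parameters
#'
#' Defaults are the canonical values: response peaking ~5 s after stimulus
#' with a late undershoot at one sixth the peak amplitude.
#'
#' @param peak_delay,undershoot_delay delays (s) of response and undershoot.
#' @param peak_dispersion,undershoot_dispersion dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param kernel_length kernel support in seconds.
#' @return object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       ratio = 6, kernel_length = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_dispersion > 0,
            undershoot_dispersion > 0, ratio > 0, kernel_length > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, kernel_length = kernel_length),
            class = "hrf_params")
}

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak) - g(t; undershoot) / ratio`, where `g` is a gamma
#' density with shape `delay / dispersion` and scale `dispersion`.
#'
#' @param t non-negative, ascending time grid (s).
#' @param params an [hrf_params()] object.
#' @return response values at `t`.
#' @export
double_gamma_hrf <- function(t, params = hrf_params()) {
  stopifnot(all(t >= 0), !is.unsorted(t))
  stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay /
                    params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) / params$ratio
}

#' Stimulation regressor: boxcar convolved with the HRF
#'
#' @inheritParams paradigm_boxcar
#' @param hrf an [hrf_params()] object.
#' @param dt convolution grid step (s).
#' @return regressor values at `times` (default: volume onsets).
#' @export
task_regressor <- function(paradigm, hrf = hrf_params(), times = NULL,
                           dt = 0.1) {
  if (is.null(times)) times <- (seq_len(paradigm$n_volumes) - 1) * paradigm$tr
  tfine <- seq(0, paradigm$total_s - dt, by = dt)
  box <- paradigm_boxcar(paradigm, tfine)
  h <- double_gamma_hrf(seq(0, hrf$kernel_length, by = dt), hrf)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tfine)] * dt
  conv[pmin(round(times / dt), length(tfine) - 1) + 1]
}

#' Build the GLM design matrix
#'
#' Column order: task regressor (boxcar x HRF), six motion regressors,
#' intercept last. The contrast selects the task column. All-zero motion
#' columns are dropped to preserve full rank.
#'
#' @inheritParams task_regressor
#' @param motion matrix (volumes x 6) of motion parameters (x/y/z translation
#'   in mm, yaw/pitch/roll in degrees), or `NULL` for none.
#' @param keep_volumes optional indices of retained (uncensored) volumes; the
#'   task regressor is evaluated at their original acquisition times.
#' @return object of class `glm_design` with elements `matrix`, `contrast`,
#'   `column_labels`, `dropped_columns`.
#' @export
build_design_matrix <- function(paradigm, motion = NULL, hrf = hrf_params(),
                                keep_volumes = NULL, dt = 0.1) {
  times <- (seq_len(paradigm$n_volumes) - 1) * paradigm$tr
  if (!is.null(keep_volumes)) times <- times[keep_volumes]
  task <- task_regressor(paradigm, hrf, times = times, dt = dt)
  X <- cbind(task = task)
  dropped <- character(0)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != length(times)) {
      stop("motion trace has ", nrow(motion), " rows but ", length(times),
           " volumes are modelled")
    }
    if (is.null(colnames(motion))) {
      colnames(motion) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")[
        seq_len(ncol(motion))]
    }
    zero <- apply(motion, 2, function(col) all(col == 0))
    dropped <- colnames(motion)[zero]
    X <- cbind(X, motion[, !zero, drop = FALSE])
  }
  X <- cbind(X, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  contrast <- c(1, rep(0, ncol(X) - 1))
  structure(list(matrix = X, contrast = contrast,
                 column_labels = colnames(X), dropped_columns = dropped),
            class = "glm_design")
}

#' A 4-d BOLD series
#'
#' @param data 4-d array `(x, y, z, volumes)`.
#' @param paradigm the acquisition [make_paradigm()].
#' @param motion volumes x 6 motion matrix.
#' @param voxel_size voxel edge lengths (mm).
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, paradigm, motion = NULL,
                        voxel_size = c(2, 2, 2)) {
  stopifnot(length(dim(data)) == 4)
  nvol <- dim(data)[4]
  if (nvol != paradigm$n_volumes) {
    stop("series has ", nvol, " volumes; paradigm expects ",
         paradigm$n_volumes)
  }
  if (is.null(motion)) motion <- matrix(0, nvol, 6)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == nvol, ncol(motion) == 6)
  if (is.null(colnames(motion))) {
    colnames(motion) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")
  }
  structure(list(data = data, paradigm = paradigm, motion = motion,
                 voxel_size = voxel_size,
                 keep_volumes = seq_len(nvol)),
            class = "bold_series")
}

#' Simulate the BOLD series a response map generates under a paradigm
#'
#' Forward model inverted by the GLM: each voxel time course is
#' `baseline + map_value * regressor(t) + noise`, with the regressor the
#' ON/OFF boxcar convolved with the HRF.
#'
#' @param map a [response_map()] (its values act as the voxelwise effect
#'   size).
#' @param paradigm a [make_paradigm()].
#' @param hrf an [hrf_params()].
#' @param noise_sd temporal noise sd.
#' @param motion optional volumes x 6 motion matrix (see
#'   [make_motion_trace()]).
#' @param baseline constant signal offset.
#' @param seed optional RNG seed for the noise.
#' @return a [bold_series()].
#' @export
render_bold_series <- function(map, paradigm, hrf = hrf_params(),
                               noise_sd = 0, motion = NULL, baseline = 100,
                               seed = NULL) {
  stopifnot(inherits(map, "response_map"))
  reg <- task_regressor(paradigm, hrf)
  d <- dim(map$data)
  nvol <- paradigm$n_volumes
  arr <- outer(as.numeric(map$data), reg) + baseline
  if (noise_sd > 0) {
    draw <- function() stats::rnorm(length(arr), sd = noise_sd)
    arr <- arr + if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  dim(arr) <- c(d, nvol)
  bold_series(arr, paradigm, motion, map$voxel_size)
}

#' Construct a motion trace, optionally with injected spikes
#'
#' @param n_volumes number of volumes.
#' @param jitter_sd sd of small random motion on all six axes (mm / degrees).
#' @param spike_volumes volume indices receiving a translation spike.
#' @param spike_mm spike magnitude (mm, applied to the x translation).
#' @param seed optional RNG seed.
#' @return volumes x 6 motion matrix.
#' @export
make_motion_trace <- function(n_volumes, jitter_sd = 0,
                              spike_volumes = integer(0), spike_mm = 3,
                              seed = NULL) {
  gen <- function() {
    m <- matrix(stats::rnorm(n_volumes * 6, sd = jitter_sd), n_volumes, 6)
    colnames(m) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")
    m[spike_volumes, "tx"] <- spike_mm
    m
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Censor high-motion volumes
#'
#' Removes volumes whose translational displacement (Euclidean norm of the
#' x/y/z translations) exceeds the threshold, from the data and the motion
#' trace alike; the retained-volume indices are kept so the design matrix can
#' be evaluated at the surviving acquisition times.
#'
#' @param series a [bold_series()].
#' @param threshold_mm censoring threshold (default 2 mm).
#' @return list with `series` (censored) and `removed` (indices).
#' @export
censor_volumes <- function(series, threshold_mm = 2) {
  stopifnot(inherits(series, "bold_series"), threshold_mm > 0)
  disp <- sqrt(rowSums(series$motion[, 1:3, drop = FALSE]^2))
  removed <- which(disp > threshold_mm)
  if (length(removed) == dim(series$data)[4]) {
    stop("all volumes exceed the ", threshold_mm, " mm motion threshold")
  }
  if (length(removed)) {
    keep <- setdiff(seq_len(dim(series$data)[4]), removed)
    series$data <- series$data[, , , keep, drop = FALSE]
    series$motion <- series$motion[keep, , drop = FALSE]
    series$keep_volumes <- series$keep_volumes[keep]
  }
  list(series = series, removed = removed)
}

# dense 1-d smoothing matrix with nearest-neighbour boundary handling;
# kernel normalised so constants are preserved exactly
gaussian_smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-r:r), 1L), n)
    for (t in seq_along(idx)) K[i, idx[t]] <- K[i, idx[t]] + w[t]
  }
  K
}

apply_along_axis <- function(arr, axis, K) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  dim(x) <- c(d[axis], prod(d[-axis]))
  x <- K %*% x
  dnew <- d
  dnew[axis] <- nrow(K)
  dim(x) <- dnew[perm]
  aperm(x, order(perm))
}

#' Spatial Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis
#' (in voxels, accounting for anisotropic voxel size); nearest-neighbour
#' boundary handling; `fwhm = 0` is the identity.
#'
#' @param volume 3-d array.
#' @param fwhm_mm full width at half maximum (mm), scalar or per axis.
#' @param voxel_size_mm voxel edge lengths (mm).
#' @return smoothed array of the same shape.
#' @export
smooth_gaussian <- function(volume, fwhm_mm = 6, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(length(dim(volume)) == 3, all(fwhm_mm >= 0))
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  for (a in 1:3) {
    sigma_vox <- fwhm_mm[a] / (voxel_size_mm[a] * 2 * sqrt(2 * log(2)))
    if (sigma_vox > 0) {
      volume <- apply_along_axis(volume, a,
        gaussian_smoothing_matrix(dim(volume)[a], sigma_vox))
    }
  }
  volume
}

#' A 3-d t-statistic response map
#'
#' @param data 3-d array of t values.
#' @param voxel_size voxel edge lengths (mm).
#' @param space one of `"native"`, `"common"`, `"resized-normalized"`.
#' @param flipped whether the map has been left-right mirrored.
#' @param dof residual degrees of freedom of the GLM fit (`NA` for synthetic
#'   maps rendered directly).
#' @return object of class `response_map`.
#' @export
response_map <- function(data, voxel_size = c(2, 2, 2), space = "common",
                         flipped = FALSE, dof = NA_real_) {
  stopifnot(length(dim(data)) == 3, all(is.finite(data)))
  structure(list(data = data, grid_shape = dim(data),
                 voxel_size = voxel_size, space = space,
                 flipped = flipped, dof = dof),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat("DBS-fMRI response map ", paste(x$grid_shape, collapse = "x"),
      " (", x$space, if (x$flipped) ", flipped" else "",
      "), t range [", sprintf("%.2f", min(x$data)), ", ",
      sprintf("%.2f", max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' Voxelwise GLM t-map
#'
#' Ordinary least squares per voxel: `beta = (X'X)^-1 X'y`,
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with `sigma2 = RSS / dof`,
#' `dof = volumes - p`. Voxels with zero residual variance receive `+-cap`
#' (sign of the contrast estimate) with a warning; an exactly zero estimate
#' gives `t = 0`.
#'
#' @param series a [bold_series()] (already censored/smoothed as desired).
#' @param design a [build_design_matrix()] result whose rows match the series
#'   volumes; built from the series paradigm and motion when `NULL`.
#' @param hrf an [hrf_params()] used when building the design.
#' @param cap t value substituted for zero-residual voxels.
#' @return a [response_map()] of t values carrying `dof`.
#' @export
fit_glm_tmap <- function(series, design = NULL, hrf = hrf_params(),
                         cap = 1e6) {
  stopifnot(inherits(series, "bold_series"))
  if (is.null(design)) {
    design <- build_design_matrix(series$paradigm, series$motion, hrf,
                                  keep_volumes = series$keep_volumes)
  }
  X <- design$matrix
  nvol <- dim(series$data)[4]
  if (nrow(X) != nvol) {
    stop("design has ", nrow(X), " rows but the series has ", nvol,
         " volumes")
  }
  p <- ncol(X)
  dof <- nvol - p
  if (dof <= 0) stop("non-positive degrees of freedom (", dof, ")")
  d <- dim(series$data)[1:3]
  Y <- matrix(aperm(series$data, c(4, 1, 2, 3)), nrow = nvol)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / dof
  cb <- as.numeric(design$contrast %*% beta)
  cvc <- as.numeric(design$contrast %*% xtx_inv %*% design$contrast)
  # residual variance indistinguishable from zero at double precision
  # (relative to the signal scale) takes the capped path
  zero_var <- sigma2 <= 1e-20 * pmax(colMeans(Y^2), .Machine$double.xmin)
  se <- sqrt(sigma2 * cvc)
  tval <- ifelse(zero_var, sign(cb) * cap, cb / se)
  if (any(zero_var)) {
    warning(sum(zero_var), " voxel(s) with zero residual variance; ",
            "t capped at ", cap)
  }
  response_map(array(tval, d), series$voxel_size, space = "common",
               dof = dof)
}

#' Correlation of motion parameters with the task regressor
#'
#' @param motion volumes x 6 motion matrix.
#' @param task task regressor (or a [glm_design] whose first column is used).
#' @return data frame with columns `parameter`, `r`, `degenerate`; constant
#'   motion columns are reported as `r = 0` with `degenerate = TRUE`.
#' @export
motion_design_correlation <- function(motion, task) {
  if (inherits(task, "glm_design")) task <- task$matrix[, 1]
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == length(task))
  res <- lapply(seq_len(ncol(motion)), function(j) {
    col <- motion[, j]
    degenerate <- stats::sd(col) == 0
    data.frame(parameter = colnames(motion)[j] %||% paste0("m", j),
               r = if (degenerate) 0 else stats::cor(col, task),
               degenerate = degenerate)
  })
  do.call(rbind, res)
}

#' Full preprocessing + GLM chain for one BOLD series
#'
#' Censors volumes with > `censor_threshold` mm translational displacement,
#' smooths every remaining volume with a Gaussian kernel, builds the design
#' matrix at the surviving acquisition times (motion regressors included),
#' and fits the voxelwise GLM.
#'
#' @inheritParams fit_glm_tmap
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param censor_threshold censoring threshold in mm.
#' @return list with `map` (the t [response_map()]), `removed` volume
#'   indices, and `motion_correlation` (see [motion_design_correlation()]).
#' @export
bold_to_tmap <- function(series, hrf = hrf_params(), fwhm_mm = 6,
                         censor_threshold = 2, cap = 1e6) {
  cen <- censor_volumes(series, censor_threshold)
  series <- cen$series
  if (any(fwhm_mm > 0)) {
    for (t in seq_len(dim(series$data)[4])) {
      series$data[, , , t] <- smooth_gaussian(series$data[, , , t], fwhm_mm,
                                              series$voxel_size)
    }
  }
  design <- build_design_matrix(series$paradigm, series$motion, hrf,
                                keep_volumes = series$keep_volumes)
  map <- fit_glm_tmap(series, design, cap = cap)
  list(map = map, removed = cen$removed,
       motion_correlation = motion_design_correlation(series$motion,
                                                      design))
}

# 1-d linear interpolation matrix (align-corners), rows sum to 1
interp_matrix <- function(n_in, n_out) {
  K <- matrix(0, n_out, n_in)
  if (n_in == 1) { K[, 1] <- 1; return(K) }
  pos <- if (n_out == 1) (n_in + 1) / 2 else
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  lo <- pmin(floor(pos), n_in - 1)
  frac <- pos - lo
  for (i in seq_len(n_out)) {
    K[i, lo[i]] <- 1 - frac[i]
    K[i, lo[i] + 1] <- frac[i]
  }
  K
}

#' Trilinear resampling of a volume
#'
#' @param arr 3-d array.
#' @param out_dim target dimensions.
#' @return resampled array.
#' @export
resize_trilinear <- function(arr, out_dim) {
  stopifnot(length(dim(arr)) == 3, length(out_dim) == 3)
  for (a in 1:3) {
    if (dim(arr)[a] != out_dim[a]) {
      arr <- apply_along_axis(arr, a, interp_matrix(dim(arr)[a], out_dim[a]))
    }
  }
  arr
}

#' Resize and normalize a response map for the autoencoder
#'
#' Trilinear resampling of the in-plane axes and slice axis to the network
#' input shape, followed by per-map min-max scaling to `[0, 1]`. A constant
#' map is mapped to 0.5 everywhere (the scaling is undefined; the midpoint
#' keeps it inside the network's expected range).
#'
#' @param map a [response_map()] or 3-d array `(x, y, z)`.
#' @param target_shape output shape `(H, W, slices)`; the slice (z) axis is
#'   the network channel axis.
#' @return 3-d array in `[0, 1]` of shape `target_shape`.
#' @export
preprocess_for_ae <- function(map, target_shape = c(96, 96, 91)) {
  arr <- if (inherits(map, "response_map")) map$data else map
  stopifnot(all(is.finite(arr)))
  arr <- resize_trilinear(arr, target_shape)
  rng <- range(arr)
  if (rng[1] == rng[2]) return(array(0.5, dim(arr)))
  (arr - rng[1]) / (rng[2] - rng[1])
}
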