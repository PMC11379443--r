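# Synthetic DBS-fMRI cohort generator.
#
# Emulates the statistical structure of a cohort of Parkinson's-disease
# patients under left-sided deep brain stimulation: every patient has one
# clinically optimal stimulation setting and up to four tolerated non-optimal
# settings (sub-/supra-therapeutic voltage, displaced contact, shifted
# frequency). The rendered response maps follow the known qualitative
# topography: deactivation of ipsilateral motor cortex and contralateral
# cerebellum with thalamic activation at optimal settings; the same topography
# at reduced magnitude sub-therapeutically; stronger responses plus
# recruitment of non-motor (inferior frontal, occipital) regions
# supra-therapeutically.

# canonical region centroids (mm, common space), left-sided stimulation
.motor_rois <- data.frame(
  region = c("ipsilateral_motor_cortex", "contralateral_cerebellum",
             "ipsilateral_thalamus"),
  x = c(-35, 22, -12), y = c(-20, -58, -18), z = c(55, -40, 8),
  sign = c(-1, -1, 1))
.nonmotor_rois <- data.frame(
  region = c("inferior_frontal", "occipital"),
  x = c(-45, 8), y = c(30, -85), z = c(8, 4),
  sign = c(1, 1))
.lead_base <- c(-12, -13, -12)

#' Cohort specification for the synthetic DBS-fMRI generator
#'
#' Default values are the study conditions the generator emulates: 39 patients
#' contributing 1-5 response maps each (one optimal setting per patient),
#' voltages 2-4 V, stimulation frequency inside the 80-160 Hz band, pulse
#' width held constant at 60 microseconds, and a quadripolar lead with 3 mm
#' contact spacing.
#'
#' @param n_patients number of synthetic patients.
#' @param maps_per_patient integer range `c(min, max)` of maps per patient.
#' @param grid_shape voxel grid `c(nx, ny, nz)` maps are rendered on.
#' @param voxel_size voxel edge lengths in mm per axis.
#' @param noise_sd standard deviation of iid Gaussian voxel noise (t units).
#' @param base_amplitude peak motor-region |t| value at the optimal setting.
#' @param blob_sigma Gaussian width (mm) of each response focus.
#' @param sub_range,supra_range ranges of the voltage ratio `v / v_opt` used
#'   for sub- and supra-therapeutic settings.
#' @param supra_slope slope (> 1) of the amplitude law above the optimal
#'   voltage: `a = base * (1 + supra_slope * (v/v_opt - 1))`.
#' @param nonmotor_gain scales the supra-therapeutic non-motor amplitude,
#'   `base * nonmotor_gain * (v/v_opt - 1)`.
#' @param voltage_range range (V) optimal voltages are drawn from.
#' @param freq_band admissible stimulation frequency band (Hz).
#' @param opt_freq_range range (Hz) optimal frequencies are drawn from.
#' @param pulse_width pulse width in microseconds, constant across the cohort.
#' @param contact_spacing centre-to-centre contact spacing (mm) along the lead.
#' @param n_contacts number of contacts on the lead.
#' @param contact_sigma distance decay (mm) of the motor amplitude when a
#'   non-optimal contact is stimulated.
#' @param contact_coupling mm of motor-centroid z-shift per mm of stimulated
#'   contact offset from the lead midpoint (makes contact depth observable in
#'   the map, the analogue of the stimulated fiber population moving with the
#'   active contact).
#' @param extent_exponent exponent of the activation-extent law
#'   `sigma_eff = blob_sigma * (v / extent_ref_voltage)^extent_exponent`
#'   (volume of activated tissue grows with voltage).
#' @param extent_ref_voltage reference voltage (V) of the extent and
#'   amplitude laws.
#' @param amp_voltage_exponent exponent of the optional patient amplitude
#'   law `base_patient = base_amplitude * (v_opt / extent_ref_voltage)^q`
#'   (default 0: a common base amplitude; positive values make patients
#'   optimized at higher voltages respond more strongly, at the cost of
#'   confounding the optimal/non-optimal amplitude contrast across
#'   patients).
#' @param anat_sd per-axis sd (mm) of the patient anatomical offset applied to
#'   region centroids and lead position alike.
#' @param seed default RNG seed for [sample_cohort()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 39, maps_per_patient = c(1, 5),
                        grid_shape = c(48, 48, 91), voxel_size = c(4, 4, 2),
                        noise_sd = 0.5, base_amplitude = 7.5, blob_sigma = 7,
                        sub_range = c(0.4, 0.7), supra_range = c(1.3, 1.8),
                        supra_slope = 1.5, nonmotor_gain = 1.5,
                        voltage_range = c(2, 4), freq_band = c(80, 160),
                        opt_freq_range = c(110, 160), pulse_width = 60,
                        contact_spacing = 3, n_contacts = 4,
                        contact_sigma = 3, contact_coupling = 2,
                        extent_exponent = 1 / 2, extent_ref_voltage = 3,
                        amp_voltage_exponent = 0, anat_sd = 1.5, seed = 1) {
  stopifnot(n_patients >= 1, length(maps_per_patient) == 2,
            maps_per_patient[1] >= 1, maps_per_patient[2] <= 5,
            maps_per_patient[1] <= maps_per_patient[2],
            length(grid_shape) == 3, all(grid_shape >= 4),
            all(voxel_size > 0), noise_sd >= 0, base_amplitude > 0,
            blob_sigma > 0, supra_slope > 1, pulse_width > 0,
            diff(freq_band) > 0, n_contacts >= 2,
            opt_freq_range[1] >= freq_band[1],
            opt_freq_range[2] <= freq_band[2])
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic DBS-fMRI cohort spec:", x$n_patients, "patients,",
      paste(x$maps_per_patient, collapse = "-"), "maps/patient, grid",
      paste(x$grid_shape, collapse = "x"), "\n")
  invisible(x)
}

#' A single stimulation setting
#'
#' @param voltage stimulation amplitude in volts (>= 0).
#' @param frequency stimulation frequency in Hz.
#' @param pulse_width pulse width in microseconds (> 0).
#' @param contact length-3 contact centroid (mm, common space).
#' @param is_optimal whether the setting is the patient's clinically optimal
#'   one.
#' @param freq_band admissible frequency band used for validation.
#' @return object of class `stim_setting`.
#' @export
stim_setting <- function(voltage, frequency, pulse_width = 60,
                         contact = c(0, 0, 0), is_optimal = FALSE,
                         freq_band = c(80, 160)) {
  stopifnot(voltage >= 0, pulse_width > 0, length(contact) == 3,
            all(is.finite(contact)),
            frequency >= freq_band[1], frequency <= freq_band[2])
  structure(list(voltage = voltage, frequency = frequency,
                 pulse_width = pulse_width, contact = as.numeric(contact),
                 is_optimal = isTRUE(is_optimal)),
            class = "stim_setting")
}

# mm coordinates of the voxel centres along each grid axis (grid centred at 0)
grid_axes <- function(grid_shape, voxel_size) {
  lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * voxel_size[a]
  })
}

snap_to_grid <- function(pt, axes) {
  vapply(1:3, function(a) axes[[a]][which.min(abs(axes[[a]] - pt[a]))], 0)
}

#' Sample a synthetic patient cohort
#'
#' Each patient receives an anatomical offset (shifting response centroids and
#' lead position coherently), a quadripolar contact array, one optimal setting
#' and 0-4 tolerated non-optimal settings (sub-/supra-therapeutic voltage or a
#' displaced contact, each with a frequency shift). Generation is a pure
#' function of `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return list of patients (class `dbs_patient`), each carrying
#'   `patient_id`, `topography`, `contact_grid`, `optimal`, and `settings`.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  axes <- grid_axes(spec$grid_shape, spec$voxel_size)
  withr::with_seed(seed, {
    lapply(seq_len(spec$n_patients), function(p) {
      anat <- stats::rnorm(3, sd = spec$anat_sd)
      lead <- .lead_base + anat
      offs <- (seq_len(spec$n_contacts) - 1) * spec$contact_spacing
      grid <- cbind(x = rep(lead[1], spec$n_contacts),
                    y = rep(lead[2], spec$n_contacts),
                    z = lead[3] + offs)
      opt_idx <- sample.int(spec$n_contacts, 1)
      v_opt <- stats::runif(1, spec$voltage_range[1], spec$voltage_range[2])
      f_opt <- stats::runif(1, spec$opt_freq_range[1], spec$opt_freq_range[2])
      motor <- .motor_rois
      motor[, c("x", "y", "z")] <-
        sweep(as.matrix(motor[, c("x", "y", "z")]), 2, anat, "+")
      nonmotor <- .nonmotor_rois
      nonmotor[, c("x", "y", "z")] <-
        sweep(as.matrix(nonmotor[, c("x", "y", "z")]), 2, anat, "+")

      optimal <- stim_setting(v_opt, f_opt, spec$pulse_width,
                              grid[opt_idx, ], TRUE, spec$freq_band)
      n_maps <- sample(seq(spec$maps_per_patient[1],
                           spec$maps_per_patient[2]), 1)
      settings <- list(optimal)
      if (n_maps > 1) {
        for (m in seq_len(n_maps - 1)) {
          type <- sample(c("sub", "supra", "contact"), 1,
                         prob = c(0.4, 0.4, 0.2))
          cidx <- opt_idx
          if (type == "contact" || stats::runif(1) < 0.3) {
            shift <- if (opt_idx == 1) 1
                     else if (opt_idx == spec$n_contacts) -1
                     else sample(c(-1, 1), 1)
            cidx <- opt_idx + shift
          }
          v <- switch(type,
            sub = v_opt * stats::runif(1, spec$sub_range[1],
                                       spec$sub_range[2]),
            supra = v_opt * stats::runif(1, spec$supra_range[1],
                                         spec$supra_range[2]),
            contact = v_opt)
          f <- min(max(f_opt + sample(c(-1, 1), 1) * stats::runif(1, 20, 40),
                       spec$freq_band[1]), spec$freq_band[2])
          settings[[m + 1]] <- stim_setting(v, f, spec$pulse_width,
                                            grid[cidx, ], FALSE,
                                            spec$freq_band)
        }
      }
      structure(list(
        patient_id = sprintf("P%02d", p),
        anat_offset = anat,
        contact_grid = grid,
        optimal_contact_index = opt_idx,
        optimal = optimal,
        settings = settings,
        topography = list(motor = motor, nonmotor = nonmotor,
                          blob_sigma = spec$blob_sigma,
                          base_amplitude = spec$base_amplitude *
                            (v_opt / spec$extent_ref_voltage)^
                              spec$amp_voltage_exponent)),
        class = "dbs_patient")
    })
  })
}

# separable Gaussian blob, peak value 1 at the (on-grid) centre
add_blob <- function(vol, axes, centre, sigma, amplitude) {
  g <- lapply(1:3, function(a) exp(-(axes[[a]] - centre[a])^2 / (2 * sigma^2)))
  vol + amplitude * (g[[1]] %o% g[[2]] %o% g[[3]])
}

#' Render the t-map a stimulation setting evokes in a synthetic patient
#'
#' Implements the parameter-to-response forward model: signed Gaussian foci at
#' the patient's motor centroids with peak amplitude `base * v/v_opt` below
#' the optimal voltage and `base * (1 + supra_slope * (v/v_opt - 1))` above
#' it; positive non-motor foci recruited only supra-therapeutically; amplitude
#' attenuation `exp(-d^2 / (2 contact_sigma^2))` with contact displacement
#' `d`; activation extent growing as `v^(1/3)`; iid Gaussian voxel noise.
#'
#' @param patient a patient from [sample_cohort()].
#' @param setting a [stim_setting()] drawn from that patient's space.
#' @param spec the [cohort_spec()] the patient was generated under.
#' @param noise_sd noise level; defaults to the spec value.
#' @param seed optional seed for the noise draw.
#' @return a [response_map()].
#' @export
render_response_map <- function(patient, setting, spec,
                                noise_sd = spec$noise_sd, seed = NULL) {
  stopifnot(inherits(patient, "dbs_patient"), inherits(setting, "stim_setting"))
  axes <- grid_axes(spec$grid_shape, spec$voxel_size)
  topo <- patient$topography
  v_opt <- patient$optimal$voltage
  r <- setting$voltage / v_opt
  amp <- if (r <= 1) topo$base_amplitude * r else
    topo$base_amplitude * (1 + spec$supra_slope * (r - 1))
  d_contact <- sqrt(sum((setting$contact - patient$optimal$contact)^2))
  atten <- exp(-d_contact^2 / (2 * spec$contact_sigma^2))
  sigma_eff <- topo$blob_sigma *
    (setting$voltage / spec$extent_ref_voltage)^spec$extent_exponent
  lead_mid <- mean(patient$contact_grid[, "z"])
  zshift <- spec$contact_coupling * (setting$contact[3] - lead_mid)

  vol <- array(0, spec$grid_shape)
  for (i in seq_len(nrow(topo$motor))) {
    ctr <- as.numeric(topo$motor[i, c("x", "y", "z")])
    ctr[3] <- ctr[3] + zshift
    ctr <- snap_to_grid(ctr, axes)
    vol <- add_blob(vol, axes, ctr, sigma_eff,
                    topo$motor$sign[i] * amp * atten)
  }
  if (r > 1) {
    amp_nm <- topo$base_amplitude * spec$nonmotor_gain * (r - 1)
    for (i in seq_len(nrow(topo$nonmotor))) {
      ctr <- snap_to_grid(as.numeric(topo$nonmotor[i, c("x", "y", "z")]), axes)
      vol <- add_blob(vol, axes, ctr, sigma_eff,
                      topo$nonmotor$sign[i] * amp_nm)
    }
  }
  if (noise_sd > 0) {
    noise <- function() array(stats::rnorm(length(vol), sd = noise_sd),
                              dim = dim(vol))
    vol <- vol + if (is.null(seed)) noise() else withr::with_seed(seed, noise())
  }
  response_map(vol, voxel_size = spec$voxel_size, space = "common")
}

#' Left-right mirror of a response map
#'
#' Mirrors voxel values along the left-right axis (first grid axis) and marks
#' the map as flipped; used as the robustness probe emulating a change of
#' stimulation side.
#'
#' @param map a [response_map()].
#' @return the mirrored [response_map()].
#' @export
flip_lr <- function(map) {
  stopifnot(inherits(map, "response_map"))
  map$data <- map$data[rev(seq_len(dim(map$data)[1])), , , drop = FALSE]
  map$flipped <- !map$flipped
  map
}

#' Assemble the model-ready dataset for a cohort
#'
#' Renders every tested setting of every patient, preprocesses each map for
#' the autoencoder ([preprocess_for_ae()]), and collects labels and per-map
#' regression targets. The regression target of every map - optimal or not -
#' is the owning patient's optimal setting (voltage, frequency, contact
#' x/y/z), which is what lets the closed-loop protocol propose optimal
#' parameters from a non-optimal map.
#'
#' @param cohort output of [sample_cohort()].
#' @param spec the matching [cohort_spec()].
#' @param target_shape `(H, W, slices)` shape for [preprocess_for_ae()].
#' @param seed base seed for the per-map noise draws.
#' @return list with `volumes` (4-d array H x W x slices x n_maps), `labels`
#'   (0/1 optimal), `targets` (data frame voltage/frequency/x/y/z),
#'   `patient_id`, `map_id`, and `table` (the cohort table as a data frame).
#' @export
build_cohort_dataset <- function(cohort, spec,
                                 target_shape = c(spec$grid_shape[1],
                                                  spec$grid_shape[2],
                                                  spec$grid_shape[3]),
                                 seed = spec$seed + 1000) {
  rows <- list(); vols <- list(); k <- 0
  for (p in cohort) {
    for (s in p$settings) {
      k <- k + 1
      map <- render_response_map(p, s, spec, seed = seed + k)
      vols[[k]] <- preprocess_for_ae(map, target_shape)
      rows[[k]] <- data.frame(
        patient_id = p$patient_id, map_id = sprintf("M%03d", k),
        voltage = s$voltage, frequency = s$frequency,
        pulse_width = s$pulse_width,
        x = s$contact[1], y = s$contact[2], z = s$contact[3],
        is_optimal = s$is_optimal,
        opt_voltage = p$optimal$voltage, opt_frequency = p$optimal$frequency,
        opt_x = p$optimal$contact[1], opt_y = p$optimal$contact[2],
        opt_z = p$optimal$contact[3])
    }
  }
  tab <- do.call(rbind, rows)
  volumes <- array(unlist(vols, use.names = FALSE),
                   dim = c(dim(vols[[1]]), k))
  list(volumes = volumes, labels = as.numeric(tab$is_optimal),
       targets = tab[, c("opt_voltage", "opt_frequency",
                         "opt_x", "opt_y", "opt_z")] |>
         stats::setNames(c("voltage", "frequency", "x", "y", "z")),
       patient_id = tab$patient_id, map_id = tab$map_id, table = tab)
}
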