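#' Default electronic-nose channel names
#'
#' The array carries two sensor families: eight TGS-type channels (`T1`-`T8`)
#' followed by eight MQ/MP-type channels (`M1`-`M8`).
#'
#' @return Character vector of the 16 channel names in array order.
#' @export
default_channel_names <- function() {
  c(paste0("T", 1:8), paste0("M", 1:8))
}

#' Sensor-array specification
#'
#' Describes the geometry of one e-nose recording: the ordered channel names
#' and the number of time points sampled per channel.
#'
#' @param channel_names Ordered character vector of 16 unique channel names;
#'   the first 8 must be prefixed `T`, the last 8 prefixed `M`.
#' @param n_timepoints Number of samples per channel (default 5940). Must be
#'   at least 16 so a depth-3 wavelet packet transform is well defined.
#' @param sampling_label Free-text provenance label.
#'
#' @return An object of class `sensor_array_spec`.
#' @export
sensor_array_spec <- function(channel_names = default_channel_names(),
                              n_timepoints = 5940,
                              sampling_label = "") {
  channel_names <- as.character(channel_names)
  if (length(channel_names) != 16L || anyDuplicated(channel_names)) {
    stop("'channel_names' must be 16 unique names", call. = FALSE)
  }
  if (!all(startsWith(channel_names[1:8], "T")) ||
      !all(startsWith(channel_names[9:16], "M"))) {
    stop("first 8 channel names must be prefixed 'T', last 8 prefixed 'M'",
         call. = FALSE)
  }
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_timepoints) || n_timepoints < 16L) {
    stop("'n_timepoints' must be an integer >= 16", call. = FALSE)
  }
  structure(
    list(channel_names = channel_names,
         n_timepoints = n_timepoints,
         sampling_label = as.character(sampling_label)),
    class = "sensor_array_spec"
  )
}

#' @export
print.sensor_array_spec <- function(x, ...) {
  cat("Sensor array:", length(x$channel_names), "channels x",
      x$n_timepoints, "timepoints\n")
  invisible(x)
}

#' Per-class response profile for the simulator
#'
#' Encodes how one odor class drives every channel of the array: the relative
#' steady-state amplitude (dimensionless, as a fraction of the channel
#' baseline), the exponential rise time (in samples) and the standard
#' deviation of a class-dependent band-limited fluctuation (volts).
#'
#' @param class_id Integer class label (>= 1).
#' @param amplitude Numeric vector, one value per channel, all >= 0.
#' @param rise_time Numeric vector, one value per channel, all > 0 (samples).
#' @param band_noise_sd Numeric vector, one value per channel, all >= 0 (volts).
#'
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_id, amplitude, rise_time, band_noise_sd) {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 1L) {
    stop("'class_id' must be a positive integer", call. = FALSE)
  }
  n <- length(amplitude)
  if (length(rise_time) != n || length(band_noise_sd) != n) {
    stop("amplitude, rise_time and band_noise_sd must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stop("'amplitude' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(rise_time)) || any(rise_time <= 0)) {
    stop("'rise_time' must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(band_noise_sd)) || any(band_noise_sd < 0)) {
    stop("'band_noise_sd' must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(class_id = class_id,
         amplitude = as.numeric(amplitude),
         rise_time = as.numeric(rise_time),
         band_noise_sd = as.numeric(band_noise_sd)),
    class = "class_profile"
  )
}

#' Voltage-divider readout circuit
#'
#' A metal-oxide sensor of resistance `Rp` is read out through a load
#' resistance `Rl` in series: the recorded signal is the voltage across the
#' load, `Vo = VRef * Rl / (Rp + Rl)`.
#'
#' @param v_ref Reference voltage in volts (> 0).
#' @param r_load Load resistance in ohms (> 0).
#'
#' @return An object of class `divider_circuit`.
#' @export
divider_circuit <- function(v_ref, r_load) {
  if (!is.finite(v_ref) || v_ref <= 0) stop("'v_ref' must be > 0", call. = FALSE)
  if (!is.finite(r_load) || r_load <= 0) stop("'r_load' must be > 0", call. = FALSE)
  structure(list(v_ref = v_ref, r_load = r_load), class = "divider_circuit")
}

#' Divider output voltage
#'
#' @param circuit A [divider_circuit()].
#' @param r_sensor Sensor resistance in ohms (> 0); may be a vector.
#'
#' @return Output voltage(s) `v_ref * r_load / (r_sensor + r_load)`, strictly
#'   between 0 and `v_ref`.
#' @export
divider_output <- function(circuit, r_sensor) {
  stopifnot(inherits(circuit, "divider_circuit"))
  if (any(!is.finite(r_sensor)) || any(r_sensor <= 0)) {
    stop("'r_sensor' must be finite and > 0", call. = FALSE)
  }
  circuit$v_ref * circuit$r_load / (r_sensor + circuit$r_load)
}

#' Divider response sensitivity
#'
#' Magnitude of the derivative of the output voltage with respect to the
#' sensor resistance, `|dVo/dRp| = v_ref * r_load / (r_sensor + r_load)^2`.
#' For a fixed sensor resistance this is maximal when the load resistance
#' equals the sensor resistance.
#'
#' @inheritParams divider_output
#' @return Sensitivity in volts/ohm.
#' @export
divider_sensitivity <- function(circuit, r_sensor) {
  stopifnot(inherits(circuit, "divider_circuit"))
  if (any(!is.finite(r_sensor)) || any(r_sensor <= 0)) {
    stop("'r_sensor' must be finite and > 0", call. = FALSE)
  }
  circuit$v_ref * circuit$r_load / (r_sensor + circuit$r_load)^2
}

#' Build the default per-class response profiles
#'
#' Constructs one [class_profile()] per class. A configurable subset of
#' channels is informative: on those channels the steady-state amplitude, the
#' rise time and the band-limited fluctuation level all depend on the class
#' (each channel sees the classes in a different cyclic order, so informative
#' features are not mutually collinear). All remaining channels respond
#' identically for every class and therefore carry no class information.
#'
#' @param n_classes Number of odor classes (default 8).
#' @param spec A [sensor_array_spec()].
#' @param informative_channels Channel names that carry class information
#'   (default `T2, T5, M1, M4, M7`, i.e. 5 of the 16 channels).
#' @param base_amplitude,amplitude_step Amplitude of class `c` on informative
#'   channel `j` is `base_amplitude + amplitude_step * ((c - 1 + j) mod n_classes)`.
#' @param base_rise,rise_step Rise time analogue (samples), cyclic shift `2j`.
#' @param base_band_sd,band_sd_step Band-limited fluctuation sd analogue
#'   (volts), cyclic shift `2j`.
#' @param flat_amplitude,flat_rise,flat_band_sd Values used on uninformative
#'   channels (identical across classes).
#'
#' @return List of `n_classes` [class_profile()] objects.
#' @export
make_class_profiles <- function(n_classes = 8,
                                spec = sensor_array_spec(),
                                informative_channels = c("T2", "T5", "M1", "M4", "M7"),
                                base_amplitude = 0.30, amplitude_step = 0.08,
                                base_rise = 200, rise_step = 100,
                                base_band_sd = 0.002, band_sd_step = 0.0015,
                                flat_amplitude = 0.5, flat_rise = 400,
                                flat_band_sd = 0.004) {
  stopifnot(inherits(spec, "sensor_array_spec"), n_classes >= 1)
  ch <- spec$channel_names
  if (!all(informative_channels %in% ch)) {
    stop("unknown channel in 'informative_channels'", call. = FALSE)
  }
  lapply(seq_len(n_classes), function(cls) {
    amp <- rep(flat_amplitude, length(ch))
    tau <- rep(flat_rise, length(ch))
    bsd <- rep(flat_band_sd, length(ch))
    for (j in seq_along(informative_channels)) {
      s <- match(informative_channels[j], ch)
      amp[s] <- base_amplitude + amplitude_step * ((cls - 1 + j) %% n_classes)
      tau[s] <- base_rise + rise_step * ((cls - 1 + 2 * j) %% n_classes)
      bsd[s] <- base_band_sd + band_sd_step * ((cls - 1 + 2 * j) %% n_classes)
    }
    class_profile(cls, amp, tau, bsd)
  })
}

# Band-limited fluctuation: unit-variance white noise smoothed with a circular
# moving average of width w, rescaled so its marginal sd stays ~1, then scaled
# per channel. Concentrates power in the low-frequency wavelet leaves.
band_limited_noise <- function(n, n_channels, width = 25L) {
  z <- matrix(stats::rnorm(n * n_channels), nrow = n, ncol = n_channels)
  sm <- stats::filter(z, rep(1 / width, width), circular = TRUE)
  matrix(as.numeric(sm), nrow = n) * sqrt(width)
}

#' Simulate one e-nose recording
#'
#' Each channel follows a saturating exponential rise above a per-recording
#' baseline, with additive linear drift, a class-dependent band-limited
#' fluctuation and white measurement noise:
#' `x_s(t) = b_s * (1 + A_s * (1 - exp(-t / tau_s))) + drift_slope * t +
#' band fluctuation + white noise`, for t = 0, ..., N-1.
#' Baselines are drawn once per recording, log-uniformly within
#' `baseline_range`, so they stay bounded away from zero (they divide the
#' relative-difference transform).
#'
#' @param profile A [class_profile()] with per-channel vectors matching `spec`.
#' @param spec A [sensor_array_spec()].
#' @param drift_slope Additive linear drift in volts/sample (>= 0).
#' @param noise_sd White measurement noise sd in volts (>= 0).
#' @param seed Integer seed; fixes all randomness in the recording.
#' @param replicate Replicate index stored on the recording (>= 1).
#' @param baseline_range Length-2 positive range for the log-uniform baseline
#'   draw (volts).
#' @param response_jitter_sd Log-sd of a per-recording multiplicative jitter
#'   on the channel amplitudes, emulating replicate-to-replicate response
#'   variability (default 0: amplitudes follow the profile exactly).
#'
#' @return An object of class `sensor_recording` with fields `spec`, `values`
#'   (channels x timepoints matrix, volts), `baseline` (named vector, volts),
#'   `label` and `replicate`.
#' @export
generate_recording <- function(profile, spec = sensor_array_spec(),
                               drift_slope = 2e-6, noise_sd = 0.01,
                               seed = 1L, replicate = 1L,
                               baseline_range = c(1, 3),
                               response_jitter_sd = 0) {
  stopifnot(inherits(profile, "class_profile"),
            inherits(spec, "sensor_array_spec"))
  n_ch <- length(spec$channel_names)
  if (length(profile$amplitude) != n_ch) {
    stop("profile channel count (", length(profile$amplitude),
         ") does not match array spec (", n_ch, ")", call. = FALSE)
  }
  if (drift_slope < 0 || noise_sd < 0) {
    stop("'drift_slope' and 'noise_sd' must be >= 0", call. = FALSE)
  }
  if (length(baseline_range) != 2L || any(baseline_range <= 0) ||
      baseline_range[2] < baseline_range[1]) {
    stop("'baseline_range' must be a positive increasing pair", call. = FALSE)
  }
  n <- spec$n_timepoints
  set.seed(as.integer(seed))
  baseline <- exp(stats::runif(n_ch, log(baseline_range[1]),
                               log(baseline_range[2])))
  names(baseline) <- spec$channel_names
  amplitude <- profile$amplitude
  if (response_jitter_sd > 0) {
    amplitude <- amplitude * exp(stats::rnorm(n_ch, 0, response_jitter_sd))
  }
  t0 <- 0:(n - 1L)
  values <- matrix(0, nrow = n_ch, ncol = n,
                   dimnames = list(spec$channel_names, NULL))
  band <- band_limited_noise(n, n_ch)
  for (s in seq_len(n_ch)) {
    rise <- 1 - exp(-t0 / profile$rise_time[s])
    det <- baseline[s] * (1 + amplitude[s] * rise) + drift_slope * t0
    values[s, ] <- det + profile$band_noise_sd[s] * band[, s]
  }
  if (noise_sd > 0) {
    values <- values + matrix(stats::rnorm(n_ch * n, sd = noise_sd),
                              nrow = n_ch)
  }
  structure(
    list(spec = spec, values = values, baseline = baseline,
         label = profile$class_id, replicate = as.integer(replicate)),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("Sensor recording: class", x$label, "replicate", x$replicate, "(",
      nrow(x$values), "channels x", ncol(x$values), "timepoints )\n")
  invisible(x)
}

#' Simulate a labeled e-nose dataset
#'
#' Generates `n_replicates` recordings per class profile, in profile order
#' (all replicates of class 1, then class 2, ...). Each recording receives its
#' own seed derived deterministically from the master seed, so the whole
#' dataset is reproducible bit for bit.
#'
#' @param profiles Non-empty list of [class_profile()] objects.
#' @param n_replicates Recordings per class (default 10).
#' @param spec A [sensor_array_spec()].
#' @param drift_slope,noise_sd,baseline_range,response_jitter_sd Passed to
#'   [generate_recording()]; the jitter default of 0.05 (5 percent relative
#'   response scatter between replicates) reflects typical repeatability of
#'   metal-oxide sensor arrays.
#' @param seed Master integer seed.
#'
#' @return List of `length(profiles) * n_replicates` `sensor_recording`
#'   objects.
#' @export
generate_dataset <- function(profiles, n_replicates = 10,
                             spec = sensor_array_spec(),
                             drift_slope = 2e-6, noise_sd = 0.01,
                             baseline_range = c(1, 3),
                             response_jitter_sd = 0.05, seed = 1L) {
  if (!length(profiles)) stop("'profiles' must be non-empty", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("'n_replicates' must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rec_seeds <- sample.int(.Machine$integer.max,
                          length(profiles) * n_replicates)
  out <- vector("list", length(profiles) * n_replicates)
  k <- 0L
  for (p in profiles) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      out[[k]] <- generate_recording(p, spec,
                                     drift_slope = drift_slope,
                                     noise_sd = noise_sd,
                                     seed = rec_seeds[k], replicate = r,
                                     baseline_range = baseline_range,
                                     response_jitter_sd = response_jitter_sd)
    }
  }
  out
}
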