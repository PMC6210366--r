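test_that("divider output follows the voltage-divider law", {
  circ <- divider_circuit(5, 1000)
  expect_equal(divider_output(circ, 1000), 2.5)          # Rl = Rp halves VRef
  expect_equal(divider_output(circ, 4000), 1.0)
  # open-divider limit: output approaches VRef as Rl grows
  expect_equal(divider_output(divider_circuit(5, 1e12), 100), 5,
               tolerance = 1e-9)
  expect_true(all(divider_output(circ, c(1, 1e9)) > 0))
  expect_true(all(divider_output(circ, c(1, 1e9)) < 5))
  expect_error(divider_output(circ, 0), "r_sensor")
  expect_error(divider_output(circ, -10), "r_sensor")
})

test_that("divider sensitivity peaks at r_load = r_sensor", {
  expect_equal(divider_sensitivity(divider_circuit(5, 1), 1), 1.25)
  r_p <- 4700
  grid <- r_p * 10^seq(-3, 3, length.out = 121)  # includes r_load = r_p
  sens <- vapply(grid, function(rl) {
    divider_sensitivity(divider_circuit(5, rl), r_p)
  }, numeric(1))
  expect_equal(grid[which.max(sens)], r_p)
  # the three-point grid of the spec: middle value (r_load = r_sensor) largest
  three <- vapply(c(r_p / 15, r_p, 10 * r_p), function(rl) {
    divider_sensitivity(divider_circuit(5, rl), r_p)
  }, numeric(1))
  expect_identical(which.max(three), 2L)
})

test_that("array spec and class profile validate their invariants", {
  expect_error(sensor_array_spec(letters[1:16]), "prefixed")
  expect_error(sensor_array_spec(n_timepoints = 8), ">= 16")
  expect_error(sensor_array_spec(c(paste0("T", 1:8), paste0("M", c(1:7, 1)))),
               "unique")
  expect_error(class_profile(1, amplitude = c(1, 2), rise_time = c(1, 2, 3),
                             band_noise_sd = c(0, 0)), "equal length")
  expect_error(class_profile(1, 1, rise_time = 0, band_noise_sd = 0), "> 0")
  expect_error(class_profile(1, -1, rise_time = 1, band_noise_sd = 0), ">= 0")
})

test_that("null-response recording is constant at the baseline", {
  spec <- small_spec()
  prof <- class_profile(1, amplitude = rep(0, 16), rise_time = rep(100, 16),
                        band_noise_sd = rep(0, 16))
  rec <- generate_recording(prof, spec, drift_slope = 0, noise_sd = 0,
                            seed = 3)
  expect_equal(rec$values, matrix(rec$baseline, 16, spec$n_timepoints,
                                  dimnames = dimnames(rec$values)))
  expect_true(all(rec$baseline > 0))
})

test_that("recordings are reproducible and follow the saturating rise", {
  spec <- small_spec()
  prof <- class_profile(2, amplitude = rep(1, 16), rise_time = rep(30, 16),
                        band_noise_sd = rep(0, 16))
  r1 <- generate_recording(prof, spec, drift_slope = 0, noise_sd = 0, seed = 9)
  r2 <- generate_recording(prof, spec, drift_slope = 0, noise_sd = 0, seed = 9)
  expect_identical(r1$values, r2$values)
  # monotone non-decreasing, asymptote 2 * baseline (amplitude 1)
  for (s in c(1, 8, 16)) {
    expect_true(all(diff(r1$values[s, ]) >= 0))
    expect_true(all(r1$values[s, ] <= 2 * r1$baseline[s]))
    expect_equal(r1$values[s, spec$n_timepoints], 2 * r1$baseline[s],
                 tolerance = 1e-3)
  }
  expect_error(
    generate_recording(class_profile(1, 1, 1, 0), spec, seed = 1),
    "does not match"
  )
})

test_that("dataset generation emits profiles x replicates in order", {
  recs <- small_dataset(3, 2, seed = 5)
  expect_length(recs, 6L)
  expect_equal(vapply(recs, `[[`, integer(1), "label"), c(1, 1, 2, 2, 3, 3))
  expect_equal(vapply(recs, `[[`, integer(1), "replicate"),
               rep(1:2, times = 3))
  one <- generate_dataset(make_class_profiles(1, small_spec()), 1,
                          small_spec(), seed = 2)
  expect_length(one, 1L)
  expect_equal(one[[1]]$replicate, 1L)
  # bit-for-bit master-seed reproducibility
  again <- small_dataset(3, 2, seed = 5)
  expect_identical(lapply(recs, `[[`, "values"),
                   lapply(again, `[[`, "values"))
})

test_that("noise-free channels stay bounded by baseline * (1 + amplitude)", {
  spec <- small_spec()
  profs <- make_class_profiles(2, spec)
  profs <- lapply(profs, function(p) {
    p$band_noise_sd[] <- 0
    p
  })
  recs <- generate_dataset(profs, 2, spec, drift_slope = 0, noise_sd = 0,
                           response_jitter_sd = 0, seed = 11)
  for (rec in recs) {
    prof <- profs[[rec$label]]
    bound <- rec$baseline * (1 + prof$amplitude)
    expect_true(all(rec$values <= bound + 1e-12))
  }
})
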