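test_that("crosstalk characterisation inverts the simulator's leakage", {
  # random leakage matrix, noiseless low-power standard: exact round trip
  set.seed(20)
  wl <- c(340, 470, 590)
  ct <- matrix(10^runif(9, -5, -2), 3, 3)
  diag(ct) <- 1
  inst <- quiet_instrument(
    instrument_spec(source_wavelengths = wl, source_powers = c(1, 1, 1),
                    channel_centers = wl, crosstalk = ct),
    power_scale = 0.05)
  fr <- simulate_frames(blank_sample(), inst, seed = 4)
  rep <- crosstalk_matrix(fr, inst)
  expect_false(any(rep$flagged))
  expected <- 100 * ct[cbind(match(rep$channel, wl), match(rep$source, wl))]
  expect_equal(rep$percent, expected, tolerance = 1e-12)
  # matched channels are 100 % by construction
  expect_true(all(rep$percent[rep$channel == rep$source] == 100))
})

test_that("the default instrument reproduces the characterised leakage values", {
  inst <- quiet_instrument(instrument_spec(), power_scale = 0.05)
  fr <- simulate_frames(blank_sample(), inst, seed = 4)
  rep <- crosstalk_matrix(fr, inst)
  expect_equal(rep$percent[rep$source == 340 & rep$channel == 470], 1e-3)
  expect_equal(rep$percent[rep$source == 440 & rep$channel == 590], 2.5e-2)
  expect_equal(rep$percent[rep$source == 340 & rep$channel == 680], 2e-3)
})

test_that("saturated matched channels are flagged, not mis-normalised", {
  inst <- quiet_instrument(instrument_spec())  # full power: diagonals clip
  fr <- simulate_frames(blank_sample(), inst, seed = 4)
  rep <- crosstalk_matrix(fr, inst)
  expect_true(any(rep$flagged))
  expect_true(all(is.na(rep$percent[rep$flagged])))
})

test_that("specificity slopes flag matched pairs only and shrink with replicates", {
  inst <- quiet_instrument(tiny_instrument(), power_scale = 0.3)
  build <- function(n_rep, noise_sd = 0.002, seed = 30) {
    set.seed(seed)
    d <- dilution_series_design("nadh", n_rep = n_rep)
    purrr::map_dfr(seq_len(nrow(d)), function(i) {
      tibble::tibble(
        fluorophore = "nadh",
        concentration = d$nadh[i],
        source = c(340, 590),
        channel = c(470, 590),
        value = c(fluorescence_voltage(d[i, ], inst, 340, 470),
                  fluorescence_voltage(d[i, ], inst, 590, 590)) +
          rnorm(2, sd = noise_sd)
      )
    })
  }
  rep5 <- specificity_slopes(build(5))
  matched <- rep5[rep5$source == 340, ]
  disjoint <- rep5[rep5$source == 590, ]
  expect_true(matched$responsive)
  expect_false(disjoint$responsive)
  # noiseless matched slope equals the forward-model response constant
  # (suppressed: summary.lm warns on the exact fit)
  exact <- suppressWarnings(specificity_slopes(build(1, noise_sd = 0)))
  unit <- fluorescence_voltage(nadh_only_sample(1), inst, 340, 470)
  expect_equal(exact$slope[exact$source == 340], unit, tolerance = 1e-10)
  # replicate averaging reduces the slope standard error
  rep1 <- specificity_slopes(build(1, seed = 31))
  expect_lt(matched$std_error, rep1$std_error[rep1$source == 340])
  # degenerate series: a single concentration level errors
  one_level <- build(5)
  one_level <- one_level[one_level$concentration == 0, ]
  expect_error(specificity_slopes(one_level), "distinct")
})

test_that("independence slopes vanish by factorial balance", {
  d <- factorial_design()
  y <- as.matrix(d[c("nadh", "fad", "ppix")])
  # predictions equal to truth: cross slopes exactly zero, self slopes 1
  fake <- structure(list(predictions = y, y = y, row_ids = d$sample_id),
                    class = "pls_cv")
  ic <- suppressWarnings(independence_check(fake, d))  # exact-fit lm warnings
  cross <- ic[ic$predicted != ic$truth_var, ]
  expect_true(all(abs(cross$slope) < 1e-12))
  expect_false(any(cross$flagged))
  self <- ic[ic$predicted == ic$truth_var, ]
  expect_equal(self$slope, rep(1, 3))
  # any prediction depending only on its own target keeps cross slopes zero
  warped <- fake
  warped$predictions <- sqrt(abs(y)) + y^2
  ic2 <- suppressWarnings(independence_check(warped, d))
  expect_true(all(abs(ic2$slope[ic2$predicted != ic2$truth_var]) < 1e-10))
  # non-factorial design draws a warning
  jittered <- y[-1, ] + seq_len(3 * 124) * 1e-4  # avoid exact-fit lm noise
  expect_warning(independence_check(
    structure(list(predictions = jittered, y = jittered), class = "pls_cv"),
    d[-1, ]), "factorial")
})

test_that("linearity range finds the linear region of a detector sweep", {
  power <- 10^seq(-2, 2.5, length.out = 40)
  gain <- 0.135
  # perfectly linear sweep: the full range is linear
  out <- linearity_range(power, gain * power)
  expect_equal(unname(out), c(min(power), max(power)))
  # hard clip at 5 V: the upper bound cannot pass the input whose ideal
  # response exceeds the ceiling by more than the allowed 5 % deviation
  clipped <- pmin(gain * power, 5)
  out2 <- linearity_range(power, clipped)
  expect_lte(out2[["max"]], 5 / (0.95 * gain))
  expect_lt(out2[["max"]], max(power))
  expect_equal(out2[["min"]], min(power))
  # noise floor at the low end is excluded
  floored <- pmax(gain * power, 0.05)
  out3 <- linearity_range(power, floored)
  expect_gt(out3[["min"]], min(power))
  expect_error(linearity_range(power[1:3], clipped[1:3]), "length")
})
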