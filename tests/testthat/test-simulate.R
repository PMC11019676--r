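test_that("fluorescence is strictly linear in each concentration", {
  inst <- tiny_instrument()
  s0 <- blank_sample()
  expect_equal(fluorescence_voltage(s0, inst, 340, 470), 0)
  s1 <- nadh_only_sample(25)
  s2 <- nadh_only_sample(50)
  v1 <- fluorescence_voltage(s1, inst, 340, 470)
  v2 <- fluorescence_voltage(s2, inst, 340, 470)
  expect_gt(v1, 0)
  expect_equal(v2, 2 * v1)
  # doubling NADH with the others fixed doubles only the NADH share
  mix <- s1; mix$fad <- 5; mix$ppix <- 5
  mix2 <- mix; mix2$nadh <- 50
  expect_equal(fluorescence_voltage(mix2, inst, 340, 470) -
                 fluorescence_voltage(mix, inst, 340, 470), v1)
  # residuals of a straight line over five levels vanish in noiseless mode
  levels <- c(0, 12.5, 25, 50, 100)
  v <- vapply(levels, function(cc) {
    fluorescence_voltage(nadh_only_sample(cc), inst, 340, 470)
  }, numeric(1))
  fit <- lm(v ~ levels)
  expect_lt(max(abs(resid(fit))), 1e-12)
})

test_that("excitation specificity: matched pair dwarfs a disjoint pair", {
  inst <- tiny_instrument()
  s <- nadh_only_sample(50)
  matched <- fluorescence_voltage(s, inst, 340, 470)
  disjoint <- fluorescence_voltage(s, inst, 590, 590)
  expect_gt(matched, 1e4 * disjoint)
})

test_that("noiseless blank frames equal crosstalk times reflected excitation", {
  inst <- quiet_instrument(tiny_instrument(), power_scale = 0.05)
  s <- blank_sample()
  fr <- simulate_frame(s, inst, seed = 7)
  cf <- subtract_background(fr, inst)
  for (j in seq_along(inst$source_wavelengths)) {
    src <- inst$source_wavelengths[j]
    reflex <- reflected_excitation(s, inst, src)
    for (i in seq_along(inst$channel_centers)) {
      got <- cf$value[cf$state == as.character(src) &
                        cf$detector == paste0("ch", inst$channel_centers[i])]
      expect_equal(got, min(inst$crosstalk[i, j] * reflex * inst$gain,
                            inst$v_max))
    }
  }
})

test_that("recorded SiPMT values never exceed the saturation ceiling", {
  inst <- instrument_spec()
  huge <- blank_sample()
  huge$nadh <- 1e6; huge$fad <- 1e5; huge$ppix <- 1e5
  fr <- simulate_frame(huge, inst, seed = 1)
  sipmt <- fr$value[grepl("^ch", fr$detector)]
  expect_true(all(sipmt <= inst$v_max))
  # something actually hit the ceiling, exactly
  expect_true(any(sipmt == inst$v_max))
})

test_that("frames are reproducible under a fixed seed and vary across seeds", {
  inst <- tiny_instrument()
  d <- dplyr::bind_rows(blank_sample(), nadh_only_sample())
  d$sample_id <- c("B001", "N001")
  f1 <- simulate_frames(d, inst, seed = 11)
  f2 <- simulate_frames(d, inst, seed = 11)
  expect_identical(f1, f2)
  f3 <- simulate_frames(d, inst, seed = 12)
  expect_false(isTRUE(all.equal(f1$value, f3$value)))
  # per-sample streams: appending a sample leaves earlier draws untouched
  d3 <- dplyr::bind_rows(d, blank_sample())
  d3$sample_id <- c("B001", "N001", "X001")
  f_ext <- simulate_frames(d3, inst, seed = 11)
  expect_equal(f_ext$value[f_ext$sample_id != "X001"], f1$value)
})

test_that("flash coupling: one source's power scales its whole state", {
  inst <- quiet_instrument(tiny_instrument(), power_scale = 0.3)
  s <- nadh_only_sample(10)
  inst_scaled <- inst
  inst_scaled$source_powers[1] <- inst$source_powers[1] * 1.7
  f1 <- subtract_background(simulate_frame(s, inst, seed = 1), inst)
  f2 <- subtract_background(simulate_frame(s, inst_scaled, seed = 1),
                            inst_scaled)
  st <- as.character(inst$source_wavelengths[1])
  expect_equal(f2$value[f2$state == st], 1.7 * f1$value[f1$state == st])
  expect_equal(f2$value[f2$state != st], f1$value[f1$state != st])
})

test_that("factorial designs match their printed structure", {
  d <- factorial_design()
  expect_equal(nrow(d), 125)
  expect_true(all(d$nadh %in% c(100, 50, 25, 12.5, 0)))
  expect_true(all(d$fad %in% c(10, 5, 2.5, 1.25, 0)))
  expect_true(all(d$ppix %in% c(10, 5, 2.5, 1.25, 0)))
  expect_equal(sum(d$nadh == 0 & d$fad == 0 & d$ppix == 0), 1)
  expect_false(anyDuplicated(d[c("nadh", "fad", "ppix")]) > 0)
  expect_true(all(d$absorber_fraction == 0.5))

  s1 <- absorber_sweep_design()
  expect_equal(nrow(s1), 20)
  expect_equal(range(s1$fad), c(0, 10))
  counts <- dplyr::count(s1, fad)
  expect_true(all(counts$n == 4))
  expect_equal(dplyr::n_distinct(s1$absorber_fraction), 4)
})

test_that("fluorophore panel invariants are enforced", {
  fl <- default_fluorophores()
  expect_true(all(fl$em_peak > fl$ex_peak))
  bad <- fl; bad$em_peak[1] <- bad$ex_peak[1] - 10
  expect_error(simulate_frame(blank_sample(), tiny_instrument(),
                              fluorophores = bad), "Stokes")
  bad_qy <- fl; bad_qy$quantum_yield[2] <- 1.5
  expect_error(simulate_frame(blank_sample(), tiny_instrument(),
                              fluorophores = bad_qy), "quantum_yield")
})
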