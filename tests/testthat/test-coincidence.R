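constant_profile <- function(level = 1) {
  gen_transcript_profile(waveform_spec("cosine", 0, 1, mean_level = level))
}

test_that("light/dark integrals split a constant and a pulse as expected", {
  p <- constant_profile(1)
  expect_equal(light_dark_integrals(p, 6), c(light = 6, dark = 18))
  # pulse on [12, 14) is wholly dark at a 6-h photoperiod
  pulse <- gen_transcript_profile(waveform_spec("rect_pulse", 13, 12,
                                                width_h = 2))
  expect_equal(light_dark_integrals(pulse, 6), c(light = 0, dark = 24))
})

test_that("analytic cosine integrals match the antiderivative", {
  p <- gen_transcript_profile(waveform_spec("cosine", 6, 2))
  ab <- light_dark_integrals(p, 12)
  expect_equal(unname(ab["light"]), cosine_integral_oracle(0, 12, 6, 2),
               tolerance = 1e-12)
  expect_equal(unname(ab["light"]), 12 + 24 / pi, tolerance = 1e-9)
})

test_that("trapezoid integration of tabulated profiles is accurate and conservative", {
  w <- waveform_spec("cosine", 6, 2)
  gp <- gen_transcript_profile(w)
  tab <- transcript_profile("g", gp$times, gp$values)   # strips the waveform
  for (td in c(3.05, 6, 11.77, 18)) {
    ab <- light_dark_integrals(tab, td)
    expect_equal(unname(ab["light"]), cosine_integral_oracle(0, td, 6, 2),
                 tolerance = 5e-4)
    # A + B equals the full-day integral to machine precision
    expect_equal(unname(ab["light"] + ab["dark"]),
                 sum(diff(tab$times) * (head(tab$values, -1) +
                                          tail(tab$values, -1)) / 2),
                 tolerance = 1e-12)
  }
})

test_that("synthesis-rate arithmetic follows the model definitions", {
  p <- constant_profile(1)
  expect_equal(daily_synthesis_rate(p, 6, T_L = 1.4, T_D = 1), 26.4)
  expect_equal(reference_synthesis_rate(6, 1.4, 1), 26.4)
  expect_equal(reference_synthesis_rate(18, 1.4, 1), 31.2)
  expect_equal(reference_synthesis_rate(7.3, 2, 2), 48)
  # dawn pulse wholly in light: k_s = T_L * 24
  pulse <- gen_transcript_profile(waveform_spec("rect_pulse", 1, 12,
                                                width_h = 2))
  expect_equal(daily_synthesis_rate(pulse, 6, 1.4, 1), 33.6, tolerance = 1e-9)
  # no light effect collapses k_s to the daily integral
  cosine <- gen_transcript_profile(waveform_spec("cosine", 9, 1.6))
  expect_equal(daily_synthesis_rate(cosine, 10, 1, 1), 24, tolerance = 1e-9)
})

test_that("steady-state abundance is synthesis over loss", {
  expect_equal(steady_state_abundance(2, 0.2, 0.3), 4)
  expect_equal(steady_state_abundance(0, 0.5), 0)
  expect_equal(steady_state_abundance(3, 0, 0.2),
               2 * steady_state_abundance(3, 0, 0.4))
  expect_error(steady_state_abundance(1, 0, 0), "positive")
})

test_that("normalised abundance degenerates correctly for flat input and R = 1", {
  set.seed(2)
  for (i in 1:100) {
    td <- runif(1, 0.5, 23.5)
    R <- runif(1, 0.3, 4)
    lvl <- runif(1, 0.2, 5)
    expect_equal(normalised_abundance(constant_profile(lvl), td, R), lvl,
                 tolerance = 1e-9 * lvl)
  }
  shapes <- list(waveform_spec("cosine", 17, 1.9),
                 waveform_spec("rect_pulse", 4, 12, width_h = 2),
                 waveform_spec("gaussian_bump", 11, 3, width_h = 4))
  for (w in shapes) {
    p <- gen_transcript_profile(w)
    expect_equal(normalised_abundance(p, 7.21, R = 1), daily_mean(p),
                 tolerance = 1e-9)
  }
})

test_that("P_normalised responds to R in the direction of the light/dark contrast", {
  set.seed(3)
  for (i in 1:20) {
    p <- gen_transcript_profile(waveform_spec("cosine", runif(1, 0, 24),
                                              runif(1, 1.1, 2)))
    td <- runif(1, 2, 22)
    R <- runif(1, 0.5, 3)
    ab <- light_dark_integrals(p, td)
    contrast <- ab["light"] / td - ab["dark"] / (24 - td)
    dPdR <- (normalised_abundance(p, td, R + 1e-6) -
               normalised_abundance(p, td, R - 1e-6)) / 2e-6
    expect_equal(sign(dPdR), sign(unname(contrast)))
  }
})

test_that("relative change is antisymmetric, bounded and matches examples", {
  expect_equal(relative_change(1, 1), 0)
  expect_equal(relative_change(1, 3), 1)
  set.seed(4)
  p1 <- runif(50, 0.01, 10); p2 <- runif(50, 0.01, 10)
  expect_equal(relative_change(p1, p2), -relative_change(p2, p1))
  expect_true(all(abs(relative_change(p1, p2)) < 2))
  expect_error(relative_change(0, 0), "positive")
})

test_that("entrainment shifts the peak by the dusk-sensitivity rule", {
  p <- gen_transcript_profile(waveform_spec("cosine", 12, 2))
  expect_equal(peak_phase(entrain_profile(p, 18, 0)), 12)
  expect_equal(peak_phase(entrain_profile(p, 18, 1)), 18)
  expect_equal(peak_phase(entrain_profile(p, 18, 0.5)), 15)
  expect_equal(peak_phase(entrain_profile(p, 6, 1)), 6)
  # daily mean is preserved by the rigid shift
  expect_equal(daily_mean(entrain_profile(p, 18, 0.73)), daily_mean(p),
               tolerance = 1e-9)
  # tabulated profiles shift identically when the shift is a grid multiple
  tab <- transcript_profile("g", p$times, p$values)
  expect_equal(entrain_profile(tab, 18, 0.5)$values,
               entrain_profile(p, 18, 0.5)$values, tolerance = 1e-9)
})

test_that("predict_response composes the elementary operations", {
  coh <- gen_transcript_cohort(5, seed = 8)
  res <- predict_response(coh, c(6, 18), R = 1.4)
  g3 <- coh[[3]]
  direct6 <- normalised_abundance(g3, 6, 1.4)
  direct18 <- normalised_abundance(g3, 18, 1.4)
  expect_equal(res$predictions$p_normalised[
    res$predictions$gene_id == g3$gene_id &
      res$predictions$photoperiod_h == 6], direct6)
  expect_equal(res$delta$delta_p[res$delta$gene_id == g3$gene_id],
               delta_oracle(direct6, direct18))
  # constant cohort: all change scores are zero
  flat <- list(constant_profile(2), constant_profile(0.5))
  flat[[1]]$gene_id <- "a"; flat[[2]]$gene_id <- "b"
  expect_equal(predict_response(flat, c(6, 18))$delta$delta_p, c(0, 0),
               tolerance = 1e-12)
})

test_that("pulse cohort sign pattern follows the closed-form oracle", {
  phases <- seq(0, 22, by = 2)
  coh <- lapply(phases, function(ph)
    gen_transcript_profile(waveform_spec("rect_pulse", (ph + 1) %% 24, 12,
                                         width_h = 2),
                           gene_id = sprintf("p%02d", ph)))
  res <- predict_response(coh, c(6, 18), R = 1.4)
  for (i in seq_along(phases)) {
    start <- phases[i]
    lit6 <- start + 2 <= 6          # pulse [start, start+2) wholly lit at 6 h
    lit18 <- start + 2 <= 18
    dp <- res$delta$delta_p[i]
    if (lit6 && lit18) {
      oracle <- delta_oracle(pulse_pn_oracle(6, 1.4, TRUE),
                             pulse_pn_oracle(18, 1.4, TRUE))
      expect_equal(dp, oracle, tolerance = 1e-9)
      expect_lt(dp, 0)
    } else if (!lit6 && lit18) {
      oracle <- delta_oracle(pulse_pn_oracle(6, 1.4, FALSE),
                             pulse_pn_oracle(18, 1.4, TRUE))
      expect_equal(dp, oracle, tolerance = 1e-9)
      expect_gt(dp, 0)
    } else if (!lit6 && !lit18) {
      oracle <- delta_oracle(pulse_pn_oracle(6, 1.4, FALSE),
                             pulse_pn_oracle(18, 1.4, FALSE))
      expect_equal(dp, oracle, tolerance = 1e-9)
      # numerator fixed in the dark; the reference divisor grows with the
      # photoperiod, so relative abundance falls
      expect_lt(dp, 0)
    }
  }
})

test_that("coincidence_model methods expose a coherent surface", {
  coh <- gen_transcript_cohort(10, seed = 21)
  m <- coincidence_model(coh)
  expect_s3_class(m, "coincidence_model")
  expect_output(print(m), "translation ratio R = 1.4")
  expect_equal(coef(m), c(R = 1.4, dusk_sensitivity = 0))
  expect_equal(nrow(predict(m)), 40)
  expect_equal(nrow(predict(m, type = "delta")), 10)
  sm <- summary(m)
  expect_equal(sm$n_up + sm$n_down, 10)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
  # new photoperiods recompute on the fly
  p2 <- predict(m, photoperiods = c(4, 20))
  expect_equal(sort(unique(p2$photoperiod_h)), c(4, 20))
})
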