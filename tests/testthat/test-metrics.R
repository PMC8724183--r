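dt100 <- 1 / 100

test_that("log dimensionless jerk matches the quadrature oracle on minimum-jerk reaches", {
  for (case in list(c(L = 120, T = 0.8), c(L = 250, T = 1.4))) {
    pos <- min_jerk_positions(case["L"], case["T"], fs = 2000)
    got <- log_dimensionless_jerk(pos, case["T"] / (nrow(pos) - 1))
    expect_equal(got, ldlj_min_jerk_oracle(case["L"], case["T"]),
                 tolerance = 1e-3)
  }
})

test_that("log dimensionless jerk is invariant to spatial and temporal scaling", {
  pos <- min_jerk_positions(150, 1, fs = 500)
  ref <- log_dimensionless_jerk(pos, 1 / 500)
  expect_equal(log_dimensionless_jerk(2 * pos, 1 / 500), ref,
               tolerance = 1e-9)
  # stretching time: same samples, doubled dt
  expect_equal(log_dimensionless_jerk(pos, 2 / 500), ref, tolerance = 1e-9)
  expect_equal(log_dimensionless_jerk(5 * pos, 3 / 500), ref,
               tolerance = 1e-9)
})

test_that("log dimensionless jerk strictly increases with tremor amplitude", {
  base <- min_jerk_positions(150, 1, fs = 100)
  t <- seq(0, 1, length.out = nrow(base))
  vals <- vapply(c(0, 1, 2, 4, 8), function(a) {
    trem <- base
    trem[, 2] <- trem[, 2] + a * sin(2 * pi * 4 * t)
    log_dimensionless_jerk(trem, dt100)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("jerk computation rejects degenerate segments", {
  expect_error(log_dimensionless_jerk(matrix(1, 10, 3), dt100),
               class = "msrehab_degenerate_segment")
  expect_error(log_dimensionless_jerk(min_jerk_positions(10, 1, 100)[1:3, ],
                                      dt100),
               class = "msrehab_degenerate_segment")
})

test_that("spectral arc length is sampling-rate invariant and penalizes tremor", {
  v1 <- min_jerk_speed(150, 1.2, fs = 100)
  v2 <- min_jerk_speed(150, 1.2, fs = 400)
  s1 <- spectral_arc_length(v1, 1 / 100)
  s2 <- spectral_arc_length(v2, 1 / 400)
  expect_lt(abs(s1 - s2), 1e-2)
  # tremor makes the value strictly more negative
  t <- seq(0, 1.2, length.out = length(v1))
  vt <- v1 + 20 * abs(sin(2 * pi * 4 * t))
  expect_lt(spectral_arc_length(vt, 1 / 100), s1)
  # amplitude invariance
  expect_equal(spectral_arc_length(3.7 * v1, 1 / 100), s1)
  # constant nonzero speed: finite, no error
  expect_true(is.finite(spectral_arc_length(rep(5, 120), dt100)))
  expect_error(spectral_arc_length(rep(0, 120), dt100),
               class = "msrehab_degenerate_segment")
})

test_that("path length ratio recovers geometry", {
  straight <- cbind(seq(0, 100, length.out = 50), 0, 0)
  expect_equal(path_length_ratio(straight), 1, tolerance = 1e-12)
  theta <- seq(0, pi, length.out = 4000)
  semicircle <- cbind(50 * cos(theta), 50 * sin(theta), 0)
  expect_equal(path_length_ratio(semicircle), pi / 2, tolerance = 1e-3)
  # monotone in curvature gain
  tau <- seq(0, 1, length.out = 200)
  vals <- vapply(c(0, 0.1, 0.2, 0.4, 0.8), function(g) {
    path_length_ratio(cbind(100 * tau, g * 100 * sin(pi * tau), 0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(path_length_ratio(semicircle[c(1, 4000), ] * 0),
               class = "msrehab_degenerate_segment")
})

test_that("velocity_max matches analytic speeds", {
  pos <- cbind(seq(0, 100, by = 1), 0, 0)  # 100 mm/s at 100 Hz
  expect_equal(velocity_max(pos, dt100), 100)
  mj <- min_jerk_positions(200, 1.6, fs = 1000)
  expect_equal(velocity_max(mj, 1.6 / (nrow(mj) - 1)),
               1.875 * 200 / 1.6, tolerance = 0.01 * 1.875 * 200 / 1.6)
  expect_equal(velocity_max(matrix(3, 10, 3), dt100), 0)
})

test_that("RMS jerk is zero for uniform motion and grows with tremor", {
  pos <- cbind(seq(0, 100, length.out = 150), 0, 0)
  expect_equal(jerk_rms(pos, dt100), 0)
  t <- seq(0, 1.49, by = dt100)
  vals <- vapply(c(0.5, 1, 2, 4), function(a) {
    jerk_rms(pos + cbind(0, a * sin(2 * pi * 4 * t), 0), dt100)
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
  # sampling-density convergence: dense vs half sampling within 5 %
  f1 <- jerk_rms(min_jerk_positions(150, 1, fs = 400), 1 / 400)
  f2 <- jerk_rms(min_jerk_positions(150, 1, fs = 200), 1 / 200)
  expect_lt(abs(f1 - f2) / f1, 0.05)
})

test_that("force-rate peak counting honors prominence", {
  t <- seq(0, 2, by = dt100)
  ramp <- 5 * t
  expect_equal(force_rate_num_peaks(ramp, dt100), 0L)
  for (k in c(2, 4, 6)) {
    # k full force cycles over 2 s, phased so the force rate is sine-like:
    # exactly one interior prominent rate maximum per cycle
    sig <- 5 * t - 2 * cos(2 * pi * k / 2 * t)
    expect_equal(force_rate_num_peaks(sig, dt100, 0.1), k)
  }
  # sub-prominence ripples are ignored
  big <- 5 * t - 2 * cos(2 * pi * 1 * t)  # 2 cycles -> 2 prominent peaks
  expect_equal(force_rate_num_peaks(big + 1e-3 * sin(2 * pi * 9 * t),
                                    dt100, 0.1), 2L)
  expect_equal(force_rate_num_peaks(rep(1, 50), dt100), 0L)
})

test_that("force-rate SPARC penalizes oscillatory grip and ignores amplitude", {
  t <- seq(0, 1.5, by = dt100)
  bell <- 10 * sin(pi * t / 1.5)^2
  osc <- bell + 1.5 * sin(2 * pi * 7 * t)
  s_bell <- force_rate_sparc(bell, dt100)
  s_osc <- force_rate_sparc(osc, dt100)
  expect_lt(s_osc, s_bell)
  expect_equal(force_rate_sparc(10 * bell, dt100), s_bell)
  expect_error(force_rate_sparc(rep(2, 100), dt100),
               class = "msrehab_degenerate_segment")
})

test_that("zero-phase preprocessing preserves the passband and removes noise power", {
  t <- seq(0, 5, by = dt100)
  sine <- sin(2 * pi * 2 * t)
  trial <- vpit_trial(t, cbind(sine, 0, 0), rep(1, length(t)))
  flt <- preprocess_trial(trial, kinematic_cutoff = 10)
  core <- seq(50, length(t) - 50)  # avoid edge transients
  expect_lt(max(abs(flt$position[core, 1] - sine[core])), 0.01)
  # constant position passes unchanged
  const <- vpit_trial(t, matrix(5, length(t), 3), rep(1, length(t)))
  expect_equal(preprocess_trial(const)$position, const$position,
               tolerance = 1e-5)
  # white-noise force loses variance
  set.seed(42)
  noisy <- vpit_trial(t, matrix(0, length(t), 3), abs(rnorm(length(t))) + 5)
  flt2 <- preprocess_trial(noisy, force_cutoff = 20)
  expect_lt(var(flt2$grip_force), var(noisy$grip_force))
  expect_error(preprocess_trial(trial, kinematic_cutoff = 60),
               class = "msrehab_parameter_error")
})
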