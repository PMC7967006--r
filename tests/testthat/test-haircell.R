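# closed-form step response used as the oracle for the discrete filters
step_response_closed_form <- function(t_ms, A, p) {
  A * (p$G_f * exp(-t_ms / (p$tau_f_s * 1000)) +
         p$G_s * exp(-t_ms / (p$tau_s_s * 1000)))
}

test_that("adaptation response to a step matches the closed form", {
  p <- adaptation_params(G_f = 2.6, G_s = 0.8, anodic_fast_attenuation = 1)
  w <- make_step(-10, onset_ms = 0, duration_ms = 20000, total_ms = 20000,
                 dt_ms = 10)
  fr <- adaptation_response(w, p)
  expected <- step_response_closed_form(w$t, 10, p)
  # the step is half-open, so the final sample has returned to zero drive
  keep <- seq_len(length(fr) - 1)
  expect_equal(fr[keep], expected[keep], tolerance = 1e-8)
  # onset value is the summed gain times the amplitude
  expect_equal(fr[1], 10 * (2.6 + 0.8), tolerance = 1e-8)
})

test_that("zero stimulus produces zero adaptation", {
  p <- adaptation_params()
  w <- make_zero(5000, dt_ms = 10)
  expect_true(all(adaptation_response(w, p) == 0))
})

test_that("adaptation is complete: the transient returns to baseline", {
  p <- adaptation_params(G_f = 2.6, G_s = 0.8)
  w <- make_step(-10, onset_ms = 0, duration_ms = 30000, total_ms = 30000,
                 dt_ms = 10)
  fr <- adaptation_response(w, p)
  expect_lt(abs(fr[w$t >= 10 * p$tau_s_s * 1000][1]), 0.5)
})

test_that("anodic steps recruit an attenuated fast component", {
  p <- adaptation_params(G_f = 2, G_s = 1, anodic_fast_attenuation = 0.5)
  cath <- adaptation_response(
    make_step(-10, 0, 10000, 10000, dt_ms = 10), p)
  anod <- adaptation_response(
    make_step(10, 0, 10000, 10000, dt_ms = 10), p)
  # cathodic onset: (G_f + G_s) A; anodic onset: (0.5 G_f + G_s) (-A)
  expect_equal(cath[1], 30, tolerance = 1e-8)
  expect_equal(anod[1], -20, tolerance = 1e-8)
})

test_that("linearity holds on steps and sinusoids", {
  p <- adaptation_params(anodic_fast_attenuation = 1)
  w1 <- make_sinusoid(5, 0.5, 5, dt_ms = 10)
  w2 <- make_sinusoid(10, 0.5, 5, dt_ms = 10)
  expect_equal(2 * adaptation_response(w1, p), adaptation_response(w2, p),
               tolerance = 1e-10)
})

test_that("transfer function obeys its closed-form limits", {
  p <- adaptation_params(G_f = 2.6, G_s = 0.8)
  lowf <- transfer_function(1e-6, p)
  expect_lt(lowf$gain, 1e-4)
  expect_equal(lowf$phase_deg, 90, tolerance = 0.01)

  # single fast pole without the low-pass: at f = 1/(2 pi tau_f) the
  # gain is G_f/sqrt(2) and the phase +45 degrees
  p1 <- adaptation_params(G_f = 2.6, G_s = 0, f_c_hz = 1e12)
  fc <- 1 / (2 * pi * p1$tau_f_s)
  tf <- transfer_function(fc, p1)
  expect_equal(tf$gain, 2.6 / sqrt(2), tolerance = 1e-6)
  expect_equal(tf$phase_deg, 45, tolerance = 1e-4)
})

test_that("phase lead is positive at low frequency and decays by 4-8 Hz", {
  p <- adaptation_params(G_f = 2.6, G_s = 0.8)
  tf <- transfer_function(c(0.1, 1, 4, 8, 25), p)
  expect_gt(tf$phase_deg[1], 30)
  expect_true(all(diff(tf$phase_deg) < 0))
  expect_lt(tf$phase_deg[tf$freq_hz == 8], 10)
})

test_that("discrete-filter frequency response matches the transfer function", {
  # FFT of the impulse response of the time-domain implementation,
  # compared with the closed form across 0.01-100 Hz
  p <- adaptation_params(G_f = 2.6, G_s = 0.8, anodic_fast_attenuation = 1,
                         f_c_hz = 1e12)
  dt_ms <- 1
  n <- 2^21                       # ~35 minutes of record at 1 ms
  x <- numeric(n)
  x[1] <- 1 / (dt_ms / 1000)      # unit-area impulse in 1/s units
  w <- new_stimulus(seq(0, by = dt_ms, length.out = n), -x, dt_ms,
                    "step", list())
  h <- adaptation_response(w, p)
  H <- stats::fft(h) * (dt_ms / 1000)
  freqs <- (seq_len(n) - 1) / (n * dt_ms / 1000)
  pick <- which(freqs >= 0.01 & freqs <= 100)
  ref <- transfer_function(freqs[pick], p, include_lowpass = FALSE)
  expect_equal(Mod(H[pick]), ref$gain, tolerance = 0.01)
  expect_equal(Arg(H[pick]) * 180 / pi, ref$phase_deg, tolerance = 0.01)
})

test_that("combined rate clips to the firing range", {
  fr_ad <- c(-30, 0, 10, 100)
  expect_equal(combined_rate(fr_ad, 20, fr_max = 55), c(0, 20, 30, 55))
  expect_equal(combined_rate(rep(0, 3), c(10, 60, 70), fr_max = 55),
               c(10, 55, 55))
  expect_error(combined_rate(1, 1, fr_max = 0), "fr_max")
})

test_that("narrow-range clipping reproduces the baseline-dependent asymmetry", {
  # rate-level analysis of the explant preparation: the axonal
  # contribution is the resting rate plus a non-adapting baseline
  # offset of about 2 spikes/s per uA of cathodic current; the
  # adaptation transient rides on top and the sum is clipped to the
  # narrow 0-55 spikes/s range
  p <- adaptation_params(G_f = 2.6, G_s = 0.8)
  fr_o <- 17
  fr_axon <- function(w) fr_o + 2 * (-w$i_ext)

  # anodic baseline lowers the working point to zero: further anodic
  # steps plateau at the zero floor
  w_an <- make_baseline_step(10, 10, 15000, 5000, dt_ms = 10)
  fr_an <- combined_rate(adaptation_response(w_an, p), fr_axon(w_an),
                         fr_max = 55)
  seg <- w_an$t >= 15000 & w_an$t < 20000
  expect_true(all(fr_an[seg] == 0))

  # cathodic baseline raises it toward the ceiling: further cathodic
  # steps plateau at the 55 spikes/s maximum
  w_ca <- make_baseline_step(-10, -10, 15000, 5000, dt_ms = 10)
  fr_ca <- combined_rate(adaptation_response(w_ca, p), fr_axon(w_ca),
                         fr_max = 55)
  expect_true(all(fr_ca[w_ca$t >= 15000 & w_ca$t <= 16000] == 55))

  # without clipping, the linear (symmetric-gain) adaptation responds
  # to a step identically from every baseline
  p_lin <- adaptation_params(G_f = 2.6, G_s = 0.8,
                             anodic_fast_attenuation = 1)
  resp_from_baseline <- function(base) {
    w <- make_baseline_step(base, -10, 15000, 5000, dt_ms = 10)
    fr <- adaptation_response(w, p_lin)
    fr[w$t >= 15000] - fr[w$t >= 15000][1]
  }
  # a ~1e-5 relative residue of the baseline-onset transient remains
  expect_equal(resp_from_baseline(0), resp_from_baseline(10),
               tolerance = 1e-3)
  expect_equal(resp_from_baseline(0), resp_from_baseline(-10),
               tolerance = 1e-3)
})

test_that("gain fitting recovers known parameters exactly without noise", {
  truth <- adaptation_params(G_f = 2.2, G_s = 0.7)
  w <- make_step(-10, 2000, 18000, 20000, dt_ms = 10)
  y <- adaptation_response(w, truth)
  fit <- fit_adaptation_gains(y, w, adaptation_params(G_f = 1, G_s = 1))
  expect_equal(fit$G_f, 2.2, tolerance = 1e-6)
  expect_equal(fit$G_s, 0.7, tolerance = 1e-6)
  expect_lt(attr(fit, "residual_norm"), 1e-6)
})

test_that("gain fitting is robust to noise across seeds", {
  truth <- adaptation_params(G_f = 2.2, G_s = 0.7)
  w <- make_step(-10, 2000, 18000, 20000, dt_ms = 10)
  clean <- adaptation_response(w, truth)
  peak <- max(abs(clean))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- clean + rnorm(length(clean), sd = 0.1 * peak)
    fit <- fit_adaptation_gains(y, w, adaptation_params(G_f = 1, G_s = 1))
    max(abs(fit$G_f - 2.2) / 2.2, abs(fit$G_s - 0.7) / 0.7)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
  expect_gt(mean(errs < 0.15), 0.8)
})

test_that("degenerate traces are rejected by the fitter", {
  w <- make_zero(1000, dt_ms = 10)
  expect_error(fit_adaptation_gains(rep(1, length(w$t)), w),
               "degenerate")
})
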