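test_that("spike statistics are exact on constructed trains", {
  per <- generate_fixtures("periodic_train",
                           list(isi_ms = 10, total_ms = 10000))
  st <- spike_statistics(per, 10000)
  expect_equal(st$mean_rate, 100)
  expect_equal(st$mean_isi, 10)
  expect_equal(st$cv, 0)

  # alternating ISIs a, b have CV = |a-b|/(a+b)
  alt <- cumsum(rep(c(5, 15), 500))
  st2 <- spike_statistics(alt, max(alt))
  expect_equal(st2$cv, 0.5, tolerance = 1e-3)
  expect_equal(st2$mean_rate * st2$mean_isi, 1000, tolerance = 1e-10)

  st3 <- spike_statistics(c(5), 1000)
  expect_equal(st3$mean_rate, 1)
  expect_true(is.na(st3$cv))
})

test_that("a homogeneous Poisson train has CV near 1", {
  st <- spike_statistics(
    generate_fixtures("poisson_train",
                      list(rate_sps = 100, total_ms = 1e5), seed = 21),
    1e5)
  expect_gt(st$n_spikes, 9000)
  # CV of exponential ISIs: sd/mean -> 1, SE of CV ~ 1/sqrt(n)
  expect_lt(abs(st$cv - 1), 3 / sqrt(st$n_spikes))
})

test_that("envelope conformance counts points between the curves", {
  env <- cv_star_envelope(c(1, 100), c(0.2, 0.2), c(0.6, 0.6))
  mid <- data.frame(isi_ms = seq(5, 50, by = 5), cv = 0.4)
  expect_equal(as.numeric(cv_star_conformance(mid, env)), 1)
  above <- data.frame(isi_ms = seq(5, 50, by = 5), cv = 0.9)
  expect_equal(as.numeric(cv_star_conformance(above, env)), 0)
  half <- rbind(mid, above)
  expect_equal(as.numeric(cv_star_conformance(half, env)), 0.5)
  out_dom <- rbind(mid, data.frame(isi_ms = 1000, cv = 0.4))
  expect_warning(frac <- cv_star_conformance(out_dom, env), "excluded")
  expect_equal(attr(frac, "n_excluded"), 1)
  expect_equal(as.numeric(frac), 1)
})

test_that("the synthetic default envelope is ordered and monotone", {
  env <- default_cv_star_envelope()
  expect_true(all(env$upper_cv >= env$lower_cv))
  expect_true(all(diff(env$lower_cv) > 0))
  expect_identical(env$source, "synthetic")
})

test_that("response slope recovers an exact line with a collapsing CI", {
  amps <- seq(-40, 40, by = 10)
  d <- expand.grid(neuron = 1:5, amplitude_uA = amps)
  d$rate_sps <- 100 - 2 * d$amplitude_uA
  rs <- response_slope(d, n_boot = 200, seed = 1)
  expect_equal(rs$slope, -2, tolerance = 1e-10)
  expect_lt(diff(rs$ci), 1e-10)
  expect_true(rs$ci[1] <= rs$slope && rs$slope <= rs$ci[2])
})

test_that("degenerate flat responses are flagged", {
  d <- expand.grid(neuron = 1:4, amplitude_uA = c(-10, 0, 10))
  d$rate_sps <- 50
  rs <- response_slope(d, n_boot = 100)
  expect_equal(rs$slope, 0)
  expect_true(rs$degenerate)
})

test_that("bootstrap CI covers the true slope at near-nominal rate", {
  amps <- seq(-40, 40, by = 10)
  hits <- vapply(1:100, function(rep) {
    set.seed(rep + 400)
    d <- expand.grid(neuron = 1:19, amplitude_uA = amps)
    d$rate_sps <- 100 - 1.5 * d$amplitude_uA + rnorm(nrow(d), sd = 5)
    rs <- response_slope(d, n_boot = 300, seed = rep)
    rs$ci[1] <= -1.5 && -1.5 <= rs$ci[2]
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("double-exponential step fits recover known parameters", {
  fx <- generate_fixtures("double_exp_rate_trace",
                          list(G_f = 2.6, G_s = 0.8, tau_f_s = 0.15,
                               tau_s_s = 2, amplitude_uA = 10,
                               baseline = 20, shift = 18,
                               onset_ms = 1000, total_ms = 16000,
                               dt_ms = 10, noise_sd = 0))
  fit <- fit_step_response(fx$rate, dt_ms = 10, stim_onset_ms = 1000,
                           amplitude_uA = 10)
  expect_equal(fit$G_f, 2.6, tolerance = 1e-4)
  expect_equal(fit$G_s, 0.8, tolerance = 1e-4)
  expect_equal(fit$tau_f_s, 0.15, tolerance = 1e-4)
  expect_equal(fit$tau_s_s, 2, tolerance = 1e-4)
  expect_equal(fit$baseline, 20, tolerance = 1e-6)
  # the persistent offset is reported on the rate scale, unscaled
  expect_equal(fit$baseline_shift, 18, tolerance = 1e-3)
})

test_that("cycle metrics recover the phase of a modulated train", {
  f <- 1
  stim <- make_sinusoid(10, f, 100, dt_ms = 1)
  # target a 30 degree lead: response peak 30 deg before the cathodic
  # peak (270 deg), i.e. peak at 240 deg => r0 + r1 sin(wt - 150 deg)
  tr <- generate_fixtures(
    "sinusoidal_poisson_train",
    list(r0 = 100, r1 = 40, freq_hz = f, phase_deg = -150,
         total_ms = max(stim$t)),
    seed = 5)
  cm <- cycle_metrics(tr, stim)
  expect_gt(cm$n_spikes, 5000)
  expect_equal(cm$phase_lead_deg, 30, tolerance = 5)
  expect_gt(cm$cathodic_rate, cm$anodic_rate)
})

test_that("unmodulated trains give equal half-cycle rates", {
  stim <- make_sinusoid(10, 1, 50, dt_ms = 1)
  tr <- generate_fixtures("poisson_train",
                          list(rate_sps = 80, total_ms = max(stim$t)),
                          seed = 9)
  cm <- cycle_metrics(tr, stim)
  expect_equal(cm$cathodic_rate, cm$anodic_rate, tolerance = 0.1)
  expect_lt(cm$vector_strength, 0.05)
  cm0 <- cycle_metrics(numeric(0), stim)
  expect_true(is.na(cm0$phase_lead_deg))
  expect_equal(cm0$cathodic_rate, 0)
})

test_that("cluster permutation test finds no clusters in identical data", {
  set.seed(2)
  a <- matrix(rnorm(8 * 120, mean = 50), nrow = 8)
  out <- cluster_permutation_test(a, a, n_perm = 200, seed = 3)
  expect_false(any(out$significant))
})

test_that("cluster permutation test localizes a strong offset segment", {
  set.seed(4)
  nt <- 200
  a <- matrix(rnorm(6 * nt, mean = 50, sd = 2), nrow = 6)
  b <- matrix(rnorm(6 * nt, mean = 50, sd = 2), nrow = 6)
  seg <- 81:120
  b[, seg] <- b[, seg] + 15
  out <- cluster_permutation_test(a, b, n_perm = 500, seed = 5)
  sig <- out[out$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$mass), ]
  expect_lt(abs(main$start - 81), 6)
  expect_lt(abs(main$end - 120), 6)
})

test_that("cluster permutation type-I error stays at the nominal level", {
  false_pos <- vapply(1:200, function(rep) {
    set.seed(rep + 900)
    a <- matrix(rnorm(6 * 80, mean = 10), nrow = 6)
    b <- matrix(rnorm(6 * 80, mean = 10), nrow = 6)
    out <- cluster_permutation_test(a, b, n_perm = 199)
    any(out$significant)
  }, logical(1))
  alpha_hat <- mean(false_pos)
  # alpha + 2 SE at alpha = 0.05, 200 runs
  expect_lte(alpha_hat, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("permutation test input contracts are enforced", {
  a <- matrix(rnorm(40), nrow = 4)
  expect_error(cluster_permutation_test(a, a, n_perm = 50), "at least 100")
  expect_error(cluster_permutation_test(a[1, , drop = FALSE], a),
               "at least 2")
})

test_that("rate traces integrate to the spike count and sit at the true rate", {
  trains <- lapply(1:4, function(i)
    generate_fixtures("poisson_train",
                      list(rate_sps = 60, total_ms = 20000), seed = i))
  rt <- rate_trace(trains, 20000, bin_ms = 10, smooth_ms = 100)
  expect_equal(dim(rt$rates), c(4, 2000))
  expect_equal(mean(rt$rates), 60, tolerance = 0.1)
})
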