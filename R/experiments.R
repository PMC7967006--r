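#' Amplitude-sweep experiment
#'
#' Simulates a population of afferents across a set of constant GVS
#' amplitudes and collects per-neuron firing statistics, the
#' rate-versus-current response curve with its bootstrap confidence
#' interval, and the population (ISI, CV) cloud. Each neuron keeps its
#' own EPSC seed across amplitudes. The current switches on at
#' `settle_ms` and statistics are computed from there to the end of the
#' record, so adaptation transients (when enabled) contribute to the
#' per-amplitude mean rate exactly as they do in step-response
#' recordings.
#'
#' @param variant model variant name (see [vestsim_params()])
#' @param amplitudes_uA electrode amplitudes (uA, cathodic negative)
#' @param n_neurons number of simulated neurons
#' @param duration_ms stimulated duration per condition (ms)
#' @param settle_ms pre-stimulus settling time (ms)
#' @param seed master seed; per-neuron seeds are derived from it
#' @param adaptation include the hair-cell adaptation pathway
#' @param params optional configuration overriding the named variant
#' @param fit_range_uA linear region used for the slope fit
#' @param n_boot bootstrap resamples for the slope CI
#' @param response_window_ms length of the post-onset window used for
#'   the firing statistics; `NULL` (default) uses the whole stimulated
#'   segment. A window of the order of the adaptation time constants
#'   captures the induced (pre-adaptation) response when the hair-cell
#'   pathway is enabled.
#' @param exclude_block restrict the slope fit to the linear region:
#'   amplitudes no more cathodic than the response peak (outside the
#'   cathodic block) at which all neurons fire
#' @return object of class `experiment_result`: list with `stats`
#'   (per neuron x amplitude), `curve` (a `response_curve`),
#'   `per_amplitude`, `spontaneous_rate`, `max_rate`,
#'   `max_rate_amplitude`, and `config`
#' @export
run_amplitude_sweep <- function(variant = "original_hk",
                                amplitudes_uA = seq(-100, 100, by = 5),
                                n_neurons = 19, duration_ms = 10000,
                                settle_ms = 500, seed = 1,
                                adaptation = FALSE, params = NULL,
                                fit_range_uA = c(-45, 45), n_boot = 500,
                                response_window_ms = NULL,
                                exclude_block = TRUE) {
  p <- if (is.null(params)) vestsim_params(variant) else params
  seeds <- neuron_seeds(seed, n_neurons)
  total_ms <- settle_ms + duration_ms
  win_end <- if (is.null(response_window_ms)) total_ms else
    min(total_ms, settle_ms + response_window_ms)
  rows <- vector("list", length(amplitudes_uA) * n_neurons)
  k <- 0
  for (amp in amplitudes_uA) {
    stim <- make_step(amp, onset_ms = settle_ms, duration_ms = duration_ms,
                      total_ms = total_ms, dt_ms = p$dt_ms)
    for (j in seq_len(n_neurons)) {
      sim <- simulate_afferent(p, stim, seed = seeds[j] + amp_offset(amp),
                               adaptation = adaptation)
      st <- spike_statistics(sim$spike_times, c(settle_ms, win_end))
      k <- k + 1
      rows[[k]] <- data.frame(neuron = j, amplitude_uA = amp,
                              rate_sps = st$mean_rate,
                              mean_isi = st$mean_isi, cv = st$cv,
                              n_spikes = st$n_spikes)
    }
  }
  stats_df <- do.call(rbind, rows)
  all_amp <- stats::aggregate(rate_sps ~ amplitude_uA, stats_df, mean)
  imax <- which.max(all_amp$rate_sps)
  if (exclude_block) {
    # fit the linear region: between anodic silencing and cathodic block
    fit_range_uA[1] <- max(fit_range_uA[1], all_amp$amplitude_uA[imax])
  }
  n_in_range <- sum(unique(stats_df$amplitude_uA) >= fit_range_uA[1] &
                      unique(stats_df$amplitude_uA) <= fit_range_uA[2])
  curve <- if (n_in_range >= 3)
    response_slope(stats_df, fit_range_uA = fit_range_uA,
                   n_boot = n_boot, seed = seed,
                   positive_rates_only = TRUE)
  sd_amp <- stats::aggregate(rate_sps ~ amplitude_uA, stats_df, stats::sd)
  per_amp <- data.frame(amplitude_uA = all_amp$amplitude_uA,
                        mean_rate = all_amp$rate_sps,
                        sd_rate = sd_amp$rate_sps)
  spont <- if (0 %in% amplitudes_uA)
    mean(stats_df$rate_sps[stats_df$amplitude_uA == 0]) else NA_real_
  structure(list(stats = stats_df, curve = curve, per_amplitude = per_amp,
                 spontaneous_rate = spont,
                 max_rate = all_amp$rate_sps[imax],
                 max_rate_amplitude = all_amp$amplitude_uA[imax],
                 config = list(experiment = "amplitude_sweep",
                               variant = p$variant,
                               amplitudes_uA = amplitudes_uA,
                               n_neurons = n_neurons,
                               duration_ms = duration_ms,
                               settle_ms = settle_ms, seed = seed,
                               adaptation = adaptation,
                               response_window_ms = response_window_ms)),
            class = "experiment_result")
}

#' Long-step adaptation experiment
#'
#' Delivers long GVS steps (optionally on top of a baseline current)
#' and returns population rate traces per condition, the
#' double-exponential fit of the mean step response, and the
#' cluster-based permutation comparison between the cathodic and anodic
#' conditions.
#'
#' @param variant model variant name
#' @param step_uA step amplitudes, one condition each (uA)
#' @param baseline_uA constant current during the pre-step segment and
#'   under the step (uA)
#' @param n_neurons neurons per condition
#' @param pre_ms,step_ms pre-step and step durations (ms)
#' @param seed master seed
#' @param adaptation include the hair-cell pathway
#' @param params optional configuration override
#' @param bin_ms,smooth_ms rate-trace binning and boxcar width (ms)
#' @param n_perm permutations for the cluster statistic
#' @return object of class `experiment_result`: list with `t`
#'   (trace grid, ms), `traces` (list of neuron x time matrices, one
#'   per step amplitude), `fits` (per condition, from
#'   [fit_step_response()]), `clusters` (cathodic vs anodic, when both
#'   polarities are present), and `config`
#' @export
run_adaptation_step <- function(variant = "invitro_low_conductance",
                                step_uA = c(-10, 10), baseline_uA = 0,
                                n_neurons = 10, pre_ms = 2000,
                                step_ms = 10000, seed = 1,
                                adaptation = TRUE, params = NULL,
                                bin_ms = 10, smooth_ms = 100,
                                n_perm = 500) {
  p <- if (is.null(params)) vestsim_params(variant) else params
  seeds <- neuron_seeds(seed, n_neurons * length(step_uA))
  total_ms <- pre_ms + step_ms
  traces <- list()
  fits <- list()
  for (ci in seq_along(step_uA)) {
    stim <- make_baseline_step(baseline_uA, step_uA[ci], pre_ms, step_ms,
                               dt_ms = p$dt_ms)
    trains <- lapply(seq_len(n_neurons), function(j)
      simulate_afferent(p, stim,
                        seed = seeds[(ci - 1) * n_neurons + j],
                        adaptation = adaptation)$spike_times)
    rt <- rate_trace(trains, total_ms, bin_ms = bin_ms,
                     smooth_ms = smooth_ms)
    key <- format_uA(step_uA[ci])
    traces[[key]] <- rt$rates
    fits[[key]] <- tryCatch(
      fit_step_response(colMeans(rt$rates), dt_ms = bin_ms,
                        stim_onset_ms = pre_ms,
                        amplitude_uA = -step_uA[ci]),
      error = function(e) e)
    t_grid <- rt$t
  }
  clusters <- NULL
  neg <- which(step_uA < 0)[1]
  pos <- which(step_uA > 0)[1]
  if (!is.na(neg) && !is.na(pos))
    clusters <- cluster_permutation_test(
      traces[[format_uA(step_uA[neg])]],
      traces[[format_uA(step_uA[pos])]],
      n_perm = n_perm, seed = seed)
  structure(list(t = t_grid, traces = traces, fits = fits,
                 clusters = clusters,
                 config = list(experiment = "adaptation_step",
                               variant = p$variant, step_uA = step_uA,
                               baseline_uA = baseline_uA,
                               n_neurons = n_neurons, pre_ms = pre_ms,
                               step_ms = step_ms, seed = seed,
                               adaptation = adaptation)),
            class = "experiment_result")
}

#' Sinusoidal frequency-sweep experiment
#'
#' Delivers sinusoidal GVS at a set of frequencies and measures the
#' cathodic/anodic half-cycle rates and the phase of the response for
#' each simulated neuron. Record length is at least 5 full cycles and
#' at least `min_ms`.
#'
#' @param variant model variant name
#' @param freqs_hz sinusoid frequencies (Hz)
#' @param amplitude_uA sinusoid amplitude (uA)
#' @param n_neurons neurons per frequency
#' @param seed master seed
#' @param adaptation include the hair-cell pathway
#' @param t_dmu_factor multiple of `mu0` used as the vesicle-release
#'   update interval (values > 1 act as a low-pass filter)
#' @param params optional configuration override
#' @param min_cycles,min_ms minimum record length constraints
#' @return object of class `experiment_result`: list with `metrics`
#'   (per neuron x frequency), `per_frequency` summary, and `config`
#' @export
run_sine_sweep <- function(variant = "invitro_low_conductance",
                           freqs_hz = c(0.1, 0.5, 1, 2, 4, 8),
                           amplitude_uA = 10, n_neurons = 10, seed = 1,
                           adaptation = TRUE, t_dmu_factor = 1,
                           params = NULL, min_cycles = 5, min_ms = 20000) {
  p <- if (is.null(params)) vestsim_params(variant) else params
  seeds <- neuron_seeds(seed, n_neurons)
  rows <- list()
  for (f in freqs_hz) {
    n_cyc <- max(min_cycles, ceiling(min_ms * f / 1000))
    stim <- make_sinusoid(amplitude_uA, f, n_cyc, dt_ms = p$dt_ms)
    for (j in seq_len(n_neurons)) {
      sim <- simulate_afferent(p, stim, seed = seeds[j] + round(1000 * f),
                               adaptation = adaptation,
                               t_dmu_factor = t_dmu_factor)
      cm <- cycle_metrics(sim$spike_times, stim)
      rows[[length(rows) + 1]] <- data.frame(
        neuron = j, freq_hz = f, cathodic_rate = cm$cathodic_rate,
        anodic_rate = cm$anodic_rate,
        phase_lead_deg = cm$phase_lead_deg,
        vector_strength = cm$vector_strength, n_spikes = cm$n_spikes)
    }
  }
  metrics <- do.call(rbind, rows)
  per_freq <- stats::aggregate(
    cbind(cathodic_rate, anodic_rate, phase_lead_deg) ~ freq_hz,
    metrics, mean, na.rm = TRUE)
  structure(list(metrics = metrics, per_frequency = per_freq,
                 config = list(experiment = "sine_sweep",
                               variant = p$variant, freqs_hz = freqs_hz,
                               amplitude_uA = amplitude_uA,
                               n_neurons = n_neurons, seed = seed,
                               adaptation = adaptation,
                               t_dmu_factor = t_dmu_factor)),
            class = "experiment_result")
}

#' Full combined-model experiment
#'
#' Runs the closed-loop model — hair-cell adaptation retargeting
#' vesicle release, stochastic EPSC drive, and the high-conductance
#' axon with the non-quantal gain — across an amplitude sweep at the
#' fast resting EPSC interval that produces the high spontaneous rate
#' of intact preparations.
#'
#' @param amplitudes_uA electrode amplitudes (uA)
#' @param n_neurons,duration_ms,seed as in [run_amplitude_sweep()]
#' @param mu0_ms resting mean inter-EPSC interval for the combined
#'   model (ms)
#' @param fr_o corresponding resting firing rate (spikes/s)
#' @param fit_range_uA linear region for the slope fit
#' @return an `experiment_result` from [run_amplitude_sweep()]
#' @export
run_full_invivo <- function(amplitudes_uA = seq(-50, 50, by = 5),
                            n_neurons = 19, duration_ms = 10000,
                            seed = 1, mu0_ms = 0.55, fr_o = 120,
                            fit_range_uA = c(-45, 45),
                            response_window_ms = 1000) {
  p <- vestsim_params("invivo_high_conductance")
  p$epsc$mu0_ms <- mu0_ms
  p$epsc$t_dmu_ms <- mu0_ms
  p$fr_o <- fr_o
  run_amplitude_sweep(amplitudes_uA = amplitudes_uA,
                      n_neurons = n_neurons, duration_ms = duration_ms,
                      seed = seed, adaptation = TRUE, params = p,
                      fit_range_uA = fit_range_uA,
                      response_window_ms = response_window_ms)
}

#' Synthetic test fixtures with known statistics
#'
#' Deterministic (seeded) generators of spike trains, EPSC trains and
#' rate traces whose ground-truth statistics are known in closed form,
#' for testing the analysis functions.
#'
#' @param kind one of `periodic_train`, `poisson_train`,
#'   `sinusoidal_poisson_train`, `double_exp_rate_trace`, `epsc_train`
#' @param params named list of generator parameters (see Details)
#' @param seed integer seed
#' @details Parameters by kind (all times ms, rates spikes/s):
#' * `periodic_train`: `isi_ms`, `total_ms` — CV is exactly 0.
#' * `poisson_train`: `rate_sps`, `total_ms` — CV tends to 1.
#' * `sinusoidal_poisson_train`: `r0`, `r1`, `freq_hz`, `phase_deg`,
#'   `total_ms` — inhomogeneous Poisson with rate
#'   `r0 + r1 sin(2 pi f t + phase)`, generated by thinning.
#' * `double_exp_rate_trace`: `G_f`, `G_s`, `tau_f_s`, `tau_s_s`,
#'   `amplitude_uA`, `baseline`, `shift`, `onset_ms`, `total_ms`,
#'   `dt_ms`, `noise_sd` — the adaptation step response plus offset.
#' * `epsc_train`: `mu0_ms`, `total_ms` — renewal EPSC times.
#' @return spike/event time vector, or for `double_exp_rate_trace` a
#'   list with `t`, `rate` and the ground-truth parameters
#' @export
generate_fixtures <- function(kind, params = list(), seed = 1) {
  set.seed(seed)
  pr <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  switch(
    kind,
    periodic_train = {
      isi <- pr("isi_ms", 10)
      seq(isi, pr("total_ms", 1000), by = isi)
    },
    poisson_train = {
      rate <- pr("rate_sps", 100)
      total <- pr("total_ms", 1000)
      n <- stats::rpois(1, rate * total / 1000 * 1.2) +
        ceiling(3 * sqrt(rate * total / 1000)) + 10
      st <- cumsum(stats::rexp(n, rate = rate / 1000))
      st[st <= total]
    },
    sinusoidal_poisson_train = {
      r0 <- pr("r0", 50); r1 <- pr("r1", 25)
      f <- pr("freq_hz", 1); ph <- pr("phase_deg", 0) * pi / 180
      total <- pr("total_ms", 10000)
      rmax <- r0 + abs(r1)
      cand <- cumsum(stats::rexp(ceiling(rmax * total / 1000 * 1.5) + 50,
                                 rate = rmax / 1000))
      cand <- cand[cand <= total]
      lambda <- r0 + r1 * sin(2 * pi * f * cand / 1000 + ph)
      cand[stats::runif(length(cand)) < lambda / rmax]
    },
    double_exp_rate_trace = {
      onset <- pr("onset_ms", 1000)
      total <- pr("total_ms", 15000)
      dt <- pr("dt_ms", 10)
      amp <- pr("amplitude_uA", 10)
      t <- seq(0, total, by = dt)
      ts_s <- pmax(t - onset, 0) / 1000
      rate <- pr("baseline", 20) +
        ifelse(t >= onset,
               pr("shift", 0) +
                 amp * (pr("G_f", 2.6) * exp(-ts_s / pr("tau_f_s", 0.15)) +
                          pr("G_s", 0.8) * exp(-ts_s / pr("tau_s_s", 2))),
               0) +
        stats::rnorm(length(t), sd = pr("noise_sd", 0))
      list(t = t, rate = rate,
           truth = list(G_f = pr("G_f", 2.6), G_s = pr("G_s", 0.8),
                        tau_f_s = pr("tau_f_s", 0.15),
                        tau_s_s = pr("tau_s_s", 2),
                        baseline = pr("baseline", 20),
                        shift = pr("shift", 0),
                        amplitude_uA = amp, onset_ms = onset,
                        dt_ms = dt))
    },
    epsc_train = draw_epsc_times(pr("mu0_ms", 3), pr("total_ms", 1000)),
    stop("unknown fixture kind: ", kind)
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$config$experiment, "/", x$config$variant, "\n")
  if (!is.null(x$curve)) print(x$curve)
  if (!is.null(x$spontaneous_rate) && !is.na(x$spontaneous_rate))
    cat(sprintf("  spontaneous rate %.1f sps, max %.1f sps at %g uA\n",
                x$spontaneous_rate, x$max_rate, x$max_rate_amplitude))
  invisible(x)
}

# per-neuron seeds derived once from the master seed
neuron_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^30, n)
}

# deterministic per-amplitude seed offset so each condition sees an
# independent EPSC realization while neurons keep their identity
amp_offset <- function(amp) as.integer(round(1000 * (amp + 200)))

format_uA <- function(x) sprintf("%+g uA", x)
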