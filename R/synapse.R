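#' EPSC generator parameters
#'
#' Parameters of the stochastic excitatory postsynaptic current (EPSC)
#' drive from the hair cell. Event times form a renewal process with
#' exponential (memoryless) inter-arrival intervals of mean `mu0_ms`
#' (the inter-EPSC interval parameter); each event contributes a
#' biexponential unitary current normalized to unit peak and scaled to
#' `K_pA`. Under hair-cell adaptation the mean interval becomes
#' time-varying, re-evaluated every `t_dmu_ms`.
#'
#' @param mu0_ms mean inter-EPSC interval at rest (ms), > 0
#' @param K_pA EPSC peak-amplitude scale (pA), > 0; per-event peaks are
#'   lognormal with mean `K_pA`
#' @param t_dmu_ms update interval of the time-varying mean (ms);
#'   defaults to `mu0_ms`
#' @param tau_rise_ms,tau_decay_ms rise and decay time constants of the
#'   unitary EPSC template (ms)
#' @param amp_sdlog log-scale spread of the per-event amplitude
#'   distribution (0 gives constant amplitudes); the amplitude
#'   distribution is fixed — it is never modulated by the stimulus
#' @return an object of class `epsc_params`
#' @export
epsc_params <- function(mu0_ms = 3, K_pA = 100, t_dmu_ms = mu0_ms,
                        tau_rise_ms = 0.3, tau_decay_ms = 0.5,
                        amp_sdlog = 0.3) {
  stopifnot(mu0_ms > 0, K_pA > 0, t_dmu_ms > 0,
            tau_rise_ms > 0, tau_decay_ms > tau_rise_ms, amp_sdlog >= 0)
  structure(list(mu0_ms = mu0_ms, K_pA = K_pA, t_dmu_ms = t_dmu_ms,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 amp_sdlog = amp_sdlog),
            class = "epsc_params")
}

#' Draw per-event EPSC peak amplitudes
#'
#' Lognormal amplitudes with mean `K_pA` and log-scale spread
#' `amp_sdlog` (exactly `K_pA` everywhere when the spread is 0). The
#' amplitude process is one of the two fixed stochastic functions
#' defining the synapse; stimulation modulates arrival rate only.
#'
#' @param n number of events
#' @param params an [epsc_params()] object
#' @return numeric vector of peak amplitudes (pA)
#' @export
draw_epsc_amplitudes <- function(n, params) {
  stopifnot(inherits(params, "epsc_params"))
  if (params$amp_sdlog == 0) return(rep(params$K_pA, n))
  params$K_pA * stats::rlnorm(n, meanlog = -params$amp_sdlog^2 / 2,
                              sdlog = params$amp_sdlog)
}

#' Draw stochastic EPSC arrival times
#'
#' Generates a renewal event train with exponential inter-arrival
#' intervals whose mean follows the (possibly piecewise-constant)
#' profile `mu`. With a scalar `mu` the train is homogeneous; with a
#' vector, `mu[k]` is the mean interval on the k-th segment of length
#' `t_dmu_ms`. Identical `(mu, total_ms, seed)` give identical trains.
#'
#' @param mu mean inter-EPSC interval (ms): scalar, or one value per
#'   `t_dmu_ms` segment; all values must be > 0
#' @param total_ms duration (ms)
#' @param seed optional integer seed (applied with [set.seed()])
#' @param t_dmu_ms segment length when `mu` is a vector (ms)
#' @return sorted numeric vector of event times in `[0, total_ms]`
#' @export
draw_epsc_times <- function(mu, total_ms, seed = NULL, t_dmu_ms = total_ms) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("invalid parameter: mu must be finite and > 0 everywhere")
  stopifnot(total_ms > 0, t_dmu_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  cpp_draw_epsc_times(as.numeric(mu), t_dmu_ms, total_ms)
}

#' Render an EPSC event train as a synaptic current trace
#'
#' Superimposes one unit-peak biexponential template per event, scaled
#' by `K_pA`: `i_syn(t) = sum_k K * template(t - t_k)`. The rendered
#' trace is non-negative everywhere (the drive is excitatory only).
#'
#' @param event_times event arrival times (ms), inside the grid span
#' @param params an [epsc_params()] object
#' @param t_grid uniform time grid (ms) starting at 0
#' @param amplitudes optional per-event peak amplitudes (pA); default
#'   `K_pA` for every event
#' @return numeric vector of synaptic current (pA) on `t_grid`
#' @export
render_epsc_current <- function(event_times, params, t_grid,
                                amplitudes = NULL) {
  stopifnot(inherits(params, "epsc_params"))
  n <- length(t_grid)
  if (n < 2) stop("t_grid must have at least 2 samples")
  dt <- t_grid[2] - t_grid[1]
  if (length(event_times) == 0) return(numeric(n))
  if (any(event_times < t_grid[1]) || any(event_times > t_grid[n]))
    stop("event times fall outside the time grid")
  if (is.null(amplitudes)) amplitudes <- rep(params$K_pA, length(event_times))
  ord <- order(event_times)
  cpp_render_epsc(event_times[ord], amplitudes[ord],
                  n, dt, params$tau_rise_ms, params$tau_decay_ms)
}

#' Unitary EPSC template
#'
#' Unit-peak biexponential waveform used for every EPSC event.
#'
#' @param t time since the event (ms)
#' @param tau_rise_ms,tau_decay_ms template time constants (ms)
#' @return template values (dimensionless, peak 1)
#' @export
epsc_template <- function(t, tau_rise_ms = 0.3, tau_decay_ms = 0.5) {
  t_peak <- log(tau_decay_ms / tau_rise_ms) /
    (1 / tau_rise_ms - 1 / tau_decay_ms)
  peak <- exp(-t_peak / tau_decay_ms) - exp(-t_peak / tau_rise_ms)
  out <- (exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)) / peak
  out[t < 0] <- 0
  out
}

#' Map a target firing-rate series to an EPSC interval profile
#'
#' Implements the inverse-proportionality rule linking hair-cell
#' vesicle release to afferent firing: the mean inter-EPSC interval is
#' `mu0 * fr_o / fr_target`, anchored at the fixed point where a target
#' of `fr_o` spikes/s leaves the interval at `mu0`. The profile is
#' piecewise constant, re-evaluated only at multiples of `t_dmu_ms`
#' (vesicle packing and recycling cannot track the target
#' instantaneously), and clipped to `[mu_min, mu_max]`; the target rate
#' is floored at `fr_floor` to avoid division by zero.
#'
#' @param fr_target target firing-rate series (spikes/s), sampled at
#'   `dt_ms`
#' @param dt_ms sampling step of `fr_target` (ms)
#' @param mu0_ms resting mean inter-EPSC interval (ms)
#' @param fr_o resting firing rate anchoring the fixed point (spikes/s)
#' @param t_dmu_ms update interval (ms); must be >= `dt_ms`
#' @param fr_floor floor on the target rate (spikes/s)
#' @param mu_min,mu_max clip bounds on the interval (ms)
#' @return list with `mu` (one mean interval per segment, ms) and
#'   `t_dmu_ms`
#' @export
update_mu <- function(fr_target, dt_ms, mu0_ms, fr_o, t_dmu_ms = mu0_ms,
                      fr_floor = 0.5, mu_min = 0.05, mu_max = 1e4) {
  stopifnot(fr_o > 0, mu0_ms > 0, all(fr_target >= 0))
  if (t_dmu_ms < dt_ms)
    stop("t_dmu_ms must be at least the sampling step dt_ms")
  total_ms <- (length(fr_target) - 1) * dt_ms
  n_seg <- max(1L, ceiling(total_ms / t_dmu_ms))
  # sample the target at the start of each update interval
  idx <- pmin(length(fr_target),
              floor((seq_len(n_seg) - 1) * t_dmu_ms / dt_ms) + 1)
  fr_k <- pmax(fr_target[idx], fr_floor)
  mu <- pmin(pmax(mu0_ms * fr_o / fr_k, mu_min), mu_max)
  list(mu = mu, t_dmu_ms = t_dmu_ms)
}
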