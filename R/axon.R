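#' Gating steady states and time constants
#'
#' Voltage dependence of the six gating variables of the axon model:
#' sodium activation/inactivation (`m`, `h`), high-voltage-gated
#' potassium (`n`, `p`) and low-voltage-gated potassium
#' activation/inactivation (`w`, `z`). Steady states are sigmoids of
#' membrane potential (activations increasing, inactivations
#' decreasing); time constants are strictly positive. This is a plain-R
#' reference implementation; the integrator uses an independently coded
#' compiled version of the same kinetics.
#'
#' @param v_mV membrane potential (mV), scalar or vector
#' @return list with matrices `xinf` and `tau_ms` (rows = voltages,
#'   columns = gates m, h, n, p, w, z)
#' @export
gating_steady_state_and_tau <- function(v_mV) {
  v <- as.numeric(v_mV)
  u <- v + 60
  xinf <- cbind(
    m = 1 / (1 + exp(-(v + 38) / 7)),
    h = 1 / (1 + exp((v + 65) / 6)),
    n = (1 + exp(-(v + 15) / 5))^-0.5,
    p = 1 / (1 + exp(-(v + 23) / 6)),
    w = (1 + exp(-(v + 48) / 6))^-0.25,
    z = 0.5 + 0.5 / (1 + exp((v + 71) / 10)))
  tau <- cbind(
    m = 10 / (5 * exp(u / 18) + 36 * exp(-u / 25)) + 0.04,
    h = 100 / (7 * exp(u / 11) + 10 * exp(-u / 25)) + 0.6,
    n = 100 / (11 * exp(u / 24) + 21 * exp(-u / 23)) + 0.7,
    p = 100 / (4 * exp(u / 32) + 5 * exp(-u / 22)) + 5,
    w = 100 / (6 * exp(u / 6) + 16 * exp(-u / 45)) + 1.5,
    z = 1000 / (exp(u / 20) + exp(-u / 8)) + 50)
  list(xinf = xinf, tau_ms = tau)
}

#' Per-channel membrane currents
#'
#' Current through each channel at a given membrane potential and
#' gating state, in current density units (uA/cm^2, outward positive).
#'
#' @param v membrane potential (mV)
#' @param gates named numeric vector with elements m, h, n, p, w, z in
#'   `[0, 1]`
#' @param params an [axon_params()] object
#' @return named numeric vector with elements `na`, `kh`, `kl`, `leak`
#' @export
channel_currents <- function(v, gates, params) {
  g <- as.list(gates)
  c(na = params$g_na * g$m^3 * g$h * (v - params$e_na),
    kh = params$g_kh * (0.85 * g$n^2 + 0.15 * g$p) * (v - params$e_k),
    kl = params$g_kl * g$w^4 * g$z * (v - params$e_k),
    leak = params$g_leak * (v - params$e_leak))
}

#' Time derivative of the axon state
#'
#' Current balance of the single-compartment axon:
#' `C_m dV/dt = -(I_Na + I_KH + I_KL + I_leak) + (i_syn + i_gvs)/area`,
#' with first-order gating relaxation `dx/dt = (x_inf - x)/tau_x`.
#' Point currents (pA) are converted to density (uA/cm^2) through the
#' membrane area.
#'
#' @param state list with `v` (mV) and `gates` (named vector m, h, n,
#'   p, w, z)
#' @param i_syn_pA,i_gvs_pA synaptic and galvanic injected currents (pA)
#' @param params an [axon_params()] object
#' @return list with `dv` (mV/ms) and `dgates` (1/ms)
#' @export
membrane_derivative <- function(state, i_syn_pA, i_gvs_pA, params) {
  ic <- channel_currents(state$v, state$gates, params)
  i_inj <- (i_syn_pA + i_gvs_pA) * 1e-6 / params$area
  gk <- gating_steady_state_and_tau(state$v)
  list(dv = (-sum(ic) + i_inj) / params$cm,
       dgates = (gk$xinf[1, ] - state$gates) / gk$tau_ms[1, ])
}

#' Resting state of the axon
#'
#' Solves the current balance `dV/dt = 0` with all gates at steady
#' state and no input, by root finding on the steady-state I-V curve.
#'
#' @param params an [axon_params()] object
#' @return list with `v` (mV) and `gates` (named vector)
#' @export
resting_state <- function(params) {
  f <- function(v) {
    gk <- gating_steady_state_and_tau(v)
    -sum(channel_currents(v, gk$xinf[1, ], params))
  }
  v0 <- stats::uniroot(f, c(-90, -40), tol = 1e-10)$root
  list(v = v0, gates = gating_steady_state_and_tau(v0)$xinf[1, ])
}

#' Simulate the axon model
#'
#' Integrates the conductance-based point-neuron axon driven by an EPSC
#' event train and an injected galvanic current, using exponential
#' Euler for the gating variables and a forward step for the membrane
#' potential. Spikes are detected online as upward crossings of
#' `threshold_mv` separated by at least `refractory_ms`. The
#' integration is deterministic given its inputs; stochasticity enters
#' only through the EPSC event times.
#'
#' @param params an [axon_params()] object
#' @param event_times EPSC arrival times (ms), sorted
#' @param i_gvs_pA injected galvanic current (pA): scalar or one value
#'   per grid sample (see [to_axonal_current()])
#' @param total_ms simulated duration (ms)
#' @param epsc an [epsc_params()] object (template shape and amplitude)
#' @param dt_ms integration step (ms)
#' @param event_amps optional per-event EPSC peak amplitudes (pA);
#'   default `K_pA` from `epsc` for every event
#' @param record_v if `TRUE`, return the membrane-potential trace
#' @param threshold_mv,refractory_ms spike detection settings
#' @return an object of class `axon_sim`: list with `spike_times` (ms),
#'   `total_ms`, `dt_ms`, and (if requested) `t` and `v`
#' @export
simulate_axon <- function(params, event_times, i_gvs_pA, total_ms,
                          epsc = epsc_params(), dt_ms = 0.01,
                          event_amps = NULL, record_v = FALSE,
                          threshold_mv = -20, refractory_ms = 1) {
  stopifnot(inherits(params, "axon_params"), inherits(epsc, "epsc_params"),
            total_ms > 0, dt_ms > 0)
  rest <- resting_state(params)
  ord <- order(event_times)
  ev <- as.numeric(event_times)[ord]
  if (is.null(event_amps)) event_amps <- rep(epsc$K_pA, length(ev))
  res <- cpp_simulate_axon(
    unclass(params),
    as.integer(round(ev / dt_ms)),
    as.numeric(event_amps)[ord],
    as.numeric(i_gvs_pA), total_ms, dt_ms,
    epsc$tau_rise_ms, epsc$tau_decay_ms,
    rest$v, rest$gates, threshold_mv, refractory_ms, record_v)
  out <- list(spike_times = res$spike_times, total_ms = total_ms,
              dt_ms = dt_ms, threshold_mv = threshold_mv,
              refractory_ms = refractory_ms)
  if (record_v) {
    out$v <- res$v
    out$t <- seq(0, by = dt_ms, length.out = length(res$v))
  }
  structure(out, class = "axon_sim")
}

#' Detect spikes in a membrane-potential trace
#'
#' One spike per upward threshold crossing; crossings within the
#' refractory window of the previous spike are merged into it. Spike
#' times are reported at the crossing sample.
#'
#' @param v membrane potential trace (mV) on a uniform grid
#' @param dt_ms grid step (ms)
#' @param threshold_mv spike threshold (mV)
#' @param refractory_ms minimum separation between spikes (ms)
#' @return numeric vector of spike times (ms)
#' @export
detect_spikes <- function(v, dt_ms, threshold_mv = -20, refractory_ms = 1) {
  stopifnot(dt_ms > 0)
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv)
  t_cross <- up * dt_ms
  keep <- numeric(0)
  last <- -Inf
  for (tc in t_cross) {
    if (tc - last >= refractory_ms) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  keep
}

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf("<axon_sim> %.0f ms @ dt=%g ms, %d spikes (%.1f sps)\n",
              x$total_ms, x$dt_ms, length(x$spike_times),
              1000 * length(x$spike_times) / x$total_ms))
  invisible(x)
}
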