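#' Simulate one hair-cell/afferent unit
#'
#' Runs the full model for a single simulated neuron: the stimulus
#' drives (i) the axon directly, through the electrode-to-axon coupling
#' and the non-quantal gain, and (ii) when `adaptation = TRUE`, the
#' hair-cell adaptation pathway, whose rate contribution retargets the
#' EPSC arrival-interval profile `mu(t)` every `t_dmu` ms around the
#' fixed point (`fr_o`, `mu0`). EPSC events are then drawn from the
#' renewal process and integrated by the axon model together with the
#' galvanic current.
#'
#' @param p a variant configuration from [vestsim_params()]
#' @param stim a `gvs_stimulus` on the integration grid (`p$dt_ms`)
#' @param seed integer seed for the EPSC train of this neuron
#' @param adaptation include the hair-cell adaptation pathway
#' @param t_dmu_factor multiple of `mu0` used as the `mu(t)` update
#'   interval; values > 1 slow the vesicle-release update and act as a
#'   low-pass filter on the stimulus
#' @param record_v return the membrane-potential trace
#' @return list with `spike_times` (ms), `n_epsc`, `mu` (per-segment
#'   interval profile, ms), `fr_adapt` (on the `t_dmu` grid, spikes/s),
#'   `total_ms`, and optionally `t`, `v`
#' @export
simulate_afferent <- function(p, stim, seed, adaptation = TRUE,
                              t_dmu_factor = 1, record_v = FALSE) {
  stopifnot(inherits(stim, "gvs_stimulus"))
  total_ms <- max(stim$t)
  i_gvs <- to_axonal_current(stim, p$coupling_pA_per_uA, p$nq_gain)
  if (length(unique(i_gvs)) == 1) i_gvs <- i_gvs[1]
  t_dmu <- t_dmu_factor * p$epsc$mu0_ms
  fr_adapt <- NULL
  if (adaptation) {
    # adaptation acts on time scales >> t_dmu, so evaluate it directly
    # on the mu-update grid
    coarse_t <- seq(0, total_ms, by = t_dmu)
    idx <- pmin(length(stim$i_ext), floor(coarse_t / stim$dt_ms) + 1)
    w_coarse <- new_stimulus(coarse_t, stim$i_ext[idx], t_dmu,
                             stim$kind, stim$meta)
    fr_adapt <- adaptation_response(w_coarse, p$adaptation)
    mu_prof <- update_mu(pmax(p$fr_o + fr_adapt, 0), t_dmu,
                         p$epsc$mu0_ms, p$fr_o, t_dmu)
    mu <- mu_prof$mu
  } else {
    mu <- p$epsc$mu0_ms
  }
  events <- draw_epsc_times(mu, total_ms, seed = seed, t_dmu_ms = t_dmu)
  amps <- draw_epsc_amplitudes(length(events), p$epsc)
  sim <- simulate_axon(p$axon, events, i_gvs, total_ms, epsc = p$epsc,
                       dt_ms = p$dt_ms, event_amps = amps,
                       record_v = record_v)
  out <- list(spike_times = sim$spike_times, n_epsc = length(events),
              mu = mu, fr_adapt = fr_adapt, total_ms = total_ms,
              seed = seed, variant = p$variant)
  if (record_v) {
    out$v <- sim$v
    out$t <- sim$t
  }
  out
}
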