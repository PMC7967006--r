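#' Axon membrane parameters
#'
#' Maximal conductance densities, reversal potentials and passive
#' properties of the single-compartment afferent axon. Defaults are the
#' published single-compartment irregular-afferent values; the model
#' variants scale them (see [vestsim_params()]).
#'
#' @param g_na,g_kh,g_kl,g_leak maximal conductances (mS/cm^2)
#' @param e_na,e_k,e_leak reversal potentials (mV)
#' @param cm membrane capacitance (uF/cm^2)
#' @param area membrane area (cm^2)
#' @param tau_scale uniform speed-up factor applied to all gating time
#'   constants (the published kinetics are room-temperature values;
#'   body temperature corresponds to a factor of about 3)
#' @return an object of class `axon_params`
#' @export
axon_params <- function(g_na = 13, g_kh = 2.8, g_kl = 1.1, g_leak = 0.03,
                        e_na = 82, e_k = -81, e_leak = -65,
                        cm = 0.9, area = 1e-5, tau_scale = 1) {
  stopifnot(g_na >= 0, g_kh >= 0, g_kl >= 0, g_leak >= 0, cm > 0, area > 0,
            tau_scale > 0)
  structure(list(g_na = g_na, g_kh = g_kh, g_kl = g_kl, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 cm = cm, area = area, tau_scale = tau_scale),
            class = "axon_params")
}

#' Model variant parameter sets
#'
#' Loads the versioned parameter file shipped with the package and
#' returns the full configuration of one model variant:
#'
#' * `original_hk` — the unmodified published single-compartment
#'   parameterization (slow EPSC arrival, no non-quantal gain);
#' * `invivo_high_conductance` — sodium and high-voltage potassium
#'   conductances scaled to the upper limit of their realistic range
#'   (low-voltage potassium held at 1.1 mS/cm^2), fast EPSC arrival,
#'   and the non-quantal gain on galvanic current;
#' * `invitro_low_conductance` — reduced sodium conductance and
#'   non-quantal gain emulating the low spontaneous rate and narrow
#'   firing range of explant recordings.
#'
#' @param variant variant name
#' @param file optional path to an alternative parameter YAML file
#' @return a list with components `axon` ([axon_params()]), `epsc`
#'   ([epsc_params()]), `adaptation` ([adaptation_params()]), plus
#'   `coupling_pA_per_uA`, `nq_gain`, `fr_o`, `fr_max`, `dt_ms` and
#'   `variant`
#' @export
vestsim_params <- function(variant = c("original_hk",
                                       "invivo_high_conductance",
                                       "invitro_low_conductance"),
                           file = NULL) {
  variant <- match.arg(variant)
  if (is.null(file))
    file <- system.file("extdata", "variants.yaml", package = "vestsim")
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$variants[[variant]]))
    stop("variant '", variant, "' not found in ", file)
  v <- utils::modifyList(cfg$common, cfg$variants[[variant]])
  out <- list(
    variant = variant,
    axon = axon_params(g_na = v$g_na, g_kh = v$g_kh, g_kl = v$g_kl,
                       g_leak = v$g_leak, e_na = v$e_na, e_k = v$e_k,
                       e_leak = v$e_leak, cm = v$cm, area = v$area,
                       tau_scale = v$tau_scale),
    epsc = epsc_params(mu0_ms = v$mu0_ms, K_pA = v$K_pA,
                       t_dmu_ms = v$mu0_ms,
                       tau_rise_ms = v$tau_rise_ms,
                       tau_decay_ms = v$tau_decay_ms,
                       amp_sdlog = v$amp_sdlog),
    adaptation = adaptation_params(
      G_f = v$G_f, G_s = v$G_s, tau_f_s = v$tau_f_s, tau_s_s = v$tau_s_s,
      anodic_fast_attenuation = v$anodic_fast_attenuation,
      f_c_hz = v$f_c_hz),
    coupling_pA_per_uA = v$coupling_pA_per_uA,
    nq_gain = v$nq_gain,
    fr_o = v$fr_o,
    fr_max = v$fr_max,
    dt_ms = v$dt_ms)
  out
}

#' @rdname vestsim_params
#' @export
list_variants <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "variants.yaml", package = "vestsim")
  names(yaml::read_yaml(file)$variants)
}
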