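#' Hair-cell adaptation parameters
#'
#' Parameters of the phenomenological fast/slow hair-cell adaptation
#' response to galvanic stimulation. The response to a current step is
#' a fast and a slow exponentially decaying transient that returns
#' fully to baseline; in the frequency domain the two components act as
#' first-order high-pass filters with cutoffs `1/tau_f` and `1/tau_s`,
#' in series with a first-order low-pass at `f_c_hz` that represents
#' the finite speed at which the neuron can follow its synaptic drive.
#'
#' @param G_f,G_s fast and slow gains (spikes/s per uA), >= 0; the fast
#'   gain exceeds the slow gain in fitted data
#' @param tau_f_s,tau_s_s fast and slow time constants (s), with
#'   `tau_f_s < tau_s_s`
#' @param anodic_fast_attenuation multiplier (<= 1) on the fast gain
#'   for inhibitory (anodic) drive, which recruits the fast component
#'   less than excitatory drive
#' @param f_c_hz low-pass cutoff (Hz)
#' @return an object of class `adaptation_params`
#' @export
adaptation_params <- function(G_f = 2.6, G_s = 0.8, tau_f_s = 0.15,
                              tau_s_s = 2, anodic_fast_attenuation = 0.5,
                              f_c_hz = 1000) {
  stopifnot(G_f >= 0, G_s >= 0, tau_f_s > 0, tau_s_s > 0,
            tau_f_s < tau_s_s, anodic_fast_attenuation <= 1,
            anodic_fast_attenuation >= 0, f_c_hz > 0)
  structure(list(G_f = G_f, G_s = G_s, tau_f_s = tau_f_s, tau_s_s = tau_s_s,
                 anodic_fast_attenuation = anodic_fast_attenuation,
                 f_c_hz = f_c_hz),
            class = "adaptation_params")
}

# first-order high-pass of a piecewise-constant input, exact between
# samples: y[k] = exp(-dt/tau) y[k-1] + (x[k] - x[k-1])
highpass_pwc <- function(x, dt_ms, tau_ms) {
  a <- exp(-dt_ms / tau_ms)
  dx <- diff(c(0, x))
  as.numeric(stats::filter(dx, a, method = "recursive"))
}

#' Hair-cell adaptation response to a stimulus
#'
#' Firing-rate contribution of the hair-cell adaptation pathway,
#' `fr_adapt(t)`, for an arbitrary galvanic waveform. The drive is
#' `x(t) = -i_ext(t)` (cathodic current excites), passed through the
#' fast and slow first-order high-pass filters and summed with gains
#' `G_f` and `G_s`. For inhibitory drive (`x < 0`) the fast gain is
#' multiplied by `anodic_fast_attenuation`. A step of amplitude A thus
#' produces `fr_adapt(t) = A (G_f e^{-t/tau_f} + G_s e^{-t/tau_s})`:
#' full adaptation back to zero.
#'
#' @param w a `gvs_stimulus` (any grid step; the filters are exact for
#'   piecewise-constant input)
#' @param p an [adaptation_params()] object
#' @return numeric vector `fr_adapt` (spikes/s) on the stimulus grid
#' @export
adaptation_response <- function(w, p) {
  stopifnot(inherits(w, "gvs_stimulus"), inherits(p, "adaptation_params"))
  if (length(w$t) > 1) {
    steps <- diff(w$t)
    if (max(steps) - min(steps) > 1e-8 * w$dt_ms)
      stop("adaptation_response requires a uniform time grid")
  }
  x <- -w$i_ext
  x_fast <- ifelse(x < 0, p$anodic_fast_attenuation * x, x)
  p$G_f * highpass_pwc(x_fast, w$dt_ms, p$tau_f_s * 1000) +
    p$G_s * highpass_pwc(x, w$dt_ms, p$tau_s_s * 1000)
}

#' Combine adaptation and axonal firing-rate contributions
#'
#' Element-wise sum of the hair-cell adaptation rate and the axonal
#' rate, clipped to the attainable firing range `[fr_min, fr_max]`.
#' The clip is what produces the baseline-dependent asymmetry of the
#' narrow-range preparation: from an anodic (low) baseline further
#' anodic steps plateau at zero, and from a cathodic (high) baseline
#' further cathodic steps plateau at the maximum rate.
#'
#' @param fr_adapt,fr_axon rate series on a common grid (spikes/s);
#'   `fr_axon` may be scalar
#' @param fr_min,fr_max firing-range bounds (spikes/s), `fr_max > 0`
#' @return clipped total rate series (spikes/s)
#' @export
combined_rate <- function(fr_adapt, fr_axon, fr_min = 0, fr_max = 55) {
  if (fr_max <= 0) stop("fr_max must be > 0")
  if (length(fr_axon) != 1 && length(fr_axon) != length(fr_adapt))
    stop("fr_axon must be scalar or match fr_adapt")
  pmin(pmax(fr_adapt + fr_axon, fr_min), fr_max)
}

#' Frequency response of the hair-cell adaptation pathway
#'
#' Closed-form transfer function of the adaptation model:
#' `H(f) = [G_f (i w tau_f)/(1 + i w tau_f) + G_s (i w tau_s)/(1 + i w
#' tau_s)] / (1 + i f/f_c)` with `w = 2 pi f`. The two high-pass
#' sections give a phase lead that is largest at low frequency and
#' decays toward zero (and below, once the low-pass dominates) as
#' frequency grows.
#'
#' @param freq_hz frequencies (Hz), > 0
#' @param p an [adaptation_params()] object
#' @param include_lowpass include the `f_c` low-pass section
#' @return data frame with columns `freq_hz`, `gain` (|H|, spikes/s per
#'   uA), `phase_deg` and the complex response `H`
#' @export
transfer_function <- function(freq_hz, p, include_lowpass = TRUE) {
  stopifnot(inherits(p, "adaptation_params"), all(freq_hz > 0))
  s <- 2i * pi * freq_hz
  H <- p$G_f * (s * p$tau_f_s) / (1 + s * p$tau_f_s) +
    p$G_s * (s * p$tau_s_s) / (1 + s * p$tau_s_s)
  if (include_lowpass) H <- H / (1 + 1i * freq_hz / p$f_c_hz)
  data.frame(freq_hz = freq_hz, gain = Mod(H),
             phase_deg = Arg(H) * 180 / pi, H = H)
}

#' Fit adaptation gains to step-response traces
#'
#' Least-squares estimation of the fast and slow gains from one or
#' more firing-rate responses to a known stimulus. With fixed time
#' constants the model is linear in the gains and solved by ordinary
#' least squares on the two filter basis functions; with `fit_taus =
#' TRUE` the time constants are refined by nonlinear least squares
#' starting from their current values.
#'
#' @param rate_traces numeric vector, or matrix with one trace per
#'   column (spikes/s), on the stimulus grid; traces are averaged
#' @param w the `gvs_stimulus` that produced the traces
#' @param p an [adaptation_params()] object holding the (initial) time
#'   constants and the anodic attenuation
#' @param fit_taus also fit `tau_f` and `tau_s`
#' @return an [adaptation_params()] object with fitted values, with
#'   attribute `residual_norm`
#' @export
fit_adaptation_gains <- function(rate_traces, w, p = adaptation_params(),
                                 fit_taus = FALSE) {
  stopifnot(inherits(w, "gvs_stimulus"), inherits(p, "adaptation_params"))
  y <- if (is.matrix(rate_traces)) rowMeans(rate_traces) else rate_traces
  if (length(y) != length(w$t))
    stop("rate trace and stimulus are on different grids")
  if (stats::sd(w$i_ext) == 0 || stats::sd(y) == 0)
    stop("fit failure: degenerate (constant) stimulus or trace")
  x <- -w$i_ext
  x_fast <- ifelse(x < 0, p$anodic_fast_attenuation * x, x)
  basis <- function(tf_ms, ts_ms)
    cbind(f = highpass_pwc(x_fast, w$dt_ms, tf_ms),
          s = highpass_pwc(x, w$dt_ms, ts_ms))
  if (!fit_taus) {
    B <- basis(p$tau_f_s * 1000, p$tau_s_s * 1000)
    fit <- stats::lm.fit(B, y)
    G <- pmax(fit$coefficients, 0)
    res <- sqrt(sum(fit$residuals^2))
    out <- adaptation_params(G_f = unname(G["f"]), G_s = unname(G["s"]),
                             tau_f_s = p$tau_f_s, tau_s_s = p$tau_s_s,
                             anodic_fast_attenuation = p$anodic_fast_attenuation,
                             f_c_hz = p$f_c_hz)
  } else {
    df <- data.frame(y = y, x = x, x_fast = x_fast)
    dt_grid <- w$dt_ms
    fit <- minpack.lm::nlsLM(
      y ~ gf * highpass_pwc(x_fast, dt_grid, tf) +
        gs * highpass_pwc(x, dt_grid, ts),
      data = df,
      start = list(gf = max(p$G_f, 0.1), gs = max(p$G_s, 0.1),
                   tf = p$tau_f_s * 1000, ts = p$tau_s_s * 1000),
      lower = c(0, 0, 1, 10),
      upper = c(Inf, Inf, 2000, length(y) * dt_grid / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    res <- sqrt(sum(stats::resid(fit)^2))
    out <- adaptation_params(G_f = unname(cf["gf"]), G_s = unname(cf["gs"]),
                             tau_f_s = unname(cf["tf"]) / 1000,
                             tau_s_s = unname(cf["ts"]) / 1000,
                             anodic_fast_attenuation = p$anodic_fast_attenuation,
                             f_c_hz = p$f_c_hz)
  }
  attr(out, "residual_norm") <- res
  out
}
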