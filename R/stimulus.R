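#' GVS stimulus waveforms
#'
#' Constructors for galvanic vestibular stimulation (GVS) protocols in
#' electrode units. All waveforms live on a uniform time grid with step
#' `dt_ms` and carry the electrode current `i_ext` in microamperes.
#' Sign convention: cathodic current is negative and excites the
#' afferent; anodic current is positive and inhibits it.
#'
#' @param amplitude_uA step or sinusoid amplitude (microamperes)
#' @param onset_ms step onset time (ms)
#' @param duration_ms step duration (ms)
#' @param total_ms total waveform duration (ms)
#' @param dt_ms time step (ms); the default 0.01 ms resolves sodium
#'   channel gating
#' @return an object of class `gvs_stimulus`: a list with fields `t`
#'   (ms), `i_ext` (uA), `dt_ms`, `kind` and `meta`
#' @examples
#' w <- make_step(-30, onset_ms = 1000, duration_ms = 10000,
#'                total_ms = 12000, dt_ms = 1)
#' range(w$i_ext)
#' @export
make_step <- function(amplitude_uA, onset_ms, duration_ms, total_ms,
                      dt_ms = 0.01) {
  check_protocol(dt_ms > 0, "dt_ms must be > 0")
  check_protocol(duration_ms >= 0 && onset_ms >= 0,
                 "onset and duration must be non-negative")
  check_protocol(total_ms >= onset_ms + duration_ms,
                 "total_ms must cover onset + duration")
  t <- time_grid(total_ms, dt_ms)
  i_ext <- numeric(length(t))
  i_ext[t >= onset_ms & t < onset_ms + duration_ms] <- amplitude_uA
  new_stimulus(t, i_ext, dt_ms,
               kind = if (amplitude_uA == 0) "zero" else "step",
               meta = list(amplitude_uA = amplitude_uA, onset_ms = onset_ms,
                           duration_ms = duration_ms))
}

#' @rdname make_step
#' @param baseline_uA current during the first segment (uA)
#' @param step_uA current added to the baseline during the second segment
#' @param t_baseline_ms duration of the baseline segment (ms)
#' @param t_step_ms duration of the step segment (ms)
#' @export
make_baseline_step <- function(baseline_uA, step_uA, t_baseline_ms,
                               t_step_ms, dt_ms = 0.01) {
  check_protocol(dt_ms > 0, "dt_ms must be > 0")
  check_protocol(t_baseline_ms > 0 && t_step_ms > 0,
                 "both segment durations must be > 0")
  t <- time_grid(t_baseline_ms + t_step_ms, dt_ms)
  i_ext <- ifelse(t < t_baseline_ms, baseline_uA, baseline_uA + step_uA)
  new_stimulus(t, i_ext, dt_ms, kind = "baseline_step",
               meta = list(baseline_uA = baseline_uA, step_uA = step_uA,
                           t_baseline_ms = t_baseline_ms,
                           t_step_ms = t_step_ms))
}

#' @rdname make_step
#' @param freq_hz sinusoid frequency (Hz)
#' @param n_cycles number of full cycles; duration is `n_cycles / freq_hz`
#' @export
make_sinusoid <- function(amplitude_uA, freq_hz, n_cycles, dt_ms = 0.01) {
  check_protocol(dt_ms > 0, "dt_ms must be > 0")
  check_protocol(freq_hz > 0, "freq_hz must be > 0")
  check_protocol(n_cycles >= 1, "n_cycles must be >= 1")
  total_ms <- n_cycles * 1000 / freq_hz
  t <- time_grid(total_ms, dt_ms)
  # phase convention: t = 0 at the zero crossing heading into the
  # anodic (positive) half; the cathodic half is the negative half-cycle
  i_ext <- amplitude_uA * sin(2 * pi * freq_hz * t / 1000)
  new_stimulus(t, i_ext, dt_ms,
               kind = if (amplitude_uA == 0) "zero" else "sinusoid",
               meta = list(amplitude_uA = amplitude_uA, freq_hz = freq_hz,
                           n_cycles = n_cycles))
}

#' @rdname make_step
#' @export
make_zero <- function(total_ms, dt_ms = 0.01) {
  check_protocol(dt_ms > 0, "dt_ms must be > 0")
  t <- time_grid(total_ms, dt_ms)
  new_stimulus(t, numeric(length(t)), dt_ms, kind = "zero",
               meta = list(amplitude_uA = 0))
}

#' Convert electrode current to axon-injected current
#'
#' Maps the electrode-referenced GVS waveform (uA) onto the current
#' injected into the axonal compartment (pA). The electrode-to-axon
#' coupling is a single calibration scalar per model variant; the
#' non-quantal (NQ) gain multiplies the injected GVS current only, not
#' the synaptic current. The sign is flipped so that cathodic
#' (negative) electrode current depolarizes the afferent.
#'
#' @param w a `gvs_stimulus`
#' @param coupling_pA_per_uA electrode-to-axon coupling (pA per uA), > 0
#' @param nq_gain non-quantal gain on GVS-injected current, >= 1
#' @return numeric vector of injected current (pA) on the waveform grid
#' @export
to_axonal_current <- function(w, coupling_pA_per_uA, nq_gain = 1) {
  stopifnot(inherits(w, "gvs_stimulus"))
  check_protocol(coupling_pA_per_uA > 0, "coupling must be > 0")
  check_protocol(nq_gain >= 1, "nq_gain must be >= 1")
  -coupling_pA_per_uA * nq_gain * w$i_ext
}

#' Export a stimulus waveform as a two-column CSV
#'
#' @param w a `gvs_stimulus`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_stimulus_csv <- function(w, path) {
  stopifnot(inherits(w, "gvs_stimulus"))
  utils::write.csv(data.frame(t_ms = w$t, i_uA = w$i_ext), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.gvs_stimulus <- function(x, ...) {
  cat(sprintf("<gvs_stimulus> kind=%s  %.1f ms @ dt=%g ms  range [%.3g, %.3g] uA\n",
              x$kind, max(x$t), x$dt_ms, min(x$i_ext), max(x$i_ext)))
  invisible(x)
}

new_stimulus <- function(t, i_ext, dt_ms, kind, meta) {
  structure(list(t = t, i_ext = i_ext, dt_ms = dt_ms, kind = kind,
                 meta = meta),
            class = "gvs_stimulus")
}

time_grid <- function(total_ms, dt_ms) {
  seq(0, total_ms, by = dt_ms)
}

check_protocol <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid protocol: ", msg, call. = FALSE)
  invisible(TRUE)
}
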