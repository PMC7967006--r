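#' Spike-train summary statistics
#'
#' Mean firing rate, mean interspike interval (ISI) and coefficient of
#' variation (CV = sd(ISI)/mean(ISI)) of a spike train within a window.
#' The rate is `(n_spikes - 1) / span` over the spanned interval, so
#' that `mean_rate * mean_isi = 1000` exactly; with fewer than two
#' spikes the rate falls back to count over window length and the CV is
#' undefined (`NA`).
#'
#' @param spike_times spike times (ms)
#' @param window_ms analysis window: `c(start, end)` in ms, or a scalar
#'   end time (window starts at 0)
#' @return list with `mean_rate` (spikes/s), `mean_isi` (ms), `cv`,
#'   `n_spikes`
#' @export
spike_statistics <- function(spike_times, window_ms) {
  if (length(window_ms) == 1) window_ms <- c(0, window_ms)
  stopifnot(length(window_ms) == 2, diff(window_ms) > 0)
  st <- spike_times[spike_times >= window_ms[1] & spike_times <= window_ms[2]]
  n <- length(st)
  if (n < 2)
    return(list(mean_rate = 1000 * n / diff(window_ms), mean_isi = NA_real_,
                cv = NA_real_, n_spikes = n))
  isi <- diff(st)
  m <- mean(isi)
  list(mean_rate = 1000 / m, mean_isi = m,
       cv = stats::sd(isi) / m, n_spikes = n)
}

#' CV-versus-ISI envelope
#'
#' A pair of boundary curves delimiting the band of regularity values
#' (CV) an afferent traverses as its mean ISI changes. The envelope is
#' supplied as matched samples of the lower and upper curve and
#' interpolated linearly; [default_cv_star_envelope()] builds a
#' synthetic band (a power law in ISI with fixed fractional width) for
#' testing and qualitative checks — it is not a digitization of any
#' empirical boundary.
#'
#' @param isi_ms ISI sample points (ms), increasing
#' @param lower_cv,upper_cv boundary values at `isi_ms`, with
#'   `upper_cv >= lower_cv` everywhere
#' @return an object of class `cv_star_envelope`
#' @export
cv_star_envelope <- function(isi_ms, lower_cv, upper_cv) {
  stopifnot(length(isi_ms) == length(lower_cv),
            length(isi_ms) == length(upper_cv),
            all(diff(isi_ms) > 0), all(upper_cv >= lower_cv))
  structure(list(isi_ms = isi_ms, lower_cv = lower_cv, upper_cv = upper_cv,
                 source = "user"),
            class = "cv_star_envelope")
}

#' @rdname cv_star_envelope
#' @param isi_range domain of the synthetic envelope (ms)
#' @param mid_at_10ms CV of the midline at 10 ms ISI
#' @param exponent power-law exponent of the midline
#' @param rel_width half-width of the band as a fraction of the midline
#' @export
default_cv_star_envelope <- function(isi_range = c(1, 1000),
                                     mid_at_10ms = 0.35, exponent = 0.45,
                                     rel_width = 0.35) {
  isi <- exp(seq(log(isi_range[1]), log(isi_range[2]), length.out = 200))
  mid <- mid_at_10ms * (isi / 10)^exponent
  env <- cv_star_envelope(isi, (1 - rel_width) * mid, (1 + rel_width) * mid)
  env$source <- "synthetic"
  env
}

#' Fraction of (ISI, CV) points inside an envelope
#'
#' @param points data frame with columns `isi_ms` and `cv`
#' @param env a [cv_star_envelope()]
#' @return fraction in `[0, 1]` of in-domain points lying between the
#'   curves, with attributes `n_used` and `n_excluded`; points whose
#'   ISI falls outside the envelope domain are excluded with a warning
#' @export
cv_star_conformance <- function(points, env) {
  stopifnot(inherits(env, "cv_star_envelope"),
            all(c("isi_ms", "cv") %in% names(points)), nrow(points) > 0)
  dom <- points$isi_ms >= min(env$isi_ms) & points$isi_ms <= max(env$isi_ms)
  if (any(!dom))
    warning(sum(!dom), " point(s) outside the envelope ISI domain excluded")
  pts <- points[dom, , drop = FALSE]
  if (nrow(pts) == 0) stop("no points within the envelope domain")
  lo <- stats::approx(env$isi_ms, env$lower_cv, pts$isi_ms)$y
  hi <- stats::approx(env$isi_ms, env$upper_cv, pts$isi_ms)$y
  frac <- mean(pts$cv >= lo & pts$cv <= hi)
  attr(frac, "n_used") <- nrow(pts)
  attr(frac, "n_excluded") <- sum(!dom)
  frac
}

#' Rate-versus-current slope with bootstrap confidence interval
#'
#' Least-squares slope of mean firing rate against stimulation
#' amplitude over the linear region, with a 95% confidence interval
#' obtained by bootstrap resampling of neurons. The slope is reported
#' as d(rate)/d(current): cathodic (negative) current excites, so an
#' excitatory response has a negative slope in electrode units.
#'
#' @param curve_data data frame with columns `neuron`, `amplitude_uA`,
#'   `rate_sps`
#' @param fit_range_uA amplitude interval of the linear region
#' @param n_boot number of bootstrap resamples
#' @param seed optional seed for the bootstrap
#' @param positive_rates_only restrict the fit to amplitudes at which
#'   every neuron fires (rates above 0), i.e. between the silenced
#'   anodic region and the cathodic block
#' @return object of class `response_curve`: list with `slope`
#'   (spikes/s per uA), `ci` (95%), `per_amplitude` summary table, and
#'   `degenerate` flag
#' @export
response_slope <- function(curve_data, fit_range_uA = c(-45, 45),
                           n_boot = 1000, seed = NULL,
                           positive_rates_only = FALSE) {
  stopifnot(all(c("neuron", "amplitude_uA", "rate_sps") %in%
                  names(curve_data)))
  d <- curve_data[curve_data$amplitude_uA >= fit_range_uA[1] &
                    curve_data$amplitude_uA <= fit_range_uA[2], ]
  if (positive_rates_only) {
    mins <- stats::aggregate(rate_sps ~ amplitude_uA, d, min)
    keep <- mins$amplitude_uA[mins$rate_sps > 0]
    if (length(keep) >= 3) d <- d[d$amplitude_uA %in% keep, ]
  }
  if (length(unique(d$amplitude_uA)) < 3)
    stop("need at least 3 amplitudes within the fit range")
  per_amp <- stats::aggregate(rate_sps ~ amplitude_uA, d,
                              function(x) c(mean = mean(x), sd = stats::sd(x)))
  per_amp <- data.frame(amplitude_uA = per_amp$amplitude_uA,
                        mean_rate = per_amp$rate_sps[, "mean"],
                        sd_rate = per_amp$rate_sps[, "sd"])
  # per-neuron mean rate at each amplitude; the fitted slope is the
  # least-squares slope of the across-neuron mean against amplitude
  M <- tapply(d$rate_sps, list(d$neuron, d$amplitude_uA), mean)
  x <- as.numeric(colnames(M))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope_of_rows <- function(rows) {
    y <- colMeans(M[rows, , drop = FALSE], na.rm = TRUE)
    sum(xc * (y - mean(y))) / sxx
  }
  slope <- slope_of_rows(seq_len(nrow(M)))
  degenerate <- stats::sd(d$rate_sps) == 0
  if (degenerate) {
    ci <- c(slope, slope)
  } else {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i)
      slope_of_rows(sample.int(nrow(M), nrow(M), replace = TRUE)),
      numeric(1))
    # t-interval on the bootstrap standard error: better small-sample
    # coverage than the raw percentile interval over few neurons
    se <- stats::sd(boots, na.rm = TRUE)
    tq <- stats::qt(0.975, max(1, nrow(M) - 1))
    ci <- c(slope - tq * se, slope + tq * se)
  }
  structure(list(slope = slope, ci = ci, per_amplitude = per_amp,
                 fit_range_uA = fit_range_uA, n_boot = n_boot,
                 degenerate = degenerate),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> slope %.3f sps/uA, 95%% CI [%.3f, %.3f] over [%g, %g] uA\n",
              x$slope, x$ci[1], x$ci[2], x$fit_range_uA[1], x$fit_range_uA[2]))
  invisible(x)
}

#' Fit a double-exponential adaptation model to a rate trace
#'
#' Fits `rate(t) = baseline + shift + A_f exp(-(t - onset)/tau_f) +
#' A_s exp(-(t - onset)/tau_s)` to the post-onset portion of a firing
#' rate trace, where `baseline` is the pre-onset mean. The persistent
#' offset `shift` is the axonal (non-adapting) contribution; the two
#' decaying terms are the hair-cell adaptation transient. Amplitudes
#' are converted to gains per uA through `amplitude_uA`.
#'
#' @param rate_trace firing-rate series (spikes/s) on a uniform grid
#' @param dt_ms grid step (ms)
#' @param stim_onset_ms step onset (ms); the trace should extend to at
#'   least `5 * tau_s` past it
#' @param amplitude_uA stimulus step amplitude used to scale amplitudes
#'   into gains (use the drive `-i_ext` sign convention: pass the
#'   cathodic magnitude as positive); default 1 returns plain
#'   amplitudes
#' @param start named list overriding starting values (`tau_f_s`,
#'   `tau_s_s`)
#' @return list with `G_f`, `G_s` (spikes/s per uA), `tau_f_s`,
#'   `tau_s_s` (s), `baseline`, `baseline_shift` (spikes/s) and the
#'   `fit` object
#' @export
fit_step_response <- function(rate_trace, dt_ms, stim_onset_ms,
                              amplitude_uA = 1,
                              start = list(tau_f_s = 0.2, tau_s_s = 2.5)) {
  t <- seq(0, by = dt_ms, length.out = length(rate_trace))
  pre <- rate_trace[t < stim_onset_ms]
  baseline <- if (length(pre)) mean(pre) else 0
  post <- t >= stim_onset_ms
  ts_s <- (t[post] - stim_onset_ms) / 1000
  y <- rate_trace[post] - baseline
  if (max(ts_s) < 5 * start$tau_s_s)
    warning("trace spans less than 5 slow time constants past onset")
  df <- data.frame(ts = ts_s, y = y)
  a0 <- y[1] - mean(y[ts_s > 0.8 * max(ts_s)])
  fit <- minpack.lm::nlsLM(
    y ~ shift + af * exp(-ts / tf) + as * exp(-ts / ts2),
    data = df,
    start = list(shift = mean(y[ts_s > 0.8 * max(ts_s)]),
                 af = 0.7 * a0, as = 0.3 * a0,
                 tf = start$tau_f_s, ts2 = start$tau_s_s),
    # the slow time constant must stay resolvable within the record,
    # otherwise it trades off freely against the offset
    lower = c(-Inf, -Inf, -Inf, 0.01, 0.2),
    upper = c(Inf, Inf, Inf, 1.5, max(ts_s) / 2),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  list(G_f = unname(cf["af"]) / amplitude_uA,
       G_s = unname(cf["as"]) / amplitude_uA,
       tau_f_s = unname(cf["tf"]), tau_s_s = unname(cf["ts2"]),
       baseline = baseline, baseline_shift = unname(cf["shift"]),
       fit = fit)
}

#' Half-cycle rates and phase of the response to sinusoidal GVS
#'
#' Mean firing rate within the cathodic (negative-current) and anodic
#' (positive-current) half-cycles, and the phase of the response
#' relative to the cathodic peak. The phase is taken from the first
#' Fourier harmonic of the spike phases (equivalent to a first-harmonic
#' fit of the cycle-averaged rate); positive values mean the response
#' peaks before the cathodic peak (a phase lead).
#'
#' @param spike_times spike times (ms)
#' @param stim the sinusoidal `gvs_stimulus` that was delivered (needs
#'   at least 5 full cycles)
#' @return list with `cathodic_rate`, `anodic_rate` (spikes/s),
#'   `phase_lead_deg` (`NA` if undefined), `vector_strength`,
#'   `n_spikes`, `freq_hz`
#' @export
cycle_metrics <- function(spike_times, stim) {
  stopifnot(inherits(stim, "gvs_stimulus"))
  if (stim$kind != "sinusoid" || is.null(stim$meta$freq_hz))
    stop("cycle_metrics requires a sinusoidal stimulus")
  if (stim$meta$n_cycles < 5) stop("need at least 5 full cycles")
  f <- stim$meta$freq_hz
  total_ms <- max(stim$t)
  st <- spike_times[spike_times >= 0 & spike_times <= total_ms]
  phase <- (2 * pi * f * st / 1000) %% (2 * pi)
  # stimulus is A*sin: the anodic half is phase (0, pi), cathodic (pi, 2pi)
  cath <- phase >= pi
  half_s <- total_ms / 2000
  out <- list(cathodic_rate = sum(cath) / half_s,
              anodic_rate = sum(!cath) / half_s,
              n_spikes = length(st), freq_hz = f)
  if (length(st) == 0) {
    out$phase_lead_deg <- NA_real_
    out$vector_strength <- NA_real_
    return(out)
  }
  C <- mean(exp(1i * phase))
  out$vector_strength <- Mod(C)
  if (Mod(C) < .Machine$double.eps^0.5) {
    out$phase_lead_deg <- NA_real_
  } else {
    peak_deg <- (Arg(C) * 180 / pi) %% 360
    lead <- (270 - peak_deg) %% 360   # cathodic peak sits at 270 degrees
    if (lead > 180) lead <- lead - 360
    out$phase_lead_deg <- lead
  }
  out
}

#' Cluster-based permutation comparison of rate traces
#'
#' Non-parametric comparison of two sets of per-neuron firing-rate
#' traces. Pointwise two-sample t statistics are thresholded at the
#' two-sided p < 0.05 critical value; contiguous supra-threshold runs
#' form clusters scored by their summed |t|; the null distribution of
#' the maximum cluster score is built by permuting condition labels.
#'
#' @param rates_a,rates_b matrices (neurons x time points) on a common
#'   grid, at least 2 neurons per condition
#' @param n_perm number of label permutations (>= 100)
#' @param alpha cluster significance level
#' @param seed optional seed
#' @param cluster_p pointwise cluster-forming threshold
#' @return data frame of clusters (`start`, `end` indices, `mass`,
#'   `p_value`, `significant`), possibly empty; attributes `t` (the
#'   pointwise statistics) and `t_crit`
#' @export
cluster_permutation_test <- function(rates_a, rates_b, n_perm = 1000,
                                     alpha = 0.05, seed = NULL,
                                     cluster_p = 0.05) {
  stopifnot(is.matrix(rates_a), is.matrix(rates_b),
            ncol(rates_a) == ncol(rates_b))
  if (nrow(rates_a) < 2 || nrow(rates_b) < 2)
    stop("need at least 2 neurons per condition")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  na <- nrow(rates_a); nb <- nrow(rates_b)
  all_tr <- rbind(rates_a, rates_b)
  t_crit <- stats::qt(1 - cluster_p / 2, na + nb - 2)
  tvec <- function(ia) {
    a <- all_tr[ia, , drop = FALSE]
    b <- all_tr[-ia, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums(a^2) - na * ma^2
    vb <- colSums(b^2) - nb * mb^2
    sp <- sqrt((va + vb) / (na + nb - 2) * (1 / na + 1 / nb))
    tt <- (ma - mb) / sp
    tt[!is.finite(tt)] <- 0
    tt
  }
  cluster_masses <- function(tt) {
    r <- rle(abs(tt) > t_crit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    list(starts = starts[keep], ends = ends[keep],
         mass = vapply(keep, function(k)
           sum(abs(tt[(ends[k] - r$lengths[k] + 1):ends[k]])), numeric(1)))
  }
  t_obs <- tvec(seq_len(na))
  obs <- cluster_masses(t_obs)
  null_max <- vapply(seq_len(n_perm), function(i) {
    cm <- cluster_masses(tvec(sample.int(na + nb, na)))
    if (length(cm$mass)) max(cm$mass) else 0
  }, numeric(1))
  p <- vapply(obs$mass, function(m) (1 + sum(null_max >= m)) / (n_perm + 1),
              numeric(1))
  out <- data.frame(start = obs$starts, end = obs$ends, mass = obs$mass,
                    p_value = p, significant = p < alpha)
  attr(out, "t") <- t_obs
  attr(out, "t_crit") <- t_crit
  out
}

#' Smoothed firing-rate traces from spike trains
#'
#' Bins spikes and smooths the binned rate with a boxcar (default
#' 100 ms), returning one trace per train on a common grid.
#'
#' @param trains list of spike-time vectors (ms)
#' @param total_ms record length (ms)
#' @param bin_ms bin width (ms)
#' @param smooth_ms boxcar width (ms); edges use the partial window
#' @return list with `t` (bin centers, ms) and `rates` (matrix, one row
#'   per train, spikes/s)
#' @export
rate_trace <- function(trains, total_ms, bin_ms = 10, smooth_ms = 100) {
  breaks <- seq(0, total_ms, by = bin_ms)
  nb <- length(breaks) - 1
  k <- max(1, round(smooth_ms / bin_ms))
  kern <- rep(1, k)
  rates <- t(vapply(trains, function(st) {
    counts <- tabulate(findInterval(st[st > 0 & st <= total_ms],
                                    breaks, left.open = TRUE), nbins = nb)
    r <- counts * 1000 / bin_ms
    sm <- as.numeric(stats::filter(r, kern / k, sides = 2))
    miss <- is.na(sm)
    if (any(miss)) {
      csum <- cumsum(c(0, r))
      half <- k %/% 2
      for (i in which(miss)) {
        lo <- max(1, i - half); hi <- min(nb, i + half)
        sm[i] <- (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
      }
    }
    sm
  }, numeric(nb)))
  list(t = (breaks[-1] + breaks[-length(breaks)]) / 2, rates = rates)
}
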