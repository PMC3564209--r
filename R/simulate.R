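#' Simulation settings for the stochastic integrator
#'
#' Defaults follow the headline numerical experiment: step `5e-5` s, 200 s of
#' simulated activity, noise strength `kappa = 0.01` mV. The noise strength
#' relates to the analytic intensity by `D = kappa^2 / 2`, so that the
#' per-step increment `kappa * sqrt(dt) * N(0,1)` realizes white noise with
#' autocorrelation `2 D delta(t)` on the excitatory line.
#'
#' @param dt Integration step, seconds.
#' @param duration Simulated time, seconds.
#' @param seed Integer seed for the noise stream.
#' @param kappa Noise strength (potential units, e.g. mV).
#' @param transient_discard Initial stretch dropped before any statistics,
#'   seconds. Should be well beyond `1/|R|`.
#' @param initial_state Numeric `(x0, y0)`.
#' @param blowup_bound Trajectory values beyond this magnitude abort the run.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 5e-5, duration = 200, seed = 1,
                              kappa = 0.01, transient_discard = 5,
                              initial_state = c(0, 0), blowup_bound = 1e8) {
  stopifnot(dt > 0, duration > dt, length(initial_state) == 2L,
            kappa >= 0, transient_discard >= 0, blowup_bound > 0)
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 kappa = kappa, transient_discard = transient_discard,
                 initial_state = as.numeric(initial_state),
                 blowup_bound = blowup_bound),
            class = "simulation_config")
}

#' Euler-Maruyama integration of the stochastic linear model
#'
#' Integrates `tau1 dx = ((N1-1) x - N1 y) dt + tau1 kappa dW`,
#' `tau2 dy = (N2 x - (N2+1) y) dt` with the first-order Euler-Maruyama
#' scheme; noise acts on the excitatory line only, with per-step increment
#' `kappa sqrt(dt) eta`, `eta ~ N(0,1)`. The increment stream is drawn from
#' R's RNG after `set.seed(config$seed)`, so identical inputs reproduce the
#' trajectory bit for bit.
#'
#' A warning is issued when `dt` exceeds a tenth of either synaptic time
#' constant (accuracy guard); the run aborts with an error when the
#' trajectory exceeds `blowup_bound` (unstable parameters).
#'
#' @param params A [model_params()] object.
#' @param config A [simulation_config()] object.
#' @param V_e0 Optional stationary excitatory potential added to `x(t)` for
#'   the display trace (e.g. -60 mV).
#' @return An object of class `simulation_record`: `time` (s), `x`, `y`,
#'   `display` (`x + V_e0`), plus the `params` and `config` used.
#' @export
euler_maruyama <- function(params, config = simulation_config(),
                           V_e0 = -60) {
  stopifnot(inherits(params, "model_params"),
            inherits(config, "simulation_config"))
  ep <- effective_params(params)
  if (config$dt > params$tau1 / 10 || config$dt > ep$tau2 / 10)
    warning("dt exceeds tau/10: the first-order scheme may be inaccurate")
  n <- floor(config$duration / config$dt)
  set.seed(config$seed)
  noise <- config$kappa * sqrt(config$dt) * stats::rnorm(n)
  res <- em_core(config$initial_state[1], config$initial_state[2],
                 params$N1, ep$N2, params$tau1, ep$tau2, config$dt,
                 noise, config$blowup_bound)
  if (isTRUE(res$blown))
    stop("trajectory exceeded the blow-up bound after ",
         format(res$n_done * config$dt), " s: parameters are unstable ",
         "at p = ", params$p)
  structure(list(time = seq(0, n) * config$dt, x = res$x, y = res$y,
                 display = res$x + V_e0, V_e0 = V_e0,
                 params = params, config = config),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf("Simulated trajectory: %g s at dt = %g s (seed %d)\n",
              x$config$duration, x$config$dt, x$config$seed))
  cat(sprintf("  sd(x) after transient: %.4g\n",
              stats::sd(x$x[x$time >= x$config$transient_discard])))
  invisible(x)
}

#' Welch spectral estimate of a simulated trajectory
#'
#' Averaged modified periodogram: the post-transient excitatory trace is
#' split into Hann-windowed segments of `segment_seconds` with fractional
#' `overlap`, each segment is demeaned, and the one-sided periodograms are
#' averaged. The normalization is such that the integral of the estimate
#' over frequency equals the time-domain variance (density per Hz).
#'
#' @param record A [simulation_record()], or a plain numeric vector (then
#'   `fs` must be given and no transient is discarded).
#' @param segment_seconds Segment length, seconds.
#' @param overlap Fractional overlap between consecutive segments, in `[0, 1)`.
#' @param fs Sampling frequency, Hz; taken from the record when omitted.
#' @return An object of class `welch_psd`: `freq_hz`, `power` (one-sided
#'   density per Hz), `peak_freq_hz`, `df_hz` (bin width), `n_segments`.
#' @export
welch_psd <- function(record, segment_seconds = 10, overlap = 0.5, fs = NULL) {
  if (inherits(record, "simulation_record")) {
    fs <- 1 / record$config$dt
    keep <- record$time >= record$config$transient_discard
    x <- record$x[keep]
  } else {
    if (is.null(fs)) stop("`fs` required when passing a raw trace")
    x <- as.numeric(record)
  }
  nper <- round(segment_seconds * fs)
  if (length(x) < 2 * nper)
    stop("insufficient data: need at least two segments (",
         2 * segment_seconds, " s) after the transient")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / nper))  # Hann
  U <- sum(w^2) * fs                                    # normalization
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg)[seq_len(nf)])^2 / U
    acc <- acc + P
  }
  pw <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper even)
  pw[-1] <- pw[-1] * 2
  if (nper %% 2 == 0) pw[nf] <- pw[nf] / 2
  freq <- (seq_len(nf) - 1L) * fs / nper
  structure(list(freq_hz = freq, power = pw,
                 peak_freq_hz = freq[which.max(pw[-1]) + 1L],
                 df_hz = fs / nper, n_segments = length(starts)),
            class = "welch_psd")
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("Welch spectrum: %d segments, bin %.4g Hz, peak %.4g Hz\n",
              x$n_segments, x$df_hz, x$peak_freq_hz))
  invisible(x)
}

band_power <- function(freq, power, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (!any(sel)) return(NA_real_)
  sum(power[sel]) * (freq[2] - freq[1])
}

#' Compare an estimated with an analytic spectrum
#'
#' Reports the peak-frequency offset (in Welch bins), the ratio of
#' integrated power over the resolved range, and power in the conventional
#' EEG bands (delta 1-4 Hz, alpha 8-13 Hz, beta 13-30 Hz; boundaries are
#' conventions, configurable).
#'
#' @param welch A [welch_psd()] estimate.
#' @param sc A [transfer_scalars()] object (with its `noise_D`), the analytic
#'   reference. Pass the scalars of the same parameters and noise convention
#'   as the simulation (`D = kappa^2/2`).
#' @param bands Named list of `c(lo, hi)` Hz pairs.
#' @param fmax_hz Upper integration limit for the power ratio, Hz.
#' @return A list: `peak_offset_bins`, `peak_freq_sim_hz`,
#'   `peak_freq_analytic_hz`, `power_ratio` (simulated / analytic over
#'   `[0, fmax_hz]`), `band_power_sim`, `band_power_analytic`.
#' @export
compare_spectra <- function(welch, sc,
                            bands = list(delta = c(1, 4), alpha = c(8, 13),
                                         beta = c(13, 30)),
                            fmax_hz = 40) {
  stopifnot(inherits(welch, "welch_psd"), inherits(sc, "transfer_scalars"))
  f_an <- peak_frequency(sc) / (2 * pi)
  offset <- (welch$peak_freq_hz - f_an) / welch$df_hz
  sel <- welch$freq_hz <= fmax_hz
  fgrid <- welch$freq_hz[sel]
  S_an <- 4 * pi * psd(sc, 2 * pi * fgrid)  # one-sided per Hz
  pr <- sum(welch$power[sel]) / sum(S_an)
  bp_sim <- vapply(bands, function(b)
    band_power(welch$freq_hz, welch$power, b[1], b[2]), numeric(1))
  bp_an <- vapply(bands, function(b)
    band_power(fgrid, S_an, b[1], b[2]), numeric(1))
  list(peak_offset_bins = offset,
       peak_freq_sim_hz = welch$peak_freq_hz,
       peak_freq_analytic_hz = f_an,
       power_ratio = pr,
       band_power_sim = bp_sim, band_power_analytic = bp_an)
}
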