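#' Critical anesthetic factor, closed form
#'
#' The closed-form critical concentration factor separating the
#' frequency-decreasing from the frequency-increasing response regime:
#' `p0 = ( N2(1) + tau2(1) (N1 - 1) / tau1 )^-1`. At the stability-threshold
#' ratio `tau2(1)/tau1 = (N2(1)+1)/(N1-1)` this reduces algebraically to
#' `p0 = 1 / (2 N2(1) + 1) < 1`: systems at the threshold are always in the
#' frequency-increasing regime.
#'
#' @param params A [model_params()] object (the drug-free `N2_base`,
#'   `tau2_base` are used; the stored `p` is irrelevant here).
#' @return The scalar `p0` (dimensionless).
#' @export
p0_verbatim <- function(params) {
  stopifnot(inherits(params, "model_params"))
  den <- params$N2_base + params$tau2_base * (params$N1 - 1) / params$tau1
  if (den <= 0)
    stop("p0 undefined: N2(1) + tau2(1)(N1-1)/tau1 = ", den, " is not positive")
  1 / den
}

# dOmega^2/dp under the scaling N2 = N2_base p, tau2 = tau2_base p,
# exact derivative of Omega^2(p) = det(p) - Tr(p)^2/4.
d_omega2_dp <- function(params, p) {
  with(params, {
    tr <- (N1 - 1) / tau1 - (N2_base * p + 1) / (tau2_base * p)
    (1 / (tau2_base * p^2)) * ((N1 - 1) / tau1 - tr / 2)
  })
}

#' Critical anesthetic factor by numerical root finding
#'
#' Numerical companion to [p0_verbatim()]: locates a critical point of the
#' squared eigenfrequency `Omega^2(p)` along the concentration sweep by
#' sampling the central-difference derivative `dOmega^2/dp` on `[1, p_max]`
#' (restricted to the stable range) and refining any sign change with
#' [stats::uniroot()] to `1e-8`. Returns `NA` when the derivative never
#' changes sign — which, under the exact scaling of both `N2` and `tau2`
#' with `p`, is the generic outcome for a stable focus with `N1 > 1` (see
#' the vignette for why the two tracks can disagree).
#'
#' @param params A [model_params()] object, stable focus at `p = 1`.
#' @param p_max Upper end of the scan.
#' @param n Number of scan points.
#' @return Critical `p0` or `NA_real_` when there is no critical point.
#' @export
p0_numeric <- function(params, p_max = 5, n = 400) {
  stopifnot(inherits(params, "model_params"))
  base <- model_params(params$N1, params$N2_base, params$tau1,
                       params$tau2_base, params$noise_D, p = 1)
  es <- eigen_closed_form(jacobian_summary(base))
  if (es$kind != "stable_focus")
    stop("p0_numeric requires a stable focus at p = 1 (got ", es$kind, ")")
  pstar <- instability_onset(params, p_max)
  hi <- if (is.na(pstar)) p_max else pstar * (1 - 1e-9)
  pg <- seq(1, hi, length.out = n)
  h <- (hi - 1) / (10 * n)
  dnum <- vapply(pg, function(p) {
    om2 <- function(pp) {
      mp <- model_params(params$N1, params$N2_base, params$tau1,
                         params$tau2_base, params$noise_D, p = pp)
      s <- jacobian_summary(mp)
      s$determinant - s$trace^2 / 4
    }
    (om2(p + h) - om2(max(p - h, 1))) / (h + p - max(p - h, 1))
  }, numeric(1))
  sw <- which(dnum[-1] * dnum[-n] < 0)
  if (length(sw) == 0L) return(NA_real_)
  i <- sw[1]
  stats::uniroot(function(p) d_omega2_dp(params, p), c(pg[i], pg[i + 1]),
                 tol = 1e-8)$root
}

#' Concentration at which stability is lost
#'
#' Along the scaling sweep the damping weakens monotonically for `N1 > 1`;
#' this finds the onset `p*` where the trace crosses zero, by bisection
#' ([stats::uniroot()] to absolute tolerance `1e-10`). `NA` if the system is
#' still stable at `p_max`.
#'
#' @param params A [model_params()] object.
#' @param p_max Upper end of the search range.
#' @return The onset `p*`, or `NA_real_`.
#' @export
instability_onset <- function(params, p_max = 5) {
  stopifnot(inherits(params, "model_params"))
  tr_at <- function(p)
    (params$N1 - 1) / params$tau1 - (params$N2_base * p + 1) / (params$tau2_base * p)
  if (tr_at(1) >= 0) return(1)
  if (tr_at(p_max) < 0) return(NA_real_)
  stats::uniroot(tr_at, c(1, p_max), tol = 1e-10)$root
}

#' Response-regime classification for the concentration sweep
#'
#' Applies the closed-form criterion: if `p0 < 1` the squared eigenfrequency
#' increases for every `p >= 1` (`"increase_all_p"`); if `p0 >= 1` the
#' criterion predicts a non-increasing interval `1 <= p <= p0` followed by an
#' increase (`"decrease_then_increase"`). The numerical track
#' ([p0_numeric()]) is attached with an agreement flag; the two tracks are
#' reported side by side because the closed-form derivative and the exact
#' derivative of `Omega^2(p)` are not algebraically identical (see the
#' vignette), and a disagreement is surfaced, not hidden.
#'
#' @param params A [model_params()] object.
#' @param p_max Scan range for the numerical track.
#' @return An object of class `regime_report`: `p0_verbatim`, `regime`,
#'   `decrease_interval` (or `NULL`), `p0_numeric`, `regime_numeric`,
#'   `tracks_agree`.
#' @export
classify_regime <- function(params, p_max = 5) {
  p0 <- p0_verbatim(params)
  if (p0 < 1) {
    regime <- "increase_all_p"
    interval <- NULL
  } else {
    regime <- "decrease_then_increase"
    interval <- c(1, p0)
  }
  p0n <- tryCatch(p0_numeric(params, p_max), error = function(e) NA_real_)
  regime_n <- if (is.na(p0n)) "increase_all_p" else "decrease_then_increase"
  structure(list(p0_verbatim = p0, regime = regime,
                 decrease_interval = interval,
                 p0_numeric = p0n, regime_numeric = regime_n,
                 tracks_agree = identical(regime, regime_n)),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("Concentration-response regime: %s (closed-form p0 = %.6g)\n",
              x$regime, x$p0_verbatim))
  if (!is.null(x$decrease_interval))
    cat(sprintf("  predicted non-increasing frequency on p in [%g, %.6g]\n",
                x$decrease_interval[1], x$decrease_interval[2]))
  cat(sprintf("  numerical critical point: %s; tracks agree: %s\n",
              if (is.na(x$p0_numeric)) "none" else format(x$p0_numeric),
              x$tracks_agree))
  invisible(x)
}

#' Concentration sweep of damping, frequency and spectral peak
#'
#' Evaluates the full pipeline per concentration factor: effective
#' inhibitory parameters, eigenstructure, transfer scalars, spectral peak
#' frequency and peak power. Entries at or beyond the instability onset `p*`
#' (trace crossing zero, refined by bisection to `1e-10`) are flagged
#' `stable = FALSE` and their spectral columns are `NA` rather than
#' extrapolated.
#'
#' @param params A [model_params()] object (its stored `p` is ignored; the
#'   sweep sets `p` per grid point).
#' @param p_grid Increasing grid of concentration factors, `>= 1`. The
#'   default covers the clinically reasonable range `[1, 1.3]` in steps of
#'   0.01.
#' @return An object of class `propofol_sweep`: a `data.frame` with columns
#'   `p`, `R_s`, `omega_rad_s`, `f_hz`, `omega_peak_rad_s`, `f_peak_hz`,
#'   `peak_power`, `stable`; attribute `p_star` holds the refined onset
#'   (`NA` when the whole grid is stable).
#' @export
sweep_p <- function(params, p_grid = seq(1, 1.3, by = 0.01)) {
  stopifnot(inherits(params, "model_params"))
  if (is.unsorted(p_grid, strictly = TRUE)) stop("`p_grid` must be strictly increasing")
  check_p(p_grid[1])
  rows <- lapply(p_grid, function(p) {
    mp <- model_params(params$N1, params$N2_base, params$tau1,
                       params$tau2_base, params$noise_D, p = p)
    es <- eigen_closed_form(jacobian_summary(mp))
    stable <- es$kind %in% c("stable_focus", "stable_node")
    if (stable && es$kind == "stable_focus") {
      sc <- transfer_scalars(mp)
      opk <- peak_frequency(sc)
      ppow <- psd(sc, opk)
    } else {
      opk <- NA_real_; ppow <- NA_real_
    }
    data.frame(p = p, R_s = es$R, omega_rad_s = es$Omega,
               f_hz = es$Omega / (2 * pi),
               omega_peak_rad_s = opk, f_peak_hz = opk / (2 * pi),
               peak_power = ppow, stable = stable)
  })
  out <- do.call(rbind, rows)
  p_star <- instability_onset(params, p_max = max(p_grid))
  attr(out, "p_star") <- p_star
  class(out) <- c("propofol_sweep", "data.frame")
  out
}

#' Power/frequency covariation along a sweep
#'
#' Checks the headline prediction of the linear model: over the stable part
#' of a concentration sweep, every interval on which the spectral peak power
#' increases is also an interval on which the peak frequency increases.
#'
#' @param sweep A [sweep_p()] result.
#' @return A list: `holds` (logical), `n_power_up` (number of grid steps with
#'   rising peak power), `violations` (indices of steps with rising power but
#'   non-rising peak frequency).
#' @export
covariation_check <- function(sweep) {
  stopifnot(inherits(sweep, "propofol_sweep"))
  s <- sweep[sweep$stable & !is.na(sweep$peak_power), , drop = FALSE]
  if (nrow(s) < 2L)
    return(list(holds = NA, n_power_up = 0L, violations = integer(0)))
  dpow <- diff(s$peak_power)
  dfrq <- diff(s$omega_peak_rad_s)
  up <- which(dpow > 0)
  bad <- up[dfrq[up] <= 0]
  list(holds = length(bad) == 0L, n_power_up = length(up), violations = bad)
}
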