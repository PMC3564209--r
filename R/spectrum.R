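#' Transfer scalars of the excitatory response
#'
#' The analytic Green's function and spectrum of the excitatory fluctuation
#' `x(t)` depend on the eigenvalue pair `R +/- i Omega` and on the inhibitory
#' relaxation rate `Z = -(N2+1)/tau2` (the zero of the numerator of the
#' transfer function). `Z < 0` for every valid parameter set.
#'
#' @inheritParams effective_params
#' @return An object of class `transfer_scalars`: `R` (1/s), `Omega` (rad/s),
#'   `Z` (1/s), `kind`, and `noise_D` carried over from the parameters.
#' @export
transfer_scalars <- function(params, scale_N2 = TRUE) {
  ep <- effective_params(params, scale_N2)
  es <- eigen_closed_form(jacobian_summary(params, scale_N2))
  structure(list(R = es$R, Omega = es$Omega, Z = -(ep$N2 + 1) / ep$tau2,
                 kind = es$kind, noise_D = params$noise_D),
            class = "transfer_scalars")
}

#' Construct transfer scalars directly
#'
#' Convenience constructor when working in the reduced `(R, Omega, Z)`
#' coordinates rather than from gains and decay times.
#'
#' @param R Real part of the eigenvalue pair, 1/s.
#' @param Omega Imaginary part, rad/s, `>= 0`.
#' @param Z Numerator zero `-(N2+1)/tau2`, 1/s, must be `< 0`.
#' @param noise_D Noise intensity.
#' @return An object of class `transfer_scalars`.
#' @export
scalars <- function(R, Omega, Z, noise_D = 1) {
  if (Omega < 0) stop("`Omega` must be >= 0 (conjugate-pair convention)")
  if (Z >= 0) stop("`Z` must be negative: Z = -(N2+1)/tau2 < 0")
  kind <- if (R < 0 && Omega > 0) "stable_focus"
          else if (R < 0) "stable_node"
          else if (R == 0) "marginal" else "unstable"
  structure(list(R = R, Omega = Omega, Z = Z, kind = kind, noise_D = noise_D),
            class = "transfer_scalars")
}

stop_if_nonstationary <- function(sc) {
  if (sc$R >= 0)
    stop("non-stationary system (R >= 0): the stationary spectrum/response ",
         "is only defined for a damped state")
  invisible(sc)
}

#' Green's function of the excitatory fluctuation
#'
#' Causal impulse response of `x(t)`: for a stable focus,
#' `G11(t) = exp(R t) * ( (R - Z)/Omega * sin(Omega t) + cos(Omega t) )` for
#' `t >= 0` and 0 for `t < 0`; it jumps to 1 at `t = 0+`, rings at `Omega`
#' and decays with `|R|`. The degenerate double-root case (`Omega = 0`) is
#' the limit `G11(t) = exp(R t) (1 + (R - Z) t)`.
#'
#' @param sc A [transfer_scalars()] object with `R < 0`.
#' @param t Time(s), seconds; vectorized.
#' @return Numeric vector of response values.
#' @export
greens_g11 <- function(sc, t) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (sc$Omega > 0) {
    out[pos] <- exp(sc$R * tp) *
      ((sc$R - sc$Z) / sc$Omega * sin(sc$Omega * tp) + cos(sc$Omega * tp))
  } else {
    out[pos] <- exp(sc$R * tp) * (1 + (sc$R - sc$Z) * tp)
  }
  out
}

#' Analytic power spectral density of the excitatory fluctuation
#'
#' Two-sided spectral density (per rad/s) of `x(t)` driven by white noise of
#' intensity `D` on the excitatory line:
#' `S(omega) = (D/pi) * (Z^2 + omega^2) / ((M - omega^2)^2 + 4 R^2 omega^2)`
#' with `M = R^2 + Omega^2` (the determinant). Even in `omega`, strictly
#' positive for `D > 0`, and `S ~ D/(pi omega^2)` at large `omega`.
#'
#' @param sc A [transfer_scalars()] object with `R < 0`.
#' @param omega Angular frequency grid, rad/s; vectorized.
#' @param noise_D Noise intensity; defaults to the value carried by `sc`.
#' @return Numeric vector of spectral densities.
#' @export
psd <- function(sc, omega, noise_D = sc$noise_D) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  if (noise_D < 0) stop("`noise_D` must be non-negative")
  M <- sc$R^2 + sc$Omega^2
  (noise_D / pi) * (sc$Z^2 + omega^2) /
    ((M - omega^2)^2 + 4 * sc$R^2 * omega^2)
}

#' Frequency of maximum spectral power (closed form)
#'
#' Stationary-point analysis of the spectral density in `u = omega^2`: the
#' interior maximum, when it exists, sits at
#' `Omega_peak^2 = -Z^2 + sqrt((M + Z^2)^2 - 4 Z^2 R^2)`, `M = R^2 + Omega^2`.
#' When that expression is non-positive — equivalently when
#' `M^2 + 2 Z^2 M - 4 Z^2 R^2 <= 0` (strong damping) — the density is maximal
#' at `Omega_peak = 0`. In the weak-damping limit `R -> 0-` the peak tends to
#' the eigenfrequency `Omega`.
#'
#' This is the exact argmax of the analytic density; see
#' [peak_frequency_printed()] for a commonly quoted approximate closed form
#' and the vignette for the distinction.
#'
#' @param sc A [transfer_scalars()] object with `R < 0`.
#' @return Peak angular frequency in rad/s (0 allowed).
#' @export
peak_frequency <- function(sc) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  M <- sc$R^2 + sc$Omega^2
  Z2 <- sc$Z^2
  u <- -Z2 + sqrt((M + Z2)^2 - 4 * Z2 * sc$R^2)
  if (u <= 0) 0 else sqrt(u)
}

#' Approximate peak-frequency expression
#'
#' The expression `Omega_peak^2 = Omega^2 + R^2 (1 - 4 Z^2/(R^2+Omega^2+Z^2))`
#' with the accompanying rule that the maximum sits at 0 when
#' `R^4 + R^2 (2 Omega^2 - 3 Z^2) + Omega^2 (Omega^2 + Z^2) < 0`. It agrees
#' with the exact argmax of the spectral density only in the limit `R -> 0-`
#' (both tend to `Omega`); at finite damping it deviates already at order
#' `R^2` and is retained here for comparison and documentation purposes only.
#' Use [peak_frequency()] for analysis.
#'
#' @inheritParams peak_frequency
#' @return Peak angular frequency in rad/s (0 allowed).
#' @export
peak_frequency_printed <- function(sc) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  M <- sc$R^2 + sc$Omega^2
  Z2 <- sc$Z^2
  if (sc$R^4 + sc$R^2 * (2 * sc$Omega^2 - 3 * Z2) + sc$Omega^2 * (sc$Omega^2 + Z2) < 0)
    return(0)
  u <- sc$Omega^2 + sc$R^2 * (1 - 4 * Z2 / (M + Z2))
  if (u <= 0) 0 else sqrt(u)
}

#' Peak frequency by dense grid search
#'
#' Brute-force argmax of the analytic density: a dense grid over
#' `[0, 5 * max(Omega, |Z|, |R|)]` refined by [stats::optimize()] (golden
#' section) around the best grid point. Serves as the independent check of
#' the closed form in [peak_frequency()].
#'
#' @inheritParams peak_frequency
#' @param n_grid Number of grid points.
#' @return Peak angular frequency in rad/s.
#' @export
peak_frequency_grid <- function(sc, n_grid = 1e5) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  hi <- 5 * max(sc$Omega, abs(sc$Z), abs(sc$R))
  w <- seq(0, hi, length.out = n_grid)
  s <- psd(sc, w, noise_D = 1)
  i <- which.max(s)
  if (i == 1L) {
    # omega = 0 is always a stationary point (the density is even); when the
    # best grid point is the boundary, refine and keep 0 unless the interior
    # wins by more than rounding noise
    opt <- stats::optimize(function(x) -psd(sc, x, noise_D = 1),
                           c(0, w[2]), tol = 1e-14)
    return(if (-opt$objective > psd(sc, 0, 1) * (1 + 1e-9)) opt$minimum else 0)
  }
  lo <- w[max(i - 1L, 1L)]; up <- w[min(i + 1L, n_grid)]
  stats::optimize(function(x) -psd(sc, x, noise_D = 1), c(lo, up),
                  tol = 1e-14)$minimum
}

#' Signs of the peak-frequency response to damping and eigenfrequency
#'
#' Determines how the spectral peak moves when the damping `R` or the
#' eigenfrequency `Omega` changes, by central finite differences of the
#' closed-form [peak_frequency()] (relative step `1e-6`), holding `Z` fixed.
#' The four possible sign pairs are labelled in the convention
#' `(+) = both positive`, `(-+) = dOmega_peak/dOmega < 0, dOmega_peak/dR > 0`,
#' `(-) = both negative`, `(+-) = dOmega_peak/dOmega > 0, dOmega_peak/dR < 0`.
#' For large eigenfrequencies (`Omega >> |Z|`) both derivatives are positive:
#' the peak rises with reduced damping and with the eigenfrequency.
#'
#' @inheritParams peak_frequency
#' @param rel_step Relative finite-difference step.
#' @return A list: `sign_dR`, `sign_dOmega` (each -1, 0 or +1), `dR`,
#'   `dOmega` (the derivative estimates) and a `label`.
#' @export
peak_gradient_signs <- function(sc, rel_step = 1e-6) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  if (peak_frequency(sc) == 0)
    stop("no interior spectral maximum: gradient signs undefined at ",
         "Omega_peak = 0")
  hR <- rel_step * max(abs(sc$R), 1e-8)
  hO <- rel_step * max(sc$Omega, 1e-8)
  pf <- function(R, Omega) {
    M <- R^2 + Omega^2; Z2 <- sc$Z^2
    u <- -Z2 + sqrt((M + Z2)^2 - 4 * Z2 * R^2)
    if (u <= 0) 0 else sqrt(u)
  }
  dR <- (pf(sc$R + hR, sc$Omega) - pf(sc$R - hR, sc$Omega)) / (2 * hR)
  dO <- (pf(sc$R, sc$Omega + hO) - pf(sc$R, sc$Omega - hO)) / (2 * hO)
  lab <- if (dO > 0 && dR > 0) "(+)"
         else if (dO < 0 && dR > 0) "(-+)"
         else if (dO < 0 && dR < 0) "(-)"
         else "(+-)"
  list(sign_dR = sign(dR), sign_dOmega = sign(dO),
       dR = dR, dOmega = dO, label = lab)
}

#' Total variance of the excitatory fluctuation by spectral quadrature
#'
#' Integrates the two-sided analytic density over the whole real line:
#' adaptive quadrature ([stats::integrate()]) on `[0, cutoff]` doubled by
#' symmetry, plus the analytic tail `integral of D/(pi omega^2)` beyond the
#' cutoff, `= D/(pi * cutoff)` per side. The result equals the stationary
#' variance of `x` from the Lyapunov (fluctuation-dissipation) balance of the
#' same linear system, which [lyapunov_variance()] computes independently.
#'
#' @inheritParams psd
#' @param cutoff_factor The cutoff is `cutoff_factor * max(Omega, |Z|, |R|)`.
#' @return Total variance (squared potential units).
#' @export
spectrum_variance <- function(sc, noise_D = sc$noise_D, cutoff_factor = 200) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  if (noise_D == 0) return(0)
  cutoff <- cutoff_factor * max(sc$Omega, abs(sc$Z), abs(sc$R))
  core <- stats::integrate(function(w) psd(sc, w, noise_D), 0, cutoff,
                           rel.tol = 1e-12, abs.tol = 0,
                           subdivisions = 2000L)$value
  tail <- noise_D / (pi * cutoff)
  2 * (core + tail)
}

#' Stationary variance from the Lyapunov balance
#'
#' Independent route to the variance of `x`: solves the continuous Lyapunov
#' equation `A P + P A' + Q = 0` for the stationary covariance `P` of the
#' linear system driven by white noise on the excitatory line
#' (`Q = diag(2 D, 0)`), via the Kronecker-product linear system. Returns
#' `P[1, 1]`.
#'
#' @inheritParams effective_params
#' @param noise_D Noise intensity; defaults to the value in `params`.
#' @return Stationary variance of `x`.
#' @export
lyapunov_variance <- function(params, scale_N2 = TRUE, noise_D = params$noise_D) {
  A <- jacobian_matrix(params, scale_N2)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("non-stationary system: Lyapunov equation has no positive solution")
  Q <- matrix(c(2 * noise_D, 0, 0, 0), 2, 2)
  I2 <- diag(2)
  vecP <- solve(kronecker(I2, A) + kronecker(A, I2), -as.vector(Q))
  vecP[1]
}

#' Analytic spectrum over a frequency grid
#'
#' Evaluates the analytic density on a regular frequency grid and bundles it
#' with the peak location, peak height and total variance.
#'
#' @param sc A [transfer_scalars()] object with `R < 0`.
#' @param noise_D Noise intensity; defaults to the value carried by `sc`.
#' @param fmax_hz Upper frequency of the grid, Hz.
#' @param df_hz Grid spacing, Hz.
#' @return An object of class `spectrum_result`: `omega_grid` (rad/s),
#'   `S_values` (two-sided density per rad/s), `freq_hz`, `S_onesided`
#'   (one-sided density per Hz, i.e. `4 pi S`), `omega_peak`, `f_peak_hz`,
#'   `peak_power`, `total_variance`, and the `scalars` used.
#' @export
spectrum_result <- function(sc, noise_D = sc$noise_D, fmax_hz = 40,
                            df_hz = 0.05) {
  stopifnot(inherits(sc, "transfer_scalars"))
  stop_if_nonstationary(sc)
  freq <- seq(0, fmax_hz, by = df_hz)
  omega <- 2 * pi * freq
  S <- psd(sc, omega, noise_D)
  opk <- peak_frequency(sc)
  structure(list(
    omega_grid = omega, S_values = S, freq_hz = freq,
    S_onesided = 4 * pi * S,
    omega_peak = opk, f_peak_hz = opk / (2 * pi),
    peak_power = psd(sc, opk, noise_D),
    total_variance = spectrum_variance(sc, noise_D),
    scalars = sc
  ), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("Analytic power spectrum\n")
  cat(sprintf("  peak at %.6g rad/s (%.6g Hz), density %.6g\n",
              x$omega_peak, x$f_peak_hz, x$peak_power))
  cat(sprintf("  total variance %.6g\n", x$total_variance))
  invisible(x)
}
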