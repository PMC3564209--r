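#' Stable-focus band in the ratio of synaptic decay times
#'
#' For gains with `N1 != 1` the eigenvalues are complex (the fixed point is a
#' focus) exactly when the ratio `r = tau2/tau1` lies strictly between the
#' two roots of the quadratic `a r^2 - 2 b r + c = 0`, with `a = (N1-1)^2`,
#' `b = N1 N2 - N1 + N2 + 1`, `c = (N2+1)^2`. The band is non-empty iff
#' `b^2 > a c`. The *stability* threshold inside the band is the trace-zero
#' ratio `sqrt(c/a) = (N2+1)/(N1-1)`, which is the geometric mean of the two
#' band edges and therefore always lies inside a non-degenerate band.
#'
#' @param summary A [jacobian_summary()] object (only the gain variables are
#'   used; the band is a statement about the ratio `tau2/tau1`).
#' @return An object of class `focus_band`: `ratio_low`, `ratio_high`,
#'   `threshold_ratio`, `exists`. When `b^2 < a c` the band is empty and the
#'   ratios are `NA`; when `b^2 = a c` it collapses to the single point `b/a`.
#' @export
focus_band <- function(summary) {
  stopifnot(inherits(summary, "jacobian_summary"))
  a <- summary$sq_a; b <- summary$sq_b; cc <- summary$sq_c
  if (a <= 0)
    stop("focus band undefined for N1 = 1 (sq_a = 0): the quadratic degenerates")
  disc <- b^2 - a * cc
  if (disc < 0)
    return(structure(list(ratio_low = NA_real_, ratio_high = NA_real_,
                          threshold_ratio = sqrt(cc / a), exists = FALSE),
                     class = "focus_band"))
  s <- sqrt(disc)
  structure(list(ratio_low = (b - s) / a, ratio_high = (b + s) / a,
                 threshold_ratio = sqrt(cc / a), exists = disc > 0),
            class = "focus_band")
}

#' @export
print.focus_band <- function(x, ...) {
  if (!x$exists && is.na(x$ratio_low)) {
    cat("Focus band: empty (b^2 < a c)\n")
  } else {
    cat(sprintf("Focus band: tau2/tau1 in [%.6g, %.6g]\n",
                x$ratio_low, x$ratio_high))
    cat(sprintf("  stability threshold at tau2/tau1 = %.6g\n", x$threshold_ratio))
  }
  invisible(x)
}

# Omega as a function of the ratio r = tau2/tau1, at fixed gains and tau1.
# Omega^2 = (2 b / r - a - c / r^2) / (4 tau1^2); negative values clipped to 0.
omega_of_ratio <- function(summary, tau1, r) {
  a <- summary$sq_a; b <- summary$sq_b; cc <- summary$sq_c
  v <- (2 * b / r - a - cc / r^2) / (4 * tau1^2)
  sqrt(pmax(v, 0))
}

#' Maximum eigenfrequency over the inhibitory decay time
#'
#' At fixed gains and fixed `tau1` the eigenfrequency `Omega(tau2)` vanishes
#' on both edges of the focus band and has a unique interior maximum at
#' `tau2/tau1 = c/b`, where it takes the value
#' `omega_m = sqrt(b^2/c - a) / (2 tau1)`. Because the stationary ratio `c/b`
#' is always inside a non-degenerate band, every parameter set with a focus
#' band has `omega_m > 0`; on a collapsed band (`b^2 = ac`) it is 0.
#'
#' @param summary A [jacobian_summary()] object.
#' @param tau1 Excitatory decay time, seconds.
#' @return A list: `tau2_star` (seconds), `ratio_star = c/b`, `omega_m`
#'   (rad/s), `f_m_hz`, and `inside_band` (logical; `FALSE` only for a
#'   degenerate band, where the argmax sits on the collapsed edge).
#' @export
max_frequency <- function(summary, tau1) {
  stopifnot(inherits(summary, "jacobian_summary"), tau1 > 0)
  band <- focus_band(summary)
  if (!band$exists && is.na(band$ratio_low))
    stop("no focus band: Omega = 0 for every tau2 at these gains")
  a <- summary$sq_a; b <- summary$sq_b; cc <- summary$sq_c
  r_star <- cc / b
  inside <- band$exists && r_star > band$ratio_low && r_star < band$ratio_high
  if (!inside && band$exists)
    warning("stationary ratio c/b falls outside the focus band; ",
            "reporting the band-edge value")
  omega_m <- sqrt(max(b^2 / cc - a, 0)) / (2 * tau1)
  list(tau2_star = tau1 * r_star, ratio_star = r_star,
       omega_m = omega_m, f_m_hz = omega_m / (2 * pi), inside_band = inside)
}

#' Hopf-threshold locus at a requested oscillation frequency
#'
#' Solves for the gain/decay-time combination at which the system sits
#' exactly on the oscillatory (Hopf) instability threshold with a prescribed
#' eigenfrequency. On the threshold the trace vanishes, giving
#' `tau2 = tau1 (N2+1)/(N1-1)`, and the squared eigenfrequency reduces to
#' `Omega^2 tau1^2 = (N2 - N1 + 1)(N1 - 1)/(N2 + 1)`, which increases
#' monotonically in `N2` toward the supremum `N1 - 1`. The solver finds `N2`
#' by root bracketing ([stats::uniroot()], tolerance `1e-12`) and errors when
#' the requested frequency exceeds the attainable limit.
#'
#' @param frequency Requested oscillation frequency, Hz, `> 0`.
#' @param tau1 Excitatory decay time, seconds.
#' @param N1 Excitatory gain, must be `> 1` (stability can only be lost for
#'   `N1 > 1`).
#' @param N2_max Upper end of the `N2` search bracket.
#' @return An object of class `hopf_locus_point`: `N1`, `N2`, `tau2`
#'   (seconds), `frequency` (Hz), `trace` (should be 0 to rounding).
#' @export
hopf_locus <- function(frequency, tau1, N1, N2_max = 10) {
  stopifnot(frequency > 0, tau1 > 0)
  if (N1 <= 1)
    stop("Hopf threshold requires N1 > 1")
  target <- (2 * pi * frequency * tau1)^2
  if (target >= N1 - 1)
    stop(sprintf(paste0("requested frequency %.4g Hz is unattainable on the ",
                        "threshold: (2 pi f tau1)^2 = %.4g >= N1 - 1 = %.4g"),
                 frequency, target, N1 - 1))
  g <- function(N2) (N2 - N1 + 1) * (N1 - 1) / (N2 + 1) - target
  lo <- N1 - 1 + 1e-12
  if (g(N2_max) < 0)
    stop("no solution with N2 <= N2_max = ", N2_max,
         "; raise `N2_max` or lower the frequency")
  N2 <- stats::uniroot(g, c(lo, N2_max), tol = 1e-12)$root
  tau2 <- tau1 * (N2 + 1) / (N1 - 1)
  structure(list(N1 = N1, N2 = N2, tau2 = tau2, frequency = frequency,
                 trace = (N1 - 1) / tau1 - (N2 + 1) / tau2),
            class = "hopf_locus_point")
}

#' @export
print.hopf_locus_point <- function(x, ...) {
  cat(sprintf("Hopf-threshold point at %g Hz:\n", x$frequency))
  cat(sprintf("  N1 = %g, N2 = %.8g, tau2 = %.8g s (trace %.3g 1/s)\n",
              x$N1, x$N2, x$tau2, x$trace))
  invisible(x)
}

#' Sign pattern of dOmega/dtau2 across the stable part of the focus band
#'
#' Classifies how the eigenfrequency responds to prolonging the inhibitory
#' decay time, by numerically sampling the sign of `dOmega/dtau2` (central
#' differences on `>= n_points` ratios) across the stable part of the focus
#' band, i.e. from the lower band edge up to the trace-zero threshold
#' `sqrt(c/a)`. Two outcomes occur: the frequency rises to an interior
#' maximum and then falls (`"increase_then_decrease"`, with the turning ratio
#' reported and polished by [stats::optimize()]), or it rises monotonically
#' all the way to the stability threshold (`"monotonic_increase"`).
#'
#' The classification is by sampling, not by closed-form bounds; the turning
#' ratio coincides with `c/b` from [max_frequency()] whenever that ratio is
#' below the threshold.
#'
#' @param summary A [jacobian_summary()] object.
#' @param tau1 Excitatory decay time, seconds.
#' @param n_points Number of sample ratios (at least 200 are used).
#' @return A list: `pattern`, `turning_ratio` (`NA` when monotonic),
#'   `ratio_range` examined, and the sampled `signs` table.
#' @export
omega_monotonicity <- function(summary, tau1, n_points = 201) {
  stopifnot(inherits(summary, "jacobian_summary"), tau1 > 0)
  band <- focus_band(summary)
  if (!band$exists)
    stop("monotonicity classification requires a non-degenerate focus band")
  r_lo <- band$ratio_low
  r_hi <- min(band$ratio_high, band$threshold_ratio)
  n_points <- max(n_points, 201)
  eps <- (r_hi - r_lo) * 1e-6
  r <- seq(r_lo + eps, r_hi - eps, length.out = n_points)
  h <- (r_hi - r_lo) / (4 * n_points)
  dOm <- (omega_of_ratio(summary, tau1, r + h) -
          omega_of_ratio(summary, tau1, r - h)) / (2 * h)
  sgn <- sign(dOm)
  if (all(sgn >= 0)) {
    pattern <- "monotonic_increase"
    turning <- NA_real_
  } else {
    pattern <- "increase_then_decrease"
    opt <- stats::optimize(function(rr) -omega_of_ratio(summary, tau1, rr),
                           c(r_lo, r_hi), tol = 1e-12)
    turning <- opt$minimum
  }
  list(pattern = pattern, turning_ratio = turning,
       ratio_range = c(r_lo, r_hi),
       signs = data.frame(ratio = r, dOmega_dratio = dOm))
}
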