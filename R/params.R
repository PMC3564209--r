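#' Model parameters of the linear two-population model
#'
#' Bundles the parameters of the zero-wavenumber (spatially constant) mode of
#' the excitatory-inhibitory population model: the dimensionless synaptic
#' gains, the synaptic decay times, the white-noise intensity driving the
#' excitatory line, and the anesthetic factor `p` that scales the inhibitory
#' synapse. All times are in seconds; `p = 1` means no anesthetic.
#'
#' The inhibitory gain and decay time stored here are the drug-free values
#' `N2_base` and `tau2_base`; the values at concentration factor `p` are
#' obtained with [effective_params()].
#'
#' @param N1 Dimensionless excitatory gain, `>= 0`.
#' @param N2_base Dimensionless inhibitory gain at `p = 1`, `>= 0`.
#' @param tau1 Excitatory synaptic decay time, seconds, `> 0`.
#' @param tau2_base Inhibitory synaptic decay time at `p = 1`, seconds, `> 0`.
#' @param noise_D Noise intensity `D` of the driving white noise
#'   (autocorrelation `2 D delta(t)`), in squared potential units times
#'   seconds. Non-negative.
#' @param p Anesthetic factor, dimensionless, `>= 1`.
#' @return An object of class `model_params` (a named list).
#' @seealso [effective_params()], [jacobian_summary()], [eigen_closed_form()]
#' @examples
#' mp <- model_params(N1 = 1.1, N2_base = 0.2236, tau1 = 0.002,
#'                    tau2_base = 0.02, noise_D = 1)
#' eigen_closed_form(jacobian_summary(mp))
#' @export
model_params <- function(N1, N2_base, tau1, tau2_base, noise_D = 1, p = 1) {
  stopifnot(is.numeric(N1), length(N1) == 1L,
            is.numeric(N2_base), length(N2_base) == 1L,
            is.numeric(tau1), length(tau1) == 1L,
            is.numeric(tau2_base), length(tau2_base) == 1L,
            is.numeric(noise_D), length(noise_D) == 1L,
            is.numeric(p), length(p) == 1L)
  if (!is.finite(tau1) || tau1 <= 0) stop("`tau1` must be a positive time in seconds")
  if (!is.finite(tau2_base) || tau2_base <= 0) stop("`tau2_base` must be a positive time in seconds")
  if (N1 < 0) stop("`N1` must be non-negative")
  if (N2_base < 0) stop("`N2_base` must be non-negative")
  if (noise_D < 0) stop("`noise_D` must be non-negative")
  check_p(p)
  structure(list(N1 = N1, N2_base = N2_base, tau1 = tau1,
                 tau2_base = tau2_base, noise_D = noise_D, p = p),
            class = "model_params")
}

check_p <- function(p) {
  if (!is.finite(p) || p < 1)
    stop("anesthetic factor `p` must satisfy p >= 1 (p = 1 is the drug-free ",
         "state; the clinical convention only scales the inhibitory synapse up)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Linear E/I population model parameters\n")
  cat(sprintf("  N1 = %g, N2(1) = %g, tau1 = %g s, tau2(1) = %g s\n",
              x$N1, x$N2_base, x$tau1, x$tau2_base))
  cat(sprintf("  noise D = %g, anesthetic factor p = %g\n", x$noise_D, x$p))
  ep <- effective_params(x)
  cat(sprintf("  at p: N2 = %g, tau2 = %g s\n", ep$N2, ep$tau2))
  invisible(x)
}

#' Inhibitory-synapse parameters at the current anesthetic factor
#'
#' Applies the propofol scaling law: the inhibitory decay time is prolonged
#' proportionally to the concentration factor, `tau2(p) = tau2(1) * p`, and,
#' because the response amplitude stays constant while the charge transfer
#' grows, the inhibitory gain scales the same way, `N2(p) = N2(1) * p`.
#'
#' `scale_N2 = FALSE` freezes the gain at its drug-free value while still
#' prolonging the decay time. This variant corresponds to the alternative
#' reading in which only the synaptic time scale responds to the drug; it is
#' provided as an explicit switch because parts of the stability discussion
#' assume it.
#'
#' @param params A [model_params()] object.
#' @param scale_N2 Logical; scale the inhibitory gain with `p` (default) or
#'   keep it frozen at `N2_base`.
#' @return A list with elements `N2` and `tau2` (seconds).
#' @export
effective_params <- function(params, scale_N2 = TRUE) {
  stopifnot(inherits(params, "model_params"))
  check_p(params$p)
  list(N2 = if (scale_N2) params$N2_base * params$p else params$N2_base,
       tau2 = params$tau2_base * params$p)
}

#' System matrix of the linearized zero-wavenumber mode
#'
#' The fluctuations `(x, y)` of the excitatory and inhibitory potentials about
#' the stationary state obey `d/dt (x, y) = A (x, y) + (gamma(t), 0)`, with
#'
#' `A = [ (N1-1)/tau1, -N1/tau1 ; N2/tau2, -(N2+1)/tau2 ]`.
#'
#' @inheritParams effective_params
#' @return A numeric 2x2 matrix (units 1/seconds).
#' @export
jacobian_matrix <- function(params, scale_N2 = TRUE) {
  ep <- effective_params(params, scale_N2)
  matrix(c((params$N1 - 1) / params$tau1, ep$N2 / ep$tau2,
           -params$N1 / params$tau1, -(ep$N2 + 1) / ep$tau2),
         nrow = 2L, ncol = 2L)
}

#' Trace, determinant and the reduced gain variables
#'
#' Computes the trace `Tr = (N1-1)/tau1 - (N2+1)/tau2` and determinant
#' `det = (N2 - N1 + 1)/(tau1 tau2)` of the 2x2 system matrix, together with
#' the reduced gain-only variables used throughout the stability geometry:
#' `sq_a = (N1-1)^2`, `sq_b = N1 N2 - N1 + N2 + 1`, `sq_c = (N2+1)^2`.
#' (The `sq_` prefix keeps these apart from the synaptic efficacies of the
#' biophysical layer, which the literature also calls `a`.)
#'
#' @inheritParams effective_params
#' @return An object of class `jacobian_summary`: list with `trace` (1/s),
#'   `determinant` (1/s^2), `sq_a`, `sq_b`, `sq_c` (dimensionless), and the
#'   effective `N1`, `N2`, `tau1`, `tau2` it was built from.
#' @export
jacobian_summary <- function(params, scale_N2 = TRUE) {
  ep <- effective_params(params, scale_N2)
  N1 <- params$N1; N2 <- ep$N2; tau1 <- params$tau1; tau2 <- ep$tau2
  structure(list(
    trace = (N1 - 1) / tau1 - (N2 + 1) / tau2,
    determinant = (N2 - N1 + 1) / (tau1 * tau2),
    sq_a = (N1 - 1)^2,
    sq_b = N1 * N2 - N1 + N2 + 1,
    sq_c = (N2 + 1)^2,
    N1 = N1, N2 = N2, tau1 = tau1, tau2 = tau2
  ), class = "jacobian_summary")
}

eigen_structure <- function(R, Omega, kind) {
  structure(list(R = R, Omega = Omega, kind = kind,
                 frequency_hz = Omega / (2 * pi)),
            class = "eigen_structure")
}

#' @export
print.eigen_structure <- function(x, ...) {
  cat(sprintf("Eigenstructure: %s\n", x$kind))
  cat(sprintf("  R = %.6g 1/s, Omega = %.6g rad/s (%.6g Hz)\n",
              x$R, x$Omega, x$frequency_hz))
  invisible(x)
}

#' Closed-form eigenstructure of the 2x2 system
#'
#' Solves the characteristic equation `lambda^2 - lambda Tr + det = 0` in
#' closed form. When the discriminant `det - Tr^2/4` is positive the roots are
#' the complex-conjugate pair `R +/- i Omega` with `R = Tr/2` and
#' `Omega = sqrt(det - Tr^2/4)`; otherwise the roots are real and `Omega = 0`.
#'
#' Classification: `stable_focus` for a damped complex pair (`R < 0`,
#' `Omega > 0`), `stable_node` for real roots all strictly negative
#' (including the degenerate double root), `marginal` when the leading root
#' is zero to within `tol`, and `unstable` when it is positive. For real
#' roots `R` reports the leading (largest) root.
#'
#' @param summary A [jacobian_summary()] object.
#' @param tol Absolute tolerance (1/s) for calling the leading real part zero.
#' @return An object of class `eigen_structure`: `R` (1/s), `Omega` (rad/s,
#'   `>= 0`), `kind`, and `frequency_hz = Omega/(2*pi)`.
#' @export
eigen_closed_form <- function(summary, tol = 1e-12) {
  stopifnot(inherits(summary, "jacobian_summary"))
  tr <- summary$trace; dt <- summary$determinant
  disc <- dt - tr^2 / 4
  scale <- max(abs(tr), sqrt(abs(dt)), 1)
  if (disc > 0) {
    R <- tr / 2
    Omega <- sqrt(disc)
    kind <- if (abs(R) <= tol * scale) "marginal"
            else if (R < 0) "stable_focus" else "unstable"
    return(eigen_structure(R, Omega, kind))
  }
  # real roots Tr/2 +/- sqrt(-disc); leading root is the larger
  lead <- tr / 2 + sqrt(-disc)
  kind <- if (abs(lead) <= tol * scale) "marginal"
          else if (lead < 0) "stable_node" else "unstable"
  eigen_structure(lead, 0, kind)
}

#' Eigenstructure by numerical eigendecomposition
#'
#' Numerically exact companion to [eigen_closed_form()]: builds the 2x2
#' system matrix and diagonalizes it with [base::eigen()]. Complex pairs are
#' reported with `Omega >= 0`.
#'
#' @inheritParams effective_params
#' @param tol Absolute tolerance (1/s) for calling the leading real part zero.
#' @return An object of class `eigen_structure`.
#' @export
eigen_numeric <- function(params, scale_N2 = TRUE, tol = 1e-12) {
  A <- jacobian_matrix(params, scale_N2)
  ev <- eigen(A, only.values = TRUE)$values
  scale <- max(abs(A), 1)
  im <- max(abs(Im(ev)))
  if (im > 0) {
    R <- Re(ev[1])
    kind <- if (abs(R) <= tol * scale) "marginal"
            else if (R < 0) "stable_focus" else "unstable"
    return(eigen_structure(R, im, kind))
  }
  lead <- max(Re(ev))
  kind <- if (abs(lead) <= tol * scale) "marginal"
          else if (lead < 0) "stable_node" else "unstable"
  eigen_structure(lead, 0, kind)
}
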