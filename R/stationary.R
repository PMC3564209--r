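#' Population firing-rate function
#'
#' Constructs a monotone firing-rate function for one population. Two families
#' are provided: the logistic sigmoid
#' `S(V) = max_rate / (1 + exp(-(V - threshold)/slope))` (the standard choice
#' in the neural-field literature) and the identity `S(V) = V` (useful for
#' analytically solvable tests). Both carry an analytic derivative.
#'
#' @param family `"logistic"` or `"identity"`.
#' @param max_rate Maximum rate of the logistic, same units as the output.
#' @param slope Slope parameter `sigma` (potential units) of the logistic;
#'   smaller is steeper. Must be `> 0`.
#' @param threshold Inflection potential `theta` of the logistic.
#' @return An object of class `rate_function`: list with `fn`, `deriv`,
#'   `family` and the parameters.
#' @export
rate_function <- function(family = c("logistic", "identity"),
                          max_rate = 1, slope = 1, threshold = 0) {
  family <- match.arg(family)
  if (family == "logistic") {
    if (slope <= 0) stop("logistic `slope` must be positive")
    fn <- function(V) max_rate / (1 + exp(-(V - threshold) / slope))
    deriv <- function(V) {
      s <- fn(V) / max_rate
      max_rate * s * (1 - s) / slope
    }
  } else {
    fn <- function(V) V
    deriv <- function(V) rep(1, length(V))
  }
  structure(list(fn = fn, deriv = deriv, family = family,
                 max_rate = max_rate, slope = slope, threshold = threshold),
            class = "rate_function")
}

#' Biophysical parameters of the two populations
#'
#' The layer beneath the dimensionless gains: synaptic efficacies, constant
#' external input, the zero-wavenumber totals of the connectivity kernels
#' (`Ktilde(0) * L` for each population), and the firing-rate functions.
#' The inhibitory efficacy at concentration factor `p` is `H0 * p` (constant
#' response amplitude, growing charge transfer).
#'
#' @param efficacy_e Excitatory synaptic efficacy `a_e`.
#' @param H0 Inhibitory efficacy scale; `a_i(p) = H0 * p`.
#' @param I0 Constant external input (potential units).
#' @param kernel_e_total,kernel_i_total Zero-wavenumber kernel totals,
#'   dimensionless, `>= 0`.
#' @param firing_e,firing_i [rate_function()] objects.
#' @return An object of class `population_params`.
#' @export
population_params <- function(efficacy_e, H0, I0 = 0,
                              kernel_e_total = 1, kernel_i_total = 1,
                              firing_e = rate_function(),
                              firing_i = rate_function()) {
  stopifnot(inherits(firing_e, "rate_function"),
            inherits(firing_i, "rate_function"))
  if (kernel_e_total < 0 || kernel_i_total < 0)
    stop("kernel totals must be non-negative")
  structure(list(efficacy_e = efficacy_e, H0 = H0, I0 = I0,
                 kernel_e_total = kernel_e_total,
                 kernel_i_total = kernel_i_total,
                 firing_e = firing_e, firing_i = firing_i),
            class = "population_params")
}

#' Stationary states of the effective potential
#'
#' Solves the scalar fixed-point equation for the effective potential
#' `V- = Ve0 - Vi0`,
#' `V- = a_e S_e(V-) - a_i(p) S_i(V-) + I0`,
#' by locating every sign change of the residual map on a grid over
#' `interval` and polishing each bracket with [stats::uniroot()]. The map may
#' have several roots; all of them are returned, sorted ascending, and
#' downstream code must select one explicitly by index.
#'
#' @param pop A [population_params()] object.
#' @param p Anesthetic factor, `>= 1`.
#' @param interval Search interval for `V-` (potential units).
#' @param n_grid Number of grid points used to bracket sign changes.
#' @param tol Absolute residual tolerance for convergence.
#' @return An object of class `fixed_points`: a list of fixed points, each
#'   with `V_minus`, `V_e0`, `V_i0`, `residual`, `converged`.
#' @export
solve_fixed_point <- function(pop, p = 1, interval = c(-100, 100),
                              n_grid = 4096, tol = 1e-10) {
  stopifnot(inherits(pop, "population_params"))
  check_p(p)
  a_i <- pop$H0 * p
  g <- function(V) {
    pop$efficacy_e * pop$firing_e$fn(V) - a_i * pop$firing_i$fn(V) +
      pop$I0 - V
  }
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  gv <- g(grid)
  roots <- grid[gv == 0]
  sw <- which(gv[-1] * gv[-n_grid] < 0)
  for (i in sw) {
    r <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = .Machine$double.eps^0.75)
    roots <- c(roots, r$root)
  }
  if (length(roots) == 0L)
    stop("no sign change of the fixed-point map on the configured interval; ",
         "widen `interval` or check the rate functions")
  roots <- sort(unique(roots))
  fps <- lapply(roots, function(V) {
    res <- abs(g(V))
    list(V_minus = V,
         V_e0 = pop$efficacy_e * pop$firing_e$fn(V) + pop$I0,
         V_i0 = a_i * pop$firing_i$fn(V),
         residual = res,
         converged = res < tol)
  })
  structure(fps, class = "fixed_points")
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("%d stationary state(s):\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  [%d] V- = %.8g (residual %.2e, %s)\n", i, x[[i]]$V_minus,
                x[[i]]$residual,
                if (x[[i]]$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Linearization gains at a stationary state
#'
#' Derives the dimensionless gains of the linear model from the biophysical
#' layer: `N1 = a_e S_e'(V-) Ke_tot` and `N2 = a_i(p) S_i'(V-) Ki_tot`,
#' where the derivative is evaluated at the selected stationary effective
#' potential. The analytic derivative of the rate family is used when
#' available and cross-checked against a central difference (step `1e-6`); a
#' relative disagreement beyond `1e-6` raises a warning.
#'
#' @param pop A [population_params()] object.
#' @param fp One element of a [solve_fixed_point()] result (or the whole
#'   `fixed_points` object, in which case `index` selects one).
#' @param p Anesthetic factor.
#' @param index Which fixed point to use when `fp` is a `fixed_points` list.
#' @return A list with `N1`, `N2` (both `>= 0` for monotone rates) and the
#'   `V_minus` they were evaluated at.
#' @export
gains_from_fixed_point <- function(pop, fp, p = 1, index = 1L) {
  stopifnot(inherits(pop, "population_params"))
  check_p(p)
  if (inherits(fp, "fixed_points")) fp <- fp[[index]]
  if (!isTRUE(fp$converged))
    stop("fixed point did not converge (residual ", fp$residual, ")")
  V <- fp$V_minus
  h <- 1e-6
  d_num <- function(rf) (rf$fn(V + h) - rf$fn(V - h)) / (2 * h)
  d_of <- function(rf) {
    da <- rf$deriv(V)
    dn <- d_num(rf)
    if (abs(da) > 0 && abs(dn - da) / abs(da) > 1e-6)
      warning("analytic and central-difference rate derivatives disagree ",
              "beyond 1e-6 relative at V- = ", V)
    da
  }
  list(N1 = pop$efficacy_e * d_of(pop$firing_e) * pop$kernel_e_total,
       N2 = pop$H0 * p * d_of(pop$firing_i) * pop$kernel_i_total,
       V_minus = V)
}
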