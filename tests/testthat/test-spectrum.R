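test_that("Green's function: causality, jump, and matrix-exponential oracle", {
  sc <- transfer_scalars(alpha_base())
  expect_identical(greens_g11(sc, c(-1, -0.01)), c(0, 0))
  expect_equal(greens_g11(sc, 0), 1)

  # impulse response of the first state equals [expm(A t)]_{11}
  A <- jacobian_matrix(alpha_base())
  for (t in c(0.001, 0.01, 0.05, 0.2)) {
    ref <- Matrix::expm(A * t)[1, 1]
    expect_equal(greens_g11(sc, t), ref, tolerance = 1e-8)
  }
})

test_that("undamped ringing of the Green's function has period 2*pi/Omega", {
  sc <- transfer_scalars(alpha_base())
  # strip the damping and locate successive zero crossings
  g <- function(t) exp(-sc$R * t) * greens_g11(sc, t)
  tt <- seq(1e-4, 0.5, by = 1e-4)
  gv <- g(tt)
  idx <- which(gv[-1] * gv[-length(gv)] < 0)
  zeros <- vapply(idx, function(i)
    uniroot(g, c(tt[i], tt[i + 1]), tol = 1e-14)$root, numeric(1))
  expect_gt(length(zeros), 5)
  expect_equal(diff(zeros), rep(pi / sc$Omega, length(zeros) - 1),
               tolerance = 1e-6)
})

test_that("analytic density: zero-frequency value, symmetry, asymptotics, linearity", {
  sc <- transfer_scalars(alpha_base(noise_D = 1))
  # hand-substitution at omega = 0: (D/pi) Z^2 / det^2
  expect_equal(psd(sc, 0), (1 / pi) * 61.18^2 / 3090^2, tolerance = 1e-12)
  expect_equal(psd(sc, 0), 1.2478e-4, tolerance = 1e-4)

  w <- c(1, 5.5, 30, 200)
  expect_equal(psd(sc, w), psd(sc, -w), tolerance = 1e-15)

  whi <- 1e3 * max(abs(sc$R), sc$Omega, abs(sc$Z))
  expect_equal(psd(sc, whi) * pi * whi^2 / 1, 1, tolerance = 1e-2)

  expect_identical(psd(sc, w, noise_D = 0), rep(0, length(w)))
  expect_equal(psd(sc, w, noise_D = 3), 3 * psd(sc, w, noise_D = 1),
               tolerance = 1e-15)
  expect_true(all(psd(sc, seq(-500, 500, by = 0.5)) > 0))
})

test_that("closed-form peak frequency equals the dense-grid argmax", {
  sc <- transfer_scalars(alpha_base())
  expect_equal(peak_frequency(sc), 55.2782, tolerance = 1e-5)
  expect_equal(peak_frequency(sc), peak_frequency_grid(sc), tolerance = 1e-8)

  # weak damping: the peak tends to the eigenfrequency
  sc0 <- scalars(R = -1e-6, Omega = 55.306, Z = -61.18)
  expect_equal(peak_frequency(sc0), 55.306, tolerance = 1e-9)

  # strong damping: interior maximum disappears, both paths report 0
  scd <- scalars(R = -10, Omega = 1, Z = -100)
  expect_identical(peak_frequency(scd), 0)
  expect_identical(peak_frequency_grid(scd), 0)
})

test_that("closed form vs grid argmax across random stable foci", {
  fx <- stable_fixtures(300, seed = 31)
  for (mp in fx) {
    sc <- transfer_scalars(mp)
    cf <- peak_frequency(sc)
    gr <- peak_frequency_grid(sc, n_grid = 2e4)
    if (cf == 0) {
      expect_identical(gr, 0)
    } else {
      expect_equal(cf, gr, tolerance = 1e-6)
    }
  }
})

test_that("commonly quoted peak expression only agrees in the weak-damping limit", {
  # at the reference parameterization the quoted expression gives 54.968,
  # visibly off the true argmax 55.278
  sc <- transfer_scalars(alpha_base())
  expect_equal(peak_frequency_printed(sc), 54.968, tolerance = 1e-4)
  expect_gt(abs(peak_frequency_printed(sc) - peak_frequency_grid(sc)), 0.1)
  # as R -> 0- the two coincide
  scw <- scalars(R = -0.01, Omega = 55.306, Z = -61.18)
  expect_equal(peak_frequency_printed(scw), peak_frequency(scw),
               tolerance = 1e-6)
})

test_that("peak-frequency gradient signs", {
  # large eigenfrequency: the peak always rises with Omega; with respect to
  # the damping it sits slightly above Omega and relaxes down onto it as
  # R -> 0-, so the R-derivative is negative there
  sc_hi <- scalars(R = -5, Omega = 500, Z = -61.18)
  g <- peak_gradient_signs(sc_hi)
  expect_gt(g$sign_dOmega, 0)
  expect_lt(g$sign_dR, 0)
  expect_identical(g$label, "(+-)")

  # at moderate Omega ~ |Z| the R-derivative is positive instead
  g_mid <- peak_gradient_signs(transfer_scalars(alpha_base()))
  expect_gt(g_mid$sign_dR, 0)
  expect_gt(g_mid$sign_dOmega, 0)

  # weak damping: dOmega_peak/dOmega -> 1
  sc_w <- scalars(R = -1e-4, Omega = 55.306, Z = -61.18)
  expect_equal(peak_gradient_signs(sc_w)$dOmega, 1, tolerance = 1e-4)

  # signs agree with finite differences taken through the grid-argmax path,
  # in both sign regimes
  for (sc in list(transfer_scalars(alpha_base()), sc_hi)) {
    g2 <- peak_gradient_signs(sc)
    h <- 1e-4
    dR_grid <- (peak_frequency_grid(scalars(sc$R + h, sc$Omega, sc$Z)) -
                peak_frequency_grid(scalars(sc$R - h, sc$Omega, sc$Z))) / (2 * h)
    dO_grid <- (peak_frequency_grid(scalars(sc$R, sc$Omega + h, sc$Z)) -
                peak_frequency_grid(scalars(sc$R, sc$Omega - h, sc$Z))) / (2 * h)
    expect_identical(sign(dR_grid), g2$sign_dR)
    expect_identical(sign(dO_grid), g2$sign_dOmega)
  }
})

test_that("spectral quadrature equals the Lyapunov variance", {
  mp <- alpha_base(noise_D = 1)
  sc <- transfer_scalars(mp)
  expect_equal(spectrum_variance(sc), lyapunov_variance(mp), tolerance = 1e-6)
  expect_identical(spectrum_variance(sc, noise_D = 0), 0)
  expect_equal(spectrum_variance(sc, noise_D = 2),
               2 * spectrum_variance(sc, noise_D = 1), tolerance = 1e-10)

  fx <- stable_fixtures(40, seed = 32)
  for (mp in fx) {
    sc <- transfer_scalars(mp)
    expect_equal(spectrum_variance(sc), lyapunov_variance(mp),
                 tolerance = 1e-6)
  }
})

test_that("spectrum_result bundles grid, peak and variance consistently", {
  sc <- transfer_scalars(alpha_base(noise_D = 1))
  sr <- spectrum_result(sc, fmax_hz = 40, df_hz = 0.05)
  expect_equal(sr$f_peak_hz, 8.7978, tolerance = 1e-4)
  expect_equal(sr$peak_power, psd(sc, sr$omega_peak), tolerance = 1e-12)
  expect_equal(sr$S_onesided, 4 * pi * sr$S_values, tolerance = 1e-12)
  # the one-sided curve integrates (over Hz) to close to the total variance
  expect_equal(sum(sr$S_onesided) * 0.05, sr$total_variance, tolerance = 0.02)

  # beyond the instability onset the stationary spectrum is refused
  sc_unstable <- transfer_scalars(alpha_base(p = 1.3))
  expect_gt(sc_unstable$R, 0)
  expect_error(psd(sc_unstable, 0), "non-stationary")
  expect_error(spectrum_variance(sc_unstable), "non-stationary")
})
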