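test_that("identical seed and settings reproduce the trajectory exactly", {
  mp <- alpha_base(noise_D = 0.01^2 / 2)
  cfg <- simulation_config(duration = 2, seed = 99)
  r1 <- euler_maruyama(mp, cfg)
  r2 <- euler_maruyama(mp, cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
  r3 <- euler_maruyama(mp, simulation_config(duration = 2, seed = 100))
  expect_false(identical(r1$x, r3$x))
})

test_that("noise-free runs: fixed point stays fixed, perturbations ring down at (R, Omega)", {
  mp <- alpha_base()
  cfg0 <- simulation_config(duration = 1, seed = 1, kappa = 0,
                            initial_state = c(0, 0), transient_discard = 0)
  r0 <- euler_maruyama(mp, cfg0)
  expect_identical(max(abs(r0$x)), 0)
  expect_identical(max(abs(r0$y)), 0)

  # the explicit first-order scheme under-damps by ~ Omega^2 dt / 2, so the
  # step is chosen per fixture to keep that bias below 1% of |R|; fixtures
  # whose step count would explode are outside the scheme's practical range
  fx <- stable_fixtures(40, seed = 51)
  n_checked <- 0L
  for (mp in fx) {
    es <- eigen_closed_form(jacobian_summary(mp))
    ep <- effective_params(mp)
    dt <- min(mp$tau1 / 20, ep$tau2 / 20,
              0.002 / abs(es$R),                              # phase bias
              0.02 * abs(es$R) / (abs(es$R^2 - es$Omega^2) + 1))  # envelope bias
    dur <- max(10 * pi / es$Omega, min(3 / abs(es$R), 1))
    if (dur / dt > 4e6) next
    cfg <- simulation_config(dt = dt, duration = dur, seed = 1, kappa = 0,
                             initial_state = c(1, 0), transient_discard = 0)
    rec <- suppressWarnings(euler_maruyama(mp, cfg))
    # log-envelope slope from successive positive maxima
    pk <- which(diff(sign(diff(rec$x))) == -2) + 1
    pk <- pk[rec$x[pk] > 0]
    if (length(pk) >= 3) {
      slope <- stats::coef(stats::lm(log(rec$x[pk]) ~ rec$time[pk]))[[2]]
      expect_equal(slope, es$R, tolerance = 0.02)
    }
    # zero-crossing spacing = half a period
    zc <- which(rec$x[-1] * rec$x[-length(rec$x)] < 0)
    if (length(zc) >= 4) {
      spacing <- mean(diff(rec$time[zc]))
      expect_equal(spacing, pi / es$Omega, tolerance = 0.01)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("unstable parameters abort with a blow-up diagnostic", {
  mp <- alpha_base(noise_D = 0.01^2 / 2, p = 1.35)
  cfg <- simulation_config(duration = 60, seed = 1, blowup_bound = 10)
  expect_error(euler_maruyama(mp, cfg), "unstable")
})

test_that("Welch estimator: sinusoid power and white-noise flatness", {
  fs <- 500
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  A <- 2; f0 <- 10
  x <- A * sin(2 * pi * f0 * tt)
  w <- welch_psd(x, segment_seconds = 2, fs = fs)
  expect_equal(w$peak_freq_hz, f0, tolerance = 1e-9)
  expect_equal(sum(w$power) * w$df_hz, A^2 / 2, tolerance = 0.02)

  set.seed(7)
  z <- rnorm(length(tt))
  wz <- welch_psd(z, segment_seconds = 0.5, fs = fs)
  band <- wz$power[wz$freq_hz > 5 & wz$freq_hz < 245]
  expect_lt(max(band) / min(band), 3)

  expect_error(welch_psd(z[1:100], segment_seconds = 2, fs = fs),
               "insufficient")
})

test_that("simulated spectrum converges to the analytic density", {
  mp <- alpha_base(noise_D = 0.01^2 / 2)
  sc <- transfer_scalars(mp)
  msrd <- function(duration) {
    rec <- euler_maruyama(mp, simulation_config(duration = duration, seed = 3))
    w <- welch_psd(rec, segment_seconds = 5)
    sel <- w$freq_hz >= 1 & w$freq_hz <= 20
    S_an <- 4 * pi * psd(sc, 2 * pi * w$freq_hz[sel])
    sqrt(mean(((w$power[sel] - S_an) / S_an)^2))
  }
  d200 <- msrd(200)
  expect_lt(d200, 0.15)
  expect_lt(d200, msrd(50))
})

test_that("time-domain variance matches the analytic spectral variance", {
  mp <- alpha_base(noise_D = 0.01^2 / 2)
  rec <- euler_maruyama(mp, simulation_config(duration = 200, seed = 5))
  keep <- rec$time >= 5
  expect_equal(var(rec$x[keep]),
               spectrum_variance(transfer_scalars(mp)), tolerance = 0.1)
})

test_that("spectra comparison report: self-consistency and the concentration effect", {
  mp1 <- alpha_base(noise_D = 0.01^2 / 2)
  sc1 <- transfer_scalars(mp1)

  # analytic curve read back through the comparison: no offset beyond the
  # grid resolution, integrated-power ratio 1
  fs <- 200; nper <- 400
  freq <- (seq_len(nper %/% 2 + 1) - 1) * fs / nper
  fake <- structure(list(freq_hz = freq,
                         power = 4 * pi * psd(sc1, 2 * pi * freq),
                         peak_freq_hz = freq[which.max(
                           psd(sc1, 2 * pi * freq)[-1]) + 1L],
                         df_hz = fs / nper, n_segments = 1L),
                    class = "welch_psd")
  self <- compare_spectra(fake, sc1)
  expect_lt(abs(self$peak_offset_bins), 1)
  expect_equal(self$power_ratio, 1, tolerance = 1e-6)

  # increased concentration: simulated peak power and frequency both rise
  mp2 <- alpha_base(noise_D = 0.01^2 / 2, p = 1.2)
  w1 <- welch_psd(euler_maruyama(mp1, simulation_config(duration = 50, seed = 2)),
                  segment_seconds = 2)
  w2 <- welch_psd(euler_maruyama(mp2, simulation_config(duration = 50, seed = 2)),
                  segment_seconds = 2)
  expect_gt(w2$peak_freq_hz, w1$peak_freq_hz)
  expect_gt(max(w2$power[-1]), max(w1$power[-1]))
  # alpha-band power rises with p
  c1 <- compare_spectra(w1, sc1)
  c2 <- compare_spectra(w2, transfer_scalars(mp2))
  expect_gt(c2$band_power_sim[["alpha"]], c1$band_power_sim[["alpha"]])
})

test_that("seed-to-seed scatter of the Welch peak stays within two bins", {
  mp <- alpha_base(noise_D = 0.01^2 / 2)
  f_an <- peak_frequency(transfer_scalars(mp)) / (2 * pi)
  peaks <- vapply(1:10, function(s) {
    w <- welch_psd(euler_maruyama(mp, simulation_config(duration = 50, seed = s)),
                   segment_seconds = 2)
    w$peak_freq_hz
  }, numeric(1))
  df <- 1 / 2  # bin width at 2 s segments
  expect_lt(max(abs(peaks - f_an)) / df, 2)
})
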