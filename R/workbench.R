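#' Specification for random parameter-set fixtures
#'
#' Controls the rejection sampler behind [generate_fixtures()]. Gains and
#' `tau1` are drawn uniformly from their ranges; `tau2` is then placed
#' according to the rule: `"inside_focus_band"` draws the ratio `tau2/tau1`
#' uniformly from the stable part of the focus band (lower band edge up to
#' the trace-zero threshold, with a small relative margin off the edges so
#' the eigenpair is well conditioned), `"at_threshold"` sets
#' `tau2 = tau1 (N2+1)/(N1-1)` exactly, and `"outside_band"` places the
#' ratio outside the focus band (real eigenvalues).
#'
#' @param count Number of parameter sets.
#' @param seed Integer seed.
#' @param N1_range,N2_range,tau1_range Sampling ranges (tau in seconds).
#' @param placement One of `"inside_focus_band"`, `"at_threshold"`,
#'   `"outside_band"`.
#' @param max_rejections Sampler gives up after this many rejected draws.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(count, seed = 1,
                         N1_range = c(1.01, 2.0),
                         N2_range = c(0.05, 2.0),
                         tau1_range = c(0.001, 0.01),
                         placement = c("inside_focus_band", "at_threshold",
                                       "outside_band"),
                         max_rejections = 1e5) {
  placement <- match.arg(placement)
  stopifnot(count >= 1, diff(N1_range) >= 0, diff(N2_range) >= 0,
            diff(tau1_range) >= 0, tau1_range[1] > 0)
  structure(list(count = as.integer(count), seed = as.integer(seed),
                 N1_range = N1_range, N2_range = N2_range,
                 tau1_range = tau1_range, placement = placement,
                 max_rejections = max_rejections),
            class = "fixture_spec")
}

#' Generate random valid parameter sets
#'
#' Rejection-samples [model_params()] sets satisfying the placement rule of
#' the [fixture_spec()]; reproducible by seed. `noise_D` is fixed at 1 (the
#' spectrum is linear in `D`).
#'
#' @param spec A [fixture_spec()] object.
#' @param edge_margin Relative margin kept off the band edges for
#'   `"inside_focus_band"` placement.
#' @return A list of `model_params` objects of length `spec$count`.
#' @export
generate_fixtures <- function(spec, edge_margin = 0.005) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  out <- vector("list", spec$count)
  got <- 0L; tries <- 0L
  runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
  while (got < spec$count) {
    tries <- tries + 1L
    if (tries > spec$max_rejections)
      stop("fixture sampler exhausted after ", spec$max_rejections,
           " draws; widen the ranges or relax the placement rule")
    N1 <- runif1(spec$N1_range); N2 <- runif1(spec$N2_range)
    tau1 <- runif1(spec$tau1_range)
    a <- (N1 - 1)^2; b <- N1 * N2 - N1 + N2 + 1; cc <- (N2 + 1)^2
    disc <- b^2 - a * cc
    if (spec$placement == "at_threshold") {
      if (N1 <= 1) next
      r <- (N2 + 1) / (N1 - 1)
    } else if (spec$placement == "inside_focus_band") {
      if (a <= 0 || disc <= 0) next
      r_lo <- (b - sqrt(disc)) / a
      r_hi <- min((b + sqrt(disc)) / a, sqrt(cc / a))
      span <- r_hi - r_lo
      if (span <= 0) next
      r <- stats::runif(1, r_lo + edge_margin * span, r_hi - edge_margin * span)
    } else {
      if (a <= 0) next
      if (disc <= 0) {
        r <- runif1(c(0.1, 100))  # no band: any ratio is outside
      } else {
        r_lo <- (b - sqrt(disc)) / a; r_hi <- (b + sqrt(disc)) / a
        r <- if (stats::runif(1) < 0.5) stats::runif(1, r_lo * 0.01, r_lo * 0.99)
             else stats::runif(1, r_hi * 1.01, r_hi * 3)
      }
    }
    got <- got + 1L
    out[[got]] <- model_params(N1, N2, tau1, tau1 * r, noise_D = 1, p = 1)
  }
  out
}

#' Read a model configuration file
#'
#' YAML configuration with one section per concern: `model` (fields of
#' [model_params()]), optional `population` (rate-family name and
#' parameters for [population_params()]), optional `simulation` (fields of
#' [simulation_config()]) and optional `sweep` (`p_max`, `p_step`). All
#' `model` fields round-trip exactly through [write_config()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements `model` (a `model_params` object) and any
#'   further sections as plain lists.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model))
    stop("config has no [model] section")
  m <- cfg$model
  needed <- c("N1", "N2_base", "tau1", "tau2_base")
  if (!all(needed %in% names(m)))
    stop("config [model] section must provide: ", paste(needed, collapse = ", "))
  cfg$model <- model_params(m$N1, m$N2_base, m$tau1, m$tau2_base,
                            noise_D = if (is.null(m$noise_D)) 1 else m$noise_D,
                            p = if (is.null(m$p)) 1 else m$p)
  cfg
}

#' Write a model configuration file
#'
#' @param config A list as returned by [read_config()], or any list whose
#'   `model` element is a [model_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config$model, "model_params"))
    config$model <- unclass(config$model)
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' Regenerate the data behind the survey figures
#'
#' Emits tidy data frames (one observation per row, snake_case columns, SI
#' units in header suffixes) for the standard diagnostic plots of the model:
#'
#' * `"band"` — focus-band edges, stability threshold and maximum-frequency
#'   ratio as functions of `N2` at fixed `N1`.
#' * `"hopf_loci"` — Hopf-threshold curves `(N1, N2, tau2)` at requested
#'   frequencies.
#' * `"peak_signs"` — sign pair of the peak-frequency gradients over an
#'   `(Omega, R)` grid at fixed `Z`.
#' * `"p0_plane"` — closed-form `p0` and both sign tracks of `dOmega^2/dp`
#'   at `p = 1` over an `(N1, N2_base)` grid at fixed `tau2(1)/tau1`.
#' * `"sim_spectra"` — simulated (Welch) and analytic spectra for a
#'   parameterization at two concentrations.
#'
#' @param which One of `"band"`, `"hopf_loci"`, `"peak_signs"`, `"p0_plane"`,
#'   `"sim_spectra"`.
#' @param out_dir Optional directory; when given, each data frame is written
#'   as a CSV and a run manifest is added.
#' @param ... Overrides passed to the individual builders: `N1`, `tau1`,
#'   `frequencies_hz`, `N2_grid`, `Z`, `ratio`, `params`, `p_values`,
#'   `duration`, `seed`.
#' @return A named list of data frames (invisibly when `out_dir` is given).
#' @export
figure_data <- function(which = c("band", "hopf_loci", "peak_signs",
                                  "p0_plane", "sim_spectra"),
                        out_dir = NULL, ...) {
  which <- match.arg(which)
  dots <- list(...)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  res <- switch(which,
    band = {
      N1 <- dots$N1 %||% 1.1
      N2_grid <- dots$N2_grid %||% seq(0.01, 2, by = 0.01)
      rows <- lapply(N2_grid, function(N2) {
        s <- jacobian_summary(model_params(N1, N2, 1, 1))
        fb <- focus_band(s)
        mf <- if (fb$exists) max_frequency(s, 1)$ratio_star else NA_real_
        data.frame(N1 = N1, N2 = N2, ratio_low = fb$ratio_low,
                   ratio_high = fb$ratio_high,
                   threshold_ratio = fb$threshold_ratio,
                   max_freq_ratio = mf)
      })
      list(band = do.call(rbind, rows))
    },
    hopf_loci = {
      tau1 <- dots$tau1 %||% 0.002
      freqs <- dots$frequencies_hz %||% c(4, 10, 15)
      N1_grid <- dots$N1 %||% seq(1.02, 2, by = 0.02)
      rows <- list()
      for (f in freqs) for (N1 in N1_grid) {
        pt <- tryCatch(hopf_locus(f, tau1, N1), error = function(e) NULL)
        if (!is.null(pt))
          rows[[length(rows) + 1L]] <-
            data.frame(freq_hz = f, N1 = N1, N2 = pt$N2, tau2_s = pt$tau2)
      }
      list(hopf_loci = do.call(rbind, rows))
    },
    peak_signs = {
      Z <- dots$Z %||% -61.18
      Om_grid <- dots$Omega_grid %||% seq(2, 150, by = 2)
      R_grid <- dots$R_grid %||% seq(-60, -0.5, by = 0.5)
      rows <- list()
      for (Om in Om_grid) for (R in R_grid) {
        sc <- scalars(R, Om, Z)
        lab <- tryCatch(peak_gradient_signs(sc)$label,
                        error = function(e) "zero_peak")
        rows[[length(rows) + 1L]] <-
          data.frame(Omega_rad_s = Om, R_s = R, label = lab)
      }
      list(peak_signs = do.call(rbind, rows))
    },
    p0_plane = {
      ratio <- dots$ratio %||% 1.11
      N1_grid <- dots$N1 %||% seq(1.01, 1.5, by = 0.01)
      N2_grid <- dots$N2_grid %||% seq(0.05, 1.5, by = 0.05)
      tau1 <- dots$tau1 %||% 0.002
      rows <- list()
      for (N1 in N1_grid) for (N2 in N2_grid) {
        mp <- model_params(N1, N2, tau1, tau1 * ratio)
        p0 <- p0_verbatim(mp)
        rows[[length(rows) + 1L]] <- data.frame(
          N1 = N1, N2_base = N2, p0_verbatim = p0,
          sign_verbatim_at_p1 = if (p0 >= 1) -1 else 1,
          sign_numeric_at_p1 = sign(d_omega2_dp(mp, 1)),
          N2_redline = 1 / 1.3 + ratio - ratio * N1)
      }
      list(p0_plane = do.call(rbind, rows))
    },
    sim_spectra = {
      params <- dots$params %||% model_params(1.1, 0.2236, 0.002, 0.02,
                                              noise_D = 0.01^2 / 2)
      p_values <- dots$p_values %||% c(1.0, 1.2)
      duration <- dots$duration %||% 50
      seed <- dots$seed %||% 1
      out <- list()
      for (p in p_values) {
        mp <- model_params(params$N1, params$N2_base, params$tau1,
                           params$tau2_base, params$noise_D, p = p)
        rec <- euler_maruyama(mp, simulation_config(duration = duration,
                                                    seed = seed))
        wl <- welch_psd(rec)
        sc <- transfer_scalars(mp)
        fgrid <- wl$freq_hz[wl$freq_hz <= 40]
        key <- sprintf("p_%s", format(p))
        out[[paste0("trace_", key)]] <-
          data.frame(t_s = rec$time, x = rec$x, y = rec$y,
                     x_plus_Ve0 = rec$display)
        out[[paste0("spectrum_", key)]] <-
          data.frame(freq_hz = fgrid,
                     welch_power = wl$power[wl$freq_hz <= 40],
                     analytic_power = 4 * pi * psd(sc, 2 * pi * fgrid))
      }
      out
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(res)) {
      f <- file.path(out_dir, paste0(which, "_", nm, ".csv"))
      utils::write.csv(res[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    write_manifest(files, list(figure = which, args = dots),
                   file.path(out_dir, paste0(which, "_manifest.json")))
    return(invisible(res))
  }
  res
}

#' Write a run manifest
#'
#' Records what a command produced: package version, timestamp, the
#' configuration used, and an MD5 checksum per output file, as JSON.
#' Re-running a deterministic command with the same configuration must
#' reproduce identical checksums.
#'
#' @param files Character vector of output paths.
#' @param config List of settings to snapshot (seeds included).
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, config, path) {
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "anespec",
    version = as.character(utils::packageVersion("anespec")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = lapply(seq_along(files), function(i)
      list(file = files[i], md5 = unname(sums[i])))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
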