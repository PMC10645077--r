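#' Known-truth configuration for synthetic data
#'
#' Bundles the generating parameters for a synthetic study: the
#' growth-rate model parameters, the initial population proxy, the
#' process-noise level on each per-generation growth rate, the calendar
#' window and generation step, and a seed.
#'
#' The default parameters define the package's reference synthetic
#' conditions, designed on the scale of an observed SPD series (population
#' proxy of order 0.001-0.02 probability mass per year). They mirror the
#' sign structure of the fitted full model on the real series — positive
#' competition `c` with positive hydroclimate and warfare couplings,
#' a small negative baseline `w` with a positive social-upscaling and a
#' negative warfare coupling — and are placed so that (i) the effective
#' cooperation coefficient `w + beta0*z'' + beta1*z'` stays negative for
#' all covariate values in `[0, 1]`, which removes the Allee extinction
#' trap and guarantees rebounds from deep busts, and (ii) the local
#' stability sum `c_eff*x + |w_eff|/x` stays below 2 at every forced
#' equilibrium, so trajectories do not diverge. The low initial density
#' gives a growth transient, and drought/warfare forcing produces
#' order-of-magnitude boom-bust cycles, which together make all seven
#' parameters identifiable from a single 54-generation series.
#'
#' @param params A `param_set`; defaults to the reference truth
#'   (`R_m = 0.45`, `c = 20`, `w = -0.002`, `alpha0 = 120`,
#'   `alpha1 = 100`, `beta0 = 0.0015`, `beta1 = -0.003`).
#' @param x_0 Initial population proxy (> 0), default 0.0025 (SPD-scale
#'   units).
#' @param noise_sd SD of Gaussian noise added to each growth rate
#'   (default 0.01).
#' @param window Calendar window in years AD, default `c(100, 1450)`.
#' @param step Generation step in years, default 25.
#' @param seed Integer seed.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(params = param_set(R_m = 0.45, c = 20, w = -0.002,
                                            alpha0 = 120, alpha1 = 100,
                                            beta0 = 0.0015, beta1 = -0.003),
                         x_0 = 0.0025, noise_sd = 0.01,
                         window = c(100, 1450), step = 25, seed = 1L) {
  if (x_0 <= 0) stop("x_0 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(params = params, x_0 = x_0, noise_sd = noise_sd,
                 window = window, step = step, seed = seed),
            class = "truth_config")
}

#' Generate a known-truth population trajectory
#'
#' Iterates the stochastic growth model
#' `X_{t+1} = X_t + R(params, X_t, covariates_t) + N(0, noise_sd)`
#' over the configured window and returns it as a generation table with
#' the realized growth rates.
#'
#' @param config A `truth_config`.
#' @param lithic,warfare,pollution Covariate `proxy_series` covering the
#'   window.
#' @return A `generation_table`; the realized `R` column includes the
#'   process noise. Attribute `truth` stores the config.
#' @export
generate_truth_trajectory <- function(config, lithic, warfare, pollution) {
  set.seed(config$seed)
  years <- seq(config$window[1], config$window[2], by = config$step)
  n <- length(years)
  sample_at <- function(s) {
    if (min(s$year_ad) > min(years) || max(s$year_ad) < max(years))
      stop("covariate does not cover the window")
    stats::approx(s$year_ad, s$value, xout = years)$y
  }
  z <- sample_at(lithic); zw <- sample_at(warfare); zp <- sample_at(pollution)
  X <- numeric(n)
  X[1] <- log(config$x_0)
  eps <- stats::rnorm(n - 1, 0, config$noise_sd)
  for (t in seq_len(n - 1)) {
    X[t + 1] <- X[t] +
      predict_growth_rate(config$params, X[t], z[t], zw[t], zp[t]) + eps[t]
    if (!is.finite(X[t + 1]))
      stop("synthetic trajectory diverged at step ", t + 1)
  }
  tab <- data.frame(t = seq_len(n), year_ad = years, x = exp(X), X = X,
                    R = c(diff(X), NA_real_),
                    z_lithic = z, z_warfare = zw, z_pollution = zp)
  structure(tab, class = c("generation_table", "data.frame"),
            step = config$step, truth = config)
}

#' Generate a synthetic radiocarbon date collection
#'
#' Operationalizes the ages-as-data premise in reverse: calendar years are
#' sampled with probability proportional to the population proxy
#' (piecewise-linear interpolation of `x` between generation steps, on an
#' annual grid), mapped through the calibration curve to a conventional
#' 14C age, and perturbed by Gaussian lab error. Sites are assigned
#' uniformly at random.
#'
#' @param trajectory A `generation_table` (or any data frame with
#'   `year_ad` and non-negative `x`).
#' @param n_dates Number of dates to draw.
#' @param n_sites Number of site identifiers to assign uniformly.
#' @param curve A `cal_curve` covering the trajectory window.
#' @param sigma_lab 1-sigma lab error in 14C years (also the reported
#'   error column; must be > 0 for a valid date table, but 0 is accepted
#'   for deterministic checks, in which case the reported error is 1).
#' @param seed Integer seed.
#' @return A `c14_dates` table with `n_dates` rows.
#' @export
generate_c14_dates <- function(trajectory, n_dates, n_sites, curve,
                               sigma_lab = 30, seed = 1L) {
  set.seed(seed)
  yrs <- seq(ceiling(min(trajectory$year_ad)), floor(max(trajectory$year_ad)))
  wgt <- stats::approx(trajectory$year_ad, trajectory$x, xout = yrs)$y
  wgt[wgt < 0] <- 0
  if (sum(wgt) <= 0) stop("population weights sum to zero")
  cal_ad <- sample(yrs, n_dates, replace = TRUE, prob = wgt)
  cal_bp <- 1950 - cal_ad
  at <- curve_at(curve, cal_bp)
  age <- stats::rnorm(n_dates, mean = at$mu, sd = sigma_lab)
  site <- sprintf("S%03d", sample.int(n_sites, n_dates, replace = TRUE))
  c14_dates(lab_id = sprintf("SYN-%05d", seq_len(n_dates)),
            age = age, error = max(sigma_lab, 1), site_id = site,
            material = "synthetic")
}

#' Generate a smooth bounded covariate series
#'
#' An annual Gaussian random walk over the window, smoothed by
#' [spline_smooth()] at the given smoothness, then min-max normalized to
#' `[0, 1]` — emulating the smooth, autocorrelated, bounded proxy series
#' the analysis consumes.
#'
#' @param window Calendar window in years AD.
#' @param smoothness spar-like smoothing parameter in `[0, 1]`
#'   (default 0.7).
#' @param seed Integer seed.
#' @param kind Label for the series.
#' @return An annual `proxy_series` with values spanning exactly `[0, 1]`.
#' @export
generate_covariates <- function(window, smoothness = 0.7, seed = 1L,
                                kind = "synthetic") {
  set.seed(seed)
  yrs <- seq(window[1], window[2])
  rw <- cumsum(stats::rnorm(length(yrs)))
  sm <- spline_smooth(proxy_series(yrs, rw, kind = kind), spar = smoothness)
  proxy_series(yrs, minmax_scale(sm$value), kind = kind)
}

#' Synthetic calibration curve
#'
#' A smooth toy atmospheric curve: identity plus a sinusoidal wiggle
#' (`mu = cal_bp + amplitude * sin(2*pi*cal_bp/period)`) with constant
#' curve error, so calibration multimodality from curve wiggles is
#' exercised without shipping a reference curve. Labelled synthetic; real
#' curves load via [load_calibration_curve()].
#'
#' @param cal_bp_range Range in calendar years BP (default `c(400, 2000)`,
#'   covering AD -50 to 1550).
#' @param amplitude Wiggle amplitude in 14C years (default 15).
#' @param period Wiggle period in calendar years (default 300).
#' @param sigma_curve Constant curve error (default 10).
#' @param by Knot spacing in years (default 5).
#' @return A `cal_curve`.
#' @export
synthetic_calibration_curve <- function(cal_bp_range = c(400, 2000),
                                        amplitude = 15, period = 300,
                                        sigma_curve = 10, by = 5) {
  bp <- seq(cal_bp_range[1], cal_bp_range[2], by = by)
  calibration_curve(bp, bp + amplitude * sin(2 * pi * bp / period),
                    sigma_curve)
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits everything the pipeline consumes: a date table CSV, a calibration
#' curve file, an annual hydroclimate covariate CSV, two pollution
#' component CSVs (to exercise min-max merging), a conflict period-score
#' CSV, and a JSON record of the generating truth. All inputs are
#' generated from the known-truth model so pipeline recovery can be
#' checked end to end.
#'
#' @param dir Output directory (created if needed).
#' @param config A `truth_config`.
#' @param n_dates,n_sites,sigma_lab Passed to [generate_c14_dates()]. The
#'   default of roughly two dates per site matches the sampling intensity
#'   of regional radiocarbon databases; heavily oversampled sites would
#'   instead be averaged away by the 50-year binning.
#' @param smoothness Covariate smoothness triplet
#'   `c(lithic, conflict, pollution)`. The defaults generate slow,
#'   multi-century forcing: dynamics faster than the 100-year rolling
#'   mean cannot be recovered from an SPD, so the reference conditions
#'   keep the forcing on timescales the SPD preserves.
#' @return Invisibly, a list with the file paths and the truth objects.
#' @export
synthetic_bundle <- function(dir, config = truth_config(), n_dates = 400,
                             n_sites = 200, sigma_lab = 30,
                             smoothness = c(0.8, 0.8, 0.75)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  win <- config$window
  # covariates on a slightly wider window so 25-yr sampling never clips
  wide <- c(win[1] - 50, win[2] + 50)
  lithic <- generate_covariates(wide, smoothness[1], seed = seed + 101L,
                                kind = "lithic")
  warfare <- generate_covariates(wide, smoothness[2], seed = seed + 202L,
                                 kind = "conflict")
  pollution <- generate_covariates(wide, smoothness[3], seed = seed + 303L,
                                   kind = "pollution")
  truth <- generate_truth_trajectory(config, lithic, warfare, pollution)
  curve <- synthetic_calibration_curve(
    cal_bp_range = c(1950 - wide[2] - 200, 1950 - wide[1] + 200))
  dates <- generate_c14_dates(truth, n_dates, n_sites, curve,
                              sigma_lab = sigma_lab, seed = seed + 404L)
  paths <- list(
    dates = file.path(dir, "dates.csv"),
    curve = file.path(dir, "curve.14c"),
    lithic = file.path(dir, "lithic.csv"),
    pollution_a = file.path(dir, "pollution_a.csv"),
    pollution_b = file.path(dir, "pollution_b.csv"),
    conflict = file.path(dir, "conflict_periods.csv"),
    truth = file.path(dir, "truth.json"))
  write_c14_dates(dates, paths$dates)
  writeLines(c("# synthetic calibration curve (cal BP, 14C age BP, error)",
               sprintf("%d,%.4f,%.1f", curve$cal_bp, curve$mu,
                       curve$sigma_curve)), paths$curve)
  write_proxy_series(lithic, paths$lithic)
  # two noisy renderings of the pollution series, offset in scale, so the
  # pipeline's min-max merge has real work to do
  set.seed(seed + 505L)
  pa <- proxy_series(pollution$year_ad,
                     2 + 3 * pollution$value + stats::rnorm(nrow(pollution), 0, 0.05),
                     kind = "pollution")
  pb <- proxy_series(pollution$year_ad,
                     10 * pollution$value + stats::rnorm(nrow(pollution), 0, 0.15),
                     kind = "pollution")
  write_proxy_series(pa, paths$pollution_a)
  write_proxy_series(pb, paths$pollution_b)
  # warfare as coarse period scores (8 periods across the window)
  edges <- round(seq(wide[1], wide[2], length.out = 9))
  mids <- (edges[-1] + edges[-9]) / 2
  sc <- stats::approx(warfare$year_ad, warfare$value, xout = mids)$y
  per <- period_scores(edges[-9], edges[-1], sc)
  utils::write.csv(data.frame(period_start = per$period_start,
                              period_end = per$period_end, score = per$score),
                   paths$conflict, row.names = FALSE, quote = FALSE)
  truth_rec <- list(params = unclass(config$params), x_0 = config$x_0,
                    noise_sd = config$noise_sd, window = config$window,
                    step = config$step, seed = config$seed,
                    n_dates = n_dates, n_sites = n_sites,
                    sigma_lab = sigma_lab)
  writeLines(to_json(truth_rec), paths$truth)
  invisible(list(paths = paths, truth_table = truth, dates = dates,
                 curve = curve,
                 covariates = list(lithic = lithic, warfare = warfare,
                                   pollution = pollution)))
}

# minimal JSON writer for the truth record (numbers, strings, flat lists)
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(sprintf('"%s": %s', names(v),
                                vapply(v, enc, character(1))),
                        collapse = ", "), "}")
    } else if (is.character(v)) {
      sprintf('"%s"', v)
    } else if (length(v) > 1) {
      paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
    } else {
      format(v, digits = 15)
    }
  }
  enc(x)
}
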