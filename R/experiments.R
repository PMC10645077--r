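#' Monte-Carlo validation experiments
#'
#' These functions run the package's own simulation studies: parameter
#' recovery, model-selection consistency, and full-pipeline recovery from
#' synthetic radiocarbon dates. They define the reference study
#' conditions used throughout the package's validation.
#'
#' @name experiments
NULL

# model-level study conditions: covariates wiggly enough to provide
# several distinct forcing episodes per series (multi-decadal to
# centennial variability)
model_level_smoothness <- c(lithic = 0.40, conflict = 0.45, pollution = 0.40)

#' Draw a reference covariate triplet
#'
#' Generates one seeded draw of the three covariate series (hydroclimate,
#' warfare, social upscaling) at the package's model-level study
#' conditions, on a window slightly wider than the analysis window so
#' generation-grid sampling never clips.
#'
#' @param seed Integer seed.
#' @param window Analysis window in years AD.
#' @param smoothness Smoothness triplet (lithic, conflict, pollution).
#' @return List with `lithic`, `warfare`, `pollution` proxy series.
#' @export
covariate_draw <- function(seed, window = c(100, 1450),
                           smoothness = model_level_smoothness) {
  wide <- c(window[1] - 50, window[2] + 50)
  list(
    lithic = generate_covariates(wide, smoothness[[1]], seed = seed + 101L,
                                 kind = "lithic"),
    warfare = generate_covariates(wide, smoothness[[2]], seed = seed + 202L,
                                  kind = "conflict"),
    pollution = generate_covariates(wide, smoothness[[3]], seed = seed + 303L,
                                    kind = "pollution"))
}

#' Residual noise scale implied by a published AICc
#'
#' Inverts the AICc convention used by [aicc()] to recover the residual
#' standard deviation `sqrt(rss/n)` that a reported AICc value implies.
#'
#' @param aicc_value Reported AICc.
#' @param n Number of observations.
#' @param n_params Number of free mean parameters.
#' @return The residual standard deviation.
#' @export
aicc_implied_noise_sd <- function(aicc_value, n, n_params) {
  K <- n_params + 1
  loglik_part <- aicc_value - 2 * K - 2 * K * (K + 1) / (n - K - 1)
  rss <- n / (2 * pi) * exp(loglik_part / n - 1)
  sqrt(rss / n)
}

#' Parameter-recovery experiment
#'
#' Simulates generation tables from the full (model D) truth under fresh
#' covariate draws and refits model D to each, returning the per-seed
#' estimates and the Monte-Carlo relative bias of each parameter.
#'
#' @param n_seeds Number of replicates.
#' @param noise_sd Process-noise sd per growth rate.
#' @param config Base `truth_config` (its seed is ignored; replicate
#'   seeds derive from `seed`).
#' @param seed Master seed.
#' @return List with `estimates` (matrix, one row per seed), `truth`,
#'   and `rel_bias` (named vector, `|mean(est) - truth| / |truth|`).
#' @export
mc_parameter_recovery <- function(n_seeds = 100, noise_sd = 0.01,
                                  config = truth_config(), seed = 1L) {
  est <- NULL
  truth <- unlist(config$params)
  s <- 0L
  done <- 0L
  while (done < n_seeds) {
    s <- s + 1L
    cov <- covariate_draw(seed * 1000L + s, window = config$window)
    cfg <- truth_config(params = config$params, x_0 = config$x_0,
                        noise_sd = noise_sd, window = config$window,
                        step = config$step, seed = seed * 2000L + s)
    tb <- tryCatch(generate_truth_trajectory(cfg, cov$lithic, cov$warfare,
                                             cov$pollution),
                   error = function(e) NULL)
    if (is.null(tb)) next
    est <- rbind(est, unlist(fit_model("D", tb)$params))
    done <- done + 1L
  }
  rel_bias <- abs(colMeans(est) - truth[colnames(est)]) / abs(truth[colnames(est)])
  list(estimates = est, truth = truth, rel_bias = rel_bias)
}

#' Model-selection consistency experiment
#'
#' Simulates generation tables from the full (model D) truth, fits all
#' four candidate models to each, and reports how often the generating
#' model attains the top Akaike weight. Replicates whose trajectory
#' diverges (rare at high noise) produce no table and are regenerated
#' with the next seed.
#'
#' @param n_rep Number of simulated tables.
#' @param noise_sd Process-noise sd; defaults to the scale implied by the
#'   published full-model AICc (-109.61 at n = 54, 7 parameters).
#' @param config Base `truth_config`.
#' @param seed Master seed.
#' @return List with `top_rate` (fraction of tables where model D ranks
#'   first), `tops` (character vector of winning models), `n_diverged`.
#' @export
mc_selection_consistency <- function(n_rep = 200,
                                     noise_sd = aicc_implied_noise_sd(-109.61, 54, 7),
                                     config = truth_config(), seed = 1L) {
  tops <- character(0)
  diverged <- 0L
  s <- 0L
  while (length(tops) < n_rep) {
    s <- s + 1L
    cov <- covariate_draw(seed * 3000L + s, window = config$window)
    cfg <- truth_config(params = config$params, x_0 = config$x_0,
                        noise_sd = noise_sd, window = config$window,
                        step = config$step, seed = seed * 4000L + s)
    tb <- tryCatch(generate_truth_trajectory(cfg, cov$lithic, cov$warfare,
                                             cov$pollution),
                   error = function(e) NULL)
    if (is.null(tb)) { diverged <- diverged + 1L; next }
    sel <- model_selection(lapply(model_family(), fit_model, table = tb))
    tops <- c(tops, sel$table$model[1])
  }
  list(top_rate = mean(tops == "D"), tops = tops, n_diverged = diverged,
       noise_sd = noise_sd)
}

#' Full synthetic-loop recovery experiment
#'
#' The end-to-end study: known-truth trajectory, radiocarbon dates
#' sampled from it, calibration, binning, SPD, generation table, fits of
#' all four models — then scoring whether the generating model ranks
#' first and whether the signs of all its parameters are recovered.
#'
#' @param n_rep Number of replicates.
#' @param config Base `truth_config`.
#' @param n_dates,n_sites,sigma_lab Date-sampling conditions.
#' @param smoothness Covariate smoothness triplet (slow, SPD-preservable
#'   forcing by default).
#' @param seed Master seed.
#' @return List with `rank_rate`, `sign_rate`, `both_rate`, and the
#'   per-replicate detail data frame.
#' @export
mc_full_loop <- function(n_rep = 50, config = truth_config(), n_dates = 400,
                         n_sites = 200, sigma_lab = 30,
                         smoothness = c(0.8, 0.8, 0.75), seed = 1L) {
  truth_sign <- sign(unlist(config$params))
  rows <- list()
  s <- 0L
  while (length(rows) < n_rep) {
    s <- s + 1L
    cov <- covariate_draw(seed * 5000L + s, window = config$window,
                          smoothness = smoothness)
    cfg <- truth_config(params = config$params, x_0 = config$x_0,
                        noise_sd = config$noise_sd, window = config$window,
                        step = config$step, seed = seed * 6000L + s)
    tb_true <- tryCatch(generate_truth_trajectory(cfg, cov$lithic,
                                                  cov$warfare, cov$pollution),
                        error = function(e) NULL)
    if (is.null(tb_true)) next
    curve <- synthetic_calibration_curve(
      cal_bp_range = c(1950 - config$window[2] - 300,
                       1950 - config$window[1] + 300),
      amplitude = 8, sigma_curve = 5)
    dates <- generate_c14_dates(tb_true, n_dates, n_sites, curve,
                                sigma_lab = sigma_lab,
                                seed = seed * 7000L + s)
    dens <- calibrate_dates(dates, curve, normalize = TRUE)
    bins <- bin_dates(dates)
    spd <- build_spd(dens, bins = bins, window = config$window,
                     rolling_window = 100)
    tb <- build_generation_table(spd, cov$lithic, cov$warfare, cov$pollution,
                                 step = config$step, window = config$window)
    fits <- lapply(model_family(), fit_model, table = tb)
    sel <- model_selection(fits)
    est_sign <- sign(unlist(fits$D$params))
    rows[[length(rows) + 1L]] <- data.frame(
      rep = length(rows) + 1L,
      top = sel$table$model[1],
      signs_ok = all(est_sign == truth_sign))
  }
  detail <- do.call(rbind, rows)
  list(rank_rate = mean(detail$top == "D"),
       sign_rate = mean(detail$signs_ok),
       both_rate = mean(detail$top == "D" & detail$signs_ok),
       detail = detail)
}
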