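#' Simulate the total population trajectory of a fitted model
#'
#' Iterates the growth-rate model forward from the first observed value
#' only: `Xhat_1 = X_1`, then
#' `Xhat_{t+1} = Xhat_t + R(params, Xhat_t, covariates at t)`.
#' The observed series never re-enters after the first step, so the
#' simulation is a genuine total-trajectory prediction; the covariates
#' fed in are the observed (smoothed) series.
#'
#' @param params A `param_set` (or a `popdyn_fit`, whose parameters are
#'   used).
#' @param table A `generation_table` supplying the initial value and the
#'   covariates at every step.
#' @return A `sim_trajectory`: data frame with `t`, `year_ad`, `X_hat`,
#'   `x_hat`.
#' @export
simulate_trajectory <- function(params, table) {
  if (inherits(params, "popdyn_fit")) params <- params$params
  n <- nrow(table)
  X <- numeric(n)
  X[1] <- table$X[1]
  for (t in seq_len(n - 1)) {
    X[t + 1] <- X[t] + predict_growth_rate(
      params, X[t], z = table$z_lithic[t], zw = table$z_warfare[t],
      zp = table$z_pollution[t])
    if (!is.finite(X[t + 1]))
      stop("simulated trajectory diverged at step ", t + 1,
           " (year AD ", table$year_ad[t + 1], ")")
  }
  structure(data.frame(t = table$t, year_ad = table$year_ad,
                       X_hat = X, x_hat = exp(X)),
            class = c("sim_trajectory", "data.frame"))
}

#' Coefficient of prediction
#'
#' `sigma2 = 1 - sum((pred_i - obs_i)^2) / sum((mean(obs) - obs_i)^2)`.
#' Equal to 1 for perfect prediction, 0 when the predictions do no better
#' than the observed mean, and negative when they do worse.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points;
#'   `observed` must not be constant).
#' @return The coefficient of prediction.
#' @export
coefficient_of_prediction <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 2) stop("need at least 2 observations")
  sst <- sum((mean(observed) - observed)^2)
  if (sst == 0) stop("observed series is constant; coefficient undefined")
  1 - sum((predicted - observed)^2) / sst
}

#' Validate a fitted model by total-trajectory simulation
#'
#' Simulates the trajectory from the first observed value and scores it
#' with the coefficient of prediction, on the log scale by default (the
#' scale on which the model is fitted); `scale = "raw"` scores `x` vs
#' `x_hat` instead.
#'
#' @param fit A `popdyn_fit` (or `param_set`).
#' @param table The `generation_table` it was fitted to.
#' @param scale `"log"` (default) or `"raw"`.
#' @return List with `sigma2` and the `trajectory`.
#' @export
validate_trajectory <- function(fit, table, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  traj <- simulate_trajectory(fit, table)
  s2 <- if (scale == "log") {
    coefficient_of_prediction(table$X, traj$X_hat)
  } else {
    coefficient_of_prediction(table$x, traj$x_hat)
  }
  list(sigma2 = s2, trajectory = traj, scale = scale)
}

#' @export
plot.sim_trajectory <- function(x, table = NULL, ...) {
  graphics::plot(x$year_ad, x$x_hat, type = "l", col = "red",
                 xlab = "year AD", ylab = "population proxy", ...)
  if (!is.null(table))
    graphics::lines(table$year_ad, table$x, col = "blue")
  invisible(x)
}
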