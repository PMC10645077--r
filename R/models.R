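#' Competition-cooperation model specifications
#'
#' The growth-rate model family is
#' `R_t = R_m - (c + a0*z + a1*z') * exp(X_t) - (w + b0*z'' + b1*z') * exp(-X_t)`
#' with `z` the hydroclimate (lithic) covariate, `z'` warfare and `z''`
#' social upscaling (palaeopollution). The four candidate models switch
#' covariate effects on and off:
#' \describe{
#'   \item{A}{pure endogenous dynamic (no covariates);}
#'   \item{B}{hydroclimate and warfare act on the competition term `c`;}
#'   \item{C}{B plus social upscaling on the cooperation term `w`;}
#'   \item{D}{C plus warfare on `w` (the full model).}
#' }
#'
#' @param name Model name, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A `model_spec`: list with `name`, `covariates_on_c`,
#'   `covariates_on_w`.
#' @export
model_spec <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  on_c <- switch(name, A = character(0), B = c("lithic", "warfare"),
                 C = c("lithic", "warfare"), D = c("lithic", "warfare"))
  on_w <- switch(name, A = character(0), B = character(0),
                 C = "pollution", D = c("pollution", "warfare"))
  structure(list(name = name, covariates_on_c = on_c, covariates_on_w = on_w),
            class = "model_spec")
}

#' The four candidate model specifications
#' @return Named list of `model_spec` objects A-D.
#' @export
model_family <- function() {
  specs <- lapply(c("A", "B", "C", "D"), model_spec)
  names(specs) <- c("A", "B", "C", "D")
  specs
}

#' Parameter set for the growth-rate model
#'
#' Absent terms are fixed at 0. `R_m` is the logarithmic (mean) maximum
#' reproductive rate, `c` the intensity of intra-population competition,
#' `w` the intensity of cooperation; `alpha0`/`alpha1` couple hydroclimate
#' and warfare to `c`, `beta0`/`beta1` couple social upscaling and warfare
#' to `w`.
#'
#' @param R_m,c,w,alpha0,alpha1,beta0,beta1 Finite numeric scalars.
#' @return A named list of class `param_set`.
#' @export
param_set <- function(R_m = 0, c = 0, w = 0, alpha0 = 0, alpha1 = 0,
                      beta0 = 0, beta1 = 0) {
  p <- list(R_m = R_m, c = c, w = w, alpha0 = alpha0, alpha1 = alpha1,
            beta0 = beta0, beta1 = beta1)
  if (any(!vapply(p, is.finite, logical(1))))
    stop("all parameters must be finite")
  structure(p, class = "param_set")
}

#' Predicted per-generation growth rate
#'
#' Evaluates
#' `R = R_m - (c + alpha0*z + alpha1*zw) * exp(X) - (w + beta0*zp + beta1*zw) * exp(-X)`.
#'
#' @param params A `param_set`.
#' @param X Log population proxy.
#' @param z,zw,zp Hydroclimate (lithic), warfare, and social-upscaling
#'   (pollution) covariate values (vectors recycled against `X`).
#' @return Predicted growth rate(s).
#' @export
predict_growth_rate <- function(params, X, z = 0, zw = 0, zp = 0) {
  params$R_m -
    (params$c + params$alpha0 * z + params$alpha1 * zw) * exp(X) -
    (params$w + params$beta0 * zp + params$beta1 * zw) * exp(-X)
}

# Design matrix for a model spec on a generation table (rows with observed R).
# Columns carry the sign convention of the model so coefficients are the
# parameters themselves.
growth_design <- function(spec, table) {
  obs <- !is.na(table$R)
  X <- table$X[obs]
  z <- table$z_lithic[obs]
  zw <- table$z_warfare[obs]
  zp <- table$z_pollution[obs]
  cols <- list(R_m = rep(1, length(X)), c = -exp(X))
  if ("lithic" %in% spec$covariates_on_c) cols$alpha0 <- -z * exp(X)
  if ("warfare" %in% spec$covariates_on_c) cols$alpha1 <- -zw * exp(X)
  cols$w <- -exp(-X)
  if ("pollution" %in% spec$covariates_on_w) cols$beta0 <- -zp * exp(-X)
  if ("warfare" %in% spec$covariates_on_w) cols$beta1 <- -zw * exp(-X)
  M <- do.call(cbind, cols)
  list(M = M, y = table$R[obs])
}

#' Fit a growth-rate model to a generation table
#'
#' The model is linear in its parameters given the data, so the
#' least-squares optimum is found exactly by ordinary least squares on the
#' regressor set `{1, e^X, z e^X, z' e^X, e^-X, z'' e^-X, z' e^-X}`
#' (restricted to the terms the spec activates). An optional
#' `method = "nls"` refits by nonlinear least squares started from the
#' linear solution; it converges to the same optimum and exists for
#' parity with nonlinear-regression workflows.
#'
#' @param spec A `model_spec` (or model name `"A"`-`"D"`).
#' @param table A `generation_table`.
#' @param method `"ols"` (default) or `"nls"`.
#' @return A `popdyn_fit`: list with `spec`, `params` (`param_set`),
#'   `rss`, `n`, `n_params`, `aicc`, `fitted`, `residuals`.
#' @export
fit_model <- function(spec, table, method = c("ols", "nls")) {
  method <- match.arg(method)
  if (is.character(spec)) spec <- model_spec(spec)
  d <- growth_design(spec, table)
  if (nrow(d$M) < ncol(d$M) + 2)
    stop("not enough growth-rate observations (", nrow(d$M),
         ") to fit ", ncol(d$M), " parameters")
  qr_m <- qr(d$M)
  if (qr_m$rank < ncol(d$M)) {
    bad <- colnames(d$M)[qr_m$pivot[(qr_m$rank + 1):ncol(d$M)]]
    stop("collinear regressors; offending terms: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_m, d$y)
  if (method == "nls") {
    pn <- colnames(d$M)
    df <- as.data.frame(d$M)
    names(df) <- paste0("v_", pn)
    df$.y <- d$y
    form <- stats::as.formula(paste(
      ".y ~", paste(sprintf("%s * v_%s", pn, pn), collapse = " + ")))
    names(beta) <- pn
    nfit <- stats::nls(form, data = df, start = as.list(beta))
    beta <- stats::coef(nfit)[pn]
  }
  pars <- as.list(beta)
  names(pars) <- colnames(d$M)
  params <- do.call(param_set, pars)
  fitted <- as.numeric(d$M %*% beta)
  resid <- d$y - fitted
  rss <- sum(resid^2)
  structure(list(spec = spec, params = params, rss = rss,
                 n = length(d$y), n_params = ncol(d$M),
                 aicc = aicc(rss, length(d$y), ncol(d$M)),
                 fitted = fitted, residuals = resid),
            class = "popdyn_fit")
}

#' Second-order Akaike information criterion
#'
#' Full Gaussian log-likelihood convention with the residual variance
#' counted as a parameter (`K = n_params + 1`):
#' `AICc = n * (log(2*pi*rss/n) + 1) + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_params Number of free mean parameters.
#' @return The AICc value.
#' @export
aicc <- function(rss, n, n_params) {
  if (rss < 0) stop("rss must be non-negative")
  K <- n_params + 1
  if (n <= K + 1)
    stop("AICc small-sample correction undefined: n = ", n, " <= K + 1 = ", K + 1)
  n * (log(2 * pi * rss / n) + 1) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc multimodel inference over a set of fits
#'
#' Computes `delta_i = AICc_i - min(AICc)`, Akaike weights
#' `w_i = exp(-delta_i/2) / sum(exp(-delta_j/2))`, ranks the fits
#' (ties broken by fewer parameters, then model name), and sums weights
#' over models containing each covariate predictor to give relative
#' importances.
#'
#' @param fits List of `popdyn_fit` objects fitted to the same table.
#' @return A `popdyn_selection`: list with `table` (data frame of model,
#'   parameters, rss, aicc, delta_aicc, weight, rank) and `importance`
#'   (named vector over predictor terms).
#' @export
model_selection <- function(fits) {
  if (length(fits) < 2) stop("model selection needs at least 2 fits")
  n <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(n)) != 1)
    stop("fits use different numbers of observations (",
         paste(unique(n), collapse = ", "), "); not comparable")
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  wts <- exp(-delta / 2)
  wts <- wts / sum(wts)
  nm <- vapply(fits, function(f) f$spec$name, character(1))
  np <- vapply(fits, function(f) f$n_params, numeric(1))
  rank_order <- order(aiccs, np, nm)
  rk <- integer(length(fits)); rk[rank_order] <- seq_along(fits)
  tab <- data.frame(model = nm, n_params = np, rss = vapply(fits, `[[`, 0, "rss"),
                    aicc = aiccs, delta_aicc = delta, weight = wts, rank = rk)
  importance <- c(
    lithic_on_c = sum(wts[vapply(fits, function(f) "lithic" %in% f$spec$covariates_on_c, TRUE)]),
    warfare_on_c = sum(wts[vapply(fits, function(f) "warfare" %in% f$spec$covariates_on_c, TRUE)]),
    pollution_on_w = sum(wts[vapply(fits, function(f) "pollution" %in% f$spec$covariates_on_w, TRUE)]),
    warfare_on_w = sum(wts[vapply(fits, function(f) "warfare" %in% f$spec$covariates_on_w, TRUE)]))
  structure(list(table = tab[order(tab$rank), ], importance = importance,
                 fits = fits),
            class = "popdyn_selection")
}

#' @export
print.popdyn_fit <- function(x, ...) {
  cat("Growth-rate model ", x$spec$name, ": n = ", x$n, ", ",
      x$n_params, " parameters, RSS = ", signif(x$rss, 4),
      ", AICc = ", round(x$aicc, 2), "\n", sep = "")
  print(unlist(x$params))
  invisible(x)
}

#' @export
print.popdyn_selection <- function(x, ...) {
  cat("AICc model selection (n =", x$fits[[1]]$n, "):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Predictor relative importance:\n")
  print(round(x$importance, 3))
  invisible(x)
}

#' Publication-style fit table
#'
#' One row per fit: parameters, AICc, delta AICc, Akaike weight and (if
#' supplied) the coefficient of prediction.
#'
#' @param selection A `popdyn_selection`.
#' @param sigma2 Optional named vector of coefficients of prediction
#'   (names = model names).
#' @return A data frame mirroring the published table layout.
#' @export
fit_table <- function(selection, sigma2 = NULL) {
  rows <- lapply(selection$fits, function(f) {
    p <- f$params
    data.frame(model = f$spec$name, R_m = p$R_m, c = p$c, w = p$w,
               alpha0 = p$alpha0, alpha1 = p$alpha1,
               beta0 = p$beta0, beta1 = p$beta1,
               AICc = f$aicc)
  })
  out <- do.call(rbind, rows)
  sel <- selection$table[match(out$model, selection$table$model), ]
  out$dAICc <- sel$delta_aicc
  out$w_i <- sel$weight
  out$sigma2 <- if (is.null(sigma2)) NA_real_ else sigma2[out$model]
  out[order(sel$rank), ]
}
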