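# Shared fixtures and independent oracles, all built in code.

# identity calibration curve: mu(cal BP) = cal BP, no curve error
identity_curve <- function(range_bp = c(0, 3000), sigma = 0) {
  calibration_curve(seq(range_bp[1], range_bp[2], by = 10),
                    seq(range_bp[1], range_bp[2], by = 10), sigma)
}

# small wiggly toy curve with 5 knots
toy_curve5 <- function() {
  calibration_curve(cal_bp = c(300, 450, 600, 750, 900),
                    mu = c(310, 440, 620, 740, 910),
                    sigma_curve = c(8, 12, 6, 10, 9))
}

write_curve_file <- function(curve, path) {
  writeLines(c("# toy curve",
               sprintf("%g,%g,%g", curve$cal_bp, curve$mu, curve$sigma_curve)),
             path)
  path
}

# a syntactically valid generation table with arbitrary dynamics
random_table <- function(seed, n = 55, step = 25) {
  set.seed(seed)
  years <- 100 + step * (seq_len(n) - 1)
  X <- cumsum(rnorm(n, 0, 0.3)) - 4
  tab <- data.frame(t = seq_len(n), year_ad = years, x = exp(X), X = X,
                    R = c(diff(X), NA_real_),
                    z_lithic = runif(n), z_warfare = runif(n),
                    z_pollution = runif(n))
  structure(tab, class = c("generation_table", "data.frame"), step = step)
}

# normal-equations least-squares oracle on the model's regressor set,
# built independently of growth_design (plain columns, signs mapped after)
ols_oracle <- function(spec, table) {
  obs <- !is.na(table$R)
  X <- table$X[obs]; z <- table$z_lithic[obs]
  zw <- table$z_warfare[obs]; zp <- table$z_pollution[obs]
  cols <- list(one = rep(1, sum(obs)), eX = exp(X))
  if ("lithic" %in% spec$covariates_on_c) cols$z_eX <- z * exp(X)
  if ("warfare" %in% spec$covariates_on_c) cols$zw_eX <- zw * exp(X)
  cols$emX <- exp(-X)
  if ("pollution" %in% spec$covariates_on_w) cols$zp_emX <- zp * exp(-X)
  if ("warfare" %in% spec$covariates_on_w) cols$zw_emX <- zw * exp(-X)
  M <- do.call(cbind, cols)
  b <- solve(crossprod(M), crossprod(M, table$R[obs]))[, 1]
  # R = b1 - (-b2) e^X ... : all non-intercept coefficients flip sign
  b[-1] <- -b[-1]
  map <- c(one = "R_m", eX = "c", z_eX = "alpha0", zw_eX = "alpha1",
           emX = "w", zp_emX = "beta0", zw_emX = "beta1")
  names(b) <- unname(map[names(b)])
  b
}

# dense exact penalized-spline solve in the all-knots cubic B-spline basis
bspline_oracle <- function(x, y, lambda) {
  n <- length(x)
  u <- (x - x[1]) / (x[n] - x[1])
  kn <- c(rep(u[1], 3), u, rep(u[n], 3))
  B <- splines::splineDesign(kn, u, ord = 4)
  p <- ncol(B)
  br <- unique(kn)
  Om <- matrix(0, p, p)
  for (i in seq_len(length(br) - 1)) {
    a <- br[i]; b <- br[i + 1]
    D <- splines::splineDesign(kn, c(a, (a + b) / 2, b), ord = 4,
                               derivs = rep(2L, 3))
    Om <- Om + t(D) %*% (((b - a) / 6 * c(1, 4, 1)) * D)
  }
  cf <- solve(crossprod(B) + lambda * Om, crossprod(B, y))
  as.numeric(B %*% cf)
}

# direct shrinking-window rolling mean by explicit loop
rolling_oracle <- function(x, width) {
  n <- length(x)
  h1 <- floor((width - 1) / 2); h2 <- width - 1 - h1
  sapply(seq_len(n), function(i) mean(x[max(1, i - h1):min(n, i + h2)]))
}

# brute-force calibration: interpolate the curve by hand on a 1-yr grid,
# evaluate the Gaussian, normalize
calibrate_oracle <- function(age, error, curve) {
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)))
  mu <- approx(curve$cal_bp, curve$mu, xout = grid)$y
  sc <- approx(curve$cal_bp, curve$sigma_curve, xout = grid)$y
  d <- exp(-(age - mu)^2 / (2 * (error^2 + sc^2))) /
    sqrt(2 * pi * (error^2 + sc^2))
  data.frame(year_ad = rev(1950 - grid), density = rev(d / sum(d)))
}

# reference covariate triplet at the model-level study conditions
covariate_draw_fixture <- function(seed) covariate_draw(seed)
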