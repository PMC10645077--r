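#' Proxy time series
#'
#' @param year_ad Calendar years AD (strictly increasing).
#' @param value Proxy values (finite).
#' @param kind One of `"lithic"`, `"conflict"`, `"pollution"`, `"spd"`,
#'   or any label.
#' @return A data frame of class `proxy_series`.
#' @export
proxy_series <- function(year_ad, value, kind = "proxy") {
  if (any(diff(year_ad) <= 0)) stop("proxy grid must be strictly increasing")
  if (any(!is.finite(value))) stop("proxy values must be finite")
  structure(data.frame(year_ad = as.numeric(year_ad), value = as.numeric(value)),
            class = c("proxy_series", "data.frame"), kind = kind)
}

#' Read/write proxy series CSV (`year_ad,value`)
#' @param path CSV path.
#' @param kind Series label.
#' @export
read_proxy_series <- function(path, kind = "proxy") {
  d <- utils::read.csv(path)
  proxy_series(d$year_ad, d$value, kind = kind)
}

#' @rdname read_proxy_series
#' @param series A `proxy_series`.
#' @export
write_proxy_series <- function(series, path) {
  utils::write.csv(data.frame(year_ad = series$year_ad, value = series$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Period score table
#'
#' Coarse chrono-cultural period scores (e.g. trauma frequencies per
#' period), to be interpolated to an annual scale.
#'
#' @param period_start,period_end Period bounds in years AD.
#' @param score Score per period.
#' @return A data frame of class `period_scores`.
#' @export
period_scores <- function(period_start, period_end, score) {
  d <- data.frame(period_start = as.numeric(period_start),
                  period_end = as.numeric(period_end),
                  score = as.numeric(score))
  d <- d[order(d$period_start), , drop = FALSE]
  if (any(d$period_end <= d$period_start))
    stop("each period must end after it starts")
  if (nrow(d) > 1 && any(d$period_start[-1] < d$period_end[-nrow(d)]))
    stop("periods must not overlap")
  if (any(!is.finite(d$score))) stop("period scores must be finite")
  rownames(d) <- NULL
  structure(d, class = c("period_scores", "data.frame"))
}

#' Read a period score table from CSV (`period_start,period_end,score`)
#' @param path CSV path.
#' @export
read_period_scores <- function(path) {
  d <- utils::read.csv(path)
  period_scores(d$period_start, d$period_end, d$score)
}

#' Interpolate period scores to an annual series
#'
#' Each score is attached to its period midpoint; annual values follow by
#' linear interpolation between midpoints and are held constant beyond the
#' outermost midpoints (covering the full span of the periods).
#'
#' @param table A `period_scores` table.
#' @param kind Label for the resulting series (default `"conflict"`).
#' @return An annual `proxy_series` from the first period start to the
#'   last period end.
#' @export
interpolate_period_scores <- function(table, kind = "conflict") {
  mid <- (table$period_start + table$period_end) / 2
  grid <- seq(min(table$period_start), max(table$period_end))
  if (nrow(table) == 1) {
    val <- rep(table$score, length(grid))
  } else {
    val <- stats::approx(mid, table$score, xout = grid, rule = 2)$y
  }
  proxy_series(grid, val, kind = kind)
}

#' Min-max normalize a series to [0, 1]
#'
#' @param x Numeric vector (non-constant).
#' @return `(x - min) / (max - min)`.
#' @export
minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] <= r[1]) stop("cannot min-max normalize a constant series")
  (x - r[1]) / (r[2] - r[1])
}

#' Merge two proxy series by averaging min-max normalized values
#'
#' The two series are aligned by linear interpolation onto the union of
#' their grids restricted to the overlap of their ranges, each is min-max
#' normalized to [0, 1], and the output is the pointwise mean.
#'
#' @param series_a,series_b `proxy_series` objects with overlapping ranges.
#' @param kind Label for the merged series.
#' @return A `proxy_series` on the union grid of the overlap.
#' @export
normalize_and_merge <- function(series_a, series_b, kind = "merged") {
  lo <- max(min(series_a$year_ad), min(series_b$year_ad))
  hi <- min(max(series_a$year_ad), max(series_b$year_ad))
  if (hi <= lo) stop("series do not overlap in time")
  grid <- sort(unique(c(series_a$year_ad, series_b$year_ad)))
  grid <- grid[grid >= lo & grid <= hi]
  va <- stats::approx(series_a$year_ad, series_a$value, xout = grid)$y
  vb <- stats::approx(series_b$year_ad, series_b$value, xout = grid)$y
  proxy_series(grid, (minmax_scale(va) + minmax_scale(vb)) / 2, kind = kind)
}

#' Cubic smoothing spline with the spar parameterization
#'
#' Exact natural cubic smoothing spline: minimizes
#' `sum((v_i - f(t_i))^2) + lambda * integral(f''(u)^2 du)` over twice
#' differentiable `f`, with the abscissae rescaled to `[0, 1]`. The
#' penalty is controlled on the conventional `spar` scale via
#' `lambda = r * 256^(3 * spar - 1)`, where `r = tr(B'B) / tr(Omega)` is
#' the trace ratio of the all-knots cubic B-spline design matrix and its
#' exact second-derivative Gram matrix. The solution is computed by the
#' Reinsch algorithm (a banded penalized solve), so the result is the
#' exact minimizer rather than an approximation.
#'
#' @param series A `proxy_series` (>= 4 points).
#' @param spar Smoothing parameter in `[0, 1]`; larger is smoother.
#' @param lambda Optional penalty on the rescaled abscissae, overriding
#'   `spar` (used mainly for linearity checks).
#' @return A `proxy_series` of smoothed values on the input grid, with
#'   attributes `spar` and `lambda`.
#' @export
spline_smooth <- function(series, spar = 0.65, lambda = NULL) {
  x <- series$year_ad
  y <- series$value
  n <- length(x)
  if (n < 4) stop("spline smoothing needs at least 4 points")
  if (is.null(lambda)) {
    if (!is.finite(spar) || spar < 0 || spar > 1)
      stop("spar must lie in [0, 1]")
    lambda <- spar_to_lambda(x, spar)
  }
  u <- (x - x[1]) / (x[n] - x[1])
  fit <- reinsch_solve(u, y, lambda)
  out <- proxy_series(x, fit, kind = attr(series, "kind"))
  attr(out, "spar") <- spar
  attr(out, "lambda") <- lambda
  out
}

# lambda = r * 256^(3 spar - 1), r = tr(B'B)/tr(Omega) on x rescaled to [0,1],
# with Omega the exact second-derivative Gram of the all-knots cubic basis
# (per-interval Simpson quadrature is exact: the integrand is quadratic).
# The trace ratio depends only on the abscissae, so it is cached: Monte-
# Carlo studies smooth thousands of series on the same annual grid.
.lambda_cache <- new.env(parent = emptyenv())

spar_to_lambda <- function(x, spar) {
  key <- paste(length(x), x[1], x[length(x)], sum(x), spar, sep = "|")
  hit <- .lambda_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(x)
  u <- (x - x[1]) / (x[n] - x[1])
  kn <- c(rep(u[1], 3), u, rep(u[n], 3))
  B <- splines::splineDesign(kn, u, ord = 4)
  tr_btb <- sum(B^2)
  br <- unique(kn)
  tr_om <- 0
  for (i in seq_len(length(br) - 1)) {
    a <- br[i]; b <- br[i + 1]
    D <- splines::splineDesign(kn, c(a, (a + b) / 2, b), ord = 4,
                               derivs = rep(2L, 3))
    tr_om <- tr_om + sum(((b - a) / 6 * c(1, 4, 1)) * D^2)
  }
  lam <- (tr_btb / tr_om) * 256^(3 * spar - 1)
  .lambda_cache[[key]] <- lam
  lam
}

# Reinsch algorithm: solve (R + lambda Q'Q) gamma = Q'y, f = y - lambda Q gamma,
# with Q, R the standard second-difference / curvature band matrices
# (Green & Silverman). Sparse banded solve via Matrix.
reinsch_solve <- function(u, y, lambda) {
  n <- length(u)
  h <- diff(u)
  if (any(h <= 0)) stop("abscissae must be strictly increasing")
  m <- n - 2
  jj <- seq_len(m)
  Q <- Matrix::sparseMatrix(
    i = c(jj, jj + 1, jj + 2),
    j = c(jj, jj, jj),
    x = c(1 / h[jj], -1 / h[jj] - 1 / h[jj + 1], 1 / h[jj + 1]),
    dims = c(n, m))
  R <- Matrix::bandSparse(m, m,
    k = -1:1,
    diagonals = list(h[2:(m)] / 6, (h[jj] + h[jj + 1]) / 3, h[2:(m)] / 6),
    symmetric = FALSE)
  gam <- Matrix::solve(R + lambda * Matrix::crossprod(Q), Matrix::crossprod(Q, y))
  as.numeric(y - lambda * (Q %*% gam))
}

#' Assemble the generation table
#'
#' Samples the SPD population proxy and the covariate series on a fixed
#' generation grid (default 25-year steps, roughly one human generation)
#' and derives the log population `X_t = log(x_t)` and per-generation
#' growth rate `R_t = X_{t+1} - X_t`.
#'
#' @param spd An `spd_series` (or any `proxy_series`-like frame with
#'   `year_ad` and a value column) used as the population proxy.
#' @param lithic,warfare,pollution `proxy_series` covariates (hydroclimate,
#'   conflict, social-upscaling proxies); sampled at the same grid years
#'   by linear interpolation.
#' @param step Generation step in years (default 25).
#' @param window Calendar window `c(start, end)` in years AD; defaults to
#'   the SPD range.
#' @return A data frame of class `generation_table` with columns
#'   `t`, `year_ad`, `x`, `X`, `R` (NA on the last row), `z_lithic`,
#'   `z_warfare`, `z_pollution`.
#' @export
build_generation_table <- function(spd, lithic, warfare, pollution,
                                   step = 25, window = NULL) {
  if (is.null(window)) window <- range(spd$year_ad)
  years <- seq(window[1], window[2], by = step)
  vcol <- if ("spd" %in% names(spd)) "spd" else "value"
  sample_at <- function(s, col = "value") {
    if (min(s$year_ad) > min(years) || max(s$year_ad) < max(years))
      stop("series does not cover the window AD ", window[1], "-", window[2])
    stats::approx(s$year_ad, s[[col]], xout = years)$y
  }
  x <- sample_at(spd, vcol)
  if (any(x <= 0))
    stop("population proxy is non-positive at year AD ",
         years[which(x <= 0)[1]])
  X <- log(x)
  tab <- data.frame(
    t = seq_along(years), year_ad = years, x = x, X = X,
    R = c(diff(X), NA_real_),
    z_lithic = sample_at(lithic),
    z_warfare = sample_at(warfare),
    z_pollution = sample_at(pollution))
  structure(tab, class = c("generation_table", "data.frame"), step = step)
}

#' Read/write a generation table CSV
#' (`t,year_ad,x,X,R,z_lithic,z_warfare,z_pollution`)
#' @param table A `generation_table`.
#' @param path CSV path.
#' @export
write_generation_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_generation_table
#' @export
read_generation_table <- function(path) {
  d <- utils::read.csv(path)
  step <- if (nrow(d) > 1) d$year_ad[2] - d$year_ad[1] else NA_real_
  structure(d, class = c("generation_table", "data.frame"), step = step)
}
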