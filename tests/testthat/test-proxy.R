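test_that("period scores interpolate linearly between midpoints", {
  tab <- period_scores(c(0, 200), c(200, 400), c(0, 1))
  s <- interpolate_period_scores(tab)
  expect_equal(s$value[s$year_ad == 200], 0.5)   # midpoints 100 and 300
  expect_equal(s$value[s$year_ad == 100], 0)
  expect_equal(s$value[s$year_ad == 400], 1)     # held beyond last midpoint

  s1 <- interpolate_period_scores(period_scores(100, 500, 0.7))
  expect_true(all(s1$value == 0.7))

  tent <- period_scores(c(0, 200, 400), c(200, 400, 600), c(0, 1, 0))
  st <- interpolate_period_scores(tent)
  mid <- c(100, 300, 500)
  ref <- approx(mid, c(0, 1, 0), xout = st$year_ad, rule = 2)$y
  expect_equal(st$value, ref, tolerance = 1e-12)

  expect_error(period_scores(c(0, 150), c(200, 400), c(0, 1)), "overlap")
})

test_that("min-max normalization and merging behave as specified", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(minmax_scale(c(3, 3, 3)), "constant")

  a <- proxy_series(c(0, 100), c(0, 1))
  b <- proxy_series(c(0, 100), c(1, 0))
  m <- normalize_and_merge(a, b)
  expect_equal(m$value, c(0.5, 0.5))

  # merging a series with itself returns its min-max image
  s <- proxy_series(seq(0, 500, 50), sin(seq(0, 5, 0.5)) * 3 + 4)
  ms <- normalize_and_merge(s, s)
  expect_equal(ms$value, minmax_scale(s$value), tolerance = 1e-12)
  expect_true(all(ms$value >= 0 & ms$value <= 1))

  expect_error(normalize_and_merge(proxy_series(0:10, 0:10),
                                   proxy_series(20:30, 0:10)), "overlap")
})

test_that("smoothing spline reproduces lines and matches the exact oracle", {
  x <- seq(100, 1450, by = 25)
  line <- proxy_series(x, 2 + 0.003 * x)
  for (sp in c(0.1, 0.65, 1)) {
    sm <- spline_smooth(line, spar = sp)
    expect_equal(sm$value, line$value, tolerance = 1e-8)
  }

  set.seed(5)
  noisy <- proxy_series(x, sin(x / 150) + rnorm(length(x), 0, 0.2))
  sm <- spline_smooth(noisy, spar = 0.65)
  expect_lt(max(abs(sm$value -
                    bspline_oracle(x, noisy$value, attr(sm, "lambda")))),
            1e-6)

  # residual sum of squares is non-decreasing in spar
  rss <- sapply(seq(0.1, 1, by = 0.1), function(sp)
    sum((spline_smooth(noisy, spar = sp)$value - noisy$value)^2))
  expect_true(all(diff(rss) >= -1e-10))

  expect_error(spline_smooth(noisy, spar = 1.5), "spar")
  expect_error(spline_smooth(proxy_series(1:3, rnorm(3)), 0.5), "4 points")
})

test_that("penalty limit approaches the least-squares line", {
  set.seed(6)
  x <- seq(0, 1000, by = 20)
  y <- 1 + 0.01 * x + rnorm(length(x), 0, 0.5)
  sm <- spline_smooth(proxy_series(x, y), lambda = 1e8)
  expect_equal(sm$value, unname(fitted(lm(y ~ x))), tolerance = 1e-4)
})

test_that("smoothing is linear in the data at fixed lambda", {
  set.seed(8)
  x <- seq(0, 500, by = 10)
  y1 <- rnorm(length(x)); y2 <- rnorm(length(x))
  lam <- 1e-4
  s1 <- spline_smooth(proxy_series(x, y1), lambda = lam)$value
  s2 <- spline_smooth(proxy_series(x, y2), lambda = lam)$value
  s12 <- spline_smooth(proxy_series(x, 2 * y1 - 3 * y2), lambda = lam)$value
  expect_equal(s12, 2 * s1 - 3 * s2, tolerance = 1e-8)
})

test_that("spar convention tracks the reference implementation on annual grids", {
  set.seed(9)
  x <- seq(100, 700)
  y <- sin(x / 80) + rnorm(length(x), 0, 0.3)
  for (sp in c(0.45, 0.65, 0.70)) {
    mine <- spline_smooth(proxy_series(x, y), spar = sp)$value
    ref <- fitted(stats::smooth.spline(x, y, spar = sp, all.knots = TRUE,
                                       penalty = 1))
    expect_lt(max(abs(mine - ref)), 0.05 * sd(y))
  }
})

test_that("generation tables sample the grid and derive growth rates", {
  yrs <- seq(50, 1500)
  flat <- proxy_series(yrs, rep(2, length(yrs)))
  cov <- proxy_series(yrs, seq(0, 1, length.out = length(yrs)))
  spd_const <- structure(data.frame(year_ad = yrs, spd = rep(0.01, length(yrs))),
                         class = c("spd_series", "data.frame"))
  tab <- build_generation_table(spd_const, cov, cov, cov,
                                window = c(100, 1450))
  expect_equal(nrow(tab), 55)
  expect_equal(sum(!is.na(tab$R)), 54)
  expect_true(all(abs(tab$R[!is.na(tab$R)]) < 1e-12))

  # doubling each 25-yr step: R = log 2 everywhere
  dbl <- structure(data.frame(year_ad = yrs, spd = 0.001 * 2^((yrs - 100) / 25)),
                   class = c("spd_series", "data.frame"))
  tab2 <- build_generation_table(dbl, cov, cov, cov, window = c(100, 1450))
  expect_equal(tab2$R[!is.na(tab2$R)], rep(log(2), 54), tolerance = 1e-9)

  # growth rates telescope exactly
  set.seed(10)
  wig <- structure(data.frame(year_ad = yrs,
                              spd = exp(cumsum(rnorm(length(yrs), 0, 0.01)))),
                   class = c("spd_series", "data.frame"))
  tab3 <- build_generation_table(wig, cov, cov, cov, window = c(100, 1450))
  expect_equal(sum(tab3$R, na.rm = TRUE), tab3$X[55] - tab3$X[1],
               tolerance = 1e-12)

  neg <- structure(data.frame(year_ad = yrs, spd = rep(0, length(yrs))),
                   class = c("spd_series", "data.frame"))
  expect_error(build_generation_table(neg, cov, cov, cov,
                                      window = c(100, 1450)), "year AD 100")
})
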