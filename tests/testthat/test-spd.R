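test_that("binning clusters within sites at the cut height", {
  d <- c14_dates(c("a", "b"), c(1000, 1010), c(20, 20), c("s1", "s1"))
  expect_equal(attr(bin_dates(d, 50), "n_bins"), 1)

  d2 <- c14_dates(c("a", "b"), c(1000, 1000), c(20, 20), c("s1", "s2"))
  expect_equal(attr(bin_dates(d2, 50), "n_bins"), 2)

  d3 <- c14_dates(c("a", "b", "c"), c(1000, 1040, 1100), c(20, 20, 20),
                  rep("s1", 3))
  b3 <- bin_dates(d3, 50)
  expect_equal(attr(b3, "n_bins"), 2)
  expect_equal(b3$bin[1], b3$bin[2])   # complete-linkage span 40 <= 50
  expect_false(b3$bin[3] == b3$bin[1]) # merging all three would span 100
})

test_that("binning is order-invariant and respects cut-height limits", {
  set.seed(42)
  n <- 40
  d <- c14_dates(sprintf("L%02d", 1:n), runif(n, 800, 1200), 20,
                 sample(c("s1", "s2", "s3"), n, replace = TRUE))
  b1 <- bin_dates(d, 50)
  perm <- sample(n)
  dp <- c14_dates(d$lab_id[perm], d$age[perm], d$error[perm], d$site_id[perm])
  b2 <- bin_dates(dp, 50)
  expect_equal(attr(b1, "n_bins"), attr(b2, "n_bins"))
  # same partition: members grouped identically after relabelling
  g1 <- lapply(unname(split(d$lab_id, b1$bin)), sort)
  g2 <- lapply(unname(split(dp$lab_id, b2$bin)), sort)
  expect_setequal(sapply(g1, paste, collapse = ","),
                  sapply(g2, paste, collapse = ","))

  expect_equal(attr(bin_dates(d, 1e-9), "n_bins"), n)        # one bin per date
  expect_equal(attr(bin_dates(d, 1e9), "n_bins"), 3)         # one bin per site
})

test_that("SPD conserves interior mass and is additive over bins", {
  crv <- identity_curve()
  d <- c14_dates("a", 1000, 20, "s1")
  dens <- calibrate_dates(d, crv)
  spd1 <- build_spd(dens, bin_dates(d), window = c(600, 1300),
                    rolling_window = 100)
  expect_equal(sum(spd1$spd), 1, tolerance = 1e-6)
  expect_true(all(spd1$spd >= 0))

  # two identical single-date bins at different sites: exactly twice the SPD
  d2 <- c14_dates(c("a", "b"), c(1000, 1000), c(20, 20), c("s1", "s2"))
  dens2 <- calibrate_dates(d2, crv)
  spd2 <- build_spd(dens2, bin_dates(d2), window = c(600, 1300),
                    rolling_window = 100)
  expect_equal(spd2$spd, 2 * spd1$spd, tolerance = 1e-12)

  # permuting date order never changes the SPD
  spd2p <- build_spd(rev(dens2), bin_dates(d2[2:1, ]), window = c(600, 1300),
                     rolling_window = 100)
  expect_equal(spd2p$spd, spd2$spd, tolerance = 1e-12)
})

test_that("total normalized SPD mass over a covering window equals n_bins", {
  crv <- identity_curve()
  set.seed(7)
  n <- 25
  d <- c14_dates(sprintf("L%02d", 1:n), runif(n, 700, 1100), 25,
                 sprintf("s%d", sample(8, n, replace = TRUE)))
  dens <- calibrate_dates(d, crv)
  bins <- bin_dates(d)
  spd <- build_spd(dens, bins, window = c(400, 1700), rolling_window = 100)
  expect_equal(sum(spd$spd), attr(bins, "n_bins"), tolerance = 1e-6)
})

test_that("rolling mean matches the direct-convolution oracle and ramps a step", {
  step_fn <- c(rep(0, 200), rep(1, 200))
  rolled <- rolling_mean(step_fn, 100)
  expect_equal(rolled, rolling_oracle(step_fn, 100), tolerance = 1e-12)
  # interior ramp has constant slope 1/100 over exactly 100 points
  ramp <- rolled[150:250]
  d <- diff(ramp)
  expect_equal(sum(d > 1e-12), 100)
  expect_equal(max(abs(d[d > 1e-12] - 1 / 100)), 0, tolerance = 1e-12)

  set.seed(1)
  x <- rnorm(500)
  for (w in c(3, 4, 100)) {
    expect_equal(rolling_mean(x, w), rolling_oracle(x, w), tolerance = 1e-12)
  }
})

test_that("SPD rejects empty input and records metadata", {
  expect_error(build_spd(list()), "no calibrated")
  crv <- identity_curve()
  d <- c14_dates("a", 900, 20, "s1")
  dens <- calibrate_dates(d, crv, normalize = FALSE)
  spd <- build_spd(dens, bin_dates(d), window = c(900, 1200))
  expect_false(attr(spd, "normalized"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spd(spd, f)
  spd2 <- read_spd(f)
  expect_equal(spd2$spd, spd$spd, tolerance = 1e-6)
})
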