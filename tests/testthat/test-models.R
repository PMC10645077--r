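test_that("growth-rate prediction evaluates the model family formula", {
  expect_equal(predict_growth_rate(param_set(R_m = 1.7), X = 0.3), 1.7)
  p <- param_set(R_m = 1, c = 10, w = 0.05)
  expect_equal(predict_growth_rate(p, X = log(0.1)), 1 - 10 * 0.1 - 0.05 * 10)
  p2 <- param_set(alpha0 = 2)
  expect_equal(predict_growth_rate(p2, X = 0, z = 0.5), -1)
  # full covariate form
  p3 <- param_set(R_m = 0.4, c = 2, w = 0.1, alpha0 = 1, alpha1 = 0.5,
                  beta0 = 0.2, beta1 = -0.3)
  X <- 0.7; z <- 0.2; zw <- 0.6; zp <- 0.9
  expect_equal(predict_growth_rate(p3, X, z, zw, zp),
               0.4 - (2 + 1 * 0.2 + 0.5 * 0.6) * exp(0.7) -
                 (0.1 + 0.2 * 0.9 - 0.3 * 0.6) * exp(-0.7))
})

test_that("model specs match the candidate-family definitions", {
  fam <- model_family()
  expect_equal(fam$A$covariates_on_c, character(0))
  expect_equal(fam$B$covariates_on_c, c("lithic", "warfare"))
  expect_equal(fam$B$covariates_on_w, character(0))
  expect_equal(fam$C$covariates_on_w, "pollution")
  expect_equal(fam$D$covariates_on_w, c("pollution", "warfare"))
})

test_that("noise-free data generated from model A is recovered exactly", {
  tab <- random_table(1)
  tab$X[1] <- log(2)  # start well below equilibrium: informative transient
  p <- param_set(R_m = 0.5, c = 0.01, w = 0.001)
  tr <- simulate_trajectory(p, tab)
  tab$X <- tr$X_hat; tab$x <- tr$x_hat; tab$R <- c(diff(tr$X_hat), NA)
  f <- fit_model("A", tab)
  expect_lt(abs(f$params$R_m - 0.5), 1e-8)
  expect_lt(abs(f$params$c - 0.01), 1e-8)
  expect_lt(abs(f$params$w - 0.001), 1e-8)
  expect_equal(f$params$alpha0, 0)
})

test_that("fits equal the normal-equations oracle on random tables", {
  for (s in 1:25) {
    tab <- random_table(100 + s)
    for (nm in c("A", "B", "C", "D")) {
      f <- fit_model(nm, tab)
      b <- ols_oracle(model_spec(nm), tab)
      expect_lt(max(abs(unlist(f$params)[names(b)] - b)), 1e-10)
    }
  }
})

test_that("ols and nls routes agree", {
  tab <- random_table(7)
  f1 <- fit_model("D", tab, method = "ols")
  f2 <- fit_model("D", tab, method = "nls")
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-7)
})

test_that("nested models satisfy RSS monotonicity", {
  for (s in 1:10) {
    tab <- random_table(200 + s)
    rss <- sapply(model_family(), function(sp) fit_model(sp, tab)$rss)
    expect_true(rss["D"] <= rss["C"] + 1e-12)
    expect_true(rss["C"] <= rss["B"] + 1e-12)
    expect_true(rss["B"] <= rss["A"] + 1e-12)
  }
})

test_that("collinear regressors raise a named error", {
  tab <- random_table(3)
  tab$z_warfare <- tab$z_lithic  # identical covariates on c
  expect_error(fit_model("B", tab), "collinear")
})

test_that("AICc follows the small-sample Gaussian formula", {
  expect_equal(aicc(0.1, 54, 3), -177.68, tolerance = 0.01)
  expect_equal(aicc(0.2, 40, 2), aicc(0.2, 40, 2))
  # penalty strictly increases with parameter count at fixed rss
  vals <- sapply(1:6, function(k) aicc(0.1, 54, k))
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(0.1, 6, 5), "undefined")
})

test_that("Akaike weights reproduce the published comparison set", {
  fits <- Map(function(nm, a, k) {
    structure(list(spec = model_spec(nm), aicc = a, n = 54, n_params = k,
                   rss = 1, params = param_set()), class = "popdyn_fit")
  }, c("A", "B", "C", "D"), c(-96.06, -92.34, -92.43, -109.61), c(3, 5, 6, 7))
  sel <- model_selection(fits)
  tab <- sel$table[match(c("A", "B", "C", "D"), sel$table$model), ]
  expect_equal(tab$delta_aicc[1], 13.55, tolerance = 1e-9)
  expect_equal(round(tab$weight, 2), c(0, 0, 0, 1))
  expect_equal(sel$table$model[1], "D")
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-9)
  # predictor present only in the weight-1 model has importance ~1
  expect_equal(unname(sel$importance["warfare_on_w"]), tab$weight[4])
})

test_that("weights are invariant to AICc shifts and split ties evenly", {
  mk <- function(nm, a, k) structure(
    list(spec = model_spec(nm), aicc = a, n = 54, n_params = k, rss = 1,
         params = param_set()), class = "popdyn_fit")
  s1 <- model_selection(list(mk("A", -10, 3), mk("B", -12, 5)))
  s2 <- model_selection(list(mk("A", 90, 3), mk("B", 88, 5)))
  expect_equal(s1$table$weight, s2$table$weight, tolerance = 1e-12)

  tie <- model_selection(list(mk("A", -5, 3), mk("B", -5, 5)))
  expect_equal(tie$table$weight, c(0.5, 0.5))
  expect_equal(tie$table$model[1], "A")  # fewer parameters ranks first

  expect_error(model_selection(list(mk("A", -5, 3))), "at least 2")
  bad <- mk("B", -5, 5); bad$n <- 40
  expect_error(model_selection(list(mk("A", -5, 3), bad)), "not comparable")
})
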