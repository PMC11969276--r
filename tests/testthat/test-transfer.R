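test_that("correlation fitting matches the frozen OLS solution", {
  t2 <- load_fixture("table2")
  fit <- fit_correlation(t2, exclude = "1H-Benzotriazole")
  # coefficients frozen from an independent lm() on the 15 pairs
  expect_equal(fit$n, 15L)
  expect_equal(fit$slope, 1.021937645, tolerance = 1e-8)
  expect_equal(fit$intercept, 11.373963519, tolerance = 1e-8)
  # two exactly collinear-plus-one points: perfect fit
  f2 <- fit_correlation(c(1, 2, 3), c(10, 12, 14))
  expect_equal(f2$slope, 2)
  expect_equal(f2$rmse_fit, 0, tolerance = 1e-12)
  expect_error(fit_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("correlation fitting is affine-equivariant in y", {
  set.seed(8)
  x <- runif(10, 10, 20); y <- 1.1 * x + rnorm(10, 0, 0.3)
  f0 <- fit_correlation(x, y)
  f1 <- fit_correlation(x, y + 2.5)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f0$intercept + 2.5, tolerance = 1e-12)
})

test_that("linear prediction evaluates the line and warns on extrapolation", {
  f <- fit_correlation(c(10, 15, 20), c(10, 15, 20))  # identity
  expect_equal(predict_linear(f, 12), 12)
  expect_warning(predict_linear(f, 25), "extrapolates")
  t2 <- load_fixture("table2")
  fit <- fit_correlation(t2, exclude = "1H-Benzotriazole")
  expect_equal(round(suppressWarnings(predict_linear(fit, 11.92)), 1), 23.6)
  expect_equal(round(suppressWarnings(predict_linear(fit, 23.0)), 1), 34.9)
  expect_equal(round(predict_linear(fit, 18.6), 1), 30.4)
})

test_that("packaged conversion models reproduce the benchmark predictions", {
  models <- default_conversion_models()
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  bench <- t2[t2$name %in% t3$name, ]
  expect_equal(nrow(bench), 15L)
  pn <- apply_conversion(models$nh_specific, bench)
  pu <- apply_conversion(models$universal, bench)
  i <- match(pn$compound, t3$name)
  expect_equal(round(pn$predicted, 2), t3$pred_nh[i], tolerance = 1e-9)
  expect_equal(round(pu$predicted, 2), t3$pred_universal[i])
  # spot values: one NH-specific and one universal prediction
  expect_equal(round(pn$predicted[pn$compound == "4-NO2-Aniline"], 2), 32.90)
  expect_equal(round(pu$predicted[pu$compound == "Benzimidazole"], 2), 28.51)
  # a degenerate all-constant model predicts its constant
  k <- conversion_model("const", c(pka_source = 0, n_hbd = 0,
                                   n_xh_xso2 = 0, n_n = 0, constant = 7))
  expect_true(all(apply_conversion(k, bench)$predicted == 7))
  expect_error(apply_conversion(models$universal,
                                data.frame(pka_dmso = 15)), "missing")
})

test_that("conversion coefficients are recoverable from the benchmark table", {
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  d <- merge(t3, t2[, c("name", "pka_dmso", "n_hbd", "n_xh_xso2", "n_n")],
             by = "name")
  d$predicted <- d$pred_nh
  m <- fit_conversion_model(d, "nh_refit")
  co <- m$coefficients
  expect_equal(unname(co["pka_source"]), 1, tolerance = 1e-6)
  expect_equal(unname(co["n_n"]), -0.3, tolerance = 1e-6)
  expect_equal(unname(co["constant"]), 12.6, tolerance = 1e-4)
  d$predicted <- d$pred_universal
  mu <- fit_conversion_model(d, "universal_refit")
  packaged <- default_conversion_models()$universal$coefficients
  expect_equal(mu$coefficients, packaged, tolerance = 1e-6)
})

test_that("prediction RMSE matches the published benchmark values", {
  t3 <- load_fixture("table3")
  expect_equal(round(prediction_rmse(t3$diff_nh), 2), 0.49)
  expect_equal(round(prediction_rmse(t3$diff_universal), 2), 0.46)
  expect_equal(prediction_rmse(rep(0, 5)), 0)
  expect_error(prediction_rmse(numeric(0)), "no predictions")
  # permutation invariance and non-negativity
  set.seed(2)
  v <- rnorm(8)
  expect_equal(prediction_rmse(v), prediction_rmse(sample(v)))
  expect_gt(prediction_rmse(v), 0)
})

test_that("recommended values are means within the estimate range", {
  r <- recommend_pka(c(34.9, 35.3, 35.5))
  expect_equal(r$mean, 35.2)
  expect_equal(r$uncertainty, 0.5)
  expect_equal(recommend_pka(c(26.5, 26.5, 26.8))$mean, 26.6)
  expect_equal(recommend_pka(c(31.1, 31.1, 31.1))$mean, 31.1)
  set.seed(3)
  for (i in 1:20) {
    est <- runif(sample(2:5, 1), 20, 35)
    m <- recommend_pka(est)$mean
    expect_gte(m, round(min(est), 1) - 0.05)
    expect_lte(m, round(max(est), 1) + 0.05)
  }
  expect_error(recommend_pka(30.1), "at least two")
})

test_that("structural acidity deltas read off the compound table", {
  t2 <- load_fixture("table2")
  d <- structure_deltas(t2, list(c("Indole", "Indazole"),
                                 c("Indole", "Indole"),
                                 c("Benzimidazole", "1H-Benzotriazole")))
  expect_equal(d$delta_pka, c(2.99, 0, 4.94))
  expect_error(structure_deltas(t2, list(c("Indole", "nonexistent"))),
               "not found")
})
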