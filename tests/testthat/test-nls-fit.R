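# Fixed-effects nonlinear least squares: starts, fitting, screening and
# covariate search.

test_that("log-linearized starts are exact on noise-free M7 data", {
  d <- m7_table(60, a = 0.31, b = 0.95, c = 0.0025, sd = 0, seed = 11)
  init <- initial_values(model_spec("M7"), d, "SBL")
  expect_equal(unname(init[c("a", "b", "c")]), c(0.31, 0.95, 0.0025),
               tolerance = 1e-8)
  # three distinct points: exactly identified, equals the closed-form
  # 3x3 solve of log y = log a + b log x - c x
  d3 <- data.frame(SDINC = c(20, 120, 380))
  d3$SBL <- 0.4 * d3$SDINC^0.9 * exp(-0.004 * d3$SDINC)
  A <- cbind(1, log(d3$SDINC), d3$SDINC)
  sol <- solve(A, log(d3$SBL))
  init3 <- initial_values(model_spec("M7"), d3, "SBL")
  expect_equal(unname(init3[c("a", "b", "c")]),
               unname(c(exp(sol[1]), sol[2], -sol[3])), tolerance = 1e-9)
  dconst <- data.frame(SDINC = rep(100, 10), SBL = runif(10, 5, 10))
  expect_error(initial_values(model_spec("M7"), dconst, "SBL"), "constant")
})

test_that("noise-free data is recovered exactly and p > n is flagged", {
  d <- m7_table(80, a = 0.25, b = 1.01, c = 0.003, a1 = 2e-4, sd = 0,
                seed = 12)
  f <- fit_nls(model_spec("M7", c(a = "PDINC")), d, "SBL")
  expect_true(f$converged)
  expect_equal(unname(f$estimates), c(0.25, 1.01, 0.003, 2e-4),
               tolerance = 1e-6)
  expect_lt(f$RMSE, 1e-6)
  d2 <- m7_table(2, sd = 0, seed = 1)
  f2 <- fit_nls(model_spec("M7"), d2, "SBL",
                init = c(a = 0.3, b = 0.9, c = 0.002))
  expect_false(f2$converged)
  expect_match(f2$message, "under-identified")
})

test_that("reported indices satisfy their defining identities", {
  d <- m7_table(400, sd = 4, seed = 13)
  f <- fit_nls(model_spec("M7"), d, "SBL")
  expect_equal(f$RMSE, sqrt(f$RSS / f$n), tolerance = 1e-12)
  expect_equal(-2 * f$logLik, f$n * log(2 * pi * f$RSS / f$n) + f$n,
               tolerance = 1e-10)
  expect_equal(f$AIC, -2 * f$logLik + 2 * 4, tolerance = 1e-10)
  expect_lte(f$Ra2, 1)
  # row order leaves every index unchanged
  set.seed(99)
  f2 <- fit_nls(model_spec("M7"), d[sample(nrow(d)), ], "SBL")
  expect_equal(f$RMSE, f2$RMSE, tolerance = 1e-9)
  expect_equal(f$MAE, f2$MAE, tolerance = 1e-9)
})

test_that("screening ranks the generating function first", {
  # data generated from the logistic M3 selects M3 over the other eight
  set.seed(14)
  d3 <- data.frame(SDINC = runif(4000, 5, 600))
  d3$SBL <- 30 / (1 + 8 * exp(-0.015 * d3$SDINC)) + rnorm(4000, 0, 2)
  tab3 <- suppressWarnings(screen_candidates(d3, response = "SBL"))
  expect_equal(tab3$function_id[1], "M3")
  expect_true(all(diff(tab3$AIC[tab3$converged]) >= 0))
  # unimodal truth with its peak inside the data range selects M7
  set.seed(15)
  d7 <- data.frame(SDINC = runif(4000, 5, 600))
  d7$SBL <- 0.25 * d7$SDINC^1.1 * exp(-0.006 * d7$SDINC) + rnorm(4000, 0, 2)
  tab7 <- suppressWarnings(screen_candidates(d7, response = "SBL"))
  expect_equal(tab7$function_id[1], "M7")
  # single candidate: a one-row table
  expect_equal(nrow(screen_candidates(d3, "M6", "SBL")), 1)
  expect_error(screen_candidates(d3, character(0)), "empty")
})

test_that("a redundant extra parameter costs AIC on average", {
  # M1 reduces to M6 at c = 1; fitting the richer M1 to M6-generated data
  # should pay the overfitting penalty
  set.seed(15)
  worse <- 0
  for (r in 1:5) {
    d <- data.frame(SDINC = runif(600, 5, 500))
    d$SBL <- 25 * (1 - exp(-0.012 * d$SDINC)) + rnorm(600, 0, 2)
    f6 <- fit_nls(model_spec("M6"), d, "SBL")
    f1 <- fit_nls(model_spec("M1"), d, "SBL")
    if (f6$converged && f1$converged && f1$AIC > f6$AIC) worse <- worse + 1
  }
  expect_gte(worse, 3)
})

test_that("covariate search recovers the generating expansion", {
  cfg <- generator_config(seed = 2, n_trees = 30, response_law = "SBL_fixed",
                          positive_only = FALSE)
  d <- dataset_table(generate_dataset(cfg))
  cs <- covariate_search(model_spec("M7"), d, c("PDINC", "PBD"), "SBL")
  expect_match(cs$model[1], "a ~ PDINC")
  f <- attr(cs, "fits")[[1]]
  expect_true(all(f$p_values[grep("1$", names(f$estimates))] < 0.05))
  # adjusted R^2 improves over the base model when the true covariate enters
  base <- fit_nls(model_spec("M7"), d, "SBL")
  expect_gt(f$Ra2, base$Ra2)

  cfgd <- generator_config(seed = 12, n_trees = 30,
                           response_law = "SBD_fixed", positive_only = FALSE)
  dd <- dataset_table(generate_dataset(cfgd))
  csd <- covariate_search(model_spec("M7"), dd, c("PDINC", "PBD"), "SBD")
  expect_match(csd$model[1], "b ~ PBD")

  # no covariate effect: the base model survives at the front
  dn <- m7_table(800, a = 0.3, b = 0.95, c = 0.003, sd = 3, seed = 17)
  csn <- covariate_search(model_spec("M7"), dn, "PBD", "SBL")
  expect_equal(csn$model[1], "base")
})
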