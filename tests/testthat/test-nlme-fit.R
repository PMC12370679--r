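# Two-level nonlinear mixed-effects estimation: degeneracies, oracle
# equivalences, likelihood behavior, EBLUP properties, prediction, and the
# variance-structure machinery.

sbl_spec <- function() model_spec("M7", c(a = "PDINC"))

small_mixed <- function(seed = 1, n_trees = 10, law = "SBL_mixed") {
  dataset_table(generate_dataset(generator_config(
    seed = seed, n_trees = n_trees, response_law = law,
    positive_only = FALSE)))
}

test_that("with no group variability the fit degenerates to NLS", {
  cfg <- generator_config(seed = 41, n_trees = 12,
                          response_law = "SBL_fixed", positive_only = FALSE)
  d <- dataset_table(generate_dataset(cfg))
  nls <- fit_nls(sbl_spec(), d, "SBL")
  mix <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec(c("b", "c"), "b"))
  for (p in names(nls$estimates))
    expect_lt(abs(mix$beta[p] - nls$estimates[p]),
              2 * nls$se[p] + 1e-8, label = p)
  expect_lt(mix$D1[1, 1], 1e-3)
  expect_lt(mix$D1[2, 2], 1e-5)
  expect_lt(mix$D2[1, 1], 1e-3)
})

test_that("Laplace log-likelihood matches adaptive quadrature", {
  # scalar level-1 effect on b: genuinely nonlinear in the random effect
  set.seed(42)
  nb <- 5; nper <- 6
  d <- data.frame(branch_id = rep(1:nb, each = nper), whorl_id = 1,
                  SDINC = runif(nb * nper, 20, 400))
  b_i <- rnorm(nb, 0, 0.05)
  d$SBL <- 2 * d$SDINC^(0.6 + b_i[d$branch_id]) * exp(-0.003 * d$SDINC) +
    rnorm(nb * nper, 0, 1.5)
  beta <- c(a = 2, b = 0.6, c = 0.003)
  fshell <- structure(list(spec = model_spec("M7"),
                           re = re_spec("b"), vs = var_spec(),
                           response = "SBL", var_par = 0,
                           corr_par = numeric(0)), class = "branch_nlme")
  lap <- nlme_loglik(fshell, d, beta = beta, D1 = matrix(0.05^2, 1, 1),
                     sigma2 = 1.5^2)
  d$y <- d$SBL
  agq <- agq_loglik(d, d$branch_id,
                    function(rows, bt, u)
                      bt["a"] * rows$SDINC^(bt["b"] + u) *
                        exp(-bt["c"] * rows$SDINC),
                    beta, "b", 0.05^2, 1.5^2)
  # the exponent effect makes the integrand non-Gaussian, so Laplace is an
  # approximation here; the gap stays small
  expect_equal(lap, agq, tolerance = 5e-3)
  # with the effect on a the model is linear in u and Laplace is exact
  fshell2 <- structure(list(spec = model_spec("M7"),
                            re = re_spec("a"), vs = var_spec(),
                            response = "SBL", var_par = 0,
                            corr_par = numeric(0)), class = "branch_nlme")
  lap2 <- nlme_loglik(fshell2, d, beta = beta, D1 = matrix(0.25, 1, 1),
                      sigma2 = 1.5^2)
  agq2 <- agq_loglik(d, d$branch_id,
                     function(rows, bt, u)
                       (bt["a"] + u) * rows$SDINC^bt["b"] *
                         exp(-bt["c"] * rows$SDINC),
                     beta, "a", 0.25, 1.5^2)
  expect_equal(lap2, agq2, tolerance = 1e-7)
})

test_that("the likelihood evaluator reduces and responds correctly", {
  d <- small_mixed(seed = 43, n_trees = 5)
  fshell <- structure(list(spec = sbl_spec(), re = re_spec(), vs = var_spec(),
                           response = "SBL", var_par = 0,
                           corr_par = numeric(0)), class = "branch_nlme")
  beta <- c(a = 0.197, b = 0.989, c = 0.003, a1 = 3e-4)
  mu <- spec_evaluate(sbl_spec(), beta, d)
  rss <- sum((d$SBL - mu)^2)
  s2hat <- rss / nrow(d)
  ll0 <- nlme_loglik(fshell, d, beta = beta, sigma2 = s2hat)
  expect_equal(ll0, -nrow(d) / 2 * (log(2 * pi * s2hat) + 1),
               tolerance = 1e-10)
  # moving sigma^2 off its optimum lowers the likelihood
  expect_lt(nlme_loglik(fshell, d, beta = beta, sigma2 = 2 * s2hat), ll0)
  # near-zero variance components reproduce the fixed-effects value
  fshell2 <- structure(list(spec = sbl_spec(), re = re_spec(c("b", "c"), "b"),
                            vs = var_spec(), response = "SBL", var_par = 0,
                            corr_par = numeric(0)), class = "branch_nlme")
  llz <- nlme_loglik(fshell2, d, beta = beta,
                     D1 = diag(c(1e-12, 1e-14)), D2 = matrix(1e-12, 1, 1),
                     sigma2 = s2hat)
  expect_equal(llz, ll0, tolerance = 1e-4)
})

test_that("estimates agree with the nlme package on the same data", {
  library(nlme)
  d <- small_mixed(seed = 44, n_trees = 8)
  d$g1 <- factor(d$branch_id)
  d$g2 <- factor(paste(d$branch_id, d$whorl_id))
  ours <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec(c("b", "c"), "b"))
  ref <- nlme(SBL ~ (a + a1 * PDINC) * SDINC^b * exp(-c * SDINC),
              fixed = a + a1 + b + c ~ 1,
              random = list(g1 = b + c ~ 1, g2 = b ~ 1),
              data = d, method = "ML",
              start = c(a = 0.197, a1 = 3e-4, b = 0.989, c = 0.003),
              control = nlmeControl(maxIter = 100, msMaxIter = 100))
  fe <- fixef(ref)
  # both routes approximate the same ML problem; small coefficients carry
  # slightly more relative slack
  for (p in c("a", "b", "c"))
    expect_lt(abs(ours$beta[p] - fe[p]) / abs(fe[p]), 0.02, label = p)
  expect_lt(abs(ours$beta["a1"] - fe["a1"]) / abs(fe["a1"]), 0.05)
  expect_lt(abs(ours$sigma2 - ref$sigma^2) / ref$sigma^2, 0.02)
  expect_lt(abs(ours$logLik - as.numeric(logLik(ref))), 2)
})

test_that("likelihood ratio tests behave on identical and nested fits", {
  d <- small_mixed(seed = 45, n_trees = 8)
  full <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec(c("b", "c"), "b"))
  nested <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec("b", "b"))
  same <- lrt(full, full)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  out <- lrt(nested, full)
  expect_gte(out$statistic, -1e-6)
  expect_equal(out$df, 2)            # extra variance + covariance of c_i
  expect_gte(full$logLik, nested$logLik - 1e-6)
  other <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec("c", "b"))
  expect_error(lrt(other, nested), "not nested")
})

test_that("EBLUPs shrink and predictions honor the mode argument", {
  d <- small_mixed(seed = 46, n_trees = 12)
  f <- fit_nlme(sbl_spec(), d, "SBL", re = re_spec(c("b", "c"), "b"))
  # group means of the random-effect predictions sit near zero
  expect_lt(abs(mean(f$eblup1$b)), 3 * sd(f$eblup1$b) / sqrt(nrow(f$eblup1)))
  # empirical spread of the EBLUPs never exceeds the estimated D1 diagonal
  expect_lte(var(f$eblup1$b), f$D1["b", "b"] * 1.05)
  expect_lte(var(f$eblup1$c), f$D1["c", "c"] * 1.05)
  pop <- predict(f, d, mode = "population")
  expect_equal(pop, spec_evaluate(f$spec, f$beta, d), tolerance = 1e-12)
  subj <- predict(f, d, mode = "subject")
  expect_lt(sqrt(mean((d$SBL - subj)^2)), sqrt(mean((d$SBL - pop)^2)))
  new <- d[1:4, ]; new$branch_id <- 99999   # unseen branch
  expect_equal(predict(f, new, mode = "subject"),
               predict(f, new, mode = "population"), tolerance = 1e-12)
  expect_error(predict(f, d[, "SBL", drop = FALSE]), "missing covariates")
})

test_that("random-effects search finds the generating combination", {
  d <- small_mixed(seed = 47, n_trees = 7)
  tab <- search_random_effects(sbl_spec(), d, "SBL", max_random = 3,
                               candidates = c("b", "c"))
  expect_true(all(c("L1{b,c} L2{b}", "L1{} L2{}") %in% tab$random_effects))
  expect_equal(tab$random_effects[1], "L1{b,c} L2{b}")
  tab0 <- search_random_effects(sbl_spec(), d, "SBL", max_random = 0)
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$random_effects, "L1{} L2{}")
})

test_that("heteroscedastic and autocorrelated structures are estimable", {
  # power-of-the-mean residual scale at delta = 0.5
  set.seed(48)
  nb <- 40; nper <- 8
  d <- data.frame(branch_id = rep(1:nb, each = nper),
                  whorl_id = rep(rep(1:2, each = 4), nb),
                  SDINC = runif(nb * nper, 20, 500))
  b_i <- rnorm(nb, 0, 0.04)
  mu <- 0.4 * d$SDINC^(0.9 + b_i[d$branch_id]) * exp(-0.002 * d$SDINC)
  d$SBL <- mu + rnorm(nb * nper, 0, 0.4 * pmax(mu, 1e-4)^0.5)
  f_const <- fit_nlme(model_spec("M7"), d, "SBL", re = re_spec("b"))
  f_pow <- fit_nlme(model_spec("M7"), d, "SBL", re = re_spec("b"),
                    vs = var_spec(variance = "power"))
  expect_true(f_pow$converged)
  expect_gt(f_pow$logLik, f_const$logLik)
  expect_gt(f_pow$var_par, 0.2)     # estimated power exponent near 0.5
  expect_lt(f_pow$var_par, 0.8)
  # AR(1) errors within whorls
  set.seed(49)
  d2 <- data.frame(branch_id = rep(1:30, each = 8),
                   whorl_id = rep(rep(1:2, each = 4), 30),
                   SDINC = runif(240, 20, 500))
  rho <- 0.6
  e <- as.vector(replicate(60, arima.sim(list(ar = rho), 4, sd = 1)))
  d2$SBL <- 0.4 * d2$SDINC^0.9 * exp(-0.002 * d2$SDINC) + 2 * e
  f_ar <- fit_nlme(model_spec("M7"), d2, "SBL", re = re_spec("b"),
                   vs = var_spec(correlation = "AR1"))
  f_id <- fit_nlme(model_spec("M7"), d2, "SBL", re = re_spec("b"))
  expect_true(f_ar$converged)
  expect_gt(f_ar$logLik, f_id$logLik)
  expect_gt(tanh(f_ar$corr_par[1]), 0.2)
})

test_that("more than four random parameters triggers the cap warning", {
  expect_warning(re_spec(c("a", "b", "c"), c("a", "b")), "unlikely")
})
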