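# Log-log scaling fits, percentile-bootstrap intervals, and the grouped
# scaling profiles.

test_that("log-log OLS reproduces exact power laws and the closed form", {
  x <- c(1, 2, 5, 10, 40)
  f <- fit_loglog(x, x)
  expect_equal(f$exponent, 1, tolerance = 1e-12)
  expect_equal(f$gamma, 0, tolerance = 1e-12)
  f2 <- fit_loglog(x, 4 * x^2)
  expect_equal(f2$exponent, 2, tolerance = 1e-12)
  expect_equal(f2$gamma, log(4), tolerance = 1e-12)
  # 20 noisy pairs against the textbook slope/intercept formulas
  set.seed(7)
  px <- runif(20, 1, 50)
  py <- 2.5 * px^0.8 * exp(rnorm(20, 0, 0.3))
  lx <- log(px); ly <- log(py)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  inter <- mean(ly) - slope * mean(lx)
  f3 <- fit_loglog(px, py)
  expect_equal(f3$exponent, slope, tolerance = 1e-12)
  expect_equal(f3$gamma, inter, tolerance = 1e-12)
  expect_error(fit_loglog(c(1, -2, 3, 4), c(1, 2, 3, 4)), "pair\\(s\\) 2")
  expect_error(fit_loglog(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bootstrap bounds equal a brute-force resampling loop exactly", {
  set.seed(8)
  px <- runif(15, 1, 30)
  py <- 1.7 * px^0.9 * exp(rnorm(15, 0, 0.25))
  bs <- bootstrap_ci(px, py, B = 50, level = 0.9, seed = 123)
  # independent loop: same RNG protocol, slopes via lm()
  set.seed(123)
  slopes <- gammas <- numeric(50)
  for (b in 1:50) {
    idx <- sample.int(15, 15, replace = TRUE)
    cf <- coef(lm(log(py[idx]) ~ log(px[idx])))
    gammas[b] <- cf[1]; slopes[b] <- cf[2]
  }
  expect_equal(bs$ci_exponent, unname(quantile(slopes, c(0.05, 0.95))),
               tolerance = 1e-12)
  expect_equal(bs$ci_gamma, unname(quantile(gammas, c(0.05, 0.95))),
               tolerance = 1e-12)
})

test_that("degenerate and single-replicate bootstraps behave", {
  x <- c(2, 4, 8, 16, 32)
  y <- 3 * x^1.5                      # noise-free: resampling cannot move the fit
  bs <- bootstrap_ci(x, y, B = 40, seed = 5)
  expect_lt(diff(bs$ci_exponent), 1e-10)
  b1 <- bootstrap_ci(x, y * exp(rnorm(5, 0, 0.1)), B = 1, seed = 9)
  expect_equal(b1$ci_exponent[1], b1$ci_exponent[2])
  expect_equal(b1$ci_exponent[1], b1$replicates[1, 2])
})

test_that("the exponent is invariant to unit rescaling", {
  set.seed(10)
  px <- runif(30, 1, 40)
  py <- 2 * px^0.7 * exp(rnorm(30, 0, 0.2))
  f <- fit_loglog(px, py)
  f_cm <- fit_loglog(px * 100, py)          # cm instead of m on x
  f_mm <- fit_loglog(px, py * 10)           # mm instead of cm on y
  expect_equal(f$exponent, f_cm$exponent, tolerance = 1e-12)
  expect_equal(f$exponent, f_mm$exponent, tolerance = 1e-12)
  expect_equal(f_mm$gamma, f$gamma + log(10), tolerance = 1e-12)
})

test_that("grouped profiles recover homogeneity and constructed trends", {
  # all branch ages share one generating exponent: estimates cluster at it
  # and the group confidence intervals overlap
  set.seed(60)
  hom <- do.call(rbind, lapply(1:4, function(ag) {
    n <- 80
    sbl <- runif(n, 5, 60)
    data.frame(tree_id = 1, branch_id = (ag - 1) * 80 + seq_len(n),
               whorl_id = 1, obs_id = 1, SAGE = 2, SDINC = 100,
               PAGE = ag + 4, PBL = 8 * sbl^0.8 * exp(rnorm(n, 0, 0.15)),
               PBD = 25, PDINC = 400, SBL = sbl, SBD = 4)
  }))
  dsh <- toy_dataset()
  dsh$secondaries <- hom
  dsh$primaries <- data.frame(tree_id = 1, branch_id = hom$branch_id,
                              PAGE = hom$PAGE, PBL = hom$PBL, PBD = 25,
                              PBC = hom$PBL * 0.95, PAZ = 0, PVA = 60,
                              PDINC = 400)
  dsh$secondaries$SDINC <- pmin(dsh$secondaries$SDINC, dsh$secondaries$PBL)
  prof <- scaling_profile(dsh, "PAGE", "length", B = 300, seed = 3)
  expect_equal(prof$exponent, rep(0.8, 4), tolerance = 0.1)
  expect_lt(max(prof$ci_low), min(prof$ci_high))
  # constructed truth: exponent rises across secondary-branch ages
  set.seed(11)
  secs <- do.call(rbind, lapply(1:3, function(ag) {
    n <- 120
    x <- runif(n, 2, 40)
    data.frame(tree_id = 1, branch_id = ag, whorl_id = seq_len(n),
               obs_id = 1, SAGE = ag, SDINC = x^(0.4 + 0.25 * ag) *
                 exp(rnorm(n, 0, 0.08)),
               PAGE = 10, PBL = 600, PBD = 30, PDINC = 500,
               SBL = x, SBD = 3)
  }))
  ds2 <- toy_dataset()
  ds2$secondaries <- secs
  ds2$primaries <- data.frame(tree_id = 1, branch_id = 1:3, PAGE = 10,
                              PBL = 600, PBD = 30, PBC = 580, PAZ = 0,
                              PVA = 60, PDINC = 500)
  prof2 <- scaling_profile(ds2, "SAGE", "length", B = 100, seed = 4)
  expect_equal(prof2$exponent, sort(prof2$exponent))
  expect_equal(prof2$exponent, 0.4 + 0.25 * (1:3), tolerance = 0.1)
  # a single group reduces to fit_loglog + bootstrap_ci
  ds3 <- ds2
  ds3$secondaries <- secs[secs$SAGE == 2, ]
  p3 <- scaling_profile(ds3, "SAGE", "length", B = 60, seed = 6)
  ref <- bootstrap_ci(ds3$secondaries$SBL, ds3$secondaries$SDINC,
                      B = 60, seed = 6 + 1)
  expect_equal(p3$exponent, ref$exponent, tolerance = 1e-12)
  expect_equal(c(p3$ci_low, p3$ci_high), ref$ci_exponent, tolerance = 1e-12)
})
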