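# The nine candidate growth curves, their gradients and peak positions.

test_that("M7 evaluation matches an independently computed value and limits", {
  # 0.364 * 100^0.928 * exp(-0.2) computed with an independent scalar oracle
  expect_equal(gf_evaluate("M7", 100, a = 0.364, b = 0.928, c = 0.002),
               21.39156148757549, tolerance = 1e-10)
  expect_equal(gf_evaluate("M7", 1e-12, a = 2, b = 0.9, c = 0.002), 0,
               tolerance = 1e-9)
  # logistic saturates at a; M6 passes through the origin
  expect_equal(gf_evaluate("M3", 1e7, a = 30, b = 5, c = 0.01), 30)
  expect_equal(gf_evaluate("M6", 0, a = 30, b = 0.01), 0)
})

test_that("analytic gradients match central finite differences", {
  # admissible draws per function: b and c act as rates, exponents or
  # offsets depending on the curve, at the magnitudes seen in branch data
  draw_params <- function(fid) switch(fid,
    M1 = c(a = runif(1, 5, 40), b = runif(1, 0.005, 0.05),
           c = runif(1, 0.5, 2)),
    M2 = {                             # keep b * 400^c in the working range
      cc <- runif(1, 0.5, 1.3)
      c(a = runif(1, 5, 40), b = runif(1, 1, 6) / 400^cc, c = cc)
    },
    M3 = c(a = runif(1, 5, 40), b = runif(1, 1, 10),
           c = runif(1, 0.005, 0.05)),
    M4 = c(a = runif(1, 5, 40), b = runif(1, 5, 60),
           c = runif(1, 0.5, 1.5)),
    M5 = c(a = runif(1, 5, 40), b = runif(1, 5, 60), c = NA),
    M6 = c(a = runif(1, 5, 40), b = runif(1, 0.005, 0.05), c = NA),
    M7 = c(a = runif(1, 0.1, 3), b = runif(1, 0.3, 1.2),
           c = runif(1, 0.001, 0.01)),
    M8 = c(a = runif(1, 5, 40), b = runif(1, 2, 20),
           c = runif(1, 0.4, 1.5)),
    M9 = c(a = runif(1, 5, 40), b = runif(1, 1, 8),
           c = runif(1, 0.005, 0.05)))
  set.seed(42)
  for (fid in gf_ids()) {
    for (rep in 1:5) {
      th <- draw_params(fid)
      x <- runif(4, 10, 400)
      g <- gf_gradient(fid, x, th["a"], th["b"], th["c"])
      for (p in colnames(g)) {
        h <- max(abs(th[p]) * 1e-4, 1e-7)  # proportional step: keeps both
                                           # truncation and round-off small
        up <- dn <- th
        up[p] <- th[p] + h; dn[p] <- th[p] - h
        fd <- (gf_evaluate(fid, x, up["a"], up["b"], up["c"]) -
               gf_evaluate(fid, x, dn["a"], dn["b"], dn["c"])) / (2 * h)
        # error measured against the column scale, as for any numeric
        # Jacobian check (tiny entries sit at FD cancellation level)
        expect_lt(max(abs(g[, p] - fd)) / (max(abs(fd)) + 1e-8), 1e-6,
                  label = paste(fid, "d/d", p))
      }
    }
  }
})

test_that("interior maximum is b/c for M7 and absent for monotone curves", {
  expect_equal(gf_interior_maximum("M7", a = 0.197, b = 0.989, c = 0.003),
               329.6666667, tolerance = 1e-6)
  expect_true(is.na(gf_interior_maximum("M6", a = 1, b = 0.1)))
  expect_true(is.na(gf_interior_maximum("M3", a = 1, b = 2, c = 0.1)))
  expect_true(is.na(gf_interior_maximum("M7", a = 1, b = 0.9, c = 0)))
})

test_that("predictions scale linearly in a, and M1 with c = 1 equals M6", {
  x <- seq(5, 500, length.out = 40)
  for (fid in gf_ids()) {
    y1 <- gf_evaluate(fid, x, a = 2, b = 0.5, c = 0.4)
    y3 <- gf_evaluate(fid, x, a = 6, b = 0.5, c = 0.4)
    expect_equal(y3, 3 * y1, tolerance = 1e-12, label = fid)
  }
  expect_equal(gf_evaluate("M1", x, a = 7, b = 0.02, c = 1),
               gf_evaluate("M6", x, a = 7, b = 0.02), tolerance = 1e-12)
})

test_that("covariate expansion evaluates and differentiates by the chain rule", {
  d <- m7_table(50, seed = 3)
  spec <- model_spec("M7", c(a = "PDINC"))
  th <- c(a = 0.2, b = 0.95, c = 0.003, a1 = 3e-4)
  mu <- spec_evaluate(spec, th, d)
  byhand <- (th["a"] + th["a1"] * d$PDINC) * d$SDINC^th["b"] *
    exp(-th["c"] * d$SDINC)
  expect_equal(mu, unname(byhand), tolerance = 1e-12)
  g <- spec_gradient(spec, th, d)
  expect_identical(colnames(g), c("a", "b", "c", "a1"))
  for (p in colnames(g)) {
    h <- max(abs(th[p]), 1e-3) * 1e-6
    up <- dn <- th
    up[p] <- th[p] + h; dn[p] <- th[p] - h
    fd <- (spec_evaluate(spec, up, d) - spec_evaluate(spec, dn, d)) / (2 * h)
    expect_equal(unname(g[, p]), fd, tolerance = 1e-5, label = p)
  }
  expect_error(model_spec("M7", c(q = "PDINC")), "base parameters")
  expect_error(gf_evaluate("M42", 1, 1, 1, 1))
  expect_error(gf_evaluate("M5", 0, 1, 1), "undefined")
})
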