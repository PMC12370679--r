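# Fixture builders shared across the test files. Everything is generated in
# code at test time; no data files are read.

# flat modelling table from the unimodal M7 law (optionally covariate-
# expanded), with iid Gaussian noise
m7_table <- function(n = 200, a = 0.364, b = 0.928, c = 0.002,
                     a1 = 0, b1 = 0, sd = 0, seed = 1,
                     sdinc_range = c(5, 600)) {
  set.seed(seed)
  d <- data.frame(
    SDINC = runif(n, sdinc_range[1], sdinc_range[2]),
    PDINC = runif(n, 50, 1500),
    PBD = runif(n, 5, 70),
    branch_id = rep(seq_len(max(1, n %/% 20)), length.out = n),
    whorl_id = rep(1:4, length.out = n))
  mu <- (a + a1 * d$PDINC) * d$SDINC^(b + b1 * d$PBD) * exp(-c * d$SDINC)
  d$SBL <- mu + rnorm(n, 0, sd)
  d$SBD <- d$SBL
  d
}

# hand-built three-level dataset with known group structure (for summaries
# and allometry fixtures)
toy_dataset <- function() {
  trees <- data.frame(tree_id = 1:2, age = c(28, 40),
                      DBH = c(20, 30), HT = c(15, 18), CW = c(2, 2.5),
                      HBLC = c(7, 8), CL = c(8, 10), CR = c(8/15, 10/18),
                      HD = c(0.75, 0.6))
  primaries <- data.frame(tree_id = c(1, 1, 2), branch_id = 1:3,
                          PAGE = c(4, 6, 5), PBL = c(200, 300, 250),
                          PBD = c(20, 30, 25), PBC = c(190, 280, 240),
                          PAZ = c(10, 100, 200), PVA = c(55, 60, 65),
                          PDINC = c(300, 500, 400))
  secondaries <- data.frame(
    tree_id = c(1, 1, 1, 1, 2, 2),
    branch_id = c(1, 1, 2, 2, 3, 3),
    whorl_id = c(1, 2, 1, 2, 1, 2),
    obs_id = 1,
    SAGE = c(1, 2, 1, 2, 1, 2),
    SDINC = c(50, 150, 60, 200, 55, 180),
    PAGE = c(4, 4, 6, 6, 5, 5),
    PBL = c(200, 200, 300, 300, 250, 250),
    PBD = c(20, 20, 30, 30, 25, 25),
    PDINC = c(300, 300, 500, 500, 400, 400),
    SBL = c(10, 20, 12, 26, 11, 23),
    SBD = c(3, 5, 3.5, 6, 3.2, 5.5))
  structure(list(trees = trees, primaries = primaries,
                 secondaries = secondaries, truth = NULL,
                 rejection_rate = NA_real_, config = NULL),
            class = "branch_dataset")
}

# adaptive Gauss-Hermite marginal log-likelihood for a single-level model
# with one scalar random effect: independent oracle for the Laplace
# approximation (quadrature recentred at the mode, rescaled by the
# mode Hessian)
agq_loglik <- function(data, groups, meanfun, beta, re_par, d1, sigma2,
                       nodes = 41) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (g in unique(groups)) {
    rows <- which(groups == g)
    nlpost <- function(u) {
      mu <- meanfun(data[rows, , drop = FALSE], beta, u)
      sum((data$y[rows] - mu)^2) / (2 * sigma2) + u^2 / (2 * d1)
    }
    opt <- optimize(nlpost, c(-50, 50) * sqrt(d1))
    uhat <- opt$minimum
    h <- (nlpost(uhat + 1e-4) - 2 * nlpost(uhat) + nlpost(uhat - 1e-4)) / 1e-8
    s <- 1 / sqrt(max(h, 1e-12))
    lw <- vapply(seq_len(nodes), function(k) {
      u <- uhat + sqrt(2) * s * gh$x[k]
      -nlpost(u) + gh$x[k]^2
    }, numeric(1))
    m <- max(lw)
    integral <- sqrt(2) * s * sum(gh$w * exp(lw - m)) * exp(m)
    ni <- length(rows)
    total <- total + log(integral) -
      ni / 2 * log(2 * pi * sigma2) - 0.5 * log(2 * pi * d1)
  }
  total
}
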