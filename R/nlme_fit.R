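# Two-level nonlinear mixed-effects estimation for secondary branch models.
#
# The model is y_ijk = f(phi_ijk, SDINC_ijk) + e_ijk with f one of the
# candidate growth functions (optionally covariate-expanded), parameter
# perturbations b_i ~ N(0, D1) at the primary-branch level and
# b_ij ~ N(0, D2) at the whorl-within-branch level, and residuals
# e_ijk ~ N(0, R_ij), R_ij = sigma^2 G^1/2 Gamma G^1/2.
#
# Estimation is maximum likelihood by the Lindstrom-Bates alternating
# algorithm: a penalized nonlinear least-squares step for the fixed effects
# and the random-effect modes, then a profiled ML linear mixed-model step on
# the working (linearized) response for the variance components. The
# reported likelihood is the Laplace approximation evaluated at the modes.

#' Random-effects specification
#'
#' Which free parameters of the model receive primary-branch (level-1)
#' and whorl-within-branch (level-2) random perturbations. The final branch
#' length model uses `level1 = c("b", "c")`, `level2 = "b"`; the diameter
#' model uses `level1 = c("b", "c")`, `level2 = "b1"`.
#'
#' More than four random parameters in total is allowed but flagged with a
#' warning: such models are prone to non-convergence at typical crown-data
#' sizes.
#'
#' @param level1,level2 character vectors of free parameter names.
#' @export
re_spec <- function(level1 = character(), level2 = character()) {
  if (length(level1) + length(level2) > 4)
    warning("more than 4 random-effect parameters; convergence is unlikely")
  structure(list(level1 = level1, level2 = level2), class = "re_spec")
}

#' Within-group variance and correlation structure
#'
#' The residual covariance of the observations within one secondary-branch
#' whorl is `sigma^2 G^1/2 Gamma G^1/2`: `G` describes heteroscedasticity
#' (constant, a power of the fitted size, or an exponential of it) and
#' `Gamma` the serial correlation along the whorl (independent, AR(1),
#' MA(1), or ARMA(1,1)). The default -- constant variance, independent
#' errors -- is the structure under which the headline models are fitted;
#' the richer structures are available for sensitivity analysis.
#'
#' @param variance one of `"constant"`, `"power"`, `"exponential"`.
#' @param correlation one of `"independent"`, `"AR1"`, `"MA1"`, `"ARMA11"`.
#' @export
var_spec <- function(variance = c("constant", "power", "exponential"),
                     correlation = c("independent", "AR1", "MA1", "ARMA11")) {
  structure(list(variance = match.arg(variance),
                 correlation = match.arg(correlation)), class = "var_spec")
}

n_var_pars <- function(vs)
  (vs$variance != "constant") + switch(vs$correlation,
    independent = 0L, AR1 = 1L, MA1 = 1L, ARMA11 = 2L)

# standard-deviation multipliers g_k from the variance function
var_weights <- function(vs, delta, mu) {
  switch(vs$variance,
    constant = rep(1, length(mu)),
    power = pmax(abs(mu), 1e-4)^delta,
    exponential = exp(pmin(delta * mu, 30)))
}

# within-whorl correlation matrix
corr_matrix <- function(vs, cpar, n) {
  if (n == 1 || vs$correlation == "independent") return(diag(n))
  h <- abs(outer(seq_len(n), seq_len(n), "-"))
  switch(vs$correlation,
    AR1 = tanh(cpar[1])^h,
    MA1 = {
      th <- tanh(cpar[1])
      r1 <- th / (1 + th^2)
      m <- diag(n); m[h == 1] <- r1; m
    },
    ARMA11 = {
      ph <- tanh(cpar[1]); th <- tanh(cpar[2])
      r1 <- (1 + ph * th) * (ph + th) / (1 + 2 * ph * th + th^2)
      m <- ifelse(h == 0, 1, r1 * ph^pmax(h - 1, 0)); m
    })
}

# log-Cholesky: parameter vector <-> SPD matrix (diagonal stored on log scale)
lc_build <- function(phi, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- phi
  diag(L) <- exp(pmin(diag(L), 20))
  L %*% t(L)
}
lc_init <- function(S) {
  q <- nrow(S)
  L <- t(chol(S + diag(1e-12, q)))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}
lc_len <- function(q) q * (q + 1L) / 2L

# sorted per-group index structures for a modelling table
nlme_prepare <- function(spec, re_spec, data, response) {
  if (is.null(data$branch_id) || is.null(data$whorl_id))
    stop("data must carry branch_id and whorl_id grouping columns")
  ord <- order(data$branch_id, data$whorl_id)
  d <- data[ord, , drop = FALSE]
  bfac <- factor(d$branch_id, levels = unique(d$branch_id))
  wfac <- factor(paste(d$branch_id, d$whorl_id, sep = "."),
                 levels = unique(paste(d$branch_id, d$whorl_id, sep = ".")))
  bidx <- split(seq_len(nrow(d)), bfac)
  widx <- split(seq_len(nrow(d)), wfac)
  wrow1 <- vapply(widx, `[`, integer(1), 1L)
  roww <- as.integer(wfac)
  q1 <- length(re_spec$level1); q2 <- length(re_spec$level2)
  # static per-branch layout: rows, global whorl ids, within-branch whorl
  # index of each row, and the stacked random-effect dimension
  blay <- lapply(bidx, function(rows) {
    wh <- unique(roww[rows])
    list(rows = rows, wh = wh, wloc = match(roww[rows], wh),
         M = length(wh), d = q1 + length(wh) * q2)
  })
  list(spec = spec, re = re_spec, data = d, ord = ord,
       y = d[[response]], response = response,
       n = nrow(d), nb = length(bidx), nw = length(widx),
       bidx = bidx, widx = widx, blay = blay,
       wb = as.integer(bfac)[wrow1],              # branch of each whorl
       rowb = as.integer(bfac), roww = roww,
       q1 = q1, q2 = q2,
       pn = spec_param_names(spec))
}

# row-wise parameter offsets implied by the current random-effect values
re_offsets <- function(prep, u1, u2) {
  offs <- matrix(0, prep$n, length(prep$pn), dimnames = list(NULL, prep$pn))
  if (prep$q1) for (k in seq_len(prep$q1))
    offs[, prep$re$level1[k]] <- offs[, prep$re$level1[k]] + u1[prep$rowb, k]
  if (prep$q2) for (k in seq_len(prep$q2))
    offs[, prep$re$level2[k]] <- offs[, prep$re$level2[k]] + u2[prep$roww, k]
  offs
}

# whitening transforms per whorl (list or NULL for the identity default)
whiten_blocks <- function(prep, vspec, vpar, cpar, mu) {
  if (vspec$variance == "constant" && vspec$correlation == "independent")
    return(NULL)
  g <- var_weights(vspec, vpar, mu)
  lapply(prep$widx, function(rows) {
    n <- length(rows)
    R0 <- outer(g[rows], g[rows]) * corr_matrix(vspec, cpar, n)
    ch <- chol(R0)
    list(rows = rows, Tm = backsolve(ch, diag(n), transpose = TRUE),
         logdet = 2 * sum(log(diag(ch))))
  })
}

apply_whiten <- function(blocks, v) {
  if (is.null(blocks)) return(v)
  v <- as.matrix(v)
  for (b in blocks) v[b$rows, ] <- b$Tm %*% v[b$rows, , drop = FALSE]
  v
}

# stacked random-effect design for branch i from full-data gradient rows:
# columns (level-1 effects | whorl-1 level-2 effects | whorl-2 ... )
build_Zu <- function(prep, lay, Gw) {
  Zu <- matrix(0, length(lay$rows), lay$d)
  if (prep$q1)
    Zu[, seq_len(prep$q1)] <- Gw[lay$rows, prep$re$level1, drop = FALSE]
  if (prep$q2) {
    Z2 <- Gw[lay$rows, prep$re$level2, drop = FALSE]
    for (k in seq_len(prep$q2))
      Zu[cbind(seq_along(lay$rows),
               prep$q1 + (lay$wloc - 1) * prep$q2 + k)] <- Z2[, k]
  }
  Zu
}

# blockdiag precision of (b_i, b_i1, ..., b_iM) and stacked current values
psi_inv_u <- function(prep, lay, D1inv, D2inv, u1i, u2, ridge = 0) {
  Pinv <- matrix(0, lay$d, lay$d)
  ui <- numeric(lay$d)
  if (prep$q1) {
    Pinv[seq_len(prep$q1), seq_len(prep$q1)] <- D1inv
    ui[seq_len(prep$q1)] <- u1i
  }
  if (prep$q2) for (jj in seq_len(lay$M)) {
    kk <- prep$q1 + (jj - 1) * prep$q2 + seq_len(prep$q2)
    Pinv[kk, kk] <- D2inv
    ui[kk] <- u2[lay$wh[jj], ]
  }
  list(Pinv = Pinv, ui = ui)
}

# penalized Gauss-Newton update of all random-effect modes (global
# step-halving on the penalized objective); beta fixed.
update_modes <- function(prep, beta, u1, u2, D1inv, D2inv, sigma2,
                         blocks = NULL, sweeps = 10, tol = 1e-9) {
  pen <- function(u1, u2) {
    offs <- re_offsets(prep, u1, u2)
    r <- prep$y - spec_evaluate(prep$spec, beta, prep$data, offs)
    rw <- apply_whiten(blocks, r)
    p <- sum(rw^2) / sigma2
    if (prep$q1) p <- p + sum((u1 %*% D1inv) * u1)
    if (prep$q2) p <- p + sum((u2 %*% D2inv) * u2)
    p
  }
  obj <- pen(u1, u2)
  for (s in seq_len(sweeps)) {
    offs <- re_offsets(prep, u1, u2)
    mu <- spec_evaluate(prep$spec, beta, prep$data, offs)
    G <- spec_gradient(prep$spec, beta, prep$data, offs)
    r <- prep$y - mu
    rw <- apply_whiten(blocks, r)
    Gw <- apply_whiten(blocks, G)
    d1 <- matrix(0, prep$nb, max(prep$q1, 1))
    d2 <- matrix(0, prep$nw, max(prep$q2, 1))
    for (i in seq_len(prep$nb)) {
      lay <- prep$blay[[i]]
      Zu <- build_Zu(prep, lay, Gw)
      pu <- psi_inv_u(prep, lay, D1inv, D2inv, if (prep$q1) u1[i, ], u2)
      H <- crossprod(Zu) / sigma2 + pu$Pinv
      rhs <- crossprod(Zu, rw[lay$rows]) / sigma2 - pu$Pinv %*% pu$ui
      step <- tryCatch(solve(H, rhs), error = function(e)
        tryCatch(solve(H + diag(1e-8 * (mean(diag(H)) + 1), lay$d), rhs),
                 error = function(e2) rhs * 0))
      if (prep$q1) d1[i, ] <- step[seq_len(prep$q1)]
      if (prep$q2) for (jj in seq_len(lay$M))
        d2[lay$wh[jj], ] <-
          step[prep$q1 + (jj - 1) * prep$q2 + seq_len(prep$q2)]
    }
    lam <- 1
    repeat {
      n1 <- u1 + lam * d1[, seq_len(max(prep$q1, 1)), drop = FALSE]
      n2 <- u2 + lam * d2[, seq_len(max(prep$q2, 1)), drop = FALSE]
      newobj <- pen(n1, n2)
      if ((is.finite(newobj) && newobj <= obj + 1e-12) || lam < 1e-4) break
      lam <- lam / 2
    }
    done <- is.finite(newobj) && abs(obj - newobj) < tol * (abs(obj) + 1)
    if (is.finite(newobj) && newobj <= obj) { u1 <- n1; u2 <- n2; obj <- newobj }
    if (done) break
  }
  list(u1 = u1, u2 = u2, penalized = obj)
}

# profiled ML objective of the two-level linear mixed model on the working
# response: phi holds log-Cholesky factors of D1/sigma^2 and D2/sigma^2 plus
# any variance-function / correlation parameters. beta and sigma^2 are
# profiled out in closed form. Returns -2 logLik with the profiled
# quantities as attributes.
#
# For the default structure (constant variance, independent errors) the
# group contributions use the Woodbury identity on per-branch sufficient
# statistics [Zu'Zu, Zu'X, Zu'w], precomputed once per linearization, so a
# phi evaluation touches only d_i x d_i matrices.
lmm_suffstats <- function(prep, X, w, Z1, Z2) {
  Gw <- matrix(0, prep$n, prep$q1 + prep$q2)
  if (prep$q1) Gw[, seq_len(prep$q1)] <- Z1
  if (prep$q2) Gw[, prep$q1 + seq_len(prep$q2)] <- Z2
  colnames(Gw) <- c(prep$re$level1, prep$re$level2)
  per <- lapply(seq_len(prep$nb), function(i) {
    lay <- prep$blay[[i]]
    Zu <- build_Zu(prep, lay, Gw)
    ii <- if (prep$q2 == 1L && lay$d > prep$q1) (prep$q1 + 1L):lay$d
    list(ZtZXw = cbind(crossprod(Zu),
                       crossprod(Zu, X[lay$rows, , drop = FALSE]),
                       crossprod(Zu, w[lay$rows])),
         diag2 = if (!is.null(ii)) cbind(ii, ii),
         M = lay$M, d = lay$d)
  })
  list(per = per, XtX0 = crossprod(X), Xtw0 = crossprod(X, w)[, 1],
       wtw0 = sum(w^2))
}

lmm_profile <- function(phi, prep, X, w, Z1, Z2, mu_vc, vspec, ss = NULL) {
  q1 <- prep$q1; q2 <- prep$q2
  i1 <- seq_len(lc_len(q1))
  i2 <- lc_len(q1) + seq_len(lc_len(q2))
  nv <- (vspec$variance != "constant")
  D1r <- if (q1) lc_build(phi[i1], q1) else matrix(0, 0, 0)
  D2r <- if (q2) lc_build(phi[i2], q2) else matrix(0, 0, 0)
  extra <- if (length(phi) > lc_len(q1) + lc_len(q2))
    phi[-c(i1, i2)] else numeric(0)
  vpar <- if (nv) extra[1] else 0
  cpar <- if (nv) extra[-1] else extra
  ident <- vspec$variance == "constant" && vspec$correlation == "independent"
  p <- ncol(X)
  XtX <- matrix(0, p, p); Xtw <- numeric(p)
  wtw <- 0; logdet <- 0
  ok <- TRUE
  if (ident && !is.null(ss)) {
    D1i <- if (q1) tryCatch(solve(D1r), error = function(e) NULL)
    D2i <- if (q2) tryCatch(solve(D2r), error = function(e) NULL)
    if ((q1 && is.null(D1i)) || (q2 && is.null(D2i)))
      return(structure(1e10, bad = TRUE))
    ld1 <- if (q1) as.numeric(determinant(D1r)$modulus) else 0
    ld2 <- if (q2) as.numeric(determinant(D2r)$modulus) else 0
    XtX <- ss$XtX0; Xtw <- ss$Xtw0; wtw <- ss$wtw0
    iq1 <- seq_len(q1)
    err <- tryCatch({
      for (pc in ss$per) {
        H <- pc$ZtZXw            # [ZtZ | ZtX | Ztw] copy; add precision blocks
        if (q1) H[iq1, iq1] <- H[iq1, iq1] + D1i
        if (q2 == 1L && pc$M)
          H[pc$diag2] <- H[pc$diag2] + D2i[1L, 1L]
        else if (q2) for (jj in seq_len(pc$M)) {
          kk <- q1 + (jj - 1L) * q2 + seq_len(q2)
          H[kk, kk] <- H[kk, kk] + D2i
        }
        ch <- chol.default(H[, seq_len(pc$d), drop = FALSE])
        logdet <- logdet + 2 * sum(log(diag(ch))) + ld1 + pc$M * ld2
        A <- backsolve(ch, H[, -seq_len(pc$d), drop = FALSE],
                       transpose = TRUE)
        XtX <- XtX - crossprod(A[, seq_len(p), drop = FALSE])
        Xtw <- Xtw - crossprod(A[, seq_len(p), drop = FALSE], A[, p + 1])[, 1]
        wtw <- wtw - sum(A[, p + 1]^2)
      }
      NULL
    }, error = function(e) e)
    if (!is.null(err)) ok <- FALSE
  } else {
    g <- if (ident) NULL else var_weights(vspec, vpar, mu_vc)
    for (i in seq_len(prep$nb)) {
      lay <- prep$blay[[i]]
      rows <- lay$rows
      ni <- length(rows)
      C <- matrix(0, ni, ni)
      if (ident) diag(C) <- 1
      else for (jj in seq_len(lay$M)) {
        sel <- which(lay$wloc == jj)
        C[sel, sel] <- outer(g[rows[sel]], g[rows[sel]]) *
          corr_matrix(vspec, cpar, length(sel))
      }
      if (q1) {
        Zi <- Z1[rows, , drop = FALSE]
        C <- C + Zi %*% D1r %*% t(Zi)
      }
      if (q2) for (jj in seq_len(lay$M)) {
        sel <- which(lay$wloc == jj)
        Zj <- Z2[rows[sel], , drop = FALSE]
        C[sel, sel] <- C[sel, sel] + Zj %*% D2r %*% t(Zj)
      }
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch)) { ok <- FALSE; break }
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, X[rows, , drop = FALSE], transpose = TRUE)
      wi <- backsolve(ch, w[rows], transpose = TRUE)
      XtX <- XtX + crossprod(Xi)
      Xtw <- Xtw + crossprod(Xi, wi)[, 1]
      wtw <- wtw + sum(wi^2)
    }
  }
  if (!ok) return(structure(1e10, bad = TRUE))
  bet <- tryCatch(solve(XtX, Xtw), error = function(e) NULL)
  if (is.null(bet)) return(structure(1e10, bad = TRUE))
  quad <- wtw - sum(bet * Xtw)
  if (!is.finite(quad) || quad <= 0) return(structure(1e10, bad = TRUE))
  sigma2 <- quad / prep$n
  m2ll <- prep$n * log(2 * pi * sigma2) + logdet + prep$n
  structure(m2ll, beta = bet, sigma2 = sigma2, XtX = XtX,
            D1r = D1r, D2r = D2r, vpar = vpar, cpar = cpar)
}

#' Fit a two-level nonlinear mixed-effects branch model
#'
#' Maximum-likelihood estimation by the Lindstrom-Bates alternating
#' algorithm. Each outer iteration (i) solves a penalized nonlinear
#' least-squares problem for the random-effect modes, (ii) linearizes the
#' model at the current estimates, and (iii) maximizes the profiled ML
#' likelihood of the resulting two-level linear mixed model over the
#' variance components (log-Cholesky parameterized, so `D1` and `D2` stay
#' positive semidefinite). Iteration stops when the relative change of the
#' working log-likelihood is below `tol` or after `max_outer` iterations;
#' the result records which condition triggered. The reported
#' log-likelihood is the Laplace approximation at the final modes.
#'
#' @param spec a [model_spec()].
#' @param data modelling table with `branch_id`, `whorl_id`, `SDINC`, the
#'   response, and any mapped covariates.
#' @param response response column (`"SBL"` or `"SBD"`).
#' @param re a [re_spec()]; empty levels reduce the fit to plain NLS.
#' @param vs a [var_spec()]; the default is constant variance with
#'   independent within-whorl errors.
#' @param init optional named fixed-effect starting values; defaults to the
#'   NLS fit of `spec`.
#' @param nls_fit optional precomputed `branch_nls` fit of the same `spec`
#'   on the same data, reused for starting values (the search over
#'   random-effects placements shares one).
#' @param max_outer,tol outer-loop control.
#' @param restarts probe extra diagonal restarts of the variance parameters
#'   over the first two outer iterations (guards against local optima of
#'   the profiled surface; the placement search disables it for speed,
#'   where only the AIC ranking matters).
#' @return an object of class `branch_nlme`: fixed effects with Wald
#'   standard errors and p-values, `D1`, `D2` (plus their
#'   variance/correlation presentation), `sigma2`, Laplace `logLik`, `AIC`,
#'   EBLUPs at both levels, conditional fit indices (`MAE`, `RMSE`, `Ra2`),
#'   and convergence diagnostics.
#' @export
fit_nlme <- function(spec, data, response = "SBL",
                     re = re_spec(), vs = var_spec(),
                     init = NULL, nls_fit = NULL, max_outer = 200,
                     tol = 1e-8, restarts = TRUE) {
  stopifnot(inherits(re, "re_spec"), inherits(vs, "var_spec"))
  bad <- setdiff(c(re$level1, re$level2), spec_param_names(spec))
  if (length(bad))
    stop("random-effect parameters not in the model: ",
         paste(bad, collapse = ", "))
  nlsfit <- if (!is.null(nls_fit)) nls_fit
    else fit_nls(spec, data, response,
                 init = if (!is.null(init)) init[spec_param_names(spec)])
  if (length(re$level1) + length(re$level2) == 0)
    return(nlme_from_nls(nlsfit, re, vs))
  prep <- nlme_prepare(spec, re, data, response)
  pn <- prep$pn
  beta <- nlsfit$estimates
  if (!is.null(init)) beta[names(init)] <- init
  sigma2 <- max(nlsfit$RSS / nlsfit$n, 1e-10)
  q1 <- prep$q1; q2 <- prep$q2
  # moment starts for the relative covariances from a loose-prior mode pass
  u1 <- matrix(0, prep$nb, max(q1, 1)); u2 <- matrix(0, prep$nw, max(q2, 1))
  sc1 <- if (q1) abs(beta[re$level1]) * 0.2 + 1e-4
  sc2 <- if (q2) abs(beta[re$level2]) * 0.2 + 1e-4
  md <- update_modes(prep, beta, u1, u2,
                     if (q1) diag(1 / sc1^2, q1) else NULL,
                     if (q2) diag(1 / sc2^2, q2) else NULL,
                     sigma2, sweeps = 3)
  D1 <- if (q1) stats::cov(md$u1) + diag(1e-6 * sc1^2, q1)
  D2 <- if (q2) stats::cov(md$u2) + diag(1e-6 * sc2^2, q2)
  u1 <- md$u1; u2 <- md$u2
  phi <- c(if (q1) lc_init(D1 / sigma2),
           if (q2) lc_init(D2 / sigma2),
           rep(0, n_var_pars(vs)))
  vpar <- 0; cpar <- numeric(0)
  ll_work <- -Inf; conv <- FALSE; reason <- "max_outer"
  it <- 0L; ridge_restarts <- 0L
  while (it < max_outer) {
    it <- it + 1L
    D1inv <- if (q1) tryCatch(solve(D1), error = function(e) NULL)
    D2inv <- if (q2) tryCatch(solve(D2), error = function(e) NULL)
    if ((q1 && is.null(D1inv)) || (q2 && is.null(D2inv))) {
      # singular covariance estimate: ridge and restart once
      if (q1) { D1 <- D1 + diag(1e-8 + 1e-6 * mean(diag(D1)), q1)
                D1inv <- solve(D1) }
      if (q2) { D2 <- D2 + diag(1e-8 + 1e-6 * mean(diag(D2)), q2)
                D2inv <- solve(D2) }
      ridge_restarts <- ridge_restarts + 1L
    }
    offs <- re_offsets(prep, u1, u2)
    mu_c <- spec_evaluate(prep$spec, beta, prep$data, offs)
    blocks <- whiten_blocks(prep, vs, vpar, cpar, mu_c)
    md <- update_modes(prep, beta, u1, u2, D1inv, D2inv, sigma2, blocks)
    u1 <- md$u1; u2 <- md$u2
    # linearize at (beta, modes)
    offs <- re_offsets(prep, u1, u2)
    mu <- spec_evaluate(prep$spec, beta, prep$data, offs)
    Gr <- spec_gradient(prep$spec, beta, prep$data, offs)
    X <- Gr[, pn, drop = FALSE]
    Z1 <- if (q1) Gr[, re$level1, drop = FALSE]
    Z2 <- if (q2) Gr[, re$level2, drop = FALSE]
    w <- prep$y - mu + as.vector(X %*% beta)
    if (q1) w <- w + rowSums(Z1 * u1[prep$rowb, , drop = FALSE])
    if (q2) w <- w + rowSums(Z2 * u2[prep$roww, , drop = FALSE])
    ss <- if (vs$variance == "constant" && vs$correlation == "independent")
      lmm_suffstats(prep, X, w, Z1, Z2)
    obj <- function(ph)
      as.numeric(lmm_profile(ph, prep, X, w, Z1, Z2, mu, vs, ss))
    # variance-function / correlation parameters live on transformed scales
    # where |4| is already extreme; log-Cholesky entries get a wide box
    nlc <- lc_len(q1) + lc_len(q2)
    lo <- c(rep(-16, nlc), rep(-4, length(phi) - nlc))
    hi <- -lo
    run <- function(ph0) stats::nlminb(ph0, obj, lower = lo, upper = hi,
      control = list(iter.max = if (it <= 2) 100 else 40, rel.tol = 1e-12))
    op <- run(phi)
    if (it <= (if (restarts) 2 else 1)) {
      # the profiled variance surface can hold local optima (strongly
      # negative level-1 correlations trading off against sigma^2); probe a
      # few diagonal restarts and keep the best
      alt <- list()
      ph <- phi
      offd <- setdiff(seq_len(lc_len(q1)), cumsum(seq(q1, 1)) - seq(q1, 1) + 1)
      diag1 <- setdiff(seq_len(lc_len(q1)), offd)
      ph[offd] <- 0
      alt <- c(alt, list(ph))
      for (s in c(-2, 2)) {
        ph2 <- ph; ph2[diag1] <- ph2[diag1] + s
        alt <- c(alt, list(ph2))
      }
      for (cand in alt) {
        op2 <- run(cand)
        if (op2$objective < op$objective - 1e-10) op <- op2
      }
    }
    phi <- op$par
    prof <- lmm_profile(phi, prep, X, w, Z1, Z2, mu, vs, ss)
    if (is.null(attr(prof, "beta"))) {            # degenerate profile point
      conv <- FALSE; reason <- "profile step failed"; break
    }
    beta_new <- attr(prof, "beta"); names(beta_new) <- pn
    sigma2 <- attr(prof, "sigma2")
    if (q1) D1 <- attr(prof, "D1r") * sigma2
    if (q2) D2 <- attr(prof, "D2r") * sigma2
    vpar <- attr(prof, "vpar"); cpar <- attr(prof, "cpar")
    ll_new <- -as.numeric(prof) / 2
    dbeta <- max(abs(beta_new - beta) / (abs(beta) + 1e-8))
    if (all(is.finite(beta_new))) beta <- beta_new
    if (is.finite(ll_work) &&
        abs(ll_new - ll_work) < tol * (abs(ll_work) + 1) && dbeta < 1e-6) {
      ll_work <- ll_new; conv <- TRUE; reason <- "loglik change"; break
    }
    ll_work <- ll_new
  }
  # final modes and Laplace likelihood at the converged estimates
  D1inv <- if (q1) solve(D1 + diag(1e-12, q1))
  D2inv <- if (q2) solve(D2 + diag(1e-12, q2))
  offs <- re_offsets(prep, u1, u2)
  mu_c <- spec_evaluate(prep$spec, beta, prep$data, offs)
  blocks <- whiten_blocks(prep, vs, vpar, cpar, mu_c)
  md <- update_modes(prep, beta, u1, u2, D1inv, D2inv, sigma2, blocks,
                     sweeps = 20)
  u1 <- md$u1; u2 <- md$u2
  lap <- laplace_loglik(prep, beta, u1, u2, D1, D2, sigma2, vs, vpar, cpar)
  offs <- re_offsets(prep, u1, u2)
  fitted_c <- spec_evaluate(prep$spec, beta, prep$data, offs)
  resid_c <- prep$y - fitted_c
  idx <- fit_indices(prep$y, resid_c, length(pn))
  npar <- length(pn) + 1 + lc_len(q1) + lc_len(q2) + n_var_pars(vs)
  # Wald SEs from the linearized information at convergence
  Gr <- spec_gradient(prep$spec, beta, prep$data, offs)
  se <- tryCatch({
    pr <- lmm_profile(phi, prep, Gr[, pn, drop = FALSE], prep$y,
                      if (q1) Gr[, re$level1, drop = FALSE],
                      if (q2) Gr[, re$level2, drop = FALSE], fitted_c, vs)
    sqrt(pmax(diag(solve(attr(pr, "XtX"))) * sigma2, 0))
  }, error = function(e) rep(NA_real_, length(pn)))
  pv <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  eb1 <- if (q1) data.frame(branch_id = as.numeric(names(prep$bidx)),
                            stats::setNames(as.data.frame(u1), re$level1))
  wids <- do.call(rbind, strsplit(names(prep$widx), ".", fixed = TRUE))
  eb2 <- if (q2) data.frame(branch_id = as.numeric(wids[, 1]),
                            whorl_id = as.numeric(wids[, 2]),
                            stats::setNames(as.data.frame(u2), re$level2))
  fitted_orig <- numeric(prep$n); fitted_orig[prep$ord] <- fitted_c
  structure(list(
    spec = spec, re = re, vs = vs, response = response,
    beta = beta, se = stats::setNames(se, pn), p_values = pv,
    D1 = if (q1) structure(D1, dimnames = list(re$level1, re$level1)),
    D2 = if (q2) structure(D2, dimnames = list(re$level2, re$level2)),
    sigma2 = sigma2, var_par = vpar, corr_par = cpar,
    logLik = lap, AIC = -2 * lap + 2 * npar, n_par = npar,
    working_logLik = ll_work,
    eblup1 = eb1, eblup2 = eb2, fitted = fitted_orig,
    n = prep$n, n_branches = prep$nb, n_whorls = prep$nw,
    MAE = idx$MAE, RMSE = idx$RMSE, Ra2 = idx$Ra2,
    converged = conv, iterations = it, stop_reason = reason,
    ridge_restarts = ridge_restarts, nls_init = nlsfit$estimates),
    class = "branch_nlme")
}

# degenerate case: no random effects requested
nlme_from_nls <- function(nlsfit, re, vs) {
  structure(list(
    spec = nlsfit$spec, re = re, vs = vs, response = nlsfit$response,
    beta = nlsfit$estimates, se = nlsfit$se, p_values = nlsfit$p_values,
    D1 = NULL, D2 = NULL, sigma2 = nlsfit$RSS / nlsfit$n,
    var_par = 0, corr_par = numeric(0),
    logLik = nlsfit$logLik, AIC = nlsfit$AIC,
    n_par = length(nlsfit$estimates) + 1,
    working_logLik = nlsfit$logLik,
    eblup1 = NULL, eblup2 = NULL, fitted = NULL,
    n = nlsfit$n, n_branches = NA, n_whorls = NA,
    MAE = nlsfit$MAE, RMSE = nlsfit$RMSE, Ra2 = nlsfit$Ra2,
    converged = nlsfit$converged, iterations = nlsfit$iterations,
    stop_reason = "fixed-effects fit", ridge_restarts = 0L,
    nls_init = nlsfit$estimates), class = "branch_nlme")
}

# Laplace-approximate marginal log-likelihood at given modes
laplace_loglik <- function(prep, beta, u1, u2, D1, D2, sigma2,
                           vs = var_spec(), vpar = 0, cpar = numeric(0)) {
  q1 <- prep$q1; q2 <- prep$q2
  offs <- re_offsets(prep, u1, u2)
  mu <- spec_evaluate(prep$spec, beta, prep$data, offs)
  blocks <- whiten_blocks(prep, vs, vpar, cpar, mu)
  r <- apply_whiten(blocks, prep$y - mu)
  Gr <- spec_gradient(prep$spec, beta, prep$data, offs)
  Gw <- apply_whiten(blocks, Gr)
  D1inv <- if (q1) solve(D1)
  D2inv <- if (q2) solve(D2)
  ld1 <- if (q1) determinant(D1)$modulus else 0
  ld2 <- if (q2) determinant(D2)$modulus else 0
  ldR0 <- 0
  if (!is.null(blocks)) ldR0 <- sum(vapply(blocks, `[[`, numeric(1), "logdet"))
  ll <- -prep$n / 2 * log(2 * pi * sigma2) - ldR0 / 2
  for (i in seq_len(prep$nb)) {
    rows <- prep$bidx[[i]]
    wh <- unique(prep$roww[rows])
    di <- q1 + length(wh) * q2
    if (di == 0) { ll <- ll - sum(r[rows]^2) / (2 * sigma2); next }
    Zu <- matrix(0, length(rows), di)
    Pinv <- matrix(0, di, di)
    ui <- numeric(di)
    if (q1) {
      Zu[, 1:q1] <- Gw[rows, prep$re$level1, drop = FALSE]
      Pinv[1:q1, 1:q1] <- D1inv
      ui[1:q1] <- u1[i, ]
    }
    if (q2) for (jj in seq_along(wh)) {
      sel <- prep$roww[rows] == wh[jj]
      kk <- q1 + (jj - 1) * q2 + seq_len(q2)
      Zu[sel, kk] <- Gw[rows, prep$re$level2, drop = FALSE][sel, ]
      Pinv[kk, kk] <- D2inv
      ui[kk] <- u2[wh[jj], ]
    }
    H <- crossprod(Zu) / sigma2 + Pinv
    q <- sum(r[rows]^2) / sigma2 + sum(ui * (Pinv %*% ui))
    ll <- ll - as.numeric(ld1) / 2 - length(wh) * as.numeric(ld2) / 2 -
      q / 2 - as.numeric(determinant(H)$modulus) / 2
  }
  as.numeric(ll)
}

#' Standalone Laplace log-likelihood of a fitted or hypothesized model
#'
#' Re-solves the random-effect modes for the supplied parameter values and
#' data, then evaluates the Laplace-approximate marginal log-likelihood.
#' With both random-effect covariances at (numerical) zero this reduces to
#' the Gaussian fixed-effects log-likelihood.
#'
#' @param fit a `branch_nlme` object (its `beta`, `D1`, `D2`, `sigma2` are
#'   used unless overridden).
#' @param data modelling table; defaults refit on the training data layout.
#' @param beta,D1,D2,sigma2 optional parameter overrides.
#' @return scalar log-likelihood.
#' @export
nlme_loglik <- function(fit, data, beta = fit$beta, D1 = fit$D1,
                        D2 = fit$D2, sigma2 = fit$sigma2) {
  if (is.null(fit$re) || (length(fit$re$level1) + length(fit$re$level2)) == 0) {
    mu <- spec_evaluate(fit$spec, beta, data)
    rss <- sum((data[[fit$response]] - mu)^2)
    return(-nrow(data) / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2))
  }
  prep <- nlme_prepare(fit$spec, fit$re, data, fit$response)
  q1 <- prep$q1; q2 <- prep$q2
  u1 <- matrix(0, prep$nb, max(q1, 1)); u2 <- matrix(0, prep$nw, max(q2, 1))
  md <- update_modes(prep, beta, u1, u2,
                     if (q1) solve(D1), if (q2) solve(D2), sigma2,
                     blocks = NULL, sweeps = 50, tol = 1e-12)
  laplace_loglik(prep, beta, md$u1, md$u2, D1, D2, sigma2,
                 fit$vs, fit$var_par, fit$corr_par)
}

#' @export
print.branch_nlme <- function(x, ...) {
  cat("Two-level nonlinear mixed-effects fit:", x$spec$fun_id,
      "on", x$response, "\n")
  cat("  random effects: level 1 (primary branch):",
      paste(x$re$level1, collapse = ", "),
      "| level 2 (whorl):", paste(x$re$level2, collapse = ", "), "\n")
  tab <- data.frame(Estimate = x$beta, SE = x$se, p = x$p_values)
  print(signif(tab, 4))
  if (!is.null(x$D1)) {
    cat("  D1 variances:", paste(signif(diag(x$D1), 3), collapse = ", "))
    if (nrow(x$D1) == 2)
      cat("  corr:", signif(stats::cov2cor(x$D1)[1, 2], 3))
    cat("\n")
  }
  if (!is.null(x$D2))
    cat("  D2 variances:", paste(signif(diag(x$D2), 3), collapse = ", "), "\n")
  cat(sprintf("  sigma2 = %.4g  logLik = %.1f  AIC = %.1f\n",
              x$sigma2, x$logLik, x$AIC))
  cat(sprintf("  MAE = %.3f RMSE = %.3f Ra2 = %.3f | %s after %d iterations (%s)\n",
              x$MAE, x$RMSE, x$Ra2,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$stop_reason))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-effects fits
#'
#' `statistic = 2 (logLik_full - logLik_nested)` referred to a chi-square
#' with the difference in free parameter counts. When the restriction lies
#' on the boundary of the parameter space (a variance fixed at zero) the
#' chi-square reference is conservative; the p-value is an upper bound.
#'
#' @param nested,full `branch_nlme` fits of the same response on the same
#'   data, `nested` a restriction of `full`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, full) {
  if (nested$response != full$response || nested$n != full$n)
    stop("fits are not on the same data")
  if (nested$n_par > full$n_par)
    stop("'nested' has more parameters than 'full'")
  tag2 <- function(re) c(re$level1,
                         if (length(re$level2)) paste0("L2.", re$level2))
  nest_pars <- tag2(nested$re)
  full_pars <- tag2(full$re)
  if (!all(nest_pars %in% full_pars) ||
      !all(names(nested$beta) %in% names(full$beta)))
    stop("models are not nested")
  stat <- max(2 * (full$logLik - nested$logLik), 0)
  df <- full$n_par - nested$n_par
  list(statistic = stat, df = df,
       p_value = if (df == 0) as.numeric(stat <= 1e-8) else
         stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Exhaustive search over random-effects placements
#'
#' Enumerates all level-1 x level-2 subsets of the candidate parameters with
#' at most `max_random` random effects in total, fits each two-level model,
#' and ranks the converged fits by AIC. `max_random = 0` returns the single
#' fixed-effects fit.
#'
#' @param spec a [model_spec()].
#' @param data modelling table.
#' @param response response column.
#' @param max_random maximum total number of random-effect parameters.
#' @param candidates parameters eligible for random effects (default: all
#'   free parameters of the model).
#' @param tol outer-loop tolerance passed to [fit_nlme()]; AIC differences
#'   between placements are orders of magnitude above it.
#' @return data frame ranked by AIC with attribute `"fits"`.
#' @export
search_random_effects <- function(spec, data, response = "SBL",
                                  max_random = 3,
                                  candidates = spec_param_names(spec),
                                  tol = 1e-6, max_outer = 50) {
  subsets <- function(v) {
    out <- list(character(0))
    for (k in seq_along(v))
      out <- c(out, utils::combn(v, k, simplify = FALSE))
    out
  }
  s1 <- subsets(candidates); s2 <- subsets(candidates)
  combos <- list()
  for (a in s1) for (b in s2)
    if (length(a) + length(b) <= max_random) combos <- c(combos, list(list(a, b)))
  base_nls <- fit_nls(spec, data, response)     # shared across placements
  fits <- lapply(combos, function(cb)
    tryCatch(suppressWarnings(
      fit_nlme(spec, data, response, re_spec(cb[[1]], cb[[2]]),
               nls_fit = base_nls, tol = tol, max_outer = max_outer,
               restarts = FALSE)),
      error = function(e) NULL))
  keep <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged),
                 logical(1))
  lab <- vapply(combos, function(cb)
    paste0("L1{", paste(cb[[1]], collapse = ","), "} L2{",
           paste(cb[[2]], collapse = ","), "}"), character(1))
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$AIC,
                numeric(1))
  aic[!keep] <- NA
  ord <- order(aic, na.last = TRUE)
  tab <- data.frame(random_effects = lab[ord], converged = keep[ord],
                    AIC = aic[ord],
                    logLik = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$logLik, numeric(1))[ord])
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Predict from a fitted mixed-effects branch model
#'
#' Population predictions use the fixed effects only; subject predictions
#' add the EBLUPs of any branch/whorl present in the training data, falling
#' back to the population curve for unseen groups.
#'
#' @param object a `branch_nlme` fit.
#' @param newdata modelling table rows to predict.
#' @param mode `"population"` or `"subject"`.
#' @param ... unused.
#' @export
predict.branch_nlme <- function(object, newdata,
                                mode = c("population", "subject"), ...) {
  mode <- match.arg(mode)
  need <- unique(c("SDINC", unname(object$spec$cov_map)))
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (mode == "population" || is.null(object$eblup1) && is.null(object$eblup2))
    return(spec_evaluate(object$spec, object$beta, newdata))
  pn <- spec_param_names(object$spec)
  offs <- matrix(0, nrow(newdata), length(pn), dimnames = list(NULL, pn))
  if (!is.null(object$eblup1)) {
    m <- match(newdata$branch_id, object$eblup1$branch_id)
    for (p in object$re$level1) {
      v <- object$eblup1[[p]][m]; v[is.na(v)] <- 0
      offs[, p] <- offs[, p] + v
    }
  }
  if (!is.null(object$eblup2)) {
    key <- paste(newdata$branch_id, newdata$whorl_id)
    m <- match(key, paste(object$eblup2$branch_id, object$eblup2$whorl_id))
    for (p in object$re$level2) {
      v <- object$eblup2[[p]][m]; v[is.na(v)] <- 0
      offs[, p] <- offs[, p] + v
    }
  }
  spec_evaluate(object$spec, object$beta, newdata, offs)
}
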