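# Fixed-effects (population-average) fitting of the candidate branch-size
# functions, with model screening and covariate-expansion search.

#' Starting values for a candidate model
#'
#' For M7 the log-linearization `log y = log a + b log SDINC - c SDINC` is
#' exact, so ordinary least squares on the logged response gives the starts
#' (and the exact solution on noise-free data). Other functions use
#' documented closed-form or heuristic starts based on the observed
#' asymptote and partial linearizations.
#'
#' @param spec a [model_spec()].
#' @param data data frame with the response and covariates.
#' @param response `"SBL"` or `"SBD"` (or any numeric column).
#' @return named vector of starting values for all free parameters
#'   (expansion coefficients start at 0).
#' @export
initial_values <- function(spec, data, response = "SBL") {
  y0 <- data[[response]]
  x0 <- data$SDINC
  stopifnot(length(y0) > 0)
  if (sum(y0 > 0) < 3) stop("need at least 3 positive responses for starts")
  if (stats::sd(x0) == 0) stop("degenerate design: SDINC is constant")
  # candidate 1: raw positive rows (exact under noise-free log-linearization);
  # candidate 2: quantile-bin means (robust when the noise is large enough to
  # make log-scale row regression badly biased); keep the lower-RSS start
  cands <- list(list(x = x0[y0 > 0], y = y0[y0 > 0]))
  ux <- sort(unique(x0))
  if (length(ux) > 12) {
    br <- unique(stats::quantile(x0, seq(0, 1, length.out = 25)))
    g <- cut(x0, br, include.lowest = TRUE)
    xb <- tapply(x0, g, mean); yb <- tapply(y0, g, mean)
    ok <- !is.na(yb) & yb > 0
    if (sum(ok) >= 3) cands <- c(cands, list(list(x = xb[ok], y = yb[ok])))
  }
  ths <- lapply(cands, function(cc)
    tryCatch(raw_starts(spec$fun_id, cc$x, cc$y), error = function(e) NULL))
  ths <- Filter(Negate(is.null), ths)
  if (!length(ths)) stop("could not compute starting values")
  rss <- vapply(ths, function(th) {
    mu <- tryCatch(gf_evaluate(spec$fun_id, x0, th[["a"]], th[["b"]],
                               if ("c" %in% names(th)) th[["c"]]),
                   error = function(e) rep(Inf, length(x0)))
    sum((y0 - mu)^2)
  }, numeric(1))
  th <- ths[[which.min(rss)]]
  ex <- setdiff(spec_param_names(spec), names(th))
  c(th, stats::setNames(rep(0, length(ex)), ex))
}

# closed-form / heuristic starts from (x, y) pairs for one candidate function
raw_starts <- function(fun_id, x, y) {
  amax <- max(y) * 1.05
  th <- switch(fun_id,
    M7 = {
      f <- stats::lm(log(y) ~ log(x) + x)
      cf <- stats::coef(f)
      c(a = exp(unname(cf[1])), b = unname(cf[2]), c = -unname(cf[3]))
    },
    M5 = {
      f <- stats::lm(log(y) ~ I(1 / x))
      c(a = exp(unname(stats::coef(f)[1])),
        b = max(-unname(stats::coef(f)[2]), 1e-4))
    },
    M6 = c(a = amax, b = 1 / mean(x)),
    M1 = c(a = amax, b = 1 / mean(x), c = 1),
    M2 = c(a = amax, b = 1 / mean(x), c = 1),
    M3 = {
      p <- pmin(pmax(y / amax, 1e-6), 1 - 1e-6)
      f <- stats::lm(log(p / (1 - p)) ~ x)
      c(a = amax, b = exp(-unname(stats::coef(f)[1])),
        c = max(unname(stats::coef(f)[2]), 1e-4))
    },
    M4 = c(a = amax, b = mean(x), c = 1),
    M8 = {
      z <- pmax(-log(pmin(y / amax, 1 - 1e-6)), 1e-8)
      f <- stats::lm(log(z) ~ log(x))
      c(a = amax, b = exp(unname(stats::coef(f)[1])),
        c = max(-unname(stats::coef(f)[2]), 1e-4))
    },
    M9 = {
      z <- pmax(-log(pmin(y / amax, 1 - 1e-6)), 1e-8)
      f <- stats::lm(log(z) ~ x)
      c(a = amax, b = exp(unname(stats::coef(f)[1])),
        c = max(-unname(stats::coef(f)[2]), 1e-4))
    })
  lo <- gf_bounds(fun_id)$lower
  th[names(lo)] <- pmax(th[names(lo)], lo + 1e-8)
  th
}

# Gaussian ML log-likelihood from a residual sum of squares
gauss_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

fit_indices <- function(y, resid, p) {
  n <- length(y)
  rss <- sum(resid^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  list(n = n, RSS = rss,
       MAE = mean(abs(resid)), RMSE = sqrt(rss / n),
       Ra2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       logLik = gauss_loglik(rss, n),
       AIC = -2 * gauss_loglik(rss, n) + 2 * (p + 1))
}

#' Fit a candidate model by bounded nonlinear least squares
#'
#' Levenberg-Marquardt with the analytic Jacobian from [spec_gradient()] and
#' the per-function box constraints. Non-convergence is reported in the
#' result, not raised, so that model-screening sweeps always complete.
#' `AIC = -2 logLik + 2 (p + 1)` with the Gaussian ML log-likelihood (the
#' residual variance counts as a parameter); `Ra2` is the adjusted R^2.
#'
#' @param spec a [model_spec()].
#' @param data data frame with `SDINC`, the response, and mapped covariates.
#' @param response response column name.
#' @param init starting values; defaults to [initial_values()].
#' @return an object of class `branch_nls` with estimates, standard errors,
#'   p-values, fit indices (`MAE`, `RMSE`, `Ra2`, `AIC`, `logLik`) and a
#'   convergence flag.
#' @export
fit_nls <- function(spec, data, response = "SBL", init = NULL) {
  y <- data[[response]]
  if (is.null(init)) init <- initial_values(spec, data, response)
  pn <- spec_param_names(spec)
  init <- init[pn]
  bd <- gf_bounds(spec$fun_id)
  lower <- stats::setNames(rep(-Inf, length(pn)), pn)
  lower[names(bd$lower)] <- bd$lower
  n <- length(y)
  p <- length(pn)
  if (n <= p) {
    return(structure(list(spec = spec, response = response,
                          estimates = init, se = rep(NA_real_, p),
                          p_values = rep(NA_real_, p), converged = FALSE,
                          message = "under-identified: n <= p",
                          iterations = 0L,
                          n = n, RSS = NA_real_, MAE = NA_real_,
                          RMSE = NA_real_, Ra2 = NA_real_,
                          logLik = NA_real_, AIC = NA_real_),
                     class = "branch_nls"))
  }
  resfun <- function(th) {
    th <- stats::setNames(th, pn)
    y - spec_evaluate(spec, th, data)
  }
  jacfun <- function(th) {
    th <- stats::setNames(th, pn)
    -spec_gradient(spec, th, data)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmax(init, lower + 0), fn = resfun, jac = jacfun,
                       lower = lower,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, response = response,
                          estimates = init, se = rep(NA_real_, p),
                          p_values = rep(NA_real_, p), converged = FALSE,
                          message = conditionMessage(fit), iterations = 0L,
                          n = n, RSS = NA_real_, MAE = NA_real_,
                          RMSE = NA_real_, Ra2 = NA_real_,
                          logLik = NA_real_, AIC = NA_real_),
                     class = "branch_nls"))
  }
  est <- stats::setNames(fit$par, pn)
  resid <- resfun(fit$par)
  idx <- fit_indices(y, resid, p)
  # Wald standard errors from the Gauss-Newton information
  J <- -jacfun(fit$par)
  s2 <- idx$RSS / (n - p)
  cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, p) else sqrt(pmax(diag(cv), 0))
  tval <- est / se
  pv <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  converged <- fit$info %in% 1:4 && all(is.finite(est))
  structure(c(list(spec = spec, response = response, estimates = est,
                   se = se, p_values = pv, converged = converged,
                   message = fit$message, iterations = fit$niter), idx),
            class = "branch_nls")
}

#' @export
print.branch_nls <- function(x, ...) {
  cat("Nonlinear least-squares fit:", x$spec$fun_id,
      if (length(x$spec$cov_map))
        paste0("(", paste(names(x$spec$cov_map), "~", x$spec$cov_map,
                          collapse = ", "), ")"),
      "on", x$response, "\n")
  tab <- data.frame(Estimate = x$estimates, SE = x$se, p = x$p_values)
  print(signif(tab, 4))
  cat(sprintf("n = %d  MAE = %.3f  RMSE = %.3f  Ra2 = %.3f  AIC = %.1f%s\n",
              x$n, x$MAE, x$RMSE, x$Ra2, x$AIC,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Screen the candidate growth functions
#'
#' Fits each candidate function to the data and ranks the results by AIC
#' (ascending). Non-convergent candidates are retained at the bottom of the
#' table with `AIC = NA`, mirroring how screening tables mark functions that
#' fail on a given response.
#'
#' @param data modelling table.
#' @param function_ids candidates, default all of [gf_ids()].
#' @param response response column.
#' @return data frame (one row per candidate, ranked) with an attribute
#'   `"fits"` holding the full `branch_nls` objects in ranked order.
#' @export
screen_candidates <- function(data, function_ids = gf_ids(),
                              response = "SBL") {
  if (!length(function_ids)) stop("empty candidate list")
  fits <- lapply(function_ids, function(fid) {
    init <- tryCatch(initial_values(model_spec(fid), data, response),
                     error = function(e) NULL)
    if (is.null(init))
      return(structure(list(spec = model_spec(fid), response = response,
                            converged = FALSE, AIC = NA_real_,
                            RMSE = NA_real_, Ra2 = NA_real_, n = nrow(data),
                            estimates = NULL,
                            message = "no starting values"),
                       class = "branch_nls"))
    fit_nls(model_spec(fid), data, response, init)
  })
  aic <- vapply(fits, function(f) if (isTRUE(f$converged)) f$AIC else NA_real_,
                numeric(1))
  ord <- order(aic, na.last = TRUE)
  tab <- data.frame(
    function_id = function_ids[ord],
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1))[ord],
    AIC = aic[ord],
    RMSE = vapply(fits, function(f) f$RMSE %||% NA_real_, numeric(1))[ord],
    Ra2 = vapply(fits, function(f) f$Ra2 %||% NA_real_, numeric(1))[ord])
  attr(tab, "fits") <- fits[ord]
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive covariate-expansion search
#'
#' Enumerates every placement of candidate covariates on the base parameters
#' (each of `a`, `b`, `c` expanded by at most one covariate, all combinations
#' across parameters), fits each expanded model, drops expansions whose added
#' coefficient is not significant at `alpha`, and ranks the survivors by AIC.
#' The unexpanded base model is always included, so a data set with no real
#' covariate effect retains the base model.
#'
#' @param base_spec the base [model_spec()] (usually without a covariate map).
#' @param data modelling table containing the candidate covariates.
#' @param candidate_covariates character vector of column names (tree-level:
#'   HT, DBH, HD, CW, CL, CR; branch-level: PBL, PBD, PDINC).
#' @param response response column.
#' @param alpha significance threshold for retaining an expansion
#'   coefficient.
#' @return ranked data frame with attribute `"fits"`, as in
#'   [screen_candidates()].
#' @export
covariate_search <- function(base_spec, data, candidate_covariates,
                             response = "SBL", alpha = 0.05) {
  stopifnot(all(candidate_covariates %in% names(data)))
  pars <- gf_param_names(base_spec$fun_id)
  choices <- lapply(pars, function(p) c(NA_character_, candidate_covariates))
  grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
  names(grid) <- pars
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    cm <- unlist(grid[i, ])
    cm <- cm[!is.na(cm)]
    model_spec(base_spec$fun_id, cm)
  })
  fits <- lapply(specs, function(sp) fit_nls(sp, data, response))
  keep <- vapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(FALSE)
    ex <- grep("1$", names(f$estimates), value = TRUE)
    all(f$p_values[ex] < alpha)           # TRUE for the base model (no ex)
  }, logical(1))
  fits <- fits[keep]
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  ord <- order(aic)
  tab <- data.frame(
    model = vapply(fits, function(f) {
      cm <- f$spec$cov_map
      if (!length(cm)) "base"
      else paste(names(cm), "~", cm, collapse = ", ")
    }, character(1))[ord],
    AIC = aic[ord],
    RMSE = vapply(fits, `[[`, numeric(1), "RMSE")[ord],
    Ra2 = vapply(fits, `[[`, numeric(1), "Ra2")[ord])
  attr(tab, "fits") <- fits[ord]
  tab
}
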