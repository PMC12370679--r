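#' Candidate growth functions for secondary branch size
#'
#' Nine empirical curves relating a secondary branch's size (length, cm, or
#' diameter, mm) to its position `SDINC`, the distance (cm) from the primary
#' branch tip to the secondary branch base. The family covers the saturating
#' and unimodal shapes in routine use for branch modelling: Mitscherlich-type
#' saturation (M1, M6), Weibull (M2), logistic (M3), Hossfeld (M4), Korf-type
#' (M5, M8), the unimodal a*x^b*exp(-c*x) curve (M7, "Roeecp"), and Gompertz
#' (M9).
#'
#' @format A character vector of the nine function identifiers.
#' @export
gf_ids <- function() paste0("M", 1:9)

# free base parameters per function (M5, M6 have no c)
gf_param_names <- function(fun_id) {
  switch(fun_id,
    M5 = c("a", "b"),
    M6 = c("a", "b"),
    c("a", "b", "c"))
}

#' Evaluate a candidate growth function
#'
#' @param fun_id one of `gf_ids()`.
#' @param x positive position values (`SDINC`, cm). M5 and M8 are undefined
#'   at 0; the others are evaluated by their limit there.
#' @param a,b,c parameters; recycled against `x`. `c` is ignored by M5/M6.
#' @return predicted branch size, same length as `x`.
#' @examples
#' gf_evaluate("M7", 100, a = 0.364, b = 0.928, c = 0.002)
#' @export
gf_evaluate <- function(fun_id, x, a, b, c = NULL) {
  stopifnot(fun_id %in% gf_ids())
  if (fun_id %in% c("M5", "M8") && any(x <= 0))
    stop(fun_id, " is undefined at SDINC <= 0")
  if (any(x < 0)) stop("SDINC must be nonnegative")
  switch(fun_id,
    M1 = a * (1 - exp(-b * x))^c,
    M2 = a * (1 - exp(-b * x^c)),
    M3 = a / (1 + b * exp(-c * x)),
    M4 = a / (1 + b * x^(-c)),
    M5 = a * exp(-b / x),
    M6 = a * (1 - exp(-b * x)),
    M7 = a * x^b * exp(-c * x),
    M8 = a * exp(-b * x^(-c)),
    M9 = a * exp(-b * exp(-c * x)))
}

#' Analytic gradient of a candidate growth function
#'
#' Partial derivatives of the predicted size with respect to each free base
#' parameter, used for least-squares Jacobians and the mixed-model design
#' matrices.
#'
#' @inheritParams gf_evaluate
#' @return numeric matrix, one column per free parameter (named).
#' @export
gf_gradient <- function(fun_id, x, a, b, c = NULL) {
  stopifnot(fun_id %in% gf_ids())
  n <- length(x)
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (!is.null(c)) c <- rep_len(c, n)
  g <- switch(fun_id,
    M1 = {
      e <- exp(-b * x); s <- 1 - e
      cbind(a = s^c,
            b = a * c * s^(c - 1) * x * e,
            c = a * s^c * ifelse(s > 0, log(s), 0))
    },
    M2 = {
      xc <- x^c; e <- exp(-b * xc)
      cbind(a = 1 - e,
            b = a * xc * e,
            c = a * b * xc * ifelse(x > 0, log(x), 0) * e)
    },
    M3 = {
      e <- exp(-c * x); d <- 1 + b * e
      cbind(a = 1 / d,
            b = -a * e / d^2,
            c = a * b * x * e / d^2)
    },
    M4 = {
      xc <- x^(-c); d <- 1 + b * xc
      cbind(a = 1 / d,
            b = -a * xc / d^2,
            c = a * b * xc * ifelse(x > 0, log(x), 0) / d^2)
    },
    M5 = {
      e <- exp(-b / x)
      cbind(a = e, b = -a * e / x)
    },
    M6 = {
      e <- exp(-b * x)
      cbind(a = 1 - e, b = a * x * e)
    },
    M7 = {
      y <- a * x^b * exp(-c * x)
      cbind(a = x^b * exp(-c * x),
            b = y * ifelse(x > 0, log(x), 0),
            c = -x * y)
    },
    M8 = {
      xc <- x^(-c); y <- a * exp(-b * xc)
      cbind(a = y / a,
            b = -xc * y,
            c = b * xc * ifelse(x > 0, log(x), 0) * y)
    },
    M9 = {
      g0 <- exp(-c * x); y <- a * exp(-b * g0)
      cbind(a = y / a,
            b = -g0 * y,
            c = b * x * g0 * y)
    })
  g
}

#' Position of the interior maximum of a growth curve
#'
#' Most candidate functions increase monotonically towards an asymptote; the
#' unimodal M7 curve peaks at `SDINC = b/c` (the stationary point of
#' `log y = log a + b log x - c x`). The peak position underlies the relative
#' depth at which mean secondary branch size is largest within a primary
#' branch.
#'
#' @inheritParams gf_evaluate
#' @return peak position in cm, or `NA_real_` when the curve is monotone
#'   (all functions but M7, and M7 with `c = 0`).
#' @export
gf_interior_maximum <- function(fun_id, a, b, c = NULL) {
  stopifnot(fun_id %in% gf_ids())
  if (fun_id != "M7") return(NA_real_)
  if (is.null(c) || c <= 0 || b <= 0) return(NA_real_)
  b / c
}

# box constraints keeping each function increasing-then-saturating or
# unimodal on (0, Inf); expansion coefficients are unbounded
gf_bounds <- function(fun_id) {
  pn <- gf_param_names(fun_id)
  lo <- c(a = 1e-8, b = 1e-8, c = 1e-8)
  if (fun_id == "M7") lo["c"] <- 0        # c = 0 allowed: pure power law
  list(lower = lo[pn], upper = rep(Inf, length(pn)))
}

#' Define a model specification
#'
#' A `model_spec` couples a candidate function with an optional linear
#' covariate expansion of its parameters: mapping parameter `a` to covariate
#' `PDINC` replaces `a` by `a + a1 * PDINC` row-wise (and likewise `b` by
#' `b + b1 * PBD`, etc.). Each base parameter takes at most one covariate.
#'
#' @param fun_id one of `gf_ids()`.
#' @param cov_map named character vector, names in the function's base
#'   parameters, values column names of the dataset
#'   (e.g. `c(a = "PDINC")`).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("M7", c(a = "PDINC"))   # length model with PDINC on a
#' model_spec("M7", c(b = "PBD"))     # diameter model with PBD on b
#' @export
model_spec <- function(fun_id, cov_map = character()) {
  stopifnot(fun_id %in% gf_ids())
  cov_map <- cov_map[order(match(names(cov_map), c("a", "b", "c")))]
  if (length(cov_map)) {
    bad <- setdiff(names(cov_map), gf_param_names(fun_id))
    if (length(bad)) stop("cov_map names must be base parameters; bad: ",
                          paste(bad, collapse = ", "))
    if (anyDuplicated(names(cov_map)))
      stop("each parameter maps to at most one covariate")
  }
  structure(list(fun_id = fun_id, cov_map = cov_map), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$fun_id)
  if (length(x$cov_map))
    cat(" [", paste(names(x$cov_map), "+", paste0(names(x$cov_map), "1"), "*",
                    x$cov_map, collapse = "; "), "]")
  cat("\n  free parameters:", paste(spec_param_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Free parameter names of a model specification
#'
#' Base parameters of the function followed by the expansion coefficients
#' (`a1`, `b1`, `c1`) implied by the covariate map.
#' @param spec a `model_spec`.
#' @export
spec_param_names <- function(spec) {
  c(gf_param_names(spec$fun_id),
    if (length(spec$cov_map)) paste0(names(spec$cov_map), "1"))
}

# row-wise effective base parameters: theta (named free params) plus optional
# per-row additive offsets (matrix, columns named after free params) from
# random effects
spec_effective <- function(spec, theta, data, offsets = NULL) {
  pn <- gf_param_names(spec$fun_id)
  n <- nrow(data)
  eff <- sapply(pn, function(p) rep_len(theta[[p]], n))
  if (is.null(dim(eff))) eff <- matrix(eff, nrow = n, dimnames = list(NULL, pn))
  add <- function(par, val) eff[, par] <<- eff[, par] + val
  if (!is.null(offsets))
    for (p in intersect(colnames(offsets), pn)) add(p, offsets[, p])
  for (p in names(spec$cov_map)) {
    cov <- data[[spec$cov_map[[p]]]]
    if (is.null(cov)) stop("covariate '", spec$cov_map[[p]], "' not in data")
    coef1 <- theta[[paste0(p, "1")]]
    if (!is.null(offsets) && paste0(p, "1") %in% colnames(offsets))
      coef1 <- coef1 + offsets[, paste0(p, "1")]
    add(p, coef1 * cov)
  }
  eff
}

#' Evaluate a model specification on data
#'
#' @param spec a `model_spec`.
#' @param theta named list/vector of free parameter values
#'   (see [spec_param_names()]).
#' @param data data frame with `SDINC` and any mapped covariates.
#' @param offsets optional numeric matrix (rows of `data` x free parameters)
#'   of additive per-row parameter perturbations, used for random effects.
#' @return predicted sizes.
#' @export
spec_evaluate <- function(spec, theta, data, offsets = NULL) {
  theta <- as.list(theta)
  eff <- spec_effective(spec, theta, data, offsets)
  gf_evaluate(spec$fun_id, data$SDINC,
              a = eff[, "a"], b = eff[, "b"],
              c = if ("c" %in% colnames(eff)) eff[, "c"])
}

#' Jacobian of a model specification
#'
#' Chain rule over the covariate expansion: the column for `a1` is the base
#' `a` column times the mapped covariate, etc.
#'
#' @inheritParams spec_evaluate
#' @return matrix with one named column per free parameter.
#' @export
spec_gradient <- function(spec, theta, data, offsets = NULL) {
  theta <- as.list(theta)
  eff <- spec_effective(spec, theta, data, offsets)
  g <- gf_gradient(spec$fun_id, data$SDINC,
                   a = eff[, "a"], b = eff[, "b"],
                   c = if ("c" %in% colnames(eff)) eff[, "c"])
  extra <- lapply(names(spec$cov_map), function(p)
    g[, p] * data[[spec$cov_map[[p]]]])
  if (length(extra)) {
    extra <- do.call(cbind, extra)
    colnames(extra) <- paste0(names(spec$cov_map), "1")
    g <- cbind(g, extra)
  }
  g[, spec_param_names(spec), drop = FALSE]
}
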