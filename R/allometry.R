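# Log-log allometric scaling between primary- and secondary-branch sizes,
# with percentile-bootstrap confidence intervals.

#' Fit a power-law scaling relationship on the log-log scale
#'
#' Ordinary least squares of `log(y)` on `log(x)`:
#' `log(y) = gamma + exponent * log(x)`, the log form of the power law
#' `y = a * x^exponent` with `a = exp(gamma)`. In the branch pairings the
#' primary-branch size is the response `y` and the secondary-branch size the
#' regressor `x`.
#'
#' @param x,y positive paired sizes, `n >= 3`.
#' @return list with `gamma`, `exponent`, `n`.
#' @export
fit_loglog <- function(x, y) {
  bad <- which(!(x > 0 & y > 0))
  if (length(bad))
    stop("nonpositive values at pair(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(x) < 3) stop("need at least 3 pairs")
  f <- stats::lm.fit(cbind(1, log(x)), log(y))
  list(gamma = unname(f$coefficients[1]),
       exponent = unname(f$coefficients[2]), n = length(x))
}

#' Percentile-bootstrap confidence interval for the scaling parameters
#'
#' Case resampling with replacement: `B` replicates of the log-log OLS fit,
#' interval bounds at the empirical `(1 - level)/2` and `(1 + level)/2`
#' quantiles of the replicate estimates. Deterministic given `seed` (one
#' `sample.int(n, n, replace = TRUE)` draw per replicate, in order).
#'
#' @inheritParams fit_loglog
#' @param B number of bootstrap replicates (3,000 in the headline analysis).
#' @param level confidence level.
#' @param seed integer seed for the resampling stream.
#' @return list with point estimates, `ci_exponent`, `ci_gamma`, `B`,
#'   `level`, and the replicate draws.
#' @export
bootstrap_ci <- function(x, y, B = 3000, level = 0.95, seed = 1L) {
  pt <- fit_loglog(x, y)
  stopifnot(B >= 1, level > 0, level < 1)
  n <- length(x)
  lx <- log(x); ly <- log(y)
  set.seed(seed)
  reps <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- stats::lm.fit(cbind(1, lx[idx]), ly[idx])
    reps[b, ] <- f$coefficients
  }
  pr <- c((1 - level) / 2, (1 + level) / 2)
  list(gamma = pt$gamma, exponent = pt$exponent, n = n,
       ci_exponent = unname(stats::quantile(reps[, 2], pr, na.rm = TRUE)),
       ci_gamma = unname(stats::quantile(reps[, 1], pr, na.rm = TRUE)),
       B = B, level = level, replicates = reps)
}

# pair construction ---------------------------------------------------------

# the secondary branch "attached to the primary branch base" = the deepest
# whorl (maximum SDINC) on each primary branch
base_whorl_pairs <- function(ds, measure) {
  s <- ds$secondaries
  deepest <- s[order(s$branch_id, -s$SDINC), ]
  deepest <- deepest[!duplicated(deepest$branch_id), ]
  pb <- ds$primaries[match(deepest$branch_id, ds$primaries$branch_id), ]
  tr <- ds$trees[match(deepest$tree_id, ds$trees$tree_id), ]
  if (measure == "length")
    data.frame(x = deepest$SBL, y = pb$PBL, PAGE = pb$PAGE,
               SAGE = deepest$SAGE, tree_age = tr$age)
  else
    data.frame(x = deepest$SBD, y = pb$PBD, PAGE = pb$PAGE,
               SAGE = deepest$SAGE, tree_age = tr$age)
}

# every secondary branch against the primary-branch segment it sits on:
# length pairs SBL with SDINC (tip-to-attachment length); diameter pairs SBD
# with the parent diameter scaled by relative depth (no mid-branch diameter
# is measured; the taper approximation is linear in relative depth)
attachment_pairs <- function(ds, measure) {
  s <- ds$secondaries
  pb <- ds$primaries[match(s$branch_id, ds$primaries$branch_id), ]
  tr <- ds$trees[match(s$tree_id, ds$trees$tree_id), ]
  if (measure == "length")
    data.frame(x = s$SBL, y = s$SDINC, PAGE = pb$PAGE, SAGE = s$SAGE,
               tree_age = tr$age)
  else
    data.frame(x = s$SBD, y = pb$PBD * pmin(s$SDINC / pb$PBL, 1),
               PAGE = pb$PAGE, SAGE = s$SAGE, tree_age = tr$age)
}

#' Allometric scaling profile across age groups
#'
#' Fits the log-log scaling relationship within each group at one of the
#' three grouping levels and attaches percentile-bootstrap intervals:
#' \describe{
#'   \item{`"PAGE"`}{primary branches of the same age, paired with the
#'     secondary branch at the branch base (deepest whorl).}
#'   \item{`"SAGE"`}{secondary branches of the same age, paired with the
#'     primary-branch length from the tip to the attachment point (or the
#'     taper-scaled parent diameter).}
#'   \item{`"tree_age"`}{trees of the same age, base-whorl pairing.}
#' }
#' Groups with fewer than `min_pairs` pairs are reported but flagged
#' unreliable.
#'
#' @param ds a `branch_dataset`.
#' @param grouping `"PAGE"`, `"SAGE"`, or `"tree_age"`.
#' @param measure `"length"` or `"diameter"`.
#' @param B,level,seed bootstrap controls, see [bootstrap_ci()].
#' @param min_pairs minimum reliable group size.
#' @return data frame, one row per group: `group`, `n`, `gamma`, `exponent`,
#'   `ci_low`, `ci_high`, `reliable`.
#' @export
scaling_profile <- function(ds, grouping = c("PAGE", "SAGE", "tree_age"),
                            measure = c("length", "diameter"),
                            B = 3000, level = 0.95, seed = 1L,
                            min_pairs = 5) {
  grouping <- match.arg(grouping)
  measure <- match.arg(measure)
  pairs <- if (grouping == "SAGE") attachment_pairs(ds, measure)
           else base_whorl_pairs(ds, measure)
  key <- pairs[[grouping]]
  groups <- sort(unique(key))
  if (!length(groups)) stop("no groups to fit")
  out <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    px <- pairs$x[key == g]; py <- pairs$y[key == g]
    ok <- px > 0 & py > 0
    px <- px[ok]; py <- py[ok]
    if (length(px) < 3)
      return(data.frame(group = g, n = length(px), gamma = NA_real_,
                        exponent = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, reliable = FALSE))
    bs <- bootstrap_ci(px, py, B = B, level = level, seed = seed + gi)
    data.frame(group = g, n = bs$n, gamma = bs$gamma, exponent = bs$exponent,
               ci_low = bs$ci_exponent[1], ci_high = bs$ci_exponent[2],
               reliable = bs$n >= min_pairs)
  })
  do.call(rbind, out)
}
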