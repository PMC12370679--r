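# Descriptive crown-profile statistics: whorl-wise and age-group means,
# current-year shoots, and the relative depth of the size maximum.

#' Mean secondary branch size by whorl / age / depth group
#'
#' Group means of `SBL` and `SBD` over the secondary branches, ordered from
#' the tree (or branch) tip downward.
#'
#' @param ds a `branch_dataset`.
#' @param by grouping variable: `"PAGE"` (primary-branch age, i.e. whorl
#'   from the tree tip), `"SAGE"` (secondary-branch age), or `"depth"`
#'   (10 equal bins of relative depth `SDINC / PBL`).
#' @param tree_age optionally restrict to one tree age class first.
#' @return data frame with `group`, `n`, `mean_SBL`, `mean_SBD`, `sd_SBL`,
#'   `sd_SBD`.
#' @export
whorl_means <- function(ds, by = c("PAGE", "SAGE", "depth"),
                        tree_age = NULL) {
  by <- match.arg(by)
  s <- ds$secondaries
  if (!nrow(s)) stop("empty dataset")
  if (!is.null(tree_age)) {
    tr <- ds$trees[match(s$tree_id, ds$trees$tree_id), ]
    s <- s[tr$age %in% tree_age, , drop = FALSE]
  }
  if (!nrow(s))
    return(data.frame(group = numeric(0), n = integer(0),
                      mean_SBL = numeric(0), mean_SBD = numeric(0),
                      sd_SBL = numeric(0), sd_SBD = numeric(0)))
  key <- switch(by,
    PAGE = s$PAGE,
    SAGE = s$SAGE,
    depth = {
      rel <- pmin(s$SDINC / s$PBL, 1)
      as.numeric(as.character(cut(rel, seq(0, 1, 0.1),
                                  labels = seq(0.05, 0.95, 0.1),
                                  include.lowest = TRUE)))
    })
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  data.frame(group = sort(unique(key)),
             n = as.integer(table(key)),
             mean_SBL = agg(s$SBL, mean), mean_SBD = agg(s$SBD, mean),
             sd_SBL = agg(s$SBL, stats::sd), sd_SBD = agg(s$SBD, stats::sd))
}

#' Current-year shoots of the secondary branches
#'
#' Secondary branches of age 1 (newly germinated shoots), summarized against
#' the age of the primary branch that carries them. An empty result (no
#' age-1 branches) is returned, not an error.
#'
#' @param ds a `branch_dataset`.
#' @return data frame as in [whorl_means()] with `group` = PAGE.
#' @export
current_year_shoots <- function(ds) {
  sub <- ds
  sub$secondaries <- ds$secondaries[ds$secondaries$SAGE == 1, , drop = FALSE]
  if (!nrow(sub$secondaries))
    return(data.frame(group = numeric(0), n = integer(0),
                      mean_SBL = numeric(0), mean_SBD = numeric(0),
                      sd_SBL = numeric(0), sd_SBD = numeric(0)))
  whorl_means(sub, by = "PAGE")
}

#' Relative depth at which mean secondary branch size peaks
#'
#' Both interpretations of the within-branch "inflection point" are
#' computed: the relative depth (`SDINC / PBL`) of the maximum of the
#' binned mean profile (`method = "binned"`, the default), and the peak
#' `b/c` of a fitted unimodal M7 curve expressed as a fraction of branch
#' length and averaged over branches (`method = "fitted"`). A profile that
#' is still rising at the branch base returns 1.0 with `monotone = TRUE`.
#'
#' @param ds a `branch_dataset`.
#' @param measure `"length"` or `"diameter"`.
#' @param method `"binned"` or `"fitted"`.
#' @param params optional named `(b, c)` to use instead of fitting (for
#'   `method = "fitted"`).
#' @return list with `relative_depth`, `method`, `monotone`.
#' @export
inflection_point <- function(ds, measure = c("length", "diameter"),
                             method = c("binned", "fitted"),
                             params = NULL) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  col <- if (measure == "length") "mean_SBL" else "mean_SBD"
  if (method == "binned") {
    prof <- whorl_means(ds, by = "depth")
    prof <- prof[!is.na(prof[[col]]), ]
    pk <- which.max(prof[[col]])
    monotone <- pk == nrow(prof)
    return(list(relative_depth = if (monotone) 1.0 else prof$group[pk],
                method = "binned", monotone = monotone))
  }
  if (is.null(params)) {
    resp <- if (measure == "length") "SBL" else "SBD"
    fit <- fit_nls(model_spec("M7"), dataset_table(ds), resp)
    params <- fit$estimates
  }
  peak <- gf_interior_maximum("M7", params[["a"]] %||% 1,
                              params[["b"]], params[["c"]])
  pbl <- ds$primaries$PBL
  if (is.na(peak))
    return(list(relative_depth = 1.0, method = "fitted", monotone = TRUE))
  rel <- mean(pmin(peak / pbl, 1))
  list(relative_depth = rel, method = "fitted", monotone = rel >= 1)
}
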