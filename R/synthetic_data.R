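# truncated-normal draws by inverse-CDF (deterministic in the RNG stream)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# envelope: c(min, mean, max, sd) as printed in the field summary tables
env_ok <- function(e) length(e) == 4 && e[1] <= e[2] && e[2] <= e[3] && e[4] >= 0
draw_env <- function(n, e) rtnorm(n, e[2], e[4], e[1], e[3])

#' Covariance matrix from variances and a correlation
#'
#' Branch-level random effects on two parameters are reported as two
#' variances plus their correlation; this assembles the corresponding 2x2
#' covariance matrix.
#' @param v1,v2 variances (>= 0).
#' @param rho correlation in `[-1, 1]`.
#' @export
re_cov2 <- function(v1, v2, rho) {
  stopifnot(v1 >= 0, v2 >= 0, abs(rho) <= 1)
  cv <- rho * sqrt(v1 * v2)
  matrix(c(v1, cv, cv, v2), 2, 2)
}

#' Default covariate envelopes for a planted Korean pine crown dataset
#'
#' `(min, mean, max, sd)` for each measured attribute, at the values of the
#' study's stand, tree and branch summary tables. Tree level: DBH (cm),
#' HT (m), CW (m), HBLC (m). Primary branch level: PAGE (yr), PBL (cm),
#' PBD (mm), PVA (deg). Positions (PDINC, SDINC) have no printed envelope
#' and are placed structurally along the crown and branch.
#' @export
default_envelopes <- function() {
  list(
    DBH  = c(7.30, 28.23, 44.60, 8.34),
    HT   = c(6.72, 17.70, 24.92, 4.35),
    CW   = c(1.27, 2.45, 3.98, 0.62),
    HBLC = c(1.34, 8.77, 15.69, 4.07),
    PAGE = c(2, 11, 34, 6.52),
    PBL  = c(8.00, 244.14, 661.00, 144.77),
    PBD  = c(4.32, 29.81, 75.01, 14.49),
    PVA  = c(0, 60, 110, 13.50)
  )
}

# printed mixed-model parameter sets for the two responses
default_law_params <- function(law) {
  switch(law,
    SBL_mixed = list(
      spec = model_spec("M7", c(a = "PDINC")),
      fixed = c(a = 0.197, b = 0.989, c = 0.003, a1 = 3.0e-4),
      re1 = c("b", "c"), re2 = "b",
      level1_cov = re_cov2(6.2e-3, 4.0e-6, 0.842),
      level2_var = 1.9e-3, sigma2 = 251.6, response = "SBL"),
    SBD_mixed = list(
      spec = model_spec("M7", c(b = "PBD")),
      fixed = c(a = 1.321, b = 0.270, c = 1.4e-3, b1 = 2.2e-3),
      re1 = c("b", "c"), re2 = "b1",
      level1_cov = re_cov2(2.1e-3, 1.9e-6, 0.891),
      level2_var = 4.1e-7, sigma2 = 3.649, response = "SBD"),
    SBL_fixed = list(
      spec = model_spec("M7", c(a = "PDINC")),
      fixed = c(a = 0.188, b = 0.974, c = 0.002, a1 = 3.0e-4),
      re1 = character(), re2 = character(),
      level1_cov = matrix(0, 0, 0), level2_var = 0,
      sigma2 = 18.96^2, response = "SBL"),
    SBD_fixed = list(
      spec = model_spec("M7", c(b = "PBD")),
      fixed = c(a = 1.292, b = 0.276, c = 1.2e-3, b1 = 1.9e-3),
      re1 = character(), re2 = character(),
      level1_cov = matrix(0, 0, 0), level2_var = 0,
      sigma2 = 2.236^2, response = "SBD"),
    stop("unknown response law: ", law))
}

#' Configuration for the hierarchical crown-data generator
#'
#' Defaults reproduce the study's sampling frame: 54 trees in six even-aged
#' stands (28, 40, 46, 53, 64, 70 years), about 717 sample primary branches
#' and about 24,000 secondary branches, with covariates drawn from truncated
#' normal envelopes at the printed summary statistics and the response
#' generated by the selected law at the printed mixed-model parameter values.
#'
#' @param n_trees number of sample trees.
#' @param branches_per_tree expected primary branches per tree (Poisson,
#'   truncated at >= 1), or an exact integer count when `fixed_counts` is
#'   TRUE.
#' @param whorls_per_branch `NA` to link whorl count to branch age (one
#'   annual whorl per secondary age class, `PAGE - 1`), or a fixed integer.
#' @param obs_per_whorl expected secondary branches per whorl
#'   (1 + Poisson(obs_per_whorl - 1)), or exact when `fixed_counts`.
#' @param fixed_counts use the count parameters exactly instead of as
#'   Poisson means (useful for small deterministic fixtures).
#' @param covariate_envelopes named list of `(min, mean, max, sd)` vectors,
#'   see [default_envelopes()].
#' @param response_law one of `"SBL_mixed"`, `"SBD_mixed"`, `"SBL_fixed"`,
#'   `"SBD_fixed"` (the two final mixed models and their fixed-effects
#'   counterparts).
#' @param fixed_effects named vector overriding the law's fixed effects
#'   (`a`, `b`, `c` and the expansion coefficient `a1` or `b1`).
#' @param level1_cov covariance matrix of the primary-branch random effects
#'   (order as in the law's `re1`, e.g. `(b_i, c_i)`).
#' @param level2_var variance of the whorl-level random effect.
#' @param sigma2 residual variance (cm^2 for length, mm^2 for diameter).
#' @param positive_only redraw the residual of any row whose simulated size
#'   is nonpositive (keeps sizes physical but truncates the error law; turn
#'   off for parameter-recovery simulations, which must match the untruncated
#'   generating model). The realized rejection rate is recorded.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_trees = 54,
                             branches_per_tree = 717 / 54,
                             whorls_per_branch = NA,
                             obs_per_whorl = 3.15,
                             fixed_counts = FALSE,
                             covariate_envelopes = default_envelopes(),
                             response_law = "SBL_mixed",
                             fixed_effects = NULL,
                             level1_cov = NULL,
                             level2_var = NULL,
                             sigma2 = NULL,
                             positive_only = TRUE,
                             seed = 1L) {
  law <- default_law_params(response_law)
  if (!is.null(fixed_effects)) {
    stopifnot(all(names(fixed_effects) %in% names(law$fixed)))
    law$fixed[names(fixed_effects)] <- fixed_effects
  }
  if (!is.null(level1_cov)) law$level1_cov <- level1_cov
  if (!is.null(level2_var)) law$level2_var <- level2_var
  if (!is.null(sigma2)) law$sigma2 <- sigma2
  d1 <- law$level1_cov
  if (length(d1)) {
    if (!isSymmetric(unname(d1)) || any(eigen(d1, TRUE, TRUE)$values < -1e-12))
      stop("level1_cov must be symmetric positive semidefinite")
  }
  stopifnot(law$level2_var >= 0, law$sigma2 >= 0)
  for (nm in names(covariate_envelopes))
    if (!env_ok(covariate_envelopes[[nm]]))
      stop("bad envelope for ", nm, " (need min <= mean <= max, sd >= 0)")
  structure(list(
    n_trees = n_trees, branches_per_tree = branches_per_tree,
    whorls_per_branch = whorls_per_branch, obs_per_whorl = obs_per_whorl,
    fixed_counts = fixed_counts, covariate_envelopes = covariate_envelopes,
    response_law = response_law, law = law,
    positive_only = positive_only, seed = as.integer(seed)),
    class = "generator_config")
}

#' Generate a hierarchical secondary-branch dataset
#'
#' Draws trees (six even-aged stands), primary branches with age-linked
#' positions along the crown, annual secondary-branch whorls along each
#' primary branch, and branch sizes from the configured response law with
#' primary-branch random effects `(b_i, c_i) ~ N(0, D1)`, whorl effects
#' `b_ij ~ N(0, D2)` and residuals `e_ijk ~ N(0, sigma^2)`.
#'
#' @param config a [generator_config()].
#' @return a `branch_dataset` list with elements `trees`, `primaries`,
#'   `secondaries` (data frames), `truth` (drawn random effects and the
#'   conditional mean of every row), `rejection_rate`, and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  env <- config$covariate_envelopes
  law <- config$law

  # -- trees: six even-aged stands cycled over the sample
  nt <- config$n_trees
  stand_ages <- c(28, 40, 46, 53, 64, 70)
  age <- rep_len(rep(stand_ages, each = max(1, ceiling(nt / 6))), nt)
  HT <- draw_env(nt, env$HT)
  DBH <- draw_env(nt, env$DBH)
  CW <- draw_env(nt, env$CW)
  HBLC <- rtnorm(nt, env$HBLC[2], env$HBLC[4],
                 env$HBLC[1], pmin(env$HBLC[3], 0.85 * HT))
  trees <- data.frame(
    tree_id = seq_len(nt), age = age, DBH = DBH, HT = HT, CW = CW,
    HBLC = HBLC, CL = HT - HBLC, CR = (HT - HBLC) / HT, HD = HT / DBH)

  # -- primary branches
  nb <- if (config$fixed_counts) rep(as.integer(config$branches_per_tree), nt)
        else pmax(1L, stats::rpois(nt, config$branches_per_tree))
  tree_of <- rep(trees$tree_id, nb)
  np <- sum(nb)
  PAGE <- round(draw_env(np, env$PAGE))
  PAGE <- pmin(pmax(PAGE, env$PAGE[1]), env$PAGE[3])
  # older (deeper) branches are longer; log-linear diameter from length
  pbl_mu <- env$PBL[2] * (PAGE / env$PAGE[2])^0.6
  PBL <- rtnorm(np, pbl_mu, env$PBL[4] * 0.6, env$PBL[1], env$PBL[3])
  PBD <- exp(-1.0 + 0.8 * log(PBL) + stats::rnorm(np, 0, 0.25))
  PBD <- pmin(pmax(PBD, env$PBD[1]), env$PBD[3])
  PBC <- PBL * stats::runif(np, 0.85, 1)
  PAZ <- stats::runif(np, 0, 360)
  PVA <- draw_env(np, env$PVA)
  # depth in the crown increases with branch age
  max_page <- stats::ave(PAGE, tree_of, FUN = max)
  CLcm <- 100 * trees$CL[match(tree_of, trees$tree_id)]
  PDINC <- CLcm * pmin((PAGE - stats::runif(np)) / max_page, 1)
  PDINC <- pmax(PDINC, 1)
  primaries <- data.frame(
    tree_id = tree_of, branch_id = seq_len(np), PAGE = PAGE, PBL = PBL,
    PBD = PBD, PBC = PBC, PAZ = PAZ, PVA = PVA, PDINC = PDINC)

  # -- secondary branches: one annual whorl per age class along the branch
  nwh <- if (is.na(config$whorls_per_branch)) pmax(1L, PAGE - 1L)
         else rep(as.integer(config$whorls_per_branch), np)
  br_row <- rep(seq_len(np), nwh)
  whorl_id <- unlist(lapply(nwh, seq_len), use.names = FALSE)
  nobs_w <- if (config$fixed_counts)
    rep(as.integer(config$obs_per_whorl), length(br_row))
  else 1L + stats::rpois(length(br_row), max(config$obs_per_whorl - 1, 0))
  srow <- rep(seq_along(br_row), nobs_w)
  ns <- length(srow)
  b_of <- br_row[srow]                         # primary-branch row per obs
  w_of <- whorl_id[srow]                       # whorl index per obs
  nwh_of <- nwh[b_of]
  # whorl j sits at relative depth j/(n+1) with jitter; whorl 1 is youngest
  rel <- (w_of - stats::runif(ns, 0.05, 0.6)) / (nwh_of + 1)
  SDINC <- pmin(pmax(rel * PBL[b_of], 0.5), PBL[b_of])
  SAGE <- w_of
  secondaries <- data.frame(
    tree_id = tree_of[b_of], branch_id = b_of, whorl_id = w_of,
    obs_id = sequence(nobs_w),
    SAGE = SAGE, SDINC = SDINC,
    PAGE = PAGE[b_of], PBL = PBL[b_of], PBD = PBD[b_of], PDINC = PDINC[b_of])

  # -- random effects and response
  q1 <- length(law$re1)
  re1 <- matrix(0, np, max(q1, 1), dimnames = list(NULL, if (q1) law$re1 else "none"))
  if (q1 && any(diag(law$level1_cov) > 0)) {
    L <- chol_psd(law$level1_cov)
    re1[, law$re1] <- matrix(stats::rnorm(np * q1), np) %*% t(L)
  }
  nw <- length(br_row)                         # one effect per (branch, whorl)
  re2 <- if (length(law$re2) && law$level2_var > 0)
    stats::rnorm(nw, 0, sqrt(law$level2_var)) else numeric(nw)

  pn <- spec_param_names(law$spec)
  offs <- matrix(0, ns, length(pn), dimnames = list(NULL, pn))
  if (q1) for (p in law$re1) offs[, p] <- offs[, p] + re1[b_of, p]
  if (length(law$re2)) offs[, law$re2] <- offs[, law$re2] + re2[srow]

  mu <- spec_evaluate(law$spec, law$fixed, secondaries, offsets = offs)
  e <- stats::rnorm(ns, 0, sqrt(law$sigma2))
  y <- mu + e
  nredraw <- 0L
  if (config$positive_only && law$sigma2 > 0) {
    for (it in 1:1000) {
      bad <- which(y <= 0)
      if (!length(bad)) break
      nredraw <- nredraw + length(bad)
      y[bad] <- mu[bad] + stats::rnorm(length(bad), 0, sqrt(law$sigma2))
    }
    y[y <= 0] <- 0.1    # pathological rows (mu << 0): floor at a token size
  }
  secondaries[[law$response]] <- y
  other <- setdiff(c("SBL", "SBD"), law$response)
  # companion size kept loosely allometric so both columns are populated
  secondaries[[other]] <- if (law$response == "SBL")
    pmax(0.4, 0.9 * y^0.62 * exp(stats::rnorm(ns, 0, 0.15)))
  else pmax(0.5, 3.2 * y^1.35 * exp(stats::rnorm(ns, 0, 0.2)))

  structure(list(
    trees = trees, primaries = primaries, secondaries = secondaries,
    truth = list(ranef1 = data.frame(branch_id = seq_len(np),
                                     re1[, seq_len(q1), drop = FALSE]),
                 ranef2 = data.frame(branch_id = br_row, whorl_id = whorl_id,
                                     effect = re2),
                 mu = mu, response = law$response),
    rejection_rate = nredraw / ns,
    config = config), class = "branch_dataset")
}

# Cholesky factor tolerating semidefinite input
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  t(ev$vectors %*% (sqrt(ev$values) * t(ev$vectors)))
}

#' @export
print.branch_dataset <- function(x, ...) {
  cat("branch_dataset:", nrow(x$trees), "trees,", nrow(x$primaries),
      "primary branches,", nrow(x$secondaries), "secondary branches\n")
  if (!is.null(x$config))
    cat("  response law:", x$config$response_law,
        "| redraw rate:", signif(x$rejection_rate, 3), "\n")
  invisible(x)
}

dataset_columns <- c("tree_id", "branch_id", "whorl_id", "obs_id", "age",
                     "DBH", "HT", "CW", "HBLC", "CL", "CR", "HD",
                     "PAGE", "PBL", "PBD", "PBC", "PAZ", "PVA", "PDINC",
                     "SAGE", "SDINC", "SBL", "SBD")

#' Flatten a branch dataset to one row per secondary branch
#'
#' Joins the tree and primary-branch covariates onto the secondary-branch
#' records, producing the flat modelling table used by all fitting routines.
#' @param ds a `branch_dataset`.
#' @export
dataset_table <- function(ds) {
  tr <- ds$trees[match(ds$secondaries$tree_id, ds$trees$tree_id), ]
  pb <- ds$primaries[match(ds$secondaries$branch_id, ds$primaries$branch_id), ]
  out <- cbind(
    ds$secondaries[c("tree_id", "branch_id", "whorl_id", "obs_id")],
    tr[c("age", "DBH", "HT", "CW", "HBLC", "CL", "CR", "HD")],
    pb[c("PAGE", "PBL", "PBD", "PBC", "PAZ", "PVA", "PDINC")],
    ds$secondaries[c("SAGE", "SDINC", "SBL", "SBD")])
  rownames(out) <- NULL
  out[dataset_columns]
}

#' Write / read a branch dataset as delimited text
#'
#' The on-disk format is a UTF-8 comma-separated file with a header row and
#' the flat column schema of [dataset_table()]. `read_dataset()` validates
#' the schema and the structural invariants and reconstructs the
#' three-level dataset.
#' @param ds a `branch_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(dataset_table(ds), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(dataset_columns, names(df))
  if (length(miss))
    stop("dataset file missing column(s): ", paste(miss, collapse = ", "))
  for (cl in dataset_columns) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))
      stop("non-numeric value in column ", cl, " at data row ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  ds <- table_to_dataset(df)
  validate_dataset(ds)
  ds
}

# split a flat table back into tree / primary / secondary records
table_to_dataset <- function(df) {
  tr <- df[!duplicated(df$tree_id),
           c("tree_id", "age", "DBH", "HT", "CW", "HBLC", "CL", "CR", "HD")]
  pb <- df[!duplicated(df$branch_id),
           c("tree_id", "branch_id", "PAGE", "PBL", "PBD", "PBC",
             "PAZ", "PVA", "PDINC")]
  sec <- df[c("tree_id", "branch_id", "whorl_id", "obs_id",
              "SAGE", "SDINC", "PAGE", "PBL", "PBD", "PDINC", "SBL", "SBD")]
  rownames(tr) <- rownames(pb) <- rownames(sec) <- NULL
  structure(list(trees = tr, primaries = pb, secondaries = sec,
                 truth = NULL, rejection_rate = NA_real_, config = NULL),
            class = "branch_dataset")
}

#' Validate the structural invariants of a branch dataset
#'
#' Checks foreign keys, positivity of sizes, `SDINC <= PBL` of the parent
#' branch, `SAGE <= PAGE`, and the tree-level identities
#' `CL = HT - HBLC > 0`, `CR = CL/HT`.
#' @param ds a `branch_dataset`.
#' @return invisibly `TRUE`; stops with a row-identifying message otherwise.
#' @export
validate_dataset <- function(ds) {
  fail <- function(rows, what)
    stop("invalid dataset: ", what, " at secondary row(s) ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) " ...", call. = FALSE)
  s <- ds$secondaries
  if (anyNA(match(s$branch_id, ds$primaries$branch_id)))
    fail(which(is.na(match(s$branch_id, ds$primaries$branch_id))),
         "unresolved branch_id")
  if (anyNA(match(s$tree_id, ds$trees$tree_id)))
    fail(which(is.na(match(s$tree_id, ds$trees$tree_id))), "unresolved tree_id")
  pb <- ds$primaries[match(s$branch_id, ds$primaries$branch_id), ]
  bad <- which(s$SDINC <= 0 | s$SDINC > pb$PBL + 1e-9)
  if (length(bad)) fail(bad, "SDINC outside (0, parent PBL]")
  bad <- which(s$SAGE > pb$PAGE)
  if (length(bad)) fail(bad, "SAGE exceeds parent PAGE")
  bad <- which(s$SBL <= 0 | s$SBD <= 0)
  if (length(bad)) fail(bad, "nonpositive branch size")
  tr <- ds$trees
  if (any(abs(tr$CL - (tr$HT - tr$HBLC)) > 1e-6) || any(tr$CL <= 0))
    stop("invalid dataset: tree CL must equal HT - HBLC and be positive",
         call. = FALSE)
  invisible(TRUE)
}
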