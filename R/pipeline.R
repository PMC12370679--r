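# One-command orchestration of the full analysis over generated (or
# supplied) crown data: generate -> screen -> covariates -> nlme ->
# allometry -> profile, every numeric table written as delimited text with
# a run manifest.

#' Run the secondary-branch analysis pipeline
#'
#' Executes the requested stages in dependency order on a generated or
#' user-supplied dataset and writes each result as a CSV table under
#' `out_dir`, together with a `manifest.txt` recording the seed, stage
#' list, package version and configuration, so a run can be reproduced
#' exactly. All randomness (generation, bootstrap resampling) derives from
#' `seed`; stage substreams are offset deterministically. Rerunning with
#' the same seed rewrites byte-identical tables.
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("generate", "screen", "covariates", "nlme",
#'   "allometry", "profile")`.
#' @param config a [generator_config()] used when `"generate"` is active.
#' @param data_file path to an existing dataset CSV (alternative to
#'   generation).
#' @param seed global seed; overrides `config$seed`.
#' @param bootstrap_B bootstrap replicates for the allometry stage.
#' @param verbose print stage progress.
#' @return (invisibly) a named list with every stage result.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("generate", "screen", "covariates",
                                    "nlme", "allometry", "profile"),
                         config = generator_config(),
                         data_file = NULL,
                         seed = config$seed,
                         bootstrap_B = 3000,
                         verbose = TRUE) {
  all_stages <- c("generate", "screen", "covariates", "nlme", "allometry",
                  "profile")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  emit <- function(tab, name) {
    utils::write.csv(tab, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  res <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("generate" %in% stages) {
    say("generate: hierarchical crown dataset (seed ", seed, ")")
    config$seed <- as.integer(seed)
    ds <- step("generate", generate_dataset(config))
    write_dataset(ds, file.path(out_dir, "dataset.csv"))
    res$dataset <- ds
  } else if (!is.null(data_file)) {
    say("load: ", data_file)
    res$dataset <- step("load", read_dataset(data_file))
  } else stop("either include the 'generate' stage or give data_file")
  ds <- res$dataset
  d <- dataset_table(ds)

  if ("screen" %in% stages) {
    say("screen: 9 candidate functions x {SBL, SBD}")
    scr <- step("screen", list(SBL = screen_candidates(d, response = "SBL"),
                               SBD = screen_candidates(d, response = "SBD")))
    emit(scr$SBL, "screen_SBL"); emit(scr$SBD, "screen_SBD")
    res$screen <- scr
  }

  if ("covariates" %in% stages) {
    say("covariates: expansion search on the M7 base model")
    cov <- step("covariates", list(
      SBL = covariate_search(model_spec("M7"), d,
                             c("PDINC", "PBL", "PBD"), "SBL"),
      SBD = covariate_search(model_spec("M7"), d,
                             c("PDINC", "PBL", "PBD"), "SBD")))
    emit(cov$SBL, "covariates_SBL"); emit(cov$SBD, "covariates_SBD")
    res$covariates <- cov
  }

  if ("nlme" %in% stages) {
    say("nlme: two-level mixed-effects fits (this is the slow stage)")
    fits <- step("nlme", list(
      SBL = fit_nlme(model_spec("M7", c(a = "PDINC")), d, "SBL",
                     re = re_spec(c("b", "c"), "b")),
      SBD = fit_nlme(model_spec("M7", c(b = "PBD")), d, "SBD",
                     re = re_spec(c("b", "c"), "b1"))))
    emit(do.call(rbind, lapply(names(fits), function(nm)
      nlme_report_row(fits[[nm]], nm))), "nlme_fits")
    res$nlme <- fits
  }

  if ("allometry" %in% stages) {
    say("allometry: scaling profiles, B = ", bootstrap_B)
    al <- step("allometry", {
      out <- list()
      for (g in c("PAGE", "SAGE", "tree_age"))
        for (m in c("length", "diameter"))
          out[[paste(g, m, sep = "_")]] <-
            scaling_profile(ds, g, m, B = bootstrap_B,
                            seed = seed + 1000 * match(g, c("PAGE", "SAGE",
                                                            "tree_age")))
      out
    })
    for (nm in names(al)) emit(al[[nm]], paste0("allometry_", nm))
    res$allometry <- al
  }

  if ("profile" %in% stages) {
    say("profile: whorl means, current-year shoots, peak depth")
    pr <- step("profile", list(
      by_page = whorl_means(ds, "PAGE"),
      by_sage = whorl_means(ds, "SAGE"),
      by_depth = whorl_means(ds, "depth"),
      current_year = current_year_shoots(ds),
      peak_length = inflection_point(ds, "length"),
      peak_diameter = inflection_point(ds, "diameter")))
    emit(pr$by_page, "profile_by_PAGE")
    emit(pr$by_sage, "profile_by_SAGE")
    emit(pr$by_depth, "profile_by_depth")
    emit(pr$current_year, "profile_current_year")
    emit(data.frame(measure = c("length", "diameter"),
                    relative_depth = c(pr$peak_length$relative_depth,
                                       pr$peak_diameter$relative_depth),
                    method = c(pr$peak_length$method,
                               pr$peak_diameter$method)),
         "profile_peak_depth")
    res$profile <- pr
  }

  manifest <- c(
    paste("package: secbranch", as.character(utils::packageVersion("secbranch"))),
    paste("R:", R.version.string),
    paste("date:", format(Sys.Date())),
    paste("seed:", seed),
    paste("stages:", paste(stages, collapse = ", ")),
    paste("bootstrap_B:", bootstrap_B),
    paste("response_law:", config$response_law),
    paste("n_trees:", config$n_trees),
    paste("config_hash:",
          sum(utils::head(utf8ToInt(paste(deparse(config), collapse = "")),
                          10000) * 31L %% .Machine$integer.max)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  say("done: ", length(stages), " stage(s) written to ", out_dir)
  invisible(res)
}

# one delimited report row per mixed-effects fit
nlme_report_row <- function(f, label) {
  d1 <- if (!is.null(f$D1)) diag(f$D1) else c(NA, NA)
  data.frame(model = label,
             a = f$beta[["a"]], b = f$beta[["b"]], c = f$beta[["c"]],
             a1 = if ("a1" %in% names(f$beta)) f$beta[["a1"]] else NA,
             b1 = if ("b1" %in% names(f$beta)) f$beta[["b1"]] else NA,
             sigma2 = f$sigma2,
             var_L1_1 = d1[1], var_L1_2 = d1[2],
             corr_L1 = if (!is.null(f$D1) && nrow(f$D1) == 2)
               stats::cov2cor(f$D1)[1, 2] else NA,
             var_L2 = if (!is.null(f$D2)) f$D2[1, 1] else NA,
             MAE = f$MAE, RMSE = f$RMSE, Ra2 = f$Ra2,
             logLik = f$logLik, AIC = f$AIC, converged = f$converged)
}
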