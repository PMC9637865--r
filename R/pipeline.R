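# End-to-end pipeline: simulate (or load) a cohort, fit normative models and
# collect out-of-fold deviation scores, decompose the behavioral blocks,
# and run the deviation-behavior association grid. Driven by a YAML config;
# every stage output is written as delimited text and summarized in a JSON
# run report.

#' Default pipeline configuration
#'
#' @param n Cohort size for the simulate stage.
#' @param seed Global seed, expanded into per-stage substreams.
#' @param output_dir Where stage outputs are written (`NULL` = nowhere).
#' @return Nested list matching the YAML config schema.
#' @export
default_config <- function(n = 500L, seed = 1L, output_dir = NULL) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    input = NULL,                   # path to a cohort CSV; NULL = simulate
    simulate = list(
      n_subjects = as.integer(n),
      age_range = c(8, 22),
      effects = list(list(feature = "FA", domain = 4L, beta = -0.1))
    ),
    normative = list(
      features = c("FA", "MD", "RD", "L1", "CT", "SA"),
      k_folds = 10L,
      n_interior_knots = 3L,
      degree = 3L
    ),
    decompose = list(
      n_components = 7L,
      n_runs = 20L
    ),
    associate = list(
      prior_sd = 1.0,
      draws = 4000L
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg Config list.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    errs <- c(errs, "seed: must be set")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    errs <- c(errs, sprintf("input: file '%s' does not exist", cfg$input))
  if (is.null(cfg$input)) {
    if (is.null(cfg$simulate$n_subjects) || cfg$simulate$n_subjects < 10)
      errs <- c(errs, "simulate.n_subjects: must be >= 10")
    ar <- cfg$simulate$age_range
    if (length(ar) != 2 || ar[1] >= ar[2])
      errs <- c(errs, "simulate.age_range: must be increasing pair")
  }
  if (cfg$normative$k_folds < 2)
    errs <- c(errs, "normative.k_folds: must be >= 2")
  if (cfg$normative$n_interior_knots < 1)
    errs <- c(errs, "normative.n_interior_knots: must be >= 1")
  if (cfg$decompose$n_components < 1)
    errs <- c(errs, "decompose.n_components: must be >= 1")
  if (cfg$decompose$n_runs < 1)
    errs <- c(errs, "decompose.n_runs: must be >= 1")
  if (cfg$associate$prior_sd <= 0)
    errs <- c(errs, "associate.prior_sd: must be > 0")
  if (cfg$associate$draws < 1000)
    errs <- c(errs, "associate.draws: must be >= 1000")
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  invisible(cfg)
}

#' Validate a cohort table
#'
#' Enforces the header contract (subject_id, age, sex, the six brain
#' features, cog_01..cog_14, psy_001..psy_129), coerces numerics, maps sex
#' codes through `sex_codes`, drops rows with any missing value
#' (complete-case rule) or out-of-range age, and reports what was dropped.
#'
#' @param table A data.frame or path to a delimited text file.
#' @param age_range Permitted age bounds (years).
#' @param sex_codes Named mapping of raw sex codes to \{0,1\}, e.g.
#'   `c("0" = 0, "1" = 1)` or `c(M = 1, F = 0)`.
#' @param features Brain feature column names expected.
#' @return The filtered cohort (class `cohort_table`), with attributes
#'   `n_dropped` and `drop_reasons`.
#' @export
validate_cohort <- function(table, age_range = c(8, 22),
                            sex_codes = c("0" = 0, "1" = 1),
                            features = c("FA", "MD", "RD", "L1", "CT", "SA")) {
  df <- if (is.character(table)) read_cohort(table) else as.data.frame(table)
  required <- c("subject_id", "age", "sex", features,
                sprintf("cog_%02d", 1:14), sprintf("psy_%03d", 1:129))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table is missing required columns: ",
         paste(utils::head(missing_cols, 8), collapse = ", "),
         if (length(missing_cols) > 8) sprintf(" (+%d more)", length(missing_cols) - 8))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id values")

  sex_chr <- as.character(df$sex)
  unknown <- setdiff(unique(sex_chr), names(sex_codes))
  if (length(unknown))
    stop("unknown sex code(s): ", paste(unknown, collapse = ", "))
  df$sex <- as.numeric(sex_codes[sex_chr])

  num_cols <- setdiff(required, "subject_id")
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))

  reasons <- character(0)
  incomplete <- !stats::complete.cases(df[required])
  if (any(incomplete))
    reasons <- c(reasons, sprintf("%d row(s) dropped: missing values", sum(incomplete)))
  bad_age <- !incomplete & (df$age < age_range[1] | df$age > age_range[2])
  if (any(bad_age))
    reasons <- c(reasons, sprintf("%d row(s) dropped: age outside [%g, %g]",
                                  sum(bad_age), age_range[1], age_range[2]))
  keep <- !incomplete & !bad_age
  if (!any(keep)) stop("no rows left after complete-case and range filtering")
  for (msg in reasons) message(msg)

  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "drop_reasons") <- reasons
  attr(out, "age_range") <- age_range
  out
}

# effects entries in config -> effect_spec list
config_effects <- function(effects) {
  lapply(effects, function(e) {
    dom <- if (identical(e$domain, "general")) "general" else as.integer(e$domain)
    effect_spec(e$feature, dom, e$beta)
  })
}

#' Run the full pipeline
#'
#' Stages: simulate (or load + validate) the cohort; normative models with
#' k-fold out-of-fold deviation Z-scores for the six brain features and the
#' cognitive general factor; ICA psychopathology domains plus the general
#' proxy; deviation-score correlation matrix; Bayesian association grid.
#' All randomness derives from `cfg$seed` through fixed per-stage
#' substreams, so identical configs give identical outputs.
#'
#' @param cfg Config list (see [default_config()]) or a YAML path.
#' @return List of class `run_report`: `cohort`, `deviations`, `metrics`,
#'   `domains`, `correlations`, `associations`, `report` (serializable
#'   summary). If `cfg$output_dir` is set, all stage tables and
#'   `report.json` are written there.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  t0 <- Sys.time()
  ss <- seed_substreams(cfg$seed, 4L)
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # --- stage 1: cohort -----------------------------------------------------
  if (is.null(cfg$input)) {
    cohort <- generate_cohort(
      n = cfg$simulate$n_subjects,
      trajectories = default_trajectories(cfg$simulate$age_range),
      dev_structure = default_deviation_structure(),
      effects = config_effects(cfg$simulate$effects),
      seed = ss[1])
    age_range <- cfg$simulate$age_range
  } else {
    age_range <- if (!is.null(cfg$simulate$age_range)) cfg$simulate$age_range else c(8, 22)
    cohort <- validate_cohort(cfg$input, age_range = age_range)
  }

  # --- stage 2: behavioral decomposition (cognition first: COG feeds the
  # normative stage like a brain feature) ----------------------------------
  cogf <- cognitive_general_factor(cohort[, sprintf("cog_%02d", 1:14)])
  cohort$COG <- cogf$scores
  domains <- withCallingHandlers(
    ica_domains(cohort[, sprintf("psy_%03d", 1:129)],
                n_components = cfg$decompose$n_components,
                n_runs = cfg$decompose$n_runs, seed = ss[2]),
    warning = log_warn)

  # --- stage 3: normative models + out-of-fold deviations ------------------
  features <- c(cfg$normative$features, "COG")
  norm <- withCallingHandlers(
    crossval_deviations_multi(cohort, features,
                              k = cfg$normative$k_folds, seed = ss[3],
                              n_interior_knots = cfg$normative$n_interior_knots,
                              degree = cfg$normative$degree),
    warning = log_warn)

  # --- stage 4: associations ----------------------------------------------
  dev_tab <- norm$deviations
  corr <- correlation_matrix(dev_tab[, paste0(features, "_dev")])
  brain_devs <- dev_tab[, c("subject_id",
                            paste0(cfg$normative$features, "_dev"))]
  assoc <- run_association_grid(
    brain_devs, domains$weights, domains$general,
    cog_dev = dev_tab$COG_dev, age = cohort$age, sex = cohort$sex,
    prior_sd = cfg$associate$prior_sd, seed = ss[4])

  report <- list(
    config = cfg,
    n_subjects = nrow(cohort),
    seeds = list(global = cfg$seed, cohort = ss[1], decompose = ss[2],
                 normative = ss[3], associate = ss[4]),
    cognitive_factor = list(variance_explained = cogf$variance_explained),
    ica_stability = as.list(domains$stability),
    normative_metrics = norm$metrics,
    deviation_correlations = list(labels = corr$labels, r = corr$r),
    association_summary = list(
      n_models = nrow(assoc),
      extreme_alternative = sum(assoc$BF01 < 0.01),
      strongest = assoc[which.min(assoc$BF01),
                        c("feature", "domain", "B", "BF01", "label")]),
    warnings = warnings_log,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("normdev"))
  )

  out <- list(cohort = cohort, cognitive_factor = cogf, domains = domains,
              deviations = dev_tab, deviations_long = norm$long,
              metrics = norm$metrics, correlations = corr,
              associations = assoc, report = report)
  class(out) <- "run_report"

  if (!is.null(cfg$output_dir)) write_outputs(out, cfg$output_dir)
  out
}

# write all stage outputs as delimited text + JSON report
write_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(run$cohort, file.path(dir, "cohort.csv"))
  write_table17(run$deviations, file.path(dir, "deviations.csv"))
  write_table17(run$deviations_long, file.path(dir, "deviations_long.csv"))
  write_table17(run$metrics, file.path(dir, "metrics.csv"))
  dom <- data.frame(subject_id = run$cohort$subject_id,
                    run$domains$weights, general = run$domains$general,
                    check.names = FALSE)
  write_table17(dom, file.path(dir, "domain_scores.csv"))
  write_table17(data.frame(item = rownames(run$domains$mixing),
                           run$domains$mixing, check.names = FALSE),
                file.path(dir, "item_loadings.csv"))
  write_table17(data.frame(component = names(run$domains$stability),
                           stability = run$domains$stability),
                file.path(dir, "stability.csv"))
  write_table17(data.frame(label = run$correlations$labels,
                           run$correlations$r, check.names = FALSE),
                file.path(dir, "correlations.csv"))
  stars <- run$correlations$stars
  write_table17(data.frame(label = rownames(stars), stars, check.names = FALSE),
                file.path(dir, "correlation_stars.csv"))
  write_table17(run$associations, file.path(dir, "associations.csv"))
  # drop non-serializable internals from the report
  rep <- run$report
  rep$deviation_correlations$r <- as.data.frame(rep$deviation_correlations$r)
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null", force = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("normdev pipeline run: %d subjects\n", x$report$n_subjects))
  cat(sprintf("cognitive general factor: %.1f%% of battery variance\n",
              100 * x$cognitive_factor$variance_explained))
  cat("out-of-sample explained variance by feature:\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-4s %5.1f%%  (SMSE %.3f, MSLL %+.3f, rho %.3f)\n",
                m$feature[i], 100 * m$explained_variance[i], m$smse[i],
                m$msll[i], m$rho[i]))
  cat(sprintf("ICA stability: %s\n",
              paste(sprintf("%.2f", x$domains$stability), collapse = " ")))
  s <- x$report$association_summary
  cat(sprintf("association grid: %d models, %d with extreme evidence (BF01 < 0.01)\n",
              s$n_models, s$extreme_alternative))
  cat(sprintf("strongest association: %s ~ %s  (B = %+.3f, BF01 = %.3g, %s)\n",
              s$strongest$feature, s$strongest$domain, s$strongest$B,
              s$strongest$BF01, s$strongest$label))
  invisible(x)
}
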