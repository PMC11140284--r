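#' Read a cohort table from CSV
#'
#' Accepts the wide layout (`id, vision_w1..vision_w<p>, ...predictors,
#' outcomes, [true_class]`) or the long layout (`id, wave, vision`), which
#' is pivoted to wide. Empty fields become missing values.
#'
#' @param path CSV file path.
#' @param n_waves expected number of waves.
#' @param time_scores wave time scores attached to the result.
#' @param format `"auto"` (detect by columns), `"wide"` or `"long"`.
#' @return A `cohort` data frame.
#' @export
read_cohort_csv <- function(path, n_waves = 4L,
                            time_scores = seq_len(n_waves) - 1,
                            format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if (all(c("wave", "vision") %in% names(raw))) "long" else "wide"
  if (format == "long") {
    need <- setdiff(c("id", "wave", "vision"), names(raw))
    if (length(need))
      stop("missing required column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    ids <- unique(raw$id)
    wide <- data.frame(id = ids)
    for (w in seq_len(n_waves)) {
      m <- raw[raw$wave == w, c("id", "vision")]
      wide[[vision_cols(n_waves)[w]]] <- m$vision[match(ids, m$id)]
    }
    raw <- wide
  } else {
    need <- setdiff(c("id", vision_cols(n_waves)), names(raw))
    if (length(need))
      stop("missing required column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  if (anyDuplicated(raw$id))
    stop("duplicate subject ids: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  v <- as.matrix(raw[, vision_cols(n_waves)])
  bad <- which(rowSums(v < 1 | v > 4, na.rm = TRUE) > 0)
  if (length(bad))
    warning("vision values outside [1, 4] in row(s): ",
            paste(utils::head(bad, 20L), collapse = ", "))
  for (nm in names(raw))
    if (is.character(raw[[nm]])) raw[[nm]] <- factor(raw[[nm]])
  as_cohort(raw, n_waves, time_scores)
}

#' Write a cohort table to CSV
#'
#' Wide layout with empty fields for missing values; the `true_class`
#' column can be withheld so downstream consumers cannot see the
#' generating labels.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @param include_true_class keep the generator's `true_class` column?
#' @export
write_cohort_csv <- function(cohort, path, include_true_class = TRUE) {
  out <- as.data.frame(cohort)
  if (!include_true_class) out$true_class <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors [sim_config()] field names; `class_means` is a list of
#' `(intercept, slope)` pairs, `factor_cov` either a 2x2 matrix or a named
#' list with `psi00`, `psi11`, `psi01`. Omitted predictor/outcome specs
#' (or the string `"default"`) fall back to the package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  fc <- cfg$factor_cov
  if (is.list(fc) && !is.null(fc$psi00))
    fc <- matrix(c(fc$psi00, fc$psi01 %||% 0, fc$psi01 %||% 0, fc$psi11),
                 2, 2)
  if (is.list(fc)) fc <- do.call(rbind, fc)
  cm <- cfg$class_means
  if (is.list(cm)) cm <- do.call(rbind, lapply(cm, unlist))
  args <- list(
    n_subjects = cfg$n_subjects %||% 2235,
    class_proportions = unlist(cfg$class_proportions) %||% c(0.819, 0.181),
    censor_to_scale = isTRUE(cfg$censor_to_scale),
    missing_rate = cfg$missing_rate %||% 0)
  if (!is.null(cfg$n_waves)) args$n_waves <- cfg$n_waves
  if (!is.null(cfg$time_scores)) args$time_scores <- unlist(cfg$time_scores)
  if (!is.null(cm)) args$class_means <- cm
  if (!is.null(fc)) args$factor_cov <- fc
  if (!is.null(cfg$residual_var)) args$residual_var <- unlist(cfg$residual_var)
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(cfg$predictor_specs) &&
      !identical(cfg$predictor_specs, "default"))
    args$predictor_specs <- cfg$predictor_specs
  if (!is.null(cfg$outcome_specs) && !identical(cfg$outcome_specs, "default"))
    args$outcome_specs <- cfg$outcome_specs
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Bundles every setting of the five-stage trajectory workflow. Supply
#' either `input` (a cohort CSV path or cohort data frame) or `sim` (a
#' [sim_config()] to generate one).
#'
#' @param input cohort CSV path or cohort data frame, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param n_waves,time_scores growth design.
#' @param K_max,alpha,min_share,B,n_starts,boot_starts enumeration settings
#'   (see [enumerate_classes()]).
#' @param allow_partial,min_waves inclusion rule (complete cases by
#'   default).
#' @param screening_threshold univariate selection threshold.
#' @param model2_covariates adjustment set for the adjusted distal models.
#' @param outcomes named list of distal outcomes mapping name to
#'   `"linear"` or `"logistic"`.
#' @param spline optional list `list(exposure=, ref=, n_knots=)` for the
#'   dose-response analysis.
#' @param mi_m imputations for models on incomplete predictors (0 = none).
#' @param seed master seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, n_waves = 4L,
                            time_scores = seq_len(n_waves) - 1,
                            K_max = 4L, alpha = 0.05, min_share = 0.05,
                            B = 100L, n_starts = 50L, boot_starts = 5L,
                            allow_partial = FALSE, min_waves = 3L,
                            screening_threshold = 0.05,
                            model2_covariates = c("female", "urban_birth",
                                                  "residence", "professional",
                                                  "educated", "economic_good",
                                                  "married"),
                            outcomes = list(cognition = "linear",
                                            adl = "linear", iadl = "linear",
                                            depression = "linear",
                                            anxiety = "linear",
                                            fall = "logistic"),
                            spline = list(exposure = "bmi", ref = 21.0,
                                          n_knots = 4L),
                            mi_m = 5L, seed = 1L) {
  if (is.null(input) && is.null(sim))
    stop("provide either an input cohort or a simulation config",
         call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the five-stage trajectory pipeline
#'
#' Executes, in order: cohort loading or simulation; the inclusion filter
#' (complete-case, or at-least-`min_waves`); the one-class growth-curve
#' fit with fit indices; class enumeration; label assignment with the
#' class mean trajectory table; univariate screening; the multivariable
#' logistic model of class membership on the screened predictors (plus the
#' optional spline dose-response); and the unadjusted (model 1) and
#' adjusted (model 2) distal-outcome models. Each stage is recorded in the
#' bundle; a failing stage marks the bundle failed there while preserving
#' earlier stages. With a one-class selection the class-contrast stages
#' are skipped with an explanatory trace.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `vistraj_pipeline`: named stage results,
#'   `status`, and a `log` of stage messages.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list(stages = list(), status = "ok", failed_stage = NULL,
                 log = character(0), seed = config$seed)
  note <- function(...) bundle$log <<- c(bundle$log, sprintf(...))
  run_stage <- function(name, expr) {
    if (!identical(bundle$status, "ok")) return(invisible(NULL))
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      bundle$status <<- "failed"
      bundle$failed_stage <<- name
      note("stage %s FAILED: %s", name, conditionMessage(res))
    } else {
      bundle$stages[[name]] <<- res
      note("stage %s done", name)
    }
    invisible(NULL)
  }
  set.seed(config$seed)
  design <- growth_design(config$n_waves, config$time_scores)

  run_stage("cohort", {
    if (!is.null(config$input)) {
      if (is.character(config$input))
        read_cohort_csv(config$input, config$n_waves, config$time_scores)
      else config$input
    } else simulate_cohort(config$sim)
  })
  run_stage("filter", {
    cohort <- bundle$stages$cohort
    kept <- if (config$allow_partial) min_waves_filter(cohort,
                                                      config$min_waves)
            else complete_cases(cohort)
    note("retained %d of %d subjects", nrow(kept), nrow(cohort))
    kept
  })
  run_stage("growth_curve", {
    lgcm(bundle$stages$filter, design, allow_partial = config$allow_partial,
         min_waves = config$min_waves)
  })
  run_stage("enumeration", {
    enumerate_classes(bundle$stages$filter, design, K_max = config$K_max,
                      alpha = config$alpha, min_share = config$min_share,
                      B = config$B, seed = config$seed,
                      n_starts = config$n_starts,
                      boot_starts = config$boot_starts,
                      allow_partial = config$allow_partial,
                      min_waves = config$min_waves)
  })
  run_stage("trajectories", {
    enum <- bundle$stages$enumeration
    fit <- enum$fits[[enum$selected_K]]
    mt <- fit$params$class_means %*% t(design$lambda)
    data.frame(class = class_label_names(fit),
               proportion = fit$params$pi,
               stats::setNames(as.data.frame(mt),
                               paste0("mean_wave", seq_len(design$n_waves))))
  })
  if (identical(bundle$status, "ok") &&
      bundle$stages$enumeration$selected_K == 1L) {
    bundle$log <- c(bundle$log,
      "single trajectory class selected: screening, predictor and distal class-contrast stages skipped")
    class(bundle) <- "vistraj_pipeline"
    return(bundle)
  }
  run_stage("labels", {
    enum <- bundle$stages$enumeration
    assign_labels(enum$fits[[enum$selected_K]])
  })
  run_stage("screening", {
    cohort <- bundle$stages$filter
    screen_predictors(cohort, bundle$stages$labels,
                      threshold = config$screening_threshold)
  })
  run_stage("predictors", {
    scr <- bundle$stages$screening
    cohort <- bundle$stages$filter
    sel <- scr$variable[scr$selected]
    if (!length(sel)) stop("no predictor passed screening", call. = FALSE)
    idx <- attr(bundle$stages$labels, "class_index")
    outcome <- as.integer(idx == 1L)  # 1 = high-baseline decline
    has_na <- any(vapply(cohort[sel], anyNA, TRUE))
    if (has_na && config$mi_m > 0L)
      impute_and_pool(cohort, outcome, sel, model = "logistic",
                      m = config$mi_m, seed = config$seed)
    else logistic_fit(cohort, outcome, sel)
  })
  if (!is.null(config$spline)) run_stage("dose_response", {
    cohort <- bundle$stages$filter
    idx <- attr(bundle$stages$labels, "class_index")
    sp <- config$spline
    covs <- intersect(config$model2_covariates, names(cohort))
    rcs_dose_response(cohort, sp$exposure, as.integer(idx == 1L),
                      covariates = covs,
                      knots = rcs_knots(cohort[[sp$exposure]],
                                        sp$n_knots %||% 4L),
                      ref = sp$ref)
  })
  run_stage("outcomes", {
    cohort <- bundle$stages$filter
    idx <- attr(bundle$stages$labels, "class_index")
    cohort$high_baseline_decline <- as.integer(idx == 1L)
    covs <- intersect(config$model2_covariates, names(cohort))
    rows <- lapply(names(config$outcomes), function(nm) {
      kind <- config$outcomes[[nm]]
      fitter <- if (kind == "logistic") logistic_fit else linear_fit
      m1 <- fitter(cohort, nm, "high_baseline_decline")
      m2 <- fitter(cohort, nm, "high_baseline_decline", covariates = covs)
      r1 <- m1[m1$term == "high_baseline_decline", ]
      r2 <- m2[m2$term == "high_baseline_decline", ]
      data.frame(outcome = nm, model_kind = kind,
                 model1_estimate = r1$estimate, model1_low = r1$ci_low,
                 model1_high = r1$ci_high, model1_p = r1$p_value,
                 model2_estimate = r2$estimate, model2_low = r2$ci_low,
                 model2_high = r2$ci_high, model2_p = r2$p_value)
    })
    do.call(rbind, rows)
  })
  class(bundle) <- "vistraj_pipeline"
  bundle
}

#' @export
print.vistraj_pipeline <- function(x, ...) {
  cat("Trajectory pipeline:", x$status,
      if (!is.null(x$failed_stage)) paste("at stage", x$failed_stage), "\n")
  cat("Stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$stages$enumeration))
    cat("Selected K =", x$stages$enumeration$selected_K, "\n")
  invisible(x)
}

fmt6 <- function(df) {
  for (nm in names(df)) if (is.numeric(df[[nm]]))
    df[[nm]] <- signif(df[[nm]], 6)
  df
}

#' Write the pipeline report bundle to disk
#'
#' One CSV per result table (growth-curve fit indices, enumeration,
#' class trajectories, screening, predictor model, distal-outcome models),
#' a master JSON summary with stage statuses, seed and selection trace,
#' and a plain-text log. Floats are written at 6 significant digits.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L)
    stop("directory not writable: ", outdir, call. = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(fmt6(df), p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  st <- bundle$stages
  if (!is.null(st$growth_curve)) {
    fi <- st$growth_curve$fit
    put(data.frame(chi_square = fi$chi_square, df = fi$df,
                   chi_df_ratio = fi$chi_df_ratio, cfi = fi$cfi,
                   tli = fi$tli, rmsea = fi$rmsea, srmr = fi$srmr,
                   intercept_mean = st$growth_curve$params$alpha[1],
                   slope_mean = st$growth_curve$params$alpha[2],
                   loglik = st$growth_curve$loglik,
                   n = st$growth_curve$n_used), "growth_curve.csv")
  }
  if (!is.null(st$enumeration)) put(st$enumeration$table, "enumeration.csv")
  if (!is.null(st$trajectories)) put(st$trajectories, "trajectories.csv")
  if (!is.null(st$screening))
    put(as.data.frame(st$screening), "screening.csv")
  if (!is.null(st$predictors))
    put(as.data.frame(st$predictors), "predictors.csv")
  if (!is.null(st$outcomes)) put(st$outcomes, "outcomes.csv")
  summary_json <- list(
    status = bundle$status, failed_stage = bundle$failed_stage,
    seed = bundle$seed, stages = names(st),
    selected_K = if (!is.null(st$enumeration)) st$enumeration$selected_K,
    selection_trace = if (!is.null(st$enumeration))
      st$enumeration$selection_trace,
    dose_response_p_nonlinear = if (!is.null(st$dose_response))
      st$dose_response$p_nonlinear,
    package_version = as.character(utils::packageVersion("vistraj")))
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  lp <- file.path(outdir, "run.log")
  writeLines(bundle$log, lp)
  invisible(c(paths, jp, lp))
}
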