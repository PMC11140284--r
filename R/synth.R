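#' Simulation configuration for a synthetic visual-trajectory cohort
#'
#' Builds the parameter set for the synthetic cohort generator. The generator
#' draws each subject's latent class from `class_proportions`, growth factors
#' (intercept, slope) from a bivariate normal around the class means with
#' shared covariance `factor_cov`, and wave-level vision scores as
#' `intercept + slope * time + noise`. Baseline predictors are drawn from
#' class-conditional distributions and distal outcomes from class-shifted
#' linear or logistic models, so every downstream stage of the trajectory
#' workflow can be exercised on data with known ground truth.
#'
#' The defaults emulate a two-class cohort of 2235 older adults measured at
#' four survey waves on a 1-4 vision scale: a large (81.9%) class starting
#' near the scale ceiling and declining, and a small (18.1%) class starting
#' in the impaired range and improving. Variance components (not published
#' for the original cohort) default to `psi00 = 0.06`, `psi11 = 0.004`,
#' `psi01 = 0`, `theta = 0.02`, calibrated so the generating model's
#' relative entropy is 0.998, the classification sharpness reported for
#' the study this structure emulates.
#'
#' @param n_subjects number of subjects.
#' @param n_waves number of measurement waves.
#' @param time_scores numeric vector of wave times (strictly increasing);
#'   the first wave is the trajectory baseline.
#' @param class_proportions probability vector over latent classes.
#' @param class_means matrix with one row per class, columns
#'   `(intercept mean, slope mean)` on the vision scale.
#' @param factor_cov 2x2 growth-factor covariance (shared across classes).
#' @param residual_var wave-level residual variance; length 1 (shared) or
#'   `n_waves` (wave-specific).
#' @param censor_to_scale clamp generated vision scores to `[1, 4]`?
#'   Off by default: recovery experiments use the uncensored model the
#'   estimator assumes; turn on to mimic the bounded ordinal instrument.
#' @param predictor_specs list of predictor specifications, see
#'   [default_predictor_specs()].
#' @param outcome_specs list of distal-outcome specifications, see
#'   [default_outcome_specs()].
#' @param missing_rate MCAR probability that any single vision observation
#'   is masked, in `[0, 1)`.
#' @param seed optional integer seed making generation reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @export
sim_config <- function(n_subjects = 2235,
                       n_waves = 4,
                       time_scores = seq_len(n_waves) - 1,
                       class_proportions = c(0.819, 0.181),
                       class_means = rbind(c(3.992, -0.174),
                                           c(2.641,  0.296)),
                       factor_cov = matrix(c(0.06, 0, 0, 0.004), 2, 2),
                       residual_var = 0.02,
                       censor_to_scale = FALSE,
                       predictor_specs = default_predictor_specs(),
                       outcome_specs = default_outcome_specs(),
                       missing_rate = 0,
                       seed = NULL) {
  class_means <- rbind(class_means)
  K <- length(class_proportions)
  if (K < 1L) stop("at least one class is required", call. = FALSE)
  if (any(class_proportions <= 0))
    stop("class proportions must all be positive", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (nrow(class_means) != K || ncol(class_means) != 2L)
    stop("class_means must be a K x 2 matrix of (intercept, slope) means",
         call. = FALSE)
  if (length(time_scores) != n_waves || any(diff(time_scores) <= 0))
    stop("time_scores must be strictly increasing with one entry per wave",
         call. = FALSE)
  factor_cov <- (factor_cov + t(factor_cov)) / 2
  if (min(eigen(factor_cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10)
    stop("factor_cov must be positive semi-definite", call. = FALSE)
  if (!length(residual_var) %in% c(1L, n_waves) || any(residual_var < 0))
    stop("residual_var must be a non-negative scalar or one value per wave",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_waves = as.integer(n_waves),
    time_scores = as.numeric(time_scores),
    class_proportions = as.numeric(class_proportions),
    class_means = unname(class_means),
    factor_cov = unname(factor_cov),
    residual_var = rep_len(as.numeric(residual_var), n_waves),
    censor_to_scale = isTRUE(censor_to_scale),
    predictor_specs = predictor_specs,
    outcome_specs = outcome_specs,
    missing_rate = as.numeric(missing_rate),
    seed = if (!is.null(seed)) as.integer(seed)
  ), class = "sim_config")
}

#' Default class-conditional predictor specifications
#'
#' One spec per baseline predictor: binary predictors carry one success
#' probability per class, categorical predictors a probability vector per
#' class (rows = classes), continuous predictors a `(mean, sd)` pair per
#' class. Class 1 is the large high-baseline class. Levels whose prevalence
#' differs between classes (age, BMI, sex, residence, education, marital
#' status, economic status, occupation, smoking, drinking, exercise, fruit
#' intake, cataract, glaucoma) are class-dependent; predictors expected to
#' be unrelated to trajectory class (birthplace, insurance, sleep, blood
#' pressure, vegetables, hypertension, diabetes, stroke, heart disease) are
#' generated class-independent so screening has true negatives.
#'
#' @return Named list of predictor specifications.
#' @export
default_predictor_specs <- function() {
  bin <- function(p) list(type = "binary", prob = p)
  cat_ <- function(levels, p) list(type = "categorical", levels = levels,
                                   prob = rbind(p[[1]], p[[2]]))
  cont <- function(mean, sd) list(type = "continuous", mean = mean, sd = sd)
  list(
    age = cont(c(73.4, 78.2), c(8.2, 9.6)),
    bmi = cont(c(21.4, 19.7), c(3.5, 3.1)),
    sleep = cont(c(7.0, 7.0), c(1.8, 1.8)),
    sbp = cont(c(135, 135), c(18, 18)),
    female = bin(c(0.506, 0.622)),
    urban_birth = bin(c(0.082, 0.082)),
    educated = bin(c(0.555, 0.373)),
    residence = cat_(c("family", "alone", "nursing_home"),
                     list(c(0.850, 0.146, 0.004), c(0.783, 0.195, 0.022))),
    married = bin(c(0.617, 0.437)),
    economic_good = bin(c(0.850, 0.800)),
    insured = bin(c(0.126, 0.126)),
    professional = bin(c(0.084, 0.054)),
    smoking = cat_(c("never", "current", "former"),
                   list(c(0.627, 0.234, 0.139), c(0.709, 0.168, 0.123))),
    drinking = cat_(c("rare", "current", "past"),
                    list(c(0.640, 0.238, 0.122), c(0.716, 0.148, 0.136))),
    exercise = cat_(c("rare", "current", "past"),
                    list(c(0.559, 0.364, 0.077), c(0.612, 0.269, 0.119))),
    fruit_often = bin(c(0.442, 0.341)),
    vegetable_often = bin(c(0.916, 0.916)),
    cataract = bin(c(0.049, 0.165)),
    glaucoma = bin(c(0.010, 0.062)),
    hypertension = bin(c(0.223, 0.223)),
    diabetes = bin(c(0.026, 0.026)),
    stroke = bin(c(0.046, 0.046)),
    heart_disease = bin(c(0.091, 0.091))
  )
}

#' Default distal-outcome specifications
#'
#' Continuous outcomes are `baseline + shift * [class == 1] + noise` with
#' class 1 the large high-baseline class; the binary fall indicator uses a
#' logistic model with a log-odds shift. Shifts are the unadjusted
#' two-group contrasts the generator is calibrated to; noise standard
#' deviations are set so the contrast standard errors at n = 2235 are of
#' realistic size for the corresponding instruments (CMMSE 0-30, ADL, IADL,
#' CES-D-10 10-50 with higher = fewer symptoms, GAD-7 0-21).
#'
#' @return Named list of outcome specifications.
#' @export
default_outcome_specs <- function() {
  num <- function(baseline, shift, sd)
    list(type = "continuous", baseline = baseline, shift = shift, sd = sd)
  list(
    cognition = num(24.0, 3.186, 6.0),
    adl = num(7.3, -0.505, 2.3),
    iadl = num(13.0, -2.447, 5.6),
    depression = num(35.0, 1.209, 5.9),
    anxiety = num(2.8, -0.349, 2.8),
    fall = list(type = "binary", baseline_logit = stats::qlogis(0.25),
                logodds_shift = log(1.075))
  )
}

vision_cols <- function(n_waves) paste0("vision_w", seq_len(n_waves))

#' Simulate latent-class growth trajectories
#'
#' Draws each subject's class, growth factors and wave-level vision scores
#' under the linear growth mixture defined by `config`. The retained
#' `true_class` column exists only for recovery experiments; estimation
#' functions never read it (see [vision_matrix()]).
#'
#' @param config a [sim_config()].
#' @return A `cohort` data frame with `id`, `true_class` and one
#'   `vision_w<w>` column per wave.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  K <- length(config$class_proportions)
  cls <- sample.int(K, n, replace = TRUE, prob = config$class_proportions)
  L <- chol_psd(config$factor_cov)
  eta <- matrix(stats::rnorm(2 * n), n, 2) %*% t(L) +
    config$class_means[cls, , drop = FALSE]
  Lambda <- cbind(1, config$time_scores)
  y <- eta %*% t(Lambda) +
    matrix(stats::rnorm(n * config$n_waves,
                        sd = rep(sqrt(config$residual_var), each = n)),
           n, config$n_waves)
  if (config$censor_to_scale) y <- pmin(pmax(y, 1), 4)
  out <- data.frame(id = seq_len(n), true_class = cls)
  out[vision_cols(config$n_waves)] <- as.data.frame(y)
  as_cohort(out, config$n_waves, config$time_scores)
}

# lower-triangular factor of a PSD matrix (tolerates zero eigenvalues)
chol_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Fill class-conditional predictors and distal outcomes
#'
#' Adds baseline predictors and distal outcomes to a simulated cohort using
#' the class-conditional specifications in `config`. Requires `true_class`.
#'
#' @param cohort a cohort from [simulate_trajectories()].
#' @param config the generating [sim_config()].
#' @return The cohort with predictor and outcome columns appended.
#' @export
simulate_covariates_outcomes <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cohort$true_class))
    stop("cohort lacks true_class; generate trajectories first", call. = FALSE)
  cls <- cohort$true_class
  n <- nrow(cohort)
  for (nm in names(config$predictor_specs)) {
    sp <- config$predictor_specs[[nm]]
    cohort[[nm]] <- switch(sp$type,
      binary = {
        p <- sp$prob[cls]
        if (any(sp$prob < 0 | sp$prob > 1))
          stop("probabilities for '", nm, "' outside [0,1]", call. = FALSE)
        as.integer(stats::runif(n) < p)
      },
      categorical = {
        if (any(sp$prob < 0 | sp$prob > 1))
          stop("probabilities for '", nm, "' outside [0,1]", call. = FALSE)
        idx <- vapply(seq_len(n), function(i)
          sample.int(length(sp$levels), 1L, prob = sp$prob[cls[i], ]), 1L)
        factor(sp$levels[idx], levels = sp$levels)
      },
      continuous = stats::rnorm(n, sp$mean[cls], sp$sd[cls]),
      stop("unknown predictor type '", sp$type, "'", call. = FALSE))
  }
  high <- as.numeric(cls == 1L)
  for (nm in names(config$outcome_specs)) {
    sp <- config$outcome_specs[[nm]]
    cohort[[nm]] <- switch(sp$type,
      continuous = sp$baseline + sp$shift * high + stats::rnorm(n, 0, sp$sd),
      binary = as.integer(stats::runif(n) <
        stats::plogis(sp$baseline_logit + sp$logodds_shift * high)),
      stop("unknown outcome type '", sp$type, "'", call. = FALSE))
  }
  cohort
}

#' Mask vision observations completely at random
#'
#' Each vision observation is independently set missing with probability
#' `rate` (MCAR). Use [complete_cases()] or [min_waves_filter()] afterwards
#' to emulate the inclusion rules of a complete-case or at-least-m-waves
#' analysis.
#'
#' @param cohort a cohort data frame.
#' @param rate per-observation missingness probability; defaults to the
#'   `missing_rate` of the generating config when `cohort` carries one.
#' @return The cohort with masked vision entries set to `NA`.
#' @export
apply_missingness <- function(cohort, rate) {
  nw <- n_waves_of(cohort)
  if (rate == 0) return(cohort)
  cols <- vision_cols(nw)
  mask <- matrix(stats::runif(nrow(cohort) * nw) < rate, nrow(cohort), nw)
  for (w in seq_len(nw)) cohort[[cols[w]]][mask[, w]] <- NA_real_
  cohort
}

#' @rdname apply_missingness
#' @export
complete_cases <- function(cohort) {
  v <- vision_matrix(cohort)
  cohort[stats::complete.cases(v), , drop = FALSE]
}

#' @param m minimum number of observed waves a subject must have.
#' @rdname apply_missingness
#' @export
min_waves_filter <- function(cohort, m) {
  v <- vision_matrix(cohort)
  cohort[rowSums(!is.na(v)) >= m, , drop = FALSE]
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_trajectories()], [simulate_covariates_outcomes()] and
#' [apply_missingness()] in sequence under one seed.
#'
#' @param config a [sim_config()].
#' @return A `cohort` data frame.
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_trajectories(config)
  cohort <- simulate_covariates_outcomes(cohort, config)
  apply_missingness(cohort, config$missing_rate)
}

as_cohort <- function(df, n_waves, time_scores) {
  attr(df, "n_waves") <- as.integer(n_waves)
  attr(df, "time_scores") <- as.numeric(time_scores)
  class(df) <- unique(c("cohort", class(df)))
  df
}

n_waves_of <- function(cohort) {
  nw <- attr(cohort, "n_waves")
  if (is.null(nw)) nw <- sum(grepl("^vision_w[0-9]+$", names(cohort)))
  if (nw == 0L) stop("no vision_w<w> columns found", call. = FALSE)
  as.integer(nw)
}

#' Extract the estimation view of a cohort
#'
#' Returns the wave-by-wave vision score matrix and nothing else. All
#' estimation functions consume this view, which guarantees the generator's
#' `true_class` label can never leak into model fitting.
#'
#' @param cohort a cohort data frame (or an n x waves numeric matrix, which
#'   is passed through).
#' @return Numeric matrix, one row per subject, one column per wave.
#' @export
vision_matrix <- function(cohort) {
  if (is.matrix(cohort)) return(cohort)
  as.matrix(cohort[, vision_cols(n_waves_of(cohort)), drop = FALSE])
}
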