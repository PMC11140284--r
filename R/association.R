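#' Multivariable logistic regression of class membership
#'
#' Fits a binomial GLM (iteratively reweighted least squares) of a binary
#' outcome on the given terms, with Wald standard errors, normal 95%
#' confidence intervals on the link scale and exponentiated effects. For
#' trajectory analyses the outcome is 1 for the high-baseline declining
#' class, so odds ratios contrast it against the low-baseline improving
#' class.
#'
#' @param data data frame.
#' @param outcome name of a binary (0/1, logical, or two-level factor)
#'   column, or a vector aligned with `data`.
#' @param terms character vector of predictor column names.
#' @param covariates additional adjustment columns.
#' @return A `regression_result` data frame: `term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `or`, `or_low`, `or_high`.
#' @export
logistic_fit <- function(data, outcome, terms, covariates = NULL) {
  prep <- prep_model_frame(data, outcome, terms, covariates, binary = TRUE)
  fit <- suppressWarnings(
    stats::glm(prep$formula, data = prep$frame, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  if (!fit$converged || any(abs(cf[-1L]) > 15))
    stop("possible complete or quasi-complete separation in term(s): ",
         paste(names(cf[-1L])[abs(cf[-1L]) > 15], collapse = ", "),
         call. = FALSE)
  regression_result(fit, kind = "logistic")
}

#' Linear regression of a distal outcome
#'
#' Ordinary least squares with Wald 95% confidence intervals. For a model
#' containing only the class indicator, the class coefficient equals the
#' raw difference in group means.
#'
#' @inheritParams logistic_fit
#' @param outcome name of a continuous column, or an aligned vector.
#' @export
linear_fit <- function(data, outcome, terms, covariates = NULL) {
  prep <- prep_model_frame(data, outcome, terms, covariates, binary = FALSE)
  fit <- stats::lm(prep$formula, data = prep$frame)
  if (anyNA(stats::coef(fit)))
    stop("singular design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  regression_result(fit, kind = "linear")
}

prep_model_frame <- function(data, outcome, terms, covariates, binary) {
  if (length(outcome) == 1L && is.character(outcome)) {
    yname <- outcome
    y <- data[[outcome]]
    if (is.null(y)) stop("unknown outcome '", outcome, "'", call. = FALSE)
  } else {
    yname <- ".outcome"
    y <- outcome
  }
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (binary) {
    if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("outcome has a single level", call. = FALSE)
  }
  vars <- unique(c(terms, covariates))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  frame <- data[, vars, drop = FALSE]
  frame[[yname]] <- y
  fml <- stats::reformulate(vars, response = yname)
  list(frame = frame, formula = fml)
}

regression_result <- function(fit, kind, coefs = NULL, ses = NULL,
                              n_used = NULL) {
  if (is.null(coefs)) {
    sm <- summary(fit)$coefficients
    coefs <- sm[, 1L]; ses <- sm[, 2L]
    n_used <- stats::nobs(fit)
  }
  z <- coefs / ses
  out <- data.frame(term = names(coefs), estimate = unname(coefs),
                    se = unname(ses),
                    ci_low = unname(coefs - 1.96 * ses),
                    ci_high = unname(coefs + 1.96 * ses),
                    p_value = unname(2 * stats::pnorm(-abs(z))))
  if (kind == "logistic") {
    out$or <- exp(out$estimate)
    out$or_low <- exp(out$ci_low)
    out$or_high <- exp(out$ci_high)
  }
  class(out) <- c("regression_result", class(out))
  attr(out, "model_kind") <- kind
  attr(out, "n_used") <- n_used
  out
}

#' @export
print.regression_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s regression (n = %s)\n", attr(x, "model_kind"),
              attr(x, "n_used")))
  print.data.frame(cbind(term = x$term,
                         round(x[, setdiff(names(x), "term")], digits)),
                   row.names = FALSE)
  invisible(x)
}

#' Knot locations for a restricted cubic spline
#'
#' Default four knots at the 0.05, 0.35, 0.65 and 0.95 quantiles of the
#' exposure.
#'
#' @param x exposure values.
#' @param n_knots number of knots (>= 3).
#' @return Numeric vector of knots.
#' @export
rcs_knots <- function(x, n_knots = 4L) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  seq(0.05, 0.95, length.out = n_knots))
  unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic basis: the linear term `x` plus
#' `k - 2` nonlinear terms
#' `[(x - t_j)+^3 - (x - t_{k-1})+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2`,
#' which is linear beyond the boundary knots by construction.
#'
#' @param x exposure values.
#' @param knots strictly increasing knot vector, length >= 3, inside the
#'   data range when `check_range` is on.
#' @param check_range require the knots to lie inside `range(x)`? On when
#'   building a design matrix; evaluation of a fitted curve at arbitrary
#'   points turns it off.
#' @return Matrix with columns `x`, `x1'`, `x2'`, ...
#' @export
rcs_basis <- function(x, knots, check_range = TRUE) {
  k <- length(knots)
  if (k < 3L || any(diff(knots) <= 0))
    stop("need >= 3 strictly increasing knots", call. = FALSE)
  rng <- range(x, na.rm = TRUE)
  if (check_range && (knots[1L] < rng[1L] || knots[k] > rng[2L]))
    stop("knots outside the data range", call. = FALSE)
  cub <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1L]
  scale2 <- (tk - knots[1L])^2
  nl <- vapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (cub(x - tj) - cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }, numeric(length(x)))
  out <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(out) <- c("x", paste0("x", seq_len(k - 2L), "p"))
  out
}

#' Spline dose-response of class membership on an exposure
#'
#' Fits a logistic model of the binary class label on a restricted cubic
#' spline of the exposure plus covariates. Returns the fitted log-odds
#' curve relative to a reference exposure value, and a Wald test that all
#' nonlinear spline coefficients are zero (the nonlinearity test).
#'
#' @param data data frame.
#' @param exposure name of the continuous exposure column.
#' @param outcome binary outcome column name or aligned vector (1 = event).
#' @param covariates adjustment column names.
#' @param knots knot vector; defaults to [rcs_knots()] of the exposure.
#' @param ref reference exposure value at which the curve is 0.
#' @param grid exposure values at which to evaluate the curve.
#' @return List with `curve` (data frame: exposure, log_odds, odds_ratio,
#'   and 95% bounds), `p_nonlinear`, `knots`, `ref` and the coefficient
#'   table.
#' @export
rcs_dose_response <- function(data, exposure, outcome, covariates = NULL,
                              knots = NULL, ref = NULL, grid = NULL) {
  x <- data[[exposure]]
  if (is.null(x)) stop("unknown exposure '", exposure, "'", call. = FALSE)
  if (is.null(knots)) knots <- rcs_knots(x)
  if (is.null(ref)) ref <- stats::median(x, na.rm = TRUE)
  basis <- rcs_basis(x, knots)
  bnames <- paste0("rcs_", colnames(basis))
  df <- data
  df[bnames] <- as.data.frame(basis)
  fit_tab <- logistic_fit(df, outcome, bnames, covariates)
  # refit to get the covariance matrix for the Wald test and the curve
  prep <- prep_model_frame(df, outcome, bnames, covariates, binary = TRUE)
  fit <- stats::glm(prep$formula, data = prep$frame,
                    family = stats::binomial())
  V <- stats::vcov(fit)
  nlin <- bnames[-1L]
  b <- stats::coef(fit)[nlin]
  W <- drop(t(b) %*% solve(V[nlin, nlin], b))
  p_nl <- stats::pchisq(W, length(nlin), lower.tail = FALSE)
  if (is.null(grid))
    grid <- seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE), length.out = 101)
  bg <- rcs_basis(c(ref, grid), knots, check_range = FALSE)
  D <- sweep(bg[-1L, , drop = FALSE], 2L, bg[1L, ])   # basis minus reference
  beta <- stats::coef(fit)[bnames]
  lo <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V[bnames, bnames]) * D))
  curve <- data.frame(exposure = grid, log_odds = lo,
                      odds_ratio = exp(lo),
                      or_low = exp(lo - 1.96 * se),
                      or_high = exp(lo + 1.96 * se))
  list(curve = curve, p_nonlinear = p_nl, knots = knots, ref = ref,
       coefficients = fit_tab)
}

#' Rubin's rules for pooling multiply imputed fits
#'
#' Pools estimates across m imputations: `Qbar = mean(Q)`, between
#' variance `B = var(Q)`, total variance `T = Wbar + (1 + 1/m) B`,
#' `SE = sqrt(T)`.
#'
#' @param estimates m x p matrix (or vector) of per-imputation estimates.
#' @param variances m x p matrix of per-imputation squared standard errors.
#' @return List with `estimate`, `se`, `between`, `within`, `total`.
#' @export
rubin_pool <- function(estimates, variances) {
  Q <- if (is.matrix(estimates)) estimates else cbind(estimates)
  W <- if (is.matrix(variances)) variances else cbind(variances)
  m <- nrow(Q)
  qbar <- colMeans(Q)
  wbar <- colMeans(W)
  B <- if (m > 1) apply(Q, 2L, stats::var) else rep(0, ncol(Q))
  Tv <- wbar + (1 + 1 / m) * B
  list(estimate = qbar, se = sqrt(Tv), between = B, within = wbar,
       total = Tv)
}

#' Multiple imputation by chained equations with Rubin pooling
#'
#' Imputes missing predictor/outcome values by chained equations —
#' linear regression plus residual noise for continuous variables,
#' logistic draws for binary variables, multinomial draws for factors —
#' then fits the requested model on each completed dataset and pools the
#' coefficients by Rubin's rules. With no missing values the result equals
#' the direct fit (between-imputation variance 0).
#'
#' @param data data frame.
#' @param outcome,terms,covariates as in [logistic_fit()] / [linear_fit()].
#' @param model `"logistic"` or `"linear"` target model.
#' @param m number of imputations.
#' @param seed integer seed.
#' @param n_cycles chained-equation sweeps per imputation.
#' @return A `regression_result` with pooled estimates; attribute
#'   `n_imputations`.
#' @export
impute_and_pool <- function(data, outcome, terms, covariates = NULL,
                            model = c("logistic", "linear"), m = 5L,
                            seed = NULL, n_cycles = 5L) {
  model <- match.arg(model)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  fitter <- if (model == "logistic") logistic_fit else linear_fit
  vars <- unique(c(if (is.character(outcome) && length(outcome) == 1L)
    outcome, terms, covariates))
  sub <- data[, vars, drop = FALSE]
  incomplete <- names(sub)[vapply(sub, anyNA, TRUE)]
  for (v in incomplete) if (all(is.na(sub[[v]])))
    stop("variable '", v, "' has no observed values", call. = FALSE)
  if (!length(incomplete)) {
    out <- fitter(data, outcome, terms, covariates)
    attr(out, "n_imputations") <- 0L
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  ests <- ses <- NULL
  for (imp in seq_len(m)) {
    completed <- impute_once(sub, incomplete, n_cycles)
    filled <- data
    filled[vars] <- completed[vars]
    fit <- fitter(filled, outcome, terms, covariates)
    ests <- rbind(ests, stats::setNames(fit$estimate, fit$term))
    ses <- rbind(ses, stats::setNames(fit$se, fit$term))
  }
  pooled <- rubin_pool(ests, ses^2)
  out <- regression_result(NULL, kind = model, coefs = pooled$estimate,
                           ses = pooled$se, n_used = nrow(data))
  attr(out, "n_imputations") <- m
  attr(out, "between_variance") <- pooled$between
  out
}

impute_once <- function(sub, incomplete, n_cycles) {
  obs_idx <- lapply(sub, function(v) which(!is.na(v)))
  filled <- sub
  for (v in incomplete) {
    miss <- which(is.na(filled[[v]]))
    filled[[v]][miss] <- sample(filled[[v]][obs_idx[[v]]], length(miss),
                                replace = TRUE)
  }
  for (cycle in seq_len(n_cycles)) {
    for (v in incomplete) {
      miss <- which(is.na(sub[[v]]))
      others <- setdiff(names(sub), v)
      if (!length(others)) next
      fml <- stats::reformulate(others, response = v)
      train <- filled[-miss, , drop = FALSE]
      target <- filled[[v]]
      if (is.factor(target) && nlevels(droplevels(target)) > 2L) {
        fit <- suppressWarnings(nnet::multinom(fml, data = train,
                                               trace = FALSE))
        pr <- stats::predict(fit, newdata = filled[miss, , drop = FALSE],
                             type = "probs")
        pr <- rbind(pr)
        draw <- apply(pr, 1L, function(p)
          sample(colnames(pr), 1L, prob = p))
        filled[[v]][miss] <- factor(draw, levels = levels(target))
      } else if (is.factor(target) || all(sub[[v]] %in% c(0, 1, NA))) {
        yy <- if (is.factor(target)) as.integer(train[[v]]) - 1L
              else train[[v]]
        fit <- suppressWarnings(stats::glm(
          stats::reformulate(others, response = ".y"),
          data = cbind(train[others], .y = yy), family = stats::binomial()))
        p <- stats::predict(fit, newdata = filled[miss, , drop = FALSE],
                            type = "response")
        draw <- as.integer(stats::runif(length(miss)) < p)
        filled[[v]][miss] <- if (is.factor(target))
          factor(levels(target)[draw + 1L], levels = levels(target))
        else draw
      } else {
        fit <- stats::lm(fml, data = train)
        sigma <- summary(fit)$sigma
        mu <- stats::predict(fit, newdata = filled[miss, , drop = FALSE])
        filled[[v]][miss] <- mu + stats::rnorm(length(miss), 0, sigma)
      }
    }
  }
  filled
}
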