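#' Growth design: factor loadings of the latent linear growth model
#'
#' The loading matrix has a column of ones (latent intercept) and a column
#' of wave time scores (latent slope). With the default `time_scores`
#' starting at 0, the intercept is the model-implied mean at the first
#' wave.
#'
#' @param n_waves number of measurement waves.
#' @param time_scores strictly increasing wave times, one per wave.
#' @return Object of class `growth_design` with elements `n_waves`,
#'   `time_scores` and the loading matrix `lambda`.
#' @export
growth_design <- function(n_waves = 4, time_scores = seq_len(n_waves) - 1) {
  if (length(time_scores) != n_waves || any(diff(time_scores) <= 0))
    stop("time_scores must be strictly increasing, one per wave",
         call. = FALSE)
  structure(list(n_waves = as.integer(n_waves),
                 time_scores = as.numeric(time_scores),
                 lambda = cbind(intercept = 1, slope = as.numeric(time_scores))),
            class = "growth_design")
}

#' Model-implied moments of the linear growth model
#'
#' Computes the mean vector `Lambda alpha` and covariance matrix
#' `Lambda Psi Lambda' + Theta` implied by growth-factor means `alpha`,
#' factor covariance `psi` and residual variances `theta`.
#'
#' @param params list with `alpha` (length 2), `psi` (2x2), `theta`
#'   (length 1 or `n_waves`).
#' @param design a [growth_design()].
#' @return List with `mean` and `cov`.
#' @export
implied_moments <- function(params, design) {
  L <- design$lambda
  theta <- rep_len(as.numeric(params$theta), design$n_waves)
  mu <- drop(L %*% params$alpha)
  Sigma <- L %*% params$psi %*% t(L) + diag(theta, design$n_waves)
  list(mean = mu, cov = (Sigma + t(Sigma)) / 2)
}

#' SEM fit indices from model and baseline test statistics
#'
#' Computes the incremental and absolute fit indices used to judge the
#' shape of the growth curve: CFI, TLI, RMSEA and (when the sample and
#' implied covariance matrices are supplied) SRMR. The baseline model is
#' the independence model with free means and variances and all
#' covariances zero. SRMR is the root mean square of the standardized
#' covariance residuals over the lower triangle including the diagonal;
#' mean residuals are excluded.
#'
#' @param chi_sq,df model test statistic and its degrees of freedom.
#' @param chi_sq_baseline,df_baseline baseline (independence) statistic
#'   and degrees of freedom; `df_baseline` must exceed `df`.
#' @param n number of subjects.
#' @param sample_cov,implied_cov optional p x p matrices for SRMR.
#' @return Object of class `fit_indices`.
#' @export
fit_indices <- function(chi_sq, df, chi_sq_baseline, df_baseline, n,
                        sample_cov = NULL, implied_cov = NULL) {
  if (df <= 0 || df_baseline <= df)
    stop("need df > 0 and df_baseline > df", call. = FALSE)
  num <- max(chi_sq - df, 0)
  den <- max(chi_sq_baseline - df_baseline, chi_sq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chi_sq_baseline / df_baseline
  tli <- if (rb <= 1) 1 else (rb - chi_sq / df) / (rb - 1)
  srmr <- NA_real_
  if (!is.null(sample_cov) && !is.null(implied_cov)) {
    d <- sqrt(diag(sample_cov))
    std_res <- (sample_cov - implied_cov) / tcrossprod(d)
    srmr <- sqrt(mean(std_res[lower.tri(std_res, diag = TRUE)]^2))
  }
  structure(list(
    chi_square = chi_sq, df = df, chi_df_ratio = chi_sq / df,
    cfi = min(max(cfi, 0), 1), tli = min(max(tli, 0), 1),
    rmsea = sqrt(num / (df * (n - 1))), srmr = srmr,
    baseline_chi_square = chi_sq_baseline, baseline_df = df_baseline,
    n_used = n), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi-square %.3f on %d df (ratio %.3f)\nCFI %.3f  TLI %.3f  RMSEA %.4f  SRMR %s  (n = %d)\n",
    x$chi_square, x$df, x$chi_df_ratio, x$cfi, x$tli, x$rmsea,
    ifelse(is.na(x$srmr), "NA", sprintf("%.4f", x$srmr)), x$n_used))
  invisible(x)
}

# saturated multivariate-normal log-likelihood and moments under
# full-information ML (EM over missing entries); exact in one step for
# complete data
saturated_mvn <- function(y, tol = 1e-8, max_iter = 200L) {
  n <- nrow(y); p <- ncol(y)
  if (!anyNA(y)) {
    mu <- colMeans(y)
    S <- crossprod(sweep(y, 2L, mu)) / n
    R <- chol(S)
    ll <- -0.5 * n * (p * log(2 * pi) + 2 * sum(log(diag(R))) + p)
    return(list(mean = mu, cov = S, loglik = ll))
  }
  mu <- colMeans(y, na.rm = TRUE)
  S <- stats::cov(y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- S + diag(1e-6, p)
  pats <- pattern_split(y)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum_y <- numeric(p); sum_yy <- matrix(0, p, p); ll <- 0
    for (pat in pats) {
      o <- pat$obs; m <- setdiff(seq_len(p), o); np <- nrow(pat$y)
      Soo <- S[o, o, drop = FALSE]
      R <- chol(Soo)
      E <- sweep(pat$y, 2L, mu[o])
      Z <- backsolve(R, t(E), transpose = TRUE)
      ll <- ll - 0.5 * (np * (length(o) * log(2 * pi) +
                              2 * sum(log(diag(R)))) + sum(Z^2))
      yfull <- matrix(0, np, p)
      yfull[, o] <- pat$y
      Vadd <- matrix(0, p, p)
      if (length(m)) {
        B <- backsolve(R, backsolve(R, S[o, m, drop = FALSE],
                                    transpose = TRUE))   # Soo^-1 Som
        yfull[, m] <- sweep(E %*% B, 2L, mu[m], `+`)
        Vmm <- S[m, m, drop = FALSE] - crossprod(S[o, m, drop = FALSE], B)
        Vadd[m, m] <- np * Vmm
      }
      sum_y <- sum_y + colSums(yfull)
      sum_yy <- sum_yy + crossprod(yfull) + Vadd
    }
    mu <- sum_y / n
    S <- sum_yy / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mean = mu, cov = S, loglik = ll)
}

# independence-model FIML log-likelihood: with free per-wave means and
# variances and zero covariances the likelihood factorizes by wave, so the
# ML fit is the marginal normal fit to each wave's observed values
baseline_mvn_loglik <- function(y) {
  sum(vapply(seq_len(ncol(y)), function(w) {
    v <- y[, w][!is.na(y[, w])]
    s2 <- mean((v - mean(v))^2)
    -0.5 * length(v) * (log(2 * pi) + log(s2) + 1)
  }, 0))
}

lgcm_n_params <- function(p, equal_theta) 2L + 3L + if (equal_theta) 1L else p

#' Fit a single-class latent linear growth-curve model
#'
#' Maximum-likelihood estimation of growth-factor means `alpha`, factor
#' covariance `psi` and wave residual variances `theta` for repeated
#' measurements, via EM (the K = 1 case of the mixture engine). With
#' `allow_partial = TRUE` the likelihood is full-information over each
#' subject's observed waves, and subjects with at least `min_waves`
#' observations are retained; otherwise complete cases only.
#'
#' Fit indices use the ML discrepancy
#' `F = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p + (ybar - mu)' Sigma^-1 (ybar - mu)`
#' with test statistic `(n - 1) F` for complete data, and the equivalent
#' likelihood-ratio statistic against the FIML saturated model for
#' partially observed data.
#'
#' @param data a cohort data frame or an n x waves numeric matrix of vision
#'   scores (only the vision columns of a cohort are read).
#' @param design a [growth_design()].
#' @param allow_partial retain subjects with incomplete vision series?
#' @param min_waves minimum observed waves per retained subject when
#'   `allow_partial`; default 3.
#' @param equal_theta constrain residual variances equal across waves?
#' @param tol,max_iter EM convergence tolerance on the log-likelihood and
#'   iteration cap.
#' @return Object of class `lgcm`: parameter estimates, log-likelihood,
#'   [fit_indices()], sample size and convergence information.
#' @export
lgcm <- function(data, design = NULL, allow_partial = FALSE, min_waves = 3L,
                 equal_theta = FALSE, tol = 1e-8, max_iter = 2000L) {
  y <- vision_matrix(data)
  if (is.null(design)) design <- default_design_for(data, ncol(y))
  p <- design$n_waves
  stopifnot(ncol(y) == p)
  if (allow_partial) {
    y <- y[rowSums(!is.na(y)) >= min_waves, , drop = FALSE]
  } else {
    y <- y[stats::complete.cases(y), , drop = FALSE]
  }
  n <- nrow(y)
  if (n <= lgcm_n_params(p, equal_theta))
    stop("fewer subjects than free parameters", call. = FALSE)
  b <- ols_growth_estimates(y, design$time_scores)
  init <- list(pi = 1, alpha = rbind(colMeans(b)),
               psi = diag(pmax(apply(b, 2L, stats::var) / 2, c(1e-3, 1e-4)), 2),
               theta = rep(max(stats::var(as.numeric(y), na.rm = TRUE) / 4,
                               0.05), p))
  run <- em_run(y, design$lambda, 1L, init, max_iter = max_iter, tol = tol,
                equal_theta = equal_theta)
  if (!run$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  params <- list(alpha = drop(run$alpha), psi = run$psi, theta = run$theta)
  im <- implied_moments(params, design)
  sat <- saturated_mvn(y)
  TM <- 2 * (sat$loglik - run$loglik)
  TB <- 2 * (sat$loglik - baseline_mvn_loglik(y))
  if (!anyNA(y)) {
    # complete data: the classical (n - 1) * F statistic
    Sm1 <- stats::cov(y)                     # denominator n - 1
    ybar <- colMeans(y)
    Rr <- chol(im$cov)
    Fd <- 2 * sum(log(diag(Rr))) - determinant(Sm1)$modulus[1] +
      sum(diag(backsolve(Rr, backsolve(Rr, Sm1, transpose = TRUE)))) - p +
      drop(crossprod(backsolve(Rr, ybar - im$mean, transpose = TRUE)))
    TM <- (n - 1) * Fd
    Sb <- diag(diag(Sm1), p)
    Fb <- determinant(Sb)$modulus[1] - determinant(Sm1)$modulus[1] +
      sum(diag(solve(Sb, Sm1))) - p
    TB <- (n - 1) * Fb
    sat$cov <- Sm1
  }
  npar <- lgcm_n_params(p, equal_theta)
  dfm <- p * (p + 3) / 2 - npar
  dfb <- p * (p + 3) / 2 - 2 * p
  fi <- fit_indices(TM, dfm, TB, dfb, n, sample_cov = sat$cov,
                    implied_cov = im$cov)
  structure(list(params = params, loglik = run$loglik, fit = fi,
                 n_used = n, converged = run$converged,
                 n_iter = run$n_iter, design = design,
                 equal_theta = equal_theta, allow_partial = allow_partial,
                 min_ll_increment = run$min_increment,
                 data = y),
            class = "lgcm")
}

default_design_for <- function(data, p) {
  ts <- attr(data, "time_scores")
  if (is.null(ts) || length(ts) != p) ts <- seq_len(p) - 1
  growth_design(p, ts)
}

#' @export
print.lgcm <- function(x, digits = 4, ...) {
  cat("Latent linear growth-curve model (ML",
      if (x$allow_partial) ", full-information over observed waves" else "",
      ")\n", sep = "")
  cat(sprintf("n = %d, log-likelihood = %.3f%s\n", x$n_used, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("Intercept mean %.*f, slope mean %.*f\n", digits,
              x$params$alpha[1], digits, x$params$alpha[2]))
  cat(sprintf("Factor variances: intercept %.*f, slope %.*f, covariance %.*f\n",
              digits, x$params$psi[1, 1], digits, x$params$psi[2, 2],
              digits, x$params$psi[1, 2]))
  cat("Residual variances:", paste(round(x$params$theta, digits),
                                   collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' @export
coef.lgcm <- function(object, ...) {
  c(intercept_mean = object$params$alpha[1],
    slope_mean = object$params$alpha[2],
    psi00 = object$params$psi[1, 1], psi11 = object$params$psi[2, 2],
    psi01 = object$params$psi[1, 2],
    stats::setNames(object$params$theta,
                    paste0("theta_w", seq_along(object$params$theta))))
}

#' @export
logLik.lgcm <- function(object, ...) {
  structure(object$loglik,
            df = lgcm_n_params(object$design$n_waves, object$equal_theta),
            nobs = object$n_used, class = "logLik")
}

#' @export
fitted.lgcm <- function(object, ...) {
  implied_moments(object$params, object$design)$mean
}

#' @export
residuals.lgcm <- function(object, ...) {
  sweep(object$data, 2L, fitted(object))
}

#' @importFrom stats simulate
#' @export
simulate.lgcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  params <- list(pi = 1, class_means = rbind(drop(object$params$alpha)),
                 psi = object$params$psi, theta = object$params$theta)
  out <- replicate(nsim, simulate_from_params(params, object$n_used,
                                              object$design)$y,
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}
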