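#' Fit a growth mixture model by multi-start EM
#'
#' Estimates a K-class linear growth mixture in which latent classes differ
#' in their growth-factor means while the factor covariance `Psi` and wave
#' residual variances `Theta` are shared across classes (the conventional
#' default specification). Estimation is EM treating both class membership
#' and the growth factors as missing data, so every iteration increases the
#' observed-data log-likelihood; the reported solution is the best
#' converged start. Classes are returned in canonical order of descending
#' intercept mean, which resolves label switching.
#'
#' The first start is derived from k-means clustering of per-subject
#' ordinary-least-squares (intercept, slope) estimates; remaining starts
#' are seed-controlled random perturbations.
#'
#' @param data a cohort data frame or n x waves numeric matrix (only the
#'   vision columns of a cohort are read; the generator's `true_class` is
#'   never visible to the fit).
#' @param K number of latent classes (>= 1).
#' @param design a [growth_design()]; defaults to times `0..n_waves-1`.
#' @param n_starts number of EM starts.
#' @param seed integer seed controlling the starts.
#' @param allow_partial marginalize the likelihood over each subject's
#'   observed waves (subjects need `min_waves` observations)? Otherwise
#'   complete cases only.
#' @param min_waves minimum observed waves when `allow_partial`.
#' @param equal_theta constrain residual variances equal across waves?
#' @param max_iter,tol per-start iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @return Object of class `gmm` with elements `params` (list: `pi`,
#'   `class_means`, `psi`, `theta`), `posteriors`, `loglik`,
#'   `n_free_params`, `entropy`, `ic` (AIC/BIC/aBIC), `converged`,
#'   `n_starts_used`, `best_start`, `n_used`.
#' @seealso [enumerate_classes()], [assign_labels()], [blrt()], [lmr_test()]
#' @export
gmm <- function(data, K, design = NULL, n_starts = 50L, seed = NULL,
                allow_partial = FALSE, min_waves = 3L, equal_theta = FALSE,
                max_iter = 500L, tol = 1e-6) {
  y <- vision_matrix(data)
  if (is.null(design)) design <- default_design_for(data, ncol(y))
  K <- as.integer(K)
  stopifnot(K >= 1L, ncol(y) == design$n_waves)
  if (allow_partial) {
    y <- y[rowSums(!is.na(y)) >= min_waves, , drop = FALSE]
  } else {
    y <- y[stats::complete.cases(y), , drop = FALSE]
  }
  n <- nrow(y)
  if (n < 10L * K)
    stop("need at least 10 subjects per class (n = ", n, ", K = ", K, ")",
         call. = FALSE)
  starts <- make_starts(y, design$lambda, K, n_starts, seed)
  best <- NULL; best_start <- NA_integer_; outcomes <- character(n_starts)
  for (s in seq_along(starts)) {
    run <- tryCatch(
      em_run(y, design$lambda, K, starts[[s]], max_iter = max_iter,
             tol = tol, equal_theta = equal_theta),
      error = function(e) e)
    if (inherits(run, "error")) { outcomes[s] <- conditionMessage(run); next }
    outcomes[s] <- if (run$converged) "converged" else "max iterations"
    better <- is.null(best) || run$loglik > best$loglik + 1e-9 ||
      (run$converged && !best$converged &&
         run$loglik > best$loglik - 1e-9)
    if (better) { best <- run; best_start <- s }
  }
  if (is.null(best))
    stop("all EM starts failed:\n  ",
         paste(sprintf("start %d: %s", seq_along(outcomes), outcomes),
               collapse = "\n  "), call. = FALSE)
  ord <- order(best$alpha[, 1L], decreasing = TRUE)
  params <- list(pi = best$pi[ord],
                 class_means = best$alpha[ord, , drop = FALSE],
                 psi = best$psi, theta = best$theta)
  dimnames(params$class_means) <- list(paste0("class_", seq_len(K)),
                                       c("intercept", "slope"))
  post <- best$posteriors[, ord, drop = FALSE]
  npar <- gmm_n_params(K, design$n_waves, equal_theta)
  structure(list(params = params, posteriors = post, loglik = best$loglik,
                 n_free_params = npar, K = K,
                 entropy = entropy(post),
                 ic = information_criteria(best$loglik, npar, n),
                 converged = best$converged,
                 n_starts_used = sum(outcomes == "converged" |
                                       outcomes == "max iterations"),
                 start_outcomes = outcomes, best_start = best_start,
                 min_ll_increment = best$min_increment,
                 n_iter = best$n_iter, n_used = n, design = design,
                 equal_theta = equal_theta, allow_partial = allow_partial,
                 data = y),
            class = "gmm")
}

gmm_n_params <- function(K, p, equal_theta = FALSE)
  as.integer(2L * K + (K - 1L) + 3L + if (equal_theta) 1L else p)

#' Observed-data log-likelihood of a growth mixture
#'
#' Sum over subjects of the log of the mixture density
#' `sum_k pi_k N(y_i; Lambda alpha_k, Lambda Psi Lambda' + Theta)`,
#' restricted to each subject's observed waves.
#'
#' @param params list with `pi`, `class_means` (K x 2), `psi`, `theta`.
#' @param data cohort or vision matrix (may contain `NA`).
#' @param design a [growth_design()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(params, data, design = NULL) {
  y <- vision_matrix(data)
  if (is.null(design)) design <- default_design_for(data, ncol(y))
  K <- length(params$pi)
  theta <- rep_len(as.numeric(params$theta), design$n_waves)
  pats <- pattern_split(y)
  logd <- matrix(NA_real_, nrow(y), K)
  for (pat in pats) for (k in seq_len(K))
    logd[pat$rows, k] <- pattern_class_estep(
      pat, params$class_means[k, ], params$psi, theta, design$lambda)$logdens
  lw <- sweep(logd, 2L, log(params$pi), `+`)
  mx <- apply(lw, 1L, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_i sum_k -p_ik log p_ik / (n log K)`: 1 for a perfectly sharp
#' classification, 0 for uniform posteriors. Undefined for a single class
#' (returns `NA`, as enumeration tables conventionally print).
#'
#' @param posteriors n x K matrix of posterior class probabilities (rows
#'   sum to 1).
#' @return Value in `[0, 1]`, or `NA` when K = 1.
#' @export
entropy <- function(posteriors) {
  posteriors <- rbind(posteriors)
  K <- ncol(posteriors)
  if (K < 2L) return(NA_real_)
  pl <- posteriors * log(posteriors)
  pl[posteriors == 0] <- 0
  1 - sum(-pl) / (nrow(posteriors) * log(K))
}

#' Information criteria for model enumeration
#'
#' `AIC = -2 LL + 2p`, `BIC = -2 LL + p log n`, and the sample-size
#' adjusted BIC `aBIC = -2 LL + p log((n + 2) / 24)`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n number of subjects.
#' @return Named vector `c(aic, bic, abic)`.
#' @export
information_criteria <- function(loglik, n_params, n) {
  stopifnot(n > 0)
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n),
    abic = -2 * loglik + n_params * log((n + 2) / 24))
}

# draw n subjects from mixture params; returns y matrix and classes
simulate_from_params <- function(params, n, design) {
  K <- length(params$pi)
  cls <- sample.int(K, n, replace = TRUE, prob = params$pi)
  L <- chol_psd(params$psi)
  eta <- matrix(stats::rnorm(2 * n), n, 2) %*% t(L) +
    params$class_means[cls, , drop = FALSE]
  theta <- rep_len(as.numeric(params$theta), design$n_waves)
  y <- eta %*% t(design$lambda) +
    matrix(stats::rnorm(n * design$n_waves,
                        sd = rep(sqrt(theta), each = n)),
           n, design$n_waves)
  list(y = y, class = cls)
}

#' Bootstrap likelihood ratio test for K vs K - 1 classes
#'
#' Parametric bootstrap: the observed statistic is
#' `2 (LL_K - LL_{K-1})`; each of `B` replicates simulates a cohort of the
#' same size from the fitted (K-1)-class model and refits both models. The
#' p-value is `(1 + #{LRT_b >= LRT_obs}) / (B + 1)`. A replicate whose
#' refits fail is re-drawn up to `retry_cap` times, then counted
#' conservatively as exceeding the observed statistic.
#'
#' @param data cohort or vision matrix.
#' @param design a [growth_design()].
#' @param K number of classes under the alternative (>= 2).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param n_starts,boot_starts EM starts for the data fits and for each
#'   bootstrap refit.
#' @param fit_K,fit_Kminus1 optional pre-computed [gmm()] fits on `data`.
#' @param retry_cap redraw attempts per failed replicate.
#' @param ... passed to [gmm()].
#' @return List with `p_value`, `lrt_obs`, `lrt_boot`, `n_conservative`.
#' @export
blrt <- function(data, design = NULL, K, B = 100L, seed = NULL,
                 n_starts = 20L, boot_starts = 5L, fit_K = NULL,
                 fit_Kminus1 = NULL, retry_cap = 3L, ...) {
  stopifnot(K >= 2L)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  y <- vision_matrix(data)
  if (is.null(design)) design <- default_design_for(data, ncol(y))
  if (is.null(fit_Kminus1))
    fit_Kminus1 <- gmm(y, K - 1L, design, n_starts = n_starts, seed = seed,
                       ...)
  if (is.null(fit_K))
    fit_K <- gmm(y, K, design, n_starts = n_starts, seed = seed, ...)
  lrt_obs <- 2 * (fit_K$loglik - fit_Kminus1$loglik)
  n <- fit_Kminus1$n_used
  if (!is.null(seed)) set.seed(seed + 1L)
  lrt_boot <- rep(NA_real_, B)
  n_conservative <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in seq_len(retry_cap)) {
      sim <- simulate_from_params(fit_Kminus1$params, n, design)
      f0 <- tryCatch(gmm(sim$y, K - 1L, design, n_starts = boot_starts,
                         seed = NULL, ...), error = function(e) NULL)
      f1 <- tryCatch(gmm(sim$y, K, design, n_starts = boot_starts,
                         seed = NULL, ...), error = function(e) NULL)
      if (!is.null(f0) && !is.null(f1)) {
        val <- 2 * (f1$loglik - f0$loglik)
        break
      }
    }
    if (is.na(val)) { val <- Inf; n_conservative <- n_conservative + 1L }
    lrt_boot[b] <- val
  }
  list(p_value = (1 + sum(lrt_boot >= lrt_obs)) / (B + 1),
       lrt_obs = lrt_obs, lrt_boot = lrt_boot,
       n_conservative = n_conservative)
}

#' Approximate Lo-Mendell-Rubin adjusted likelihood ratio test
#'
#' Compares a K-class fit against the (K-1)-class fit on the same data
#' using the likelihood ratio `2 (LL_K - LL_{K-1})` shrunk by the ad hoc
#' small-sample correction `c = 1 + 1 / (d log n)` (d = difference in free
#' parameters) and referred to a chi-square distribution with d degrees of
#' freedom. This is an approximation to the LMR reference distribution and
#' is always reported alongside [blrt()], which is authoritative when the
#' two disagree.
#'
#' @param fit_K,fit_Kminus1 [gmm()] fits of K and K - 1 classes on the same
#'   data.
#' @param n sample size; defaults to `fit_K$n_used`.
#' @return List with `p_value` (approximate), `statistic`, `df`.
#' @export
lmr_test <- function(fit_K, fit_Kminus1, n = fit_K$n_used) {
  if (fit_K$n_used != fit_Kminus1$n_used)
    stop("fits must be on the same data", call. = FALSE)
  d <- fit_K$n_free_params - fit_Kminus1$n_free_params
  lr <- 2 * (fit_K$loglik - fit_Kminus1$loglik)
  if (lr < 0) {
    warning("K-class fit has lower likelihood than the (K-1)-class fit; ",
            "EM starts likely failed")
    return(list(p_value = 1, statistic = lr, df = d, approximate = TRUE))
  }
  stat <- lr / (1 + 1 / (d * log(n)))
  list(p_value = stats::pchisq(stat, d, lower.tail = FALSE),
       statistic = stat, df = d, approximate = TRUE)
}

#' Enumerate latent trajectory classes
#'
#' Fits growth mixtures with 1 to `K_max` classes and assembles the
#' enumeration table (AIC, BIC, aBIC, approximate LMR and bootstrap LRT
#' p-values, entropy, modal class shares). The selected class count is the
#' largest K such that at every step `k <= K` both tests reject at `alpha`
#' and every modal class share is at least `min_share`; among candidates
#' with equal support the smallest BIC decides.
#'
#' @param data cohort or vision matrix.
#' @param design a [growth_design()].
#' @param K_max largest class count to consider (>= 2).
#' @param alpha significance level for the LMR and bootstrap tests.
#' @param min_share smallest admissible modal class share (the "5% rule").
#' @param B bootstrap replicates for [blrt()].
#' @param seed integer seed.
#' @param n_starts,boot_starts EM starts for data fits / bootstrap refits.
#' @param ... passed to [gmm()].
#' @return Object of class `gmm_enumeration`: `table` (one row per K),
#'   `selected_K`, `selection_trace`, and the per-K `fits`.
#' @export
enumerate_classes <- function(data, design = NULL, K_max = 4L, alpha = 0.05,
                              min_share = 0.05, B = 100L, seed = NULL,
                              n_starts = 50L, boot_starts = 5L, ...) {
  stopifnot(K_max >= 2L)
  if (1 / (B + 1) >= alpha)
    warning("with B = ", B, " the smallest attainable bootstrap p-value is ",
            signif(1 / (B + 1), 3), " >= alpha = ", alpha,
            "; the bootstrap test can never support K > 1")
  y <- vision_matrix(data)
  if (is.null(design)) design <- default_design_for(data, ncol(y))
  fits <- vector("list", K_max)
  errors <- character(K_max)
  for (K in seq_len(K_max)) {
    fits[[K]] <- tryCatch(
      gmm(y, K, design, n_starts = n_starts,
          seed = if (!is.null(seed)) seed + K, ...),
      error = function(e) { errors[K] <<- conditionMessage(e); NULL })
  }
  rows <- lapply(seq_len(K_max), function(K) {
    f <- fits[[K]]
    if (is.null(f))
      return(data.frame(K = K, aic = NA, bic = NA, abic = NA, vlmr_p = NA,
                        blrt_p = NA, entropy = NA, class_shares = NA,
                        converged = FALSE))
    shares <- modal_shares(f)
    lmr_p <- blrt_p <- NA_real_
    if (K >= 2L && !is.null(fits[[K - 1L]])) {
      lmr_p <- lmr_test(f, fits[[K - 1L]])$p_value
      blrt_p <- blrt(y, design, K, B = B,
                     seed = if (!is.null(seed)) seed + 100L + K,
                     boot_starts = boot_starts, fit_K = f,
                     fit_Kminus1 = fits[[K - 1L]], ...)$p_value
    }
    data.frame(K = K, aic = f$ic[["aic"]], bic = f$ic[["bic"]],
               abic = f$ic[["abic"]], vlmr_p = lmr_p, blrt_p = blrt_p,
               entropy = f$entropy,
               class_shares = paste(sprintf("%.3f", shares), collapse = "/"),
               converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  trace <- character(0)
  selected <- 1L
  for (K in 2:K_max) {
    f <- fits[[K]]
    if (is.null(f)) {
      trace <- c(trace, sprintf("K=%d: estimation failed (%s)", K, errors[K]))
      break
    }
    row <- tab[K, ]
    ok_tests <- !is.na(row$vlmr_p) && !is.na(row$blrt_p) &&
      row$vlmr_p < alpha && row$blrt_p < alpha
    ok_share <- min(modal_shares(f)) >= min_share
    if (ok_tests && ok_share) {
      selected <- K
      trace <- c(trace, sprintf(
        "K=%d supported: LMR p=%.4g, BLRT p=%.4g, min share %.3f >= %.2f",
        K, row$vlmr_p, row$blrt_p, min(modal_shares(f)), min_share))
    } else {
      why <- c(
        if (!ok_tests) sprintf("LMR p=%.4g / BLRT p=%.4g not both < %.2f",
                               row$vlmr_p, row$blrt_p, alpha),
        if (!ok_share) sprintf("smallest class share %.3f < %.2f (5%% rule)",
                               min(modal_shares(f)), min_share))
      trace <- c(trace, sprintf("K=%d rejected: %s", K,
                                paste(why, collapse = "; ")))
      break
    }
  }
  structure(list(table = tab, selected_K = selected,
                 selection_trace = trace, fits = fits,
                 alpha = alpha, min_share = min_share),
            class = "gmm_enumeration")
}

modal_shares <- function(fit) {
  cls <- max.col(fit$posteriors, ties.method = "first")
  tabulate(cls, fit$K) / fit$n_used
}

#' @export
print.gmm_enumeration <- function(x, ...) {
  cat("Class enumeration (1..", nrow(x$table), " classes)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 6)
  cat("Selected K =", x$selected_K, "\n")
  for (tr in x$selection_trace) cat("  -", tr, "\n")
  invisible(x)
}

#' Modal class assignment with trajectory labels
#'
#' Assigns each subject to the class with the highest posterior
#' probability (ties broken toward the lower, i.e. higher-intercept,
#' class index). For a two-class fit the canonical classes are labelled
#' `high-baseline decline` (higher intercept mean) and
#' `low-baseline improvement`; otherwise classes are labelled by their
#' canonical index and intercept.
#'
#' @param fit a converged [gmm()] fit.
#' @return Factor of per-subject labels, with attributes `shares` (named
#'   label shares) and `class_index` (integer modal class).
#' @export
assign_labels <- function(fit) {
  cls <- max.col(fit$posteriors, ties.method = "first")
  labs <- class_label_names(fit)
  out <- factor(labs[cls], levels = labs)
  attr(out, "shares") <- stats::setNames(tabulate(cls, fit$K) / fit$n_used,
                                         labs)
  attr(out, "class_index") <- cls
  out
}

class_label_names <- function(fit) {
  if (fit$K == 2L) c("high-baseline decline", "low-baseline improvement")
  else sprintf("class %d (intercept %.2f)", seq_len(fit$K),
               fit$params$class_means[, 1])
}

#' @export
print.gmm <- function(x, digits = 4, ...) {
  cat(sprintf("Growth mixture model, K = %d (n = %d)\n", x$K, x$n_used))
  cat(sprintf("log-likelihood %.3f%s; AIC %.3f, BIC %.3f, aBIC %.3f\n",
              x$loglik, if (x$converged) "" else " [NOT CONVERGED]",
              x$ic[["aic"]], x$ic[["bic"]], x$ic[["abic"]]))
  if (!is.na(x$entropy)) cat(sprintf("entropy %.3f\n", x$entropy))
  tab <- cbind(proportion = x$params$pi, x$params$class_means)
  rownames(tab) <- class_label_names(x)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.gmm <- function(object, ...) {
  shares <- modal_shares(object)
  structure(list(fit = object, modal_shares = shares,
                 implied = lapply(seq_len(object$K), function(k)
                   implied_moments(list(alpha = object$params$class_means[k, ],
                                        psi = object$params$psi,
                                        theta = object$params$theta),
                                   object$design))),
            class = "summary.gmm")
}

#' @export
print.summary.gmm <- function(x, ...) {
  print(x$fit)
  cat("\nModal class shares:", paste(sprintf("%.3f", x$modal_shares),
                                     collapse = " / "), "\n")
  cat("Implied class mean trajectories:\n")
  mt <- do.call(rbind, lapply(x$implied, `[[`, "mean"))
  dimnames(mt) <- list(class_label_names(x$fit),
                       paste0("wave_", seq_len(x$fit$design$n_waves)))
  print(round(mt, 3))
  invisible(x)
}

#' @export
coef.gmm <- function(object, ...) {
  list(pi = object$params$pi, class_means = object$params$class_means,
       psi = object$params$psi, theta = object$params$theta)
}

#' @export
logLik.gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, nobs = object$n_used,
            class = "logLik")
}

#' Posterior probabilities or modal classes for a fitted mixture
#'
#' @param object a [gmm()] fit.
#' @param newdata optional cohort or vision matrix; defaults to the fitting
#'   data.
#' @param type `"posterior"` for the n x K probability matrix, `"class"`
#'   for modal assignments.
#' @param ... unused.
#' @export
predict.gmm <- function(object, newdata = NULL,
                        type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    post <- object$posteriors
  } else {
    y <- vision_matrix(newdata)
    K <- object$K
    logd <- matrix(NA_real_, nrow(y), K)
    theta <- object$params$theta
    for (pat in pattern_split(y)) for (k in seq_len(K))
      logd[pat$rows, k] <- pattern_class_estep(
        pat, object$params$class_means[k, ], object$params$psi, theta,
        object$design$lambda)$logdens
    lw <- sweep(logd, 2L, log(object$params$pi), `+`)
    mx <- apply(lw, 1L, max)
    post <- exp(lw - mx) / rowSums(exp(lw - mx))
  }
  if (type == "posterior") post else max.col(post, ties.method = "first")
}

#' @export
fitted.gmm <- function(object, ...) {
  mu <- object$params$class_means %*% t(object$design$lambda)
  object$posteriors %*% mu
}

#' @export
residuals.gmm <- function(object, ...) object$data - fitted(object)

#' @export
simulate.gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim,
                   simulate_from_params(object$params, object$n_used,
                                        object$design)$y,
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' Plot implied class mean trajectories
#'
#' @param x a [gmm()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gmm <- function(x, ...) {
  mt <- x$params$class_means %*% t(x$design$lambda)
  graphics::matplot(x$design$time_scores, t(mt), type = "b", pch = 19,
                    lty = 1, xlab = "time score", ylab = "vision score",
                    ylim = c(1, 4), ...)
  graphics::legend("bottomleft",
                   legend = sprintf("%s (%.1f%%)", class_label_names(x),
                                    100 * x$params$pi),
                   col = seq_len(x$K), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
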