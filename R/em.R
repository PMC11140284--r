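# EM engine for the latent linear growth model and its K-class mixture.
#
# Model, per subject i with observed wave set o(i):
#   class c_i ~ Categorical(pi),  eta_i | c_i = k ~ N(alpha_k, Psi),
#   y_i = Lambda[o(i), ] eta_i + eps_i,  eps_i ~ N(0, diag(theta)[o(i)]).
# Psi and theta are shared across classes; only the growth-factor means
# differ. EM treats (c_i, eta_i) as missing data, so each iteration is a
# closed-form update and the observed-data log-likelihood is monotone.

THETA_FLOOR <- 1e-4
PSI_EIG_FLOOR <- 1e-6

# split rows of y by missingness pattern; rows with no observed wave excluded
pattern_split <- function(y) {
  obs <- !is.na(y)
  keep <- rowSums(obs) > 0L
  if (!all(keep)) stop("subjects with no observed waves present", call. = FALSE)
  key <- apply(obs, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(y)), key), function(idx) {
    o <- which(obs[idx[1L], ])
    list(rows = idx, obs = o, y = y[idx, o, drop = FALSE])
  })
}

# log-density + conditional growth-factor moments for one pattern/class
pattern_class_estep <- function(pat, alpha_k, Psi, theta, Lambda) {
  Lo <- Lambda[pat$obs, , drop = FALSE]
  Sig <- Lo %*% Psi %*% t(Lo) + diag(theta[pat$obs], length(pat$obs))
  R <- tryCatch(chol(Sig), error = function(e)
    stop("singular implied covariance (condition number ~ ",
         format(kappa(Sig)), ")", call. = FALSE))
  mu <- drop(Lo %*% alpha_k)
  E <- sweep(pat$y, 2L, mu)                        # centered observations
  Z <- backsolve(R, t(E), transpose = TRUE)        # R^-T E'
  logdens <- -0.5 * (length(pat$obs) * log(2 * pi) +
                     2 * sum(log(diag(R))) + colSums(Z^2))
  Ct <- backsolve(R, backsolve(R, Lo %*% Psi, transpose = TRUE)) # Sig^-1 Lo Psi
  m <- sweep(E %*% Ct, 2L, alpha_k, `+`)           # E[eta | y, class k]
  V <- Psi - t(Ct) %*% (Lo %*% Psi)                # Var[eta | y, class k]
  list(logdens = logdens, m = m, V = (V + t(V)) / 2)
}

floor_psi <- function(Psi) {
  e <- eigen((Psi + t(Psi)) / 2, symmetric = TRUE)
  if (all(e$values >= PSI_EIG_FLOOR)) return(list(Psi = (Psi + t(Psi)) / 2,
                                                  floored = FALSE))
  list(Psi = e$vectors %*% diag(pmax(e$values, PSI_EIG_FLOOR), 2) %*%
         t(e$vectors), floored = TRUE)
}

# one EM run from a given start; returns NULL-free list or condition
em_run <- function(y, Lambda, K, init, max_iter = 500L, tol = 1e-6,
                   equal_theta = FALSE) {
  n <- nrow(y); p <- ncol(y)
  pats <- pattern_split(y)
  pi_k <- init$pi; alpha <- init$alpha; Psi <- init$psi; theta <- init$theta
  ll_old <- -Inf; ll_trace <- numeric(0)
  min_increment <- Inf; floors <- 0L
  post <- matrix(NA_real_, n, K)
  for (iter in seq_len(max_iter)) {
    # E-step
    logd <- matrix(NA_real_, n, K)
    es <- vector("list", length(pats))
    for (j in seq_along(pats)) {
      es[[j]] <- lapply(seq_len(K), function(k)
        pattern_class_estep(pats[[j]], alpha[k, ], Psi, theta, Lambda))
      for (k in seq_len(K)) logd[pats[[j]]$rows, k] <- es[[j]][[k]]$logdens
    }
    lw <- sweep(logd, 2L, log(pi_k), `+`)
    mx <- apply(lw, 1L, max)
    w <- exp(lw - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    post <- w / rs
    if (iter > 1L) min_increment <- min(min_increment, ll - ll_old)
    ll_trace <- c(ll_trace, ll)
    converged <- is.finite(ll_old) && abs(ll - ll_old) < tol
    ll_old <- ll
    if (converged) break
    # M-step
    nk <- colSums(post)
    if (any(nk < 1e-8)) stop("class collapsed to zero weight", call. = FALSE)
    pi_k <- nk / n
    alpha_new <- matrix(0, K, 2)
    Psi_acc <- matrix(0, 2, 2)
    theta_num <- numeric(p); theta_den <- numeric(p)
    for (k in seq_len(K)) {
      num <- c(0, 0)
      for (j in seq_along(pats)) {
        pk <- post[pats[[j]]$rows, k]
        num <- num + colSums(es[[j]][[k]]$m * pk)
      }
      alpha_new[k, ] <- num / nk[k]
    }
    for (j in seq_along(pats)) {
      pat <- pats[[j]]
      Lo <- Lambda[pat$obs, , drop = FALSE]
      for (k in seq_len(K)) {
        pk <- post[pat$rows, k]
        M <- sweep(es[[j]][[k]]$m, 2L, alpha_new[k, ])
        Psi_acc <- Psi_acc + crossprod(M, M * pk) + sum(pk) * es[[j]][[k]]$V
        Eres <- pat$y - es[[j]][[k]]$m %*% t(Lo)
        lvl <- rowSums((Lo %*% es[[j]][[k]]$V) * Lo)  # diag(Lo V Lo')
        theta_num[pat$obs] <- theta_num[pat$obs] +
          colSums(Eres^2 * pk) + sum(pk) * lvl
        theta_den[pat$obs] <- theta_den[pat$obs] + sum(pk)
      }
    }
    alpha <- alpha_new
    fp <- floor_psi(Psi_acc / n)
    Psi <- fp$Psi
    theta <- theta_num / pmax(theta_den, 1)
    if (equal_theta) theta <- rep(sum(theta_num) / sum(theta_den), p)
    if (fp$floored || any(theta < THETA_FLOOR)) floors <- floors + 1L
    theta <- pmax(theta, THETA_FLOOR)
  }
  list(pi = pi_k, alpha = alpha, psi = Psi, theta = theta,
       posteriors = post, loglik = ll_old, n_iter = iter,
       converged = converged, min_increment = min_increment,
       ll_trace = ll_trace, n_floor_activations = floors)
}

# per-subject OLS (intercept, slope) estimates used to seed EM starts
ols_growth_estimates <- function(y, time_scores) {
  n <- nrow(y)
  b <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    o <- which(!is.na(y[i, ]))
    if (length(o) >= 2L) {
      fit <- stats::lm.fit(cbind(1, time_scores[o]), y[i, o])
      b[i, ] <- fit$coefficients
    } else {
      b[i, ] <- c(mean(y[i, o]), 0)
    }
  }
  b
}

# start list: start 1 from k-means on OLS growth estimates, the rest
# seed-controlled random perturbations of it
make_starts <- function(y, Lambda, K, n_starts, seed) {
  time_scores <- Lambda[, 2L]
  b <- ols_growth_estimates(y, time_scores)
  if (!is.null(seed)) set.seed(seed)
  km <- tryCatch(stats::kmeans(b, centers = K, nstart = 5L),
                 error = function(e) NULL)
  if (is.null(km)) {
    ord <- order(b[, 1L])
    grp <- cut(seq_along(ord), K, labels = FALSE)[order(ord)]
    centers <- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(b[grp == k, , drop = FALSE])))
    shares <- tabulate(grp, K) / nrow(b)
  } else {
    centers <- km$centers
    shares <- km$size / nrow(b)
  }
  within_var <- pmax(apply(b, 2L, stats::var) / 4, c(1e-3, 1e-4))
  psi0 <- diag(within_var, 2)
  theta0 <- rep(max(stats::var(as.numeric(y), na.rm = TRUE) / 4, 0.05),
                ncol(y))
  base <- list(pi = pmax(shares, 0.05) / sum(pmax(shares, 0.05)),
               alpha = unname(centers), psi = psi0, theta = theta0)
  starts <- vector("list", n_starts)
  starts[[1L]] <- base
  sds <- apply(b, 2L, stats::sd)
  for (s in seq_len(n_starts)[-1L]) {
    st <- base
    st$alpha <- base$alpha +
      matrix(stats::rnorm(2 * K, sd = rep(sds / 2, each = K)), K, 2)
    u <- stats::runif(K, 0.2, 1)
    st$pi <- u / sum(u)
    starts[[s]] <- st
  }
  starts
}
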