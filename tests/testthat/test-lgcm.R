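test_that("implied moments follow the loading structure", {
  des <- growth_design(4)
  m <- implied_moments(list(alpha = c(4, 0), psi = matrix(0, 2, 2),
                            theta = 0), des)
  expect_equal(m$mean, rep(4, 4))
  expect_equal(m$cov, matrix(0, 4, 4))

  m <- implied_moments(list(alpha = c(3.992, -0.174), psi = matrix(0, 2, 2),
                            theta = 0), des)
  expect_equal(m$mean, c(3.992, 3.818, 3.644, 3.470))

  m <- implied_moments(list(alpha = c(0, 0), psi = diag(2), theta = 0.2), des)
  t <- des$time_scores
  expect_equal(m$cov, outer(t, t) + 1 + 0.2 * diag(4))
})

test_that("implied moments are linear in the parameters", {
  des <- growth_design(4)
  p1 <- list(alpha = c(1, 2), psi = matrix(c(2, 1, 1, 3), 2), theta = 1:4)
  p2 <- list(alpha = c(-3, 1), psi = diag(c(1, 2)), theta = rep(0.5, 4))
  psum <- list(alpha = p1$alpha + p2$alpha, psi = p1$psi + p2$psi,
               theta = p1$theta + p2$theta)
  m1 <- implied_moments(p1, des); m2 <- implied_moments(p2, des)
  ms <- implied_moments(psum, des)
  expect_equal(ms$mean, m1$mean + m2$mean)
  expect_equal(ms$cov, m1$cov + m2$cov)
})

test_that("fit indices match their closed forms", {
  fi <- fit_indices(14.345, 5, 500, 6, 2235)
  expect_equal(fi$rmsea, sqrt(9.345 / (5 * 2234)), tolerance = 1e-10)
  expect_equal(round(fi$rmsea, 3), 0.029)
  expect_equal(fi$cfi, 1 - 9.345 / 494, tolerance = 1e-10)
  expect_equal(fi$chi_df_ratio, 2.869)

  # perfect-fit limit
  fi0 <- fit_indices(5, 5, 500, 6, 2235)
  expect_equal(fi0$rmsea, 0)
  expect_equal(fi0$cfi, 1)

  # SRMR: hand-computed on a 2x2 residual
  S <- matrix(c(4, 1, 1, 9), 2)
  Sg <- matrix(c(4, 0.4, 0.4, 9), 2)
  fi2 <- fit_indices(10, 1, 50, 1.5, 100, sample_cov = S, implied_cov = Sg)
  expect_equal(fi2$srmr, sqrt(mean(c(0, (0.6 / 6)^2, 0))))

  expect_error(fit_indices(10, 5, 20, 5, 100), "df_baseline")
})

test_that("saturated input is fit perfectly and parameters recovered", {
  des <- growth_design(4)
  truth <- list(alpha = c(3.7, -0.1), psi = diag(c(0.06, 0.004)),
                theta = rep(0.02, 4))
  im <- implied_moments(truth, des)
  set.seed(42)
  n <- 500
  Z <- matrix(rnorm(n * 4), n, 4)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  W <- Zc %*% solve(chol(cov(Zc)))          # exact identity covariance
  y <- W %*% chol(im$cov) + matrix(im$mean, n, 4, byrow = TRUE)
  fit <- lgcm(y, des)
  expect_lt(fit$fit$chi_square, 0.05)
  expect_equal(fit$fit$cfi, 1)
  expect_lt(fit$fit$rmsea, 0.01)
  expect_lt(fit$fit$srmr, 0.005)
  expect_equal(unname(fit$params$alpha), truth$alpha, tolerance = 0.01)
  expect_equal(fit$params$theta, truth$theta, tolerance = 0.05)
})

test_that("ML recovers generating one-class parameters at n = 2000", {
  cfg <- one_class_config(n = 2000, seed = 77)
  fit <- lgcm(simulate_trajectories(cfg))
  expect_lt(abs(fit$params$alpha[1] - 3.745), 0.03)
  expect_lt(abs(fit$params$alpha[2] + 0.088), 0.01)
  expect_lt(abs(fit$params$psi[1, 1] - 0.06), 0.02)
  expect_lt(abs(fit$params$psi[2, 2] - 0.004), 0.003)
  expect_true(all(abs(fit$params$theta - 0.02) < 0.01))
  # ML optimality: fitted likelihood beats the generating parameters
  truth <- list(pi = 1, class_means = rbind(c(3.745, -0.088)),
                psi = diag(c(0.06, 0.004)), theta = rep(0.02, 4))
  expect_gte(fit$loglik, mixture_loglik(truth, fit$data))
})

test_that("full-information fit over observed waves matches complete-data fit", {
  cfg <- one_class_config(n = 2000, seed = 31)
  co <- simulate_trajectories(cfg)
  full <- lgcm(co)
  set.seed(31)
  masked <- apply_missingness(co, 0.2)
  part <- lgcm(masked, allow_partial = TRUE, min_waves = 3)
  expect_gt(part$n_used, 1200)
  expect_equal(unname(part$params$alpha), unname(full$params$alpha),
               tolerance = 0.02)
  expect_equal(part$params$theta, full$params$theta, tolerance = 0.25)
  expect_true(is.finite(part$fit$chi_square))
  expect_gt(part$fit$cfi, 0.95)
})

test_that("fit is invariant to subject ordering", {
  cfg <- one_class_config(n = 400, seed = 55)
  y <- vision_matrix(simulate_trajectories(cfg))
  f1 <- lgcm(y)
  f2 <- lgcm(y[sample(nrow(y)), ])
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$fit$chi_square, f2$fit$chi_square, tolerance = 1e-6)
  expect_equal(f1$params$alpha, f2$params$alpha, tolerance = 1e-6)
})

test_that("too-small samples are rejected", {
  y <- matrix(rnorm(20), 5, 4)
  expect_error(lgcm(y), "fewer subjects")
})
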