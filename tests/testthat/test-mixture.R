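test_that("mixture likelihood collapses correctly for K = 1 and twin classes", {
  cfg <- one_class_config(n = 300, seed = 9)
  y <- vision_matrix(simulate_trajectories(cfg))
  f <- lgcm(y)
  p1 <- list(pi = 1, class_means = rbind(unname(f$params$alpha)),
             psi = f$params$psi, theta = f$params$theta)
  expect_equal(mixture_loglik(p1, y), f$loglik, tolerance = 1e-8)
  twin <- list(pi = c(0.5, 0.5),
               class_means = rbind(p1$class_means, p1$class_means),
               psi = f$params$psi, theta = f$params$theta)
  expect_equal(mixture_loglik(twin, y), f$loglik, tolerance = 1e-8)
})

test_that("mixture likelihood matches a brute-force density oracle", {
  des <- growth_design(4)
  y <- rbind(c(4.0, 3.8, 3.7, 3.4),
             c(2.5, 2.9, 3.1, 3.5),
             c(3.2, 3.1, NA, 2.8))
  params <- list(pi = c(0.7, 0.3),
                 class_means = rbind(c(3.9, -0.17), c(2.6, 0.3)),
                 psi = matrix(c(0.06, 0.01, 0.01, 0.004), 2),
                 theta = c(0.02, 0.03, 0.02, 0.05))
  ll_oracle <- 0
  for (i in 1:3) {
    o <- which(!is.na(y[i, ]))
    L <- des$lambda[o, , drop = FALSE]
    dens <- sapply(1:2, function(k) {
      mu <- drop(L %*% params$class_means[k, ])
      S <- L %*% params$psi %*% t(L) + diag(params$theta[o], length(o))
      exp(dmvnorm_log_oracle(y[i, o], mu, S))
    })
    ll_oracle <- ll_oracle + log(sum(params$pi * dens))
  }
  expect_equal(mixture_loglik(params, y, des), ll_oracle, tolerance = 1e-10)
})

test_that("singular implied covariance is reported with a diagnostic", {
  params <- list(pi = 1, class_means = rbind(c(3, 0)),
                 psi = matrix(0, 2, 2), theta = rep(0, 4))
  y <- matrix(rnorm(40, 3), 10, 4)
  expect_error(mixture_loglik(params, y), "singular|condition")
})

test_that("one-class EM reproduces the growth-curve fit", {
  cfg <- one_class_config(n = 500, seed = 15)
  y <- vision_matrix(simulate_trajectories(cfg))
  f_lgcm <- lgcm(y, tol = 1e-10)
  f_gmm <- gmm(y, 1, n_starts = 3, seed = 1, tol = 1e-10, max_iter = 3000)
  expect_equal(f_gmm$loglik, f_lgcm$loglik, tolerance = 1e-6)
  expect_equal(unname(f_gmm$params$class_means[1, ]),
               unname(f_lgcm$params$alpha), tolerance = 1e-3)
  # IC equality between the two one-class routes (same free parameters)
  ic <- information_criteria(f_lgcm$loglik, 9, nrow(y))
  expect_equal(unname(f_gmm$ic), unname(ic), tolerance = 1e-5)
})

test_that("EM recovers a well-separated two-class structure", {
  co <- simulate_trajectories(paper_config(n = 1200, seed = 21))
  fit <- gmm(co, 2, n_starts = 20, seed = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$pi[1] - 0.819), 0.03)
  expect_lt(max(abs(fit$params$class_means -
                      rbind(c(3.992, -0.174), c(2.641, 0.296)))), 0.06)
  expect_gt(fit$entropy, 0.98)
  # recovery of true memberships
  agree <- mean(max.col(fit$posteriors) == co$true_class)
  expect_gt(agree, 0.98)
})

test_that("solutions are canonical: permutation and seed invariance", {
  y <- vision_matrix(simulate_trajectories(paper_config(n = 600, seed = 33)))
  f1 <- gmm(y, 2, n_starts = 10, seed = 1)
  f2 <- gmm(y[sample(nrow(y)), ], 2, n_starts = 10, seed = 99)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$params$class_means, f2$params$class_means,
               tolerance = 1e-4)
  expect_equal(f1$params$pi, f2$params$pi, tolerance = 1e-4)
  # class 1 is always the higher-intercept class
  expect_gt(f1$params$class_means[1, 1], f1$params$class_means[2, 1])
})

test_that("EM log-likelihood is monotone on every run", {
  set.seed(44)
  for (rep in 1:4) {
    n <- sample(100:300, 1)
    co <- simulate_trajectories(sim_config(
      n_subjects = n,
      class_proportions = c(0.6, 0.4),
      class_means = rbind(c(3.8, -0.1), c(2.8, 0.2)),
      seed = NULL))
    fit <- gmm(co, 2, n_starts = 4, max_iter = 200, tol = 1e-5)
    expect_gt(fit$min_ll_increment, -1e-6)
  }
})

test_that("posterior rows sum to one and entropy behaves", {
  y <- vision_matrix(simulate_trajectories(paper_config(n = 400, seed = 8)))
  fit <- gmm(y, 2, n_starts = 6, seed = 2)
  expect_true(all(abs(rowSums(fit$posteriors) - 1) < 1e-10))
  expect_true(fit$entropy >= 0 && fit$entropy <= 1)

  expect_equal(entropy(diag(3)[c(1, 2, 3, 1), ]), 1)
  expect_equal(entropy(matrix(1 / 4, 6, 4)), 0)
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_equal(entropy(p), 0.404539, tolerance = 5e-4)
  expect_equal(entropy(p), entropy(p[, 2:1]))   # relabel invariance
  expect_true(is.na(entropy(matrix(1, 5, 1))))
})

test_that("information criteria follow their definitions", {
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0, 0))
  ic <- information_criteria(-100, 12, 2235)
  expect_equal(unname(ic), c(224, 200 + 12 * log(2235),
                             200 + 12 * log(2237 / 24)))
  # parameter count: K=2, 4 waves, wave-specific residuals, full psi
  fit <- gmm(vision_matrix(simulate_trajectories(paper_config(n = 200,
                                                              seed = 2))),
             2, n_starts = 4, seed = 1)
  expect_identical(fit$n_free_params, 12L)
})

test_that("bootstrap LRT attains its minimum p on strongly two-class data", {
  y <- vision_matrix(simulate_trajectories(paper_config(n = 500, seed = 61)))
  res <- blrt(y, K = 2, B = 39, seed = 5, n_starts = 6, boot_starts = 2,
              max_iter = 200, tol = 1e-4)
  expect_equal(res$p_value, 1 / 40)
  expect_gt(res$lrt_obs, max(res$lrt_boot[is.finite(res$lrt_boot)]))
  expect_error(blrt(y, K = 2, B = 0), "B must be")
})

test_that("approximate LMR test agrees with BLRT decisions", {
  y <- vision_matrix(simulate_trajectories(paper_config(n = 500, seed = 62)))
  f1 <- gmm(y, 1, n_starts = 3, seed = 1)
  f2 <- gmm(y, 2, n_starts = 6, seed = 1)
  res <- lmr_test(f2, f1)
  expect_lt(res$p_value, 0.001)
  expect_true(res$approximate)
  # worse K-class fit returns p = 1 with a warning
  expect_warning(res_bad <- lmr_test(f1_fake <- f1, f2), "lower likelihood")
  expect_equal(res_bad$p_value, 1)
})

test_that("LMR rarely rejects on one-class data", {
  set.seed(70)
  ps <- replicate(25, {
    y <- vision_matrix(simulate_trajectories(one_class_config(n = 200,
                                                              seed = NULL)))
    f1 <- gmm(y, 1, n_starts = 2, max_iter = 100, tol = 1e-4)
    f2 <- gmm(y, 2, n_starts = 4, max_iter = 100, tol = 1e-4)
    suppressWarnings(lmr_test(f2, f1)$p_value)  # K=2 may fit worse than K=1
  })
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("enumeration selects two classes and reports the full table", {
  co <- simulate_trajectories(paper_config(n = 600, seed = 81))
  enum <- enumerate_classes(co, K_max = 3, B = 20, seed = 4, n_starts = 8,
                            boot_starts = 2, max_iter = 300, tol = 1e-5)
  expect_equal(enum$selected_K, 2L)
  expect_equal(nrow(enum$table), 3L)
  expect_true(is.na(enum$table$vlmr_p[1]))
  shares <- as.numeric(strsplit(enum$table$class_shares[2], "/")[[1]])
  expect_lt(abs(shares[1] - 0.819), 0.06)
  # BIC should prefer 2 classes over 1
  expect_lt(enum$table$bic[2], enum$table$bic[1])
})

test_that("enumeration stays at one class for one-class data", {
  co <- simulate_trajectories(one_class_config(n = 400, seed = 82))
  enum <- enumerate_classes(co, K_max = 2, B = 20, seed = 6, n_starts = 4,
                            boot_starts = 2, max_iter = 150, tol = 1e-4)
  expect_equal(enum$selected_K, 1L)
})

test_that("the 5% rule vetoes a tiny second class", {
  cfg <- sim_config(n_subjects = 1000, class_proportions = c(0.97, 0.03),
                    seed = 83)
  co <- simulate_trajectories(cfg)
  enum <- enumerate_classes(co, K_max = 2, B = 20, seed = 7, n_starts = 8,
                            boot_starts = 2, max_iter = 300, tol = 1e-5)
  expect_equal(enum$selected_K, 1L)
  expect_true(any(grepl("5% rule", enum$selection_trace)))
})

test_that("modal labels, shares and tie-breaking are as documented", {
  y <- vision_matrix(simulate_trajectories(paper_config(n = 600, seed = 91)))
  fit <- gmm(y, 2, n_starts = 8, seed = 3)
  labs <- assign_labels(fit)
  expect_setequal(levels(labs),
                  c("high-baseline decline", "low-baseline improvement"))
  shares <- attr(labs, "shares")
  expect_lt(abs(shares[["high-baseline decline"]] - 0.819), 0.06)
  # tie goes to the lower (higher-intercept) class index
  fit_tie <- fit
  fit_tie$posteriors[1, ] <- c(0.5, 0.5)
  labs_tie <- assign_labels(fit_tie)
  expect_equal(as.character(labs_tie[1]), "high-baseline decline")
  # posterior prediction on new data reproduces training posteriors
  post <- predict(fit, newdata = y)
  expect_equal(post, fit$posteriors, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("one-class growth means equal the mixture-weighted class means", {
  co <- simulate_trajectories(paper_config(n = 2000, seed = 95))
  f <- lgcm(co)
  expect_lt(abs(f$params$alpha[1] - 3.7475), 0.04)
  expect_lt(abs(f$params$alpha[2] + 0.0889), 0.02)
})
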