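test_that("logistic fit on a 2x2 table equals the closed-form odds ratio", {
  co <- make_2x2_cohort(90, 1740, 67, 338)   # cataract by class counts
  res <- logistic_fit(co, "y", "x")
  or_closed <- (90 * 338) / (67 * 1740)
  expect_equal(res$or[res$term == "x"], or_closed, tolerance = 1e-8)
  expect_equal(res$estimate[res$term == "x"], log(or_closed),
               tolerance = 1e-8)
  expect_equal(res$or_low[res$term == "x"],
               exp(res$ci_low[res$term == "x"]))
})

test_that("null predictors give odds ratios near 1 with covering intervals", {
  set.seed(5)
  n <- 4000
  df <- data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n))
  res <- logistic_fit(df, "y", "x")
  row <- res[res$term == "x", ]
  expect_lt(abs(row$or - 1), 0.1)
  expect_true(row$ci_low < 0 && row$ci_high > 0)
})

test_that("logistic recovery of generating log-odds effects", {
  set.seed(17)
  n <- 3000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.3)
  eta <- -0.5 + 0.8 * x1 - 0.6 * x2
  df <- data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2)
  res <- logistic_fit(df, "y", c("x1", "x2"))
  expect_lt(abs(res$estimate[res$term == "x1"] - 0.8),
            3 * res$se[res$term == "x1"])
  expect_lt(abs(res$estimate[res$term == "x2"] + 0.6),
            3 * res$se[res$term == "x2"])
})

test_that("separation and collinearity are reported", {
  df <- data.frame(y = rep(c(0, 1), each = 20),
                   x = rep(c(0, 1), each = 20) + 0)
  expect_error(logistic_fit(df, "y", "x"), "separation")
  df2 <- data.frame(y = rbinom(40, 1, 0.5), a = rnorm(40))
  df2$b <- df2$a
  expect_error(logistic_fit(df2, "y", c("a", "b")), "collinear")
})

test_that("linear model-1 coefficient equals the raw group mean difference", {
  set.seed(23)
  g <- rbinom(500, 1, 0.8)
  out <- 24 + 3.186 * g + rnorm(500, 0, 6)
  df <- data.frame(cognition = out, high = g)
  res <- linear_fit(df, "cognition", "high")
  expect_equal(res$estimate[res$term == "high"],
               mean(out[g == 1]) - mean(out[g == 0]), tolerance = 1e-12)
  # outcome identical to the indicator: slope 1, zero residual
  df$exact <- df$high
  res2 <- suppressWarnings(linear_fit(df, "exact", "high"))  # exact fit
  expect_equal(res2$estimate[res2$term == "high"], 1, tolerance = 1e-12)
  expect_lt(res2$se[res2$term == "high"], 1e-8)
})

test_that("distal-outcome shifts are recovered from the generator", {
  co <- simulate_cohort(paper_config(seed = 71))
  co$high <- as.integer(co$true_class == 1L)
  for (spec in list(c("cognition", 3.186), c("adl", -0.505),
                    c("iadl", -2.447), c("depression", 1.209))) {
    res <- linear_fit(co, spec[1], "high")
    row <- res[res$term == "high", ]
    expect_lt(abs(row$estimate - as.numeric(spec[2])), 3 * row$se)
  }
  fall <- logistic_fit(co, "fall", "high")
  row <- fall[fall$term == "high", ]
  expect_lt(abs(row$estimate - log(1.075)), 3 * row$se)
})

test_that("Wald intervals achieve near-nominal coverage for the class effect", {
  set.seed(29)
  hits <- replicate(200, {
    g <- rbinom(400, 1, 0.8)
    out <- 24 + 2 * g + rnorm(400, 0, 6)
    res <- linear_fit(data.frame(y = out, g = g), "y", "g")
    row <- res[res$term == "g", ]
    row$ci_low <= 2 && 2 <= row$ci_high
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("regression output is invariant to row order and rescaling", {
  set.seed(37)
  df <- data.frame(y = rbinom(300, 1, 0.5), x = rnorm(300, 2, 3))
  r1 <- logistic_fit(df, "y", "x")
  r2 <- logistic_fit(df[sample(300), ], "y", "x")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  df$x10 <- df$x / 10
  r3 <- logistic_fit(df, "y", "x10")
  expect_equal(r3$estimate[r3$term == "x10"],
               10 * r1$estimate[r1$term == "x"], tolerance = 1e-6)
})

test_that("restricted cubic spline basis matches its truncated-power form", {
  knots <- c(18, 21, 24, 28)
  x <- c(15, 22, 30, 35)
  B <- rcs_basis(x, knots)
  expect_identical(dim(B), c(4L, 3L))
  # below the first knot all nonlinear terms vanish
  expect_equal(unname(B[1, 2:3]), c(0, 0))
  # hand evaluation at x = 22
  cub <- function(u) pmax(u, 0)^3
  hand <- function(xx, tj) {
    (cub(xx - tj) - cub(xx - 24) * (28 - tj) / (28 - 24) +
       cub(xx - 28) * (24 - tj) / (28 - 24)) / (28 - 18)^2
  }
  expect_equal(unname(B[2, 2]), hand(22, 18), tolerance = 1e-12)
  expect_equal(unname(B[2, 3]), hand(22, 21), tolerance = 1e-12)
  # linear beyond the boundary knots: second differences vanish
  xg <- c(29, 30, 31, 32)
  Bg <- rcs_basis(c(knots, xg), knots)[-(1:4), ]
  for (j in 1:3) {
    sd2 <- diff(diff(Bg[, j]))
    expect_true(all(abs(sd2) < 1e-9))
  }
  expect_error(rcs_basis(c(19, 20), knots), "outside the data range")
  expect_error(rcs_basis(x, c(21, 18)), "increasing")
})

test_that("spline dose-response detects curvature and centres at the reference", {
  set.seed(41)
  n <- 3000
  bmi <- rnorm(n, 21, 3)
  eta <- 0.3 * (bmi - 21) - 0.08 * (bmi - 21)^2
  df <- data.frame(y = rbinom(n, 1, plogis(eta)), bmi = bmi)
  res <- rcs_dose_response(df, "bmi", "y", ref = 21)
  expect_lt(res$p_nonlinear, 0.05)
  at_ref <- rcs_dose_response(df, "bmi", "y", ref = 21,
                              grid = 21)$curve$log_odds
  expect_equal(at_ref, 0, tolerance = 1e-12)
  # a purely linear effect rarely triggers the nonlinearity test
  rejections <- replicate(25, {
    b <- rnorm(500, 21, 3)
    d <- data.frame(y = rbinom(500, 1, plogis(0.2 * (b - 21))), bmi = b)
    rcs_dose_response(d, "bmi", "y")$p_nonlinear < 0.05
  })
  expect_lt(mean(rejections), 0.25)
})

test_that("Rubin pooling reproduces the hand-computed toy case", {
  pooled <- rubin_pool(c(1.0, 1.2, 1.4), c(0.04, 0.04, 0.04))
  expect_equal(unname(pooled$estimate), 1.2)
  expect_equal(unname(pooled$between), 0.04)
  expect_equal(unname(pooled$total), 0.04 + (1 + 1 / 3) * 0.04,
               tolerance = 1e-12)
  expect_equal(unname(pooled$se), sqrt(0.09333333), tolerance = 1e-6)
})

test_that("imputation falls back to the direct fit when nothing is missing", {
  set.seed(47)
  df <- data.frame(y = rbinom(400, 1, 0.5), x = rnorm(400))
  direct <- logistic_fit(df, "y", "x")
  mi <- impute_and_pool(df, "y", "x", m = 3, seed = 1)
  expect_equal(mi$estimate, direct$estimate, tolerance = 1e-12)
  expect_identical(attr(mi, "n_imputations"), 0L)
})

test_that("chained imputation recovers effects under 15% MCAR missingness", {
  set.seed(53)
  n <- 1500
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.7 * x1 + 0.4 * x2))
  df <- data.frame(y = y, x1 = x1, x2 = x2)
  df$x2[runif(n) < 0.15] <- NA
  res <- impute_and_pool(df, "y", c("x1", "x2"), m = 5, seed = 2)
  expect_identical(attr(res, "n_imputations"), 5L)
  r1 <- res[res$term == "x1", ]; r2 <- res[res$term == "x2", ]
  expect_lt(abs(r1$estimate - 0.7), 3 * r1$se)
  expect_lt(abs(r2$estimate - 0.4), 3 * r2$se)
  expect_true(all(attr(res, "between_variance")[-1] > 0))
  df_bad <- df; df_bad$x2 <- NA
  expect_error(impute_and_pool(df_bad, "y", c("x1", "x2")),
               "no observed values")
})
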