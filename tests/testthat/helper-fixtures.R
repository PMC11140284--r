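# shared fixtures: all data built in code, seeds fixed per call site

paper_config <- function(n = 2235, seed = 101, ...) {
  sim_config(n_subjects = n, seed = seed, ...)
}

one_class_config <- function(n = 800, seed = 202, ...) {
  sim_config(n_subjects = n, class_proportions = 1,
             class_means = rbind(c(3.745, -0.088)), seed = seed, ...)
}

# independent multivariate-normal log-density oracle: direct solve/det,
# no Cholesky backsolves shared with the implementation
dmvnorm_log_oracle <- function(x, mu, Sigma) {
  d <- length(mu)
  -0.5 * (d * log(2 * pi) + log(det(Sigma)) +
            drop(t(x - mu) %*% solve(Sigma) %*% (x - mu)))
}

make_2x2_cohort <- function(a, b, c_, d) {
  # a: exposed events, b: unexposed events, c_: exposed non-events,
  # d: unexposed non-events
  data.frame(
    y = rep(c(1, 1, 0, 0), c(a, b, c_, d)),
    x = rep(c(1, 0, 1, 0), c(a, b, c_, d)))
}

# cache for expensive shared fits used by several acceptance blocks
.accept_cache <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (!is.null(.accept_cache$pipeline)) return(.accept_cache$pipeline)
  sim <- read_sim_config(system.file("extdata", "paper_like.yaml",
                                     package = "vistraj"))
  sim$n_subjects <- 700L
  pc <- pipeline_config(sim = sim, K_max = 2, B = 20, n_starts = 8,
                        boot_starts = 2, seed = 42, mi_m = 0)
  .accept_cache$pipeline <- list(pc = pc, bundle = run_pipeline(pc))
  .accept_cache$pipeline
}

accept_fixture <- function() {
  if (!is.null(.accept_cache$fits)) return(.accept_cache$fits)
  cohort <- simulate_trajectories(paper_config(seed = 2026))
  fit1 <- lgcm(cohort)
  fit2 <- gmm(cohort, 2, n_starts = 50, seed = 11)
  .accept_cache$fits <- list(cohort = cohort, fit1 = fit1, fit2 = fit2)
  .accept_cache$fits
}
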