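# all-L histories make the likelihood depend on (s, p) only, giving
# closed-form posterior moments under the uniform priors -- an independent
# oracle for the sampler
all_L_set <- function(m, n_years = 2) {
  ev <- stats::setNames(rep("L", n_years), 2000 + seq_len(n_years))
  capture_history_set(paste0("B", seq_len(m)), rep(2000, m),
                      rep("nestling", m),
                      replicate(m, ev, simplify = FALSE),
                      c(2000, 2000 + n_years))
}

test_that("same seed reproduces draws exactly; different seeds differ", {
  set <- all_L_set(3)
  f1 <- mrr_fit(set, mrr_model("S"), warmup = 50, iter = 50, seed = 7)
  f2 <- mrr_fit(set, mrr_model("S"), warmup = 50, iter = 50, seed = 7)
  f3 <- mrr_fit(set, mrr_model("S"), warmup = 50, iter = 50, seed = 8)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("sampler matches the analytic posterior in conjugate reductions", {
  # m birds, two post-marking L's each: likelihood (s p)^(2m); under
  # U(0,1) x U(0,0.5) priors, E[s] = (2m+1)/(2m+2), E[p] = 0.5 E[s],
  # and r, eta stay at their priors (mean 0.25)
  m <- 4
  fit <- mrr_fit(all_L_set(m), mrr_model("S"), warmup = 2000, iter = 6000,
                 seed = 42)
  post <- coef(fit)
  expect_equal(unname(post["s"]), (2 * m + 1) / (2 * m + 2),
               tolerance = 0.02)
  expect_equal(unname(post["p"]), 0.5 * (2 * m + 1) / (2 * m + 2),
               tolerance = 0.02)
  expect_lt(abs(post[["r"]] - 0.25), 0.02)
  expect_lt(abs(post[["eta"]] - 0.25), 0.02)

  # degenerate one-bird dataset vs 2-D grid integration of the posterior
  fit1 <- mrr_fit(all_L_set(1, n_years = 1), mrr_model("S"),
                  warmup = 2000, iter = 6000, seed = 5)
  gs <- seq(1e-4, 1 - 1e-4, length.out = 400)
  gp <- seq(1e-4, 0.5 - 1e-4, length.out = 400)
  dens <- outer(gs, gp)              # likelihood s * p on the grid
  E_p_grid <- sum(t(dens) * gp) / sum(dens)
  E_s_grid <- sum(dens * gs) / sum(dens)
  expect_equal(unname(coef(fit1)["p"]), E_p_grid, tolerance = 0.02)
  expect_equal(unname(coef(fit1)["s"]), E_s_grid, tolerance = 0.03)
})

test_that("split rank-normalized R-hat flags mixing failures only", {
  # identical constant chains
  expect_equal(rhat(matrix(3.2, 100, 3)), 1)
  # same-distribution chains approach 1
  set.seed(2)
  expect_lt(rhat(matrix(rnorm(30000), 10000, 3)), 1.01)
  # disjoint supports
  bad <- cbind(rnorm(500), rnorm(500) + 50)
  expect_gt(rhat(bad), 1.5)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  # heavy-tailed location shift is caught through rank normalization
  shifted <- cbind(rcauchy(2000), rcauchy(2000) + 5)
  expect_gt(rhat(shifted), 1.1)
})

test_that("posterior summaries report pooled means, quantiles and R-hat", {
  const <- fake_fit(array(0.7, c(100, 3, 1),
                          dimnames = list(NULL, NULL, "s1")))
  s <- summary(const)
  expect_equal(s$mean, 0.7)
  expect_equal(s$lower95, 0.7)
  expect_equal(s$upper95, 0.7)
  expect_equal(s$rhat, 1)
  set.seed(12)
  big <- fake_fit(array(rnorm(6e5), c(2e5, 3, 1),
                        dimnames = list(NULL, NULL, "z")))
  s <- summary(big)
  expect_equal(s$lower95, -1.96, tolerance = 0.01)
  expect_equal(s$upper95, 1.96, tolerance = 0.01)
  expect_equal(s$mean, 0, tolerance = 0.01)
})

test_that("with no informative data the sampler recovers the priors", {
  fit <- mrr_fit(uninformative_set(), mrr_model("A"),
                 warmup = 2000, iter = 5000, seed = 31)
  m <- gyrsurv:::draw_matrix(fit)
  idx <- round(seq(1, nrow(m), length.out = 3000))
  ks_dist <- function(x, cdf) {
    x <- sort(x)
    n <- length(x)
    max(abs(cdf(x) - seq_len(n) / n), abs(cdf(x) - (seq_len(n) - 1) / n))
  }
  expect_lt(ks_dist(m[idx, "s1"], function(q) punif(q)), 0.05)
  expect_lt(ks_dist(m[idx, "s2"], function(q) punif(q)), 0.05)
  expect_lt(ks_dist(m[idx, "p"], function(q) punif(q, 0, 0.5)), 0.05)
  expect_lt(ks_dist(m[idx, "r"], function(q) punif(q, 0, 0.5)), 0.05)
  expect_lt(ks_dist(m[idx, "eta"], function(q) punif(q, 0, 0.5)), 0.05)
})

test_that("credible intervals shrink as data accumulate", {
  pars <- c(s1 = 0.4, s2 = 0.83, p = 0.1, r = 0.2, eta = 0.05)
  widths <- sapply(c(10, 100), function(cohort) {
    sim <- simulate_histories(simulation_config(
      c(2000, 2015), nestlings_per_year = cohort, params = pars,
      seed = 77))
    s <- summary(mrr_fit(sim$set, warmup = 1500, iter = 2500, seed = 78))
    s$upper95 - s$lower95
  })
  expect_true(all(widths[, 2] < widths[, 1]))
})

test_that("fit objects expose coef, logLik, predict and draw export", {
  sim <- simulate_histories(simulation_config(
    c(2000, 2012), nestlings_per_year = 25,
    params = c(s1 = 0.4, s2 = 0.8, p = 0.1, r = 0.2, eta = 0.05),
    seed = 3))
  fit <- mrr_fit(sim$set, warmup = 300, iter = 300, seed = 4)
  expect_named(coef(fit), c("s1", "s2", "p", "r", "eta"))
  expect_s3_class(summary(fit), "summary.mrr_fit")
  expect_lt(as.numeric(logLik(fit)), 0)
  pr <- predict(fit)
  expect_equal(nrow(pr), 101L)
  expect_true(all(pr$lower95 <= pr$mean & pr$mean <= pr$upper95))
  path <- tempfile(fileext = ".csv")
  export_draws(fit, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 900L)
  expect_equal(back$s1[1], unname(fit$draws[1, 1, "s1"]),
               tolerance = 1e-10)
  ll <- loglik_matrix(fit, thin = 10)
  expect_equal(dim(ll), c(90L, length(sim$set)))
  expect_equal(sum(ll[1, ]),
               dataset_loglik(sim$set, gyrsurv:::draw_matrix(fit)[1, ])$total,
               tolerance = 1e-8)
})

test_that("posterior-predictive replication preserves the study design", {
  sim <- simulate_histories(simulation_config(
    c(2000, 2010), nestlings_per_year = 12,
    adult_trappings = c("2005" = 3L),
    params = c(s1 = 0.4, s2 = 0.8, p = 0.1, r = 0.2, eta = 0.05),
    seed = 41))
  fit <- mrr_fit(sim$set, warmup = 200, iter = 200, seed = 42)
  reps <- simulate(fit, nsim = 2, seed = 43)
  expect_length(reps, 2L)
  for (rp in reps) {
    expect_identical(length(rp$set), length(sim$set))
    expect_identical(sort(rp$set$year_ringed), sort(sim$set$year_ringed))
    expect_identical(sum(rp$set$stage_at_ringing == "adult"), 3L)
  }
  # same seed reproduces the replicates
  expect_identical(simulate(fit, nsim = 2, seed = 43)[[1]]$set$codes,
                   reps[[1]]$set$codes)
})
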