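test_that("emission and transition matrices have the MRR structure", {
  O <- emission_matrix(0.020, 0.139)
  expect_equal(unname(O[1, ]), c(0.020, 0, 0.980))
  expect_equal(unname(O[2, ]), c(0, 0.139, 0.861))
  expect_equal(unname(O[3, ]), c(0, 0, 1))
  G <- transition_matrix(0.830, 0.008)
  expect_equal(unname(G[1, ]), c(0.830, 0.170, 0))
  expect_equal(unname(G[2, ]), c(0, 0.008, 0.992))
  expect_equal(unname(G[3, ]), c(0, 0, 1))
  # no-detection limit: all mass on U
  expect_equal(unname(emission_matrix(0, 0)[, "U"]), c(1, 1, 1))
  # boundary: certain survival, no carcass persistence
  G0 <- transition_matrix(1, 0)
  expect_equal(unname(G0[1, ]), c(1, 0, 0))
  expect_equal(unname(G0[2, ]), c(0, 0, 1))
  expect_error(emission_matrix(1.2, 0))
  expect_error(transition_matrix(0.5, -0.1))
})

test_that("rows are stochastic and long-dead absorbs all mass", {
  set.seed(1)
  for (k in 1:1000) {
    p <- runif(1); r <- runif(1)
    expect_equal(rowSums(emission_matrix(p, r)), c(alive = 1,
                 recently_dead = 1, long_dead = 1), tolerance = 1e-12)
  }
  # power iteration: Gamma^n sends all mass to state 3 when s < 1
  G <- transition_matrix(0.97, 0.4)
  v <- c(1, 0, 0)
  for (i in 1:1e4) v <- v %*% G
  expect_equal(as.vector(v), c(0, 0, 1), tolerance = 1e-10)
})

test_that("survival dispatches between stages and covariate links", {
  covs <- covariate_table(2000:2010, x1 = seq(-2, 2, length.out = 11))
  pa <- c(s1 = 0.4, s2 = 0.83, p = 0.02, r = 0.14, eta = 0.008)
  A <- mrr_model("A")
  expect_identical(survival_probability(pa, A, 5, 2003), 0.83)
  expect_identical(survival_probability(pa, A, 1, 2003), 0.4)
  expect_identical(survival_probability(pa, A, 3, 2003), 0.83)
  expect_error(survival_probability(pa, A, -1, 2003))
  B <- mrr_model("B")
  pb <- c(mu_s1 = 0, beta = 0, s2 = 0.83, p = 0.02, r = 0.14, eta = 0.008)
  expect_equal(survival_probability(pb, B, 0, 2005, covs), 0.5)
  # B with beta = 0 reduces to A with s1 = logistic(mu_s1), every year
  pb["mu_s1"] <- 0.7
  pa2 <- pa; pa2["s1"] <- plogis(0.7)
  for (t in 2000:2009)
    expect_equal(survival_probability(pb, B, 1, t, covs),
                 survival_probability(pa2, A, 1, t), tolerance = 1e-12)
  # threshold parameterization
  Bt <- mrr_model("B", parameterization = "threshold")
  pt <- c(gamma = 1.5, mu_x = 0.5, s2 = 0.8, p = 0.1, r = 0.1, eta = 0.01)
  expect_equal(survival_probability(pt, Bt, 0, 2005, covs),
               plogis(-1.5 * (covs$x1[6] - 0.5)), tolerance = 1e-12)
  # two-transition juvenile option
  A2 <- mrr_model("A", juvenile_transitions = 2)
  expect_identical(survival_probability(pa, A2, 2, 2003), 0.83)
  expect_identical(survival_probability(pa, A2, 1, 2003), 0.4)
})

test_that("forward log-likelihood matches hand enumeration on the L,U,D case", {
  # one stage, all rates 1/2: P = r(1-s)[s(1-p) + (1-r)eta] = 0.125
  h <- one_bird(c("2002" = "D"), y_end = 2002)
  pars <- c(s1 = 0.5, s2 = 0.5, p = 0.5, r = 0.5, eta = 0.5)
  expect_equal(forward_loglik(h, pars), log(0.125), tolerance = 1e-12)
  # a history with no post-marking years conditions away entirely
  expect_identical(forward_loglik(uninformative_set(), pars), 0)
})

test_that("forward recursion equals the exhaustive-path oracle", {
  set.seed(33)
  pars <- c(s1 = 0.35, s2 = 0.82, p = 0.15, r = 0.25, eta = 0.12)
  for (k in 1:40) {
    ev <- random_events(sample(1:5, 1))
    stage <- sample(c("nestling", "adult"), 1)
    h <- one_bird(ev, y_end = 2000 + length(ev), stage = stage)
    expect_equal(forward_loglik(h, pars), brute_forward(h, pars),
                 tolerance = 1e-10)
    expect_equal(dataset_loglik(h, pars)$total, brute_forward(h, pars),
                 tolerance = 1e-10)
  }
  # and with a covariate model
  covs <- covariate_table(1999:2007, x1 = seq(-1.5, 2.5, length.out = 9))
  B <- mrr_model("B")
  pb <- c(mu_s1 = -0.4, beta = 0.5, s2 = 0.82, p = 0.15, r = 0.25,
          eta = 0.12)
  for (k in 1:10) {
    ev <- random_events(sample(1:5, 1))
    h <- one_bird(ev, y_end = 2000 + length(ev))
    expect_equal(forward_loglik(h, pb, B, covs),
                 brute_forward(h, pb, B, covs), tolerance = 1e-10)
  }
})

test_that("forward likelihood is a probability distribution over event sequences", {
  pars <- c(s1 = 0.4, s2 = 0.8, p = 0.1, r = 0.3, eta = 0.05)
  for (Tn in 2:4) {
    seqs <- expand.grid(rep(list(c("L", "D", "U")), Tn),
                        stringsAsFactors = FALSE)
    total <- 0
    for (k in seq_len(nrow(seqs))) {
      cod <- unlist(seqs[k, ])
      dpos <- which(cod == "D")
      if (length(dpos) > 1) next          # impossible under truncation
      if (length(dpos) == 1 && dpos[1] < Tn) {
        # observable outcome is the D-terminated history; count it once,
        # against the all-U continuation pattern
        if (!all(cod[(dpos[1] + 1):Tn] == "U")) next
      }
      ev <- stats::setNames(cod, 2000 + seq_len(Tn))
      if (length(dpos) == 1) ev <- ev[seq_len(dpos[1])]
      h <- one_bird(ev, y_end = 2000 + Tn)
      total <- total + exp(forward_loglik(h, pars))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("all-U likelihood is non-increasing in detection and recovery", {
  h <- one_bird(stats::setNames(rep("U", 6), 2001:2006), y_end = 2006)
  base <- c(s1 = 0.4, s2 = 0.8, p = 0.1, r = 0.2, eta = 0.05)
  for (par in c("p", "r")) {
    lls <- sapply(seq(0.01, 0.49, by = 0.04), function(v) {
      pp <- base; pp[par] <- v
      forward_loglik(h, pp)
    })
    expect_true(all(diff(lls) <= 1e-12))
  }
})

test_that("adult survival does not touch birds dead before age 3", {
  h <- one_bird(c("2001" = "U", "2002" = "D"), y_end = 2002)
  p1 <- c(s1 = 0.4, s2 = 0.83, p = 0.02, r = 0.14, eta = 0.01)
  p2 <- p1; p2["s2"] <- 0.5
  expect_identical(forward_loglik(h, p1), forward_loglik(h, p2))
  # but it does matter for an adult-trapped bird
  ha <- one_bird(c("2001" = "U", "2002" = "D"), y_end = 2002,
                 stage = "adult")
  expect_false(forward_loglik(ha, p1) == forward_loglik(ha, p2))
})

test_that("Model S equals Model A with equal stage survivals", {
  set.seed(9)
  ps <- c(s = 0.6, p = 0.1, r = 0.2, eta = 0.05)
  pa <- c(s1 = 0.6, s2 = 0.6, p = 0.1, r = 0.2, eta = 0.05)
  for (k in 1:15) {
    ev <- random_events(sample(1:6, 1))
    h <- one_bird(ev, y_end = 2000 + length(ev))
    expect_equal(forward_loglik(h, ps, mrr_model("S")),
                 forward_loglik(h, pa, mrr_model("A")), tolerance = 1e-12)
  }
})

test_that("dataset likelihood is additive and pooling is exact", {
  pars <- c(s1 = 0.4, s2 = 0.8, p = 0.1, r = 0.3, eta = 0.05)
  ev <- c("2001" = "L", "2003" = "D")
  two <- capture_history_set(c("A", "B"), c(2000, 2000),
                             rep("nestling", 2), list(ev, ev),
                             c(2000, 2003))
  single <- one_bird(ev, y_end = 2003)
  dl <- dataset_loglik(two, pars)
  expect_equal(dl$total, 2 * forward_loglik(single, pars),
               tolerance = 1e-12)
  expect_equal(dl$per_individual, rep(forward_loglik(single, pars), 2),
               tolerance = 1e-12)
  # empty set
  empty <- capture_history_set(character(), integer(), character(),
                               list(), c(2000, 2003))
  expect_identical(dataset_loglik(empty, pars)$total, 0)
  # pooled vs per-bird (unpooled) computation on a simulated set
  sim <- simulate_histories(simulation_config(
    c(2000, 2014), nestlings_per_year = 20,
    params = pars, seed = 5))
  dl <- dataset_loglik(sim$set, pars)
  unpooled <- vapply(seq_along(sim$set), function(i)
    forward_loglik(sim$set[i], pars), numeric(1))
  expect_equal(dl$per_individual, unpooled, tolerance = 1e-10)
  expect_equal(dl$total, sum(unpooled), tolerance = 1e-10)
})
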