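#' Fit a mark-recapture-recovery survival model
#'
#' Samples the posterior of an MRR hidden-Markov survival model by adaptive
#' random-walk Metropolis on the unconstrained scale (logit transforms for
#' interval-supported probabilities, log for the positive threshold slope,
#' identity for coefficients, with the Jacobian correction), targeting the
#' exact posterior `exp(dataset_loglik + log_prior)`. Chains are
#' initialized from independent prior draws; the proposal covariance and a
#' global scale are tuned during warmup and frozen afterwards.
#'
#' @param set a [capture_history_set()].
#' @param spec an [mrr_model()] spec.
#' @param priors an [mrr_priors()] set.
#' @param covariates a [covariate_table()] (required for Models B, C).
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup adaptation iterations discarded per chain.
#' @param iter retained iterations per chain.
#' @param seed RNG seed; the full run is reproducible given the seed.
#' @param init optional named list/vector of starting values (constrained
#'   scale), recycled across chains; default: prior draws.
#' @return an object of class `mrr_fit` with posterior draws
#'   (`iter x chains x parameters`, constrained scale), unconstrained
#'   draws, per-draw log-posterior, acceptance rates and run metadata.
#' @seealso [summary.mrr_fit()], [rhat()], [loglik_matrix()],
#'   [log_marginal_likelihood()]
#' @export
mrr_fit <- function(set, spec = mrr_model("A"), priors = mrr_priors(),
                    covariates = NULL, chains = 3, warmup = 1000,
                    iter = 1000, seed = 1, init = NULL) {
  stopifnot(inherits(set, "capture_history_set"), chains >= 1,
            warmup >= 10, iter >= 10)
  if (length(spec$covariate_ids) > 0) {
    if (is.null(covariates))
      stop("Model ", spec$model_id, " requires a covariate table")
    need <- set$study_years[-length(set$study_years)]
    if (!all(need %in% covariates$year))
      stop("covariate table must cover years ",
           need[1], "-", need[length(need)])
  }
  man <- parameter_manifest(spec)
  d <- nrow(man)
  pooled <- pool_histories(set)
  log_post_unc <- make_log_post_unc(spec, priors, man, pooled, covariates,
                                    set$study_years)
  trans <- make_transforms(man, priors)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  total <- warmup + iter
  draws <- array(NA_real_, c(iter, chains, d),
                 dimnames = list(NULL, NULL, man$name))
  draws_unc <- draws
  lp_mat <- matrix(NA_real_, iter, chains)
  accept <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    # initialize at a point with finite log-posterior
    z <- NULL
    for (a in seq_len(100)) {
      x0 <- if (is.null(init)) draw_prior(spec, priors) else unlist(init)
      z0 <- trans$to(x0)
      if (is.finite(log_post_unc(z0))) { z <- z0; break }
      if (!is.null(init)) stop("supplied init has non-finite log-posterior")
    }
    if (is.null(z)) stop("failed to find a finite starting point ",
                         "in 100 prior draws")
    lp <- log_post_unc(z)

    # adaptation state; initial proposal scaled to each parameter's prior
    # scale on the unconstrained axis (logit/log scales are order 1)
    prior_scale <- ifelse(man$kind == "coef", priors$coef_sd, 1)
    log_scale <- 0
    mu_run <- z
    cov_run <- diag((0.15 * prior_scale)^2, d)
    chol_prop <- chol(cov_run)
    n_acc <- 0
    target <- 0.234

    for (t in seq_len(total)) {
      step <- exp(log_scale) * drop(stats::rnorm(d) %*% chol_prop)
      z_new <- z + step
      lp_new <- log_post_unc(z_new)
      alpha <- if (is.finite(lp_new)) min(1, exp(lp_new - lp)) else 0
      if (stats::runif(1) < alpha) {
        z <- z_new; lp <- lp_new
        if (t > warmup) n_acc <- n_acc + 1
      }
      if (t <= warmup) {
        g <- 1 / max(t, 10)^0.6
        log_scale <- log_scale + g * (alpha - target)
        dz <- z - mu_run
        mu_run <- mu_run + g * dz
        cov_run <- cov_run + g * (tcrossprod(dz) - cov_run)
        if (t %% 25 == 0 && t >= 100)
          chol_prop <- chol(2.38^2 / d * cov_run + diag(1e-8, d))
      } else {
        k <- t - warmup
        draws_unc[k, ch, ] <- z
        draws[k, ch, ] <- trans$from(z)
        lp_mat[k, ch] <- lp
      }
    }
    accept[ch] <- n_acc / iter
  }

  structure(list(draws = draws, unconstrained = draws_unc, lp = lp_mat,
                 spec = spec, priors = priors, manifest = man,
                 set = set, covariates = covariates, pooled = pooled,
                 run = list(chains = chains, warmup = warmup, iter = iter,
                            seed = seed, chain_seeds = chain_seeds),
                 accept_rate = accept),
            class = "mrr_fit")
}

# fast evaluator of the juvenile-survival series over the study intervals,
# with the covariate matrix aligned once
make_s1_fun <- function(spec, covariates, interval_years) {
  nT <- length(interval_years)
  if (length(spec$covariate_ids) == 0) {
    nm <- if (spec$model_id == "S") "s" else "s1"
    return(function(x) rep.int(unname(x[nm]), nT))
  }
  X <- vapply(spec$covariate_ids, function(nm)
    covariates[[nm]][match(interval_years, covariates$year)],
    numeric(nT))
  X <- matrix(X, nrow = nT)
  if (anyNA(X)) stop("covariate table does not cover all study intervals")
  if (spec$parameterization == "threshold")
    function(x) stats::plogis(-unname(x["gamma"]) *
                              (X[, 1] - unname(x["mu_x"])))
  else {
    bn <- if (spec$model_id == "B") "beta" else c("beta1", "beta2", "beta3")
    function(x) stats::plogis(unname(x["mu_s1"]) +
                              drop(X %*% unname(x[bn])))
  }
}

# unnormalized log-posterior on the unconstrained scale (with Jacobian),
# shared by the sampler and the bridge-sampling evidence estimator
make_log_post_unc <- function(spec, priors, man, pooled, covariates,
                              study_years) {
  trans <- make_transforms(man, priors)
  s1_fun <- make_s1_fun(spec, covariates, study_years[-length(study_years)])
  s2_name <- if (spec$model_id == "S") "s" else "s2"
  jt <- if (spec$model_id == "S") 0L else spec$juvenile_transitions
  function(z) {
    x <- trans$from(z)
    lp <- trans$lprior(x)
    if (!is.finite(lp)) return(-Inf)
    lls <- forward_loglik_patterns(pooled$t0, pooled$age0, pooled$obs,
                                   s1_fun(x), unname(x[s2_name]),
                                   unname(x["p"]), unname(x["r"]),
                                   unname(x["eta"]), jt)
    ll <- sum(lls * pooled$mult)
    if (!is.finite(ll)) return(-Inf)
    lp + ll + trans$ljac(z)
  }
}

# pooled draw matrix (N x d, constrained scale)
draw_matrix <- function(fit, unconstrained = FALSE) {
  a <- if (unconstrained) fit$unconstrained else fit$draws
  d <- dim(a)[3]
  m <- matrix(aperm(a, c(1, 2, 3)), ncol = d)
  colnames(m) <- dimnames(a)[[3]]
  m
}

#' Split rank-normalized R-hat convergence diagnostic
#'
#' The modern potential-scale-reduction statistic: chains are split in
#' half, draws are rank-normalized, and the classic between/within variance
#' ratio is computed for both the rank-normalized draws (bulk) and the
#' folded version (tail); the larger of the two is returned. Constant
#' chains return 1.
#'
#' @param x an `mrr_fit` object or an iterations-by-chains numeric matrix.
#' @param parameter parameter name (when `x` is a fit).
#' @return R-hat (scalar).
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "mrr_fit")) {
    stopifnot(!is.null(parameter))
    x <- x$draws[, , parameter, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("R-hat needs at least 2 chains")
  if (nrow(x) < 10L) stop("R-hat needs at least 10 iterations")
  if (max(x) - min(x) < .Machine$double.eps * 100) return(1)
  z_bulk <- rank_normalize(x)
  z_tail <- rank_normalize(abs(x - stats::median(x)))
  max(rhat_basic(split_half(z_bulk)), rhat_basic(split_half(z_tail)))
}

split_half <- function(m) {
  n <- floor(nrow(m) / 2)
  cbind(m[seq_len(n), , drop = FALSE],
        m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- stats::qnorm((rank(m) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary of a fitted MRR model
#'
#' Pooled-chain posterior mean, sd, central 95% credible interval
#' (2.5%-97.5% quantiles) and split rank-normalized R-hat per parameter.
#' Summaries of probability parameters are computed on the probability
#' scale (note the mean of logistic-transformed draws is not the logistic
#' of the mean).
#'
#' @param object an `mrr_fit`.
#' @param ... unused.
#' @return a data frame, one row per parameter, of class
#'   `summary.mrr_fit`.
#' @export
summary.mrr_fit <- function(object, ...) {
  m <- draw_matrix(object)
  out <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    lower95 = apply(m, 2, stats::quantile, 0.025),
    upper95 = apply(m, 2, stats::quantile, 0.975),
    rhat = vapply(colnames(m), function(nm) rhat(object, nm), numeric(1)),
    row.names = NULL)
  class(out) <- c("summary.mrr_fit", "data.frame")
  out
}

#' @export
print.summary.mrr_fit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  for (v in c("mean", "sd", "lower95", "upper95")) y[[v]] <- round(y[[v]], digits)
  y$rhat <- round(y$rhat, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.mrr_fit <- function(x, ...) {
  cat("Bayesian MRR survival model ", x$spec$model_id, " (",
      x$run$chains, " chains x ", x$run$iter, " draws after ",
      x$run$warmup, " warmup; acceptance ",
      paste(sprintf("%.2f", x$accept_rate), collapse = "/"), ")\n",
      sep = "")
  print(summary(x))
  bad <- summary(x)
  if (any(bad$rhat > 1.01))
    cat("warning: R-hat > 1.01 for ",
        paste(bad$parameter[bad$rhat > 1.01], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mrr_fit <- function(object, ...) {
  m <- draw_matrix(object)
  stats::setNames(colMeans(m), colnames(m))
}

#' @export
logLik.mrr_fit <- function(object, ...) {
  ll <- dataset_loglik(object$set, coef(object), object$spec,
                       object$covariates, object$pooled)$total
  structure(ll, df = nrow(object$manifest), class = "logLik")
}

#' Posterior juvenile-survival curve over a covariate grid
#'
#' For covariate models, evaluates the posterior distribution of juvenile
#' survival `s1` on a grid of standardized prey-density values and returns
#' the posterior mean with a central 95% band — the standard
#' covariate-effect display. For covariate-free models the constant `s1`
#' posterior is summarized at every grid point.
#'
#' @param object an `mrr_fit`.
#' @param x1 numeric grid of standardized covariate values (default: 101
#'   points over the observed range, or \[-1.43, 2.58\] for covariate-free
#'   fits).
#' @param x2,x3 values at which to hold the weather covariates (Model C).
#' @param ... unused.
#' @return data frame with columns `x1`, `mean`, `lower95`, `upper95`.
#' @export
predict.mrr_fit <- function(object, x1 = NULL, x2 = 0, x3 = 0, ...) {
  spec <- object$spec
  if (is.null(x1)) {
    rng <- if (!is.null(object$covariates) && "x1" %in% names(object$covariates))
      range(object$covariates$x1) else c(-1.43, 2.58)
    x1 <- seq(rng[1], rng[2], length.out = 101)
  }
  m <- draw_matrix(object)
  s1_draws <- switch(spec$model_id,
    A = matrix(m[, "s1"], nrow(m), length(x1)),
    S = matrix(m[, "s"], nrow(m), length(x1)),
    B = if (spec$parameterization == "threshold")
      stats::plogis(-m[, "gamma"] %o% rep(1, length(x1)) *
                    outer(rep(1, nrow(m)), x1) +
                    m[, "gamma"] * m[, "mu_x"])
    else stats::plogis(outer(m[, "mu_s1"], rep(1, length(x1))) +
                       m[, "beta"] %o% x1),
    C = stats::plogis(outer(m[, "mu_s1"] + m[, "beta2"] * x2 +
                            m[, "beta3"] * x3, rep(1, length(x1))) +
                      m[, "beta1"] %o% x1))
  data.frame(x1 = x1,
             mean = colMeans(s1_draws),
             lower95 = apply(s1_draws, 2, stats::quantile, 0.025),
             upper95 = apply(s1_draws, 2, stats::quantile, 0.975))
}

#' Plot a fitted MRR model
#'
#' For covariate models, draws the posterior mean and 95% band of juvenile
#' survival against standardized prey density; for covariate-free models,
#' traceplots of the chains.
#'
#' @param x an `mrr_fit`.
#' @param type `"curve"` or `"trace"`.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.mrr_fit <- function(x, type = if (length(x$spec$covariate_ids))
                                     "curve" else "trace", ...) {
  if (type == "curve") {
    pr <- predict(x)
    plot(pr$x1, pr$mean, type = "n", ylim = range(pr$lower95, pr$upper95),
         xlab = "standardized prey density x1",
         ylab = "juvenile survival s1", ...)
    graphics::polygon(c(pr$x1, rev(pr$x1)), c(pr$lower95, rev(pr$upper95)),
                      col = "grey85", border = NA)
    graphics::lines(pr$x1, pr$mean, lwd = 2)
  } else {
    d <- dim(x$draws)[3]
    old <- graphics::par(mfrow = c(ceiling(d / 2), 2), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(old))
    for (j in seq_len(d)) {
      graphics::matplot(x$draws[, , j], type = "l", lty = 1,
                        ylab = dimnames(x$draws)[[3]][j], xlab = "")
    }
  }
  invisible(x)
}

#' Simulate capture-history datasets from a fitted model
#'
#' Draws parameter vectors from the posterior and generates replicate
#' datasets with the same study years and ringing schedule as the fitted
#' data (posterior predictive replication).
#'
#' @param object an `mrr_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `mrr_simulation` objects.
#' @export
simulate.mrr_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  m <- draw_matrix(object)
  set <- object$set
  years <- set$study_years
  sched <- tabulate(match(set$year_ringed[set$stage_at_ringing == "nestling"],
                          years), length(years))
  ad <- set$year_ringed[set$stage_at_ringing == "adult"]
  adult_trappings <- if (length(ad)) table(ad) else NULL
  if (!is.null(adult_trappings)) {
    adult_trappings <- stats::setNames(as.integer(adult_trappings),
                                       names(adult_trappings))
  }
  idx <- sample.int(nrow(m), nsim, replace = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seq_len(nsim), function(k) {
    simulate_histories(simulation_config(
      years, nestlings_per_year = sched, adult_trappings = adult_trappings,
      params = m[idx[k], ], spec = object$spec,
      covariates = object$covariates, seed = sub_seeds[k]))
  })
}

#' Per-draw per-individual log-likelihood matrix
#'
#' Evaluates the forward log-likelihood of every individual at every
#' (optionally thinned) posterior draw — the input to [psis_loo()].
#'
#' @param fit an `mrr_fit`.
#' @param thin keep every `thin`-th pooled draw.
#' @return numeric matrix, draws x individuals.
#' @export
loglik_matrix <- function(fit, thin = 1L) {
  m <- draw_matrix(fit)
  keep <- seq(1, nrow(m), by = thin)
  spec <- fit$spec
  years <- fit$set$study_years
  s1_fun <- make_s1_fun(spec, fit$covariates, years[-length(years)])
  s2_name <- if (spec$model_id == "S") "s" else "s2"
  jt <- if (spec$model_id == "S") 0L else spec$juvenile_transitions
  pooled <- fit$pooled
  out <- matrix(NA_real_, length(keep), length(fit$set))
  for (s in seq_along(keep)) {
    x <- m[keep[s], ]
    ll <- forward_loglik_patterns(pooled$t0, pooled$age0, pooled$obs,
                                  s1_fun(x), unname(x[s2_name]),
                                  unname(x["p"]), unname(x["r"]),
                                  unname(x["eta"]), jt)
    out[s, ] <- ll[pooled$index_map]
  }
  colnames(out) <- fit$set$ring_id
  out
}

#' Export posterior draws as CSV
#'
#' Long-to-wide layout: columns `chain`, `iteration`, then one column per
#' parameter (constrained scale).
#'
#' @param fit an `mrr_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_draws <- function(fit, path) {
  d <- dim(fit$draws)
  out <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1]),
    iteration = rep(seq_len(d[1]), d[2]))
  for (j in seq_len(d[3]))
    out[[dimnames(fit$draws)[[3]][j]]] <- as.vector(fit$draws[, , j])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
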