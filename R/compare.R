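#' Bridge-sampling estimate of the log marginal likelihood
#'
#' Estimates the model evidence from posterior draws with the optimal
#' (Meng-Wong) bridge function. Half of the pooled draws (the first half of
#' each chain) fit a moment-matched multivariate-normal proposal on the
#' unconstrained scale; the other half enter the bridge iteration together
#' with an equal number of fresh proposal samples. The iteration stops when
#' the relative change falls below `tol` or after `max_iter` steps (flagged
#' as non-converged).
#'
#' When `log_posterior` is supplied (a function of an unconstrained
#' parameter vector returning the unnormalized log posterior) it overrides
#' the one implied by the fit — used by the closed-form toy checks.
#'
#' @param fit an `mrr_fit` (or a list with elements `unconstrained`
#'   (iter x chains x d array) and `manifest` when `log_posterior` is
#'   given).
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the proposal samples.
#' @param log_posterior optional override, see above.
#' @return object of class `mrr_logml`: `logml`, Monte-Carlo `se`,
#'   `iterations`, `converged`.
#' @export
log_marginal_likelihood <- function(fit, tol = 1e-8, max_iter = 1000,
                                    seed = 1, log_posterior = NULL) {
  if (is.null(log_posterior))
    log_posterior <- make_log_post_unc(fit$spec, fit$priors, fit$manifest,
                                       fit$pooled, fit$covariates,
                                       fit$set$study_years)
  a <- fit$unconstrained
  half <- floor(dim(a)[1] / 2)
  Zp <- matrix(a[seq_len(half), , , drop = FALSE], ncol = dim(a)[3])
  Zb <- matrix(a[(half + 1):dim(a)[1], , , drop = FALSE], ncol = dim(a)[3])
  d <- ncol(Zb)
  stopifnot(nrow(Zb) + nrow(Zp) >= 1000)

  mu <- colMeans(Zp)
  S <- stats::cov(Zp) + diag(1e-10, d)
  R <- chol(S)
  N1 <- nrow(Zb)
  N2 <- N1
  set.seed(seed)
  prop <- matrix(stats::rnorm(N2 * d), N2, d) %*% R +
    matrix(mu, N2, d, byrow = TRUE)

  log_g <- function(M) {
    Mc <- sweep(M, 2, mu)
    V <- backsolve(R, t(Mc), transpose = TRUE)
    -d / 2 * log(2 * pi) - sum(log(diag(R))) - colSums(V^2) / 2
  }
  l1 <- apply(Zb, 1, log_posterior) - log_g(Zb)
  l2 <- apply(prop, 1, log_posterior) - log_g(prop)
  lstar <- stats::median(l1[is.finite(l1)])
  s1 <- N1 / (N1 + N2); s2 <- N2 / (N1 + N2)
  e1 <- exp(l1 - lstar); e2 <- exp(l2 - lstar)
  rp <- 1
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    num <- mean(e2 / (s1 * e2 + s2 * rp))
    den <- mean(1 / (s1 * e1 + s2 * rp))
    rp_new <- num / den
    if (is.finite(rp_new) && abs(rp_new - rp) / rp < tol) {
      rp <- rp_new; converged <- TRUE; break
    }
    rp <- rp_new
  }
  f1 <- 1 / (s1 * e1 + s2 * rp)
  f2 <- e2 / (s1 * e2 + s2 * rp)
  re2 <- stats::var(f2) / (N2 * mean(f2)^2) +
         stats::var(f1) / (N1 * mean(f1)^2)
  structure(list(logml = lstar + log(rp), se = sqrt(re2),
                 iterations = it, converged = converged,
                 n_posterior = N1, n_proposal = N2),
            class = "mrr_logml")
}

#' @export
print.mrr_logml <- function(x, ...) {
  cat("log marginal likelihood: ", format(x$logml, digits = 6),
      " (MC-SE ", format(x$se, digits = 3), ", ", x$iterations,
      " bridge iterations",
      if (!x$converged) ", NOT CONVERGED", ")\n", sep = "")
  invisible(x)
}

#' Bayes factor from two marginal-likelihood estimates
#'
#' `BF(1,2) = exp(logml1 - logml2)`, also reported on the log10 scale
#' (the natural scale when evidence is overwhelming and `exp` overflows).
#'
#' @param ml1,ml2 `mrr_logml` objects (numerator, denominator models).
#' @return object of class `mrr_bayes_factor`: `bf` (NA on overflow),
#'   `log_bf`, `log10_bf`, approximate `se_log` (MC-SEs combined in
#'   quadrature).
#' @export
bayes_factor <- function(ml1, ml2) {
  if (!ml1$converged || !ml2$converged)
    warning("Bayes factor from a non-converged bridge estimate")
  d <- ml1$logml - ml2$logml
  bf <- exp(d)
  if (!is.finite(bf)) bf <- NA_real_
  structure(list(bf = bf, log_bf = d, log10_bf = d / log(10),
                 se_log = sqrt(ml1$se^2 + ml2$se^2)),
            class = "mrr_bayes_factor")
}

#' @export
print.mrr_bayes_factor <- function(x, ...) {
  cat("Bayes factor: ",
      if (is.na(x$bf)) paste0("10^", format(x$log10_bf, digits = 4),
                              " (overflow; log scale only)")
      else format(x$bf, digits = 4),
      "  (log10 = ", format(x$log10_bf, digits = 4), ")\n", sep = "")
  invisible(x)
}

# Generalized-Pareto tail fit (profile-likelihood quadrature with a weak
# prior pulling k toward 1/2, the standard estimator for importance-ratio
# tails). x: positive exceedances. Returns shape k (>0 = heavy tail) and
# scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0 || stats::sd(x) == 0)
    return(list(k = 0, sigma = max(mean(x), .Machine$double.eps)))
  m <- 30 + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_th <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_th <- n * (log(-theta / k_th) - k_th - 1)
  ok <- is.finite(l_th)
  w <- exp(l_th[ok] - log_sum_exp(l_th[ok]))
  theta_hat <- sum(theta[ok] * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + 10 * 0.5) / (n + 10)   # weak prior regularization
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log(1 - p)
  else sigma * ((1 - p)^(-k) - 1) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates each individual's leave-one-out predictive density by
#' importance sampling over posterior draws, stabilizing the heavy-tailed
#' raw ratios by fitting a generalized Pareto distribution to the top 20%
#' and replacing them with the fit's expected order statistics (truncated
#' at the raw maximum). The Pareto shape `k` per individual diagnoses
#' reliability; `k > 0.7` triggers a warning.
#'
#' @param loglik draws-by-individuals log-likelihood matrix (see
#'   [loglik_matrix()]), or an `mrr_fit` (matrix computed internally).
#' @param thin thinning passed to [loglik_matrix()] when a fit is given.
#' @return object of class `mrr_loo`: `elpd` (expected log predictive
#'   density), `se`, and `pointwise` data frame (`elpd_i`, `pareto_k`).
#' @export
psis_loo <- function(loglik, thin = 1L) {
  if (inherits(loglik, "mrr_fit")) loglik <- loglik_matrix(loglik, thin)
  stopifnot(is.matrix(loglik))
  S <- nrow(loglik); N <- ncol(loglik)
  finite <- apply(loglik, 2, function(z) all(is.finite(z)))
  if (!all(finite)) {
    id <- if (!is.null(colnames(loglik))) colnames(loglik)[!finite][1]
          else which(!finite)[1]
    stop("non-finite log-likelihood for individual ", id)
  }
  elpd_i <- numeric(N); k_i <- numeric(N)
  M <- ceiling(0.2 * S)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    exc <- exp(lw[tail_ids]) - exp(cutoff)
    if (stats::sd(exc) > 0) {
      g <- gpd_fit(exc)
      k_i[i] <- g$k
      pq <- (seq_len(M) - 0.5) / M
      sm <- log(exp(cutoff) + gpd_quantile(pq, g$k, g$sigma))
      lw[tail_ids[order(lw[tail_ids])]] <- pmin(sm, 0)
    } else k_i[i] <- 0
    lw <- lw - log_sum_exp(lw)
    elpd_i[i] <- log_sum_exp(lw + ll)
  }
  if (any(k_i > 0.7))
    warning(sum(k_i > 0.7), " individuals with Pareto k > 0.7; ",
            "PSIS-LOO estimate may be unreliable")
  structure(list(elpd = sum(elpd_i),
                 se = sqrt(N * stats::var(elpd_i)),
                 pointwise = data.frame(elpd_i = elpd_i, pareto_k = k_i),
                 n_draws = S, n_obs = N),
            class = "mrr_loo")
}

#' @export
print.mrr_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd = ", format(x$elpd, digits = 6), " (SE ",
      format(x$se, digits = 3), "), ", x$n_obs, " individuals, ",
      sum(x$pointwise$pareto_k > 0.7), " with Pareto k > 0.7\n", sep = "")
  invisible(x)
}
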