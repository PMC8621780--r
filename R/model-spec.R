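#' Define a juvenile-survival model
#'
#' Four model structures for stage-specific survival:
#' * `"A"` — constant juvenile survival `s1`, adult survival `s2`.
#' * `"B"` — juvenile survival responds to prey density:
#'   `s1(t) = logistic(mu_s1 + beta * x1[t])`, or in the alternative
#'   `"threshold"` parameterization `s1(t) = logistic(-gamma * (x1[t] - mu_x))`
#'   with `gamma > 0`.
#' * `"C"` — prey plus winter weather:
#'   `s1(t) = logistic(mu_s1 + beta1*x1 + beta2*x2 + beta3*x3)`.
#' * `"S"` — a deliberately wrong control in which juveniles and adults
#'   share one survival rate, used to verify that model selection works.
#'
#' `juvenile_transitions` sets how many annual transitions a nestling-ringed
#' bird spends in the juvenile stage before `s2` applies (default 3: ages
#' 0, 1, 2 use juvenile survival, birds aged 3+ are adults).
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"S"`.
#' @param parameterization `"intercept_slope"` (default) or `"threshold"`
#'   (Model B only).
#' @param juvenile_transitions 2 or 3.
#' @return an object of class `mrr_model_spec`.
#' @export
mrr_model <- function(model_id = c("A", "B", "C", "S"),
                      parameterization = c("intercept_slope", "threshold"),
                      juvenile_transitions = 3) {
  model_id <- match.arg(model_id)
  parameterization <- match.arg(parameterization)
  if (parameterization == "threshold" && model_id != "B")
    stop("the threshold parameterization applies to Model B only")
  stopifnot(juvenile_transitions %in% c(2, 3))
  covariate_ids <- switch(model_id, A = character(), S = character(),
                          B = "x1", C = c("x1", "x2", "x3"))
  structure(list(model_id = model_id, covariate_ids = covariate_ids,
                 parameterization = parameterization,
                 juvenile_transitions = as.integer(juvenile_transitions)),
            class = "mrr_model_spec")
}

#' @export
print.mrr_model_spec <- function(x, ...) {
  cat("MRR model ", x$model_id,
      if (x$model_id == "B") paste0(" (", x$parameterization, ")"),
      ": covariates {", paste(x$covariate_ids, collapse = ", "), "}, ",
      x$juvenile_transitions, " juvenile transitions\n", sep = "")
  invisible(x)
}

#' Prior sets for MRR parameters
#'
#' The default weakly informative set: Uniform(0,1) on survival
#' probabilities, Uniform(0,0.5) on detection `p`, recovery `r` and carcass
#' persistence `eta` (known a priori to be small), standard normal on
#' logit-scale intercepts and regression coefficients, and half-Normal(0,1)
#' on the positive slope `gamma` of the threshold parameterization. The
#' `"beta"` set replaces the uniforms with Beta distributions (default
#' Beta(1,1)) rescaled to each parameter's support.
#'
#' @param set `"uniform"` or `"beta"`.
#' @param beta_shape1,beta_shape2 Beta hyperparameters for the `"beta"` set.
#' @param coef_sd standard deviation of the normal prior on logit-scale
#'   intercepts and regression coefficients (default 1).
#' @return an object of class `mrr_prior_set`.
#' @export
mrr_priors <- function(set = c("uniform", "beta"),
                       beta_shape1 = 1, beta_shape2 = 1, coef_sd = 1) {
  set <- match.arg(set)
  stopifnot(beta_shape1 > 0, beta_shape2 > 0, coef_sd > 0)
  structure(list(set = set, beta_shape1 = beta_shape1,
                 beta_shape2 = beta_shape2, coef_sd = coef_sd),
            class = "mrr_prior_set")
}

#' Ordered parameter names and supports for a model
#'
#' @param spec an [mrr_model()] spec.
#' @return data frame with columns `name`, `lower`, `upper`, `kind`
#'   (`prob` for interval-supported probabilities, `coef` for unbounded
#'   coefficients, `positive` for the threshold slope).
#' @export
parameter_manifest <- function(spec) {
  prob <- function(nm, up) data.frame(name = nm, lower = 0, upper = up,
                                      kind = "prob")
  coef <- function(nm) data.frame(name = nm, lower = -Inf, upper = Inf,
                                  kind = "coef")
  juv <- switch(spec$model_id,
    A = prob("s1", 1),
    S = NULL,
    B = if (spec$parameterization == "threshold")
          rbind(data.frame(name = "gamma", lower = 0, upper = Inf,
                           kind = "positive"),
                coef("mu_x"))
        else rbind(coef("mu_s1"), coef("beta")),
    C = rbind(coef("mu_s1"), coef("beta1"), coef("beta2"), coef("beta3")))
  s2_name <- if (spec$model_id == "S") "s" else "s2"
  out <- rbind(juv, prob(s2_name, 1), prob("p", 0.5), prob("r", 0.5),
               prob("eta", 0.5))
  rownames(out) <- NULL
  out
}

#' Log prior density of a parameter vector
#'
#' Sum of the component log densities under the chosen prior set; returns
#' `-Inf` outside the support.
#'
#' @param params named numeric vector (names per [parameter_manifest()]).
#' @param spec an [mrr_model()] spec.
#' @param priors an [mrr_priors()] set.
#' @return log density (scalar; `-Inf` allowed).
#' @export
log_prior <- function(params, spec, priors = mrr_priors()) {
  man <- parameter_manifest(spec)
  stopifnot(all(man$name %in% names(params)))
  lp <- 0
  for (i in seq_len(nrow(man))) {
    x <- unname(params[man$name[i]])
    if (x < man$lower[i] || x > man$upper[i]) return(-Inf)
    lp <- lp + switch(man$kind[i],
      prob = if (priors$set == "uniform") -log(man$upper[i])
             else stats::dbeta(x / man$upper[i], priors$beta_shape1,
                               priors$beta_shape2, log = TRUE) -
                  log(man$upper[i]),
      coef = stats::dnorm(x, 0, priors$coef_sd, log = TRUE),
      positive = stats::dnorm(x, 0, 1, log = TRUE) + log(2))
  }
  lp
}

#' Draw one parameter vector from the prior
#' @param spec an [mrr_model()] spec.
#' @param priors an [mrr_priors()] set.
#' @return named numeric vector.
#' @export
draw_prior <- function(spec, priors = mrr_priors()) {
  man <- parameter_manifest(spec)
  vals <- vapply(seq_len(nrow(man)), function(i) {
    switch(man$kind[i],
      prob = if (priors$set == "uniform")
               stats::runif(1, 0, man$upper[i])
             else man$upper[i] * stats::rbeta(1, priors$beta_shape1,
                                              priors$beta_shape2),
      coef = stats::rnorm(1, 0, priors$coef_sd),
      positive = abs(stats::rnorm(1)))
  }, numeric(1))
  stats::setNames(vals, man$name)
}

# ---- unconstrained-scale transforms (sampler internals) ----------------

# constrained -> unconstrained
to_unconstrained <- function(params, man) {
  z <- numeric(nrow(man))
  for (i in seq_len(nrow(man))) {
    x <- params[man$name[i]]
    z[i] <- switch(man$kind[i],
                   prob = interval_logit(x, man$lower[i], man$upper[i]),
                   coef = x,
                   positive = log(x))
  }
  stats::setNames(z, man$name)
}

# unconstrained -> constrained
from_unconstrained <- function(z, man) {
  x <- numeric(nrow(man))
  for (i in seq_len(nrow(man))) {
    x[i] <- switch(man$kind[i],
                   prob = interval_invlogit(z[i], man$lower[i],
                                            man$upper[i]),
                   coef = z[i],
                   positive = exp(z[i]))
  }
  stats::setNames(x, man$name)
}

# log |d constrained / d unconstrained| at z
log_jacobian <- function(z, man) {
  lj <- 0
  for (i in seq_len(nrow(man))) {
    lj <- lj + switch(man$kind[i],
      prob = log(man$upper[i] - man$lower[i]) +
             stats::plogis(z[i], log.p = TRUE) +
             stats::plogis(-z[i], log.p = TRUE),
      coef = 0,
      positive = unname(z[i]))
  }
  unname(lj)
}

# Vectorized transform/prior bundle for the sampler hot path; semantics
# identical to to_unconstrained/from_unconstrained/log_jacobian/log_prior.
make_transforms <- function(man, priors) {
  kind <- man$kind; lo <- man$lower; up <- man$upper; nms <- man$name
  isp <- kind == "prob"; isc <- kind == "coef"; ispos <- kind == "positive"
  width <- up[isp] - lo[isp]
  unif_lp <- -sum(log(width))
  a <- priors$beta_shape1; b <- priors$beta_shape2
  list(
    from = function(z) {
      x <- z
      x[isp] <- lo[isp] + width * stats::plogis(z[isp])
      x[ispos] <- exp(z[ispos])
      names(x) <- nms
      x
    },
    to = function(x) {
      z <- unname(x[nms])
      z[isp] <- stats::qlogis((z[isp] - lo[isp]) / width)
      z[ispos] <- log(z[ispos])
      stats::setNames(z, nms)
    },
    ljac = function(z) {
      sum(log(width) + stats::plogis(z[isp], log.p = TRUE) +
            stats::plogis(-z[isp], log.p = TRUE)) + sum(z[ispos])
    },
    lprior = function(x) {
      if (any(x[isp] <= lo[isp]) || any(x[isp] >= up[isp]) ||
          any(x[ispos] < 0)) return(-Inf)
      lp <- if (priors$set == "uniform") unif_lp
            else sum(stats::dbeta((x[isp] - lo[isp]) / width, a, b,
                                  log = TRUE) - log(width))
      lp + sum(stats::dnorm(x[isc], 0, priors$coef_sd, log = TRUE)) +
        sum(stats::dnorm(x[ispos], 0, 1, log = TRUE) + log(2))
    })
}

# yearly juvenile-survival series implied by (params, spec) over interval
# years `years`; returns s2-valued vector for Model S (single rate).
juvenile_survival_series <- function(params, spec, covariates, years) {
  g <- function(nm) unname(params[nm])
  switch(spec$model_id,
    A = rep(g("s1"), length(years)),
    S = rep(g("s"), length(years)),
    B = {
      x1 <- vapply(years, covariate_for_interval, numeric(1),
                   table = covariates, name = "x1")
      if (spec$parameterization == "threshold")
        stats::plogis(-g("gamma") * (x1 - g("mu_x")))
      else stats::plogis(g("mu_s1") + g("beta") * x1)
    },
    C = {
      xs <- sapply(c("x1", "x2", "x3"), function(nm)
        vapply(years, covariate_for_interval, numeric(1),
               table = covariates, name = nm))
      xs <- matrix(xs, ncol = 3)
      stats::plogis(g("mu_s1") + xs %*% c(g("beta1"), g("beta2"),
                                          g("beta3")))[, 1]
    })
}
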