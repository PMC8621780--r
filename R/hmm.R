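#' Observation (emission) matrix of the MRR hidden Markov model
#'
#' Rows are hidden states (alive, recently dead, long dead), columns the
#' observed codes (`L`, `D`, `U`). Live birds are seen with probability `p`;
#' carcasses are recovered with probability `r`; long-dead birds are never
#' encountered.
#'
#' @param p live detection (resighting/recapture) probability.
#' @param r dead-recovery probability.
#' @return a 3x3 row-stochastic matrix.
#' @export
#' @examples
#' emission_matrix(0.020, 0.139)
emission_matrix <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  matrix(c(p, 0, 1 - p,
           0, r, 1 - r,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("alive", "recently_dead", "long_dead"),
                         c("L", "D", "U")))
}

#' Transition matrix of the hidden state process
#'
#' Live birds survive one year with probability `s`; those that die become
#' recoverable carcasses, which persist another year with probability `eta`
#' (typically very small in the field) before becoming long dead, an
#' absorbing state.
#'
#' @param s annual survival probability (stage/year specific).
#' @param eta annual carcass persistence probability.
#' @return a 3x3 row-stochastic matrix.
#' @export
#' @examples
#' transition_matrix(0.830, 0.008)
transition_matrix <- function(s, eta) {
  stopifnot(s >= 0, s <= 1, eta >= 0, eta <= 1)
  st <- c("alive", "recently_dead", "long_dead")
  matrix(c(s, 1 - s, 0,
           0, eta, 1 - eta,
           0, 0, 1),
         nrow = 3, byrow = TRUE, dimnames = list(st, st))
}

#' Stage- and year-specific survival probability
#'
#' Dispatches between juvenile and adult survival: a bird of age `age` at
#' the start of the interval `(t, t+1)` survives with the adult rate when
#' `age >= juvenile_transitions` (default: age 3 and above) and otherwise
#' with the juvenile rate implied by the model (constant, or a logistic
#' function of the year's covariates).
#'
#' @param params named parameter vector (see [parameter_manifest()]).
#' @param spec an [mrr_model()] spec.
#' @param age age in years at the start of the interval.
#' @param t calendar year at the start of the interval.
#' @param covariates a [covariate_table()] (required for Models B, C).
#' @return survival probability (scalar).
#' @export
survival_probability <- function(params, spec, age, t, covariates = NULL) {
  stopifnot(age >= 0)
  s2 <- unname(params[if (spec$model_id == "S") "s" else "s2"])
  if (age >= spec$juvenile_transitions) return(s2)
  unname(juvenile_survival_series(params, spec, covariates, t))
}

# Pool identical capture histories into patterns for the likelihood.
# A pattern is (ringing-year index, age at ringing, post-marking code
# sequence truncated at D); returns 0-based t0 for the C++ core and the
# per-individual pattern index so pooled results can be expanded.
pool_histories <- function(set) {
  n <- length(set)
  K <- length(set$study_years)
  y1 <- set$study_years[1]
  t0 <- set$year_ringed - y1                   # 0-based
  age0 <- ifelse(set$stage_at_ringing == "adult", 3L, 0L)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    codes <- set$codes[i, ]
    codes <- codes[!is.na(codes)]
    post <- codes[-1L]                         # drop marking event
    obs[[i]] <- match(unname(post), c("L", "D", "U"))
  }
  key <- paste(t0, age0, vapply(obs, paste, "", collapse = ""))
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(t0 = as.integer(t0[u]), age0 = as.integer(age0[u]),
       obs = obs[u], mult = tabulate(idx, nbins = sum(u)),
       index_map = idx, n_years = K)
}

# log-likelihood of all pooled patterns at one parameter vector
pattern_logliks <- function(pooled, params, spec, covariates, study_years) {
  interval_years <- study_years[-length(study_years)]
  s1t <- juvenile_survival_series(params, spec, covariates, interval_years)
  s2 <- unname(params[if (spec$model_id == "S") "s" else "s2"])
  jt <- if (spec$model_id == "S") 0L else spec$juvenile_transitions
  forward_loglik_patterns(pooled$t0, pooled$age0, pooled$obs, s1t,
                          s2, unname(params["p"]), unname(params["r"]),
                          unname(params["eta"]), jt)
}

#' Forward-algorithm log-likelihood of one capture history
#'
#' Conditions on the marking event: mass 1 on the alive state in the
#' ringing year, then for each subsequent year propagates through the
#' stage/year-specific [transition_matrix()] and weights by the
#' [emission_matrix()] column of the observed code, with per-step scaling.
#' A history with no post-marking years has log-likelihood 0. A dead
#' recovery ends the informative history (the ring is collected).
#'
#' This is the pure-R reference recursion; [dataset_loglik()] uses the
#' compiled pooled equivalent.
#'
#' @param history a length-1 [capture_history_set()].
#' @param params named parameter vector.
#' @param spec an [mrr_model()] spec.
#' @param covariates a [covariate_table()] (Models B, C).
#' @return log-probability (scalar; `-Inf` possible at boundary parameters).
#' @export
forward_loglik <- function(history, params, spec = mrr_model("A"),
                           covariates = NULL) {
  stopifnot(length(history) == 1L)
  years <- history$study_years
  codes <- history$codes[1, ]
  codes <- codes[!is.na(codes)]
  obs_years <- as.integer(names(codes))
  y0 <- history$year_ringed[1]
  age0 <- if (history$stage_at_ringing[1] == "adult") 3L else 0L
  O <- emission_matrix(unname(params["p"]), unname(params["r"]))
  alpha <- c(1, 0, 0)
  ll <- 0
  for (y in obs_years[-1L]) {
    age <- age0 + (y - 1L - y0)
    s <- unname(survival_probability(params, spec, age, y - 1L, covariates))
    alpha <- as.vector(alpha %*% transition_matrix(s, unname(params["eta"])))
    alpha <- alpha * O[, codes[as.character(y)]]
    tot <- sum(alpha)
    if (!(tot > 0)) return(-Inf)
    ll <- ll + log(tot)
    alpha <- alpha / tot
  }
  ll
}

#' Dataset log-likelihood with per-individual contributions
#'
#' Total forward log-likelihood over all histories. Identical histories are
#' pooled internally (one forward pass per distinct pattern) but the
#' per-individual vector is reported in set order, as required for
#' leave-one-out cross-validation.
#'
#' @param set a [capture_history_set()].
#' @param params named parameter vector.
#' @param spec an [mrr_model()] spec.
#' @param covariates a [covariate_table()] (Models B, C).
#' @param pooled optional precomputed [pool_histories()] result (internal
#'   caching).
#' @return list with `total` (scalar) and `per_individual` (numeric vector,
#'   one entry per history).
#' @export
dataset_loglik <- function(set, params, spec = mrr_model("A"),
                           covariates = NULL, pooled = NULL) {
  if (is.null(pooled)) pooled <- pool_histories(set)
  ll <- pattern_logliks(pooled, params, spec, covariates, set$study_years)
  list(total = sum(ll * pooled$mult), per_individual = ll[pooled$index_map])
}
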