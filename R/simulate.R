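#' Simulate standardized yearly covariates
#'
#' Independent standard-normal draws per covariate per year, re-standardized
#' to exact sample mean 0 and sd 1 — the scale on which the survival models
#' consume covariates.
#'
#' @param years integer vector of consecutive years (or length-2 range).
#' @param seed optional RNG seed.
#' @return a [covariate_table()] with columns `x1`, `x2`, `x3`.
#' @export
simulate_covariates <- function(years, seed = NULL) {
  if (length(years) == 2L && diff(years) > 1L) years <- years[1]:years[2]
  stopifnot(length(years) >= 2)
  if (!is.null(seed)) set.seed(seed)
  std <- function() standardize_series(stats::rnorm(length(years)))$values
  covariate_table(years, x1 = std(), x2 = std(), x3 = std())
}

#' Configure a capture-history simulation
#'
#' @param study_years inclusive year range (length-2 or full vector).
#' @param nestlings_per_year nestlings ringed each year (scalar or one value
#'   per year; final-year cohorts have no post-marking occasions and
#'   contribute nothing to the likelihood).
#' @param adult_trappings named integer vector, year -> number of
#'   territorial adults trapped that year (default none).
#' @param params named true parameter vector (see [parameter_manifest()]).
#' @param spec an [mrr_model()] generating spec.
#' @param covariates a [covariate_table()], or `NULL` to draw one with
#'   [simulate_covariates()].
#' @param seed RNG seed.
#' @return an object of class `mrr_sim_config`.
#' @export
simulation_config <- function(study_years, nestlings_per_year = 35,
                              adult_trappings = NULL,
                              params, spec = mrr_model("A"),
                              covariates = NULL, seed = 1) {
  if (length(study_years) == 2L) study_years <- study_years[1]:study_years[2]
  K <- length(study_years)
  if (length(nestlings_per_year) == 1L)
    nestlings_per_year <- rep(nestlings_per_year, K)
  stopifnot(length(nestlings_per_year) == K, all(nestlings_per_year >= 0))
  if (!is.null(adult_trappings))
    stopifnot(!is.null(names(adult_trappings)),
              all(as.integer(names(adult_trappings)) %in% study_years))
  man <- parameter_manifest(spec)
  stopifnot(all(man$name %in% names(params)))
  structure(list(study_years = as.integer(study_years),
                 nestlings_per_year = as.integer(nestlings_per_year),
                 adult_trappings = adult_trappings,
                 params = params, spec = spec, covariates = covariates,
                 seed = as.integer(seed)),
            class = "mrr_sim_config")
}

#' Paper-scale simulation scenario
#'
#' A 47-year study with 35 nestlings ringed per year plus 24 adults trapped
#' mid-study, generated under Model A at survival, detection, recovery and
#' carcass-persistence values matching published estimates for Icelandic
#' gyrfalcons: s1 = 0.40, s2 = 0.83, p = 0.02, r = 0.14, eta = 0.008.
#'
#' @param seed RNG seed.
#' @return an `mrr_sim_config`.
#' @export
scenario_paperlike <- function(seed = 1) {
  simulation_config(
    study_years = c(1973, 2019),
    nestlings_per_year = 35,
    adult_trappings = c("1995" = 24L),
    params = c(s1 = 0.40, s2 = 0.83, p = 0.02, r = 0.14, eta = 0.008),
    spec = mrr_model("A"),
    seed = seed)
}

#' Simulate capture histories from the generative MRR process
#'
#' Each bird's hidden chain (alive, recently dead, long dead) is simulated
#' from the transition model with age/covariate-specific survival from its
#' ringing year to the study end; yearly observations are then drawn from
#' the emission model. Histories are truncated after a dead recovery (the
#' ring is collected). The hidden truth is retained for oracle tests and is
#' never visible to inference.
#'
#' @param config an [simulation_config()].
#' @return an object of class `mrr_simulation`: list with `set` (a
#'   [capture_history_set()]), `covariates`, `truth` (hidden-state matrix,
#'   rows birds, columns study years), and `tally` (simulator event log:
#'   post-marking L and D observation counts).
#' @export
simulate_histories <- function(config) {
  set.seed(config$seed)
  years <- config$study_years
  K <- length(years)
  spec <- config$spec
  params <- config$params
  covariates <- config$covariates
  if (is.null(covariates) && length(spec$covariate_ids) > 0)
    covariates <- simulate_covariates(years)
  s1t <- juvenile_survival_series(params, spec, covariates, years[-K])
  s2 <- unname(params[if (spec$model_id == "S") "s" else "s2"])
  p <- unname(params["p"]); r <- unname(params["r"])
  eta <- unname(params["eta"])
  jt <- if (spec$model_id == "S") 0L else spec$juvenile_transitions

  # birth table
  ring_year <- rep(years, config$nestlings_per_year)
  stage <- rep("nestling", length(ring_year))
  if (!is.null(config$adult_trappings)) {
    ay <- rep(as.integer(names(config$adult_trappings)),
              config$adult_trappings)
    ring_year <- c(ring_year, ay)
    stage <- c(stage, rep("adult", length(ay)))
  }
  n <- length(ring_year)
  ord <- order(ring_year, stage)
  ring_year <- ring_year[ord]; stage <- stage[ord]
  age0 <- ifelse(stage == "adult", 3L, 0L)

  state <- matrix(NA_integer_, n, K, dimnames = list(NULL, years))
  obs <- matrix(NA_character_, n, K, dimnames = list(NULL, years))
  t0 <- match(ring_year, years)
  for (i in seq_len(n)) state[i, t0[i]] <- 1L
  recovered <- rep(FALSE, n)
  n_L <- 0L; n_D <- 0L

  for (j in seq_len(K - 1L)) {
    active <- which(t0 <= j & !recovered)
    if (!length(active)) next
    st <- state[cbind(active, j)]
    age <- age0[active] + (j - t0[active])
    s <- ifelse(age >= jt, s2, s1t[j])
    u <- stats::runif(length(active))
    new <- integer(length(active))
    new[st == 1L] <- ifelse(u[st == 1L] < s[st == 1L], 1L, 2L)
    new[st == 2L] <- ifelse(u[st == 2L] < eta, 2L, 3L)
    new[st == 3L] <- 3L
    state[cbind(active, j + 1L)] <- new
    # observation at year j+1
    v <- stats::runif(length(active))
    code <- rep("U", length(active))
    code[new == 1L & v < p] <- "L"
    code[new == 2L & v < r] <- "D"
    obs[cbind(active, j + 1L)] <- code
    n_L <- n_L + sum(code == "L")
    n_D <- n_D + sum(code == "D")
    recovered[active[code == "D"]] <- TRUE
  }

  events <- vector("list", n)
  for (i in seq_len(n)) {
    oi <- obs[i, ]
    keep <- !is.na(oi) & oi != "U"
    ev <- stats::setNames(oi[keep], colnames(obs)[keep])
    if (any(ev == "D")) {   # defensive: keep nothing past the recovery
      dpos <- which(names(ev) == names(ev)[ev == "D"])
      ev <- ev[seq_len(dpos)]
    }
    events[[i]] <- ev
  }
  ids <- sprintf("SIM%05d", seq_len(n))
  set <- capture_history_set(ids, ring_year, stage, events, years)
  structure(list(set = set, covariates = covariates,
                 truth = state,
                 tally = list(live_encounters = n_L, dead_recoveries = n_D),
                 config = config),
            class = "mrr_simulation")
}

#' @export
print.mrr_simulation <- function(x, ...) {
  cat("Simulated MRR dataset (model ", x$config$spec$model_id, ", seed ",
      x$config$seed, ")\n", sep = "")
  print(x$set)
  invisible(x)
}
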