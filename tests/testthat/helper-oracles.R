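# Shared fixtures and independent oracles used across test files.

# one-bird capture-history set over years y0..y_end; events is a named
# character vector of post-marking codes
one_bird <- function(events, y0 = 2000, y_end = NULL,
                     stage = "nestling") {
  if (is.null(y_end))
    y_end <- max(y0, as.integer(names(events)))
  capture_history_set("B1", y0, stage, list(events), c(y0, y_end))
}

# exhaustive-path oracle: sum the joint probability over every hidden-state
# sequence, independent of the forward recursion
brute_forward <- function(history, params, spec = mrr_model("A"),
                          covariates = NULL) {
  codes <- history$codes[1, ]
  codes <- codes[!is.na(codes)]
  obs_years <- as.integer(names(codes))
  Tn <- length(codes) - 1L
  if (Tn == 0L) return(0)
  y0 <- history$year_ringed[1]
  age0 <- if (history$stage_at_ringing[1] == "adult") 3L else 0L
  O <- emission_matrix(unname(params["p"]), unname(params["r"]))
  paths <- as.matrix(expand.grid(rep(list(1:3), Tn)))
  total <- 0
  for (k in seq_len(nrow(paths))) {
    path <- c(1L, paths[k, ])
    pr <- 1
    for (j in seq_len(Tn)) {
      age <- age0 + (obs_years[j] - y0)
      s <- survival_probability(params, spec, age, obs_years[j], covariates)
      G <- transition_matrix(s, unname(params["eta"]))
      pr <- pr * G[path[j], path[j + 1]] * O[path[j + 1], codes[j + 1]]
    }
    total <- total + pr
  }
  log(total)
}

# random valid post-marking code sequence of length n (truncated at a D)
random_events <- function(n, y0 = 2000) {
  codes <- sample(c("L", "D", "U"), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.5))
  d <- which(codes == "D")
  if (length(d)) codes <- codes[seq_len(min(d))]
  stats::setNames(codes, y0 + seq_along(codes))
}

# a set whose histories carry no information (marking in the final study
# year): the likelihood is identically zero, so the posterior is the prior
uninformative_set <- function() {
  capture_history_set("P1", 2005, "nestling", list(NULL), c(2000, 2005))
}

# minimal object accepted by summary()/rhat()/draw_matrix for synthetic
# draw arrays (diagnostics tests)
fake_fit <- function(draws_array) {
  structure(list(draws = draws_array, unconstrained = draws_array,
                 lp = matrix(0, dim(draws_array)[1], dim(draws_array)[2]),
                 run = list(chains = dim(draws_array)[2])),
            class = "mrr_fit")
}
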