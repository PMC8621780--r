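#' Yearly covariate tables for juvenile survival
#'
#' The covariate table holds, per study year `t`, the standardized values
#' driving juvenile survival over the interval `(t, t+1)`:
#' `x1` prey (rock ptarmigan) density index, `x2` winter mean temperature,
#' `x3` winter mean log-precipitation. Standardization constants (mean, sd)
#' are stored as attributes so values can be mapped back to natural units.
#'
#' @param year integer vector of consecutive years.
#' @param x1,x2,x3 numeric standardized covariate values (any may be
#'   omitted; missing columns are only an error when a model requests them).
#' @param constants optional named list of `c(mean, sd)` pairs per covariate.
#' @return an object of class `covariate_table` (a data frame).
#' @export
covariate_table <- function(year, x1 = NULL, x2 = NULL, x3 = NULL,
                            constants = list()) {
  year <- as.integer(year)
  stopifnot(all(diff(year) == 1L))
  df <- data.frame(year = year)
  for (nm in c("x1", "x2", "x3")) {
    v <- get(nm)
    if (!is.null(v)) {
      stopifnot(length(v) == length(year), all(is.finite(v)))
      df[[nm]] <- v
    }
  }
  structure(df, constants = constants,
            class = c("covariate_table", "data.frame"))
}

#' Average a monthly series over one October--March winter
#'
#' The winter experienced by the cohort hatched in year `t` spans October of
#' `t` through March of `t+1`; it is indexed as covariate year `t` so that
#' it governs survival over the interval `(t, t+1)`. For precipitation the
#' natural log is applied to monthly values *before* averaging (set
#' `log_transform = TRUE`); zero monthly totals are an error unless a
#' positive `log_offset` is supplied.
#'
#' @param series data frame with columns `year`, `month`, `value` (degrees C
#'   for temperature, mm for precipitation).
#' @param year winter index year `t`.
#' @param log_transform log-transform monthly values before averaging.
#' @param log_offset added inside the log for zero-handling (default 0:
#'   zeros are an error).
#' @return the winter mean (numeric scalar).
#' @export
winter_average <- function(series, year, log_transform = FALSE,
                           log_offset = 0) {
  stopifnot(all(c("year", "month", "value") %in% names(series)),
            all(series$month %in% 1:12),
            !anyDuplicated(series[c("year", "month")]))
  want <- rbind(data.frame(year = year, month = 10:12),
                data.frame(year = year + 1L, month = 1:3))
  vals <- numeric(6)
  for (k in seq_len(6)) {
    hit <- series$year == want$year[k] & series$month == want$month[k]
    if (!any(hit))
      stop("missing month (", want$year[k], ", ", want$month[k], ")")
    vals[k] <- series$value[which(hit)[1]]
  }
  if (log_transform) {
    if (any(vals + log_offset <= 0))
      stop("non-positive monthly value under log transform; ",
           "supply a positive log_offset")
    vals <- log(vals + log_offset)
  }
  mean(vals)
}

#' Standardize a yearly series to mean 0, sd 1
#'
#' Uses the sample standard deviation (n-1 denominator) and returns the
#' constants needed to back-transform.
#'
#' @param x numeric vector (at least two distinct values).
#' @return list with `values` (standardized series) and `constants`
#'   (`c(mean, sd)`).
#' @export
standardize_series <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("zero variance: cannot standardize a constant series")
  list(values = (x - m) / s, constants = c(mean = m, sd = s))
}

#' Build a covariate table from raw yearly series
#'
#' Standardizes each supplied raw series and assembles a
#' [covariate_table()].
#'
#' @param year integer vector of consecutive years.
#' @param ptarmigan,winter_temp,winter_log_precip raw yearly series (already
#'   winter-averaged for the weather variables; see [winter_average()]).
#' @return a [covariate_table()] with stored constants.
#' @export
build_covariate_table <- function(year, ptarmigan = NULL,
                                  winter_temp = NULL,
                                  winter_log_precip = NULL) {
  raw <- list(x1 = ptarmigan, x2 = winter_temp, x3 = winter_log_precip)
  std <- list(); constants <- list()
  for (nm in names(raw)) {
    if (!is.null(raw[[nm]])) {
      z <- standardize_series(raw[[nm]])
      std[[nm]] <- z$values
      constants[[nm]] <- z$constants
    }
  }
  covariate_table(year, x1 = std$x1, x2 = std$x2, x3 = std$x3,
                  constants = constants)
}

#' Look up the covariate governing survival over interval (t, t+1)
#'
#' @param table a [covariate_table()].
#' @param t year at the start of the survival interval.
#' @param name covariate id, one of `"x1"`, `"x2"`, `"x3"`.
#' @return the standardized covariate value (numeric scalar).
#' @export
covariate_for_interval <- function(table, t, name = "x1") {
  if (!name %in% names(table))
    stop("covariate ", name, " not present in table")
  i <- match(t, table$year)
  if (is.na(i)) stop("year ", t, " not in covariate table")
  table[[name]][i]
}

#' Read a covariate CSV (columns year, x1, x2, x3)
#' @param path CSV path.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path)
  stopifnot("year" %in% names(df))
  covariate_table(df$year, x1 = df$x1, x2 = df$x2, x3 = df$x3)
}

#' Write a covariate table to CSV
#' @param table a [covariate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
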