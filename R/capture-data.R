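#' Capture-history sets
#'
#' A capture history records, for one ringed bird, the yearly encounter code
#' from its ringing year to the end of the study (or its dead recovery,
#' whichever comes first): `L` seen or captured alive, `D` recovered dead,
#' `U` neither. The marking event itself is coded `L` for both
#' nestling-ringed and adult-trapped birds; `stage_at_ringing` distinguishes
#' them. A `capture_history_set` stores a collection of such histories over
#' an inclusive range of study years.
#'
#' Internally the set is columnar: an `n x K` character matrix of codes
#' (rows birds, columns study years) with `NA` outside each bird's
#' observable window (before ringing, after a dead recovery).
#'
#' @param ring_id character vector of unique ring identifiers.
#' @param year_ringed integer vector of ringing years.
#' @param stage_at_ringing character vector, `"nestling"` or `"adult"`.
#' @param events list (one element per bird) of named character vectors
#'   mapping year to code in `L`, `D`, `U`. The marking year may be omitted
#'   (it is always `L`); unlisted years are filled with `U`.
#' @param study_years integer vector of consecutive study years (or a
#'   length-2 range).
#' @param rehabilitated,improper_ring logical exclusion flags (recycled).
#' @return an object of class `capture_history_set`.
#' @export
#' @examples
#' chs <- capture_history_set(
#'   ring_id = "F001", year_ringed = 2000, stage_at_ringing = "nestling",
#'   events = list(c("2002" = "D")), study_years = c(2000, 2005))
#' encounter_tally(chs)
capture_history_set <- function(ring_id, year_ringed, stage_at_ringing,
                                events = vector("list", length(ring_id)),
                                study_years,
                                rehabilitated = FALSE,
                                improper_ring = FALSE) {
  if (length(study_years) == 2L) study_years <- study_years[1]:study_years[2]
  study_years <- as.integer(study_years)
  stopifnot(all(diff(study_years) == 1L))
  n <- length(ring_id)
  ring_id <- as.character(ring_id)
  year_ringed <- as.integer(year_ringed)
  stage_at_ringing <- as.character(stage_at_ringing)
  stopifnot(length(year_ringed) == n, length(stage_at_ringing) == n,
            length(events) == n)
  rehabilitated <- rep_len(as.logical(rehabilitated), n)
  improper_ring <- rep_len(as.logical(improper_ring), n)

  if (anyDuplicated(ring_id))
    stop("duplicate ring_id: ", paste(unique(ring_id[duplicated(ring_id)]),
                                      collapse = ", "))
  if (!all(stage_at_ringing %in% c("nestling", "adult")))
    stop("stage_at_ringing must be 'nestling' or 'adult'")
  if (any(year_ringed < study_years[1] | year_ringed > study_years[length(study_years)]))
    stop("year_ringed outside study_years for ring_id ",
         paste(ring_id[year_ringed < study_years[1] |
                       year_ringed > study_years[length(study_years)]],
               collapse = ", "))

  K <- length(study_years)
  mat <- matrix(NA_character_, n, K,
                dimnames = list(ring_id, as.character(study_years)))
  for (i in seq_len(n)) {
    ev <- events[[i]]
    yrs <- as.integer(names(ev))
    codes <- as.character(ev)
    bad <- !codes %in% c("L", "D", "U")
    if (any(bad))
      stop("unknown code '", codes[bad][1], "' for ring_id ", ring_id[i],
           " year ", yrs[bad][1])
    if (any(yrs < year_ringed[i] & codes != "U"))
      stop("encounter before year_ringed for ring_id ", ring_id[i])
    if (anyDuplicated(yrs))
      stop("duplicate year for ring_id ", ring_id[i])
    if (sum(codes == "D") > 1L)
      stop("multiple D events for ring_id ", ring_id[i])
    d_year <- if (any(codes == "D")) yrs[codes == "D"] else NA_integer_
    if (!is.na(d_year) && any(yrs > d_year & codes != "U"))
      stop("event after dead recovery for ring_id ", ring_id[i],
           " year ", min(yrs[yrs > d_year & codes != "U"]))
    last <- if (is.na(d_year)) study_years[K] else d_year
    span <- as.character(year_ringed[i]:last)
    mat[i, span] <- "U"
    mat[i, as.character(year_ringed[i])] <- "L"   # marking event
    keep <- yrs >= year_ringed[i] & yrs <= last
    mat[i, as.character(yrs[keep])] <- codes[keep]
    if (mat[i, as.character(year_ringed[i])] != "L")
      stop("marking year must be coded L for ring_id ", ring_id[i])
  }

  structure(
    list(ring_id = ring_id, year_ringed = year_ringed,
         stage_at_ringing = stage_at_ringing, codes = mat,
         rehabilitated = rehabilitated, improper_ring = improper_ring,
         study_years = study_years),
    class = "capture_history_set")
}

#' @export
length.capture_history_set <- function(x) length(x$ring_id)

#' @export
`[.capture_history_set` <- function(x, i) {
  structure(
    list(ring_id = x$ring_id[i], year_ringed = x$year_ringed[i],
         stage_at_ringing = x$stage_at_ringing[i],
         codes = x$codes[i, , drop = FALSE],
         rehabilitated = x$rehabilitated[i],
         improper_ring = x$improper_ring[i],
         study_years = x$study_years),
    class = "capture_history_set")
}

#' @export
print.capture_history_set <- function(x, ...) {
  tl <- encounter_tally(x)
  cat("Capture-history set: ", length(x), " birds, study years ",
      x$study_years[1], "-", x$study_years[length(x$study_years)], "\n",
      "  nestling-ringed: ", sum(x$stage_at_ringing == "nestling"),
      ", adult-trapped: ", sum(x$stage_at_ringing == "adult"), "\n",
      "  post-marking live encounters: ", tl$live_encounters,
      ", dead recoveries: ", tl$dead_recoveries,
      ", birds ever re-encountered: ", tl$birds_reencountered, "\n",
      sep = "")
  invisible(x)
}

#' Read capture histories from a long-format CSV
#'
#' One row per bird-year event with columns `ring_id`, `year_ringed`,
#' `stage_at_ringing`, `year`, `code` (optional logical columns
#' `rehabilitated`, `improper_ring`). `U` rows may be omitted; missing years
#' are filled with `U`. Invalid rows (codes outside L/D/U, encounters before
#' ringing, a second `D`, events after a `D`) are rejected with an
#' identifying message.
#'
#' @param path CSV file path.
#' @param study_years inclusive year range (length-2 or full vector).
#' @return a [capture_history_set()].
#' @export
read_capture_histories <- function(path, study_years) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ring_id", "year_ringed", "stage_at_ringing", "year", "code")
  if (!all(need %in% names(df)))
    stop("capture-history CSV must have columns ",
         paste(need, collapse = ", "))
  ids <- unique(df$ring_id)
  meta <- df[!duplicated(df$ring_id), ]
  # per-bird metadata must not conflict across rows
  for (v in c("year_ringed", "stage_at_ringing")) {
    chk <- tapply(df[[v]], df$ring_id, function(z) length(unique(z)))
    if (any(chk > 1L))
      stop("conflicting ", v, " for ring_id ",
           names(chk)[which(chk > 1L)[1]])
  }
  meta <- meta[match(ids, meta$ring_id), ]
  events <- lapply(ids, function(id) {
    rows <- df[df$ring_id == id, ]
    stats::setNames(as.character(rows$code), rows$year)
  })
  flags <- list(rehabilitated = FALSE, improper_ring = FALSE)
  for (f in names(flags))
    if (f %in% names(df))
      flags[[f]] <- as.logical(meta[[f]])
  capture_history_set(ids, meta$year_ringed, meta$stage_at_ringing,
                      events, study_years,
                      rehabilitated = flags$rehabilitated,
                      improper_ring = flags$improper_ring)
}

#' Write capture histories to the long-format CSV dialect
#'
#' The marking row and all non-`U` events are written, ordered by
#' `ring_id` then `year`; `U` rows are omitted (the reader restores them).
#'
#' @param set a [capture_history_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_capture_histories <- function(set, path) {
  rows <- list()
  any_flag <- any(set$rehabilitated) || any(set$improper_ring)
  for (i in seq_along(set$ring_id)) {
    codes <- set$codes[i, ]
    keep <- !is.na(codes) & (codes != "U" |
                             names(codes) == as.character(set$year_ringed[i]))
    df <- data.frame(ring_id = set$ring_id[i],
                     year_ringed = set$year_ringed[i],
                     stage_at_ringing = set$stage_at_ringing[i],
                     year = as.integer(names(codes)[keep]),
                     code = unname(codes[keep]),
                     stringsAsFactors = FALSE)
    if (any_flag) {
      df$rehabilitated <- set$rehabilitated[i]
      df$improper_ring <- set$improper_ring[i]
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ring_id, out$year), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove rehabilitated and improperly ringed birds
#'
#' Birds released after rehabilitation, and nestlings marked with improperly
#' sized rings, are excluded whole; the number removed per reason is
#' reported via `message()`.
#'
#' @param set a [capture_history_set()].
#' @return the filtered set.
#' @export
apply_exclusions <- function(set) {
  n_rehab <- sum(set$rehabilitated)
  n_ring <- sum(set$improper_ring & !set$rehabilitated)
  message("excluded ", n_rehab, " rehabilitated and ", n_ring,
          " improperly ringed birds")
  set[!(set$rehabilitated | set$improper_ring)]
}

#' Drop birds marked before a cutoff year
#'
#' Whole-bird exclusion (not event censoring): any bird with
#' `year_ringed < cutoff_year` is removed. Used to align capture histories
#' with the years for which covariates exist.
#'
#' @param set a [capture_history_set()].
#' @param cutoff_year first ringing year to keep.
#' @return the truncated set.
#' @export
truncate_before <- function(set, cutoff_year) {
  stopifnot(cutoff_year >= set$study_years[1],
            cutoff_year <= set$study_years[length(set$study_years)])
  set[set$year_ringed >= cutoff_year]
}

#' Tally post-marking encounters
#'
#' @param set a [capture_history_set()].
#' @return list with `live_encounters` (post-marking `L` events),
#'   `dead_recoveries` (`D` events) and `birds_reencountered` (birds with at
#'   least one post-marking encounter).
#' @export
encounter_tally <- function(set) {
  n <- length(set)
  live <- 0L; dead <- 0L; reenc <- 0L
  for (i in seq_len(n)) {
    codes <- set$codes[i, ]
    post <- codes[!is.na(codes) &
                  as.integer(names(codes)) > set$year_ringed[i]]
    nl <- sum(post == "L"); nd <- sum(post == "D")
    live <- live + nl; dead <- dead + nd
    if (nl + nd > 0L) reenc <- reenc + 1L
  }
  list(live_encounters = live, dead_recoveries = dead,
       birds_reencountered = reenc)
}
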