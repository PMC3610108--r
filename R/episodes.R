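# Care-episode construction: chain discharge records into episodes with the
# gap rule (a record joins the running episode when its admission is at most
# `gap_days` after the latest discharge seen so far for that person), and
# bed-day arithmetic on the union of record intervals.

REGISTER_COLUMNS <- c("person_id", "admission_date", "discharge_date",
                      "provider_type", "specialty", "long_term_care", "era",
                      "main_ncode", "ncode2", "ncode3", "ecode")

#' Validate a register extract
#'
#' Checks the ingest schema: required columns, parseable dates,
#' `discharge_date >= admission_date`, and a non-empty main N-code on every
#' row (rows without any N-code are rejected, with their row numbers
#' reported). Dates are coerced to `Date`, `long_term_care` to logical.
#'
#' @param records data frame in the ingest schema (see [read_register()]).
#' @param drop_invalid drop rows lacking a main N-code with a warning
#'   instead of erroring.
#' @return the validated (possibly reduced) data frame.
#' @export
validate_register <- function(records, drop_invalid = TRUE) {
  missing_cols <- setdiff(REGISTER_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("register is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$admission_date <- .as_date(records$admission_date)
  records$discharge_date <- .as_date(records$discharge_date)
  bad_date <- which(is.na(records$admission_date) | is.na(records$discharge_date))
  if (length(bad_date)) {
    stop("unparseable admission/discharge date on row(s): ",
         paste(utils::head(bad_date, 10), collapse = ", "))
  }
  neg <- which(records$discharge_date < records$admission_date)
  if (length(neg)) {
    stop("discharge before admission on row(s): ",
         paste(utils::head(neg, 10), collapse = ", "))
  }
  if (!all(records$era %in% c("ICD9", "ICD10"))) {
    stop("era must be ICD9 or ICD10 on every row")
  }
  records$long_term_care <- as.logical(records$long_term_care)
  no_ncode <- which(is.na(records$main_ncode) |
                      !nzchar(trimws(as.character(records$main_ncode))))
  if (length(no_ncode)) {
    if (!drop_invalid) {
      stop("missing main N-code on row(s): ",
           paste(utils::head(no_ncode, 10), collapse = ", "))
    }
    warning(sprintf("rejected %d record(s) without a main N-code (rows %s%s)",
                    length(no_ncode),
                    paste(utils::head(no_ncode, 10), collapse = ", "),
                    if (length(no_ncode) > 10) ", ..." else ""))
    records <- records[-no_ncode, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Assign episode identifiers to discharge records
#'
#' Sorts records by person, admission date (ties broken by discharge date
#' descending, so the longest stay leads and supplies the episode's first
#' record) and chains them: a record belongs to the running episode when its
#' admission is at most `gap_days` days after the latest discharge date seen
#' so far in that episode. Overlapping records (e.g. day surgery during a
#' ward stay) chain trivially. Chaining is transitive through the running
#' maximum discharge, which makes the rule equivalent to merging the record
#' intervals after extending each by the tolerance.
#'
#' @param records validated register data frame.
#' @param gap_days maximum allowed gap in days between a discharge and the
#'   next admission within one episode (default 2).
#' @return `records`, reordered, with an integer `episode_id` column
#'   (consecutive, unique across persons).
#' @export
assign_episodes <- function(records, gap_days = 2) {
  stopifnot(gap_days >= 0)
  if (nrow(records) == 0L) {
    records$episode_id <- integer(0)
    return(records)
  }
  records$admission_date <- .as_date(records$admission_date)
  records$discharge_date <- .as_date(records$discharge_date)
  o <- order(records$person_id, records$admission_date,
             -as.numeric(records$discharge_date), method = "radix")
  records <- records[o, , drop = FALSE]
  adm <- as.numeric(records$admission_date)
  dis <- as.numeric(records$discharge_date)
  pid <- records$person_id
  runmax <- .cummax_by(dis, pid)
  n <- nrow(records)
  prev_max <- c(-Inf, runmax[-n])
  new_person <- .group_first(pid)
  new_episode <- new_person | (adm - prev_max) > gap_days
  records$episode_id <- cumsum(new_episode)
  rownames(records) <- NULL
  records
}

#' Chain one person's records into care episodes
#'
#' The per-person form of [assign_episodes()]: returns the partition of the
#' records into episodes as a list of data frames, each ordered by admission
#' date. A record that does not chain to any other forms a single-record
#' episode. Errors if records from more than one person are supplied.
#'
#' @param records data frame of one person's discharge records.
#' @param gap_days chaining tolerance in days.
#' @return list of data frames (one per episode, chronological).
#' @export
build_episodes <- function(records, gap_days = 2) {
  if (nrow(records) == 0L) return(list())
  if (length(unique(records$person_id)) > 1L) {
    stop("build_episodes() expects records of a single person; got ",
         length(unique(records$person_id)), " person_ids")
  }
  with_id <- assign_episodes(records, gap_days)
  unname(split(with_id, with_id$episode_id))
}

# union of half-open day intervals [admission, discharge) per group,
# with the same-day rule applied at episode level: a non-empty set of
# records always contributes at least 1 day.
.union_days_by <- function(adm, dis, g) {
  if (length(adm) == 0L) return(numeric(0))
  o <- order(g, adm, method = "radix")
  adm <- as.numeric(adm)[o]; dis <- as.numeric(dis)[o]; g <- g[o]
  runmax <- .cummax_by(dis, g)
  n <- length(adm)
  prev_max <- c(-Inf, runmax[-n])
  prev_max[.group_first(g)] <- -Inf
  contrib <- pmax(0, dis - pmax(adm, prev_max))
  days <- .sum_by(contrib, g)
  pmax(days, 1)
}

#' Bed days of a care episode
#'
#' Calendar days covered by the union of the `[admission, discharge)`
#' intervals of the included records; overlap from transfer records is not
#' double-counted. A same-day stay counts as 1 day; an empty record subset
#' gives 0.
#'
#' @param episode data frame of one episode's records.
#' @param included logical vector selecting records (default all).
#' @return non-negative integer day count.
#' @examples
#' ep <- data.frame(admission_date = as.Date(c("2010-01-01", "2010-01-04")),
#'                  discharge_date = as.Date(c("2010-01-06", "2010-01-10")))
#' episode_bed_days(ep)  # 9
#' @export
episode_bed_days <- function(episode, included = NULL) {
  if (is.null(included)) included <- rep(TRUE, nrow(episode))
  stopifnot(length(included) == nrow(episode))
  ep <- episode[included, , drop = FALSE]
  if (nrow(ep) == 0L) return(0)
  as.numeric(.union_days_by(.as_date(ep$admission_date),
                            .as_date(ep$discharge_date),
                            rep(1L, nrow(ep))))
}

#' Length of a care episode in bed days
#'
#' Bed days of the full episode, all records included.
#'
#' @inheritParams episode_bed_days
#' @return integer day count (same-day episodes count 1).
#' @export
episode_length_days <- function(episode) episode_bed_days(episode)

#' Per-episode summary table
#'
#' One row per episode: person, start date (earliest admission), end date
#' (latest discharge), record count, start year (the year the episode's bed
#' days are attributed to) and length in bed days.
#'
#' @param records register data frame with an `episode_id` column (from
#'   [assign_episodes()]).
#' @return data frame with columns `episode_id`, `person_id`, `start_date`,
#'   `end_date`, `n_records`, `year`, `length_days`.
#' @export
episode_summary <- function(records) {
  stopifnot("episode_id" %in% names(records))
  if (nrow(records) == 0L) {
    return(data.frame(episode_id = integer(0), person_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      n_records = integer(0), year = integer(0),
                      length_days = numeric(0)))
  }
  o <- order(records$episode_id, records$admission_date, method = "radix")
  r <- records[o, , drop = FALSE]
  ep <- r$episode_id
  first_idx <- which(.group_first(ep))
  last_idx <- c(first_idx[-1L] - 1L, length(ep))
  adm <- .as_date(r$admission_date); dis <- .as_date(r$discharge_date)
  start <- adm[first_idx]
  end <- as.Date(.cummax_by(as.numeric(dis), ep)[last_idx], origin = "1970-01-01")
  data.frame(
    episode_id = ep[first_idx],
    person_id = r$person_id[first_idx],
    start_date = start,
    end_date = end,
    n_records = last_idx - first_idx + 1L,
    year = as.integer(format(start, "%Y")),
    length_days = as.numeric(.union_days_by(adm, dis, ep)),
    row.names = NULL
  )
}
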