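# Inclusion-criteria engine for counting inpatient days of fire-related
# care episodes. Criteria (applied record-wise, before the union-of-days
# computation):
#   UNRESTRICTED - every record of a fire-related episode
#   A - care in the field of psychiatry excluded
#   B - care with a long-term care decision excluded
#   C - only records with an injury diagnosis (S00-T98; ICD-9 range
#       configurable, default 800-999) among the first three N-codes
#   D - only records with an injury diagnosis as the main diagnosis
#   E - only records with a fire-related E-code (X00-X09, X76, X97, Y26;
#       ICD-9 E890-E899); a missing E-code cannot match, which is exactly
#       why this criterion underestimates the injury-attributable stay

BED_DAY_CRITERIA <- c("UNRESTRICTED", "A", "B", "C", "D", "E")

#' Evaluate a bed-day inclusion criterion record-wise
#'
#' @param records register data frame (rows assumed to belong to
#'   fire-related episodes; the predicate itself does not check this).
#' @param criterion one of `"UNRESTRICTED"`, `"A"`..`"E"`.
#' @param catalog a [code_catalog()].
#' @return logical vector: does each record pass the criterion.
#' @export
apply_criterion <- function(records, criterion = BED_DAY_CRITERIA,
                            catalog = code_catalog()) {
  criterion <- match.arg(criterion)
  if (criterion == "UNRESTRICTED") return(rep(TRUE, nrow(records)))
  if (criterion == "A") return(records$specialty != "PSYCHIATRY")
  if (criterion == "B") return(!as.logical(records$long_term_care))
  flags <- .record_flags(records, catalog)
  switch(criterion,
         C = flags$injury_first3,
         D = flags$injury_main,
         E = flags$fire_e)
}

#' Yearly bed-day totals under the inclusion criteria
#'
#' For fire-related episodes only: per calendar year (an episode's days are
#' attributed to the year its first admission falls in) and per criterion,
#' the total bed days over the union of intervals of the records passing
#' the criterion, and that total as a percentage of the unrestricted total.
#' Also reports the median full-episode length per year.
#'
#' @param records register data frame with `episode_id`.
#' @param mechanisms result of [classify_episodes()]; computed when `NULL`.
#' @param criteria which criteria to evaluate besides UNRESTRICTED.
#' @param catalog a [code_catalog()].
#' @return object of class `criteria_report`: list with `table` (long data
#'   frame: `year`, `criterion`, `bed_days`, `pct`) and `medians`
#'   (`year`, `n_episodes`, `median_length_days`).
#' @export
yearly_bed_day_report <- function(records, mechanisms = NULL,
                                  criteria = c("A", "B", "C", "D", "E"),
                                  catalog = code_catalog()) {
  stopifnot("episode_id" %in% names(records),
            all(criteria %in% BED_DAY_CRITERIA))
  if (is.null(mechanisms)) mechanisms <- classify_episodes(records, catalog)
  fire_eps <- mechanisms$episode_id[mechanisms$mechanism == "FIRE"]
  r <- records[records$episode_id %in% fire_eps, , drop = FALSE]
  eps <- episode_summary(r)
  years <- sort(unique(eps$year))
  ep_year <- eps$year[match(r$episode_id, eps$episode_id)]

  days_by_year <- function(included) {
    rr <- r[included, , drop = FALSE]
    if (nrow(rr) == 0L) return(stats::setNames(rep(0, length(years)), years))
    d <- .union_days_by(.as_date(rr$admission_date),
                        .as_date(rr$discharge_date), rr$episode_id)
    ep_ids <- as.integer(names(d))
    y <- eps$year[match(ep_ids, eps$episode_id)]
    tot <- .sum_by(d, y)
    out <- stats::setNames(rep(0, length(years)), years)
    out[names(tot)] <- tot
    out
  }

  unrestricted <- days_by_year(rep(TRUE, nrow(r)))
  rows <- list(data.frame(year = years, criterion = "UNRESTRICTED",
                          bed_days = as.numeric(unrestricted),
                          pct = share_pct(unrestricted, unrestricted)))
  for (cr in criteria) {
    inc <- apply_criterion(r, cr, catalog)
    d <- days_by_year(inc)
    rows[[length(rows) + 1L]] <- data.frame(
      year = years, criterion = cr, bed_days = as.numeric(d),
      pct = share_pct(d, unrestricted))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  med <- data.frame(
    year = years,
    n_episodes = as.integer(table(factor(eps$year, levels = years))),
    median_length_days = as.numeric(tapply(eps$length_days,
                                           factor(eps$year, levels = years),
                                           stats::median))
  )
  structure(list(table = tab, medians = med), class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat("Yearly inpatient-day totals of fire-related episodes by inclusion criterion\n\n")
  print(format_criteria_report(x), row.names = FALSE)
  invisible(x)
}

#' Wide (table-style) layout of a criteria report
#'
#' Criteria as rows, years as columns (percentage of the unrestricted
#' yearly total), preceded by the median episode length per year.
#'
#' @param report a `criteria_report`.
#' @param value `"pct"` or `"bed_days"`.
#' @return data frame suitable for CSV export.
#' @export
format_criteria_report <- function(report, value = c("pct", "bed_days")) {
  value <- match.arg(value)
  tab <- report$table
  years <- sort(unique(tab$year))
  crits <- unique(tab$criterion)
  wide <- data.frame(criterion = c("median_length_days", crits))
  for (y in years) {
    col <- c(report$medians$median_length_days[report$medians$year == y],
             vapply(crits, function(cr) {
               tab[[value]][tab$year == y & tab$criterion == cr]
             }, numeric(1)))
    wide[[as.character(y)]] <- col
  }
  wide
}
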