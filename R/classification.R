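# Mechanism-of-injury classification of care episodes, E-coding
# completeness auditing, and the two data-quality detectors (contradicting
# mechanism codes within fire episodes; inpatient-onset injuries).
#
# Classification is episode-level: evidence from ANY record of the episode
# counts, which keeps the mechanism identifiable when only some records of
# an episode carry an E-code. Precedence is strict:
#   FIRE  - any record with a fire-related E-code
#   BURN  - otherwise, any record with a burn N-code in any position
#   GAS   - otherwise, any record with a combustion-gas N-code
#   OTHER - none of the above

.ncode_columns <- function(records) {
  c("main_ncode", grep("^ncode[0-9]+$", names(records), value = TRUE))
}

# per-record evidence flags, era-aware
.record_flags <- function(records, catalog = code_catalog(),
                          gas_ecode_evidence = TRUE) {
  n <- nrow(records)
  flags <- data.frame(
    fire_e = logical(n), burn_n = logical(n), gas_n = logical(n),
    gas_e = logical(n), contradict_e = logical(n),
    injury_main = logical(n), injury_first3 = logical(n),
    psych_main = logical(n)
  )
  ncols <- .ncode_columns(records)
  first3 <- intersect(c("main_ncode", "ncode2", "ncode3"), names(records))
  for (e in intersect(c("ICD10", "ICD9"), unique(records$era))) {
    i <- which(records$era == e)
    sets <- catalog[[e]]
    in_set <- function(col, set) {
      v <- records[[col]][i]
      code_matches(v, set, era = e)
    }
    flags$fire_e[i] <- in_set("ecode", sets$FIRE_E)
    if (e == "ICD10") {
      flags$gas_e[i] <- in_set("ecode", sets$GAS_E)
      flags$contradict_e[i] <- in_set("ecode", sets$CONTRADICT_E)
    }
    for (col in ncols) {
      flags$burn_n[i] <- flags$burn_n[i] | in_set(col, sets$BURN_N)
      flags$gas_n[i] <- flags$gas_n[i] | in_set(col, sets$GAS_N)
    }
    for (col in first3) {
      flags$injury_first3[i] <- flags$injury_first3[i] | in_set(col, sets$INJURY_N)
    }
    flags$injury_main[i] <- in_set("main_ncode", sets$INJURY_N)
    flags$psych_main[i] <- in_set("main_ncode", sets$PSYCH_DX)
  }
  if (!gas_ecode_evidence) flags$gas_e[] <- FALSE
  flags
}

#' Classify episodes by mechanism of injury
#'
#' Applies the strict precedence FIRE > BURN > GAS > OTHER using evidence
#' from every record of each episode (see the package vignette). The
#' gas-exposure E-code X47 contributes gas evidence by default; set
#' `gas_ecode_evidence = FALSE` to define gas strictly by N-code.
#'
#' @param records register data frame with `episode_id` (from
#'   [assign_episodes()]).
#' @param catalog a [code_catalog()].
#' @param gas_ecode_evidence should X47 count as gas-mechanism evidence.
#' @return data frame: `episode_id`, `mechanism` (factor FIRE/BURN/GAS/OTHER).
#' @export
classify_episodes <- function(records, catalog = code_catalog(),
                              gas_ecode_evidence = TRUE) {
  stopifnot("episode_id" %in% names(records))
  flags <- .record_flags(records, catalog, gas_ecode_evidence)
  ep <- records$episode_id
  fire <- .any_by(flags$fire_e, ep)
  burn <- .any_by(flags$burn_n, ep)
  gas <- .any_by(flags$gas_n | flags$gas_e, ep)
  mech <- ifelse(fire, "FIRE", ifelse(burn, "BURN", ifelse(gas, "GAS", "OTHER")))
  data.frame(episode_id = as.integer(names(fire)),
             mechanism = factor(mech, levels = c("FIRE", "BURN", "GAS", "OTHER")),
             row.names = NULL)
}

#' Mechanism of a single care episode
#'
#' @param episode data frame of one episode's records.
#' @inheritParams classify_episodes
#' @return one of `"FIRE"`, `"BURN"`, `"GAS"`, `"OTHER"`.
#' @export
classify_mechanism <- function(episode, catalog = code_catalog(),
                               gas_ecode_evidence = TRUE) {
  stopifnot(nrow(episode) > 0L)
  episode$episode_id <- 1L
  as.character(classify_episodes(episode, catalog, gas_ecode_evidence)$mechanism)
}

#' Episode-level E-coding completeness
#'
#' `ALL_MISSING` when every record's E-code is absent, `UNSPECIFIC_ONLY`
#' when at least one is present and all present ones are X58/X59,
#' `IDENTIFIED` otherwise.
#'
#' @inheritParams classify_episodes
#' @return data frame: `episode_id`, `completeness` (factor).
#' @export
episode_completeness <- function(records, catalog = code_catalog()) {
  stopifnot("episode_id" %in% names(records))
  cls <- ecode_completeness(records$ecode, records$era, catalog, warn = FALSE)
  ep <- records$episode_id
  any_present <- .any_by(cls != "MISSING", ep)
  any_specific <- .any_by(cls == "SPECIFIC", ep)
  out <- ifelse(!any_present, "ALL_MISSING",
                ifelse(any_specific, "IDENTIFIED", "UNSPECIFIC_ONLY"))
  data.frame(episode_id = as.integer(names(any_present)),
             completeness = factor(out, levels = c("IDENTIFIED",
                                                   "UNSPECIFIC_ONLY",
                                                   "ALL_MISSING")),
             row.names = NULL)
}

#' Record-level E-coding completeness report
#'
#' Tabulates, among records whose MAIN diagnosis is a burn (T20-T32, T95;
#' ICD-9 940-949) or a combustion gas poisoning (T58-T59; ICD-9 986), the
#' share with an unspecific (X58/X59) and with a missing E-code, by the
#' requested stratifiers. Percentages are rounded to one decimal; strata
#' with `n = 0` report `NA` percentages.
#'
#' @param records register data frame.
#' @param group `"BURNS"` or `"GAS"` — which main-diagnosis group to audit.
#' @param by stratifier columns: any of `"year"` (admission year) and
#'   `"provider_type"`.
#' @param catalog a [code_catalog()].
#' @return data frame with the stratifiers, `group`, `n`,
#'   `pct_unspecific`, `pct_missing`.
#' @export
record_completeness_report <- function(records, group = c("BURNS", "GAS"),
                                       by = "year",
                                       catalog = code_catalog()) {
  group <- match.arg(group)
  stopifnot(all(by %in% c("year", "provider_type")))
  set_name <- if (group == "BURNS") "BURN_N" else "GAS_N"
  sel <- logical(nrow(records))
  for (e in intersect(c("ICD10", "ICD9"), unique(records$era))) {
    i <- which(records$era == e)
    sel[i] <- code_matches(records$main_ncode[i], catalog[[e]][[set_name]], era = e)
  }
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(integer(0), 0, length(by))), by)
    out$group <- character(0); out$n <- integer(0)
    out$pct_unspecific <- numeric(0); out$pct_missing <- numeric(0)
    return(out)
  }
  r$year <- as.integer(format(.as_date(r$admission_date), "%Y"))
  cls <- ecode_completeness(r$ecode, r$era, catalog, warn = FALSE)
  key <- interaction(r[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  n <- as.integer(table(key))
  unspec <- as.integer(rowsum(as.integer(cls == "UNSPECIFIC"), key))
  missing <- as.integer(rowsum(as.integer(cls == "MISSING"), key))
  strata <- unique(r[order(key), by, drop = FALSE])
  out <- cbind(strata,
               data.frame(group = group, n = n,
                          pct_unspecific = share_pct(unspec, n, 1),
                          pct_missing = share_pct(missing, n, 1)))
  rownames(out) <- NULL
  out
}

#' Mechanism partition summary
#'
#' Table of record and episode counts per mechanism class with a total row
#' and, for the identified mechanisms (FIRE, BURN, GAS), each class's
#' integer-rounded share of the identified episodes. Accepts either a
#' classified register (records + episode mechanisms) or pre-tabulated
#' counts via `counts`.
#'
#' @param records register data frame with `episode_id`, or `NULL` when
#'   `counts` is given.
#' @param mechanisms result of [classify_episodes()] for `records`.
#' @param counts optional data frame with columns `category` (values
#'   `FIRE`, `BURN`, `GAS`, `OTHER`), `records`, `episodes`.
#' @return data frame with rows TOTAL, FIRE, BURN, GAS, OTHER and columns
#'   `records`, `episodes`, `identified_share_pct`.
#' @export
mechanism_partition <- function(records = NULL, mechanisms = NULL,
                                counts = NULL) {
  lev <- c("FIRE", "BURN", "GAS", "OTHER")
  if (is.null(counts)) {
    stopifnot(!is.null(records), !is.null(mechanisms))
    m <- factor(mechanisms$mechanism, levels = lev)
    ep_counts <- as.integer(table(m))
    rec_mech <- m[match(records$episode_id, mechanisms$episode_id)]
    rec_counts <- as.integer(table(rec_mech))
  } else {
    i <- match(lev, counts$category)
    if (anyNA(i)) stop("counts must cover categories FIRE, BURN, GAS, OTHER")
    ep_counts <- as.integer(counts$episodes[i])
    rec_counts <- as.integer(counts$records[i])
  }
  identified <- sum(ep_counts[1:3])
  share <- c(share_pct(ep_counts[1:3], identified), NA_real_)
  out <- data.frame(
    category = c("TOTAL", lev),
    records = c(sum(rec_counts), rec_counts),
    episodes = c(sum(ep_counts), ep_counts),
    identified_share_pct = c(NA_real_, share)
  )
  out
}

#' Share of identified mechanisms from raw counts
#'
#' The partition arithmetic alone: integer-rounded percentage of each
#' identified mechanism class among the fire + burn + gas episodes.
#'
#' @param counts named numeric vector with elements `fire`, `burn`, `gas`.
#' @return named numeric vector of integer percentages.
#' @examples
#' partition_shares(c(fire = 21, burn = 74, gas = 5))
#' @export
partition_shares <- function(counts) {
  stopifnot(all(c("fire", "burn", "gas") %in% names(counts)))
  counts <- counts[c("fire", "burn", "gas")]
  stats::setNames(share_pct(counts, sum(counts)), c("fire", "burn", "gas"))
}

#' Share of burn episodes mixing present and missing E-codes
#'
#' Among burn-mechanism episodes that have at least one record with an
#' E-code present, the share that simultaneously contain records with a
#' burn main diagnosis but a missing E-code. Integer-rounded, matching the
#' partition-summary convention.
#'
#' @param records register data frame with `episode_id`.
#' @param mechanisms result of [classify_episodes()].
#' @param catalog a [code_catalog()].
#' @return list with `n_mixed`, `n_base` (episodes with >=1 E-code present)
#'   and `pct`.
#' @export
mixed_ecode_share <- function(records, mechanisms, catalog = code_catalog()) {
  burn_eps <- mechanisms$episode_id[mechanisms$mechanism == "BURN"]
  r <- records[records$episode_id %in% burn_eps, , drop = FALSE]
  if (nrow(r) == 0L) return(list(n_mixed = 0L, n_base = 0L, pct = NA_real_))
  cls <- ecode_completeness(r$ecode, r$era, catalog, warn = FALSE)
  burn_main <- logical(nrow(r))
  for (e in intersect(c("ICD10", "ICD9"), unique(r$era))) {
    i <- which(r$era == e)
    burn_main[i] <- code_matches(r$main_ncode[i], catalog[[e]]$BURN_N, era = e)
  }
  ep <- r$episode_id
  has_present <- .any_by(cls != "MISSING", ep)
  has_burn_missing <- .any_by(burn_main & cls == "MISSING", ep)
  n_base <- sum(has_present)
  n_mixed <- sum(has_present & has_burn_missing)
  list(n_mixed = n_mixed, n_base = n_base, pct = share_pct(n_mixed, n_base))
}

#' Detect contradicting mechanism codes within fire episodes
#'
#' For episodes classified FIRE, pairs each record carrying a fire-related
#' E-code with every record of the same episode whose E-code belongs to the
#' contradicting ranges (X10-X19 heat contact, X30-X39 forces of nature,
#' W32-W40 firearms/explosions, W85-W99 electric current / radiation /
#' extreme ambient conditions). Reported only — contradicting episodes are
#' never excluded.
#'
#' @param records register data frame with `episode_id`.
#' @param mechanisms result of [classify_episodes()]; if `NULL` it is
#'   computed.
#' @param catalog a [code_catalog()].
#' @return data frame: `episode_id`, `person_id`, `fire_row`,
#'   `contradict_row` (row indices into `records`), `fire_ecode`,
#'   `contradict_ecode`. Zero rows when no contradiction exists.
#' @export
detect_contradictions <- function(records, mechanisms = NULL,
                                  catalog = code_catalog()) {
  stopifnot("episode_id" %in% names(records))
  if (is.null(mechanisms)) mechanisms <- classify_episodes(records, catalog)
  flags <- .record_flags(records, catalog)
  fire_eps <- mechanisms$episode_id[mechanisms$mechanism == "FIRE"]
  cand <- records$episode_id %in% fire_eps & (flags$fire_e | flags$contradict_e)
  idx <- which(cand)
  empty <- data.frame(episode_id = integer(0), person_id = character(0),
                      fire_row = integer(0), contradict_row = integer(0),
                      fire_ecode = character(0), contradict_ecode = character(0))
  if (!length(idx)) return(empty)
  out <- lapply(split(idx, records$episode_id[idx]), function(i) {
    f <- i[flags$fire_e[i]]
    k <- i[flags$contradict_e[i]]
    if (!length(f) || !length(k)) return(NULL)
    g <- expand.grid(fire_row = f, contradict_row = k)
    data.frame(episode_id = records$episode_id[g$fire_row],
               person_id = records$person_id[g$fire_row],
               fire_row = g$fire_row, contradict_row = g$contradict_row,
               fire_ecode = as.character(records$ecode[g$fire_row]),
               contradict_ecode = as.character(records$ecode[g$contradict_row]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Detect likely inpatient-onset fire injuries
#'
#' For each person with at least one FIRE episode, inspects the first
#' record of their first FIRE episode. The case is flagged when that record
#' carries no fire-related E-code, no burn N-code and no combustion-gas
#' N-code in any position — i.e. the episode opens with care unrelated to
#' the injury, suggesting the injury occurred during an ongoing stay. The
#' context reports whether that record's main diagnosis is psychiatric
#' (F00-F99) and whether its specialty field is psychiatric care.
#'
#' @param records register data frame with `episode_id`, ordered as
#'   returned by [assign_episodes()].
#' @param mechanisms result of [classify_episodes()]; computed when `NULL`.
#' @param catalog a [code_catalog()].
#' @return data frame, one row per person with a FIRE episode:
#'   `person_id`, `episode_id`, `first_record_row`, `flagged`,
#'   `psych_main_dx`, `psych_specialty`.
#' @export
detect_inpatient_onset <- function(records, mechanisms = NULL,
                                   catalog = code_catalog()) {
  stopifnot("episode_id" %in% names(records))
  if (is.null(mechanisms)) mechanisms <- classify_episodes(records, catalog)
  fire_eps <- mechanisms$episode_id[mechanisms$mechanism == "FIRE"]
  is_fire <- records$episode_id %in% fire_eps
  if (!any(is_fire)) {
    return(data.frame(person_id = character(0), episode_id = integer(0),
                      first_record_row = integer(0), flagged = logical(0),
                      psych_main_dx = logical(0), psych_specialty = logical(0)))
  }
  # records come ordered person x admission; the first fire-episode row per
  # person is the first record of that person's first fire episode
  idx <- which(is_fire)
  first_per_person <- idx[.group_first(records$person_id[idx])]
  flags <- .record_flags(records[first_per_person, , drop = FALSE], catalog)
  flagged <- !(flags$fire_e | flags$burn_n | flags$gas_n)
  data.frame(
    person_id = records$person_id[first_per_person],
    episode_id = records$episode_id[first_per_person],
    first_record_row = first_per_person,
    flagged = flagged,
    psych_main_dx = flags$psych_main,
    psych_specialty = records$specialty[first_per_person] == "PSYCHIATRY",
    row.names = NULL
  )
}
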