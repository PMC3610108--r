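# Synthetic discharge-register generator with ground truth.
#
# Emulates the structures the analysis assumes: injury episodes split
# across transfer records (1 + Geometric record counts, inter-record gaps
# of 0-2 days), a readmission process whose hazard is h1 until the
# changepoint tau and h0 after (piecewise-constant, the simplest structure
# consistent with an "elevated then nearly constant" backward-time
# hazard), year- and provider-dependent E-code missingness and unspecific
# (X58/X59) coding, psychiatric inpatient-onset fire injuries, long-term
# care flags, occasional contradicting mechanism codes on secondary
# records, and background (non-injury) care. All randomness flows from the
# config seed; the same config gives byte-identical output.

.default_missing_pattern <- stats::setNames(
  c(0.65, 0.53, 0.26, 0.13, 0.11, 0.10, 0.09, 0.10, 0.09, 0.07, 0.08,
    0.04, 0.045, 0.023),
  1996:2009)

.default_unspecific_pattern <- stats::setNames(
  c(0.02, 0.04, 0.056, 0.042, 0.037, 0.047, 0.064, 0.083, 0.079, 0.098,
    0.096, 0.098, 0.136, 0.114),
  1996:2009)

#' Year-specific default E-code quality rates
#'
#' The default missing/unspecific rates follow the historical pattern of
#' E-coding after the ICD-10 introduction: missingness near 0.65 in the
#' first year, declining steeply to about 0.02 by the 14th year, while
#' unspecific coding slowly rises. Years outside the 14-year pattern are
#' clamped to its ends.
#'
#' @param years integer vector of calendar years.
#' @param type `"missing"` or `"unspecific"`.
#' @return named numeric vector of per-record probabilities.
#' @export
default_ecode_rates <- function(years, type = c("missing", "unspecific")) {
  type <- match.arg(type)
  pat <- if (type == "missing") .default_missing_pattern else .default_unspecific_pattern
  key <- pmin(pmax(years, 1996L), 2009L)
  stats::setNames(as.numeric(pat[as.character(key)]), years)
}

#' Configuration for the synthetic register generator
#'
#' Defaults describe a cohort enriched for fire/burn/gas injuries over a
#' 14-year window; see the package vignette for the rationale behind each
#' value.
#'
#' @param n_persons cohort size.
#' @param study_window `c(first_year, last_year)`.
#' @param injury_rate per-person-year probability of a new injury.
#' @param mechanism_mix named probabilities over FIRE/BURN/GAS.
#' @param transfer_geometric_p geometric parameter; an episode has
#'   `1 + Geometric(p)` records (capped at 6).
#' @param gap_days_distribution named probabilities over the inter-record
#'   gaps (days) within an episode.
#' @param stay_meanlog,stay_sdlog log-normal record stay length (days).
#' @param readmission named vector `h1`, `h0`, `tau`: readmission hazard
#'   (per year) before/after the changepoint `tau` (years), anchored at
#'   the previous episode's end.
#' @param ecode_missing_rate,ecode_unspecific_rate named per-year
#'   probabilities (default [default_ecode_rates()]).
#' @param provider_mix named probabilities over provider types.
#' @param provider_missing_multiplier per-provider multipliers on the
#'   missingness rate; the defaults have mix-weighted mean 1 so the
#'   marginal yearly rate equals `ecode_missing_rate`.
#' @param psych_onset_rate share of incident fire episodes preceded
#'   in-episode by a psychiatric record.
#' @param psych_aftercare_rate share of fire episodes followed in-episode
#'   by a psychiatric record.
#' @param long_term_care_rate per-record probability of a long-term-care
#'   flag.
#' @param contradiction_rate share of multi-record fire episodes given one
#'   contradicting E-code on a secondary record.
#' @param complication_rate probability that a transfer/readmission record
#'   carries a complication main diagnosis with the injury code demoted to
#'   a supplementary position.
#' @param sequela_rate probability that a burn readmission episode is
#'   coded with the sequelae code T95 instead of an acute burn code.
#' @param background_care_rate per-person-year probability of an unrelated
#'   care episode.
#' @param background_psych_share share of background episodes that are
#'   psychiatric.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return validated list of class `register_config`.
#' @export
register_config <- function(n_persons = 2000,
                            study_window = c(1996, 2009),
                            injury_rate = 0.03,
                            mechanism_mix = c(FIRE = 0.21, BURN = 0.74, GAS = 0.05),
                            transfer_geometric_p = 0.8,
                            gap_days_distribution = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
                            stay_meanlog = log(5), stay_sdlog = 0.8,
                            readmission = c(h1 = 1.0, h0 = 0.1, tau = 2),
                            ecode_missing_rate = NULL,
                            ecode_unspecific_rate = NULL,
                            provider_mix = c(UNIVERSITY = 0.4,
                                             CENTRAL_DISTRICT = 0.4,
                                             HEALTH_CENTRE_PRIVATE = 0.2),
                            provider_missing_multiplier = c(UNIVERSITY = 0.6,
                                                            CENTRAL_DISTRICT = 1.3,
                                                            HEALTH_CENTRE_PRIVATE = 1.2),
                            psych_onset_rate = 0.03,
                            psych_aftercare_rate = 0.05,
                            long_term_care_rate = 0.02,
                            contradiction_rate = 0.035,
                            complication_rate = 0.15,
                            sequela_rate = 0.15,
                            background_care_rate = 0.3,
                            background_psych_share = 0.15,
                            seed = NULL) {
  years <- study_window[1]:study_window[2]
  if (is.null(ecode_missing_rate)) {
    ecode_missing_rate <- default_ecode_rates(years, "missing")
  }
  if (is.null(ecode_unspecific_rate)) {
    ecode_unspecific_rate <- default_ecode_rates(years, "unspecific")
  }
  cfg <- list(
    n_persons = n_persons, study_window = study_window,
    injury_rate = injury_rate, mechanism_mix = mechanism_mix,
    transfer_geometric_p = transfer_geometric_p,
    gap_days_distribution = gap_days_distribution,
    stay_meanlog = stay_meanlog, stay_sdlog = stay_sdlog,
    readmission = readmission,
    ecode_missing_rate = ecode_missing_rate,
    ecode_unspecific_rate = ecode_unspecific_rate,
    provider_mix = provider_mix,
    provider_missing_multiplier = provider_missing_multiplier,
    psych_onset_rate = psych_onset_rate,
    psych_aftercare_rate = psych_aftercare_rate,
    long_term_care_rate = long_term_care_rate,
    contradiction_rate = contradiction_rate,
    complication_rate = complication_rate,
    sequela_rate = sequela_rate,
    background_care_rate = background_care_rate,
    background_psych_share = background_psych_share,
    seed = seed
  )
  class(cfg) <- "register_config"
  validate_config(cfg)
}

#' Validate a generator configuration
#'
#' Errors (before any generation) on invalid probabilities, a
#' non-positive changepoint, `h1 <= h0`, or mismatched rate tables.
#'
#' @param cfg a `register_config`.
#' @return the config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "register_config"))
  probs <- c(cfg$injury_rate, cfg$mechanism_mix, cfg$transfer_geometric_p,
             cfg$gap_days_distribution, cfg$psych_onset_rate,
             cfg$psych_aftercare_rate, cfg$long_term_care_rate,
             cfg$contradiction_rate, cfg$complication_rate, cfg$sequela_rate,
             cfg$background_care_rate, cfg$background_psych_share,
             cfg$ecode_missing_rate, cfg$ecode_unspecific_rate,
             cfg$provider_mix)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$n_persons < 1) stop("n_persons must be positive")
  if (cfg$study_window[2] < cfg$study_window[1]) stop("study_window reversed")
  r <- cfg$readmission
  if (!all(c("h1", "h0", "tau") %in% names(r))) {
    stop("readmission needs named elements h1, h0, tau")
  }
  if (r[["tau"]] <= 0) stop("readmission changepoint tau must be positive")
  if (!(r[["h1"]] > r[["h0"]] && r[["h0"]] >= 0)) {
    stop("readmission hazards must satisfy h1 > h0 >= 0")
  }
  years <- cfg$study_window[1]:cfg$study_window[2]
  for (f in c("ecode_missing_rate", "ecode_unspecific_rate")) {
    if (!all(as.character(years) %in% names(cfg[[f]]))) {
      stop(f, " must name every study-window year")
    }
  }
  if (any(cfg$ecode_missing_rate[as.character(years)] +
            cfg$ecode_unspecific_rate[as.character(years)] > 1)) {
    stop("missing + unspecific rate exceeds 1 for some year")
  }
  if (abs(sum(cfg$provider_mix) - 1) > 1e-8) stop("provider_mix must sum to 1")
  if (abs(sum(cfg$mechanism_mix) - 1) > 1e-8) stop("mechanism_mix must sum to 1")
  cfg
}

# sample inter-episode gaps (years) from the piecewise-constant hazard
.piecewise_gap <- function(n, h1, h0, tau) {
  e <- stats::rexp(n)
  ifelse(e < h1 * tau, e / h1,
         if (h0 > 0) tau + (e - h1 * tau) / h0 else Inf)
}

.rand_digit <- function(n) as.character(sample(0:9, n, replace = TRUE))

# era-appropriate code emission ------------------------------------------

.fire_ecode <- function(n, era) {
  i10 <- era == "ICD10"
  out <- character(n)
  pool10 <- c(sprintf("X%02d", 0:9), "X76", "X97", "Y26")
  w10 <- c(rep(2, 10), 0.6, 0.2, 0.4)
  out[i10] <- sample(pool10, sum(i10), TRUE, prob = w10)
  # recorded forms sometimes carry a subcategory digit without a dot
  deco <- i10 & stats::runif(n) < 0.3
  out[deco] <- paste0(out[deco], .rand_digit(sum(deco)))
  out[!i10] <- paste0("E", 890 + sample(0:9, sum(!i10), TRUE))
  out
}

.burn_ncode <- function(n, era, sequela = rep(FALSE, n)) {
  i10 <- era == "ICD10"
  out <- character(n)
  stub <- sprintf("T%d", sample(20:31, n, TRUE))
  dotted <- stats::runif(n) < 0.5
  out[i10] <- ifelse(dotted[i10],
                     paste0(stub[i10], ".", .rand_digit(sum(i10))),
                     paste0(stub[i10], .rand_digit(sum(i10))))
  out[i10 & sequela] <- "T95"
  out[!i10] <- paste0("94", sample(0:8, sum(!i10), TRUE), .rand_digit(sum(!i10)))
  out
}

.gas_ncode <- function(n, era) {
  ifelse(era == "ICD10", sample(c("T58", "T59"), n, TRUE), "986")
}

COMPLICATION_CODES <- c("J18", "N39", "J96", "A41")
BACKGROUND_CODES <- c("J18", "I21", "I50", "K35", "M16", "E11", "C34", "N39", "J44")
PSYCH_CODES <- c("F20", "F25", "F29", "F31", "F32", "F10")
CONTRADICTION_POOL <- c("X12", "X15", "W87", "X37", "W39")

#' Generate a synthetic discharge register with ground truth
#'
#' See [register_config()] for the generative model. The emitted records
#' follow the ingest schema of [read_register()] plus a `record_id` column
#' linking each row to the ground truth.
#'
#' @param config a [register_config()].
#' @return list of class `synthetic_register`: `records` (data frame),
#'   `truth` (list: `episodes`, `records`, `params`), `config`.
#' @export
generate_register <- function(config = register_config()) {
  cfg <- validate_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  y0 <- cfg$study_window[1]; y1 <- cfg$study_window[2]
  years <- y0:y1; ny <- length(years)
  win_start <- as.numeric(as.Date(sprintf("%d-01-01", y0)))
  win_end <- as.numeric(as.Date(sprintf("%d-12-31", y1)))
  np <- cfg$n_persons

  ## incident injuries: one Bernoulli trial per person-year
  hit <- which(stats::runif(np * ny) < cfg$injury_rate)
  if (!length(hit)) stop("no injuries generated; increase injury_rate or n_persons")
  p_idx <- ((hit - 1L) %% np) + 1L
  yr <- years[((hit - 1L) %/% np) + 1L]
  inj_start <- as.numeric(as.Date(sprintf("%d-01-01", yr))) +
    sample.int(365L, length(hit), replace = TRUE) - 1L
  inj_start <- pmin(inj_start, win_end)
  mix <- cfg$mechanism_mix[c("FIRE", "BURN", "GAS")]
  mech0 <- sample(names(mix), length(hit), TRUE, prob = mix)

  ## episode chains: incident episode then piecewise-hazard readmissions
  h1 <- cfg$readmission[["h1"]]; h0 <- cfg$readmission[["h0"]]
  tau <- cfg$readmission[["tau"]]
  gap_days <- as.numeric(names(cfg$gap_days_distribution))
  ep_list <- list(); rec_list <- list()
  uid0 <- 0L
  pending <- data.frame(injury_id = seq_along(hit), person = p_idx,
                        mech = mech0, start = inj_start,
                        incident = TRUE, gap_years = NA_real_)
  round_i <- 0L
  while (nrow(pending) > 0L && round_i < 500L) {
    round_i <- round_i + 1L
    n <- nrow(pending)
    uid <- uid0 + seq_len(n); uid0 <- uid0 + n
    nrec <- pmin(1L + stats::rgeom(n, cfg$transfer_geometric_p), 6L)
    idx <- rep(seq_len(n), nrec)
    stay <- pmax(0, round(stats::rlnorm(length(idx), cfg$stay_meanlog, cfg$stay_sdlog)))
    gapv <- sample(gap_days, length(idx), TRUE, prob = cfg$gap_days_distribution)
    firstr <- !duplicated(idx)
    gapv[firstr] <- 0
    adm <- pending$start[idx] + (.cumsum_by(stay, idx) - stay) + .cumsum_by(gapv, idx)
    dis <- adm + stay
    lastr <- c(firstr[-1L], TRUE)
    rec_list[[round_i]] <- data.frame(
      ep_uid = uid[idx], adm = adm, dis = dis,
      pos = .cumsum_by(rep(1L, length(idx)), idx))
    ep_list[[round_i]] <- data.frame(
      uid = uid, injury_id = pending$injury_id, person = pending$person,
      mech = pending$mech, start = pending$start, end = dis[lastr],
      incident = pending$incident, gap_years = pending$gap_years)
    gy <- .piecewise_gap(n, h1, h0, tau)
    gap_d <- pmax(3, round(gy * DAYS_PER_YEAR))
    nxt <- dis[lastr] + gap_d
    keep <- which(is.finite(nxt) & nxt <= win_end)
    pending <- data.frame(injury_id = pending$injury_id[keep],
                          person = pending$person[keep],
                          mech = pending$mech[keep], start = nxt[keep],
                          incident = rep(FALSE, length(keep)),
                          gap_years = gap_d[keep] / DAYS_PER_YEAR)
  }
  eps <- do.call(rbind, ep_list)
  recs <- do.call(rbind, rec_list)
  recs$rec_type <- "injury"

  ## per-episode attributes
  n_ep <- nrow(eps)
  eps$subtype <- eps$mech
  is_fire <- eps$mech == "FIRE"
  eps$subtype[is_fire] <- sample(c("BURN", "GAS", "OTHER"), sum(is_fire),
                                 TRUE, prob = c(0.81, 0.13, 0.06))
  eps$sequela <- !eps$incident & eps$subtype == "BURN" &
    stats::runif(n_ep) < cfg$sequela_rate

  ## psychiatric inpatient-onset records before incident fire episodes
  onset_sel <- which(eps$incident & is_fire &
                       stats::runif(n_ep) < cfg$psych_onset_rate)
  if (length(onset_sel)) {
    stay_p <- pmax(5, round(stats::rlnorm(length(onset_sel), log(30), 0.7)))
    adm_p <- pmax(win_start, eps$start[onset_sel] - stay_p)
    rec_list_extra <- data.frame(ep_uid = eps$uid[onset_sel], adm = adm_p,
                                 dis = eps$start[onset_sel], pos = 0L,
                                 rec_type = "psych")
    recs <- rbind(recs, rec_list_extra)
    eps$start[onset_sel] <- adm_p
  }
  eps$psych_onset <- seq_len(n_ep) %in% onset_sel

  ## psychiatric aftercare records at the end of some fire episodes
  after_sel <- which(is_fire & !eps$psych_onset &
                       stats::runif(n_ep) < cfg$psych_aftercare_rate)
  if (length(after_sel)) {
    gap_a <- sample(gap_days, length(after_sel), TRUE,
                    prob = cfg$gap_days_distribution)
    adm_a <- eps$end[after_sel] + gap_a
    stay_a <- pmax(3, round(stats::rlnorm(length(after_sel), log(20), 0.7)))
    dis_a <- pmin(adm_a + stay_a, win_end + 60)
    recs <- rbind(recs, data.frame(ep_uid = eps$uid[after_sel], adm = adm_a,
                                   dis = dis_a, pos = 98L,
                                   rec_type = "psych"))
    eps$end[after_sel] <- dis_a
  }

  ## background (non-injury) single-record episodes
  bhit <- which(stats::runif(np * ny) < cfg$background_care_rate)
  if (length(bhit)) {
    bp <- ((bhit - 1L) %% np) + 1L
    byr <- years[((bhit - 1L) %/% np) + 1L]
    badm <- as.numeric(as.Date(sprintf("%d-01-01", byr))) +
      sample.int(365L, length(bhit), replace = TRUE) - 1L
    badm <- pmin(badm, win_end)
    bstay <- pmax(0, round(stats::rlnorm(length(bhit), log(4), 1)))
    buid <- uid0 + seq_along(bhit); uid0 <- uid0 + length(bhit)
    bpsych <- stats::runif(length(bhit)) < cfg$background_psych_share
    eps <- rbind(eps, data.frame(
      uid = buid, injury_id = NA_integer_, person = bp, mech = "OTHER",
      start = badm, end = badm + bstay, incident = FALSE,
      gap_years = NA_real_, subtype = ifelse(bpsych, "PSYCH_BG", "BG"),
      sequela = FALSE, psych_onset = FALSE))
    recs <- rbind(recs, data.frame(ep_uid = buid, adm = badm,
                                   dis = badm + bstay, pos = 1L,
                                   rec_type = ifelse(bpsych, "psych_bg", "background")))
  }

  ## record-level attributes ---------------------------------------------
  m <- match(recs$ep_uid, eps$uid)
  recs$person <- eps$person[m]
  recs$mech <- eps$mech[m]
  recs$subtype <- eps$subtype[m]
  recs$sequela <- eps$sequela[m]
  nr <- nrow(recs)
  rec_year <- as.integer(format(as.Date(recs$adm, origin = "1970-01-01"), "%Y"))
  recs$era <- ifelse(rec_year <= 1995L, "ICD9", "ICD10")
  recs$provider <- sample(names(cfg$provider_mix), nr, TRUE,
                          prob = cfg$provider_mix)
  recs$specialty <- ifelse(recs$rec_type %in% c("psych", "psych_bg"),
                           "PSYCHIATRY", "OTHER")
  recs$ltc <- stats::runif(nr) < cfg$long_term_care_rate

  ## diagnosis codes
  main <- character(nr); ncode2 <- character(nr); ncode3 <- character(nr)
  ecode <- rep(NA_character_, nr)
  inj <- recs$rec_type == "injury"
  sub <- recs$subtype
  i_burn <- which(inj & sub == "BURN")
  main[i_burn] <- .burn_ncode(length(i_burn), recs$era[i_burn],
                              recs$sequela[i_burn])
  i_gas <- which(inj & sub == "GAS")
  main[i_gas] <- .gas_ncode(length(i_gas), recs$era[i_gas])
  i_oth <- which(inj & sub == "OTHER")
  main[i_oth] <- sample(c("S06", "T71", "J68", "R09"), length(i_oth), TRUE)
  i_psy <- which(recs$rec_type %in% c("psych", "psych_bg"))
  main[i_psy] <- ifelse(recs$era[i_psy] == "ICD10",
                        sample(PSYCH_CODES, length(i_psy), TRUE),
                        paste0("29", sample(0:9, length(i_psy), TRUE)))
  i_bg <- which(recs$rec_type == "background")
  main[i_bg] <- sample(BACKGROUND_CODES, length(i_bg), TRUE)

  # complications on transfer/readmission records: main diagnosis becomes a
  # complication, the injury code moves to the second N-code position
  compl <- inj & recs$pos >= 2L & recs$era == "ICD10" &
    stats::runif(nr) < cfg$complication_rate
  ncode2[compl] <- main[compl]
  main[compl] <- sample(COMPLICATION_CODES, sum(compl), TRUE)
  # occasional supplementary codes
  extra2 <- inj & !compl & stats::runif(nr) < 0.3
  ncode2[extra2] <- sample(c("J18", "N39", "L55", "T79"), sum(extra2), TRUE)
  extra3 <- inj & stats::runif(nr) < 0.1
  ncode3[extra3] <- sample(c("J96", "R57", "B95"), sum(extra3), TRUE)

  ## external-cause codes on injury records
  i_fire <- which(inj & recs$mech == "FIRE")
  ecode[i_fire] <- .fire_ecode(length(i_fire), recs$era[i_fire])
  i_bmech <- which(inj & recs$mech == "BURN")
  ecode[i_bmech] <- ifelse(recs$era[i_bmech] == "ICD10",
                           sample(sprintf("X1%d", c(0:6, 8, 9)),
                                  length(i_bmech), TRUE),
                           sample(c("E880", "E885", "E900"),
                                  length(i_bmech), TRUE))
  i_gmech <- which(inj & recs$mech == "GAS")
  ecode[i_gmech] <- ifelse(recs$era[i_gmech] == "ICD10", "X47", "E888")

  ## E-code degradation: missing, then unspecific replacement
  mult <- cfg$provider_missing_multiplier[recs$provider]
  rate_year <- pmin(pmax(rec_year, y0), y1)
  p_miss <- pmin(1, cfg$ecode_missing_rate[as.character(rate_year)] * mult)
  p_unspec <- cfg$ecode_unspecific_rate[as.character(rate_year)]
  u <- stats::runif(nr)
  had_ecode <- inj & !is.na(ecode)
  deleted <- had_ecode & u < p_miss
  replaced <- had_ecode & !deleted & u < p_miss + p_unspec & recs$era == "ICD10"
  ecode[deleted] <- NA_character_
  ecode[replaced] <- sample(c("X58", "X59"), sum(replaced), TRUE)

  ## contradicting mechanism codes on secondary records of fire episodes
  fire_uids <- eps$uid[eps$mech == "FIRE"]
  cand <- which(recs$ep_uid %in% fire_uids & inj & recs$pos >= 2L &
                  recs$era == "ICD10")
  contra <- logical(nr)
  if (length(cand)) {
    # at most one contradicting record per episode
    first_cand <- cand[!duplicated(recs$ep_uid[cand])]
    pick <- first_cand[stats::runif(length(first_cand)) < cfg$contradiction_rate]
    ecode[pick] <- sample(CONTRADICTION_POOL, length(pick), TRUE)
    contra[pick] <- TRUE
  }

  ## assemble, order, and build ground truth ------------------------------
  recs$record_id <- sprintf("R%07d", seq_len(nr))
  records <- data.frame(
    person_id = sprintf("P%06d", recs$person),
    admission_date = as.Date(recs$adm, origin = "1970-01-01"),
    discharge_date = as.Date(recs$dis, origin = "1970-01-01"),
    provider_type = recs$provider,
    specialty = recs$specialty,
    long_term_care = recs$ltc,
    era = recs$era,
    main_ncode = main,
    ncode2 = ncode2,
    ncode3 = ncode3,
    ecode = ecode,
    record_id = recs$record_id
  )
  o <- order(records$person_id, records$admission_date,
             -as.numeric(records$discharge_date), method = "radix")
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL

  ## truth episodes: merge intended episodes whose intervals fall within
  ## the 2-day chaining tolerance of each other (they are indistinguishable
  ## in the emitted records)
  oe <- order(eps$person, eps$start, method = "radix")
  te <- eps[oe, , drop = FALSE]
  runmax <- .cummax_by(te$end, te$person)
  prev_max <- c(-Inf, runmax[-nrow(te)])
  new_grp <- .group_first(te$person) | (te$start - prev_max) > 2
  te$truth_id <- cumsum(new_grp)
  mech_rank <- c(FIRE = 1L, BURN = 2L, GAS = 3L, OTHER = 4L)
  g <- te$truth_id
  first_idx <- which(.group_first(g))
  last_idx <- c(first_idx[-1L] - 1L, length(g))
  best_mech <- names(mech_rank)[vapply(seq_along(first_idx), function(k) {
    min(mech_rank[te$mech[first_idx[k]:last_idx[k]]])
  }, integer(1))]
  truth_eps <- data.frame(
    truth_id = g[first_idx],
    person_id = sprintf("P%06d", te$person[first_idx]),
    start_date = as.Date(te$start[first_idx], origin = "1970-01-01"),
    end_date = as.Date(.cummax_by(te$end, g)[last_idx], origin = "1970-01-01"),
    mechanism = best_mech,
    incident = as.logical(.any_by(te$incident, g)),
    psych_onset = as.logical(.any_by(te$psych_onset, g)),
    n_members = last_idx - first_idx + 1L
  )
  uid_to_truth <- stats::setNames(te$truth_id, te$uid)
  rec_truth <- uid_to_truth[as.character(recs$ep_uid)]
  truth_recs <- data.frame(
    record_id = recs$record_id,
    truth_episode = as.integer(rec_truth),
    record_type = recs$rec_type,
    ecode_deleted = deleted,
    ecode_unspecific = replaced,
    contradiction = contra
  )
  truth_recs <- truth_recs[match(records$record_id, truth_recs$record_id), ]
  rownames(truth_recs) <- NULL
  # record counts per truth episode
  cnt <- table(truth_recs$truth_episode)
  truth_eps$n_records <- as.integer(cnt[as.character(truth_eps$truth_id)])

  structure(list(records = records,
                 truth = list(episodes = truth_eps, records = truth_recs,
                              params = cfg),
                 config = cfg),
            class = "synthetic_register")
}

#' @export
print.synthetic_register <- function(x, ...) {
  cat(sprintf("<synthetic_register: %d records, %d true episodes, %d persons>\n",
              nrow(x$records), nrow(x$truth$episodes),
              length(unique(x$records$person_id))))
  invisible(x)
}

#' Score analysis outputs against the generator's ground truth
#'
#' @param sim a `synthetic_register`.
#' @param assigned the simulated records after [assign_episodes()].
#' @param mechanisms optional result of [classify_episodes()] on
#'   `assigned`.
#' @param clearance optional `clearance_fit` (or clearance period in
#'   years) to score against the generating changepoint `tau`.
#' @param incident optional data frame `episode_id`, `incident` with
#'   predicted incident flags.
#' @return list of class `truth_check`: `episode_recovery` (fraction of
#'   true episodes reconstructed exactly), `n_true`, `n_built`,
#'   `confusion` (mechanism table, recovered episodes only),
#'   `clearance_error` (years), `incident_sensitivity`,
#'   `incident_specificity` (NA where not evaluated).
#' @export
truth_check <- function(sim, assigned, mechanisms = NULL, clearance = NULL,
                        incident = NULL) {
  stopifnot(inherits(sim, "synthetic_register"),
            "episode_id" %in% names(assigned),
            "record_id" %in% names(assigned))
  tr <- sim$truth$records
  i <- match(assigned$record_id, tr$record_id)
  if (anyNA(i)) stop("assigned records do not match the ground truth (record_id)")
  truth_ep <- tr$truth_episode[i]
  built_ep <- assigned$episode_id
  # a true episode is recovered when its records form exactly one built
  # episode and that built episode contains nothing else
  tf <- factor(truth_ep); bf <- factor(built_ep)
  ti <- as.integer(tf); bi <- as.integer(bf)
  truth_size <- tabulate(ti, nbins = nlevels(tf))
  built_size <- tabulate(bi, nbins = nlevels(bf))
  up <- !duplicated(paste(ti, bi))
  tu <- ti[up]; bu <- bi[up]
  npairs <- tabulate(tu, nbins = nlevels(tf))
  built_of_truth <- integer(nlevels(tf))
  built_of_truth[tu] <- bu
  recovered <- npairs == 1L & truth_size == built_size[pmax(built_of_truth, 1L)]
  n_true <- nlevels(tf)
  rec_truth_ids <- as.integer(levels(tf))[recovered]
  rec_built_ids <- as.integer(levels(bf))[built_of_truth[recovered]]
  out <- list(
    episode_recovery = sum(recovered) / n_true,
    n_true = n_true,
    n_built = nlevels(bf),
    confusion = NULL,
    clearance_error = NA_real_,
    incident_sensitivity = NA_real_,
    incident_specificity = NA_real_
  )
  if (!is.null(mechanisms)) {
    true_m <- sim$truth$episodes$mechanism[match(rec_truth_ids, sim$truth$episodes$truth_id)]
    pred_m <- mechanisms$mechanism[match(rec_built_ids, mechanisms$episode_id)]
    out$confusion <- table(truth = factor(true_m, c("FIRE", "BURN", "GAS", "OTHER")),
                           predicted = factor(pred_m, c("FIRE", "BURN", "GAS", "OTHER")))
  }
  if (!is.null(clearance)) {
    cp <- if (inherits(clearance, "clearance_fit")) clearance$clearance_period else clearance
    out$clearance_error <- cp - sim$config$readmission[["tau"]]
  }
  if (!is.null(incident)) {
    j <- match(rec_built_ids, incident$episode_id)
    ok <- !is.na(j)
    truth_inc <- sim$truth$episodes$incident[match(rec_truth_ids, sim$truth$episodes$truth_id)][ok]
    pred_inc <- incident$incident[j[ok]]
    out$incident_sensitivity <- mean(pred_inc[truth_inc])
    out$incident_specificity <- mean(!pred_inc[!truth_inc])
  }
  class(out) <- "truth_check"
  out
}

#' @export
print.truth_check <- function(x, ...) {
  cat("Ground-truth check\n")
  cat(sprintf("  episode recovery: %.1f%% of %d true episodes (%d built)\n",
              100 * x$episode_recovery, x$n_true, x$n_built))
  if (!is.null(x$confusion)) {
    cat("  mechanism confusion (recovered episodes):\n")
    print(x$confusion)
  }
  if (!is.na(x$clearance_error)) {
    cat(sprintf("  clearance error vs generating changepoint: %+.2f y\n",
                x$clearance_error))
  }
  if (!is.na(x$incident_sensitivity)) {
    cat(sprintf("  incident flags: sensitivity %.2f, specificity %.2f\n",
                x$incident_sensitivity, x$incident_specificity))
  }
  invisible(x)
}

#' Write a register (and optional truth) to CSV
#'
#' @param records register data frame.
#' @param path output CSV path.
#' @export
write_register <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a register extract from CSV
#'
#' Ingest schema: `person_id`, `admission_date` (ISO-8601),
#' `discharge_date`, `provider_type`, `specialty`, `long_term_care`
#' (0/1 or TRUE/FALSE), `era` (ICD9/ICD10), `main_ncode`, `ncode2`,
#' `ncode3`, `ecode` (empty = missing). Additional `ncodeK` columns are
#' accepted. Validation errors name the offending rows.
#'
#' @param path CSV file path.
#' @return validated register data frame.
#' @export
read_register <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (nrow(raw) == 0L) stop("empty register input: ", path)
  raw$long_term_care <- raw$long_term_care %in% c("1", "TRUE", "true", "T")
  for (col in c("ncode2", "ncode3", "ecode")) {
    if (col %in% names(raw)) raw[[col]][!nzchar(raw[[col]])] <- NA_character_
  }
  validate_register(raw)
}
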