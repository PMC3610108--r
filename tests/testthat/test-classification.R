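with_ids <- function(df) assign_episodes(df)

test_that("mechanism classification applies the FIRE > BURN > GAS > OTHER precedence", {
  expect_equal(classify_mechanism(rec("2010-01-01", "2010-01-05",
                                      main = "T24", e = "X76")), "FIRE")
  expect_equal(classify_mechanism(rec("2010-01-01", "2010-01-05",
                                      main = "T24")), "BURN")
  expect_equal(classify_mechanism(rec("2010-01-01", "2010-01-05",
                                      main = "T58")), "GAS")
  expect_equal(classify_mechanism(rec("2010-01-01", "2010-01-05",
                                      main = "J18")), "OTHER")
  # burn N-code anywhere beats gas; fire E-code on any record beats both
  ep <- regs(rec("2010-01-01", "2010-01-03", main = "T58"),
             rec("2010-01-03", "2010-01-08", main = "J18", n2 = "T24"))
  expect_equal(classify_mechanism(ep), "BURN")
  ep$ecode[1] <- "X05"
  expect_equal(classify_mechanism(ep), "FIRE")
  # ICD-9 era evidence resolves through the ICD-9 sets
  expect_equal(classify_mechanism(rec("1994-01-01", "1994-01-05", era = "ICD9",
                                      main = "9402")), "BURN")
  expect_equal(classify_mechanism(rec("1994-01-01", "1994-01-05", era = "ICD9",
                                      main = "986")), "GAS")
  expect_equal(classify_mechanism(rec("1994-01-01", "1994-01-05", era = "ICD9",
                                      main = "986", e = "E890")), "FIRE")
})

test_that("classification is exhaustive, exclusive, and E-code monotone", {
  sim <- generate_register(register_config(n_persons = 150, seed = 7))
  a <- with_ids(sim$records)
  m <- classify_episodes(a)
  expect_equal(nrow(m), length(unique(a$episode_id)))
  expect_false(anyNA(m$mechanism))
  part <- mechanism_partition(a, m)
  expect_equal(part$episodes[part$category == "TOTAL"],
               sum(part$episodes[part$category != "TOTAL"]))
  # adding a fire E-code to a BURN/GAS episode reclassifies it FIRE
  target <- m$episode_id[m$mechanism %in% c("BURN", "GAS")][1]
  rows <- which(a$episode_id == target)
  b <- a
  b$ecode[rows[1]] <- "X00"
  m2 <- classify_episodes(b)
  expect_equal(as.character(m2$mechanism[m2$episode_id == target]), "FIRE")
  # removing every E-code never changes a BURN/GAS assignment (N-code driven)
  c2 <- a
  c2$ecode <- NA_character_
  m3 <- classify_episodes(c2)
  bg <- m$mechanism %in% c("BURN", "GAS")
  expect_equal(as.character(m3$mechanism[bg]), as.character(m$mechanism[bg]))
})

test_that("episode completeness distinguishes identified, unspecific-only and all-missing", {
  mixed <- with_ids(regs(
    rec("2010-01-01", "2010-01-03"),
    rec("2010-01-03", "2010-01-08", e = "X00")))
  expect_equal(as.character(episode_completeness(mixed)$completeness),
               "IDENTIFIED")
  unspec <- with_ids(regs(
    rec("2010-01-01", "2010-01-03", e = "X58"),
    rec("2010-01-03", "2010-01-08")))
  expect_equal(as.character(episode_completeness(unspec)$completeness),
               "UNSPECIFIC_ONLY")
  none <- with_ids(regs(rec("2010-01-01", "2010-01-03"),
                        rec("2010-01-03", "2010-01-08")))
  expect_equal(as.character(episode_completeness(none)$completeness),
               "ALL_MISSING")
})

test_that("the record completeness report counts and rounds per stratum", {
  df <- regs(rec("2005-02-01", "2005-02-05", main = "T24"),
             rec("2005-03-01", "2005-03-05", main = "T25", e = "X58"),
             rec("2005-04-01", "2005-04-05", main = "T31", e = "X00"))
  rep1 <- record_completeness_report(df, "BURNS", "year")
  expect_equal(rep1$n, 3L)
  expect_equal(rep1$pct_unspecific, 33.3)
  expect_equal(rep1$pct_missing, 33.3)
  # all specific
  df2 <- regs(rec("2005-02-01", "2005-02-05", main = "T58", e = "X47"),
              rec("2005-03-01", "2005-03-05", main = "T59", e = "X47"))
  rep2 <- record_completeness_report(df2, "GAS", "year")
  expect_equal(rep2$pct_unspecific, 0)
  expect_equal(rep2$pct_missing, 0)
  # non-burn main diagnoses never enter the BURNS audit
  expect_equal(nrow(record_completeness_report(
    rec("2005-02-01", "2005-02-05", main = "J18"), "BURNS", "year")), 0L)
  # provider stratification yields one row per provider present
  df3 <- regs(rec("2005-02-01", "2005-02-05", main = "T24", provider = "UNIVERSITY"),
              rec("2005-03-01", "2005-03-05", main = "T24", provider = "CENTRAL_DISTRICT"))
  rep3 <- record_completeness_report(df3, "BURNS", c("year", "provider_type"))
  expect_equal(nrow(rep3), 2L)
  expect_setequal(rep3$provider_type, c("UNIVERSITY", "CENTRAL_DISTRICT"))
})

test_that("the audit recovers the generating missingness rates within 3 binomial SEs", {
  cfg <- register_config(n_persons = 1200, seed = 99)
  sim <- generate_register(cfg)
  a <- with_ids(sim$records)
  rep <- record_completeness_report(a, "BURNS", "year")
  expect_gt(nrow(rep), 10)
  # episodes can run past the window end; those records draw the last
  # window year's rates
  win <- cfg$study_window
  for (k in seq_len(nrow(rep))) {
    y <- as.character(min(max(rep$year[k], win[1]), win[2]))
    p <- cfg$ecode_missing_rate[[y]]
    se <- sqrt(p * (1 - p) / rep$n[k])
    expect_lt(abs(rep$pct_missing[k] / 100 - p), 3 * se + 1e-9)
  }
})

test_that("contradicting mechanism codes inside fire episodes are paired", {
  ep <- with_ids(regs(
    rec("2010-01-01", "2010-01-05", main = "T24", e = "X05"),
    rec("2010-01-05", "2010-01-12", main = "T24", e = "X12")))
  out <- detect_contradictions(ep)
  expect_equal(nrow(out), 1L)
  expect_equal(out$contradict_ecode, "X12")
  ep2 <- with_ids(regs(
    rec("2010-01-01", "2010-01-05", main = "T24", e = "X05"),
    rec("2010-01-05", "2010-01-12", main = "T24", e = "W87")))
  expect_equal(detect_contradictions(ep2)$contradict_ecode, "W87")
  single <- with_ids(rec("2010-01-01", "2010-01-05", main = "T24", e = "X05"))
  expect_equal(nrow(detect_contradictions(single)), 0L)
  # a contradicting E-code in a non-fire episode is not reported
  burn_only <- with_ids(regs(
    rec("2010-01-01", "2010-01-05", main = "T24"),
    rec("2010-01-05", "2010-01-12", main = "T24", e = "X12")))
  expect_equal(nrow(detect_contradictions(burn_only)), 0L)
})

test_that("inpatient-onset detection inspects the first record of the first fire episode", {
  psych_first <- with_ids(regs(
    rec("2010-01-01", "2010-02-01", main = "F20", specialty = "PSYCHIATRY"),
    rec("2010-02-01", "2010-02-20", main = "T24", e = "X00")))
  out <- detect_inpatient_onset(psych_first)
  expect_true(out$flagged)
  expect_true(out$psych_main_dx)
  expect_true(out$psych_specialty)
  injury_first <- with_ids(regs(
    rec("2010-01-01", "2010-01-10", main = "T24", e = "X00"),
    rec("2010-01-10", "2010-01-20", main = "J18")))
  out2 <- detect_inpatient_onset(injury_first)
  expect_false(out2$flagged)
  somatic_first <- with_ids(regs(
    rec("2010-01-01", "2010-01-10", main = "J44"),
    rec("2010-01-10", "2010-01-20", main = "T24", e = "X00")))
  out3 <- detect_inpatient_onset(somatic_first)
  expect_true(out3$flagged)
  expect_false(out3$psych_main_dx)
  expect_false(out3$psych_specialty)
})

test_that("the mixed-completeness share uses the partition rounding rule", {
  two_mixed_one_not <- with_ids(regs(
    rec("2010-01-01", "2010-01-03", main = "T24", e = "X10", person = "A"),
    rec("2010-01-03", "2010-01-08", main = "T24", person = "A"),
    rec("2010-03-01", "2010-03-03", main = "T24", e = "X10", person = "B"),
    rec("2011-01-01", "2011-01-03", main = "T25", e = "X11", person = "C"),
    rec("2011-01-03", "2011-01-08", main = "T25", person = "C")))
  m <- classify_episodes(two_mixed_one_not)
  out <- mixed_ecode_share(two_mixed_one_not, m)
  expect_equal(out$n_base, 3L)
  expect_equal(out$n_mixed, 2L)
  expect_equal(out$pct, share_pct(2, 3))
})
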