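# index date, inclusion/exclusion, experience, severity, CCI, polypharmacy

cfg <- ppp_config()

dx <- function(pid, dates, code = "L40.3") {
  tibble::tibble(patient_id = pid, claim_date = as.Date(dates), icd10 = code,
                 setting = "outpatient")
}

test_that("index date is the earliest disease claim in the study window", {
  d <- dx("a", c("2013-01-01", "2012-05-01"))
  expect_equal(find_index_date(d, cfg)$index_date, as.Date("2012-05-01"))
  # same-day earliest ties are irrelevant
  d2 <- dx("a", c("2012-05-01", "2012-05-01"))
  expect_equal(find_index_date(d2, cfg)$index_date, as.Date("2012-05-01"))
  # other codes or out-of-window claims do not create an index
  expect_equal(nrow(find_index_date(dx("a", "2012-05-01", "L40.0"), cfg)), 0L)
  expect_equal(nrow(find_index_date(dx("a", "2009-05-01"), cfg)), 0L)
})

test_that("diagnosis confirmation needs two claims; same-day pair counts", {
  expect_false(confirm_diagnosis(dx("a", "2012-05-01"), cfg)$confirmed)
  expect_true(confirm_diagnosis(
    dx("a", c("2012-05-01", "2012-08-09")), cfg)$confirmed)
  same_day <- dx("a", c("2012-05-01", "2012-05-01"))
  expect_true(confirm_diagnosis(same_day, cfg)$confirmed)
  strict <- ppp_config(require_distinct_dates = TRUE)
  expect_false(confirm_diagnosis(same_day, strict)$confirmed)
})

test_that("continuous enrollment covers the pre/post window exactly", {
  per <- function(s, e) tibble::tibble(patient_id = "a",
                                       start_date = as.Date(s),
                                       end_date = as.Date(e))
  index <- as.Date("2012-06-01")
  expect_true(check_continuous_enrollment(
    per("2011-01-01", "2014-12-31"), index, 183, 183))
  # enrollment begins 100 days before index: 100 < 183
  expect_false(check_continuous_enrollment(
    per("2012-02-22", "2014-12-31"), index, 183, 183))
  # a 1-day gap inside the pre-window breaks continuity
  broken <- normalize_enrollment(dplyr::bind_rows(
    per("2011-01-01", "2012-03-01"), per("2012-03-03", "2014-12-31")))
  expect_false(check_continuous_enrollment(broken, index, 183, 183))
})

test_that("treatment experience: naive / experienced / na", {
  index <- as.Date("2012-06-01")
  rx <- function(dates, category) tibble::tibble(
    patient_id = "a", dispense_date = as.Date(dates), category = category)
  no_proc <- tibble::tibble(patient_id = character(), date = as.Date(integer()),
                            kind = character())
  expect_equal(classify_experience(
    rx("2012-07-01", "topical"), no_proc, index, cfg), "naive")
  expect_equal(classify_experience(
    rx(c("2012-05-02", "2012-07-01"), "systemic_nonbio"), no_proc, index, cfg),
    "experienced")
  expect_equal(classify_experience(
    rx(character(0), character(0)), no_proc, index, cfg), "na")
  # background (other-category) drugs never count as treatment
  expect_equal(classify_experience(
    rx("2012-05-02", "other"), no_proc, index, cfg), "na")
  # phototherapy in the wash-out window counts as treatment
  ph <- tibble::tibble(patient_id = "a", date = as.Date("2012-05-15"),
                       kind = "phototherapy")
  expect_equal(classify_experience(
    rx(character(0), character(0)), ph, index, cfg), "experienced")
})

test_that("severity proxy: topical-only (or nothing) is mild", {
  expect_equal(classify_severity("topical"), "mild")
  expect_equal(classify_severity(character(0)), "mild")
  expect_equal(classify_severity(c("topical", "phototherapy")),
               "moderate_severe")
  expect_equal(classify_severity("systemic_nonbio"), "moderate_severe")
})

test_that("Charlson index: group weights counted once, dots ignored", {
  expect_equal(charlson_index(character(0)), 0)
  expect_equal(charlson_index("M05.9"), 1)          # rheumatologic
  expect_equal(charlson_index(c("M05.9", "M06.0")), 1) # same group, once
  expect_equal(charlson_index(c("M05.9", "I21.0")), 2) # two groups
  expect_equal(charlson_index(c("C77.0", "C18.9")), 8) # metastatic 6 + ca 2
  expect_equal(charlson_index("Z99.9"), 0)
})

test_that("polypharmacy counts distinct ATC prefixes at a level", {
  expect_equal(polypharmacy(character(0), 3), 0L)
  expect_equal(polypharmacy(c("A01AB", "A01BC"), 3), 2L)
  expect_equal(polypharmacy(c("A01AB", "A01BC"), 1), 1L)
  expect_equal(polypharmacy(rep("A01AB", 5), 3), 1L) # duplicate fills
  expect_error(polypharmacy("A01AB", 2))
})

test_that("attrition is monotone, one precedence-ordered reason each", {
  cfgq <- ppp_config()
  d <- synth_claims(120, cfgq, seed = 31)
  d <- plant_exclusions(d, c(single_diagnosis = 0.15, under_18 = 0.05,
                             pre_enrollment = 0.1, post_enrollment = 0.05),
                        seed = 32)
  res <- build_cohort(d$enrollment, d$diagnosis, d$prescription,
                      d$procedure, cfgq)
  a <- res$attrition
  expect_true(all(diff(a$n_remaining) <= 0))
  expect_equal(a$n_remaining[5], sum(res$cohort$eligible))
  # one reason per excluded patient
  exc <- res$cohort[!res$cohort$eligible, ]
  expect_true(all(!is.na(exc$exclusion_reason)))
  expect_true(all(is.na(res$cohort$exclusion_reason[res$cohort$eligible])))
  # a patient failing several criteria gets the earliest reason: plant a
  # patient who is both unconfirmed and under-age
  enr <- tibble::tibble(patient_id = "x",
                        start_date = as.Date("2012-01-01"),
                        end_date = as.Date("2016-01-01"),
                        birth_date = as.Date("2000-06-01"), sex = "male")
  res2 <- build_cohort(enr, dx("x", "2013-01-01"),
                       tibble::tibble(patient_id = character(),
                                      claim_record_date = as.Date(integer()),
                                      drug_code = character()),
                       tibble::tibble(patient_id = character(),
                                      date = as.Date(integer()),
                                      kind = character(),
                                      cost_yen = numeric()), cfgq)
  expect_equal(res2$cohort$exclusion_reason, "single_diagnosis")
})

test_that("severity partitions the eligible set; na patients are mild", {
  d <- synth_claims(150, cfg, seed = 33)
  res <- build_cohort(d$enrollment, d$diagnosis, d$prescription,
                      d$procedure, cfg)
  co <- res$cohort
  elig <- co[co$eligible, ]
  expect_true(all(elig$severity %in% c("mild", "moderate_severe")))
  expect_true(all(is.na(co$severity[!co$eligible])))
  expect_true(all(elig$severity[elig$treatment_experience == "na"] == "mild"))
})
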