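# readers/writers, schema validation, enrollment normalization

make_prescriptions <- function() {
  tibble::tibble(
    patient_id = c("a", "a", "b"),
    dispense_date = as.Date(c("2012-01-01", NA, "2012-02-01")),
    claim_record_date = as.Date(c("2012-01-03", "2012-01-20", "2012-02-01")),
    drug_code = c("calcipotriol", "ciclosporin", "methotrexate"),
    ddd_days = c(NA, 30, 14),
    cost_yen = c(1200, 5400, 3300)
  )
}

test_that("claims round-trip through CSV unchanged", {
  for (kind in c("enrollment", "diagnosis", "prescription", "procedure")) {
    df <- switch(kind,
      enrollment = tibble::tibble(
        patient_id = "a", start_date = as.Date("2011-02-03"),
        end_date = as.Date("2014-10-09"),
        birth_date = as.Date("1970-05-05"), sex = "female"),
      diagnosis = tibble::tibble(
        patient_id = c("a", "a"),
        claim_date = as.Date(c("2012-01-01", "2012-03-05")),
        icd10 = c("L40.3", "M05.9"), setting = c("outpatient", "inpatient")),
      prescription = make_prescriptions(),
      procedure = tibble::tibble(
        patient_id = "a", date = as.Date("2012-04-01"),
        kind = "phototherapy", cost_yen = 6000))
    path <- withr::local_tempfile(fileext = ".csv")
    write_claims(df, path)
    back <- read_claims(path, kind)
    expect_equal(nrow(back$rejects), 0L)
    expect_equal(as.data.frame(back$records)[names(df)], as.data.frame(df),
                 ignore_attr = TRUE)
  }
})

test_that("empty file with header yields empty collection, zero rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,claim_date,icd10,setting", path)
  out <- read_claims(path, "diagnosis")
  expect_equal(nrow(out$records), 0L)
  expect_equal(nrow(out$rejects), 0L)
})

test_that("missing mandatory column is a schema error naming it", {
  df <- data.frame(patient_id = "a", icd10 = "L40.3")
  expect_error(validate_claims(df, "diagnosis"), "claim_date")
})

test_that("malformed rows are collected as rejects, not dropped silently", {
  df <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    date = c("2012-01-01", "not-a-date", "2012-02-01", "2012-03-01"),
    kind = c("xray", "xray", "mri", "mri"),
    cost_yen = c("100", "100", "-5", "250")
  )
  out <- validate_claims(df, "procedure")
  expect_equal(nrow(out$records), 2L)
  expect_setequal(out$rejects$reason,
                  c("unparseable date in date", "negative cost"))
  # prescriptions: both dates missing is a reject; one date present is fine
  rx <- data.frame(patient_id = c("a", "b"),
                   dispense_date = c("", "2012-01-05"),
                   claim_record_date = c("", ""),
                   drug_code = c("x", "y"))
  out2 <- validate_claims(rx, "prescription")
  expect_equal(out2$rejects$reason, "no dispense or claim record date")
  expect_equal(out2$records$patient_id, "b")
})

test_that("missing dispense date is imputed from the claim record date", {
  rx <- impute_dispense_date(make_prescriptions())
  expect_equal(rx$dispense_date[2], rx$claim_record_date[2])
  expect_equal(rx$dispense_date[1], as.Date("2012-01-01")) # untouched
})

test_that("categorization joins the drug map and derives ATC levels", {
  cfg <- ppp_config()
  rx <- categorize_prescriptions(
    tibble::tibble(patient_id = "a", drug_code = c("ciclosporin", "zzz")),
    cfg)
  expect_equal(rx$category, c("systemic_nonbio", "other"))
  expect_equal(rx$atc_level3[1], "L04A")
  expect_equal(rx$atc_level1[1], "L")
  expect_false(any(rx$steroid))
})

test_that("same-day duplicates of one drug are deduplicated and logged", {
  rx <- impute_dispense_date(make_prescriptions())
  rx2 <- dplyr::bind_rows(rx, rx[1, ])
  dd <- dedupe_prescriptions(rx2)
  expect_equal(nrow(dd$records), 3L)
  expect_equal(nrow(dd$duplicates), 1L)
})

test_that("enrollment normalization merges overlaps and adjacency", {
  p <- tibble::tibble(
    patient_id = "a",
    start_date = as.Date(c("2012-01-01", "2012-02-01")),
    end_date = as.Date(c("2012-03-31", "2012-04-30")))
  out <- normalize_enrollment(p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start_date, as.Date("2012-01-01"))
  expect_equal(out$end_date, as.Date("2012-04-30"))

  adj <- tibble::tibble(
    patient_id = "a",
    start_date = as.Date(c("2012-01-01", "2012-04-01")),
    end_date = as.Date(c("2012-03-31", "2012-06-30")))
  expect_equal(nrow(normalize_enrollment(adj)), 1L)

  single <- tibble::tibble(patient_id = "a",
                           start_date = as.Date("2012-01-01"),
                           end_date = as.Date("2012-03-31"))
  expect_equal(as.data.frame(normalize_enrollment(single)),
               as.data.frame(single))
})

test_that("normalization equals the brute-force day-set union", {
  set.seed(42)
  origin <- as.Date("2012-01-01")
  for (rep in 1:60) {
    k <- sample(1:10, 1)
    s <- sample(0:400, k, replace = TRUE)
    e <- s + sample(0:80, k, replace = TRUE)
    p <- tibble::tibble(patient_id = "a", start_date = origin + s,
                        end_date = origin + e)
    out <- normalize_enrollment(p)
    got <- oracle_covered_days(as.integer(out$start_date),
                               as.integer(out$end_date))
    want <- oracle_covered_days(as.integer(p$start_date),
                                as.integer(p$end_date))
    expect_identical(got, want)
    # disjoint with gaps > 1 day
    if (nrow(out) > 1) {
      expect_true(all(diff(as.integer(out$start_date)) > 0))
      expect_true(all(as.integer(out$start_date[-1]) -
                        as.integer(out$end_date[-nrow(out)]) > 1))
    }
  }
})

test_that("config round-trips through YAML and rejects bad values", {
  cfg <- ppp_config(grace_period_days = 45L, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$grace_period_days, 45L)
  expect_equal(back$study_start, cfg$study_start)
  expect_equal(as.data.frame(back$category_map),
               as.data.frame(cfg$category_map))
  expect_error(ppp_config(grace_period_days = -1), "grace_period_days")
  expect_error(ppp_config(study_start = "2018-01-01",
                          study_end = "2017-01-01"), "study_start")
})

test_that("every category maps to one line class or is excluded", {
  cm <- default_category_map()
  cls <- line_class_of(cm$category)
  expect_true(all(is.na(cls) | cls %in% LINE_CLASSES))
  expect_true(all(is.na(line_class_of("other"))))
  expect_equal(line_class_of(c("retinoid", "steroid_systemic", "antibiotic")),
               rep("systemic_nonbio", 3))
})
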