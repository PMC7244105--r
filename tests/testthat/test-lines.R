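# exposure expansion, grace merging, overlap arbitration, segmentation,
# event labelling -- the core reconstruction algorithm

cfg <- ppp_config()

ep <- function(class, start, end, steroid = FALSE) {
  data.frame(class = class, start = start, end = end, steroid = steroid)
}

test_that("claims expand to the assumed exposure windows", {
  cohort <- tibble::tibble(patient_id = "a",
                           index_date = as.Date("2012-01-01"),
                           follow_up_end = as.Date("2013-01-01"))
  rx <- tibble::tibble(
    patient_id = "a",
    dispense_date = as.Date(c("2012-01-01", "2012-02-01", "2012-03-01")),
    claim_record_date = as.Date(NA),
    drug_code = c("calcipotriol", "ciclosporin", "methotrexate"),
    category = c("topical", "systemic_nonbio", "systemic_nonbio"),
    route = "oral", steroid = FALSE,
    ddd_days = c(NA, 30, NA))
  proc <- tibble::tibble(patient_id = "a", date = as.Date("2012-04-01"),
                         kind = "phototherapy", cost_yen = 0)
  out <- expand_episodes(rx, proc, cohort, cfg)
  out <- out[order(out$start), ]
  expect_equal(as.integer(out$end - out$start), c(14L, 30L, 30L, 28L))
  expect_equal(out$class,
               c("topical", "systemic_nonbio", "systemic_nonbio",
                 "phototherapy"))
  # claims before index or after follow-up end are dropped; ends clipped
  rx2 <- rx
  rx2$dispense_date <- as.Date(c("2011-12-20", "2012-12-25", "2013-02-01"))
  out2 <- expand_episodes(rx2, proc[0, ], cohort, cfg)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$end, as.Date("2013-01-01")) # clipped at follow-up end
})

test_that("within-class merging bridges gaps up to the grace period", {
  m <- merge_within_class(ep("topical", c(0, 20), c(14, 34)), 61)
  expect_equal(m$start, 0); expect_equal(m$end, 34)
  m2 <- merge_within_class(ep("topical", c(0, 90), c(14, 104)), 61)
  expect_equal(nrow(m2), 2L) # gap 76 > 61
  m3 <- merge_within_class(ep("topical", 0, 14), 61)
  expect_equal(m3$end, 14)
  # exact-grace gap merges; one day more does not
  expect_equal(nrow(merge_within_class(ep("topical", c(0, 75), c(14, 80)),
                                       61)), 1L)
  expect_equal(nrow(merge_within_class(ep("topical", c(0, 76), c(14, 80)),
                                       61)), 2L)
  # steroid flag propagates through a merge
  m4 <- merge_within_class(ep("topical", c(0, 20), c(14, 34),
                              steroid = c(FALSE, TRUE)), 61)
  expect_true(m4$steroid)
})

test_that("first-line topical therapy stops when systemic therapy starts", {
  adj <- arbitrate_overlaps(ep(c("topical", "systemic_nonbio"),
                               c(0, 20), c(60, 100)), cfg)
  expect_equal(adj$end[adj$class == "topical"], 20)
  # corticosteroid-flagged topical is exempt (tapering)
  adj2 <- arbitrate_overlaps(ep(c("topical", "systemic_nonbio"),
                                c(0, 20), c(60, 100),
                                steroid = c(TRUE, FALSE)), cfg)
  expect_equal(adj2$end[adj2$class == "topical"], 60)
  # topical not strictly first: no truncation
  adj3 <- arbitrate_overlaps(ep(c("topical", "systemic_nonbio"),
                                c(0, 0), c(60, 100)), cfg)
  expect_equal(adj3$end[adj3$class == "topical"], 60)
})

test_that("phototherapy/systemic overlap: combination vs truncation", {
  # full overlap (28 > 14): both kept -> one combination line
  adj <- arbitrate_overlaps(ep(c("phototherapy", "systemic_nonbio"),
                               c(0, 0), c(28, 28)), cfg)
  expect_equal(adj$end, c(28, 28))
  ln <- reconstruct_lines(ep(c("phototherapy", "systemic_nonbio"),
                             c(0, 0), c(28, 28)), 50, cfg)
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$regimen, "phototherapy+systemic_nonbio")
  expect_true(ln$combination)
  # short overlap (10 <= 14): earlier exposure truncated at later start
  adj2 <- arbitrate_overlaps(ep(c("phototherapy", "systemic_nonbio"),
                                c(0, 18), c(28, 60)), cfg)
  expect_equal(adj2$end[adj2$class == "phototherapy"], 18)
})

test_that("segmentation: change-points in the active class set", {
  s1 <- segment_lines(ep("topical", 0, 34))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$regimen, "topical")
  s2 <- segment_lines(ep(c("topical", "systemic_nonbio"), c(0, 20),
                         c(20, 100)))
  expect_equal(s2$regimen, c("topical", "systemic_nonbio"))
  expect_equal(s2$start, c(0, 20))
  # concurrent start: one line with the union regimen
  s3 <- segment_lines(ep(c("topical", "systemic_nonbio"), c(0, 0),
                         c(100, 100)))
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$regimen, "topical+systemic_nonbio")
})

test_that("event labels follow gap and regimen-relation rules", {
  lines <- segment_lines(ep(c("topical", "systemic_nonbio"), c(0, 60),
                            c(50, 150)))
  lab <- label_events(lines, 365, 61)
  expect_equal(lab$event, c("switch", "discontinuation")) # gaps 10, 215
  # nothing after a line until follow-up end day 365: discontinuation
  lab2 <- label_events(segment_lines(ep("topical", 0, 50)), 365, 61)
  expect_equal(lab2$event, "discontinuation")
  # line running to (or within grace of) follow-up end: no change
  lab3 <- label_events(segment_lines(ep("topical", 0, 50)), 100, 61)
  expect_equal(lab3$event, "no_change")
  # add-on and reduction from strict regimen nesting
  nest <- segment_lines(ep(c("systemic_nonbio", "topical"), c(0, 30),
                           c(100, 70)))
  expect_equal(nest$regimen,
               c("systemic_nonbio", "topical+systemic_nonbio",
                 "systemic_nonbio"))
  labn <- label_events(nest, 120, 61)
  expect_equal(labn$event, c("add_on", "reduction", "no_change"))
})

test_that("antibiotics count only beyond the one-month cumulative rule", {
  # one 14-day course: excluded entirely
  short <- reconstruct_lines(ep("antibiotic", 0, 14), 300, cfg)
  expect_equal(nrow(short), 0L)
  # two courses 14 + 20 = 34 days merged across a small gap: included
  long <- reconstruct_lines(ep("antibiotic", c(0, 20), c(14, 40)), 300, cfg)
  expect_equal(long$regimen, "systemic_nonbio")
  expect_equal(c(long$start, long$end), c(0, 40))
  # merged-span days (including bridged gap) count toward the threshold
  bridged <- reconstruct_lines(ep("antibiotic", c(0, 20), c(14, 34)), 300, cfg)
  expect_equal(nrow(bridged), 1L) # span 34 >= 31 though only 28 dosed days
})

test_that("reconstruction is invariant to input row order", {
  set.seed(7)
  for (k in 1:20) {
    rp <- random_patient_episodes(cfg)
    a <- reconstruct_lines(rp$episodes, rp$fu_end, cfg)
    shuffled <- rp$episodes[sample(nrow(rp$episodes)), , drop = FALSE]
    b <- reconstruct_lines(shuffled, rp$fu_end, cfg)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("reconstruction matches the day-occupancy brute force", {
  set.seed(99)
  for (k in 1:150) {
    rp <- random_patient_episodes(cfg)
    got <- reconstruct_lines(rp$episodes, rp$fu_end, cfg)
    want <- oracle_lines(rp$episodes, rp$fu_end, cfg)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$regimen, want$regimen)
    expect_equal(got$event, want$event)
  }
})

test_that("duration statistics summarise cells and partition events", {
  lines <- tibble::tibble(
    patient_id = c("a", "b", "c", "a"),
    line_number = c(1L, 1L, 1L, 2L),
    head_class = c("topical", "topical", "topical", "systemic_nonbio"),
    duration_days = c(10, 20, 30, 53),
    event = c("switch", "switch", "discontinuation", "no_change"))
  st <- line_duration_stats(lines)
  top <- st[st$line_number == 1 & st$head_class == "topical", ]
  expect_equal(top$mean_days, 20)
  expect_equal(top$median_days, 20)
  expect_equal(top$n_switch, 2L)
  pct <- as.numeric(top[paste0("pct_", EVENT_TYPES)])
  expect_equal(sum(pct), 100)
  sys <- st[st$head_class == "systemic_nonbio", ]
  expect_equal(sys$median_days, 53)
  # empty cells are absent, not zero
  expect_false(any(st$head_class == "biologic"))
})
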