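## line-of-therapy reconstruction --------------------------------------------
##
## All interval arithmetic is half-open on integer days: an exposure
## [start, end) excludes `end`; a duration is end - start.

#' Expand claims into treatment-exposure episodes
#'
#' Each categorized prescription or phototherapy procedure becomes one
#' exposure episode: topical fills cover a fixed 14-day window, phototherapy
#' sessions a fixed 28-day window, and systemic/biologic fills the days
#' supplied (`ddd_days`, falling back to `systemic_default_days`). Claims
#' outside the patient's follow-up are dropped; episodes extending past the
#' follow-up end are clipped there. Antibiotic claims keep the provisional
#' class `"antibiotic"` until the cumulative more-than-one-month rule is
#' applied in [reconstruct_lines()]. Category `other` is skipped.
#'
#' @param prescriptions categorized prescription tibble (see
#'   [categorize_prescriptions()]) with imputed dispense dates.
#' @param procedures procedure tibble (only `phototherapy` rows generate
#'   episodes).
#' @param cohort cohort tibble with `patient_id`, `index_date`,
#'   `follow_up_end` (half-open) for the patients of interest.
#' @param config a [ppp_config()].
#' @return tibble with `patient_id`, `class`, `start`, `end` (Dates,
#'   half-open) and `steroid`.
#' @export
expand_episodes <- function(prescriptions, procedures, cohort, config) {
  fu <- cohort[, c("patient_id", "index_date", "follow_up_end")]

  px <- prescriptions[prescriptions$category != "other" &
                        prescriptions$category != "phototherapy", , drop = FALSE]
  px <- dedupe_prescriptions(px)$records
  px <- dplyr::inner_join(px, fu, by = "patient_id")
  cls <- ifelse(px$category == "antibiotic", "antibiotic",
                line_class_of(px$category))
  if (!"ddd_days" %in% names(px)) px$ddd_days <- NA_real_
  dur <- ifelse(cls == "topical", config$topical_duration_days,
                ifelse(is.na(px$ddd_days), config$systemic_default_days,
                       px$ddd_days))
  ep1 <- tibble::tibble(
    patient_id = px$patient_id,
    class = cls,
    start = as.integer(px$dispense_date),
    end = as.integer(px$dispense_date) + as.integer(round(dur)),
    steroid = px$steroid,
    index = as.integer(px$index_date),
    fu_end = as.integer(px$follow_up_end)
  )

  pr <- procedures[procedures$kind == "phototherapy", , drop = FALSE]
  if (nrow(pr) > 0) {
    key <- paste(pr$patient_id, pr$date)
    pr <- pr[!duplicated(key), , drop = FALSE]
    pr <- dplyr::inner_join(pr, fu, by = "patient_id")
    ep2 <- tibble::tibble(
      patient_id = pr$patient_id,
      class = "phototherapy",
      start = as.integer(pr$date),
      end = as.integer(pr$date) + config$phototherapy_duration_days,
      steroid = FALSE,
      index = as.integer(pr$index_date),
      fu_end = as.integer(pr$follow_up_end)
    )
    ep1 <- dplyr::bind_rows(ep1, ep2)
  }

  keep <- !is.na(ep1$start) & ep1$start >= ep1$index & ep1$start < ep1$fu_end
  ep <- ep1[keep, , drop = FALSE]
  ep$end <- pmin(ep$end, ep$fu_end)
  ep <- ep[ep$end > ep$start, , drop = FALSE]
  tibble::tibble(
    patient_id = ep$patient_id,
    class = ep$class,
    start = as.Date(ep$start, origin = "1970-01-01"),
    end = as.Date(ep$end, origin = "1970-01-01"),
    steroid = ep$steroid
  )
}

# merge sorted half-open intervals of one class, bridging gaps <= grace.
# x: data.frame with start, end (integers), steroid. Returns same shape.
merge_intervals <- function(start, end, steroid, grace) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]; steroid <- steroid[o]
  ms <- start[1L]; me <- end[1L]; st <- steroid[1L]
  out_s <- integer(); out_e <- integer(); out_st <- logical()
  n <- length(start)
  if (n > 1L) {
    for (i in 2L:n) {
      if (start[i] - me <= grace) {
        me <- max(me, end[i]); st <- st || steroid[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me); out_st <- c(out_st, st)
        ms <- start[i]; me <- end[i]; st <- steroid[i]
      }
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me), steroid = c(out_st, st))
}

#' Merge exposure episodes of one class across renewal gaps
#'
#' Two consecutive episodes of the same class merge when the gap between
#' them (next start minus previous end) does not exceed the grace period
#' (maximum allowed gap duration); the merged span covers the gap days.
#' The corticosteroid flag propagates if any merged episode carried it.
#'
#' @param episodes tibble with `class`, `start`, `end` (Date or integer
#'   days), `steroid`, for a single patient.
#' @param grace_days the grace period in days.
#' @return tibble of disjoint merged episodes, sorted by start.
#' @export
merge_within_class <- function(episodes, grace_days) {
  dates <- inherits(episodes$start, "Date")
  s <- as.integer(episodes$start); e <- as.integer(episodes$end)
  pieces <- lapply(split(seq_len(nrow(episodes)), episodes$class), function(i) {
    m <- merge_intervals(s[i], e[i], episodes$steroid[i], grace_days)
    tibble::tibble(class = episodes$class[i][1L], start = m$start,
                   end = m$end, steroid = m$steroid)
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$start, out$class), , drop = FALSE]
  if (dates) {
    out$start <- as.Date(out$start, origin = "1970-01-01")
    out$end <- as.Date(out$end, origin = "1970-01-01")
  }
  out
}

# Overlap arbitration on merged per-class episodes (integer days).
# (a) first-line topical truncation: when topical therapy strictly precedes
#     any other class, the initial topical exposure is cut at the start of the
#     first phototherapy or oral-systemic exposure (corticosteroid-flagged
#     topical exempt: tapering).
# (b) phototherapy/systemic overlap: > combination_overlap_days both are kept
#     (combination therapy); a shorter overlap truncates the earlier exposure
#     at the later one's start; equal starts keep both (union regimen).
arbitrate_overlaps_int <- function(ep, config) {
  if (nrow(ep) == 0L) return(ep)
  # (a)
  topi <- which(ep$class == "topical")
  if (length(topi) > 0L) {
    first_top <- topi[which.min(ep$start[topi])]
    others <- setdiff(seq_len(nrow(ep)), topi)
    strictly_first <- length(others) == 0L ||
      min(ep$start[others]) > ep$start[first_top]
    trig <- which(ep$class %in% c("phototherapy", "systemic_nonbio"))
    if (strictly_first && length(trig) > 0L && !ep$steroid[first_top]) {
      t0 <- min(ep$start[trig])
      if (t0 > ep$start[first_top] && t0 < ep$end[first_top]) {
        ep$end[first_top] <- t0
      }
    }
  }
  # (b)
  ps <- which(ep$class %in% c("phototherapy", "systemic_nonbio"))
  if (length(ps) > 1L) {
    ps <- ps[order(ep$start[ps], ep$class[ps])]
    for (a in seq_len(length(ps) - 1L)) {
      for (b in (a + 1L):length(ps)) {
        i <- ps[a]; j <- ps[b]
        if (ep$class[i] == ep$class[j]) next
        ov <- min(ep$end[i], ep$end[j]) - max(ep$start[i], ep$start[j])
        if (ov <= 0L) next
        if (ep$start[i] < ep$start[j] && ov <= config$combination_overlap_days) {
          ep$end[i] <- ep$start[j]
        }
      }
    }
  }
  ep
}

#' Arbitrate overlaps between merged exposure episodes of different classes
#'
#' Applies the overlap rules: overlap among topical drugs is never
#' concomitant therapy (they already share one class); topical therapy given
#' strictly first is stopped when phototherapy or an oral systemic drug is
#' initiated, except corticosteroid-flagged exposures (dose tapering); a
#' phototherapy/systemic overlap longer than the combination threshold keeps
#' both exposures (combination therapy) while a shorter one truncates the
#' earlier exposure at the later one's start.
#'
#' @param episodes merged per-class episodes of one patient
#'   ([merge_within_class()]).
#' @param config a [ppp_config()].
#' @return tibble of adjusted episodes.
#' @export
arbitrate_overlaps <- function(episodes, config) {
  dates <- inherits(episodes$start, "Date")
  ep <- episodes
  ep$start <- as.integer(ep$start); ep$end <- as.integer(ep$end)
  ep <- arbitrate_overlaps_int(ep, config)
  if (dates) {
    ep$start <- as.Date(ep$start, origin = "1970-01-01")
    ep$end <- as.Date(ep$end, origin = "1970-01-01")
  }
  ep
}

# Segment adjusted episodes (integer days) into maximal intervals of constant
# nonempty concurrently-active class set.
segment_lines_int <- function(ep) {
  if (nrow(ep) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      regimen = character(), stringsAsFactors = FALSE))
  }
  bounds <- sort(unique(c(ep$start, ep$end)))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  segs$regimen <- vapply(seq_len(nrow(segs)), function(k) {
    act <- ep$class[ep$start <= segs$start[k] & ep$end > segs$start[k]]
    regimen_string(unique(act))
  }, character(1L))
  segs <- segs[nzchar(segs$regimen), , drop = FALSE]
  if (nrow(segs) <= 1L) {
    rownames(segs) <- NULL
    return(segs)
  }
  # coalesce contiguous segments with identical regimens
  keep_s <- segs$start[1L]; keep_e <- segs$end[1L]; keep_r <- segs$regimen[1L]
  out <- segs[0L, ]
  for (k in 2L:nrow(segs)) {
    if (segs$start[k] == keep_e && segs$regimen[k] == keep_r) {
      keep_e <- segs$end[k]
    } else {
      out <- rbind(out, data.frame(start = keep_s, end = keep_e,
                                   regimen = keep_r))
      keep_s <- segs$start[k]; keep_e <- segs$end[k]; keep_r <- segs$regimen[k]
    }
  }
  out <- rbind(out, data.frame(start = keep_s, end = keep_e, regimen = keep_r))
  rownames(out) <- NULL
  out
}

#' Segment adjusted episodes into numbered treatment lines
#'
#' A treatment line is a maximal interval over which the set of concurrently
#' active line-level classes is constant and nonempty; a new line begins at
#' each change-point of that set. Ties (two classes starting the same day)
#' start one line with the union regimen.
#'
#' @param episodes adjusted episodes of one patient
#'   ([arbitrate_overlaps()]).
#' @return tibble with `line_number`, `start`, `end`, `regimen` (a
#'   `+`-joined string in canonical class order), `duration_days`.
#' @export
segment_lines <- function(episodes) {
  dates <- inherits(episodes$start, "Date")
  ep <- episodes
  ep$start <- as.integer(ep$start); ep$end <- as.integer(ep$end)
  segs <- segment_lines_int(ep)
  out <- tibble::tibble(
    line_number = seq_len(nrow(segs)),
    start = segs$start, end = segs$end,
    regimen = segs$regimen,
    duration_days = segs$end - segs$start
  )
  if (dates) {
    out$start <- as.Date(out$start, origin = "1970-01-01")
    out$end <- as.Date(out$end, origin = "1970-01-01")
  }
  out
}

# relation of successor regimen to current regimen
regimen_relation <- function(cur, nxt) {
  a <- strsplit(cur, "+", fixed = TRUE)[[1L]]
  b <- strsplit(nxt, "+", fixed = TRUE)[[1L]]
  if (all(a %in% b) && length(b) > length(a)) return("add_on")
  if (all(b %in% a) && length(a) > length(b)) return("reduction")
  "switch"
}

#' Label each treatment line's terminating event
#'
#' A line is *discontinued* when no successor activity starts within the
#' grace period after its end while follow-up continues beyond end + grace;
#' a successor within grace is an *add-on* (regimen strictly grows), a
#' *reduction* (strictly shrinks) or a *switch* (at least one class
#' replaced; replacement dominates mixed changes). A line still active at
#' the end of follow-up, or whose grace window is cut short by censoring,
#' is *no change*.
#'
#' @param lines tibble from [segment_lines()] (one patient, ordered).
#' @param follow_up_end half-open end of follow-up (Date or integer day).
#' @param grace_days the grace period in days.
#' @return `lines` with an `event` column.
#' @export
label_events <- function(lines, follow_up_end, grace_days) {
  n <- nrow(lines)
  fu <- as.integer(follow_up_end)
  ev <- character(n)
  s <- as.integer(lines$start); e <- as.integer(lines$end)
  for (i in seq_len(n)) {
    if (i < n) {
      gap <- s[i + 1L] - e[i]
      ev[i] <- if (gap > grace_days) "discontinuation" else
        regimen_relation(lines$regimen[i], lines$regimen[i + 1L])
    } else {
      ev[i] <- if (fu - e[i] > grace_days) "discontinuation" else "no_change"
    }
  }
  lines$event <- ev
  lines
}

# full per-patient pipeline on integer-day episodes (raw, incl. "antibiotic")
reconstruct_lines_int <- function(ep, fu_end, config) {
  # antibiotic cumulative rule: grace-merge antibiotic exposures; they count
  # as systemic therapy only when the summed merged spans reach the
  # more-than-one-month threshold, otherwise they are excluded entirely.
  abx <- ep$class == "antibiotic"
  if (any(abx)) {
    m <- merge_intervals(ep$start[abx], ep$end[abx], ep$steroid[abx],
                         config$grace_period_days)
    ep <- ep[!abx, , drop = FALSE]
    if (sum(m$end - m$start) >= config$antibiotic_min_days) {
      ep <- rbind(ep, data.frame(class = "systemic_nonbio", start = m$start,
                                 end = m$end, steroid = m$steroid))
    }
  }
  if (nrow(ep) == 0L) {
    return(data.frame(line_number = integer(), start = integer(),
                      end = integer(), regimen = character(),
                      duration_days = integer(), event = character()))
  }
  merged <- merge_within_class(ep, config$grace_period_days)
  merged <- as.data.frame(merged)
  adj <- arbitrate_overlaps_int(merged, config)
  segs <- segment_lines_int(adj)
  lines <- data.frame(
    line_number = seq_len(nrow(segs)), start = segs$start, end = segs$end,
    regimen = segs$regimen, duration_days = segs$end - segs$start
  )
  label_events(lines, fu_end, config$grace_period_days)
}

#' Reconstruct a patient's treatment lines from raw exposure episodes
#'
#' Runs the whole per-patient algorithm: antibiotic cumulative rule,
#' within-class grace merging, overlap arbitration, change-point
#' segmentation and event labelling. Input row order is irrelevant.
#'
#' @param episodes tibble of raw (unmerged) episodes with `class` (a line
#'   class or `"antibiotic"`), `start`, `end` (Date or integer, half-open)
#'   and `steroid`.
#' @param follow_up_end half-open end of follow-up.
#' @param config a [ppp_config()].
#' @return tibble of numbered lines with `regimen`, `duration_days`,
#'   `event`, `combination` (phototherapy and systemic therapy concurrent),
#'   `with_topical`.
#' @export
reconstruct_lines <- function(episodes, follow_up_end, config) {
  dates <- inherits(episodes$start, "Date")
  ep <- data.frame(class = episodes$class,
                   start = as.integer(episodes$start),
                   end = as.integer(episodes$end),
                   steroid = episodes$steroid)
  res <- reconstruct_lines_int(ep, as.integer(follow_up_end), config)
  out <- tibble::as_tibble(res)
  out$combination <- grepl("phototherapy", out$regimen, fixed = TRUE) &
    grepl("systemic_nonbio", out$regimen, fixed = TRUE)
  out$with_topical <- grepl("topical", out$regimen, fixed = TRUE)
  if (dates && nrow(out) > 0) {
    out$start <- as.Date(out$start, origin = "1970-01-01")
    out$end <- as.Date(out$end, origin = "1970-01-01")
  } else if (dates) {
    out$start <- as.Date(integer(), origin = "1970-01-01")
    out$end <- as.Date(integer(), origin = "1970-01-01")
  }
  out
}

#' Build treatment lines for every eligible patient in a cohort
#'
#' @param cohort cohort tibble from [build_cohort()] (only eligible patients
#'   are processed).
#' @param prescriptions,procedures claims tibbles (prescriptions will be
#'   categorized and dispense-imputed if needed).
#' @param config a [ppp_config()].
#' @return tibble of lines with `patient_id`, `line_number`, `start`, `end`,
#'   `regimen`, `head_class`, `duration_days`, `event`, `combination`,
#'   `with_topical`.
#' @export
build_treatment_lines <- function(cohort, prescriptions, procedures, config) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  prescriptions <- impute_dispense_date(
    categorize_prescriptions(prescriptions, config))
  ep <- expand_episodes(prescriptions, procedures, elig, config)
  fu <- stats::setNames(as.integer(elig$follow_up_end), elig$patient_id)
  ep_int <- data.frame(patient_id = ep$patient_id, class = ep$class,
                       start = as.integer(ep$start), end = as.integer(ep$end),
                       steroid = ep$steroid)
  pieces <- lapply(split(ep_int, ep_int$patient_id), function(p) {
    res <- reconstruct_lines_int(p[, -1L], fu[[p$patient_id[1L]]], config)
    if (nrow(res) == 0L) return(NULL)
    res$patient_id <- p$patient_id[1L]
    res
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      patient_id = character(), line_number = integer(),
      start = as.Date(integer(), origin = "1970-01-01"),
      end = as.Date(integer(), origin = "1970-01-01"),
      regimen = character(), head_class = character(),
      duration_days = integer(), event = character(),
      combination = logical(), with_topical = logical()
    ))
  }
  tibble::tibble(
    patient_id = out$patient_id,
    line_number = out$line_number,
    start = as.Date(out$start, origin = "1970-01-01"),
    end = as.Date(out$end, origin = "1970-01-01"),
    regimen = out$regimen,
    head_class = head_class(out$regimen),
    duration_days = out$duration_days,
    event = out$event,
    combination = grepl("phototherapy", out$regimen, fixed = TRUE) &
      grepl("systemic_nonbio", out$regimen, fixed = TRUE),
    with_topical = grepl("topical", out$regimen, fixed = TRUE)
  )
}

#' Duration and event statistics by line number and head class
#'
#' Descriptive statistics per (line number, head class) cell: number of
#' lines, mean/SD/median duration in days, and counts plus proportions of
#' each terminating event. Empty cells are absent from the output, not zero.
#'
#' @param lines tibble from [build_treatment_lines()].
#' @param max_line highest line number to tabulate.
#' @return tibble with one row per non-empty cell.
#' @export
line_duration_stats <- function(lines, max_line = 3L) {
  sub <- lines[lines$line_number <= max_line, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(line_number = integer(), head_class = character(),
                          n = integer()))
  }
  grp <- dplyr::group_by(sub, .data$line_number, .data$head_class)
  stats_tbl <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    mean_days = mean(.data$duration_days),
    sd_days = stats::sd(.data$duration_days),
    median_days = stats::median(.data$duration_days),
    .groups = "drop"
  )
  for (ev in EVENT_TYPES) {
    cnt <- dplyr::summarise(
      grp, x = sum(.data$event == ev), .groups = "drop")$x
    stats_tbl[[paste0("n_", ev)]] <- cnt
    stats_tbl[[paste0("pct_", ev)]] <- 100 * cnt / stats_tbl$n
  }
  stats_tbl
}
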