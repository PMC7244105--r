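# Independent reference implementations used to cross-check the package.
# These work literally, day by day, on logical day-coverage vectors --
# deliberately a different route from the package's interval arithmetic.

ORACLE_CLASSES <- c("topical", "phototherapy", "systemic_nonbio", "biologic")

# day-set union of inclusive calendar periods (enrollment oracle)
oracle_covered_days <- function(start, end) {
  days <- integer(0)
  for (i in seq_along(start)) days <- union(days, seq(start[i], end[i]))
  sort(days)
}

# episodes -> logical coverage over days 0..H-1 (index d+1 = day d)
.cover <- function(rows, H) {
  v <- logical(H)
  for (i in seq_len(nrow(rows))) {
    s <- rows$start[i]; e <- min(rows$end[i], H)
    if (e > s) v[(s + 1):e] <- TRUE
  }
  v
}

# fill interior empty runs of length <= grace
.bridge <- function(v, grace) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= grace) {
      v[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
    }
  }
  v
}

# coverage -> half-open runs in day units
.runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

.rel <- function(cur, nxt) {
  a <- strsplit(cur, "+", fixed = TRUE)[[1]]
  b <- strsplit(nxt, "+", fixed = TRUE)[[1]]
  if (all(a %in% b) && length(b) > length(a)) return("add_on")
  if (all(b %in% a) && length(a) > length(b)) return("reduction")
  "switch"
}

# brute-force day-occupancy reconstruction of treatment lines
oracle_lines <- function(ep, fu_end, config) {
  H <- fu_end
  cov <- lapply(ORACLE_CLASSES, function(cl) {
    .cover(ep[ep$class == cl, , drop = FALSE], H)
  })
  names(cov) <- ORACLE_CLASSES

  # antibiotic more-than-one-month rule on the bridged day set
  abx <- .bridge(.cover(ep[ep$class == "antibiotic", , drop = FALSE], H),
                 config$grace_period_days)
  if (sum(abx) >= config$antibiotic_min_days) {
    cov$systemic_nonbio <- cov$systemic_nonbio | abx
  }
  cov <- lapply(cov, .bridge, grace = config$grace_period_days)

  # first-line topical stop at phototherapy / oral-systemic initiation
  active_any <- Reduce(`|`, cov)
  if (any(active_any)) {
    d0 <- which(active_any)[1]
    others_at_d0 <- any(vapply(cov[c("phototherapy", "systemic_nonbio",
                                     "biologic")],
                               function(v) v[d0], logical(1)))
    if (cov$topical[d0] && !others_at_d0) {
      first_run <- .runs(cov$topical)[1, ]
      ster_rows <- ep[ep$class == "topical" & ep$steroid, , drop = FALSE]
      steroid <- any(ster_rows$start < first_run$end &
                       pmin(ster_rows$end, H) > first_run$start)
      trig <- which(cov$phototherapy | cov$systemic_nonbio)
      if (!steroid && length(trig) > 0) {
        t0 <- trig[1] - 1 # 0-based trigger day
        if (t0 > first_run$start && t0 < first_run$end) {
          cov$topical[(t0 + 1):first_run$end] <- FALSE
        }
      }
    }
  }

  # phototherapy/systemic short-overlap truncation (long overlap = combo)
  pr <- .runs(cov$phototherapy); sr <- .runs(cov$systemic_nonbio)
  if (nrow(pr) > 0) pr$class <- "phototherapy"
  if (nrow(sr) > 0) sr$class <- "systemic_nonbio"
  ps <- rbind(pr, sr)
  if (nrow(ps) > 1) {
    ps <- ps[order(ps$start, ps$class), , drop = FALSE]
    for (a in seq_len(nrow(ps) - 1)) {
      for (b in (a + 1):nrow(ps)) {
        if (ps$class[a] == ps$class[b]) next
        ov <- min(ps$end[a], ps$end[b]) - max(ps$start[a], ps$start[b])
        if (ov <= 0) next
        if (ps$start[a] < ps$start[b] &&
            ov <= config$combination_overlap_days) {
          ps$end[a] <- ps$start[b]
        }
      }
    }
    for (cl in c("phototherapy", "systemic_nonbio")) {
      v <- logical(H)
      rr <- ps[ps$class == cl, , drop = FALSE]
      for (i in seq_len(nrow(rr))) {
        if (rr$end[i] > rr$start[i]) v[(rr$start[i] + 1):rr$end[i]] <- TRUE
      }
      cov[[cl]] <- v
    }
  }

  # maximal constant nonempty active-class-set segments
  m <- do.call(cbind, cov)
  sets <- rep("", H)
  for (cl in ORACLE_CLASSES) {
    sets <- paste0(sets, ifelse(m[, cl], paste0(cl, "+"), ""))
  }
  sets <- sub("\\+$", "", sets)
  r <- rle(sets)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  segs <- data.frame(start = starts, end = ends, regimen = r$values,
                     stringsAsFactors = FALSE)
  segs <- segs[nzchar(segs$regimen), , drop = FALSE]
  rownames(segs) <- NULL

  n <- nrow(segs)
  ev <- character(n)
  for (i in seq_len(n)) {
    if (i < n) {
      gap <- segs$start[i + 1] - segs$end[i]
      ev[i] <- if (gap > config$grace_period_days) "discontinuation" else
        .rel(segs$regimen[i], segs$regimen[i + 1])
    } else {
      ev[i] <- if (fu_end - segs$end[i] > config$grace_period_days)
        "discontinuation" else "no_change"
    }
  }
  segs$event <- ev
  segs$line_number <- seq_len(n)
  segs
}

# random small patient for oracle equivalence testing: <= 8 claims over a
# <= 400-day horizon, mixing all classes, steroid flags and durations
random_patient_episodes <- function(config) {
  n <- sample(1:8, 1)
  cls <- sample(c("topical", "phototherapy", "systemic_nonbio", "biologic",
                  "antibiotic"), n, replace = TRUE,
                prob = c(0.35, 0.2, 0.25, 0.1, 0.1))
  start <- sample(0:400, n, replace = TRUE)
  dur <- ifelse(cls == "topical", config$topical_duration_days,
                ifelse(cls == "phototherapy",
                       config$phototherapy_duration_days,
                       sample(7:60, n, replace = TRUE)))
  steroid <- cls == "topical" & stats::runif(n) < 0.3
  fu_end <- 400 + sample(0:100, 1)
  ep <- data.frame(class = cls, start = start,
                   end = pmin(start + dur, fu_end), steroid = steroid)
  list(episodes = ep[ep$end > ep$start, , drop = FALSE], fu_end = fu_end)
}

# reference Kaplan-Meier via the survival package (oracle only)
reference_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "none")
  keep <- sf$n.event > 0
  data.frame(time = sf$time[keep], survival = sf$surv[keep])
}
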