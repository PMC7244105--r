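## data model: claims table schemas, readers/writers, validation --------------

CLAIMS_SCHEMAS <- list(
  enrollment = list(
    required = c("patient_id", "start_date", "end_date"),
    optional = c("birth_date", "sex"),
    dates = c("start_date", "end_date", "birth_date")
  ),
  diagnosis = list(
    required = c("patient_id", "claim_date", "icd10"),
    optional = "setting",
    dates = "claim_date"
  ),
  prescription = list(
    required = c("patient_id", "claim_record_date", "drug_code"),
    optional = c("dispense_date", "atc", "category", "route", "steroid",
                 "ddd_days", "cost_yen"),
    dates = c("dispense_date", "claim_record_date")
  ),
  procedure = list(
    required = c("patient_id", "date", "kind"),
    optional = "cost_yen",
    dates = "date"
  )
)

parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  nonblank <- !is.na(x) & nzchar(x)
  out[nonblank] <- as.Date(x[nonblank], format = "%Y-%m-%d", optional = TRUE)
  attr(out, "unparseable") <- nonblank & is.na(out)
  out
}

#' Validate a claims table against its schema
#'
#' Checks one of the four claims tables (`enrollment`, `diagnosis`,
#' `prescription`, `procedure`). A missing mandatory column is a hard schema
#' error naming the column; malformed rows (unparseable dates, negative
#' costs, non-positive days supplied, empty diagnosis codes, prescriptions
#' with neither a dispense nor a claim-record date, enrollment with
#' start after end) are collected into a rejects report and removed, never
#' silently dropped.
#'
#' @param df data frame with character or typed columns.
#' @param kind one of `names(CLAIMS_SCHEMAS)`.
#' @return list with `records` (typed tibble of accepted rows) and `rejects`
#'   (tibble with `row` and `reason`).
#' @export
validate_claims <- function(df, kind) {
  kind <- match.arg(kind, names(CLAIMS_SCHEMAS))
  schema <- CLAIMS_SCHEMAS[[kind]]
  missing_cols <- setdiff(schema$required, names(df))
  if (length(missing_cols) > 0) {
    stop("claims table `", kind, "` is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  reject_reason <- rep(NA_character_, n)
  note <- function(bad, reason) {
    take <- bad & is.na(reject_reason)
    reject_reason[take] <<- reason
  }

  for (col in intersect(schema$dates, names(df))) {
    if (inherits(df[[col]], "Date")) next
    parsed <- parse_iso_date(df[[col]])
    note(attr(parsed, "unparseable"), paste0("unparseable date in ", col))
    attr(parsed, "unparseable") <- NULL
    df[[col]] <- parsed
  }
  if ("cost_yen" %in% names(df)) {
    df$cost_yen <- suppressWarnings(as.numeric(df$cost_yen))
    note(!is.na(df$cost_yen) & df$cost_yen < 0, "negative cost")
  }
  if (kind == "enrollment") {
    note(is.na(df$start_date) | is.na(df$end_date), "missing enrollment date")
    note(!is.na(df$start_date) & !is.na(df$end_date) &
           df$start_date > df$end_date, "start after end")
  }
  if (kind == "diagnosis") {
    note(is.na(df$icd10) | !nzchar(trimws(df$icd10)), "empty icd10 code")
    note(is.na(df$claim_date), "missing claim date")
  }
  if (kind == "prescription") {
    if (!"dispense_date" %in% names(df)) df$dispense_date <- as.Date(NA)
    note(is.na(df$dispense_date) & is.na(df$claim_record_date),
         "no dispense or claim record date")
    if ("ddd_days" %in% names(df)) {
      df$ddd_days <- suppressWarnings(as.numeric(df$ddd_days))
      note(!is.na(df$ddd_days) & df$ddd_days <= 0, "non-positive ddd_days")
    }
    if ("steroid" %in% names(df)) df$steroid <- as.logical(df$steroid)
    if ("category" %in% names(df)) {
      note(!is.na(df$category) & !(df$category %in% TREATMENT_CATEGORIES),
           "unknown treatment category")
    }
  }
  if (kind == "procedure") {
    note(is.na(df$date), "missing procedure date")
    note(!is.na(df$kind) & !(df$kind %in% PROCEDURE_KINDS),
         "unknown procedure kind")
  }

  bad <- !is.na(reject_reason)
  list(
    records = df[!bad, , drop = FALSE],
    rejects = tibble::tibble(row = which(bad), reason = reject_reason[bad])
  )
}

#' Read a claims table from CSV
#'
#' Columns are read as text and validated with [validate_claims()]; dates
#' must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path CSV file path.
#' @param kind table kind, one of `"enrollment"`, `"diagnosis"`,
#'   `"prescription"`, `"procedure"`.
#' @return list with `records` and `rejects` tibbles.
#' @export
read_claims <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_claims(df, kind)
}

#' Write a claims table to CSV (ISO-8601 dates)
#'
#' Inverse of [read_claims()]: writing then reading a valid collection is the
#' identity on all fields.
#'
#' @param df claims tibble.
#' @param path output CSV path.
#' @export
write_claims <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Merge a patient's enrollment periods into disjoint spans
#'
#' Periods are inclusive calendar-date intervals; overlapping or adjacent
#' periods (next start on the day after the previous end) are unioned so the
#' set of covered days is preserved.
#'
#' @param periods tibble with `patient_id`, `start_date`, `end_date` (and any
#'   constant-per-patient extras such as `birth_date`, `sex`, which are kept
#'   from the first period).
#' @return tibble of sorted, disjoint periods per patient.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   patient_id = "a",
#'   start_date = as.Date(c("2012-01-01", "2012-02-01")),
#'   end_date = as.Date(c("2012-03-31", "2012-04-30"))
#' )
#' normalize_enrollment(p)
normalize_enrollment <- function(periods) {
  stopifnot(all(c("patient_id", "start_date", "end_date") %in% names(periods)))
  extras <- setdiff(names(periods), c("patient_id", "start_date", "end_date"))
  pieces <- lapply(split(periods, periods$patient_id), function(p) {
    p <- p[order(p$start_date, p$end_date), , drop = FALSE]
    s <- as.integer(p$start_date)
    e <- as.integer(p$end_date)
    ms <- s[1L]; me <- e[1L]
    out_s <- integer(); out_e <- integer()
    if (length(s) > 1L) {
      for (i in 2L:length(s)) {
        if (s[i] <= me + 1L) {
          me <- max(me, e[i])
        } else {
          out_s <- c(out_s, ms); out_e <- c(out_e, me)
          ms <- s[i]; me <- e[i]
        }
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    res <- tibble::tibble(
      patient_id = p$patient_id[1L],
      start_date = as.Date(out_s, origin = "1970-01-01"),
      end_date = as.Date(out_e, origin = "1970-01-01")
    )
    for (x in extras) res[[x]] <- p[[x]][1L]
    res
  })
  dplyr::bind_rows(pieces)
}

#' Impute missing dispense dates from the claim-record date
#'
#' When a prescription's dispense date is absent, the date the claim was
#' recorded is used as the estimated prescription date.
#'
#' @param prescriptions prescription tibble.
#' @return tibble with `dispense_date` filled.
#' @export
impute_dispense_date <- function(prescriptions) {
  if (!"dispense_date" %in% names(prescriptions)) {
    prescriptions$dispense_date <- as.Date(NA)
  }
  miss <- is.na(prescriptions$dispense_date)
  prescriptions$dispense_date[miss] <- prescriptions$claim_record_date[miss]
  prescriptions
}

#' Attach treatment categories to prescriptions via the drug map
#'
#' Joins the configured drug-to-category map by `drug_code`; drugs not in
#' the map become category `other` (never part of line construction).
#' Derives `atc_level1` and `atc_level3` prefixes. Columns already present
#' in the input are kept as-is.
#'
#' @param prescriptions prescription tibble with `drug_code`.
#' @param config a [ppp_config()].
#' @return tibble with `category`, `route`, `steroid`, `atc`, `atc_level1`,
#'   `atc_level3` columns.
#' @export
categorize_prescriptions <- function(prescriptions, config) {
  cm <- config$category_map
  idx <- match(prescriptions$drug_code, cm$drug_code)
  fill <- function(col, default) {
    if (!col %in% names(prescriptions) || all(is.na(prescriptions[[col]]))) {
      v <- cm[[col]][idx]
      v[is.na(idx)] <- default
      prescriptions[[col]] <<- v
    }
  }
  fill("category", "other")
  fill("route", "na")
  fill("atc", NA_character_)
  fill("steroid", FALSE)
  prescriptions$steroid[is.na(prescriptions$steroid)] <- FALSE
  prescriptions$atc_level1 <- substr(prescriptions$atc, 1L, 1L)
  prescriptions$atc_level3 <- substr(prescriptions$atc, 1L, 4L)
  prescriptions
}

#' Deduplicate same-day prescriptions of the same drug
#'
#' Same-day duplicate dispensings of one drug are counted once; duplicates
#' are returned alongside for logging.
#'
#' @param prescriptions prescription tibble with imputed `dispense_date`.
#' @return list with `records` (deduplicated) and `duplicates`.
#' @export
dedupe_prescriptions <- function(prescriptions) {
  key <- paste(prescriptions$patient_id, prescriptions$dispense_date,
               prescriptions$drug_code, sep = "\r")
  dup <- duplicated(key)
  list(records = prescriptions[!dup, , drop = FALSE],
       duplicates = prescriptions[dup, , drop = FALSE])
}
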