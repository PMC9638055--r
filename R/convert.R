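# SCATE -> TimeML conversion.
#
# Explicit dates/times become DATE/TIME annotations with ISO-8601 values;
# quantity+unit Period and Calendar-Interval entities become DURATION with a
# PnU value under the naive rule, or are routed through the temporal type
# disambiguation (TTD) classifier when one is attached, in which case a
# DATE verdict yields an empty value (anchor-time resolution is a separate,
# unimplemented step). Frequencies are normalized only when the abbreviation
# lexicon supplies a value.

#' Load the approximate-quantity table
#'
#' Maps vague quantity words to the integer used in the normalized value
#' ("several days" -> 3 days). The packaged defaults are `couple` = 2,
#' `few` = 3, `several` = 3, `many` = 7; the table is a config file, not a
#' constant.
#'
#' @param path tab-separated word/quantity file.
#' @return Named integer vector.
#' @export
approx_table <- function(path = lexicon_path("approx.tsv")) {
  lx <- read_lexicon(path)
  q <- as.integer(lx$V2)
  if (any(is.na(q)) || any(q < 1L))
    stop("approximate quantities must be integers >= 1")
  stats::setNames(q, tolower(lx$term))
}

#' Conversion configuration
#'
#' @param approx approximate-quantity table ([approx_table()]).
#' @param ttd_model optional fitted [ttd_svm()] model; when absent every
#'   Period/Calendar-Interval entity falls back to the naive all-DURATION
#'   rule.
#' @param date_order `"mdy"` (US month/day/year, the default) or `"dmy"`
#'   for slash dates.
#' @param year_fill_window days around the admission date within which a
#'   year-less date adopts the admission year (default 183, i.e. +/- 6
#'   months); outside it the nearer of the admission/discharge years wins.
#' @return A list of class `conversion_config`.
#' @export
conversion_config <- function(approx = approx_table(), ttd_model = NULL,
                              date_order = c("mdy", "dmy"),
                              year_fill_window = 183L) {
  structure(list(approx = approx, ttd_model = ttd_model,
                 date_order = match.arg(date_order),
                 year_fill_window = as.integer(year_fill_window)),
            class = "conversion_config")
}

#' Format an ISO-8601 duration
#'
#' Calendar units use the `P` designator (`P2D`, `P1W`, `P3M`, `P1Y`); clock
#' units use the `PT` designator (`PT6H`, `PT30M`).
#'
#' @param quantity positive number of units.
#' @param unit one of `minute`, `hour`, `day`, `week`, `month`, `year`.
#' @return The ISO duration string.
#' @export
iso_duration <- function(quantity, unit) {
  if (!is.finite(quantity) || quantity <= 0)
    stop("duration quantity must be positive")
  unit <- match.arg(unit, CALENDAR_UNITS)
  q <- if (quantity == round(quantity)) format(as.integer(quantity)) else
    format(quantity)
  switch(unit,
         minute = paste0("PT", q, "M"),
         hour = paste0("PT", q, "H"),
         day = paste0("P", q, "D"),
         week = paste0("P", q, "W"),
         month = paste0("P", q, "M"),
         year = paste0("P", q, "Y"))
}

#' Resolve an approximate quantity word
#'
#' @param word a vague quantity word such as `"several"`.
#' @param table an [approx_table()].
#' @return `list(quantity = <int>, modifier = "APPROX")`.
#' @export
approximate_quantity <- function(word, table = approx_table()) {
  key <- tolower(word)
  if (!key %in% names(table))
    stop(sprintf("no approximate quantity defined for %s", dQuote(word)))
  list(quantity = unname(table[[key]]), modifier = "APPROX")
}

month_number <- function(name) {
  match(tolower(name), tolower(month.name))
}

make_iso_date <- function(y, m, d) {
  out <- sprintf("%04d-%02d-%02d", y, m, d)
  if (is.na(as.Date(out, format = "%Y-%m-%d"))) NA_character_ else out
}

expand_two_digit_year <- function(y) {
  if (y >= 100L) return(y)
  if (y < 50L) 2000L + y else 1900L + y
}

# choose a year for a month/day with no year, using the document's
# admission/discharge dates
fill_year <- function(month, day, doc, window = 183L) {
  adm <- doc$admission_date
  dis <- doc$discharge_date
  if (is.na(adm) && is.na(dis)) return(NA_character_)
  ref <- if (!is.na(adm)) adm else dis
  cand <- as.Date(make_iso_date(as.integer(format(ref, "%Y")), month, day))
  if (!is.na(adm) && !is.na(cand) &&
      abs(as.numeric(cand - adm)) <= window)
    return(format(cand))
  # nearer of the admission/discharge years
  years <- unique(stats::na.omit(c(
    if (!is.na(adm)) as.integer(format(adm, "%Y")),
    if (!is.na(dis)) as.integer(format(dis, "%Y")))))
  best <- NA_character_
  best_dist <- Inf
  for (y in c(years, years - 1L, years + 1L)) {
    c2 <- as.Date(make_iso_date(y, month, day))
    if (is.na(c2)) next
    dist <- min(abs(as.numeric(c2 - ref)),
                if (!is.na(dis)) abs(as.numeric(c2 - dis)) else Inf)
    if (dist < best_dist) {
      best_dist <- dist
      best <- format(c2)
    }
  }
  best
}

#' Normalize an explicit date or time phrase to ISO-8601
#'
#' Handles `YYYY-MM-DD`, slash dates (US month-first by default), written
#' dates (`January 3, 2021`), month + day without a year, and 2-place dates
#' (`01/10`), filling the missing year from the document's admission date
#' when the result lands within the configured window and otherwise from the
#' nearer of the admission/discharge years. Phrases that carry no calendar
#' day (a bare month or weekday name, a clock time) normalize to `""`.
#'
#' @param entity one-row entity data.frame of kind `ExplicitDate`,
#'   `ExplicitTime` or `TwoPlaceDate`.
#' @param doc the `tern_document` supplying reference dates.
#' @param cfg a [conversion_config()].
#' @return ISO `YYYY-MM-DD` string, or `""` when normalization fails.
#' @export
normalize_explicit_date <- function(entity, doc, cfg = conversion_config()) {
  stopifnot(entity$kind %in% c("ExplicitDate", "ExplicitTime",
                               "TwoPlaceDate"))
  txt <- trimws(entity$text)
  if (entity$kind == "ExplicitTime") return("")
  m <- regmatches(txt, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", txt))[[1]]
  if (length(m)) {
    out <- make_iso_date(as.integer(m[2]), as.integer(m[3]),
                         as.integer(m[4]))
    return(if (is.na(out)) "" else out)
  }
  m <- regmatches(txt,
                  regexec("^(\\d{1,2})/(\\d{1,2})/(\\d{2,4})$", txt))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    y <- expand_two_digit_year(as.integer(m[4]))
    mo <- if (cfg$date_order == "mdy") a else b
    dy <- if (cfg$date_order == "mdy") b else a
    out <- make_iso_date(y, mo, dy)
    return(if (is.na(out)) "" else out)
  }
  m <- regmatches(txt, regexec(
    "^([A-Za-z]+)\\s+(\\d{1,2}),\\s+(\\d{4})$", txt))[[1]]
  if (length(m)) {
    mo <- month_number(m[2])
    if (is.na(mo)) return("")
    out <- make_iso_date(as.integer(m[4]), mo, as.integer(m[3]))
    return(if (is.na(out)) "" else out)
  }
  m <- regmatches(txt, regexec("^([A-Za-z]+)\\s+(\\d{1,2})$", txt))[[1]]
  if (length(m)) {
    mo <- month_number(m[2])
    if (is.na(mo)) return("")
    out <- fill_year(mo, as.integer(m[3]), doc, cfg$year_fill_window)
    return(if (is.na(out)) "" else out)
  }
  m <- regmatches(txt, regexec("^(\\d{1,2})/(\\d{1,2})$", txt))[[1]]
  if (length(m)) {
    out <- fill_year(as.integer(m[2]), as.integer(m[3]), doc,
                     cfg$year_fill_window)
    return(if (is.na(out)) "" else out)
  }
  ""  # bare month/weekday/holiday: no calendar day to normalize
}

#' Convert one SCATE entity to a TimeML TIMEX3 annotation
#'
#' Explicit dates and 2-place dates become DATE; clock times become TIME;
#' frequencies become FREQUENCY (normalized only when the abbreviation
#' lexicon supplied a value). Period and Calendar-Interval entities are
#' routed through the attached TTD model when `cfg$ttd_model` is set (the
#' caller must then supply the phrase `feature`); without a model the naive
#' rule assigns DURATION. A DURATION verdict with a known quantity/unit is
#' normalized with [iso_duration()]; vague quantities are resolved through
#' the approximate table and flagged `APPROX`; a DATE verdict for a relative
#' phrase keeps an empty value.
#'
#' @param entity one-row entity data.frame from [recognize()].
#' @param doc the owning `tern_document`.
#' @param cfg a [conversion_config()].
#' @param feature optional `phrase_feature` for TTD routing.
#' @return One-row annotation data.frame (see [timex_annotations()]), with
#'   an empty `ann_id` for the caller to fill.
#' @export
scate_to_timeml <- function(entity, doc, cfg = conversion_config(),
                            feature = NULL) {
  kind <- entity$kind
  ttype <- "DATE"; value <- ""; modifier <- "NA"
  if (kind %in% c("ExplicitDate", "TwoPlaceDate")) {
    ttype <- "DATE"
    value <- normalize_explicit_date(entity, doc, cfg)
  } else if (kind == "ExplicitTime") {
    ttype <- "TIME"
    value <- ""
  } else if (kind == "Frequency") {
    ttype <- "FREQUENCY"
    value <- if (!is.na(entity$value)) entity$value else ""
  } else if (kind %in% c("Period", "CalendarInterval")) {
    quantity <- entity$quantity
    if (!is.na(entity$approx_word)) {
      aq <- approximate_quantity(entity$approx_word, cfg$approx)
      quantity <- aq$quantity
      modifier <- aq$modifier
    }
    if (!is.null(cfg$ttd_model)) {
      if (is.null(feature))
        stop("a phrase feature is required to route ", dQuote(entity$text),
             " through the TTD model")
      ttype <- predict_type(cfg$ttd_model, feature)
    } else {
      ttype <- "DURATION"  # naive rule
    }
    if (ttype == "DURATION" && !is.na(quantity) && !is.na(entity$unit))
      value <- iso_duration(quantity, entity$unit)
  } else if (kind == "TemporalAdverb") {
    ttype <- "DATE"
    value <- ""
  } else {
    stop("unknown entity kind: ", kind)
  }
  timex_annotations(ann_id = "", start = entity$start, end = entity$end,
                    text = entity$text, ttype = ttype, value = value,
                    modifier = modifier)
}
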