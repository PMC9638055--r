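# Rule/dictionary temporal phrase recognizer.
#
# Produces fine-grained SCATE-style entities (Period, Calendar-Interval,
# explicit dates/times, 2-place dates, Frequency, TemporalAdverb) from raw
# note text. The grammar covers the rule families clinical discharge
# summaries exercise most: explicit and partial dates, clock times,
# numeric/worded quantity + calendar unit phrases with their relative cue
# words, clinical abbreviations (b.i.d., POD#n, ...), frequencies and a
# configurable temporal-adverb list. Overlaps among rule matches are
# resolved longest-match-first.

SCATE_KINDS <- c("ExplicitDate", "ExplicitTime", "TwoPlaceDate", "Period",
                 "CalendarInterval", "Frequency", "TemporalAdverb")

CALENDAR_UNITS <- c("minute", "hour", "day", "week", "month", "year")

WORDED_NUMBERS <- c(one = 1, two = 2, three = 3, four = 4, five = 5,
                    six = 6, seven = 7, eight = 8, nine = 9, ten = 10)

APPROX_WORDS <- c("couple", "few", "several", "many")

# kind priority for overlap tie-breaks (smaller wins)
KIND_PRIORITY <- c(ExplicitDate = 1, ExplicitTime = 1, TwoPlaceDate = 2,
                   Period = 3, CalendarInterval = 3, Frequency = 4,
                   TemporalAdverb = 5)

#' Read a line-oriented lexicon file
#'
#' One entry per line; fields are tab-separated. Lines starting with `#` and
#' blank lines are skipped.
#'
#' @param path file path.
#' @return A data.frame with columns `term` and any further payload fields
#'   `V2`, `V3`, ... present in the file.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- max(c(1L, lengths(parts)))
  out <- data.frame(term = vapply(parts, `[`, "", 1L),
                    stringsAsFactors = FALSE)
  for (j in seq_len(width - 1L)) {
    out[[paste0("V", j + 1L)]] <-
      vapply(parts, function(p) if (length(p) > j) p[j + 1L] else "", "")
  }
  out
}

lexicon_path <- function(name) {
  system.file("extdata", "lexicons", name, package = "ternr", mustWork = TRUE)
}

normalize_abbrev_key <- function(x) {
  gsub("\\.", "", tolower(x))
}

#' Load the clinical abbreviation lexicon
#'
#' Maps abbreviation surface forms (matched case- and period-insensitively,
#' so `bid` and `B.I.D.` hit the `b.i.d.` entry) to an entity kind, an
#' expansion and a pre-normalized value.
#'
#' @param path lexicon file; defaults to the packaged clinical lexicon.
#' @return A data.frame with columns `term`, `key`, `kind`, `expansion`,
#'   `value`.
#' @export
abbreviation_lexicon <- function(path = lexicon_path("abbreviations.tsv")) {
  lx <- read_lexicon(path)
  out <- data.frame(term = lx$term,
                    key = normalize_abbrev_key(lx$term),
                    kind = lx$V2, expansion = lx$V3, value = lx$V4,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$key))
    stop("abbreviation lexicon keys are not unique after normalization")
  out
}

#' Recognizer configuration
#'
#' @param abbreviations abbreviation lexicon data.frame
#'   ([abbreviation_lexicon()]).
#' @param adverbs character vector of temporal adverbs.
#' @param months,weekdays,holidays character vectors used by the explicit
#'   date rules (and by the RelIV filter).
#' @param drop_adverbs drop recognized temporal adverbs from the output
#'   (the i2b2 gold standard does not annotate them).
#' @return A list of class `recognizer_config`.
#' @export
recognizer_config <- function(abbreviations = abbreviation_lexicon(),
                              adverbs = read_lexicon(lexicon_path("adverbs.txt"))$term,
                              months = read_lexicon(lexicon_path("months.txt"))$term,
                              weekdays = read_lexicon(lexicon_path("weekdays.txt"))$term,
                              holidays = read_lexicon(lexicon_path("holidays.txt"))$term,
                              drop_adverbs = TRUE) {
  structure(list(abbreviations = abbreviations, adverbs = adverbs,
                 months = months, weekdays = weekdays, holidays = holidays,
                 drop_adverbs = drop_adverbs),
            class = "recognizer_config")
}

scate_entities <- function(start = integer(), end = integer(),
                           text = character(), kind = character(),
                           quantity = numeric(), unit = character(),
                           approx_word = character(), value = character()) {
  n <- length(start)
  fill <- function(x, default) if (length(x) == 0L && n > 0L)
    rep(default, n) else x
  data.frame(start = as.integer(start), end = as.integer(end),
             text = as.character(text), kind = as.character(kind),
             quantity = as.numeric(fill(quantity, NA_real_)),
             unit = as.character(fill(unit, NA_character_)),
             approx_word = as.character(fill(approx_word, NA_character_)),
             value = as.character(fill(value, NA_character_)),
             stringsAsFactors = FALSE)
}

# run one regex over the text, returning 0-based half-open spans and the
# regmatches, plus capture groups when perl capture is used
regex_spans <- function(text, pattern, ignore_case = FALSE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) return(NULL)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  res <- list(start = start, end = start + len,
              text = slice_text(text, start, start + len))
  cs <- attr(m, "capture.start")
  if (!is.null(cs)) {
    cl <- attr(m, "capture.length")
    caps <- lapply(seq_len(ncol(cs)), function(j) {
      ifelse(cs[, j] > 0L,
             substring(text, cs[, j], cs[, j] + cl[, j] - 1L),
             NA_character_)
    })
    names(caps) <- colnames(cs)
    res$captures <- caps
  }
  res
}

parse_quantity <- function(word) {
  word <- tolower(word)
  if (grepl("^\\d+$", word)) return(as.numeric(word))
  if (word %in% names(WORDED_NUMBERS)) return(unname(WORDED_NUMBERS[[word]]))
  NA_real_  # approximate word: resolved at conversion time
}

singular_unit <- function(u) sub("s$", "", tolower(u))

QUANTITY_RE <- paste0("(?:\\d+|", paste(names(WORDED_NUMBERS), collapse = "|"),
                      "|", paste(APPROX_WORDS, collapse = "|"), ")")
UNIT_RE <- "(?:minutes?|hours?|days?|weeks?|months?|years?)"

#' Recognize temporal phrases as SCATE-style entities
#'
#' Runs every rule family over the text and resolves overlapping matches:
#' the longest match wins, ties go to the earliest start, remaining ties to
#' the more specific rule family (explicit date > 2-place date > period >
#' frequency > adverb). Relative cue words (`ago`, `prior`, `past`, `next`,
#' ...) adjoining a quantity+unit phrase are included in the entity span.
#'
#' @param text the note text.
#' @param config a [recognizer_config()].
#' @return A `data.frame` of entities sorted by `start`: columns `start`,
#'   `end` (0-based half-open), `text`, `kind`, `quantity`, `unit`,
#'   `approx_word`, `value`. Non-overlapping by construction.
#' @export
recognize <- function(text, config = recognizer_config()) {
  stopifnot(inherits(config, "recognizer_config"))
  cand <- list()
  add <- function(spans, kind, quantity = NULL, unit = NULL,
                  approx_word = NULL, value = NULL) {
    if (is.null(spans)) return()
    n <- length(spans$start)
    cand[[length(cand) + 1L]] <<- scate_entities(
      spans$start, spans$end, spans$text, rep(kind, n),
      if (is.null(quantity)) rep(NA_real_, n) else quantity,
      if (is.null(unit)) rep(NA_character_, n) else unit,
      if (is.null(approx_word)) rep(NA_character_, n) else approx_word,
      if (is.null(value)) rep(NA_character_, n) else value)
  }

  month_re <- paste(config$months, collapse = "|")

  # --- explicit dates ---
  add(regex_spans(text, "\\b\\d{4}-\\d{2}-\\d{2}\\b"), "ExplicitDate")
  add(regex_spans(text, "\\b\\d{1,2}/\\d{1,2}/\\d{2,4}\\b"), "ExplicitDate")
  add(regex_spans(text, paste0("\\b(?:", month_re,
                               ")\\s+\\d{1,2},\\s+\\d{4}\\b"),
                  ignore_case = TRUE), "ExplicitDate")
  add(regex_spans(text, paste0("\\b(?:", month_re,
                               ")\\s+\\d{1,2}\\b(?!\\s*,\\s*\\d{4})"),
                  ignore_case = TRUE), "ExplicitDate")
  add(regex_spans(text, paste0("\\b(?:", month_re, ")\\b"),
                  ignore_case = TRUE), "ExplicitDate")
  add(regex_spans(text, paste0("\\b(?:",
                               paste(config$weekdays, collapse = "|"),
                               ")\\b"), ignore_case = TRUE), "ExplicitDate")
  if (length(config$holidays))
    add(regex_spans(text, paste0("\\b(?:",
                                 paste(config$holidays, collapse = "|"),
                                 ")\\b"), ignore_case = TRUE), "ExplicitDate")

  # --- explicit times ---
  add(regex_spans(text,
      "\\b\\d{1,2}:\\d{2}(?::\\d{2})?(?:\\s?(?:a\\.?m\\.?|p\\.?m\\.?))?",
      ignore_case = TRUE), "ExplicitTime")
  add(regex_spans(text, "\\b\\d{1,2}\\s?(?:a\\.?m\\.?|p\\.?m\\.?)",
                  ignore_case = TRUE), "ExplicitTime")

  # --- 2-place dates ---
  tp <- regex_spans(text, "\\b(\\d{1,2})/(\\d{1,2})\\b(?!/)")
  if (!is.null(tp)) {
    mo <- as.integer(tp$captures[[1]])
    dy <- as.integer(tp$captures[[2]])
    ok <- mo >= 1L & mo <= 12L & dy >= 1L & dy <= 31L
    if (any(ok))
      add(lapply(tp[c("start", "end", "text")], `[`, ok), "TwoPlaceDate")
  }

  # --- quantity + unit periods, with optional leading/trailing cue words ---
  per <- regex_spans(text, paste0(
    "(?:\\b(?:over|in|for)\\s+)?",
    "(?:\\bthe\\s+(?:past|next|last)\\s+|\\ba\\s+|\\ban\\s+)?",
    "\\b(", QUANTITY_RE, ")(?:\\s+of)?[\\s-](", UNIT_RE, ")\\b",
    "(?:\\s+(?:ago|later|earlier|prior(?:\\s+to\\s+(?:admission|discharge|presentation))?|before\\s+admission))?"),
    ignore_case = TRUE)
  if (!is.null(per)) {
    q_word <- tolower(per$captures[[1]])
    add(per, "Period",
        quantity = vapply(q_word, parse_quantity, 0),
        unit = vapply(per$captures[[2]], singular_unit, ""),
        approx_word = ifelse(q_word %in% APPROX_WORDS, q_word,
                             NA_character_))
  }

  # --- bare-unit calendar intervals ("a week ago", "the day of admission") ---
  ci <- regex_spans(text, paste0(
    "\\b(?:a|an|the)\\s+(minute|hour|day|week|month|year)\\b",
    "(?:\\s+(?:ago|later|earlier|prior",
    "|of\\s+(?:admission|discharge|surgery|life|presentation)))?"),
    ignore_case = TRUE)
  if (!is.null(ci))
    add(ci, "CalendarInterval", quantity = 1,
        unit = tolower(ci$captures[[1]]))

  # --- clinical abbreviation patterns with a numeric slot ---
  pod <- regex_spans(text, paste0(
    "\\b(?:POD\\s?#?\\s?(\\d+)",
    "|(?:post-?operative|post-?op)\\s+day\\s+#?\\s?(\\d+|",
    paste(names(WORDED_NUMBERS), collapse = "|"), ")",
    "|day\\s+of\\s+life\\s+#?\\s?(\\d+|",
    paste(names(WORDED_NUMBERS), collapse = "|"), ")",
    "|hospital\\s+day\\s+#?\\s?(\\d+|",
    paste(names(WORDED_NUMBERS), collapse = "|"), "))\\b"),
    ignore_case = TRUE)
  if (!is.null(pod)) {
    qs <- rep(NA_real_, length(pod$start))
    for (cap in pod$captures) {
      has <- !is.na(cap)
      qs[has] <- vapply(cap[has], parse_quantity, 0)
    }
    add(pod, "Period", quantity = qs, unit = "day")
  }

  # --- literal abbreviations (lexicon) ---
  toks <- regex_spans(text, "\\S+")
  if (!is.null(toks)) {
    key <- normalize_abbrev_key(gsub("[,;:]+$", "", toks$text))
    hit <- match(key, config$abbreviations$key)
    has <- !is.na(hit)
    if (any(has)) {
      trimmed <- gsub("[,;:]+$", "", toks$text[has])
      add(list(start = toks$start[has],
               end = toks$start[has] + nchar(trimmed),
               text = trimmed),
          "Frequency", value = config$abbreviations$value[hit[has]])
    }
  }

  # --- frequencies ---
  add(regex_spans(text, "(?<![\\w])[x×]\\s?\\d+\\b", ignore_case = TRUE),
      "Frequency")
  add(regex_spans(text, "\\b(?:daily|nightly|weekly|monthly|hourly)\\b",
                  ignore_case = TRUE), "Frequency")
  add(regex_spans(text,
      "\\b(?:twice|once|three\\s+times|four\\s+times)\\s+(?:a|per)\\s+(?:day|week|month|hour)\\b",
      ignore_case = TRUE), "Frequency")
  add(regex_spans(text, paste0("\\bevery\\s+\\d+\\s+", UNIT_RE, "\\b"),
                  ignore_case = TRUE), "Frequency")

  # --- temporal adverbs ---
  if (length(config$adverbs))
    add(regex_spans(text, paste0("\\b(?:",
                                 paste(config$adverbs, collapse = "|"),
                                 ")\\b"), ignore_case = TRUE),
        "TemporalAdverb")

  ents <- do.call(rbind, cand)
  if (is.null(ents) || nrow(ents) == 0L) return(scate_entities())
  ents <- resolve_overlaps(ents)
  ents <- filter_adverbs(ents, config$adverbs, drop = config$drop_adverbs)
  rownames(ents) <- NULL
  ents
}

# longest match wins; ties by earliest start, then rule-family priority
resolve_overlaps <- function(ents) {
  len <- ents$end - ents$start
  prio <- KIND_PRIORITY[ents$kind]
  ord <- order(-len, ents$start, prio)
  ents <- ents[ord, , drop = FALSE]
  keep <- logical(nrow(ents))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(ents))) {
    s <- ents$start[i]; e <- ents$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  out <- ents[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Match a single token as a 2-place date
#'
#' @param token one whitespace token.
#' @return `c(month, day)` when the token is `d{1,2}/d{1,2}` with a valid
#'   month (1-12) and day (1-31), otherwise `NULL`.
#' @export
match_two_place_date <- function(token) {
  stopifnot(length(token) == 1L)
  m <- regmatches(token, regexec("^(\\d{1,2})/(\\d{1,2})$", token))[[1]]
  if (length(m) == 0L) return(NULL)
  mo <- as.integer(m[2]); dy <- as.integer(m[3])
  if (mo < 1L || mo > 12L || dy < 1L || dy > 31L) return(NULL)
  c(month = mo, day = dy)
}

#' Match tokens against the clinical abbreviation lexicon
#'
#' Matching is case-insensitive and tolerant of period variants (`bid`,
#' `B.I.D.`, `b.i.d.` all hit the same entry). Single-token postoperative-day
#' forms (`POD#2`) yield a Period-like day entity.
#'
#' @param tokens character vector of whitespace tokens.
#' @param lexicon an [abbreviation_lexicon()].
#' @return A data.frame with one row per matched token: `token_index`,
#'   `text`, `kind`, `expansion`, `value`, `quantity`, `unit`.
#' @export
match_abbreviations <- function(tokens, lexicon = abbreviation_lexicon()) {
  out <- data.frame(token_index = integer(), text = character(),
                    kind = character(), expansion = character(),
                    value = character(), quantity = numeric(),
                    unit = character(), stringsAsFactors = FALSE)
  for (i in seq_along(tokens)) {
    tok <- gsub("[,;:]+$", "", tokens[i])
    key <- normalize_abbrev_key(tok)
    j <- match(key, lexicon$key)
    if (!is.na(j)) {
      out[nrow(out) + 1L, ] <- list(i, tok, lexicon$kind[j],
                                    lexicon$expansion[j], lexicon$value[j],
                                    NA_real_, NA_character_)
    } else if (grepl("^pod#?\\d+$", key)) {
      q <- as.numeric(sub("^pod#?", "", key))
      out[nrow(out) + 1L, ] <- list(i, tok, "Period",
                                    sprintf("postoperative day %d", q),
                                    NA_character_, q, "day")
    }
  }
  out
}

#' Drop recognized temporal adverbs
#'
#' The i2b2-style gold standards do not annotate bare temporal adverbs
#' ("before", "often"); dropping them from recognizer output raises
#' precision without touching recall. With `drop = FALSE` this is the
#' identity.
#'
#' @param entities entity data.frame from [recognize()].
#' @param adverb_lexicon character vector of adverbs.
#' @param drop logical; when `FALSE` the input is returned unchanged.
#' @return Filtered entity data.frame.
#' @export
filter_adverbs <- function(entities, adverb_lexicon, drop = TRUE) {
  if (!drop || nrow(entities) == 0L) return(entities)
  bad <- entities$kind == "TemporalAdverb" &
    tolower(entities$text) %in% tolower(adverb_lexicon)
  out <- entities[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}
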