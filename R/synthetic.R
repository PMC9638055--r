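# Synthetic sectioned discharge summaries with gold TIMEX3 annotations.
#
# The generator emulates the structure of a de-identified discharge-summary
# corpus: HISTORY / HOSPITAL COURSE / DISCHARGE sections, admission and
# discharge reference dates, and a configurable mixture of explicit DATE
# phrases (full, written, and 2-place dates, month/weekday/holiday names),
# relative DATE phrases (quantity-unit + cue word, postoperative-day and
# day-of-life forms), DURATIONs, clock TIMEs, frequencies and clinical
# abbreviations. Every annotation's span slices its note exactly;
# bookkeeping records each phrase's family and whether it is explicit or
# relative — the ground truth the filter and evaluation tests check
# against. Generation is fully deterministic under a fixed seed.

#' Generator configuration
#'
#' The default mixture follows the type proportions of a clinical TERN
#' evaluation corpus: two thirds DATEs (roughly 65/35 explicit/relative
#' within them), a fifth DURATIONs, and small TIME/FREQUENCY shares.
#'
#' @param n_documents number of documents.
#' @param seed integer seed; fixed seed gives a byte-identical corpus.
#' @param weights named non-negative weights for phrase families
#'   `date_explicit`, `date_relative`, `duration`, `time`, `frequency`,
#'   `abbreviation`.
#' @param sentences_per_section range (length-2) of sentences per section.
#' @param p_temporal probability a sentence carries a temporal phrase.
#' @param sections section header templates.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_documents = 20L, seed = 42L,
                             weights = c(date_explicit = 0.44,
                                         date_relative = 0.23,
                                         duration = 0.19,
                                         time = 0.03,
                                         frequency = 0.06,
                                         abbreviation = 0.05),
                             sentences_per_section = c(3L, 6L),
                             p_temporal = 0.6,
                             sections = c("HISTORY OF PRESENT ILLNESS",
                                          "HOSPITAL COURSE",
                                          "DISCHARGE INSTRUCTIONS")) {
  fam <- c("date_explicit", "date_relative", "duration", "time",
           "frequency", "abbreviation")
  w <- stats::setNames(rep(0, length(fam)), fam)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) <= 0) stop("weights must be >= 0 and sum > 0")
  structure(list(n_documents = as.integer(n_documents),
                 seed = as.integer(seed), weights = w,
                 sentences_per_section = sentences_per_section,
                 p_temporal = p_temporal, sections = sections),
            class = "generator_config")
}

PLAIN_SENTENCES <- c(
  "The patient remained hemodynamically stable.",
  "Vital signs were within normal limits.",
  "She tolerated the diet well.",
  "Physical exam was unremarkable.",
  "Laboratory values were reviewed with the team.",
  "He was counseled regarding medication compliance.",
  "The wound was clean, dry and intact.",
  "No acute events occurred overnight.")

# frames: sprintf-style with one %s slot for the temporal phrase
DATE_FRAMES <- c("The patient was admitted on %s.",
                 "She was seen in clinic on %s.",
                 "He underwent the procedure on %s.",
                 "Symptoms began %s.",
                 "Follow-up is scheduled for %s.")
DUR_FRAMES <- c("Antibiotics were continued for %s.",
                "She remained afebrile for %s.",
                "He reported fatigue lasting %s.",
                "The course was completed over %s.")
TIME_FRAMES <- c("The procedure started at %s that morning.",
                 "She arrived in the unit at %s.",
                 "Rounds were completed by %s.")
FREQ_FRAMES <- c("Aspirin was administered %s.",
                 "He takes metoprolol %s.",
                 "The dressing was changed %s.",
                 "Nebulizer treatments were given %s.")

rint <- function(lo, hi) sample.int(hi - lo + 1L, 1L) + lo - 1L

make_explicit_date <- function(doc_admission) {
  d <- doc_admission + rint(-30L, 30L)
  y <- as.integer(format(d, "%Y")); m <- as.integer(format(d, "%m"))
  dy <- as.integer(format(d, "%d"))
  style <- rint(1L, 5L)
  if (style == 1L) {
    list(text = sprintf("%d/%d/%d", m, dy, y), value = format(d))
  } else if (style == 2L) {
    list(text = paste0(month.name[m], " ", dy, ", ", y),
         value = format(d))
  } else if (style == 3L) {
    # 2-place date within the admission-year fill window
    d2 <- doc_admission + rint(-60L, 60L)
    list(text = format(d2, "%m/%d"), value = format(d2))
  } else if (style == 4L) {
    list(text = sample(c("Monday", "Tuesday", "Friday", "Sunday"), 1L),
         value = "")
  } else {
    list(text = sample(c("Halloween", "Thanksgiving", "Christmas"), 1L),
         value = "")
  }
}

make_relative_date <- function() {
  n <- rint(2L, 9L)
  word <- names(WORDED_NUMBERS)[n]
  sample(list(
    sprintf("%d weeks prior to admission", rint(1L, 4L)),
    sprintf("%d days ago", n),
    "the day of admission",
    "the day prior",
    sprintf("postoperative day %s", word),
    sprintf("POD#%d", n),
    sprintf("day of life %d", n),
    sprintf("hospital day %d", rint(2L, 9L)),
    "a week ago"), 1L)[[1]]
}

make_duration <- function(approx) {
  pick <- rint(1L, 4L)
  if (pick == 1L) {
    n <- rint(2L, 9L)
    u <- sample(c("days", "weeks", "months"), 1L)
    list(text = sprintf("%d %s", n, u),
         value = iso_duration(n, singular_unit(u)), modifier = "NA")
  } else if (pick == 2L) {
    n <- rint(2L, 9L)
    list(text = sprintf("%s days", names(WORDED_NUMBERS)[n]),
         value = iso_duration(n, "day"), modifier = "NA")
  } else if (pick == 3L) {
    w <- sample(names(approx), 1L)
    u <- sample(c("days", "weeks"), 1L)
    list(text = sprintf("%s %s", w, u),
         value = iso_duration(approx[[w]], singular_unit(u)),
         modifier = "APPROX")
  } else {
    n <- sample(c(24L, 48L, 72L), 1L)
    list(text = sprintf("%d hours", n), value = iso_duration(n, "hour"),
         modifier = "NA")
  }
}

make_time <- function() {
  if (rint(1L, 2L) == 1L)
    sprintf("%d %s", rint(1L, 12L), sample(c("a.m.", "p.m."), 1L))
  else sprintf("%d:%02d", rint(1L, 23L), rint(0L, 59L))
}

make_frequency <- function() {
  sample(c("daily", "twice a day", "every 6 hours", "X4", "x 10"), 1L)
}

#' Generate a synthetic annotated corpus
#'
#' @param cfg a [generator_config()].
#' @return A list with `documents` (list of `tern_document`s) and
#'   `bookkeeping`, a data.frame recording for every gold annotation its
#'   `doc_id`, `ann_id`, phrase `family`, `ttype` and whether it is
#'   `explicit` (ground truth for the RelIV filter).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  approx <- approx_table()
  abbrev <- abbreviation_lexicon()
  fam_names <- names(cfg$weights)
  prob <- cfg$weights / sum(cfg$weights)
  documents <- vector("list", cfg$n_documents)
  book <- list()
  for (di in seq_len(cfg$n_documents)) {
    doc_id <- sprintf("synth-%03d", di)
    admission <- as.Date("2013-01-01") + rint(0L, 1095L)
    discharge <- admission + rint(3L, 21L)
    buf <- character(); cursor <- 0L
    ann <- list(); counter <- 0L
    emit <- function(s) {
      buf[[length(buf) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    add_sentence <- function() {
      family <- if (stats::runif(1) < cfg$p_temporal)
        sample(fam_names, 1L, prob = prob) else "plain"
      if (family == "plain" || cfg$weights[[family]] == 0) {
        emit(sample(PLAIN_SENTENCES, 1L))
        return()
      }
      ttype <- "DATE"; value <- ""; modifier <- "NA"; explicit <- FALSE
      if (family == "date_explicit") {
        p <- make_explicit_date(admission)
        phrase <- p$text; value <- p$value; explicit <- TRUE
        frame <- sample(DATE_FRAMES, 1L)
      } else if (family == "date_relative") {
        phrase <- make_relative_date()
        frame <- sample(DATE_FRAMES, 1L)
      } else if (family == "duration") {
        p <- make_duration(approx)
        phrase <- p$text; value <- p$value; modifier <- p$modifier
        ttype <- "DURATION"
        frame <- sample(DUR_FRAMES, 1L)
      } else if (family == "time") {
        phrase <- make_time(); ttype <- "TIME"; explicit <- TRUE
        frame <- sample(TIME_FRAMES, 1L)
      } else if (family == "frequency") {
        phrase <- make_frequency(); ttype <- "FREQUENCY"
        frame <- sample(FREQ_FRAMES, 1L)
      } else {
        i <- rint(1L, nrow(abbrev))
        phrase <- abbrev$term[i]; value <- abbrev$value[i]
        ttype <- "FREQUENCY"
        frame <- sample(FREQ_FRAMES, 1L)
      }
      pre_len <- as.integer(regexpr("%s", frame, fixed = TRUE)) - 1L
      start <- cursor + pre_len
      counter <<- counter + 1L
      ann[[counter]] <<- list(
        ann_id = sprintf("%s-T%d", doc_id, counter),
        start = start, end = start + nchar(phrase), text = phrase,
        ttype = ttype, value = value, modifier = modifier,
        family = family, explicit = explicit)
      emit(sprintf(frame, phrase))
    }
    for (sec in cfg$sections) {
      emit(paste0(sec, ":"))
      emit("\n")
      n_s <- rint(cfg$sentences_per_section[1], cfg$sentences_per_section[2])
      for (k in seq_len(n_s)) {
        add_sentence()
        emit(if (k == n_s) "\n\n" else " ")
      }
    }
    text <- paste(buf, collapse = "")
    ad <- if (counter > 0L) do.call(rbind, lapply(ann, function(a)
      data.frame(a[c("ann_id", "start", "end", "text", "ttype", "value",
                     "modifier")], stringsAsFactors = FALSE)))
    else NULL
    anns <- if (is.null(ad)) timex_annotations() else
      timex_annotations(ad$ann_id, ad$start, ad$end, ad$text, ad$ttype,
                        ad$value, ad$modifier)
    documents[[di]] <- tern_document(doc_id, text, anns,
                                     admission_date = admission,
                                     discharge_date = discharge)
    for (a in ann)
      book[[length(book) + 1L]] <- data.frame(
        doc_id = doc_id, ann_id = a$ann_id, family = a$family,
        ttype = a$ttype, explicit = a$explicit,
        stringsAsFactors = FALSE)
  }
  bookkeeping <- if (length(book)) do.call(rbind, book) else
    data.frame(doc_id = character(), ann_id = character(),
               family = character(), ttype = character(),
               explicit = logical(), stringsAsFactors = FALSE)
  rownames(bookkeeping) <- NULL
  list(documents = documents, bookkeeping = bookkeeping)
}

flip_type <- function(t) ifelse(t == "DATE", "DURATION",
                                ifelse(t == "DURATION", "DATE", t))

# produce a different but still grammatical value: dates shift one day,
# anything with a magnitude (P2D, RP12H) bumps it; returns the input
# unchanged when no safe corruption exists
corrupt_value <- function(value, ttype) {
  if (!nzchar(value)) return(value)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", value)) {
    format(as.Date(value) + 1L)
  } else if (grepl("\\d", value)) {
    n <- as.integer(regmatches(value, regexpr("\\d+", value)))
    sub("\\d+", as.character(n + 1L), value)
  } else {
    value
  }
}

#' Derive a perturbed "system run" from gold documents
#'
#' Perturbs gold annotations at the given Bernoulli rates — dropping
#' (missed), adding spurious spans (added), flipping DATE/DURATION types
#' (label errors) and corrupting normalized values (value errors) — and
#' returns both the perturbed documents and a log of every perturbation,
#' the ground truth for evaluation tests. All rates 0 reproduces gold
#' exactly.
#'
#' @param gold_docs list of gold `tern_document`s.
#' @param error_rates named rates in `[0, 1]`: `drop`, `add`, `flip`,
#'   `value`.
#' @param seed integer seed.
#' @return A list with `documents` (system-style `tern_document`s) and
#'   `log` (data.frame `doc_id`, `ann_id`, `action`).
#' @export
generate_system_run <- function(gold_docs,
                                error_rates = c(drop = 0, add = 0,
                                                flip = 0, value = 0),
                                seed = 1L) {
  rates <- c(drop = 0, add = 0, flip = 0, value = 0)
  rates[names(error_rates)] <- error_rates
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  set.seed(seed)
  log <- list()
  note <- function(doc_id, ann_id, action)
    log[[length(log) + 1L]] <<- data.frame(doc_id = doc_id,
                                           ann_id = ann_id,
                                           action = action,
                                           stringsAsFactors = FALSE)
  documents <- lapply(gold_docs, function(doc) {
    ann <- doc$annotations
    n <- nrow(ann)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (stats::runif(1) < rates["drop"]) {
        keep[i] <- FALSE
        note(doc$doc_id, ann$ann_id[i], "drop")
        next
      }
      if (ann$ttype[i] %in% c("DATE", "DURATION") &&
          stats::runif(1) < rates["flip"]) {
        ann$ttype[i] <- flip_type(ann$ttype[i])
        # a flipped duration value no longer parses as a date; clear it
        ann$value[i] <- ""
        note(doc$doc_id, ann$ann_id[i], "flip")
      } else if (nzchar(ann$value[i]) && stats::runif(1) < rates["value"]) {
        corrupted <- corrupt_value(ann$value[i], ann$ttype[i])
        if (!identical(corrupted, ann$value[i])) {
          ann$value[i] <- corrupted
          note(doc$doc_id, ann$ann_id[i], "value")
        }
      }
    }
    ann <- ann[keep, , drop = FALSE]
    n_add <- stats::rbinom(1L, max(n, 1L), rates["add"])
    if (n_add > 0L) {
      sents <- segment(doc$text)
      toks <- do.call(rbind, lapply(sents, function(s) s$tokens))
      # spurious spans must not touch any gold span (dropped ones included)
      # so every "add" stays an unmatched system annotation
      gold_ann <- doc$annotations
      free <- toks[!vapply(seq_len(nrow(toks)), function(i)
        any(overlaps(toks[i, "start"], toks[i, "end"],
                     gold_ann$start, gold_ann$end)), TRUE), , drop = FALSE]
      n_add <- min(n_add, nrow(free))
      if (n_add > 0L) {
        pick <- free[sample.int(nrow(free), n_add), , drop = FALSE]
        for (j in seq_len(n_add)) {
          aid <- sprintf("%s-ADD%d", doc$doc_id, j)
          ann <- rbind(ann, timex_annotations(
            aid, pick[j, "start"], pick[j, "end"],
            slice_text(doc$text, pick[j, "start"], pick[j, "end"]),
            sample(TIMEX_TYPES, 1L), "", "NA"))
          note(doc$doc_id, aid, "add")
        }
      }
    }
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    tern_document(doc$doc_id, doc$text, ann,
                  admission_date = doc$admission_date,
                  discharge_date = doc$discharge_date)
  })
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(doc_id = character(), ann_id = character(),
               action = character(), stringsAsFactors = FALSE)
  rownames(log_df) <- NULL
  list(documents = documents, log = log_df)
}
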