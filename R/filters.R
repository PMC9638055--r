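# Corpus filters: DD-TIMEX, RelIV-TIMEX, and gold-overlap restriction.
#
# DD-TIMEX keeps only DATE and DURATION annotations (the two types the TTD
# classifier is trained on). RelIV-TIMEX further removes every
# absolute/explicit or incomplete expression — anything with a
# digit-bearing date form, a clock time, a month or weekday name, or a
# holiday name — leaving the relative/implicit/vague phrases the
# disambiguation task targets. The overlap restriction trims a system's
# output to the annotations overlapping that relative gold set so systems
# are compared on the same phrases.

#' Lexicons for the explicit-expression test
#'
#' @param months,weekdays,holidays character vectors, matched
#'   case-insensitively.
#' @return A list of class `reliv_lexicons`.
#' @export
reliv_lexicons <- function(months = read_lexicon(lexicon_path("months.txt"))$term,
                           weekdays = read_lexicon(lexicon_path("weekdays.txt"))$term,
                           holidays = read_lexicon(lexicon_path("holidays.txt"))$term) {
  stopifnot(length(months) > 0L, length(weekdays) > 0L)
  structure(list(months = months, weekdays = weekdays,
                 holidays = holidays),
            class = "reliv_lexicons")
}

#' Filter a corpus to DATE and DURATION annotations (DD-TIMEX)
#'
#' Removes every TIME and FREQUENCY annotation; documents are retained even
#' when no annotation survives.
#'
#' @param corpus list of `tern_document`s.
#' @return The filtered corpus.
#' @export
filter_dd <- function(corpus) {
  lapply(corpus, function(doc) {
    keep <- doc$annotations$ttype %in% c("DATE", "DURATION")
    doc$annotations <- doc$annotations[keep, , drop = FALSE]
    rownames(doc$annotations) <- NULL
    doc
  })
}

#' Is an annotation absolute/explicit or incomplete?
#'
#' TRUE when the surface text carries a digit-bearing date form, full or
#' partial (`2/4/2013`, `2013-02-04`, `5/6`, a bare 4-digit year), a clock
#' time (`9 a.m.`, `14:30`), a proper month or weekday name, or a holiday
#' name. Relative quantity phrases keep their digits attached to a unit
#' word, not a date separator, so `"2 weeks prior"` is not explicit.
#'
#' @param text annotation surface text (vectorized).
#' @param lexicons a [reliv_lexicons()].
#' @return Logical vector.
#' @export
is_explicit <- function(text, lexicons = reliv_lexicons()) {
  date_form <- grepl("\\d{1,4}[/-]\\d{1,2}([/-]\\d{1,4})?", text)
  clock <- grepl("\\d{1,2}:\\d{2}", text) |
    grepl("\\d\\s?(a\\.?m\\.?|p\\.?m\\.?)\\b", text, ignore.case = TRUE)
  year_alone <- grepl("\\b(19|20)\\d{2}\\b", text)
  named <- grepl(paste0("\\b(?:",
                        paste(c(lexicons$months, lexicons$weekdays,
                                lexicons$holidays), collapse = "|"),
                        ")\\b"), text, ignore.case = TRUE, perl = TRUE)
  date_form | clock | year_alone | named
}

#' Filter a DD-TIMEX corpus to relative/implicit/vague annotations
#'
#' Removes every annotation [is_explicit()] flags; what remains is the
#' RelIV-TIMEX evaluation set. Apply [filter_dd()] first.
#'
#' @param dd_corpus DD-filtered list of `tern_document`s.
#' @param lexicons a [reliv_lexicons()].
#' @return The filtered corpus.
#' @export
filter_reliv <- function(dd_corpus, lexicons = reliv_lexicons()) {
  lapply(dd_corpus, function(doc) {
    keep <- !is_explicit(doc$annotations$text, lexicons)
    doc$annotations <- doc$annotations[keep, , drop = FALSE]
    rownames(doc$annotations) <- NULL
    doc
  })
}

#' Restrict system annotations to those overlapping RelIV gold
#'
#' Keeps every system annotation whose span overlaps at least one gold
#' annotation of the RelIV set for the same document. A gold phrase split
#' into several system phrases retains all of them.
#'
#' @param system_annotations annotation data.frame (system output for one
#'   document).
#' @param reliv_gold annotation data.frame (RelIV gold for the same
#'   document).
#' @return The retained system annotations.
#' @export
restrict_to_gold_overlap <- function(system_annotations, reliv_gold) {
  if (nrow(system_annotations) == 0L) return(system_annotations)
  keep <- vapply(seq_len(nrow(system_annotations)), function(i)
    any(overlaps(system_annotations$start[i], system_annotations$end[i],
                 reliv_gold$start, reliv_gold$end)), TRUE)
  out <- system_annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
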