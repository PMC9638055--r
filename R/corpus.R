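# Corpus containers and standoff I/O.
#
# A document is a clinical note plus its standoff TIMEX3 annotations. All
# character offsets in this package are 0-based, half-open [start, end);
# the surface text of an annotation must equal the slice of the note text
# at its span. Annotations live in a plain data.frame so the usual R
# verbs (subset, order, merge) apply directly.

TIMEX_TYPES <- c("DATE", "TIME", "DURATION", "FREQUENCY")

#' Construct a TIMEX3 annotation table
#'
#' Builds the annotation data.frame used throughout the package. Offsets are
#' 0-based, half-open character positions into the note text.
#'
#' @param ann_id character vector of annotation ids.
#' @param start,end integer vectors of character offsets (0-based, half-open).
#' @param text character vector of surface strings.
#' @param ttype TimeML type, one of `DATE`, `TIME`, `DURATION`, `FREQUENCY`.
#' @param value normalized ISO-8601 value, or `""` when not normalized.
#' @param modifier annotation modifier, e.g. `"NA"` or `"APPROX"`.
#' @return A data.frame with one row per annotation.
#' @export
timex_annotations <- function(ann_id = character(), start = integer(),
                              end = integer(), text = character(),
                              ttype = character(), value = character(),
                              modifier = character()) {
  n <- length(ann_id)
  if (length(value) == 0L && n > 0L) value <- rep("", n)
  if (length(modifier) == 0L && n > 0L) modifier <- rep("NA", n)
  data.frame(
    ann_id = as.character(ann_id),
    start = as.integer(start),
    end = as.integer(end),
    text = as.character(text),
    ttype = as.character(ttype),
    value = as.character(value),
    modifier = as.character(modifier),
    stringsAsFactors = FALSE
  )
}

#' Construct a document
#'
#' A document bundles a note's text with its TIMEX3 annotations and optional
#' reference dates (admission/discharge), the anchors a discharge summary is
#' written against.
#'
#' @param doc_id document identifier.
#' @param text the full note text (UTF-8).
#' @param annotations annotation data.frame as built by [timex_annotations()].
#' @param admission_date,discharge_date optional `Date`s (or `NA`).
#' @param validate check invariants via [validate_document()].
#' @return An object of class `tern_document`.
#' @export
tern_document <- function(doc_id, text, annotations = timex_annotations(),
                          admission_date = NA, discharge_date = NA,
                          validate = TRUE) {
  doc <- structure(
    list(
      doc_id = as.character(doc_id),
      text = as.character(text),
      admission_date = as_date_or_na(admission_date),
      discharge_date = as_date_or_na(discharge_date),
      annotations = annotations
    ),
    class = "tern_document"
  )
  if (validate) validate_document(doc)
  doc
}

as_date_or_na <- function(x) {
  if (length(x) != 1L || is.na(x)) return(as.Date(NA))
  as.Date(x)
}

#' @export
print.tern_document <- function(x, ...) {
  cat(sprintf("<tern_document> %s: %d chars, %d annotations\n",
              x$doc_id, nchar(x$text), nrow(x$annotations)))
  if (!is.na(x$admission_date))
    cat("  admission:", format(x$admission_date), "\n")
  if (!is.na(x$discharge_date))
    cat("  discharge:", format(x$discharge_date), "\n")
  invisible(x)
}

# slice of `text` at 0-based half-open [start, end)
slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

is_iso_datetime <- function(x) {
  grepl("^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}(:\\d{2})?)?)?)?$", x)
}

is_iso_duration <- function(x) {
  grepl("^P(?=.)(\\d+Y)?(\\d+M)?(\\d+W)?(\\d+D)?(T(?=.)(\\d+H)?(\\d+M)?)?$",
        x, perl = TRUE)
}

#' Validate a document's invariants
#'
#' Checks that every annotation span lies within the note, that spans are
#' proper (`start < end`), that each annotation's surface text equals the note
#' slice at its span, that types are TimeML TIMEX3 types, and that nonempty
#' values obey the ISO-8601 grammar for their type (calendar date/time for
#' DATE and TIME, `PnYnMnWnD[TnHnM]` for DURATION).
#'
#' @param doc a `tern_document`.
#' @return `doc`, invisibly; stops with an informative error on violation.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "tern_document"))
  ann <- doc$annotations
  n <- nchar(doc$text)
  for (i in seq_len(nrow(ann))) {
    id <- ann$ann_id[i]
    if (ann$start[i] < 0L || ann$end[i] > n)
      stop(sprintf("annotation %s: span [%d,%d) outside document [0,%d)",
                   id, ann$start[i], ann$end[i], n))
    if (ann$start[i] >= ann$end[i])
      stop(sprintf("annotation %s: empty or inverted span", id))
    got <- slice_text(doc$text, ann$start[i], ann$end[i])
    if (!identical(got, ann$text[i]))
      stop(sprintf(
        "annotation %s: surface text %s does not match note slice %s",
        id, dQuote(ann$text[i]), dQuote(got)))
    if (!ann$ttype[i] %in% TIMEX_TYPES)
      stop(sprintf("annotation %s: unknown type %s", id, dQuote(ann$ttype[i])))
    val <- ann$value[i]
    if (nzchar(val)) {
      if (ann$ttype[i] %in% c("DATE", "TIME") && !is_iso_datetime(val))
        stop(sprintf("annotation %s: value %s is not an ISO-8601 date/time",
                     id, dQuote(val)))
      if (ann$ttype[i] == "DURATION" && !is_iso_duration(val))
        stop(sprintf("annotation %s: value %s is not an ISO-8601 duration",
                     id, dQuote(val)))
    }
  }
  invisible(doc)
}

#' Read standoff TIMEX3 XML
#'
#' Parses one standoff annotation file into a document. The dialect is one
#' `<annotations>` root (attributes `doc_id`, `admission`, `discharge`) with
#' one `<TIMEX3 id start end text type val mod/>` element per annotation,
#' offsets 0-based half-open. Surface-text consistency against `note_text` is
#' always validated; a mismatch is an error naming the offending annotation.
#'
#' @param xml_text the XML as a single string (or an `xml2` document).
#' @param note_text the full note text the offsets refer to.
#' @return A `tern_document`.
#' @export
read_standoff_xml <- function(xml_text, note_text) {
  x <- if (inherits(xml_text, "xml_document")) xml_text else
    xml2::read_xml(xml_text)
  root <- xml2::xml_root(x)
  doc_id <- xml2::xml_attr(root, "doc_id")
  if (is.na(doc_id)) doc_id <- "doc"
  adm <- xml2::xml_attr(root, "admission")
  dis <- xml2::xml_attr(root, "discharge")
  nodes <- xml2::xml_find_all(x, ".//TIMEX3")
  att <- function(a, default = NA_character_) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), default, v)
  }
  ann <- timex_annotations(
    ann_id = att("id"),
    start = as.integer(att("start")),
    end = as.integer(att("end")),
    text = att("text"),
    ttype = att("type"),
    value = att("val", ""),
    modifier = att("mod", "NA")
  )
  tern_document(
    doc_id, note_text, ann,
    admission_date = if (is.na(adm)) NA else as.Date(adm),
    discharge_date = if (is.na(dis)) NA else as.Date(dis)
  )
}

#' Write standoff TIMEX3 XML
#'
#' Serializes a document's annotations to the standoff dialect read by
#' [read_standoff_xml()]. Invariants are re-checked first, so an invalid
#' document is refused rather than written. `read_standoff_xml()` of the
#' result, together with the note text, reproduces the document exactly.
#'
#' @param doc a valid `tern_document`.
#' @return The XML as a single character string.
#' @export
write_standoff_xml <- function(doc) {
  validate_document(doc)
  root <- xml2::xml_new_root("annotations", doc_id = doc$doc_id)
  if (!is.na(doc$admission_date))
    xml2::xml_set_attr(root, "admission", format(doc$admission_date))
  if (!is.na(doc$discharge_date))
    xml2::xml_set_attr(root, "discharge", format(doc$discharge_date))
  ann <- doc$annotations
  for (i in seq_len(nrow(ann))) {
    xml2::xml_add_child(
      root, "TIMEX3",
      id = ann$ann_id[i],
      start = as.character(ann$start[i]),
      end = as.character(ann$end[i]),
      text = ann$text[i],
      type = ann$ttype[i],
      val = ann$value[i],
      mod = ann$modifier[i]
    )
  }
  as.character(root)
}

#' Read a note + annotation file pair from disk
#'
#' @param txt_path path to the UTF-8 note text file.
#' @param xml_path path to the standoff XML file.
#' @return A `tern_document`.
#' @export
read_document <- function(txt_path, xml_path) {
  note <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  read_standoff_xml(paste(readLines(xml_path, encoding = "UTF-8",
                                    warn = FALSE), collapse = "\n"),
                    note)
}

#' Write a document's note and annotations to disk
#'
#' @param doc a `tern_document`.
#' @param txt_path,xml_path output paths.
#' @return `doc`, invisibly.
#' @export
write_document <- function(doc, txt_path, xml_path) {
  writeLines(doc$text, txt_path, useBytes = TRUE)
  writeLines(write_standoff_xml(doc), xml_path, useBytes = TRUE)
  invisible(doc)
}

# Abbreviation guard for the sentence splitter: a token equal to one of these
# never ends a sentence even though it ends in a period.
SENTENCE_GUARD <- c(
  "dr.", "mr.", "mrs.", "ms.", "st.", "vs.", "e.g.", "i.e.", "approx.",
  "a.m.", "p.m.", "b.i.d.", "t.i.d.", "q.d.", "q.i.d.", "q.h.s.", "p.r.n."
)

#' Segment text into sentences and whitespace tokens
#'
#' Deterministic rule-based segmentation: tokens are maximal non-whitespace
#' runs; a sentence boundary falls between two tokens when the first ends in
#' `.`, `?` or `!` (and is not on the abbreviation guard list) and the next
#' starts with a capital letter or digit, or when a blank line separates them.
#' Punctuation is never split off tokens.
#'
#' @param text a single string.
#' @return A list of sentences, each a list with 0-based half-open `start`,
#'   `end` offsets and a two-column `tokens` matrix of token spans.
#' @export
segment <- function(text) {
  stopifnot(length(text) == 1L)
  if (!nzchar(text)) return(list())
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(list())
  tok_start <- as.integer(m) - 1L
  tok_end <- tok_start + attr(m, "match.length")
  words <- slice_text(text, tok_start, tok_end)
  n <- length(words)
  boundary_after <- logical(n)
  for (i in seq_len(n - 1L)) {
    gap <- slice_text(text, tok_end[i], tok_start[i + 1L])
    if (grepl("\n[ \t\r]*\n", gap)) {
      boundary_after[i] <- TRUE
      next
    }
    if (grepl("[.?!]['\")]*$", words[i]) &&
        !(tolower(words[i]) %in% SENTENCE_GUARD) &&
        grepl("^['\"(]*[A-Z0-9]", words[i + 1L])) {
      boundary_after[i] <- TRUE
    }
  }
  boundary_after[n] <- TRUE
  sentences <- list()
  first <- 1L
  for (i in seq_len(n)) {
    if (boundary_after[i]) {
      idx <- first:i
      sentences[[length(sentences) + 1L]] <- list(
        start = tok_start[first],
        end = tok_end[i],
        tokens = cbind(start = tok_start[idx], end = tok_end[idx])
      )
      first <- i + 1L
    }
  }
  sentences
}

#' Extract token surface strings for a sentence
#'
#' @param text the full note text.
#' @param sentence one element of the list returned by [segment()].
#' @return Character vector of token strings.
#' @export
sentence_tokens <- function(text, sentence) {
  slice_text(text, sentence$tokens[, "start"], sentence$tokens[, "end"])
}
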