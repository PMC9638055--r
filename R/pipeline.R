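# End-to-end wiring: recognize -> convert (-> TTD) -> evaluate.
#
# The three evaluation phases mirror how a disambiguation module is
# assessed: (1) gold-timex — classify the gold relative phrases directly,
# no recognition involved; (2) system-timex — run recognition, restrict
# system output to spans overlapping the relative gold subset, score the
# DATE/DURATION verdicts with na-as-FN class metrics; (3) end2end — score
# the complete system output against the full gold standard with span
# metrics plus type/value accuracy, optionally after removing FREQUENCY
# annotations from both sides.

# locate each span's sentence and phrase token indices; embed each needed
# sentence once
doc_phrase_features <- function(doc, starts, ends, provider,
                                variant = c("PhraseOnly", "PhraseContext")) {
  variant <- match.arg(variant)
  if (length(starts) == 0L) return(list())
  sents <- segment(doc$text)
  sent_of <- integer(length(starts))
  idx_of <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    si <- which(vapply(sents, function(s)
      starts[i] < s$end && ends[i] > s$start, TRUE))[1]
    if (is.na(si))
      stop(sprintf("span [%d,%d) lies outside every sentence",
                   starts[i], ends[i]))
    toks <- sents[[si]]$tokens
    hit <- which(overlaps(toks[, "start"], toks[, "end"],
                          starts[i], ends[i]))
    if (length(hit) == 0L)
      stop(sprintf("span [%d,%d) covers no token", starts[i], ends[i]))
    sent_of[i] <- si
    idx_of[[i]] <- hit
  }
  needed <- sort(unique(sent_of))
  batches <- embed_sentences(
    provider, lapply(sents[needed], function(s)
      sentence_tokens(doc$text, s)))
  token_vecs <- lapply(batches, resolve_tokens)
  names(token_vecs) <- as.character(needed)
  lapply(seq_along(starts), function(i) {
    tv <- token_vecs[[as.character(sent_of[i])]]
    if (variant == "PhraseOnly") phrase_only(tv, idx_of[[i]])
    else phrase_context(tv, idx_of[[i]], nrow(tv))
  })
}

#' Build TTD training data from an annotated corpus
#'
#' Filters the corpus to DATE/DURATION annotations (the DD subset used for
#' training — explicit phrases included so the model sees more data) and
#' builds one phrase feature per annotation with the given provider.
#'
#' @param corpus list of `tern_document`s with gold annotations.
#' @param provider a `tern_provider`.
#' @param variant feature variant.
#' @return A list with `features` (list of `phrase_feature`) and `labels`
#'   (character vector of DATE/DURATION).
#' @export
ttd_training_data <- function(corpus, provider,
                              variant = c("PhraseOnly", "PhraseContext")) {
  variant <- match.arg(variant)
  dd <- filter_dd(corpus)
  features <- list(); labels <- character()
  for (doc in dd) {
    ann <- doc$annotations
    if (nrow(ann) == 0L) next
    fs <- doc_phrase_features(doc, ann$start, ann$end, provider, variant)
    features <- c(features, fs)
    labels <- c(labels, ann$ttype)
  }
  list(features = features, labels = labels)
}

#' Annotate one document end to end
#'
#' Runs the recognizer, then converts every entity to a TIMEX3 annotation.
#' When the conversion config carries a TTD model, phrase features are
#' built for each Period/Calendar-Interval entity with the supplied
#' provider and the entity is routed through the model; otherwise the naive
#' all-DURATION rule applies.
#'
#' @param doc a `tern_document` (gold annotations, if any, are ignored).
#' @param rec_config a [recognizer_config()].
#' @param conv_config a [conversion_config()].
#' @param provider a `tern_provider`; required when a TTD model is
#'   attached.
#' @param variant feature variant; must match the model's.
#' @return A `tern_document` carrying the system annotations.
#' @export
annotate_document <- function(doc, rec_config = recognizer_config(),
                              conv_config = conversion_config(),
                              provider = NULL,
                              variant = c("PhraseOnly", "PhraseContext")) {
  variant <- match.arg(variant)
  ents <- recognize(doc$text, rec_config)
  features <- vector("list", nrow(ents))
  if (!is.null(conv_config$ttd_model)) {
    if (is.null(provider))
      stop("a TTD-enabled run needs an embedding provider")
    routed <- which(ents$kind %in% c("Period", "CalendarInterval"))
    if (length(routed) > 0L)
      features[routed] <- doc_phrase_features(
        doc, ents$start[routed], ents$end[routed], provider, variant)
  }
  rows <- lapply(seq_len(nrow(ents)), function(i)
    scate_to_timeml(ents[i, , drop = FALSE], doc, conv_config,
                    features[[i]]))
  ann <- if (length(rows)) do.call(rbind, rows) else timex_annotations()
  if (nrow(ann) > 0L)
    ann$ann_id <- sprintf("%s-S%d", doc$doc_id, seq_len(nrow(ann)))
  tern_document(doc$doc_id, doc$text, ann,
                admission_date = doc$admission_date,
                discharge_date = doc$discharge_date)
}

#' Annotate a corpus
#'
#' @inheritParams annotate_document
#' @param corpus list of `tern_document`s.
#' @return List of annotated `tern_document`s.
#' @export
annotate_corpus <- function(corpus, rec_config = recognizer_config(),
                            conv_config = conversion_config(),
                            provider = NULL,
                            variant = c("PhraseOnly", "PhraseContext")) {
  variant <- match.arg(variant)
  lapply(corpus, annotate_document, rec_config = rec_config,
         conv_config = conv_config, provider = provider,
         variant = variant)
}

end2end_metrics <- function(gold_docs, system_docs,
                            drop_frequency = FALSE) {
  tp <- fp <- fn <- 0L
  type_ok <- type_tot <- value_ok <- 0L
  for (i in seq_along(gold_docs)) {
    g <- gold_docs[[i]]$annotations
    s <- system_docs[[i]]$annotations
    if (drop_frequency) {
      g <- g[g$ttype != "FREQUENCY", , drop = FALSE]
      s <- s[s$ttype != "FREQUENCY", , drop = FALSE]
    }
    m <- match_pairs(g, s)
    tp <- tp + nrow(m$pairs)
    fp <- fp + length(m$added)
    fn <- fn + length(m$missed)
    agree <- g$ttype[m$pairs$gold_idx] == s$ttype[m$pairs$system_idx]
    type_ok <- type_ok + sum(agree)
    type_tot <- type_tot + nrow(m$pairs)
    value_ok <- value_ok +
      sum(canonical_value(g$value[m$pairs$gold_idx]) ==
            canonical_value(s$value[m$pairs$system_idx]))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f,
    type_accuracy = if (type_tot > 0) type_ok / type_tot else 0,
    value_accuracy = if (type_tot > 0) value_ok / type_tot else 0)
}

#' Run one evaluation phase
#'
#' * `gold-timex`: classify the gold RelIV phrases directly with the TTD
#'   model (no recognition); returns the 2x3 confusion (na column empty)
#'   and class metrics.
#' * `system-timex`: restrict each document's system annotations to those
#'   overlapping the RelIV gold subset, then score DATE/DURATION verdicts
#'   with na-as-FN class metrics.
#' * `end2end`: span precision/recall/F1 over the complete output plus
#'   type and value accuracy over matched pairs; set `drop_frequency` to
#'   re-score with FREQUENCY annotations removed from both sides.
#'
#' @param phase one of `"gold-timex"`, `"system-timex"`, `"end2end"`.
#' @param gold_docs list of gold `tern_document`s (full corpus; the RelIV
#'   subset is derived internally where needed).
#' @param system_docs list of system-annotated documents (phases 2-3).
#' @param model a fitted [ttd_svm()] (phase 1).
#' @param provider a `tern_provider` (phase 1).
#' @param variant feature variant (phase 1).
#' @param lexicons a [reliv_lexicons()].
#' @param drop_frequency phase-3 FREQUENCY-removed re-scoring.
#' @return A list with the phase's `confusion`/`metrics` (phases 1-2) or a
#'   named metric vector (phase 3).
#' @export
run_phase <- function(phase = c("gold-timex", "system-timex", "end2end"),
                      gold_docs, system_docs = NULL, model = NULL,
                      provider = NULL,
                      variant = c("PhraseOnly", "PhraseContext"),
                      lexicons = reliv_lexicons(),
                      drop_frequency = FALSE) {
  phase <- match.arg(phase)
  variant <- match.arg(variant)
  reliv <- filter_reliv(filter_dd(gold_docs), lexicons)
  if (phase == "gold-timex") {
    if (is.null(model) || is.null(provider))
      stop("phase gold-timex needs a TTD model and a provider")
    cm <- confusion_matrix(c(0, 0, 0), c(0, 0, 0))
    for (doc in reliv) {
      ann <- doc$annotations
      if (nrow(ann) == 0L) next
      fs <- doc_phrase_features(doc, ann$start, ann$end, provider,
                                variant)
      pred <- vapply(fs, function(f) predict_type(model, f), "")
      for (i in seq_len(nrow(ann)))
        cm[ann$ttype[i], pred[i]] <- cm[ann$ttype[i], pred[i]] + 1L
    }
    list(confusion = cm, metrics = class_metrics(cm))
  } else if (phase == "system-timex") {
    if (is.null(system_docs))
      stop("phase system-timex needs system documents")
    cm <- confusion_matrix(c(0, 0, 0), c(0, 0, 0))
    for (i in seq_along(reliv)) {
      g <- reliv[[i]]$annotations
      s <- restrict_to_gold_overlap(system_docs[[i]]$annotations, g)
      cm <- cm + type_confusion(g, s)
    }
    list(confusion = cm, metrics = class_metrics(cm))
  } else {
    if (is.null(system_docs))
      stop("phase end2end needs system documents")
    end2end_metrics(gold_docs, system_docs, drop_frequency)
  }
}
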