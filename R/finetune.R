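# Temporal fine-tuning datasets and token metrics.
#
# Two dataset builders feed the temporal fine-tuning tasks: a binary
# sentence task (does the sentence contain temporal information?) and a
# Seq2Seq token task under either the BIO scheme (9 labels: B-/I- per
# TIMEX3 type plus O) or the Ttype scheme (5 labels: the type or O).
# Token metrics exclude the dominant O label and weight the remaining
# labels by gold support. Fine-tuning itself is a harness contract
# exercised at tiny scale, not a transformer training run.

#' Label scheme for token classification
#'
#' @param name `"BIO"` (B-/I- per TIMEX3 type + O, 9 labels) or `"Ttype"`
#'   (the 4 types + O, 5 labels).
#' @return A list with `name` and the ordered `labels` vector.
#' @export
label_scheme <- function(name = c("BIO", "Ttype")) {
  name <- match.arg(name)
  types <- tolower(TIMEX_TYPES)
  labels <- if (name == "BIO")
    c(as.vector(rbind(paste0("B-", types), paste0("I-", types))), "O")
  else c(types, "O")
  structure(list(name = name, labels = labels), class = "label_scheme")
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

#' Build the binary sentence-classification dataset
#'
#' One row per sentence over all documents; label 1 when at least one gold
#' annotation overlaps the sentence span, else 0.
#'
#' @param corpus list of `tern_document`s.
#' @return data.frame with `doc_id`, `sentence` (text) and `label`.
#' @export
make_binary_dataset <- function(corpus) {
  rows <- lapply(corpus, function(doc) {
    sents <- segment(doc$text)
    ann <- doc$annotations
    data.frame(
      doc_id = rep(doc$doc_id, length(sents)),
      sentence = vapply(sents, function(s)
        slice_text(doc$text, s$start, s$end), ""),
      label = vapply(sents, function(s)
        as.integer(any(overlaps(ann$start, ann$end, s$start, s$end))),
        0L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build the Seq2Seq token-classification dataset
#'
#' Labels each whitespace token of each sentence: a token overlapping a gold
#' annotation is inside it. Under BIO the annotation's first token gets
#' `B-<type>` and the rest `I-<type>`; under Ttype every annotation token
#' gets the bare type. Overlapping gold annotations (malformed but possible)
#' are resolved longest-first with a warning.
#'
#' @param corpus list of `tern_document`s.
#' @param scheme a [label_scheme()].
#' @return A list with one element per sentence: `doc_id`, `tokens`
#'   (character) and `labels` (character, same length).
#' @export
make_token_dataset <- function(corpus, scheme = label_scheme("BIO")) {
  stopifnot(inherits(scheme, "label_scheme"))
  out <- list()
  for (doc in corpus) {
    ann <- doc$annotations
    if (nrow(ann) > 1L) {
      ol <- outer(seq_len(nrow(ann)), seq_len(nrow(ann)), function(i, j)
        i < j & overlaps(ann$start[i], ann$end[i], ann$start[j], ann$end[j]))
      if (any(ol)) {
        warning("overlapping gold annotations in ", doc$doc_id,
                "; longest wins token ownership")
        ann <- ann[order(ann$end - ann$start, decreasing = TRUE), ,
                   drop = FALSE]
      }
    }
    for (s in segment(doc$text)) {
      toks <- s$tokens
      n <- nrow(toks)
      labels <- rep("O", n)
      owner <- rep(NA_integer_, n)
      for (a in seq_len(nrow(ann))) {
        hit <- which(overlaps(toks[, "start"], toks[, "end"],
                              ann$start[a], ann$end[a]) & is.na(owner))
        owner[hit] <- a
        if (length(hit) == 0L) next
        ty <- tolower(ann$ttype[a])
        if (scheme$name == "BIO") {
          labels[hit[1]] <- paste0("B-", ty)
          if (length(hit) > 1L) labels[hit[-1]] <- paste0("I-", ty)
        } else {
          labels[hit] <- ty
        }
      }
      out[[length(out) + 1L]] <- list(
        doc_id = doc$doc_id,
        tokens = sentence_tokens(doc$text, s),
        labels = labels)
    }
  }
  out
}

#' Token-classification metrics with the O label excluded
#'
#' Per-label precision, recall and F1 over the temporal labels only (the
#' dominant O label is excluded from the averages), plus the gold-support
#' weighted average across those labels.
#'
#' @param gold_labels,predicted_labels character vectors of equal length.
#' @param scheme a [label_scheme()] fixing the label universe.
#' @return A list: `per_label` data.frame (`label`, `support`, `precision`,
#'   `recall`, `f1`) and `weighted` named vector.
#' @export
token_metrics <- function(gold_labels, predicted_labels,
                          scheme = label_scheme("BIO")) {
  if (length(gold_labels) != length(predicted_labels))
    stop("gold and predicted label vectors differ in length")
  labs <- setdiff(scheme$labels, "O")
  per <- data.frame(label = labs, support = 0L, precision = 0,
                    recall = 0, f1 = 0, stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    l <- labs[i]
    tp <- sum(gold_labels == l & predicted_labels == l)
    fp <- sum(gold_labels != l & predicted_labels == l)
    fn <- sum(gold_labels == l & predicted_labels != l)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    per[i, c("support", "precision", "recall", "f1")] <-
      list(tp + fn, p, r, f)
  }
  w <- per$support
  weighted <- if (sum(w) > 0)
    c(precision = sum(per$precision * w) / sum(w),
      recall = sum(per$recall * w) / sum(w),
      f1 = sum(per$f1 * w) / sum(w))
  else c(precision = 0, recall = 0, f1 = 0)
  list(per_label = per, weighted = weighted)
}

#' Write a token dataset in CoNLL style
#'
#' Tab-separated token/label pairs, one token per line, sentences separated
#' by blank lines.
#'
#' @param dataset output of [make_token_dataset()].
#' @param path output file.
#' @export
write_conll <- function(dataset, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in dataset) {
    writeLines(paste(s$tokens, s$labels, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write the binary sentence dataset
#'
#' Two tab-separated columns: sentence text and 0/1 label.
#'
#' @param dataset output of [make_binary_dataset()].
#' @param path output file.
#' @export
write_sentence_dataset <- function(dataset, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  # sentences spanning line breaks are flattened so each row is one line
  flat <- gsub("[\r\n]+", " ", dataset$sentence)
  writeLines(paste(flat, dataset$label, sep = "\t"), con)
  invisible(path)
}

# order-insensitive dataset fingerprint used to derive the tuned provider's
# seed
dataset_hash <- function(dataset) {
  if (is.data.frame(dataset)) {
    parts <- paste(dataset$sentence, dataset$label)
  } else {
    parts <- vapply(dataset, function(s)
      paste(paste(s$tokens, s$labels, sep = "/"), collapse = " "), "")
  }
  sum(vapply(parts, string_hash, 0L) %% 1000003) %% 1000003
}

#' Fine-tuning harness (contract)
#'
#' The fine-tuning interface the pipeline composes: `fit(dataset, base
#' provider, epochs, seed) -> provider`. At package scale this is a contract
#' stub — it returns a new deterministic mock provider whose seed mixes the
#' base provider's seed, the epoch count, the caller's seed and a hash of
#' the dataset, so "fine-tuned" embeddings differ from the base model's and
#' are reproducible. Sequential fine-tuning (binary then Seq2Seq) is plain
#' composition: call this twice, chaining the returned provider. Training a
#' real transformer is out of scope; swap in a real provider implementing
#' [embed_sentences()] to do so.
#'
#' @param dataset a binary or token dataset.
#' @param base_provider the provider to start from.
#' @param epochs number of epochs (part of the derived seed only).
#' @param seed integer seed.
#' @return A new `tern_provider` with the same shape parameters.
#' @export
finetune_provider <- function(dataset, base_provider, epochs = 1L,
                              seed = 1L) {
  stopifnot(inherits(base_provider, "tern_provider"))
  derived <- (base_provider$seed * 33 + epochs * 7 + seed * 17 +
                dataset_hash(dataset)) %% 2147480000
  mock_provider(seed = derived,
                hidden_size = base_provider$hidden_size,
                layers = base_provider$layers)
}
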