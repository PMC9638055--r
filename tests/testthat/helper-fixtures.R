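# Shared fixtures: tiny hand-built documents and cached synthetic corpora.

make_doc <- function(text, starts = integer(), ends = integer(),
                     ttypes = character(), values = NULL, ids = NULL,
                     doc_id = "t1", admission = NA, discharge = NA) {
  n <- length(starts)
  ann <- timex_annotations(
    ann_id = if (is.null(ids)) sprintf("T%d", seq_len(n)) else ids,
    start = starts, end = ends,
    text = if (n == 0L) character() else substring(text, starts + 1L, ends),
    ttype = ttypes,
    value = if (is.null(values)) rep("", n) else values,
    modifier = rep("NA", n))
  tern_document(doc_id, text, ann, admission_date = admission,
                discharge_date = discharge)
}

# memoised synthetic corpora so repeated tests do not regenerate
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(n_documents, seed, ...) {
  key <- paste0("c", n_documents, "_", seed)
  if (is.null(.corpus_cache[[key]]))
    .corpus_cache[[key]] <- generate_corpus(
      generator_config(n_documents = n_documents, seed = seed, ...))
  .corpus_cache[[key]]
}

# small provider for feature tests (keeps embedding work cheap)
small_provider <- function(seed = 5L) {
  mock_provider(seed = seed, hidden_size = 16L, layers = 6L)
}

# hand-built subword batch with explicit values (layers x subwords x hidden)
toy_batch <- function(emb, token_of_subword,
                      subwords = paste0("s", seq_along(token_of_subword))) {
  list(subwords = subwords, token_of_subword = token_of_subword, emb = emb)
}

# independent oracle for class-based metrics: expand the confusion matrix
# into (gold, verdict) instances and tally per instance
oracle_class_metrics <- function(cm) {
  gold <- c(rep("DATE", sum(cm["DATE", ])),
            rep("DURATION", sum(cm["DURATION", ])))
  verdict <- c(rep(colnames(cm), cm["DATE", ]),
               rep(colnames(cm), cm["DURATION", ]))
  out <- list()
  for (cls in c("DATE", "DURATION")) {
    tp <- sum(gold == cls & verdict == cls)
    fp <- sum(gold != cls & verdict == cls)
    fn <- sum(gold == cls & verdict != cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[cls]] <- c(p = p, r = r, f = f, w = sum(gold == cls))
  }
  w <- c(out$DATE["w"], out$DURATION["w"])
  list(
    weighted = c(
      precision = sum(c(out$DATE["p"], out$DURATION["p"]) * w) / sum(w),
      recall = sum(c(out$DATE["r"], out$DURATION["r"]) * w) / sum(w),
      f1 = sum(c(out$DATE["f"], out$DURATION["f"]) * w) / sum(w)),
    accuracy = {
      matched <- verdict != "na"
      if (any(matched)) mean(gold[matched] == verdict[matched]) else 0
    })
}

# weighted metrics for an all-DURATION predictor on a labelled set
all_duration_baseline <- function(labels) {
  cm <- confusion_matrix(
    c(0, sum(labels == "DATE"), 0),
    c(0, sum(labels == "DURATION"), 0))
  class_metrics(cm)$weighted
}
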