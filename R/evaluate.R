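# Evaluation: span matching, class-based metrics, error analysis.
#
# Matching is lenient: any character-span overlap between a gold and a
# system annotation counts, resolved greedily one-to-one by maximal
# overlap. Span-based precision/recall/F1 score the matching itself;
# class-based metrics score the DATE/DURATION type verdicts of matched
# pairs, with unmatched gold ("na") counted as false negatives for its
# class and system-only annotations excluded. Summaries across the two
# classes are weighted by gold support. Confidence intervals come from a
# percentile bootstrap over documents.

#' Pairwise lenient span matching
#'
#' Greedy one-to-one matching between gold and system annotations of one
#' document by maximal character overlap; ties break to the earliest system
#' start, then the earliest gold start. Unmatched gold annotations are
#' "missed", unmatched system annotations "added".
#'
#' @param gold,system annotation data.frames ([timex_annotations()]).
#' @return A `match_result`: `pairs` (data.frame `gold_idx`, `system_idx`,
#'   `overlap`), `missed` and `added` index vectors.
#' @export
match_pairs <- function(gold, system) {
  ng <- nrow(gold); ns <- nrow(system)
  cand <- NULL
  if (ng > 0L && ns > 0L) {
    grid <- expand.grid(gold_idx = seq_len(ng), system_idx = seq_len(ns))
    ov <- pmin(gold$end[grid$gold_idx], system$end[grid$system_idx]) -
      pmax(gold$start[grid$gold_idx], system$start[grid$system_idx])
    cand <- grid[ov > 0L, , drop = FALSE]
    cand$overlap <- ov[ov > 0L]
  }
  pairs <- data.frame(gold_idx = integer(), system_idx = integer(),
                      overlap = integer())
  if (!is.null(cand) && nrow(cand) > 0L) {
    cand <- cand[order(-cand$overlap, system$start[cand$system_idx],
                       gold$start[cand$gold_idx]), , drop = FALSE]
    g_used <- logical(ng); s_used <- logical(ns)
    for (i in seq_len(nrow(cand))) {
      g <- cand$gold_idx[i]; s <- cand$system_idx[i]
      if (!g_used[g] && !s_used[s]) {
        g_used[g] <- TRUE; s_used[s] <- TRUE
        pairs[nrow(pairs) + 1L, ] <- list(g, s, cand$overlap[i])
      }
    }
  }
  structure(list(
    pairs = pairs,
    missed = setdiff(seq_len(ng), pairs$gold_idx),
    added = setdiff(seq_len(ns), pairs$system_idx)
  ), class = "match_result")
}

#' Span-based precision, recall and F1
#'
#' TP = matched pairs, FP = added, FN = missed; an empty denominator gives
#' 0 by convention.
#'
#' @param match a [match_pairs()] result.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
span_prf <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$added)
  fn <- length(match$missed)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Build a DATE/DURATION type confusion matrix with an na column
#'
#' Rows are gold types, columns the system verdict for the matched pair;
#' gold annotations with no overlapping system annotation land in `na`.
#' Matched system annotations typed neither DATE nor DURATION also count as
#' `na` (no usable verdict). System-only annotations are excluded.
#'
#' @param gold,system annotation data.frames for one document (or
#'   concatenated with distinct spans).
#' @param match optional precomputed [match_pairs()] result.
#' @return A 2x3 integer matrix, rows `DATE`/`DURATION`, columns
#'   `DATE`/`DURATION`/`na`.
#' @export
type_confusion <- function(gold, system, match = match_pairs(gold, system)) {
  cm <- confusion_matrix(c(0, 0, 0), c(0, 0, 0))
  sys_of_gold <- rep(NA_integer_, nrow(gold))
  sys_of_gold[match$pairs$gold_idx] <- match$pairs$system_idx
  for (g in seq_len(nrow(gold))) {
    gt <- gold$ttype[g]
    if (!gt %in% rownames(cm)) next
    s <- sys_of_gold[g]
    verdict <- if (is.na(s)) "na" else system$ttype[s]
    if (!verdict %in% colnames(cm)) verdict <- "na"
    cm[gt, verdict] <- cm[gt, verdict] + 1L
  }
  cm
}

#' Confusion matrix from raw counts
#'
#' @param date_row,duration_row length-3 count vectors: predicted DATE,
#'   predicted DURATION, na (unmatched), for gold DATE and gold DURATION
#'   rows respectively.
#' @return A 2x3 matrix with the package's dimnames.
#' @export
confusion_matrix <- function(date_row, duration_row) {
  m <- rbind(DATE = date_row, DURATION = duration_row)
  colnames(m) <- c("DATE", "DURATION", "na")
  m
}

#' Class-based metrics from a type confusion matrix
#'
#' Per class: TP is the diagonal cell, FP the other class's gold predicted
#' as this class, FN the off-diagonal plus the na cell (an unmatched gold
#' annotation is a false negative for its class). The weighted summary
#' averages the per-class scores with gold row totals as weights. Accuracy
#' is the agreement rate over matched annotations only (the na column and
#' system-only annotations lie outside its universe).
#'
#' @param cm a 2x3 matrix as from [type_confusion()] or
#'   [confusion_matrix()].
#' @return A list: `per_class` data.frame, `weighted` named vector
#'   (`precision`, `recall`, `f1`), `accuracy`, and `weights`.
#' @export
class_metrics <- function(cm) {
  if (is.null(dim(cm)) || any(dim(cm) != c(2L, 3L)) || sum(cm) == 0)
    stop("cm must be a nonempty 2x3 gold-by-verdict count matrix")
  classes <- c("DATE", "DURATION")
  per <- data.frame(class = classes, support = 0, precision = 0,
                    recall = 0, f1 = 0, stringsAsFactors = FALSE)
  for (i in 1:2) {
    cls <- classes[i]; other <- classes[3 - i]
    tp <- cm[cls, cls]
    fp <- cm[other, cls]
    fn <- cm[cls, other] + cm[cls, "na"]
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    per[i, c("support", "precision", "recall", "f1")] <-
      list(sum(cm[cls, ]), p, r, f)
  }
  w <- per$support
  weighted <- c(
    precision = sum(per$precision * w) / sum(w),
    recall = sum(per$recall * w) / sum(w),
    f1 = sum(per$f1 * w) / sum(w))
  matched <- sum(cm[, classes])
  accuracy <- if (matched > 0)
    (cm["DATE", "DATE"] + cm["DURATION", "DURATION"]) / matched else 0
  list(per_class = per, weighted = weighted, accuracy = accuracy,
       weights = stats::setNames(w, classes))
}

#' Canonicalize a normalized value for comparison
#'
#' Uppercases, trims, and strips leading zeros from duration magnitudes so
#' formatting variants (`P02D` vs `P2D`) compare equal.
#'
#' @param v character vector of values.
#' @return Canonical character vector.
#' @export
canonical_value <- function(v) {
  v <- toupper(trimws(v))
  iso_dur <- grepl("^P", v)
  v[iso_dur] <- gsub("(?<=[PTYMWDH])0+(?=\\d)", "", v[iso_dur], perl = TRUE)
  v
}

#' Error-category breakdown of a system run
#'
#' Categorizes disagreements between gold and system annotations of one
#' document set: label errors (matched pair, wrong type), value errors
#' (matched pair, correct type, values differ — values are only examined
#' when the label is correct), missed gold, and added system annotations.
#' Percentages are over the total error count. The relative-expression
#' shares report what fraction of the value and label errors fall on
#' annotations in the RelIV gold subset.
#'
#' @param gold,system annotation data.frames for the same document.
#' @param reliv_gold RelIV-filtered gold annotations of the same document
#'   (membership is decided by identical spans).
#' @return A list of class `error_report` with counts, percentages and
#'   relative shares.
#' @export
error_breakdown <- function(gold, system, reliv_gold = gold[0, ]) {
  m <- match_pairs(gold, system)
  in_reliv <- function(g_idx) {
    if (length(g_idx) == 0L) return(logical(0))
    vapply(g_idx, function(g)
      any(reliv_gold$start == gold$start[g] &
            reliv_gold$end == gold$end[g]), TRUE)
  }
  gp <- m$pairs$gold_idx; sp <- m$pairs$system_idx
  label_err <- gp[gold$ttype[gp] != system$ttype[sp]]
  correct_label <- gold$ttype[gp] == system$ttype[sp]
  value_err <- gp[correct_label &
                    canonical_value(gold$value[gp]) !=
                    canonical_value(system$value[sp])]
  n_missed <- length(m$missed)
  n_added <- length(m$added)
  total <- length(label_err) + length(value_err) + n_missed + n_added
  pct <- function(n) if (total > 0) 100 * n / total else 0
  share <- function(idx) {
    if (length(idx) == 0L) return(0)
    100 * mean(in_reliv(idx))
  }
  structure(list(
    total_errors = total,
    value_errors = length(value_err),
    value_error_pct = pct(length(value_err)),
    value_error_rel_pct = share(value_err),
    label_errors = length(label_err),
    label_error_pct = pct(length(label_err)),
    label_error_rel_pct = share(label_err),
    missed = n_missed, missed_pct = pct(n_missed),
    added = n_added, added_pct = pct(n_added)
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> %d errors: value %d (%.1f%%, rel %.1f%%), label %d (%.1f%%, rel %.1f%%), missed %d (%.1f%%), added %d (%.1f%%)\n",
    x$total_errors, x$value_errors, x$value_error_pct,
    x$value_error_rel_pct, x$label_errors, x$label_error_pct,
    x$label_error_rel_pct, x$missed, x$missed_pct, x$added, x$added_pct))
  invisible(x)
}

#' Per-file span and value metrics
#'
#' Span precision/recall plus value accuracy (fraction of matched pairs
#' whose canonical values agree), the three quantities the difficult-file
#' selection looks at.
#'
#' @param gold,system annotation data.frames for one document.
#' @return Named numeric vector `precision`, `recall`, `value_accuracy`.
#' @export
file_metrics <- function(gold, system) {
  m <- match_pairs(gold, system)
  prf <- span_prf(m)
  va <- if (nrow(m$pairs) > 0)
    mean(canonical_value(gold$value[m$pairs$gold_idx]) ==
           canonical_value(system$value[m$pairs$system_idx]))
  else 0
  c(precision = unname(prf["precision"]), recall = unname(prf["recall"]),
    value_accuracy = va)
}

#' Select difficult files
#'
#' Flags every file whose precision, recall or value accuracy is at or
#' below the threshold (default 0.75) for closer manual review.
#'
#' @param per_file_metrics data.frame with columns `file`, `precision`,
#'   `recall`, `value_accuracy`.
#' @param threshold selection cut (default 0.75).
#' @return Character vector of selected file identifiers.
#' @export
select_difficult_files <- function(per_file_metrics, threshold = 0.75) {
  worst <- pmin(per_file_metrics$precision, per_file_metrics$recall,
                per_file_metrics$value_accuracy)
  as.character(per_file_metrics$file[worst <= threshold])
}

#' Percentile bootstrap confidence interval over documents
#'
#' Resamples documents with replacement `B` times, recomputes the metric on
#' each replicate corpus, and returns the percentile interval around the
#' full-data point estimate. Seeded and reproducible.
#'
#' @param documents a list (each element one document's worth of data, in
#'   whatever form `metric` consumes).
#' @param metric function taking a list of documents and returning one
#'   number.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return Named vector `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(documents, metric, B = 1000L, seed = 1L,
                         level = 0.95) {
  n <- length(documents)
  if (n < 2L) stop("bootstrap needs at least 2 documents")
  if (B < 100L) stop("use at least 100 bootstrap replicates")
  est <- metric(documents)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b)
    metric(documents[sample.int(n, n, replace = TRUE)]), 0)
  alpha <- (1 - level) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  c(estimate = est, lower = q[1], upper = q[2])
}
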