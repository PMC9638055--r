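ann_spans <- function(starts, ends, ttypes = NULL, values = NULL) {
  n <- length(starts)
  timex_annotations(sprintf("A%d", seq_len(n)), starts, ends,
                    text = strrep("x", ends - starts),
                    ttype = if (is.null(ttypes)) rep("DATE", n) else ttypes,
                    value = if (is.null(values)) rep("", n) else values)
}

test_that("lenient pairwise matching is greedy by maximal overlap", {
  m <- match_pairs(ann_spans(10, 20), ann_spans(15, 25))
  expect_equal(nrow(m$pairs), 1L)
  expect_length(m$missed, 0L)
  expect_length(m$added, 0L)

  m2 <- match_pairs(ann_spans(10, 20), ann_spans(30, 40))
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$missed, 1L)
  expect_equal(m2$added, 1L)

  # two system spans over one gold: the larger overlap wins the match
  m3 <- match_pairs(ann_spans(10, 20), ann_spans(c(12, 18), c(19, 22)))
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$system_idx, 1L)  # overlap 7 beats overlap 2
  expect_equal(m3$added, 2L)

  # brute-force check of the greedy assignment on a small random set
  set.seed(12)
  for (rep in 1:20) {
    gs <- sort(sample(0:40, 4)); ss <- sort(sample(0:40, 4))
    gold <- ann_spans(gs[c(1, 3)], gs[c(2, 4)])
    sys <- ann_spans(ss[c(1, 3)], ss[c(2, 4)])
    m <- match_pairs(gold, sys)
    # every matched pair genuinely overlaps; counts partition both sides
    for (k in seq_len(nrow(m$pairs)))
      expect_gt(min(gold$end[m$pairs$gold_idx[k]],
                    sys$end[m$pairs$system_idx[k]]) -
                  max(gold$start[m$pairs$gold_idx[k]],
                      sys$start[m$pairs$system_idx[k]]), 0)
    expect_equal(nrow(m$pairs) + length(m$missed), nrow(gold))
    expect_equal(nrow(m$pairs) + length(m$added), nrow(sys))
  }
})

test_that("span PRF arithmetic and conventions hold", {
  fake <- structure(list(pairs = data.frame(gold_idx = 1:8,
                                            system_idx = 1:8,
                                            overlap = 1),
                         missed = 1:2 + 8L, added = 1:2),
                    class = "match_result")
  expect_equal(unname(span_prf(fake)), c(0.8, 0.8, 0.8))

  perfect <- match_pairs(ann_spans(c(0, 10), c(5, 15)),
                         ann_spans(c(0, 10), c(5, 15)))
  expect_equal(unname(span_prf(perfect)), c(1, 1, 1))

  silent <- match_pairs(ann_spans(0, 5), ann_spans(integer(), integer()))
  expect_equal(unname(span_prf(silent)), c(0, 0, 0))

  # swapping gold and system swaps precision and recall
  g <- ann_spans(c(0, 10, 20), c(5, 15, 25))
  s <- ann_spans(c(0, 40), c(5, 45))
  a <- span_prf(match_pairs(g, s))
  b <- span_prf(match_pairs(s, g))
  expect_equal(unname(a["precision"]), unname(b["recall"]))
  expect_equal(unname(a["recall"]), unname(b["precision"]))
})

test_that("class metrics implement na-as-FN with gold-support weighting", {
  cm <- reported_confusion("chrono_ttd")
  met <- class_metrics(cm)
  d <- met$per_class[met$per_class$class == "DATE", ]
  expect_equal(d$precision, 383 / 402, tolerance = 1e-12)
  expect_equal(d$recall, 383 / 460, tolerance = 1e-12)
  expect_equal(unname(met$weights), c(460, 337))

  diag_only <- confusion_matrix(c(5, 0, 0), c(0, 7, 0))
  md <- class_metrics(diag_only)
  expect_equal(unname(md$weighted), c(1, 1, 1))
  expect_equal(md$accuracy, 1)

  expect_error(class_metrics(matrix(0, 2, 3)), "nonempty")
})

test_that("class metrics agree with the instance-level oracle on 1000 matrices", {
  set.seed(99)
  for (i in 1:1000) {
    cm <- confusion_matrix(sample(0:12, 3, replace = TRUE),
                           sample(0:12, 3, replace = TRUE))
    if (sum(cm) == 0) next
    got <- class_metrics(cm)
    want <- oracle_class_metrics(cm)
    expect_equal(got$weighted, want$weighted, tolerance = 1e-12)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    # convexity: the weighted score lies between the class scores
    for (s in c("precision", "recall", "f1")) {
      rng <- range(got$per_class[[s]])
      expect_gte(got$weighted[[s]], rng[1] - 1e-12)
      expect_lte(got$weighted[[s]], rng[2] + 1e-12)
    }
  }
})

test_that("error categories follow the label-before-value rule", {
  gold <- ann_spans(c(0, 10), c(5, 15), c("DATE", "DATE"),
                    c("2013-02-04", "2013-03-01"))
  # same spans; first has wrong value, second wrong label
  sys <- ann_spans(c(0, 10), c(5, 15), c("DATE", "DURATION"),
                   c("2013-02-05", ""))
  rep <- error_breakdown(gold, sys)
  expect_equal(rep$value_errors, 1L)
  expect_equal(rep$label_errors, 1L)
  expect_equal(rep$missed, 0L)
  expect_equal(rep$added, 0L)
  expect_equal(rep$total_errors, 2L)
  # value formatting variants are canonicalized before comparison
  sys2 <- ann_spans(0, 5, "DURATION", "P02D")
  gold2 <- ann_spans(0, 5, "DURATION", "P2D")
  expect_equal(error_breakdown(gold2, sys2)$value_errors, 0L)
})

test_that("injected error bookkeeping equals the evaluation breakdown", {
  corp <- cached_corpus(10, 23)
  run <- generate_system_run(corp$documents,
                             c(drop = 0.15, add = 0.1, flip = 0.1,
                               value = 0.2), seed = 6)
  tot <- c(value = 0L, label = 0L, missed = 0L, added = 0L)
  reliv <- filter_reliv(filter_dd(corp$documents))
  for (i in seq_along(corp$documents)) {
    r <- error_breakdown(corp$documents[[i]]$annotations,
                         run$documents[[i]]$annotations,
                         reliv[[i]]$annotations)
    tot <- tot + c(r$value_errors, r$label_errors, r$missed, r$added)
  }
  log <- run$log
  expect_equal(unname(tot["missed"]), sum(log$action == "drop"))
  expect_equal(unname(tot["added"]), sum(log$action == "add"))
  expect_equal(unname(tot["label"]), sum(log$action == "flip"))
  expect_equal(unname(tot["value"]), sum(log$action == "value"))
})

test_that("difficult-file selection cuts at the metric minimum", {
  pf <- data.frame(file = c("f1", "f2", "f3"),
                   precision = c(0.9, 0.8, 0.76),
                   recall = c(0.9, 0.95, 0.9),
                   value_accuracy = c(0.70, 0.80, 0.76))
  expect_equal(select_difficult_files(pf), "f1")
  expect_equal(select_difficult_files(pf, threshold = 1.0),
               c("f1", "f2", "f3"))
  expect_length(select_difficult_files(pf[2:3, ]), 0L)
})

test_that("bootstrap intervals are seeded, degenerate-safe, and cover", {
  docs <- as.list(rep(0.8, 5))
  metric <- function(ds) mean(unlist(ds))
  ci <- bootstrap_ci(docs, metric, B = 200, seed = 4)
  expect_equal(unname(ci), c(0.8, 0.8, 0.8))  # zero width when constant

  docs2 <- as.list(runif(12, 0.5, 1))
  ci1 <- bootstrap_ci(docs2, metric, B = 300, seed = 9)
  ci2 <- bootstrap_ci(docs2, metric, B = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1["lower"], ci1["estimate"])
  expect_gte(ci1["upper"], ci1["estimate"])

  expect_error(bootstrap_ci(docs2[1], metric, B = 200, seed = 1), "2")
  expect_error(bootstrap_ci(docs2, metric, B = 10, seed = 1), "100")
})
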