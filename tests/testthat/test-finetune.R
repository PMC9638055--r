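test_that("label schemes have the fixed sizes", {
  expect_length(label_scheme("BIO")$labels, 9L)
  expect_length(label_scheme("Ttype")$labels, 5L)
  expect_true("O" %in% label_scheme("BIO")$labels)
  expect_setequal(label_scheme("Ttype")$labels,
                  c("date", "time", "duration", "frequency", "O"))
})

test_that("token labeling follows the BIO and Ttype schemes", {
  doc <- make_doc("admitted 2 days ago", 9, 19, "DATE")
  bio <- make_token_dataset(list(doc), label_scheme("BIO"))
  expect_equal(bio[[1]]$labels, c("O", "B-date", "I-date", "I-date"))
  tty <- make_token_dataset(list(doc), label_scheme("Ttype"))
  expect_equal(tty[[1]]$labels, c("O", "date", "date", "date"))
  none <- make_token_dataset(list(make_doc("no times here at all")),
                             label_scheme("BIO"))
  expect_equal(none[[1]]$labels, rep("O", 5))
})

test_that("BIO output is well-formed over synthetic corpora", {
  corp <- cached_corpus(8, 19)
  ds <- make_token_dataset(corp$documents, label_scheme("BIO"))
  for (s in ds) {
    labs <- s$labels
    for (i in seq_along(labs)) {
      if (startsWith(labs[i], "I-")) {
        expect_gt(i, 1L)
        prev <- labs[i - 1L]
        expect_true(prev %in% paste0(c("B-", "I-"), sub("^I-", "", labs[i])),
                    info = paste(labs, collapse = " "))
      }
    }
  }
})

test_that("binary sentence labels equal brute-force overlap scans", {
  corp <- cached_corpus(8, 19)
  ds <- make_binary_dataset(corp$documents)
  # brute force: recount positives by scanning every sentence x annotation
  expected_pos <- 0L
  for (doc in corp$documents) {
    for (s in segment(doc$text)) {
      ann <- doc$annotations
      hit <- FALSE
      for (i in seq_len(nrow(ann)))
        if (ann$start[i] < s$end && ann$end[i] > s$start) hit <- TRUE
      expected_pos <- expected_pos + hit
    }
  }
  expect_equal(sum(ds$label), expected_pos)

  # invariance to annotation order
  doc <- corp$documents[[1]]
  flipped <- doc
  flipped$annotations <- doc$annotations[rev(seq_len(nrow(doc$annotations))), ]
  rownames(flipped$annotations) <- NULL
  expect_equal(make_binary_dataset(list(doc))$label,
               make_binary_dataset(list(flipped))$label)
})

test_that("token metrics exclude O and match a hand tally", {
  sch <- label_scheme("Ttype")
  gold <- c("O", "date", "date", "O", "duration", "O")
  perfect <- token_metrics(gold, gold, sch)
  expect_equal(unname(perfect$weighted), c(1, 1, 1))

  all_o <- token_metrics(gold, rep("O", 6), sch)
  expect_equal(unname(all_o$weighted["recall"]), 0)
  expect_equal(all_o$per_label$recall, rep(0, 4))

  # 20-token case against an independent confusion tally
  set.seed(77)
  g20 <- sample(sch$labels, 20, replace = TRUE)
  p20 <- sample(sch$labels, 20, replace = TRUE)
  got <- token_metrics(g20, p20, sch)
  for (l in setdiff(sch$labels, "O")) {
    tp <- sum(g20 == l & p20 == l)
    fp <- sum(g20 != l & p20 == l)
    fn <- sum(g20 == l & p20 != l)
    row <- got$per_label[got$per_label$label == l, ]
    expect_equal(row$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(row$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  expect_error(token_metrics(g20, p20[-1], sch), "length")
})

test_that("dataset writers emit readable CoNLL and sentence files", {
  corp <- cached_corpus(6, 31)
  ds <- make_token_dataset(corp$documents[1:2], label_scheme("BIO"))
  f <- tempfile(fileext = ".conll")
  write_conll(ds, f)
  lines <- readLines(f)
  expect_equal(sum(!nzchar(lines)), length(ds))
  expect_true(all(grepl("\t", lines[nzchar(lines)], fixed = TRUE)))

  bs <- make_binary_dataset(corp$documents[1:2])
  f2 <- tempfile(fileext = ".tsv")
  write_sentence_dataset(bs, f2)
  expect_equal(length(readLines(f2)), nrow(bs))
})

test_that("fine-tuning harness is deterministic and composable", {
  corp <- cached_corpus(6, 31)
  base <- small_provider()
  bin <- make_binary_dataset(corp$documents)
  tuned1 <- finetune_provider(bin, base, epochs = 1, seed = 2)
  tuned2 <- finetune_provider(bin, base, epochs = 1, seed = 2)
  expect_identical(tuned1, tuned2)
  expect_false(identical(tuned1$seed, base$seed))
  expect_equal(tuned1$hidden_size, base$hidden_size)
  # sequential fine-tuning = composition (binary then Seq2Seq)
  seq_ds <- make_token_dataset(corp$documents, label_scheme("Ttype"))
  chained <- finetune_provider(seq_ds, tuned1, epochs = 1, seed = 2)
  expect_s3_class(chained, "tern_provider")
  expect_false(identical(chained$seed, tuned1$seed))
  # tuned embeddings differ from the base model's
  toks <- list(c("on", "2", "days"))
  expect_false(identical(embed_sentences(base, toks),
                         embed_sentences(tuned1, toks)))
})
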