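test_that("DD filter keeps exactly the DATE and DURATION annotations", {
  doc <- make_doc("on 2/4/2013 for 3 days at 9 a.m. taking aspirin daily",
                  starts = c(3, 16, 25, 48),
                  ends = c(11, 22, 32, 53),
                  ttypes = c("DATE", "DURATION", "TIME", "FREQUENCY"))
  out <- filter_dd(list(doc))[[1]]
  expect_equal(nrow(out$annotations), 2L)
  expect_setequal(out$annotations$ttype, c("DATE", "DURATION"))

  only_freq <- make_doc("aspirin daily", 8, 13, "FREQUENCY")
  expect_equal(nrow(filter_dd(list(only_freq))[[1]]$annotations), 0L)

  # brute-force count over a synthetic corpus
  corp <- cached_corpus(8, 19)
  dd <- filter_dd(corp$documents)
  got <- sum(vapply(dd, function(d) nrow(d$annotations), 0L))
  want <- sum(corp$bookkeeping$ttype %in% c("DATE", "DURATION"))
  expect_equal(got, want)
})

test_that("explicitness test reproduces the canonical removal decisions", {
  lex <- reliv_lexicons()
  removed <- c("2/4/2013", "9 a.m.", "5/6", "February", "Monday",
               "Halloween", "2013-02-04", "14:30", "May 1998")
  kept <- c("a week ago", "2 weeks prior", "3 days",
            "postoperative day three", "the day of admission",
            "several days", "POD#2")
  expect_true(all(is_explicit(removed, lex)))
  expect_false(any(is_explicit(kept, lex)))
})

test_that("RelIV filter removes explicit phrases and keeps relative ones", {
  doc <- make_doc("on 2/4/2013 and 2 weeks prior she stayed 3 days",
                  starts = c(3, 16, 41),
                  ends = c(11, 29, 47),
                  ttypes = c("DATE", "DATE", "DURATION"))
  out <- filter_reliv(filter_dd(list(doc)))[[1]]
  expect_equal(out$annotations$text, c("2 weeks prior", "3 days"))

  all_explicit <- make_doc("seen 2/4/2013 then Monday",
                           starts = c(5, 19), ends = c(13, 25),
                           ttypes = c("DATE", "DATE"))
  expect_equal(nrow(filter_reliv(filter_dd(list(all_explicit)))[[1]]$annotations),
               0L)
})

test_that("filters are monotone, idempotent, and match generator truth", {
  corp <- cached_corpus(8, 19)
  dd <- filter_dd(corp$documents)
  reliv <- filter_reliv(dd)
  for (i in seq_along(corp$documents)) {
    a0 <- corp$documents[[i]]$annotations$ann_id
    a1 <- dd[[i]]$annotations$ann_id
    a2 <- reliv[[i]]$annotations$ann_id
    expect_true(all(a1 %in% a0))
    expect_true(all(a2 %in% a1))
  }
  expect_identical(filter_dd(dd), dd)
  expect_identical(filter_reliv(reliv), reliv)

  # the retained set is exactly the bookkept non-explicit DD subset
  bk <- corp$bookkeeping
  want <- sort(bk$ann_id[bk$ttype %in% c("DATE", "DURATION") &
                           !bk$explicit])
  got <- sort(unlist(lapply(reliv, function(d) d$annotations$ann_id)))
  expect_identical(got, want)
})

test_that("gold-overlap restriction keeps split phrases, drops strays", {
  gold <- timex_annotations("G1", 10, 48,
                            text = paste(rep("x", 38), collapse = ""),
                            ttype = "DATE")
  gold$text <- "hospital day #2 through hospital day #3"  # span only matters
  sys <- timex_annotations(c("S1", "S2", "S3"),
                           start = c(10, 34, 60),
                           end = c(25, 49, 66),
                           text = c("a", "b", "c"),
                           ttype = c("DATE", "DATE", "DATE"))
  out <- restrict_to_gold_overlap(sys, gold)
  expect_equal(out$ann_id, c("S1", "S2"))  # both sub-phrases kept
  expect_equal(nrow(restrict_to_gold_overlap(sys[0, ], gold)), 0L)
  # every retained system annotation overlaps some gold span
  corp <- cached_corpus(8, 19)
  reliv <- filter_reliv(filter_dd(corp$documents))
  for (i in seq_along(corp$documents)) {
    sys_doc <- annotate_document(corp$documents[[i]])
    kept <- restrict_to_gold_overlap(sys_doc$annotations,
                                     reliv[[i]]$annotations)
    g <- reliv[[i]]$annotations
    for (j in seq_len(nrow(kept)))
      expect_true(any(kept$start[j] < g$end & kept$end[j] > g$start))
  }
})
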