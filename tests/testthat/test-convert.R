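test_that("ISO durations use P for calendar and PT for clock units", {
  expect_equal(iso_duration(2, "day"), "P2D")
  expect_equal(iso_duration(1, "week"), "P1W")
  expect_equal(iso_duration(3, "month"), "P3M")
  expect_equal(iso_duration(1, "year"), "P1Y")
  expect_equal(iso_duration(6, "hour"), "PT6H")
  expect_equal(iso_duration(30, "minute"), "PT30M")
  expect_error(iso_duration(0, "day"), "positive")
  expect_error(iso_duration(-2, "week"), "positive")
})

test_that("approximate quantities resolve through the table with APPROX", {
  expect_equal(approximate_quantity("several"),
               list(quantity = 3, modifier = "APPROX"))
  expect_equal(approximate_quantity("couple")$quantity, 2)
  expect_equal(approximate_quantity("Many")$quantity, 7)
  expect_error(approximate_quantity("soon"), "soon")
})

test_that("explicit dates normalize to ISO with year fill for partials", {
  doc14 <- make_doc("x", admission = as.Date("2014-06-01"),
                    discharge = as.Date("2014-06-10"))
  ent <- function(text, kind = "ExplicitDate")
    data.frame(start = 0L, end = nchar(text), text = text, kind = kind,
               quantity = NA_real_, unit = NA_character_,
               approx_word = NA_character_, value = NA_character_,
               stringsAsFactors = FALSE)
  expect_equal(normalize_explicit_date(ent("2/4/2013"), doc14),
               "2013-02-04")
  expect_equal(normalize_explicit_date(ent("January 3, 2021"), doc14),
               "2021-01-03")
  expect_equal(normalize_explicit_date(ent("2014-12-31"), doc14),
               "2014-12-31")
  expect_equal(
    normalize_explicit_date(ent("01/10", "TwoPlaceDate"), doc14),
    "2014-01-10")
  # across a year boundary the nearer year wins over the admission year
  late <- make_doc("x", admission = as.Date("2013-12-15"),
                   discharge = as.Date("2013-12-28"))
  expect_equal(
    normalize_explicit_date(ent("01/10", "TwoPlaceDate"), late),
    "2014-01-10")
  # day-first locale is a config flag
  expect_equal(
    normalize_explicit_date(ent("2/4/2013"), doc14,
                            conversion_config(date_order = "dmy")),
    "2013-04-02")
  # no calendar day to place: empty value, not an error
  expect_equal(normalize_explicit_date(ent("February"), doc14), "")
  expect_equal(normalize_explicit_date(ent("9 a.m.", "ExplicitTime"),
                                       doc14), "")
})

test_that("conversion applies the naive all-DURATION rule without a model", {
  doc <- make_doc("stayed 2 days then left")
  e <- recognize(doc$text)
  ann <- scate_to_timeml(e[1, ], doc)
  expect_equal(ann$ttype, "DURATION")
  expect_equal(ann$value, "P2D")

  # every Period/Calendar-Interval in a whole corpus converts to DURATION
  corp <- cached_corpus(6, 31)
  for (doc in corp$documents) {
    ents <- recognize(doc$text)
    routed <- ents[ents$kind %in% c("Period", "CalendarInterval"), ,
                   drop = FALSE]
    for (i in seq_len(nrow(routed))) {
      out <- scate_to_timeml(routed[i, , drop = FALSE], doc)
      expect_equal(out$ttype, "DURATION")
      if (nzchar(out$value))
        expect_match(out$value, "^P")
    }
  }
})

test_that("approximate phrases convert to APPROX-flagged durations", {
  doc <- make_doc("sick for several days now")
  e <- recognize(doc$text)
  ann <- scate_to_timeml(e[1, ], doc)
  expect_equal(ann$ttype, "DURATION")
  expect_equal(ann$value, "P3D")
  expect_equal(ann$modifier, "APPROX")
})

test_that("frequency values come only from the abbreviation lexicon", {
  doc <- make_doc("metoprolol b.i.d. and walks daily")
  e <- recognize(doc$text)
  bid <- scate_to_timeml(e[e$text == "b.i.d.", ], doc)
  expect_equal(bid$ttype, "FREQUENCY")
  expect_equal(bid$value, "RP12H")
  daily <- scate_to_timeml(e[e$text == "daily", ], doc)
  expect_equal(daily$ttype, "FREQUENCY")
  expect_equal(daily$value, "")
})

test_that("a routed entity takes the model verdict; DATE keeps empty value", {
  # separable toy model in the 4H-dim feature space of the small provider
  prov <- small_provider()
  doc <- make_doc("home for 2 days now")
  ents <- recognize(doc$text)
  routed <- ents[ents$kind == "Period", , drop = FALSE]
  feats <- ternr:::doc_phrase_features(doc, routed$start, routed$end,
                                       prov, "PhraseOnly")
  # force a DATE verdict by training DATE on the observed feature itself
  x2 <- rbind(feats[[1]]$vector, -feats[[1]]$vector)
  m_date <- ttd_svm(rbind(x2, 0.9 * x2),
                    rep(c("DATE", "DURATION"), 2))
  cfg <- conversion_config(ttd_model = m_date)
  out <- scate_to_timeml(routed[1, , drop = FALSE], doc, cfg, feats[[1]])
  expect_equal(out$ttype, "DATE")
  expect_equal(out$value, "")
  # without the feature the routed conversion refuses
  expect_error(scate_to_timeml(routed[1, , drop = FALSE], doc, cfg),
               "feature")
})

test_that("conversion is total over recognized entities", {
  corp <- cached_corpus(6, 31)
  for (doc in corp$documents) {
    ents <- recognize(doc$text)
    for (i in seq_len(nrow(ents))) {
      out <- scate_to_timeml(ents[i, , drop = FALSE], doc)
      expect_equal(nrow(out), 1L)
      expect_true(out$ttype %in% c("DATE", "TIME", "DURATION",
                                   "FREQUENCY"))
    }
  }
})
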