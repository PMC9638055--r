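test_that("mock provider is deterministic and seed-sensitive", {
  toks <- list(c("admitted", "2", "days", "ago"))
  a <- embed_sentences(mock_provider(3, 8, 5), toks)
  b <- embed_sentences(mock_provider(3, 8, 5), toks)
  expect_identical(a, b)
  c <- embed_sentences(mock_provider(4, 8, 5), toks)
  expect_false(identical(a[[1]]$emb, c[[1]]$emb))
  # long tokens split into two subwords, each token owns >= 1 subword
  expect_equal(a[[1]]$token_of_subword, c(1, 1, 2, 3, 4))
})

test_that("token resolution concatenates the last 4 layers of the last subword", {
  # layers filled with constants 1..6 at H = 4: the last-4-layer concat of
  # any subword is the block vector [3x4, 4x4, 5x4, 6x4]
  L <- 6L; H <- 4L
  emb <- array(rep(1:L, times = 2 * H), dim = c(L, 2, H))
  tv <- resolve_tokens(toy_batch(emb, c(1L, 1L)))
  expect_equal(dim(tv), c(1L, 4L * H))
  expect_equal(tv[1, ], rep(3:6, each = H))

  # a token split into 3 subwords uses only subword #3
  set.seed(9)
  emb3 <- array(rnorm(L * 3 * H), dim = c(L, 3, H))
  tv3 <- resolve_tokens(toy_batch(emb3, c(1L, 1L, 1L)))
  expect_equal(tv3[1, ], as.numeric(t(emb3[3:6, 3, ])))

  # structural error: a token owning no subwords
  expect_error(resolve_tokens(toy_batch(emb, c(2L, 2L))), "no subwords")
})

test_that("feature dims are 4H and 12H across hidden sizes", {
  for (H in c(4L, 16L, 768L)) {
    prov <- mock_provider(1, H, 4L)
    batch <- embed_sentences(prov, list(c("on", "2", "days", "ago")))[[1]]
    tv <- resolve_tokens(batch)
    expect_equal(ncol(tv), 4L * H)
    expect_equal(phrase_only(tv, 2:4)$dim, 4L * H)
    expect_equal(phrase_context(tv, 2:4)$dim, 12L * H)
  }
})

test_that("phrase-only feature is the mean of member token vectors", {
  tv <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  one <- phrase_only(tv, 2L)
  expect_equal(one$vector, c(3, 4))
  expect_equal(one$variant, "PhraseOnly")
  # opposite vectors cancel
  opp <- matrix(c(1, -1, -1, 1), nrow = 2, byrow = TRUE)
  expect_equal(phrase_only(opp, 1:2)$vector, c(0, 0))
  # three-token hand mean
  expect_equal(phrase_only(tv, 1:3)$vector, c(3, 4))
  expect_error(phrase_only(tv, integer()), "at least one")
  expect_error(phrase_only(tv, c(1L, 3L)), "contiguous")
})

test_that("context windows obey the 1-to-3-token and edge rules", {
  set.seed(4)
  tv <- matrix(rnorm(6 * 4), nrow = 6)
  phrase <- colMeans(tv[3:4, , drop = FALSE])

  # interior phrase: up to 3 before, up to 3 after (2 available here)
  pc <- phrase_context(tv, 3:4)
  expect_equal(pc$vector,
               c(colMeans(tv[1:2, , drop = FALSE]), phrase,
                 colMeans(tv[5:6, , drop = FALSE])))

  # phrase at sentence start: before window = duplicated phrase vector
  pc0 <- phrase_context(tv, 1L)
  expect_equal(pc0$vector[1:4], tv[1, ])
  expect_equal(pc0$vector[5:8], tv[1, ])
  expect_equal(pc0$vector[9:12], colMeans(tv[2:4, , drop = FALSE]))

  # whole-sentence phrase: feature = phrase tiled three times
  whole <- phrase_context(tv, 1:6)
  expect_equal(whole$vector, rep(colMeans(tv), 3))

  # never more than 3 context tokens
  tv9 <- matrix(rnorm(9 * 2), nrow = 9)
  pc9 <- phrase_context(tv9, 5L)
  expect_equal(pc9$vector[1:2], colMeans(tv9[2:4, , drop = FALSE]))
  expect_equal(pc9$vector[5:6], colMeans(tv9[6:8, , drop = FALSE]))
})

test_that("feature rules are provider-agnostic: shapes survive provider swaps", {
  toks <- c("admitted", "2", "days", "ago")
  f1 <- phrase_feature(mock_provider(1, 8, 4), toks, 2:4, "PhraseContext")
  f2 <- phrase_feature(mock_provider(99, 8, 12), toks, 2:4, "PhraseContext")
  expect_equal(f1$dim, f2$dim)
  expect_equal(f1$variant, f2$variant)
  expect_false(identical(f1$vector, f2$vector))
})

test_that("embedding lookups do not perturb user-level RNG state", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(embed_sentences(mock_provider(1, 4, 4), list(c("a", "b"))))
  after <- runif(1)
  expect_identical(before, after)
})
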