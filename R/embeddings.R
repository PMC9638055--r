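# Phrase features from per-subword, per-layer contextual embeddings.
#
# A provider turns tokenized sentences into subword-level embedding batches
# (layers x subwords x hidden). Feature construction is provider-agnostic:
# per whitespace token, the LAST subword's last-4-layer concatenation
# (shallowest of the four first) represents the token (4H dims); a phrase is
# the mean of its token vectors (Phrase-Only, 4H = 3,072 at H = 768); the
# Phrase+Context variant brackets that with the means of up-to-3-token
# windows before and after (12H = 9,216), substituting the phrase vector
# itself for an empty window.
#
# The packaged provider is a deterministic mock: each subword vector is a
# seeded hash of (subword surface, position, layer), with a small positional
# component so the lexical identity of a token dominates its embedding.

#' Deterministic mock embedding provider
#'
#' A stand-in for a transformer encoder used by tests and the synthetic
#' pipeline. Embeddings are a pure function of (subword surface, position,
#' layer) and the provider seed; identical inputs give byte-identical
#' output. Tokens longer than 6 characters split into two subwords.
#'
#' @param seed integer seed.
#' @param hidden_size embedding width `H` (default 768, giving the standard
#'   3,072/9,216 feature dims).
#' @param layers number of hidden layers `L` (default 12; must be >= 4).
#' @return A provider object of class `c("mock_provider", "tern_provider")`.
#' @export
mock_provider <- function(seed = 1L, hidden_size = 768L, layers = 12L) {
  stopifnot(layers >= 4L, hidden_size >= 1L)
  structure(list(id = sprintf("mock-h%d-l%d-s%d", hidden_size, layers, seed),
                 seed = as.integer(seed),
                 hidden_size = as.integer(hidden_size),
                 layers = as.integer(layers)),
            class = c("mock_provider", "tern_provider"))
}

# 31-fold string hash, kept well under 2^31
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 268435399
  as.integer(h)
}

mock_subwords <- function(token) {
  n <- nchar(token)
  if (n > 6L) {
    k <- ceiling(n / 2)
    c(substr(token, 1L, k), substr(token, k + 1L, n))
  } else token
}

mock_vector <- function(provider, surface, position, layer) {
  base_seed <- (provider$seed * 7919 + string_hash(surface) * 13 +
                  layer) %% 2147480000
  pos_seed <- (provider$seed * 104729 + position * 31 +
                 layer) %% 2147480000
  old <- .Random.seed_guard()
  on.exit(old(), add = TRUE)
  set.seed(base_seed)
  v <- stats::rnorm(provider$hidden_size)
  set.seed(pos_seed)
  v + 0.1 * stats::rnorm(provider$hidden_size)
}

# save/restore the global RNG state so embedding lookups never perturb
# user-visible randomness
.Random.seed_guard <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Embed tokenized sentences
#'
#' @param provider a `tern_provider`.
#' @param sentences a list of character vectors, one vector of whitespace
#'   tokens per sentence.
#' @return A list of subword embedding batches, one per sentence: each has
#'   `subwords` (character), `token_of_subword` (integer map to whitespace
#'   token index) and `emb`, an array of shape (layers, subwords, hidden).
#' @export
embed_sentences <- function(provider, sentences) {
  UseMethod("embed_sentences")
}

#' @export
embed_sentences.mock_provider <- function(provider, sentences) {
  lapply(sentences, function(tokens) {
    subs <- character()
    owner <- integer()
    for (i in seq_along(tokens)) {
      sw <- mock_subwords(tokens[i])
      subs <- c(subs, sw)
      owner <- c(owner, rep(i, length(sw)))
    }
    S <- length(subs)
    emb <- array(0, dim = c(provider$layers, S, provider$hidden_size))
    for (s in seq_len(S))
      for (l in seq_len(provider$layers))
        emb[l, s, ] <- mock_vector(provider, subs[s], s, l)
    list(subwords = subs, token_of_subword = owner, emb = emb)
  })
}

#' Resolve a subword batch to per-token vectors
#'
#' Each whitespace token is represented by its LAST subword; the last four
#' hidden layers of that subword are concatenated, shallowest of the four
#' first, giving a vector of length `4 * H` (3,072 at H = 768).
#'
#' @param batch one element of the list returned by [embed_sentences()].
#' @return A numeric matrix, one row per whitespace token, `4 * H` columns.
#' @export
resolve_tokens <- function(batch) {
  L <- dim(batch$emb)[1]
  H <- dim(batch$emb)[3]
  stopifnot(L >= 4L)
  n_tok <- max(batch$token_of_subword, 0L)
  out <- matrix(0, nrow = n_tok, ncol = 4L * H)
  for (t in seq_len(n_tok)) {
    subs <- which(batch$token_of_subword == t)
    if (length(subs) == 0L)
      stop(sprintf("token %d owns no subwords", t))
    last <- subs[length(subs)]
    out[t, ] <- as.numeric(t(batch$emb[(L - 3L):L, last, ]))
  }
  out
}

phrase_feature_obj <- function(vector, variant) {
  structure(list(vector = as.numeric(vector), variant = variant,
                 dim = length(vector)),
            class = "phrase_feature")
}

#' @export
print.phrase_feature <- function(x, ...) {
  cat(sprintf("<phrase_feature> %s, dim %d\n", x$variant, x$dim))
  invisible(x)
}

check_phrase_indices <- function(idx, n_tokens) {
  if (length(idx) == 0L) stop("phrase must contain at least one token")
  idx <- sort(unique(as.integer(idx)))
  if (idx[1] < 1L || idx[length(idx)] > n_tokens)
    stop("phrase token indices outside sentence")
  if (!all(diff(idx) == 1L))
    stop("phrase token indices must be contiguous")
  idx
}

#' Phrase-Only feature: mean of the phrase's token vectors
#'
#' @param token_vectors matrix from [resolve_tokens()].
#' @param phrase_token_indices 1-based indices of the phrase's whitespace
#'   tokens (non-empty, contiguous).
#' @return A `phrase_feature` of dimension `4 * H`.
#' @export
phrase_only <- function(token_vectors, phrase_token_indices) {
  idx <- check_phrase_indices(phrase_token_indices, nrow(token_vectors))
  phrase_feature_obj(colMeans(token_vectors[idx, , drop = FALSE]),
                     "PhraseOnly")
}

#' Phrase+Context feature: before-window, phrase, after-window
#'
#' The context windows take up to 3 whitespace tokens immediately before and
#' after the phrase within the same sentence (at least 1 when any are
#' available); a window with no available tokens — the phrase sits at the
#' sentence edge or spans the whole sentence — is replaced by the phrase
#' vector itself. Output dimension is `12 * H` (9,216 at H = 768).
#'
#' @inheritParams phrase_only
#' @param sentence_token_count number of tokens in the sentence (defaults to
#'   `nrow(token_vectors)`).
#' @return A `phrase_feature` of dimension `12 * H`.
#' @export
phrase_context <- function(token_vectors, phrase_token_indices,
                           sentence_token_count = nrow(token_vectors)) {
  idx <- check_phrase_indices(phrase_token_indices, sentence_token_count)
  phrase <- colMeans(token_vectors[idx, , drop = FALSE])
  window_mean <- function(w) {
    if (length(w) == 0L) phrase
    else colMeans(token_vectors[w, , drop = FALSE])
  }
  lo <- idx[1]; hi <- idx[length(idx)]
  before <- if (lo <= 1L) integer(0) else seq.int(max(1L, lo - 3L), lo - 1L)
  after <- if (hi >= sentence_token_count) integer(0) else
    seq.int(hi + 1L, min(sentence_token_count, hi + 3L))
  phrase_feature_obj(c(window_mean(before), phrase, window_mean(after)),
                     "PhraseContext")
}

#' Build the phrase feature for one tokenized sentence
#'
#' Convenience wrapper: embed the sentence with the provider, resolve token
#' vectors, and apply the requested feature variant.
#'
#' @param provider a `tern_provider`.
#' @param tokens character vector of the sentence's whitespace tokens.
#' @param phrase_token_indices indices of the phrase tokens.
#' @param variant `"PhraseOnly"` or `"PhraseContext"`.
#' @return A `phrase_feature`.
#' @export
phrase_feature <- function(provider, tokens, phrase_token_indices,
                           variant = c("PhraseOnly", "PhraseContext")) {
  variant <- match.arg(variant)
  batch <- embed_sentences(provider, list(tokens))[[1]]
  tv <- resolve_tokens(batch)
  if (variant == "PhraseOnly") phrase_only(tv, phrase_token_indices)
  else phrase_context(tv, phrase_token_indices, length(tokens))
}
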