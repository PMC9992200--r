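#' Skip-gram embedding configuration
#'
#' The stated training geometry is a context window of 10 and vector
#' dimension 100. Remaining knobs (epochs, min_count, negative samples,
#' initial learning rate) are exposed with conservative word2vec-style
#' defaults.
#'
#' @param window Context window size (>= 1).
#' @param dim Vector dimension (>= 1).
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param epochs Training epochs (>= 1).
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (decays linearly).
#' @param seed Integer RNG seed (training is deterministic given the seed).
#' @param objective Training objective; only `"negative_sampling"` is
#'   implemented.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(window = 10L, dim = 100L, min_count = 2L,
                             epochs = 20L, negative = 5L, alpha = 0.025,
                             seed = 1L,
                             objective = c("negative_sampling",
                                           "hierarchical_softmax")) {
  objective <- match.arg(objective)
  if (objective != "negative_sampling") {
    stop("objective 'hierarchical_softmax' is not implemented; ",
         "use 'negative_sampling'", call. = FALSE)
  }
  if (dim < 1L) stop("config error: dim must be >= 1", call. = FALSE)
  if (window < 1L) stop("config error: window must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("config error: epochs must be >= 1", call. = FALSE)
  structure(list(window = as.integer(window), dim = as.integer(dim),
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed), objective = objective),
            class = "embedding_config")
}

# Coerce raw texts / token lists to a list of token character vectors.
as_token_list <- function(corpus) {
  if (is.data.frame(corpus)) corpus <- corpus$text
  if (is.character(corpus)) {
    corpus <- lapply(corpus, function(t) tokenize(normalize_text(t)))
  }
  stopifnot(is.list(corpus))
  corpus
}

#' Train skip-gram word embeddings
#'
#' Trains word2vec-style skip-gram vectors with negative sampling on a
#' tokenized corpus. Single-threaded and bitwise-reproducible for a fixed
#' seed. Tokens below `min_count` are dropped from the vocabulary.
#'
#' @param corpus A corpus `data.frame`, a character vector of report texts,
#'   or a list of token vectors.
#' @param config An [embedding_config()].
#' @return An `embedding_model`: list with `vectors` (vocab x dim matrix,
#'   rownames = tokens) and `config`.
#' @export
train_skipgram <- function(corpus, config = embedding_config()) {
  toks <- as_token_list(corpus)
  if (length(toks) == 0L || sum(lengths(toks)) == 0L) {
    stop("cannot train embeddings on an empty corpus", call. = FALSE)
  }
  freq <- table(unlist(toks, use.names = FALSE))
  freq <- freq[freq >= config$min_count]
  if (length(freq) == 0L) {
    stop("no tokens reach min_count = ", config$min_count, call. = FALSE)
  }
  # Deterministic vocabulary order: by decreasing frequency, ties
  # alphabetical.
  vocab <- names(freq)[order(-as.integer(freq), names(freq))]
  counts <- as.integer(freq[vocab])
  index <- setNames(seq_along(vocab), vocab)
  sentences <- lapply(toks, function(tt) {
    ids <- index[tt]
    as.integer(ids[!is.na(ids)]) - 1L
  })
  sentences <- sentences[lengths(sentences) > 0L]
  vec <- .sgns_train(sentences, length(vocab), counts, config$dim,
                     config$window, config$epochs, config$negative,
                     config$alpha, config$seed)
  rownames(vec) <- vocab
  structure(list(vectors = vec, config = config), class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("skip-gram embedding model:", nrow(x$vectors), "tokens, dim",
      ncol(x$vectors), "\n")
  invisible(x)
}

#' Embed a phrase by token averaging
#'
#' Element-wise mean of the embedding vectors of the phrase's in-vocabulary
#' tokens; out-of-vocabulary tokens are skipped (not zero-imputed).
#'
#' @param phrase Character scalar (normalized+tokenized internally) or a
#'   token character vector.
#' @param model An `embedding_model`.
#' @return Numeric vector of length `dim`.
#' @export
embed_phrase <- function(phrase, model) {
  tokens <- if (length(phrase) == 1L && grepl(" ", phrase)) {
    tokenize(normalize_text(phrase))
  } else as.character(phrase)
  hit <- tokens[tokens %in% rownames(model$vectors)]
  if (length(hit) == 0L) {
    stop("all tokens out of vocabulary for phrase: ",
         paste(tokens, collapse = " "), call. = FALSE)
  }
  colMeans(model$vectors[hit, , drop = FALSE])
}

#' Cosine similarity
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Default reference phrases for the embedding classifier
#'
#' Positive references are the lexicon's pneumonia-indicating phrases;
#' negative references are its no-pneumonia phrases plus the negated variants
#' of every expandable positive phrase.
#'
#' @param lexicon A `cxr_lexicon`.
#' @param cues Negation cues.
#' @return List with `positive` and `negative` character vectors.
#' @export
default_reference_phrases <- function(lexicon = default_lexicon(),
                                      cues = default_negation_cues()) {
  pos <- lexicon$phrase[lexicon$polarity == "indicates_pneumonia"]
  neg <- lexicon$phrase[lexicon$polarity == "indicates_no_pneumonia"]
  expand <- unlist(lapply(which(lexicon$expandable &
                                  lexicon$polarity == "indicates_pneumonia"),
                          function(j) expand_negations(lexicon$phrase[j], cues)))
  list(positive = pos, negative = unique(c(neg, expand)))
}

# Embed a set of reference phrases, dropping phrases that are fully OOV.
# Returns the embedding matrix plus each phrase's in-vocabulary token count
# (the window length used for length-matched scoring).
embed_references <- function(phrases, model) {
  vocab <- rownames(model$vectors)
  toks <- lapply(phrases, function(p) {
    tt <- if (length(p) == 1L) tokenize(normalize_text(p)) else as.character(p)
    tt[tt %in% vocab]
  })
  keep <- lengths(toks) > 0L
  if (!any(keep)) return(NULL)
  vecs <- t(vapply(toks[keep], function(tt)
    colMeans(model$vectors[tt, , drop = FALSE]),
    numeric(ncol(model$vectors))))
  list(vectors = vecs, len = lengths(toks[keep]))
}

row_normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Max cosine between any report window and any reference phrase. With
# length-matched windows (window = NULL) each reference is scored against
# windows of its own token length, so a verbatim phrase occurrence scores 1.
max_window_cosine <- function(tokens, model, ref, window) {
  if (is.null(window)) {
    best <- -1
    for (L in sort(unique(ref$len))) {
      wins <- row_normalize(window_means(tokens, model, L))
      sub <- row_normalize(ref$vectors[ref$len == L, , drop = FALSE])
      best <- max(best, wins %*% t(sub))
    }
    best
  } else {
    wins <- row_normalize(window_means(tokens, model, window))
    max(wins %*% t(row_normalize(ref$vectors)))
  }
}

#' Classify a report by windowed cosine similarity
#'
#' Embeds sliding token windows of the report by token averaging and scores
#' them against the positive and negative reference phrases; the report is
#' called pneumonia iff the best positive cosine exceeds the best negative
#' cosine beyond a small numerical guard (ties are called negative). By
#' default each reference phrase is scored against windows of its own token
#' length, so a verbatim phrase occurrence scores exactly 1 and a negated
#' occurrence ("no focal consolidation") produces matching positive and
#' negative scores that resolve, via the tie-break, to a negative call. Pass
#' a fixed integer `window` (e.g. the training window, 10) to score every
#' reference against the same windows instead.
#'
#' @param report Character text or token vector for one report.
#' @param model An `embedding_model`.
#' @param refs Reference phrases, as from [default_reference_phrases()].
#' @param window `NULL` for length-matched windows (default), or a fixed
#'   window length in tokens.
#' @return List with `label` (1 = pneumonia), `score_pos`, `score_neg`.
#' @export
classify_by_embedding <- function(report, model,
                                  refs = default_reference_phrases(),
                                  window = NULL) {
  if (length(refs$positive) == 0L || length(refs$negative) == 0L) {
    stop("config error: both reference phrase lists must be non-empty",
         call. = FALSE)
  }
  tokens <- if (is.character(report) && length(report) == 1L) {
    tokenize(normalize_text(report))
  } else as.character(report)
  tokens <- tokens[tokens %in% rownames(model$vectors)]
  if (length(tokens) == 0L) {
    stop("report has no in-vocabulary tokens", call. = FALSE)
  }
  pos_ref <- embed_references(refs$positive, model)
  neg_ref <- embed_references(refs$negative, model)
  if (is.null(pos_ref) || is.null(neg_ref)) {
    stop("config error: a reference class has no in-vocabulary phrase",
         call. = FALSE)
  }
  score_pos <- max_window_cosine(tokens, model, pos_ref, window)
  score_neg <- max_window_cosine(tokens, model, neg_ref, window)
  list(label = as.integer(score_pos > score_neg + 1e-9),
       score_pos = score_pos, score_neg = score_neg)
}

# Rolling window means over the token embedding sequence; number of windows
# is max(1, n_tokens - window + 1).
window_means <- function(tokens, model, window) {
  m <- model$vectors[tokens, , drop = FALSE]
  n <- nrow(m)
  w <- min(window, n)
  cs <- rbind(0, apply(m, 2L, cumsum))
  k <- n - w + 1L
  (cs[(w + 1L):(w + k), , drop = FALSE] - cs[1L:k, , drop = FALSE]) / w
}

#' Classify every report in a corpus by embedding
#'
#' Vectorized wrapper over [classify_by_embedding()] that embeds the
#' reference phrases once.
#'
#' @param corpus Corpus `data.frame`.
#' @inheritParams classify_by_embedding
#' @return `data.frame` with `report_id`, `label`, `score_pos`, `score_neg`.
#' @export
embedding_classify_corpus <- function(corpus, model,
                                      refs = default_reference_phrases(),
                                      window = NULL) {
  pos_ref <- embed_references(refs$positive, model)
  neg_ref <- embed_references(refs$negative, model)
  if (is.null(pos_ref) || is.null(neg_ref)) {
    stop("config error: a reference class has no in-vocabulary phrase",
         call. = FALSE)
  }
  vocab <- rownames(model$vectors)
  one <- function(text) {
    tokens <- tokenize(normalize_text(text))
    tokens <- tokens[tokens %in% vocab]
    if (length(tokens) == 0L) {
      stop("report has no in-vocabulary tokens", call. = FALSE)
    }
    sp <- max_window_cosine(tokens, model, pos_ref, window)
    sn <- max_window_cosine(tokens, model, neg_ref, window)
    c(as.integer(sp > sn + 1e-9), sp, sn)
  }
  res <- vapply(corpus$text, one, numeric(3), USE.NAMES = FALSE)
  data.frame(report_id = corpus$report_id,
             label = as.integer(res[1, ]),
             score_pos = res[2, ], score_neg = res[3, ],
             stringsAsFactors = FALSE)
}

#' Write / read embeddings in word2vec text format
#'
#' First line `"<vocab_size> <dim>"`, then one `token v1 ... v_dim` line per
#' token.
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), ncol(model$vectors)), con)
  lines <- paste(rownames(model$vectors),
                 apply(model$vectors, 1L, function(v)
                   paste(formatC(v, format = "g", digits = 17),
                         collapse = " ")))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vec) <- vocab
  stopifnot(nrow(vec) == hdr[1])
  structure(list(vectors = vec,
                 config = embedding_config(dim = hdr[2])),
            class = "embedding_model")
}
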