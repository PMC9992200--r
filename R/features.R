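# Count lexicon-phrase matches in one token sequence: left-to-right,
# non-overlapping, longest-match-wins at each position.
match_tokens <- function(tokens, dict) {
  counts <- integer(length(dict$feature_names))
  n <- length(tokens)
  i <- 1L
  while (i <= n) {
    cand <- dict$by_first[[tokens[i]]]
    step <- 1L
    if (!is.null(cand)) {
      for (k in cand) {  # candidates sorted longest-first
        L <- dict$len[k]
        if (i + L - 1L <= n &&
            identical(tokens[i:(i + L - 1L)], dict$tokens[[k]])) {
          f <- dict$feature[k]
          counts[f] <- counts[f] + 1L
          step <- L
          break
        }
      }
    }
    i <- i + step
  }
  counts
}

#' Extract lexicon features from a report
#'
#' Counts non-overlapping occurrences of each lexicon phrase and of each
#' negated variant (`<phrase>|negated`) of expandable entries in the
#' normalized report text. Matching is phrase-level on the token stream,
#' left-to-right, longest-match-wins, so a positive phrase inside a matched
#' negated phrase increments only the negated feature.
#'
#' @param report A single report: character text, or a one-row corpus
#'   `data.frame` with a `text` column.
#' @param lexicon A `cxr_lexicon`.
#' @param cues Negation cues used for expansion.
#' @return Named integer vector of counts, aligned to
#'   [lexicon_feature_names()].
#' @export
extract_features <- function(report, lexicon = default_lexicon(),
                             cues = default_negation_cues()) {
  if (is.data.frame(report)) {
    stopifnot(nrow(report) == 1L, "text" %in% names(report))
    report <- report$text
  }
  if (nrow(lexicon) == 0L) stop("lexicon must be non-empty", call. = FALSE)
  dict <- build_match_dictionary(lexicon, cues)
  counts <- match_tokens(tokenize(normalize_text(report)), dict)
  setNames(counts, dict$feature_names)
}

#' Extract the feature matrix for a whole corpus
#'
#' @param corpus Corpus `data.frame`.
#' @inheritParams extract_features
#' @return Integer matrix, one row per report (rownames = `report_id`),
#'   columns aligned to [lexicon_feature_names()].
#' @export
extract_feature_matrix <- function(corpus, lexicon = default_lexicon(),
                                   cues = default_negation_cues()) {
  if (nrow(lexicon) == 0L) stop("lexicon must be non-empty", call. = FALSE)
  dict <- build_match_dictionary(lexicon, cues)
  toks <- lapply(corpus$text, function(t) tokenize(normalize_text(t)))
  m <- t(vapply(toks, match_tokens, integer(length(dict$feature_names)),
                dict = dict))
  dimnames(m) <- list(corpus$report_id, dict$feature_names)
  m
}

#' Rule-based reference labeling
#'
#' Labels a feature vector positive when it carries any un-negated
#' pneumonia-indicating evidence. Negated variants never count as positive
#' evidence (longest-match extraction already prevents a negated phrase from
#' incrementing its bare twin). Hedged phrases ("pneumonia cannot be
#' excluded") count as positive under the default sensitivity-oriented
#' policy.
#'
#' @param features Named count vector from [extract_features()] or a matrix
#'   from [extract_feature_matrix()].
#' @param lexicon The lexicon the features were extracted with.
#' @param hedged_positive Treat hedged phrases as positive evidence
#'   (default `TRUE`).
#' @return Integer 0/1 label (vector when `features` is a matrix).
#' @export
label_by_rules <- function(features, lexicon = default_lexicon(),
                           hedged_positive = TRUE) {
  pos_feats <- lexicon$phrase[lexicon$polarity == "indicates_pneumonia"]
  if (hedged_positive) {
    pos_feats <- c(pos_feats, lexicon$phrase[lexicon$polarity == "hedged"])
  }
  if (is.matrix(features)) {
    stopifnot(all(pos_feats %in% colnames(features)))
    as.integer(rowSums(features[, pos_feats, drop = FALSE]) > 0)
  } else {
    stopifnot(all(pos_feats %in% names(features)))
    as.integer(sum(features[pos_feats]) > 0)
  }
}

#' Export a feature matrix as CSV
#'
#' Writes one row per report with a leading `report_id` column and one
#' column per feature name.
#'
#' @param features Matrix from [extract_feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(report_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
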