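#' The default keyword lexicon
#'
#' Returns the built-in keyword lexicon of radiology phrases used to denote
#' radiographic pneumonia, its absence, or hedged uncertainty. Each entry
#' carries a `polarity` (`indicates_pneumonia`, `indicates_no_pneumonia`,
#' `hedged`) and an `expandable` flag marking phrases eligible for negation
#' expansion ("no infiltrate" style). Phrases that already contain a negation
#' cue ("no pleural effusion") and all non-positive phrases are not
#' expandable. Entry order is stable: feature index = entry index.
#'
#' @return A `data.frame` of class `cxr_lexicon` with columns `phrase`,
#'   `polarity`, `expandable`.
#' @export
default_lexicon <- function() {
  pos <- c("areas of pneumonia", "features of bacterial pneumonia",
           "focal airspace consolidation", "focal consolidation",
           "focal pulmonary infiltrate", "ground glass opacities",
           "multifocal airspace disease", "patchy consolidation",
           "perihilar opacities", "pleural effusion", "pneumonia")
  neg <- c("acute cardiopulmonary abnormality", "clear lungs",
           "evidence of acute cardiopulmonary disease", "lungs are clear",
           "negative chest", "no abnormality", "no pleural effusion",
           "normal chest radiograph", "normal chest x-ray",
           "within normal limits", "hyperinflation",
           "reactive airway disease", "viral bronchiolitis")
  hedge <- "pneumonia cannot be excluded"
  lex <- data.frame(
    phrase = c(pos, neg, hedge),
    polarity = c(rep("indicates_pneumonia", length(pos)),
                 rep("indicates_no_pneumonia", length(neg)),
                 "hedged"),
    expandable = c(rep(TRUE, length(pos)), rep(FALSE, length(neg)), FALSE),
    stringsAsFactors = FALSE)
  as_lexicon(lex)
}

#' Construct / validate a lexicon
#'
#' @param x A `data.frame` with columns `phrase`, `polarity`, `expandable`.
#' @param version Version string stored as an attribute.
#' @return The validated lexicon (class `cxr_lexicon`).
#' @export
as_lexicon <- function(x, version = "table1-v1") {
  stopifnot(is.data.frame(x),
            all(c("phrase", "polarity", "expandable") %in% names(x)))
  x$phrase <- vapply(x$phrase, normalize_text, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(x$phrase))) stop("lexicon phrases must be non-empty",
                                   call. = FALSE)
  if (anyDuplicated(x$phrase)) {
    stop("lexicon phrases must be unique after normalization", call. = FALSE)
  }
  bad <- !x$polarity %in% c("indicates_pneumonia", "indicates_no_pneumonia",
                            "hedged")
  if (any(bad)) stop("unknown polarity: ", paste(unique(x$polarity[bad]),
                                                 collapse = ", "),
                     call. = FALSE)
  x$expandable <- as.logical(x$expandable)
  # A phrase that already opens with a negation cue cannot be expanded again.
  cue_re <- paste0("^(", paste(default_negation_cues(), collapse = "|"), ") ")
  x$expandable[grepl(cue_re, x$phrase)] <- FALSE
  attr(x, "version") <- version
  class(x) <- c("cxr_lexicon", "data.frame")
  x
}

#' Read / write a lexicon CSV (`phrase`, `polarity`, `expandable`)
#' @param path CSV path.
#' @export
read_lexicon <- function(path) {
  as_lexicon(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_lexicon
#' @param lexicon A `cxr_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- as.data.frame(lexicon)[, c("phrase", "polarity", "expandable")]
  out$expandable <- as.integer(out$expandable)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default negation cue set
#'
#' Minimal, high-precision cues prepended to expandable keywords to form
#' negated variants.
#' @return Character vector of cues.
#' @export
default_negation_cues <- function() {
  c("no", "without", "no evidence of", "negative for")
}

#' Normalize report text
#'
#' Lowercases, replaces punctuation with spaces (intra-word hyphens are
#' preserved), and collapses whitespace. Deterministic; empty in, empty out.
#'
#' @param raw A character string.
#' @return The normalized string.
#' @export
normalize_text <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) raw <- as.character(raw %||% "")
  x <- tolower(raw)
  x <- gsub("(?<=[a-z0-9])-(?=[a-z0-9])", "\001", x, perl = TRUE)
  x <- gsub("[^a-z0-9\001]+", " ", x)
  x <- gsub("\001", "-", x, fixed = TRUE)
  trimws(gsub(" +", " ", x))
}

#' Tokenize normalized text
#'
#' Splits on single spaces, preserving order. Input is expected to be output
#' of [normalize_text()].
#'
#' @param text Normalized text.
#' @return Character vector of tokens (length 0 for empty input).
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  strsplit(text, " ", fixed = TRUE)[[1]]
}

#' Expand a keyword into its negated variants
#'
#' @param phrase An expandable lexicon phrase (normalized).
#' @param cues Negation cues; defaults to [default_negation_cues()].
#' @param expandable Expandability flag of the entry; calling this on a
#'   non-expandable entry is a contract error.
#' @return Character vector, one negated phrase per cue, in cue order. The
#'   original phrase is not included.
#' @export
expand_negations <- function(phrase, cues = default_negation_cues(),
                             expandable = TRUE) {
  if (!isTRUE(expandable)) {
    stop("expand_negations() called on a non-expandable entry: ", phrase,
         call. = FALSE)
  }
  paste(cues, phrase)
}

#' Feature names induced by a lexicon
#'
#' One feature per lexicon entry (its phrase) plus one `<phrase>|negated`
#' feature per expandable entry, in lexicon order.
#'
#' @param lexicon A `cxr_lexicon`.
#' @param cues Negation cues.
#' @return Character vector of feature names.
#' @export
lexicon_feature_names <- function(lexicon, cues = default_negation_cues()) {
  c(lexicon$phrase, paste0(lexicon$phrase[lexicon$expandable], "|negated"))
}

# Matching dictionary: one row per matchable token sequence, mapping to a
# feature index. Negated expansions that collide with an explicit lexicon
# phrase (e.g. "no pleural effusion") defer to the explicit entry.
build_match_dictionary <- function(lexicon, cues = default_negation_cues()) {
  feats <- lexicon_feature_names(lexicon, cues)
  phrases <- lexicon$phrase
  feat_idx <- seq_along(phrases)
  exp_idx <- which(lexicon$expandable)
  for (j in exp_idx) {
    negf <- match(paste0(phrases[j], "|negated"), feats)
    for (cue in cues) {
      cand <- paste(cue, phrases[j])
      if (cand %in% phrases) next  # explicit entry wins
      phrases <- c(phrases, cand)
      feat_idx <- c(feat_idx, negf)
    }
  }
  toks <- strsplit(phrases, " ", fixed = TRUE)
  len <- lengths(toks)
  first <- vapply(toks, `[[`, character(1), 1L)
  ord <- order(first, -len)
  list(feature_names = feats,
       tokens = toks[ord], len = len[ord], first = first[ord],
       feature = feat_idx[ord],
       by_first = split(seq_along(ord), first[ord]))
}
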