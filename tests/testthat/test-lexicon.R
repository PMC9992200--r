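test_that("normalize_text lowercases, strips punctuation and keeps hyphens", {
  expect_equal(normalize_text("Lungs are CLEAR."), "lungs are clear")
  expect_equal(normalize_text("FINDINGS:  No focal\nconsolidation"),
               "findings no focal consolidation")
  expect_equal(normalize_text("x-ray"), "x-ray")
  expect_equal(normalize_text(""), "")
})

test_that("tokenize splits on single spaces and counts match a whitespace oracle", {
  expect_equal(tokenize("no focal consolidation"),
               c("no", "focal", "consolidation"))
  expect_length(tokenize(""), 0L)
  report <- paste("EXAM: Two view chest radiograph. CLINICAL HISTORY:",
                  "Cough and fever. FINDINGS: There is focal consolidation",
                  "in the right lower lobe. IMPRESSION: Pneumonia.")
  norm <- normalize_text(report)
  # independent count: number of space-separated units
  oracle <- length(gregexpr(" ", norm, fixed = TRUE)[[1]]) + 1L
  expect_length(tokenize(norm), oracle)
})

test_that("expand_negations prepends each cue and refuses non-expandable entries", {
  expect_equal(expand_negations("infiltrate", cues = "no"), "no infiltrate")
  out <- expand_negations("pneumonia")
  expect_length(out, 4L)
  expect_true(all(startsWith(
    out, c("no ", "without ", "no evidence of ", "negative for "))))
  expect_error(expand_negations("lungs are clear", expandable = FALSE),
               "non-expandable")
})

test_that("lexicon feature space is stable and collision-safe", {
  lex <- default_lexicon()
  feats <- lexicon_feature_names(lex)
  expect_equal(length(feats),
               nrow(lex) + sum(lex$expandable))
  # entry order defines feature index
  expect_identical(feats[seq_len(nrow(lex))], lex$phrase)
  # "no pleural effusion" is an explicit entry, so the expansion defers to it
  f <- extract_features("no pleural effusion")
  expect_equal(unname(f["no pleural effusion"]), 1L)
  expect_equal(unname(f["pleural effusion|negated"]), 0L)
  # other cues still reach the negated feature
  f2 <- extract_features("without pleural effusion")
  expect_equal(unname(f2["pleural effusion|negated"]), 1L)
})

test_that("extract_features counts phrases with longest-match-wins", {
  f <- extract_features("Lungs are clear.")
  expect_equal(unname(f["lungs are clear"]), 1L)
  expect_equal(sum(f), 1L)
  f <- extract_features("No focal consolidation.")
  expect_equal(unname(f["focal consolidation|negated"]), 1L)
  expect_equal(unname(f["focal consolidation"]), 0L)
  expect_true(all(extract_features("") == 0L))
})

test_that("longest-match exclusivity holds for every expandable phrase and cue", {
  lex <- default_lexicon()
  cues <- default_negation_cues()
  for (p in lex$phrase[lex$expandable]) {
    for (cue in cues) {
      f <- extract_features(paste(cue, p))
      if (paste(cue, p) %in% lex$phrase) next  # explicit-entry collision
      expect_equal(unname(f[paste0(p, "|negated")]), 1L,
                   label = paste(cue, p))
      expect_equal(unname(f[p]), 0L, label = paste(cue, p))
    }
  }
})

test_that("feature counts are deterministic and additive across texts", {
  t1 <- "There is focal consolidation. No pleural effusion."
  t2 <- "The lungs are clear. Without pneumonia."
  f1 <- extract_features(t1)
  expect_identical(f1, extract_features(t1))
  # sentinel separator prevents cross-boundary matches
  joint <- extract_features(paste(t1, "xqzsep", t2))
  expect_equal(joint, f1 + extract_features(t2))
})

test_that("counts match a naive position-scan oracle on random texts", {
  lex <- default_lexicon()
  dict <- cxrnlp:::build_match_dictionary(lex)
  # Independent oracle: at each position try every dictionary phrase by
  # direct token comparison, longest first, consuming matched tokens.
  oracle_counts <- function(tokens) {
    counts <- integer(length(dict$feature_names))
    lens <- dict$len
    ord <- order(-lens)
    i <- 1L
    while (i <= length(tokens)) {
      hit <- 0L
      for (k in ord) {
        L <- dict$len[k]
        if (i + L - 1L > length(tokens)) next
        if (all(tokens[i:(i + L - 1L)] == dict$tokens[[k]])) {
          hit <- k
          break
        }
      }
      if (hit > 0L) {
        counts[dict$feature[hit]] <- counts[dict$feature[hit]] + 1L
        i <- i + dict$len[hit]
      } else {
        i <- i + 1L
      }
    }
    counts
  }
  vocab <- c(unlist(strsplit(lex$phrase, " ")), "the", "right", "lobe",
             "is", "seen", "no", "without", "for", "evidence")
  cxrnlp:::with_seed(99, {
    for (i in 1:1000) {
      tokens <- sample(vocab, sample(1:25, 1), replace = TRUE)
      got <- extract_features(paste(tokens, collapse = " "))
      expect_equal(unname(got), oracle_counts(tokens),
                   label = paste("case", i))
    }
  })
})

test_that("label_by_rules follows the positive-evidence rule", {
  expect_equal(label_by_rules(extract_features("Focal consolidation.")), 1L)
  expect_equal(label_by_rules(extract_features("Clear lungs.")), 0L)
  expect_equal(label_by_rules(extract_features("")), 0L)
  # hedged phrase is positive by default, negative under the switch
  hedge <- extract_features("Pneumonia cannot be excluded.")
  expect_equal(label_by_rules(hedge), 1L)
  expect_equal(label_by_rules(hedge, hedged_positive = FALSE), 0L)
  # matrix form
  m <- extract_feature_matrix(data.frame(
    report_id = c("a", "b"),
    text = c("Focal consolidation.", "No focal consolidation."),
    stringsAsFactors = FALSE))
  expect_equal(label_by_rules(m), c(1L, 0L))
})

test_that("lexicon CSV round-trips and validates polarity", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".csv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_equal(back$phrase, lex$phrase)
  expect_equal(back$polarity, lex$polarity)
  expect_equal(back$expandable, lex$expandable)
  bad <- data.frame(phrase = "x", polarity = "maybe", expandable = TRUE)
  expect_error(as_lexicon(bad), "unknown polarity")
  dup <- data.frame(phrase = c("Pneumonia", "pneumonia!"),
                    polarity = "indicates_pneumonia", expandable = TRUE)
  expect_error(as_lexicon(dup), "unique")
})
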