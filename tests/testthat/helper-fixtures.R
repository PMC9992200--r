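# Shared fixtures: small corpora and toy models built in code.

# A deterministic hand-written mini corpus exercising dedup, age bounds and
# empty text.
mini_corpus <- function() {
  data.frame(
    report_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7"),
    encounter_id = c("e1", "e1", "e2", "e3", "e4", "e5", "e6"),
    acquired_at = c("2010-01-01T10:00:00Z", "2010-01-01T12:00:00Z",
                    "2010-02-01T09:00:00Z", "2010-02-02T09:00:00Z",
                    "2010-02-03T09:00:00Z", "2010-02-04T09:00:00Z",
                    "2010-02-05T09:00:00Z"),
    age_months = c(24L, 24L, 2L, 220L, 36L, 48L, 60L),
    disposition = c("admitted", "admitted", "discharged", "discharged",
                    "admitted", "discharged", "discharged"),
    site = c("siteA", "siteA", "siteB", NA, "siteA", "siteB", "siteB"),
    text = c("IMPRESSION: Focal consolidation in the right lower lobe.",
             "IMPRESSION: Persistent focal consolidation.",
             "IMPRESSION: The lungs are clear.",
             "IMPRESSION: No focal consolidation.",
             "",
             "IMPRESSION: Clear lungs bilaterally.",
             "IMPRESSION: Pneumonia cannot be excluded."),
    stringsAsFactors = FALSE)
}

# Random corpus for round-trip property tests (texts include punctuation,
# quotes, commas and newlines to stress the serializers).
random_corpus <- function(n, seed) {
  words <- c("lungs", "clear", "focal", "consolidation", "no", "effusion",
             "heart", "normal,", "IMPRESSION:", "x-ray", '"quoted"',
             "tube;")
  cxrnlp:::with_seed(seed, {
    data.frame(
      report_id = sprintf("r%04d", seq_len(n)),
      encounter_id = sprintf("e%04d", sample.int(n, n)),
      acquired_at = format(as.POSIXct("2011-06-01", tz = "UTC") +
                             sample.int(1e6, n), "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
      age_months = sample(3:216, n, replace = TRUE),
      disposition = sample(c("admitted", "discharged"), n, replace = TRUE),
      site = ifelse(runif(n) < 0.2, NA_character_,
                    sample(c("siteA", "siteB"), n, replace = TRUE)),
      text = vapply(seq_len(n), function(i)
        paste(sample(words, sample(3:12, 1), replace = TRUE),
              collapse = " "), character(1)),
      stringsAsFactors = FALSE)
  })
}

# Toy embedding model with known vectors, for closed-form checks.
toy_embedding <- function() {
  v <- rbind(alpha = c(1, 0, 0),
             beta  = c(0, 1, 0),
             gamma = c(0, 0, 1),
             delta = c(1, 1, 0))
  structure(list(vectors = v, config = embedding_config(dim = 3L)),
            class = "embedding_model")
}

# Linearly separable toy training set: positives have count >= 1 on
# feature f1, negatives are all zero.
separable_toy <- function(n_pos = 10L, n_neg = 10L) {
  x <- rbind(cbind(f1 = sample(1:3, n_pos, replace = TRUE), f2 = 0L),
             cbind(f1 = 0L, f2 = 0L)[rep(1, n_neg), , drop = FALSE])
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  list(x = x, y = c(rep(1L, n_pos), rep(0L, n_neg)))
}
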