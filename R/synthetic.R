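#' Synthetic corpus generator configuration
#'
#' The generator emulates the structure of pediatric ED chest radiograph
#' reports (image type, clinical prompt, findings, impression), embedding
#' lexicon phrases with negated and hedged variants, and produces both an
#' expert truth label and a diagnosis-code label degraded at a configurable
#' operating point.
#'
#' Defaults state the emulated world: prevalence 0.156 (corpus-wide
#' diagnosis-code prevalence), code-label sensitivity 0.933 and specificity
#' 0.692 (the reported code-vs-expert operating point), admitted share 0.35.
#'
#' @param n Number of reports (>= 1).
#' @param prevalence Truth-label prevalence.
#' @param hedge_rate Probability a positive report carries only hedged
#'   language ("pneumonia cannot be excluded").
#' @param negation_rate Probability a negative report states a negated
#'   positive phrase ("no focal consolidation") rather than a normal-study
#'   phrase.
#' @param distractor_rate Probability of inserting each of up to two
#'   distractor sentences (lines/tubes, anatomy, comparisons).
#' @param code_sensitivity,code_specificity Operating point of the
#'   diagnosis-code label against truth.
#' @param admitted_rate Probability a report's encounter was admitted.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @param section_style `"full"` (four sections) or `"impression_only"`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n, prevalence = 0.156, hedge_rate = 0.05,
                             negation_rate = 0.5, distractor_rate = 0.3,
                             code_sensitivity = 0.933,
                             code_specificity = 0.692,
                             admitted_rate = 0.35, seed = 1L,
                             section_style = c("full", "impression_only")) {
  section_style <- match.arg(section_style)
  props <- c(prevalence, hedge_rate, negation_rate, distractor_rate,
             code_sensitivity, code_specificity, admitted_rate)
  if (any(props < 0 | props > 1)) {
    stop("all rate parameters must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 hedge_rate = hedge_rate, negation_rate = negation_rate,
                 distractor_rate = distractor_rate,
                 code_sensitivity = code_sensitivity,
                 code_specificity = code_specificity,
                 admitted_rate = admitted_rate, seed = as.integer(seed),
                 section_style = section_style),
            class = "generator_config")
}

# Template bank. Positive/negative finding and impression templates carry a
# "%s" slot for a lexicon phrase; distractors are complete sentences chosen
# to contain no lexicon phrase and no cue + expandable-phrase bigram.
synthetic_templates <- function() {
  list(
    exam = c("Single view chest radiograph.",
             "Two view chest radiograph.",
             "PA and lateral chest radiograph.",
             "Portable AP chest radiograph."),
    prompt = c("Cough and fever.", "Shortness of breath.",
               "Fever and tachypnea.", "Wheezing.", "Chest pain.",
               "Hypoxia.", "Respiratory distress.", "Cough for five days."),
    pos_find = c(
      "There is %s in the right lower lobe.",
      "There is %s involving the left lower lobe.",
      "Increased opacity with %s is seen at the right base.",
      "%s is present in the lingula.",
      "New %s compared with the prior study.",
      "There is %s obscuring the left heart border.",
      "Dense %s is identified in the retrocardiac region.",
      "Hazy %s is noted bilaterally.",
      "%s with associated volume loss is seen.",
      "Persistent %s at the right base.",
      "There is developing %s in the right middle lobe.",
      "%s is seen in the left perihilar region."),
    pos_impr = c(
      "Findings consistent with %s.",
      "%s in the right lower lobe.",
      "Findings concerning for %s.",
      "%s as described above.",
      "Findings compatible with %s.",
      "%s, clinical correlation recommended."),
    hedge_find = c(
      "Streaky bibasilar airspace markings.",
      "Vague opacity at the right base, incompletely characterized.",
      "Subtle increased density behind the heart of uncertain significance."),
    neg_comb_find = c(
      "There is %s.",
      "%s is identified.",
      "%s is seen.",
      "%s in either lung.",
      "%s on the current examination."),
    neg_comb_impr = c(
      "%s.",
      "There is %s.",
      "%s identified."),
    neg_phrase = c(
      "clear lungs" = "Clear lungs bilaterally.",
      "lungs are clear" = "The lungs are clear.",
      "no pleural effusion" = "There is no pleural effusion or pneumothorax.",
      "no abnormality" = "No abnormality is detected.",
      "normal chest radiograph" = "Normal chest radiograph.",
      "normal chest x-ray" = "Normal chest x-ray for age.",
      "within normal limits" = "The chest is within normal limits.",
      "negative chest" = "Negative chest examination.",
      "acute cardiopulmonary abnormality" =
        "No acute cardiopulmonary abnormality.",
      "evidence of acute cardiopulmonary disease" =
        "No evidence of acute cardiopulmonary disease.",
      "hyperinflation" = "Hyperinflation without focal opacity.",
      "reactive airway disease" = "Findings suggest reactive airway disease.",
      "viral bronchiolitis" = "Findings compatible with viral bronchiolitis."),
    distractor = c(
      "The cardiomediastinal silhouette is unremarkable.",
      "Endotracheal tube tip terminates above the carina.",
      "Enteric tube courses below the diaphragm.",
      "Comparison is made with the prior study.",
      "The bony thorax is intact.",
      "Mild rotation limits assessment.",
      "Visualized upper abdomen is unremarkable.",
      "Right upper extremity picc line tip in the superior vena cava.",
      "The trachea is midline.",
      "Heart size is at the upper range for age.",
      "Thymic shadow is prominent, consistent with age.",
      "Degree of inspiration is adequate.",
      "No displaced rib fracture is identified.",
      "Support lines and tubes are in standard position.",
      "The costophrenic angles are sharp.",
      "Soft tissues are unremarkable.",
      "Prior median sternotomy wires are noted.",
      "The aortic arch is left sided.",
      "Pulmonary vascularity is normal for age.",
      "Gaseous distension of the stomach is noted."))
}

# One report body; returns list(text, provenance). Consumes the current RNG
# stream.
synth_one_text <- function(truth, config, tmpl, lex_pos, lex_neg, cues) {
  prov <- character(0)
  pick <- function(bank, prefix) {
    i <- sample.int(length(bank), 1L)
    prov <<- c(prov, paste0(prefix, "_", sprintf("%02d", i)))
    bank[[i]]
  }
  hedged <- truth == 1L && runif(1) < config$hedge_rate
  if (truth == 1L) {
    if (hedged) {
      find_sent <- pick(tmpl$hedge_find, "hedge_find")
      impr_sent <- "Pneumonia cannot be excluded."
      prov <- c(prov, "hedge_impr")
    } else {
      find_sent <- sprintf(pick(tmpl$pos_find, "pos_find"),
                           pick(lex_pos, "pos_phrase"))
      impr_sent <- sprintf(pick(tmpl$pos_impr, "pos_impr"),
                           pick(lex_pos, "pos_phrase"))
      substr(impr_sent, 1, 1) <- toupper(substr(impr_sent, 1, 1))
    }
  } else {
    negated <- runif(1) < config$negation_rate
    if (negated) {
      comb <- paste(pick(cues, "cue"), pick(lex_pos, "pos_phrase"))
      find_sent <- sprintf(pick(tmpl$neg_comb_find, "neg_comb_find"), comb)
      impr_sent <- sprintf(pick(tmpl$neg_comb_impr, "neg_comb_impr"), comb)
      substr(find_sent, 1, 1) <- toupper(substr(find_sent, 1, 1))
      substr(impr_sent, 1, 1) <- toupper(substr(impr_sent, 1, 1))
    } else {
      find_sent <- pick(tmpl$neg_phrase, "neg_phrase")
      impr_sent <- pick(tmpl$neg_phrase, "neg_phrase")
    }
  }
  findings <- find_sent
  for (d in 1:2) {
    if (runif(1) < config$distractor_rate) {
      findings <- paste(findings, pick(tmpl$distractor, "dist"))
    }
  }
  text <- if (config$section_style == "impression_only") {
    paste0("IMPRESSION: ", impr_sent)
  } else {
    paste0("EXAM: ", pick(tmpl$exam, "exam"),
           " CLINICAL HISTORY: ", pick(tmpl$prompt, "prompt"),
           " FINDINGS: ", findings,
           " IMPRESSION: ", impr_sent)
  }
  list(text = text, provenance = prov)
}

#' Generate one synthetic report text
#'
#' Draws from the template bank under the current RNG state; callers wanting
#' reproducibility should seed the RNG (as [generate_corpus()] does).
#'
#' @param truth Binary truth label for the report.
#' @param config A [generator_config()].
#' @param lexicon Lexicon supplying the embedded phrases.
#' @return List with `text` and `provenance` (template ids used).
#' @export
generate_report_text <- function(truth, config, lexicon = default_lexicon()) {
  tmpl <- synthetic_templates()
  lex_pos <- lexicon$phrase[lexicon$polarity == "indicates_pneumonia" &
                              lexicon$expandable]
  synth_one_text(as.integer(truth), config, tmpl, lex_pos,
                 lexicon$phrase[lexicon$polarity == "indicates_no_pneumonia"],
                 default_negation_cues())
}

#' Generate a synthetic report corpus with labels
#'
#' Produces exactly `n` records: a corpus `data.frame` (schema of
#' [read_corpus()]) plus per-record `truth_label`, `code_label`, and
#' `provenance`. Truth labels are Bernoulli(`prevalence`); positive reports
#' embed at least one pneumonia-indicating phrase (hedged with probability
#' `hedge_rate`); negative reports embed a normal-study phrase or a negated
#' positive phrase; the code label is truth degraded through
#' (`code_sensitivity`, `code_specificity`). Identical seeds give identical
#' corpora.
#'
#' @param config A [generator_config()].
#' @param lexicon Lexicon supplying the embedded phrases.
#' @return List of class `synthetic_corpus`: `corpus` (`data.frame`),
#'   `labels` (`data.frame` with `encounter_id`, `truth_label`,
#'   `code_label`), `provenance` (list), `config`.
#' @export
generate_corpus <- function(config, lexicon = default_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  tmpl <- synthetic_templates()
  lex_pos <- lexicon$phrase[lexicon$polarity == "indicates_pneumonia" &
                              lexicon$expandable]
  lex_neg <- lexicon$phrase[lexicon$polarity == "indicates_no_pneumonia"]
  cues <- default_negation_cues()
  n <- config$n
  out <- with_seed(config$seed, {
    truth <- as.integer(runif(n) < config$prevalence)
    code <- ifelse(truth == 1L,
                   as.integer(runif(n) < config$code_sensitivity),
                   as.integer(runif(n) >= config$code_specificity))
    age <- pmin(216L, pmax(3L, as.integer(round(exp(
      runif(n, log(3), log(216)))))))
    admitted <- runif(n) < config$admitted_rate
    minutes <- sort(sample.int(3L * 365L * 24L * 60L, n, replace = TRUE))
    texts <- vector("list", n)
    for (i in seq_len(n)) {
      texts[[i]] <- synth_one_text(truth[i], config, tmpl, lex_pos, lex_neg,
                                   cues)
    }
    list(truth = truth, code = code, age = age, admitted = admitted,
         minutes = minutes, texts = texts)
  })
  if (length(unique(out$truth)) < 2L) {
    warning("generated corpus contains a single truth class")
  }
  ids <- sprintf("%06d", seq_len(n))
  corpus <- data.frame(
    report_id = paste0("rpt", ids),
    encounter_id = paste0("enc", ids),
    acquired_at = format(as.POSIXct("2010-01-01 00:00:00", tz = "UTC") +
                           out$minutes * 60, "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"),
    age_months = out$age,
    disposition = ifelse(out$admitted, "admitted", "discharged"),
    site = "siteA",
    text = vapply(out$texts, `[[`, character(1), "text"),
    stringsAsFactors = FALSE)
  labels <- data.frame(encounter_id = corpus$encounter_id,
                       truth_label = out$truth, code_label = out$code,
                       stringsAsFactors = FALSE)
  structure(list(corpus = corpus, labels = labels,
                 provenance = lapply(out$texts, `[[`, "provenance"),
                 config = config,
                 single_class = length(unique(out$truth)) < 2L),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("synthetic corpus: n =", nrow(x$corpus), ", truth prevalence =",
      round(mean(x$labels$truth_label), 3), ", code prevalence =",
      round(mean(x$labels$code_label), 3), "\n")
  invisible(x)
}
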