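# Derive a per-stage seed from the run seed and the stage name, so each
# stage is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed); the pipeline never
#'   writes outside it.
#' @param corpus_path,labels_path Input corpus (JSONL/CSV) and labels CSV;
#'   `NULL` to generate a synthetic corpus instead.
#' @param generator A [generator_config()] used when no corpus is supplied.
#' @param lexicon_path Optional lexicon CSV; default lexicon otherwise.
#' @param validation_fraction,admitted_share Split parameters.
#' @param models List of [model_spec()]s; `NULL` for all five defaults.
#' @param embedding An [embedding_config()], or `NULL` to disable the
#'   embedding classifier.
#' @param reference_standards Subset of `c("expert", "code")`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, corpus_path = NULL, labels_path = NULL,
                       generator = generator_config(n = 5000L),
                       lexicon_path = NULL, validation_fraction = 0.01,
                       admitted_share = 0.35, models = NULL,
                       embedding = embedding_config(),
                       reference_standards = c("expert", "code"),
                       seed = 1L) {
  reference_standards <- match.arg(reference_standards,
                                   c("expert", "code"), several.ok = TRUE)
  models <- models %||% default_model_specs(seed)
  if (length(models) == 0L && is.null(embedding)) {
    stop("config error: enable at least one model or the embedding ",
         "classifier", call. = FALSE)
  }
  structure(list(out_dir = out_dir, corpus_path = corpus_path,
                 labels_path = labels_path, generator = generator,
                 lexicon_path = lexicon_path,
                 validation_fraction = validation_fraction,
                 admitted_share = admitted_share, models = models,
                 embedding = embedding,
                 reference_standards = reference_standards,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; `.yaml`/`.yml` requires the yaml package,
#'   anything else is parsed as JSON.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  gen <- if (!is.null(raw$generator)) do.call(generator_config, raw$generator)
         else generator_config(n = 5000L)
  emb <- if (isFALSE(raw$embedding)) NULL
         else do.call(embedding_config, raw$embedding %||% list())
  models <- if (!is.null(raw$models)) {
    lapply(raw$models, function(m) do.call(model_spec, m))
  } else NULL
  run_config(out_dir = raw$out_dir %||% ".",
             corpus_path = raw$corpus_path, labels_path = raw$labels_path,
             generator = gen, lexicon_path = raw$lexicon_path,
             validation_fraction = raw$validation_fraction %||% 0.01,
             admitted_share = raw$admitted_share %||% 0.35,
             models = models, embedding = emb,
             reference_standards = raw$reference_standards %||%
               c("expert", "code"),
             seed = raw$seed %||% 1L)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(stage, t0, n) {
  message(sprintf("[%s] elapsed %.2fs, n = %d", stage,
                  as.numeric(proc.time()[3]) - t0, n))
}

#' Run the full classification pipeline
#'
#' Generate (or read) a corpus, apply inclusion criteria, split into
#' derivation/validation, featurize, train the supervised models on
#' diagnosis-code labels, classify with the embedding model, and evaluate
#' every method against the configured reference standards. Writes
#' `metrics.csv`, `exclusions.csv`, the split corpora, and a `manifest.json`
#' with the config echo, seed, package version, and content hashes of every
#' output file.
#'
#' @param config A [run_config()].
#' @return List with `metrics` (`data.frame`), `manifest`, and file paths,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()[3])
  lexicon <- if (!is.null(config$lexicon_path)) {
    read_lexicon(config$lexicon_path)
  } else default_lexicon()

  # --- corpus ---------------------------------------------------------
  if (is.null(config$corpus_path)) {
    gen <- config$generator
    gen$seed <- stage_seed(config$seed, "generate")
    synth <- pipeline_stage("generate", generate_corpus(gen, lexicon))
    corpus <- synth$corpus
    labels <- data.frame(encounter_id = synth$labels$encounter_id,
                         expert_label = synth$labels$truth_label,
                         code_label = synth$labels$code_label,
                         stringsAsFactors = FALSE)
  } else {
    fmt <- if (grepl("\\.csv$", config$corpus_path)) "csv" else "jsonl"
    corpus <- pipeline_stage("read", read_corpus(config$corpus_path, fmt))
    labels <- pipeline_stage("read", read_labels(config$labels_path))
  }
  log_stage("corpus", t0, nrow(corpus))

  # --- inclusion + split ----------------------------------------------
  inc <- pipeline_stage("inclusion", apply_inclusion(corpus))
  split <- pipeline_stage("split", stratified_split(
    inc$included, config$validation_fraction, config$admitted_share,
    seed = stage_seed(config$seed, "split")))
  log_stage("split", t0, nrow(split$validation))

  # --- featurize -------------------------------------------------------
  feats_train <- pipeline_stage("featurize",
                                extract_feature_matrix(split$derivation,
                                                       lexicon))
  feats_eval <- pipeline_stage("featurize",
                               extract_feature_matrix(split$validation,
                                                      lexicon))
  log_stage("featurize", t0, nrow(feats_train) + nrow(feats_eval))

  lab_of <- function(corp, col) {
    setNames(labels[[col]], labels$encounter_id)[corp$encounter_id]
  }
  refs <- lapply(setNames(nm = config$reference_standards), function(std) {
    lab_of(split$validation,
           if (std == "expert") "expert_label" else "code_label")
  })
  y_train <- lab_of(split$derivation, "code_label")

  # --- supervised models ----------------------------------------------
  rows <- list()
  if (length(config$models) > 0L) {
    tbl <- pipeline_stage("train", benchmark_suite(
      feats_train, y_train, feats_eval, refs, config$models))
    rows[[length(rows) + 1L]] <- tbl
  }
  log_stage("train", t0, length(config$models))

  # --- embedding classifier -------------------------------------------
  if (!is.null(config$embedding)) {
    emb_cfg <- config$embedding
    emb_cfg$seed <- stage_seed(config$seed, "embedding")
    model <- pipeline_stage("embedding",
                            train_skipgram(split$derivation, emb_cfg))
    pred <- pipeline_stage("embedding", embedding_classify_corpus(
      split$validation, model, default_reference_phrases(lexicon)))
    for (std in names(refs)) {
      ms <- metrics(confusion(pred$label, refs[[std]]))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = "word_embedding", reference = std,
                   stringsAsFactors = FALSE),
        as.data.frame(ms))
    }
    log_stage("embedding", t0, nrow(split$validation))
  }

  metrics_tbl <- do.call(rbind, rows)
  metrics_tbl$seed <- config$seed

  # --- outputs + manifest ---------------------------------------------
  paths <- list(metrics = file.path(config$out_dir, "metrics.csv"),
                exclusions = file.path(config$out_dir, "exclusions.csv"),
                derivation = file.path(config$out_dir, "derivation.jsonl"),
                validation = file.path(config$out_dir, "validation.jsonl"),
                labels = file.path(config$out_dir, "labels.csv"))
  utils::write.csv(metrics_tbl, paths$metrics, row.names = FALSE)
  utils::write.csv(inc$exclusion_log, paths$exclusions, row.names = FALSE)
  write_corpus(split$derivation, paths$derivation, "jsonl")
  write_corpus(split$validation, paths$validation, "jsonl")
  labels$reviewer1 <- NA_integer_
  labels$reviewer2 <- NA_integer_
  labels$adjudicated_by_third <- FALSE
  write_labels(labels, paths$labels)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cxrnlp")),
    seed = config$seed,
    config = list(validation_fraction = config$validation_fraction,
                  admitted_share = config$admitted_share,
                  reference_standards = config$reference_standards,
                  models = vapply(config$models, `[[`, character(1),
                                  "family"),
                  embedding_enabled = !is.null(config$embedding)),
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics_tbl, manifest = manifest, paths = paths))
}

#' Verify a pipeline manifest
#'
#' Recomputes the content hash of each file listed in a `manifest.json` and
#' reports mismatches.
#'
#' @param out_dir Directory holding `manifest.json` and the outputs.
#' @return `TRUE` if all hashes match, otherwise a character vector of
#'   mismatched files.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  bad <- character(0)
  for (o in manifest$outputs) {
    actual <- unname(tools::md5sum(file.path(out_dir, o$path)))
    if (!identical(actual, o$md5)) bad <- c(bad, o$path)
  }
  if (length(bad) == 0L) TRUE else bad
}
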