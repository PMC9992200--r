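#' Corpus data model and I/O
#'
#' A report corpus is a plain `data.frame` with one row per chest radiograph
#' (CXR) report and the columns `report_id`, `encounter_id`, `acquired_at`
#' (ISO-8601 timestamp string, lexicographically orderable), `age_months`
#' (integer), `disposition` (`"admitted"` or `"discharged"`), `site`
#' (optional, may be `NA`) and `text` (free text; may be empty before
#' inclusion filtering). Optional `modality` and `setting` columns, when
#' present, participate in inclusion filtering.
#'
#' @param corpus A corpus `data.frame`.
#' @param allow_empty_text Permit empty report text (pre-inclusion corpora).
#' @return The validated corpus, invisibly.
#' @export
validate_corpus <- function(corpus, allow_empty_text = TRUE) {
  required <- c("report_id", "encounter_id", "acquired_at", "age_months",
                "disposition", "text")
  missing <- setdiff(required, names(corpus))
  if (length(missing) > 0L) {
    stop("corpus is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(corpus$report_id)) {
    stop("report_id values must be unique within a corpus", call. = FALSE)
  }
  bad_disp <- !corpus$disposition %in% c("admitted", "discharged")
  if (any(bad_disp)) {
    stop("disposition must be 'admitted' or 'discharged'; offending report_id: ",
         paste(head(corpus$report_id[bad_disp], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!allow_empty_text && any(is.na(corpus$text) | !nzchar(trimws(corpus$text)))) {
    stop("corpus contains empty report text", call. = FALSE)
  }
  invisible(corpus)
}

corpus_columns <- c("report_id", "encounter_id", "acquired_at", "age_months",
                    "disposition", "site", "text")

#' Read a report corpus from JSONL or CSV
#'
#' JSONL holds one report object per line (UTF-8). CSV must carry a header
#' with the corpus columns; `text` is CSV-quoted. Records with missing or
#' empty `text` are kept and flagged in the returned `flag_empty_text`
#' attribute rather than dropped; a record lacking a required *key* is a
#' schema error naming the field and line.
#'
#' @param path File to read.
#' @param format `"jsonl"` or `"csv"`.
#' @return A corpus `data.frame` in input order.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus: no such file: ", path,
                               call. = FALSE)
  required <- setdiff(corpus_columns, "site")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("malformed JSON on line ", i,
                                               ": ", conditionMessage(e),
                                               call. = FALSE))
      miss <- setdiff(required, names(rec))
      if (length(miss) > 0L) {
        stop("schema error: line ", i, " is missing field(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      data.frame(report_id = as.character(rec$report_id),
                 encounter_id = as.character(rec$encounter_id),
                 acquired_at = as.character(rec$acquired_at),
                 age_months = as.integer(rec$age_months),
                 disposition = as.character(rec$disposition),
                 site = as.character(rec$site %||% NA_character_),
                 text = as.character(rec$text),
                 stringsAsFactors = FALSE)
    })
    corpus <- do.call(rbind, recs)
  } else {
    corpus <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character", encoding = "UTF-8")
    miss <- setdiff(required, names(corpus))
    if (length(miss) > 0L) {
      stop("schema error: CSV header is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!"site" %in% names(corpus)) corpus$site <- NA_character_
    corpus$site[!is.na(corpus$site) & corpus$site == ""] <- NA_character_
    corpus$age_months <- as.integer(corpus$age_months)
    corpus <- corpus[, union(corpus_columns, names(corpus)), drop = FALSE]
  }
  if (is.null(corpus)) {
    corpus <- data.frame(report_id = character(), encounter_id = character(),
                         acquired_at = character(), age_months = integer(),
                         disposition = character(), site = character(),
                         text = character(), stringsAsFactors = FALSE)
  }
  validate_corpus(corpus)
  attr(corpus, "flag_empty_text") <-
    corpus$report_id[is.na(corpus$text) | !nzchar(trimws(corpus$text))]
  corpus
}

#' Write a report corpus to JSONL or CSV
#'
#' @inheritParams read_corpus
#' @param corpus Corpus `data.frame`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  corpus <- corpus[, corpus_columns, drop = FALSE]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- as.list(corpus[i, , drop = FALSE])
      if (is.na(rec$site)) rec$site <- NULL
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(corpus, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read / write label records
#'
#' Labels travel as CSV with columns `encounter_id`, `expert_label`,
#' `code_label`, `reviewer1`, `reviewer2`, `adjudicated_by_third`, with 0/1
#' encoding (empty = not available).
#'
#' @param path File path.
#' @return A `data.frame` of label records.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"encounter_id" %in% names(df)) {
    stop("schema error: labels CSV is missing column: encounter_id",
         call. = FALSE)
  }
  df$encounter_id <- as.character(df$encounter_id)
  for (col in c("expert_label", "code_label", "reviewer1", "reviewer2")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  if ("adjudicated_by_third" %in% names(df)) {
    df$adjudicated_by_third <- as.logical(as.integer(df$adjudicated_by_third))
  }
  df
}

#' @rdname read_labels
#' @param labels Label `data.frame`.
#' @export
write_labels <- function(labels, path) {
  out <- labels
  if ("adjudicated_by_third" %in% names(out)) {
    out$adjudicated_by_third <- as.integer(out$adjudicated_by_third)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply cohort inclusion criteria
#'
#' Filters a corpus to the analysis cohort: pediatric emergency-department
#' CXR reports with non-empty text, ages 3 months to 18 years, one report
#' per encounter (the earliest by `acquired_at`; timestamp ties broken
#' lexicographically by `report_id`). Exclusion reasons are mutually
#' exclusive and applied in the fixed order non_cxr, missing_report, non_ed,
#' age, duplicate_cxr; the first two funnel stages only apply when the
#' optional `modality` / `setting` columns are present.
#'
#' @param reports Corpus `data.frame`.
#' @param age_range Inclusive age bounds in months (default 3-216).
#' @return A list with `included` (the filtered corpus, input order
#'   preserved) and `exclusion_log` (`data.frame` of `reason`, `n`).
#' @export
apply_inclusion <- function(reports, age_range = c(3L, 216L)) {
  validate_corpus(reports)
  reasons <- c("non_cxr", "missing_report", "non_ed", "age", "duplicate_cxr")
  excl <- setNames(integer(length(reasons)), reasons)
  keep <- rep(TRUE, nrow(reports))

  if ("modality" %in% names(reports)) {
    drop <- keep & reports$modality != "CXR"
    excl[["non_cxr"]] <- sum(drop)
    keep <- keep & !drop
  }
  drop <- keep & (is.na(reports$text) | !nzchar(trimws(reports$text)))
  excl[["missing_report"]] <- sum(drop)
  keep <- keep & !drop

  if ("setting" %in% names(reports)) {
    drop <- keep & reports$setting != "ED"
    excl[["non_ed"]] <- sum(drop)
    keep <- keep & !drop
  }
  drop <- keep & (is.na(reports$age_months) |
                    reports$age_months < age_range[1] |
                    reports$age_months > age_range[2])
  excl[["age"]] <- sum(drop)
  keep <- keep & !drop

  # Dedup: earliest acquired_at per encounter among survivors; ties broken by
  # report_id so the result is deterministic.
  idx <- which(keep)
  if (length(idx) > 0L) {
    ord <- idx[order(reports$encounter_id[idx], reports$acquired_at[idx],
                     reports$report_id[idx])]
    first <- ord[!duplicated(reports$encounter_id[ord])]
    dup <- setdiff(idx, first)
    excl[["duplicate_cxr"]] <- length(dup)
    keep[dup] <- FALSE
  }

  list(included = reports[keep, , drop = FALSE],
       exclusion_log = data.frame(reason = reasons, n = as.integer(excl),
                                  stringsAsFactors = FALSE))
}

#' Disposition-stratified derivation/validation split
#'
#' Draws a validation sample of `round(validation_fraction * N)` reports
#' (rounding half away from zero) stratified so that the admitted share of
#' the validation sample is within one report of `admitted_share`; all
#' remaining reports form the derivation sample. The split is deterministic
#' for a fixed `seed`.
#'
#' @param reports Included corpus `data.frame`.
#' @param validation_fraction Proportion in (0,1); default 0.01.
#' @param admitted_share Target admitted proportion of the validation sample,
#'   in 0-1; default 0.35.
#' @param seed Integer RNG seed.
#' @return List with `derivation` and `validation` corpora (disjoint; their
#'   union is the input).
#' @export
stratified_split <- function(reports, validation_fraction = 0.01,
                             admitted_share = 0.35, seed = 1L) {
  validate_corpus(reports)
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    stop("validation_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (admitted_share < 0 || admitted_share > 1) {
    stop("admitted_share must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(reports)
  size <- max(1L, as.integer(round_half_up(validation_fraction * n)))
  n_adm <- as.integer(round_half_up(admitted_share * size))
  n_dis <- size - n_adm
  adm_idx <- which(reports$disposition == "admitted")
  dis_idx <- which(reports$disposition == "discharged")
  if (length(adm_idx) < n_adm) {
    stop("admitted stratum too small: need ", n_adm, " but only ",
         length(adm_idx), " available; achievable maximum admitted_share is ",
         signif(length(adm_idx) / size, 3), call. = FALSE)
  }
  if (length(dis_idx) < n_dis) {
    stop("discharged stratum too small: need ", n_dis, " but only ",
         length(dis_idx), " available; achievable maximum admitted_share is ",
         signif(1 - length(dis_idx) / size, 3), call. = FALSE)
  }
  val_idx <- with_seed(seed, {
    c(if (n_adm > 0L) sample(adm_idx, n_adm),
      if (n_dis > 0L) sample(dis_idx, n_dis))
  })
  val_idx <- sort(val_idx)
  list(derivation = reports[-val_idx, , drop = FALSE],
       validation = reports[val_idx, , drop = FALSE])
}

#' Adjudicate dual-annotator labels
#'
#' Concordant encounters take the shared label; discordant encounters take
#' the third reviewer's tie-break label and are flagged
#' `adjudicated_by_third`.
#'
#' @param r1,r2 Named 0/1 vectors (names = encounter ids) from the two
#'   primary reviewers; must cover identical id sets.
#' @param tiebreak Named 0/1 vector covering exactly the discordant ids.
#' @return A label-record `data.frame` with columns `encounter_id`,
#'   `reviewer1`, `reviewer2`, `expert_label`, `adjudicated_by_third`.
#' @export
adjudicate <- function(r1, r2, tiebreak = NULL) {
  ids <- names(r1)
  if (is.null(ids) || is.null(names(r2))) {
    stop("r1 and r2 must be named vectors (names are encounter ids)",
         call. = FALSE)
  }
  if (!setequal(ids, names(r2))) {
    stop("r1 and r2 must cover identical encounter id sets", call. = FALSE)
  }
  r2 <- r2[ids]
  stopifnot(all(r1 %in% 0:1), all(r2 %in% 0:1))
  discordant <- ids[r1 != r2]
  tiebreak <- tiebreak %||% setNames(integer(0), character(0))
  missing <- setdiff(discordant, names(tiebreak))
  if (length(missing) > 0L) {
    stop("tiebreak labels missing for discordant encounter id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tiebreak), discordant)
  if (length(extra) > 0L) {
    stop("tiebreak covers non-discordant encounter id(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  expert <- as.integer(r1)
  adj <- ids %in% discordant
  expert[adj] <- as.integer(tiebreak[ids[adj]])
  data.frame(encounter_id = ids,
             reviewer1 = as.integer(r1),
             reviewer2 = as.integer(r2),
             expert_label = expert,
             adjudicated_by_third = adj,
             stringsAsFactors = FALSE)
}
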