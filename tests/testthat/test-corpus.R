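test_that("JSONL and CSV round-trips are the identity on all fields", {
  for (seed in 1:5) {
    corpus <- random_corpus(40, seed)
    for (fmt in c("jsonl", "csv")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_corpus(corpus, path, fmt)
      back <- read_corpus(path, fmt)
      for (col in names(corpus)) {
        expect_identical(back[[col]], corpus[[col]],
                         label = paste(fmt, col, "seed", seed))
      }
    }
  }
})

test_that("read_corpus reports schema errors with field and line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"a","encounter_id":"e1","acquired_at":"2010-01-01T00:00:00Z","age_months":12,"disposition":"admitted","text":"ok"}',
    '{"report_id":"b","encounter_id":"e2","acquired_at":"2010-01-01T00:00:00Z","age_months":12,"disposition":"admitted"}'),
    path)
  expect_error(read_corpus(path, "jsonl"), "line 2.*text")
  expect_error(read_corpus(tempfile(), "jsonl"), "no such file")
})

test_that("empty-text records are flagged, not dropped", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(mini_corpus(), path, "jsonl")
  got <- read_corpus(path, "jsonl")
  expect_equal(nrow(got), 7L)
  expect_equal(attr(got, "flag_empty_text"), "r5")
})

test_that("apply_inclusion keeps the first CXR per encounter and logs reasons", {
  res <- apply_inclusion(mini_corpus())
  inc <- res$included
  # e1 keeps the earlier r1; r3 excluded (age 2), r4 excluded (age 220),
  # r5 excluded (empty text)
  expect_setequal(inc$report_id, c("r1", "r6", "r7"))
  log <- setNames(res$exclusion_log$n, res$exclusion_log$reason)
  expect_equal(unname(log[c("missing_report", "age", "duplicate_cxr")]),
               c(1L, 2L, 1L))
  expect_equal(unname(log[c("non_cxr", "non_ed")]), c(0L, 0L))
})

test_that("inclusion handles timestamp ties deterministically and is idempotent", {
  corpus <- mini_corpus()
  corpus$acquired_at[2] <- corpus$acquired_at[1]  # tie on e1
  res <- apply_inclusion(corpus)
  expect_true("r1" %in% res$included$report_id)  # lexicographic tie-break
  again <- apply_inclusion(res$included)
  expect_identical(again$included, res$included)
  expect_true(all(again$exclusion_log$n == 0L))
})

test_that("optional modality/setting columns drive the first funnel stages", {
  corpus <- mini_corpus()
  corpus$modality <- c("CXR", "CXR", "CT", "CXR", "CXR", "CXR", "CXR")
  corpus$setting <- c("ED", "ED", "ED", "ED", "ED", "inpatient", "ED")
  res <- apply_inclusion(corpus)
  log <- setNames(res$exclusion_log$n, res$exclusion_log$reason)
  expect_equal(unname(log["non_cxr"]), 1L)   # r3 (CT) before its age check
  expect_equal(unname(log["non_ed"]), 1L)    # r6
  expect_setequal(res$included$report_id, c("r1", "r7"))
})

test_that("stratified_split sizes and strata follow the contract", {
  n <- 135000L
  corpus <- data.frame(
    report_id = sprintf("r%06d", seq_len(n)),
    encounter_id = sprintf("e%06d", seq_len(n)),
    acquired_at = "2010-01-01T00:00:00Z",
    age_months = 24L,
    disposition = rep(c("admitted", "discharged"), c(47000L, 88000L)),
    site = NA_character_, text = "IMPRESSION: The lungs are clear.",
    stringsAsFactors = FALSE)
  sp <- stratified_split(corpus, 0.01, 0.35, seed = 3)
  expect_equal(nrow(sp$validation), 1350L)
  n_adm <- sum(sp$validation$disposition == "admitted")
  expect_true(n_adm %in% c(472L, 473L))
  # conservation and disjointness
  expect_equal(nrow(sp$derivation) + nrow(sp$validation), n)
  expect_length(intersect(sp$derivation$report_id,
                          sp$validation$report_id), 0L)
  # determinism
  sp2 <- stratified_split(corpus, 0.01, 0.35, seed = 3)
  expect_identical(sp2$validation$report_id, sp$validation$report_id)
})

test_that("stratified_split rounds small validation sets to >= 1 and errors on thin strata", {
  corpus <- random_corpus(100, 1)
  sp <- stratified_split(corpus, 0.01, admitted_share = 0, seed = 1)
  expect_equal(nrow(sp$validation), 1L)
  all_adm <- corpus
  all_adm$disposition <- "admitted"
  expect_error(stratified_split(all_adm, 0.2, admitted_share = 0.35, seed = 1),
               "achievable maximum")
})

test_that("mean admitted share over 200 seeded splits matches the target", {
  corpus <- random_corpus(2000, 42)
  shares <- vapply(1:200, function(s) {
    v <- stratified_split(corpus, 0.05, 0.35, seed = s)$validation
    mean(v$disposition == "admitted")
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.35), 0.01)
})

test_that("adjudicate resolves concordant and discordant ids per contract", {
  ids <- sprintf("e%02d", 1:10)
  r1 <- setNames(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0), ids)
  # identity case
  out <- adjudicate(r1, r1)
  expect_equal(out$expert_label, unname(as.integer(r1)))
  expect_false(any(out$adjudicated_by_third))
  # one discordant id resolved positive
  r2 <- r1
  r2["e04"] <- 1
  out <- adjudicate(r1, r2, tiebreak = c(e04 = 1))
  expect_equal(out$expert_label[out$encounter_id == "e04"], 1L)
  expect_equal(sum(out$adjudicated_by_third), 1L)
  # missing tiebreak id is an error naming the id
  expect_error(adjudicate(r1, r2), "e04")
  expect_error(adjudicate(r1, r2, tiebreak = c(e04 = 1, e05 = 0)),
               "non-discordant")
})

test_that("an agreement table constructed for kappa 0.86 adjudicates exactly its discordant ids", {
  # Brute-force search over symmetric 2x2 integer agreement tables of size
  # 1350 for unweighted kappa printing as 0.86 (independent arithmetic).
  n <- 1350L
  found <- NULL
  for (a in 150:250) {
    for (b in 0:60) {
      d <- n - a - 2L * b
      if (d < 0L) next
      po <- (a + d) / n
      p1 <- (a + b) / n
      p2 <- (a + b) / n
      pe <- p1 * p2 + (1 - p1) * (1 - p2)
      kap <- (po - pe) / (1 - pe)
      if (round(kap, 2) == 0.86) {
        found <- c(a = a, b = b, d = d)
        break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  ids <- sprintf("e%04d", seq_len(n))
  r1 <- setNames(rep(0L, n), ids)
  r2 <- r1
  a <- found["a"]; b <- found["b"]
  r1[1:(a + b)] <- 1L                       # rater 1 positives
  r2[1:a] <- 1L                             # shared positives
  r2[(a + b + 1):(a + 2 * b)] <- 1L         # rater 2 only
  agr <- cohens_kappa(unname(r1), unname(r2))
  expect_equal(round(agr$kappa, 2), 0.86)
  disc <- ids[r1 != r2]
  out <- adjudicate(r1, r2, tiebreak = setNames(rep(1L, length(disc)), disc))
  expect_equal(sum(out$adjudicated_by_third), length(disc))
  expect_equal(length(disc), unname(2L * b))
})

test_that("label records survive a CSV round trip", {
  labs <- data.frame(encounter_id = c("e1", "e2"), expert_label = c(1L, 0L),
                     code_label = c(1L, 1L), reviewer1 = c(1L, 0L),
                     reviewer2 = c(1L, 1L),
                     adjudicated_by_third = c(FALSE, TRUE),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(labs, path)
  expect_identical(read_labels(path), labs)
})
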