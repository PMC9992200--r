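#' Build a 2x2 confusion matrix
#'
#' @param pred,truth Binary 0/1 vectors of equal length.
#' @return An object of class `confusion`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length", call. = FALSE)
  }
  if (length(pred) < 1L) stop("need at least one observation", call. = FALSE)
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  confusion_matrix(tp = sum(pred == 1L & truth == 1L),
                   fp = sum(pred == 1L & truth == 0L),
                   fn = sum(pred == 0L & truth == 1L),
                   tn = sum(pred == 0L & truth == 0L))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("confusion matrix is all zero", call. = FALSE)
  structure(as.list(as.integer(cells)) |> setNames(names(cells)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(pred = c("1", "0"), truth = c("1", "0")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param level Two-sided confidence level (default 0.95).
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return Numeric `c(lo, hi)`; `lo = 0` when `k = 0`, `hi = 1` when
#'   `k = n` (Clopper-Pearson).
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("k must lie in [0, n]", call. = FALSE)
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (k == 0L) 0 else qbeta(a / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  } else {
    z <- qnorm(1 - a / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  c(lo = lo, hi = hi)
}

#' Log-method confidence intervals for likelihood ratios
#'
#' `exp(log LR +/- z * SE)` with `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) +
#' 1/fp - 1/(fp+tn))` and the analogous expression for LR-. When a cell in
#' the relevant numerator is zero, a 0.5 continuity correction is applied to
#' all four cells and the result is flagged `corrected`.
#'
#' @param cm A `confusion`.
#' @param level Confidence level.
#' @return List with `lr_pos`, `lr_neg`, each `c(est, lo, hi)`, and
#'   `corrected` flags.
#' @export
likelihood_ratio_ci <- function(cm, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  one <- function(a, b, c_, d) {
    # LR = (a/(a+b)) / (c_/(c_+d)); SE on the log scale.
    corrected <- a == 0L || c_ == 0L
    if (corrected) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    lr <- (a / (a + b)) / (c_ / (c_ + d))
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
    c(est = lr, lo = exp(log(lr) - z * se), hi = exp(log(lr) + z * se),
      corrected = as.numeric(corrected))
  }
  # LR+ = sens/(1-spec) compares tp/(tp+fn) with fp/(fp+tn);
  # LR- = (1-sens)/spec compares fn/(tp+fn) with tn/(fp+tn).
  pos <- one(cm$tp, cm$fn, cm$fp, cm$tn)
  neg <- one(cm$fn, cm$tp, cm$tn, cm$fp)
  list(lr_pos = pos[1:3], lr_neg = neg[1:3],
       corrected = c(lr_pos = unname(pos[4]) == 1,
                     lr_neg = unname(neg[4]) == 1))
}

#' Diagnostic-accuracy metrics from a confusion matrix
#'
#' Computes sensitivity (recall), specificity, PPV (precision), NPV,
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, F1 `2(precision x recall)/(precision +
#' recall)`, and the positive/negative likelihood ratios, with confidence
#' intervals (exact Clopper-Pearson for proportions, log method for LRs).
#' A metric whose denominator is zero is reported `NA` (not applicable),
#' never silently 0.
#'
#' @param cm A `confusion`.
#' @param ci_level Confidence level (default 0.95).
#' @param ci_method CI method for proportions.
#' @return A list of class `metric_set`; proportions on the 0-1 scale.
#'   `as.data.frame()` flattens it to one row.
#' @export
metrics <- function(cm, ci_level = 0.95,
                    ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cm, "confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  prop <- function(k, d) {
    if (d == 0L) return(list(est = NA_real_, ci = c(lo = NA_real_,
                                                    hi = NA_real_)))
    list(est = k / d, ci = proportion_ci(k, d, ci_level, ci_method))
  }
  sens <- prop(cm$tp, cm$tp + cm$fn)
  spec <- prop(cm$tn, cm$tn + cm$fp)
  ppv <- prop(cm$tp, cm$tp + cm$fp)
  npv <- prop(cm$tn, cm$tn + cm$fn)
  acc <- prop(cm$tp + cm$tn, n)
  f1 <- if (2L * cm$tp + cm$fp + cm$fn == 0L) NA_real_ else {
    2 * cm$tp / (2L * cm$tp + cm$fp + cm$fn)
  }
  lr <- likelihood_ratio_ci(cm, ci_level)
  structure(list(cm = cm, n = n,
                 sensitivity = sens$est, sensitivity_ci = sens$ci,
                 specificity = spec$est, specificity_ci = spec$ci,
                 ppv = ppv$est, ppv_ci = ppv$ci,
                 npv = npv$est, npv_ci = npv$ci,
                 accuracy = acc$est, accuracy_ci = acc$ci,
                 f1 = f1,
                 lr_pos = unname(lr$lr_pos["est"]),
                 lr_pos_ci = lr$lr_pos[c("lo", "hi")],
                 lr_neg = unname(lr$lr_neg["est"]),
                 lr_neg_ci = lr$lr_neg[c("lo", "hi")],
                 lr_corrected = lr$corrected,
                 ci_level = ci_level, ci_method = ci_method),
            class = "metric_set")
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(tp = x$cm$tp, fp = x$cm$fp, fn = x$cm$fn, tn = x$cm$tn,
             sensitivity = x$sensitivity,
             sens_lo = unname(x$sensitivity_ci["lo"]),
             sens_hi = unname(x$sensitivity_ci["hi"]),
             specificity = x$specificity,
             spec_lo = unname(x$specificity_ci["lo"]),
             spec_hi = unname(x$specificity_ci["hi"]),
             ppv = x$ppv, ppv_lo = unname(x$ppv_ci["lo"]),
             ppv_hi = unname(x$ppv_ci["hi"]),
             npv = x$npv, npv_lo = unname(x$npv_ci["lo"]),
             npv_hi = unname(x$npv_ci["hi"]),
             lr_pos = x$lr_pos, lr_pos_lo = unname(x$lr_pos_ci["lo"]),
             lr_pos_hi = unname(x$lr_pos_ci["hi"]),
             lr_neg = x$lr_neg, lr_neg_lo = unname(x$lr_neg_ci["lo"]),
             lr_neg_hi = unname(x$lr_neg_ci["hi"]),
             accuracy = x$accuracy, f1 = x$f1)
}

#' @export
print.metric_set <- function(x, ...) {
  pct <- function(p, ci) {
    if (is.na(p)) return("n/a")
    sprintf("%.1f (%.1f-%.1f)", round_half_up(100 * p, 1),
            round_half_up(100 * ci["lo"], 1), round_half_up(100 * ci["hi"], 1))
  }
  cat(sprintf(
    paste0("n = %d; sens %s; spec %s; PPV %s; NPV %s;\n",
           "LR+ %.2f (%.2f-%.2f); LR- %.2f (%.2f-%.2f); ",
           "acc %.1f%%; F1 %.1f\n"),
    x$n, pct(x$sensitivity, x$sensitivity_ci),
    pct(x$specificity, x$specificity_ci), pct(x$ppv, x$ppv_ci),
    pct(x$npv, x$npv_ci),
    x$lr_pos, x$lr_pos_ci["lo"], x$lr_pos_ci["hi"],
    x$lr_neg, x$lr_neg_ci["lo"], x$lr_neg_ci["hi"],
    round_half_up(100 * x$accuracy, 1), round_half_up(100 * x$f1, 1)))
  invisible(x)
}

#' Unweighted Cohen's kappa
#'
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed agreement
#' proportion and `pe` the chance agreement from the marginal products.
#' When both raters are constant and identical (`pe = 1`), kappa is
#' undefined and returned `NA` with `defined = FALSE`.
#'
#' @param r1,r2 Binary 0/1 vectors of equal length >= 2.
#' @return List of class `agreement_result`: `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`, `defined`.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("raters differ in length", call. = FALSE)
  n <- length(r1)
  if (n < 2L) stop("need at least 2 rated items", call. = FALSE)
  r1 <- as.integer(r1); r2 <- as.integer(r2)
  stopifnot(all(r1 %in% 0:1), all(r2 %in% 0:1))
  po <- mean(r1 == r2)
  pe <- mean(r1 == 1L) * mean(r2 == 1L) + mean(r1 == 0L) * mean(r2 == 0L)
  defined <- pe < 1
  structure(list(kappa = if (defined) (po - pe) / (1 - pe) else NA_real_,
                 observed_agreement = po, expected_agreement = pe,
                 n = n, defined = defined),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %s (po = %.3f, pe = %.3f, n = %d)\n",
              if (x$defined) sprintf("%.3f", x$kappa) else "undefined",
              x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Reconstruct an integer confusion matrix from printed marginals
#'
#' Published diagnostic-accuracy tables print sensitivity, specificity and
#' PPV to one decimal (percent) along with the validation size and positive
#' count, but not the underlying 2x2 counts. This searches the integer
#' confusion matrices consistent with those printed values (rounding half
#' away from zero to one decimal) and returns the consistent solution;
#' among multiple candidates the one whose exact percentages are closest to
#' the printed ones is chosen (ties: smallest `tp`, then smallest `fp`).
#'
#' @param n Validation size (`tp+fp+fn+tn`).
#' @param n_pos Number of reference-positive cases (`tp+fn`).
#' @param sensitivity,specificity,ppv Printed percentages (e.g. `61.1`).
#' @param digits Printed decimal places (default 1).
#' @return A `confusion` object.
#' @export
reconstruct_confusion <- function(n, n_pos, sensitivity, specificity, ppv,
                                  digits = 1L) {
  n_neg <- n - n_pos
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  rp <- function(k, d) round_half_up(100 * k / d, digits)
  tp_cand <- which(rp(0:n_pos, n_pos) == sensitivity) - 1L
  tn_cand <- which(rp(0:n_neg, n_neg) == specificity) - 1L
  if (length(tp_cand) == 0L || length(tn_cand) == 0L) {
    stop("no integer confusion matrix matches the printed sensitivity/",
         "specificity", call. = FALSE)
  }
  grid <- expand.grid(tp = tp_cand, tn = tn_cand)
  grid$fp <- n_neg - grid$tn
  grid$fn <- n_pos - grid$tp
  ok <- grid$tp + grid$fp > 0L &
    rp(grid$tp, grid$tp + grid$fp) == ppv
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L) {
    stop("no integer confusion matrix matches the printed PPV", call. = FALSE)
  }
  err <- (100 * grid$tp / n_pos - sensitivity)^2 +
    (100 * grid$tn / n_neg - specificity)^2 +
    (100 * grid$tp / (grid$tp + grid$fp) - ppv)^2
  grid <- grid[order(err, grid$tp, grid$fp), , drop = FALSE]
  confusion_matrix(tp = grid$tp[1], fp = grid$fp[1], fn = grid$fn[1],
                   tn = grid$tn[1])
}
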