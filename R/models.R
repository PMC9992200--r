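#' Supervised model specification
#'
#' Uniform specification over the five supervised families. Defaults follow
#' the stated configurations: depth-wise boosting with `max_depth = 3`,
#' `learning_rate = 0.3` (`xgboost`); leaf-wise boosting with
#' `num_leaves = 31`, `learning_rate = 0.05` (`lightgbm`); a linear-kernel
#' SVM; Gaussian naive Bayes; L2-penalized logistic regression. Boosting
#' rounds default to 100 (unstated upstream).
#'
#' @param family One of `"xgboost"`, `"lightgbm"`, `"svm_linear"`,
#'   `"gaussian_nb"`, `"logistic_regression"`.
#' @param ... Hyperparameter overrides (see Details).
#' @param seed Integer seed stored with the spec; all five families are
#'   deterministic, so the seed only documents the run.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("xgboost", "lightgbm", "svm_linear",
                                  "gaussian_nb", "logistic_regression"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    xgboost = list(max_depth = 3L, learning_rate = 0.3, nrounds = 100L,
                   lambda = 1, min_child_weight = 1),
    lightgbm = list(num_leaves = 31L, learning_rate = 0.05, nrounds = 100L,
                    lambda = 0, min_data_in_leaf = 20L,
                    min_sum_hessian = 1e-3),
    svm_linear = list(C = 1),
    gaussian_nb = list(var_smoothing = 1e-9),
    logistic_regression = list(C = 1))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(override)] <- override
  structure(list(family = family, hyperparameters = defaults,
                 seed = as.integer(seed)), class = "model_spec")
}

check_xy <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("feature matrix must have column names",
                                 call. = FALSE)
  y <- as.integer(y)
  if (nrow(x) < 10L) stop("need at least 10 training rows", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed",
                                 call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  stopifnot(all(y %in% 0:1), length(y) == nrow(x))
  list(x = x, y = y)
}

#' Fit a supervised classifier
#'
#' @param x Feature matrix (rows = reports, named columns aligned to the
#'   lexicon feature names).
#' @param y Binary 0/1 training labels (typically diagnosis-code labels).
#' @param spec A [model_spec()].
#' @return A `cxr_model` with the fitted state, `feature_names`, and a
#'   `training_summary` (n, prevalence, training accuracy, hyperparameters).
#' @export
fit_model <- function(x, y, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  d <- check_xy(x, y)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    xgboost = gbt_fit(d$x, d$y, nrounds = hp$nrounds,
                      eta = hp$learning_rate, growth = "depthwise",
                      max_depth = hp$max_depth, lambda = hp$lambda,
                      min_hess = hp$min_child_weight),
    lightgbm = gbt_fit(d$x, d$y, nrounds = hp$nrounds,
                       eta = hp$learning_rate, growth = "leafwise",
                       num_leaves = hp$num_leaves, lambda = hp$lambda,
                       min_hess = hp$min_sum_hessian,
                       min_data = hp$min_data_in_leaf),
    svm_linear = svm_linear_fit(d$x, d$y, C = hp$C),
    gaussian_nb = gnb_fit(d$x, d$y, var_smoothing = hp$var_smoothing),
    logistic_regression = logreg_fit(d$x, d$y, C = hp$C))
  model <- structure(
    list(spec = spec, fit = fit, feature_names = colnames(d$x),
         training_summary = NULL),
    class = c(paste0("cxr_model_", spec$family), "cxr_model"))
  pred <- predict(model, d$x)
  model$training_summary <- c(
    list(n = nrow(d$x), prevalence = mean(d$y),
         training_accuracy = mean(pred$label == d$y)), hp)
  model
}

#' @export
print.cxr_model <- function(x, ...) {
  ts <- x$training_summary
  cat("cxr_model [", x$spec$family, "]: n =", ts$n,
      ", prevalence =", round(ts$prevalence, 3),
      ", training accuracy =", round(ts$training_accuracy, 3), "\n")
  invisible(x)
}

check_newdata <- function(object, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || !identical(colnames(x), object$feature_names)) {
    stop("feature columns do not match the model's feature_names",
         call. = FALSE)
  }
  x
}

#' Predict with a fitted classifier
#'
#' Scores are probabilities (or a monotone probability-scale transform of
#' the SVM margin) in `[0, 1]`. Labels threshold the score at 0.5; for the
#' linear SVM this is equivalent to thresholding the signed margin at 0.
#'
#' @param object A `cxr_model`.
#' @param x Feature matrix with columns matching the training features.
#' @param ... Unused.
#' @return List with `label` (integer 0/1) and `score` (numeric in `[0,1]`).
#' @export
predict.cxr_model <- function(object, x, ...) {
  x <- check_newdata(object, x)
  score <- switch(object$spec$family,
    xgboost = plogis(gbt_predict(object$fit, x)),
    lightgbm = plogis(gbt_predict(object$fit, x)),
    svm_linear = plogis(drop(x %*% object$fit$w + object$fit$b)),
    gaussian_nb = gnb_score(object$fit, x),
    logistic_regression = plogis(drop(x %*% object$fit$w + object$fit$b)))
  list(label = as.integer(score > 0.5), score = score)
}

# Linear-kernel SVM: primal squared-hinge loss, 0.5*||w||^2 + C * sum
# max(0, 1 - z f)^2, z in {-1, +1}, intercept unpenalized; BFGS from zero
# start (deterministic).
svm_linear_fit <- function(x, y, C = 1) {
  z <- ifelse(y == 1L, 1, -1)
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - z * (drop(x %*% w) + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - z * (drop(x %*% w) + b))
    gw <- w - 2 * C * drop(crossprod(x, m * z))
    gb <- -2 * C * sum(m * z)
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L], converged = fit$convergence == 0)
}

# Gaussian naive Bayes with sklearn-style variance smoothing: every class
# variance gets var_smoothing * max over features of the pooled variance.
gnb_fit <- function(x, y, var_smoothing = 1e-9) {
  classes <- c(0L, 1L)
  mu <- var <- matrix(0, 2L, ncol(x))
  prior <- numeric(2L)
  vsm <- var_smoothing * max(apply(x, 2L, function(v) mean((v - mean(v))^2)))
  for (k in 1:2) {
    xi <- x[y == classes[k], , drop = FALSE]
    mu[k, ] <- colMeans(xi)
    var[k, ] <- colMeans(sweep(xi, 2L, mu[k, ])^2) + vsm
    prior[k] <- nrow(xi) / nrow(x)
  }
  list(mu = mu, var = var, prior = prior)
}

gnb_score <- function(fit, x) {
  logpost <- function(k) {
    d <- sweep(x, 2L, fit$mu[k, ])
    q <- sweep(d^2, 2L, 2 * fit$var[k, ], "/")
    -rowSums(q) - sum(0.5 * log(2 * pi * fit$var[k, ])) + log(fit$prior[k])
  }
  # Posterior P(y = 1 | x), numerically stable.
  1 / (1 + exp(logpost(1L) - logpost(2L)))
}

# L2-penalized logistic regression, sklearn-style objective
# 0.5*||w||^2 + C * sum log(1 + exp(-z f)), intercept unpenalized.
logreg_fit <- function(x, y, C = 1) {
  z <- ifelse(y == 1L, 1, -1)
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    f <- z * (drop(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(log1p(exp(-abs(f))) + pmax(-f, 0))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    f <- z * (drop(x %*% w) + b)
    s <- -z * plogis(-f)
    c(w + C * drop(crossprod(x, s)), C * sum(s))
  }
  fit <- optim(rep(0, p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L],
       converged = fit$convergence == 0)
}

#' Benchmark all models against both reference standards
#'
#' Fits every spec on the derivation features/labels, predicts the
#' validation set, and assembles one metric row per model and reference
#' standard, in the style of a diagnostic-accuracy results table.
#'
#' @param features_train,features_eval Feature matrices for disjoint
#'   derivation and validation sets.
#' @param labels_train Binary training labels (e.g. diagnosis-code labels).
#' @param reference_standards Named list of binary label vectors for the
#'   validation set (e.g. `list(expert = ..., code = ...)`).
#' @param specs List of [model_spec()]s.
#' @param ci_level Confidence level for the metric CIs.
#' @return A `data.frame`: one row per model x reference standard with the
#'   diagnostic-accuracy metrics from [metrics()].
#' @export
benchmark_suite <- function(features_train, labels_train, features_eval,
                            reference_standards, specs = default_model_specs(),
                            ci_level = 0.95) {
  if (nrow(features_eval) == 0L) stop("empty validation set", call. = FALSE)
  overlap <- intersect(rownames(features_train), rownames(features_eval))
  if (length(overlap) > 0L) {
    stop("derivation and validation sets overlap: ",
         paste(head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.list(reference_standards), length(reference_standards) > 0L)
  rows <- list()
  for (spec in specs) {
    model <- fit_model(features_train, labels_train, spec)
    pred <- predict(model, features_eval)
    for (std in names(reference_standards)) {
      ms <- metrics(confusion(pred$label, reference_standards[[std]]),
                    ci_level = ci_level)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model = spec$family, reference = std,
                         stringsAsFactors = FALSE),
              as.data.frame(ms))
    }
  }
  do.call(rbind, rows)
}

#' The five default supervised model specs
#' @param seed Seed recorded in each spec.
#' @return List of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  lapply(c("xgboost", "lightgbm", "svm_linear", "gaussian_nb",
           "logistic_regression"),
         function(f) model_spec(f, seed = seed))
}

#' Persist / load a fitted model
#'
#' Writes a directory with `spec.json`, `feature_names.txt`, and the fitted
#' state serialized as JSON (`fit.json`).
#'
#' @param model A `cxr_model`.
#' @param dir Output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$feature_names, file.path(dir, "feature_names.txt"))
  jsonlite::write_json(jsonlite::serializeJSON(model$fit, digits = NA),
                       file.path(dir, "fit.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  spec_raw <- jsonlite::read_json(file.path(dir, "spec.json"))
  spec <- do.call(model_spec,
                  c(list(family = spec_raw$family, seed = spec_raw$seed),
                    spec_raw$hyperparameters))
  fit <- jsonlite::unserializeJSON(
    jsonlite::read_json(file.path(dir, "fit.json"))[[1]])
  structure(list(spec = spec, fit = fit,
                 feature_names = readLines(file.path(dir, "feature_names.txt")),
                 training_summary = NULL),
            class = c(paste0("cxr_model_", spec$family), "cxr_model"))
}
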