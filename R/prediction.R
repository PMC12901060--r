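#' Feature table for gradient-based prediction
#'
#' @param features subjects x P numeric matrix (typically the aligned
#'   principal gradient per subject).
#' @param target length-n numeric vector (continuous) or factor/character
#'   (binary) prediction target.
#' @param confounds optional subjects x q numeric matrix with named columns
#'   (e.g. \code{fd}, \code{age}).
#' @param subject_ids optional identifiers.
#' @return object of class \code{feature_table}.
#' @export
feature_table <- function(features, target, confounds = NULL,
                          subject_ids = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n) stop("target length must match feature rows")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confound rows must match feature rows")
    if (is.null(colnames(confounds))) stop("confounds must have column names")
  }
  if (anyNA(features) || anyNA(target) || (!is.null(confounds) && anyNA(confounds)))
    stop("missing values are not allowed")
  structure(list(features = features, target = target, confounds = confounds,
                 subject_ids = subject_ids), class = "feature_table")
}

#' Nested cross-validation configuration
#'
#' Defaults follow the common neuroimaging protocol: 10-times repeated
#' 5-fold outer cross-validation with an inner 5-fold grid search; ridge
#' penalty grid of 50 log-spaced values in [1e-3, 1e4]; SVM cost grid of 10
#' log-spaced values in [1e-4, 1e4]; RBF gamma grid of 10 log-spaced values
#' in [1e-9, 1e4]; random-forest maximum depth in \{5, 10, 20, unbounded\}.
#'
#' @param outer_folds,outer_repeats,inner_folds fold structure.
#' @param ridge_alpha_grid,svm_c_grid,rbf_gamma_grid,rf_max_depth_grid
#'   hyperparameter grids (\code{Inf} in the depth grid means unbounded).
#' @param n_trees random-forest ensemble size.
#' @param standardize z-score features within each training partition.
#' @param seed RNG seed governing all fold assignments.
#' @return list of class \code{cv_config}.
#' @export
cv_config <- function(outer_folds = 5L, outer_repeats = 10L, inner_folds = 5L,
                      ridge_alpha_grid = .geomspace(1e-3, 1e4, 50),
                      svm_c_grid = .geomspace(1e-4, 1e4, 10),
                      rbf_gamma_grid = .geomspace(1e-9, 1e4, 10),
                      rf_max_depth_grid = c(5, 10, 20, Inf),
                      n_trees = 300L, standardize = TRUE, seed = 1L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L, outer_repeats >= 1L,
            all(ridge_alpha_grid > 0), all(svm_c_grid > 0),
            all(rbf_gamma_grid > 0))
  structure(as.list(environment()), class = "cv_config")
}

# log-spaced grid, endpoints inclusive (numpy geomspace convention)
.geomspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Confound removal fit on a training partition only
#'
#' Fits, per feature column, an intercept-plus-linear model on the confound
#' columns using the training rows; \code{\link{apply_confound_remover}}
#' subtracts the fitted model's prediction, so training residuals are
#' exactly orthogonal to every confound column.
#'
#' @param train_features n x P matrix.
#' @param train_confounds n x q matrix.
#' @return object of class \code{confound_remover}.
#' @export
fit_confound_remover <- function(train_features, train_confounds) {
  C <- as.matrix(train_confounds)
  # constant confound columns carry no information beyond the intercept;
  # drop them so an all-zero confound reduces to mean removal
  keep <- apply(C, 2L, function(x) stats::sd(x) > 0)
  X <- cbind(1, C[, keep, drop = FALSE])
  if (nrow(X) < ncol(X) + 1L) stop("too few training rows for confound model")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient confound matrix")
  coef <- qr.solve(X, as.matrix(train_features))
  structure(list(coef = coef, keep = keep), class = "confound_remover")
}

#' @rdname fit_confound_remover
#' @param remover fitted \code{confound_remover}.
#' @param features,confounds rows to residualize (train or test).
#' @return residualized feature matrix.
#' @export
apply_confound_remover <- function(remover, features, confounds) {
  C <- as.matrix(confounds)[, remover$keep, drop = FALSE]
  as.matrix(features) - cbind(1, C) %*% remover$coef
}

# fold assignment using the current RNG state; optionally stratified
.make_folds <- function(n, k, strata = NULL) {
  fold <- integer(n)
  if (is.null(strata)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    for (lev in unique(strata)) {
      idx <- which(strata == lev)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

# ridge solutions for a whole penalty grid from one SVD of the centred
# design (intercept unpenalized); matches the standard "alpha" convention
# of penalizing the coefficient l2-norm of the (standardized) features
.ridge_fit_grid <- function(X, y, alphas) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  sv <- svd(Xc)
  uty <- drop(crossprod(sv$u, y - ym))
  beta <- vapply(alphas, function(a)
    drop(sv$v %*% (sv$d * uty / (sv$d^2 + a))), numeric(ncol(X)))
  beta <- matrix(beta, ncol = length(alphas))
  intercept <- ym - drop(xm %*% beta)
  list(beta = beta, intercept = intercept)
}

.ridge_predict <- function(fit, X, j = 1L)
  drop(as.matrix(X) %*% fit$beta[, j]) + fit$intercept[j]

.r2_score <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)  # undefined on (near-)singleton partitions
  1 - sum((y - yhat)^2) / ss_tot
}

# residualize + standardize train/test, with all statistics from train rows
.prepare_features <- function(table, train, test, scenario, standardize) {
  Xtr <- table$features[train, , drop = FALSE]
  Xte <- table$features[test, , drop = FALSE]
  if (length(scenario)) {
    if (is.null(table$confounds) || !all(scenario %in% colnames(table$confounds)))
      stop("scenario names confound columns absent from the table")
    Ctr <- table$confounds[train, scenario, drop = FALSE]
    Cte <- table$confounds[test, scenario, drop = FALSE]
    rem <- fit_confound_remover(Xtr, Ctr)
    Xtr <- apply_confound_remover(rem, Xtr, Ctr)
    Xte <- apply_confound_remover(rem, Xte, Cte)
  }
  if (standardize) {
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sd, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sd, "/")
  }
  list(train = Xtr, test = Xte)
}

#' Nested cross-validated ridge regression
#'
#' Outer k-fold cross-validation repeated \code{outer_repeats} times with
#' seeded shuffling; within each outer training partition an inner k-fold
#' grid search selects the ridge penalty; confound removal (when a scenario
#' is given) and feature standardization are fit on the outer training rows
#' only and applied to both partitions. Scores are out-of-sample coefficients
#' of determination (R^2) per outer fold.
#'
#' @param table \code{\link{feature_table}} with a continuous target.
#' @param config \code{\link{cv_config}}.
#' @param scenario character vector of confound columns to remove
#'   (\code{character(0)} removes none).
#' @return list of class \code{prediction_result}: \code{scores} data.frame
#'   (repeat, fold, score, alpha), \code{mean_score}, \code{sd_score}
#'   (standard deviation across the repeat-level fold means),
#'   \code{scenario}, \code{model}.
#' @export
nested_cv_regression <- function(table, config = cv_config(),
                                 scenario = character(0)) {
  y <- as.numeric(table$target)
  if (stats::sd(y) == 0) stop("degenerate target variance")
  n <- length(y)
  set.seed(config$seed)
  rows <- list()
  for (rep_i in seq_len(config$outer_repeats)) {
    fold <- .make_folds(n, config$outer_folds)
    for (k in seq_len(config$outer_folds)) {
      test <- which(fold == k); train <- which(fold != k)
      prep <- .prepare_features(table, train, test, scenario,
                                config$standardize)
      ytr <- y[train]
      inner <- .make_folds(length(train), config$inner_folds)
      grid_scores <- matrix(NA_real_, config$inner_folds,
                            length(config$ridge_alpha_grid))
      for (j in seq_len(config$inner_folds)) {
        itr <- which(inner != j); ite <- which(inner == j)
        fit <- .ridge_fit_grid(prep$train[itr, , drop = FALSE], ytr[itr],
                               config$ridge_alpha_grid)
        for (a in seq_along(config$ridge_alpha_grid))
          grid_scores[j, a] <- .r2_score(ytr[ite],
                                         .ridge_predict(fit, prep$train[ite, , drop = FALSE], a))
      }
      mean_r2 <- suppressWarnings(colMeans(grid_scores, na.rm = TRUE))
      best <- if (all(!is.finite(mean_r2))) 1L else which.max(mean_r2)
      fit <- .ridge_fit_grid(prep$train, ytr,
                             config$ridge_alpha_grid[best])
      score <- .r2_score(y[test], .ridge_predict(fit, prep$test))
      if (is.na(score))
        stop("degenerate target variance in an outer test partition")
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = k, score = score,
        alpha = config$ridge_alpha_grid[best])
    }
  }
  .prediction_result(do.call(rbind, rows), scenario, "ridge")
}

.prediction_result <- function(scores, scenario, model, extra = NULL) {
  rep_means <- tapply(scores$score, scores$rep, mean)
  out <- list(scores = scores, mean_score = mean(scores$score),
              sd_score = stats::sd(rep_means),
              scenario = if (length(scenario)) paste(scenario, collapse = "+") else "none",
              model = model)
  structure(c(out, extra), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: model=%s scenario=%s mean=%.3f sd=%.3f (%d scores)\n",
              x$model, x$scenario, x$mean_score, x$sd_score, nrow(x$scores)))
  invisible(x)
}

#' Median split of a continuous motion measure
#'
#' Values strictly above the median are labelled \code{"high"}; values at or
#' below the median \code{"low"} (ties at the median are assigned to the
#' low-motion class).
#'
#' @param values numeric vector, length >= 2.
#' @return factor with levels \code{c("low", "high")}.
#' @export
binarize_by_median <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  med <- stats::median(values)
  if (all(values == values[1])) stop("all values identical: single class")
  lab <- ifelse(values > med, "high", "low")
  if (length(unique(lab)) < 2L) stop("median split produced a single class")
  factor(lab, levels = c("low", "high"))
}

# classifier backends: fit on (X, y factor low/high), return prediction
# function giving list(class, score) with score oriented toward "high"
.fit_classifier <- function(model, X, y, pars, config) {
  switch(model,
    ridge = {
      yy <- ifelse(y == "high", 1, -1)
      fit <- .ridge_fit_grid(X, yy, pars$alpha)
      function(Xn) {
        s <- .ridge_predict(fit, Xn)
        list(class = factor(ifelse(s > 0, "high", "low"),
                            levels = c("low", "high")), score = s)
      }
    },
    svm_linear = ,
    svm_rbf = {
      fit <- e1071::svm(X, y, kernel = if (model == "svm_rbf") "radial" else "linear",
                        cost = pars$cost, gamma = if (model == "svm_rbf") pars$gamma else 1 / ncol(X),
                        scale = FALSE)
      function(Xn) {
        pr <- stats::predict(fit, Xn, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        s <- dv[, 1]
        if (!grepl("^high", colnames(dv)[1])) s <- -s
        list(class = factor(as.character(pr), levels = c("low", "high")),
             score = s)
      }
    },
    rf = {
      depth <- if (is.finite(pars$depth)) pars$depth else 0L
      if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
      fnames <- colnames(X)
      fit <- ranger::ranger(x = X, y = y, num.trees = config$n_trees,
                            max.depth = depth, probability = TRUE,
                            seed = pars$rf_seed, num.threads = 1L)
      function(Xn) {
        colnames(Xn) <- fnames
        p <- stats::predict(fit, data = Xn, num.threads = 1L)$predictions
        s <- p[, "high"]
        list(class = factor(ifelse(s > 0.5, "high", "low"),
                            levels = c("low", "high")), score = s)
      }
    },
    stop("unknown model: ", model))
}

.classifier_grid <- function(model, config) {
  switch(model,
    ridge = data.frame(alpha = config$ridge_alpha_grid),
    svm_linear = data.frame(cost = config$svm_c_grid),
    svm_rbf = expand.grid(cost = config$svm_c_grid,
                          gamma = config$rbf_gamma_grid),
    rf = data.frame(depth = config$rf_max_depth_grid))
}

.auc_score <- function(y, score) {
  r <- pROC::roc(response = y, predictor = score,
                 levels = c("low", "high"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Nested cross-validated binary classification
#'
#' Same nested protocol as \code{\link{nested_cv_regression}} with
#' stratified outer and inner splits; the inner grid search tunes the
#' model-specific hyperparameters on accuracy. Reports out-of-sample
#' accuracy (correct predictions divided by total predictions) and AUC per
#' outer fold; chance level is 0.5 for balanced classes.
#'
#' @param table \code{\link{feature_table}} with a binary target (factor
#'   with levels \code{c("low", "high")}, as produced by
#'   \code{\link{binarize_by_median}}).
#' @param config \code{\link{cv_config}}.
#' @param model one of \code{"ridge"}, \code{"svm_linear"},
#'   \code{"svm_rbf"}, \code{"rf"}.
#' @param scenario confound columns to remove (as in regression).
#' @return \code{prediction_result} whose \code{scores} carry both
#'   \code{score} (accuracy) and \code{auc} columns; \code{mean_auc} and
#'   \code{sd_auc} summarize AUC the same way as accuracy.
#' @export
nested_cv_classification <- function(table, config = cv_config(),
                                     model = c("ridge", "svm_linear",
                                               "svm_rbf", "rf"),
                                     scenario = character(0)) {
  model <- match.arg(model)
  y <- factor(table$target, levels = c("low", "high"))
  if (anyNA(y) || length(unique(y)) < 2L)
    stop("target must be binary with levels low/high and both classes present")
  n <- length(y)
  grid <- .classifier_grid(model, config)
  set.seed(config$seed)
  rows <- list()
  for (rep_i in seq_len(config$outer_repeats)) {
    fold <- .make_folds(n, config$outer_folds, strata = y)
    for (k in seq_len(config$outer_folds)) {
      test <- which(fold == k); train <- which(fold != k)
      if (length(unique(y[train])) < 2L)
        stop("single-class training partition; change the stratification seed")
      prep <- .prepare_features(table, train, test, scenario,
                                config$standardize)
      ytr <- y[train]
      inner <- .make_folds(length(train), config$inner_folds, strata = ytr)
      rf_seed <- sample.int(2^30, 1L)
      acc <- matrix(NA_real_, config$inner_folds, nrow(grid))
      for (j in seq_len(config$inner_folds)) {
        itr <- which(inner != j); ite <- which(inner == j)
        for (g in seq_len(nrow(grid))) {
          pars <- c(as.list(grid[g, , drop = FALSE]), rf_seed = rf_seed)
          pred <- .fit_classifier(model, prep$train[itr, , drop = FALSE],
                                  ytr[itr], pars, config)
          acc[j, g] <- mean(pred(prep$train[ite, , drop = FALSE])$class == ytr[ite])
        }
      }
      mean_acc <- colMeans(acc, na.rm = TRUE)
      best <- if (all(!is.finite(mean_acc))) 1L else which.max(mean_acc)
      pars <- c(as.list(grid[best, , drop = FALSE]), rf_seed = rf_seed)
      pred <- .fit_classifier(model, prep$train, ytr, pars, config)
      out <- pred(prep$test)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = k,
        score = mean(out$class == y[test]),
        auc = .auc_score(y[test], out$score))
    }
  }
  scores <- do.call(rbind, rows)
  res <- .prediction_result(scores, scenario, model)
  rep_auc <- tapply(scores$auc, scores$rep, mean)
  res$mean_auc <- mean(scores$auc)
  res$sd_auc <- stats::sd(rep_auc)
  res
}

#' First differences of scores over alignment dimensionality
#'
#' The discrete rate of change of prediction scores with respect to the
#' number of gradients used in alignment: score(k+1) - score(k) for
#' consecutive n_align values.
#'
#' @param scores numeric vector.
#' @param n_align integer vector of the same length; must be consecutive
#'   after sorting.
#' @return named numeric vector of first differences.
#' @export
score_derivative <- function(scores, n_align = seq_along(scores)) {
  if (length(scores) < 2L) stop("need at least 2 consecutive scores")
  ord <- order(n_align)
  n_align <- n_align[ord]; scores <- scores[ord]
  if (any(diff(n_align) != 1L)) stop("n_align values must be consecutive")
  d <- diff(scores)
  names(d) <- paste(n_align[-1], n_align[-length(n_align)], sep = "-")
  d
}
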