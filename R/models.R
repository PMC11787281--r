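#' Apnea severity class from an hourly event index
#'
#' Standard cutoffs: `< 5` normal, `5-15` mild, `15-30` moderate, `>= 30`
#' severe.
#'
#' @param x Hourly event index (AHI or REI).
#' @return Ordered factor with levels normal, mild, moderate, severe.
#' @export
severity_class <- function(x) {
  cut(x, breaks = c(-Inf, 5, 15, 30, Inf),
      labels = c("normal", "mild", "moderate", "severe"),
      right = FALSE, ordered_result = TRUE)
}

#' Severity-stratified subject split
#'
#' Splits subjects into training and test groups at the given ratio while
#' preserving the severity-class mix: the overall training count is
#' `round(ratio * n)` and is allocated across severity strata by largest
#' remainder, then filled by seeded random sampling within each stratum.
#'
#' @param subjects Data frame with columns `subject_id` and `ahi`.
#' @param ratio Training fraction (default 2/3).
#' @param seed Integer seed; the same seed always yields the same plan.
#' @return A `split_plan`: list with `train` and `test` subject tibbles.
#' @export
split_subjects <- function(subjects, ratio = 2 / 3, seed = 1) {
  n <- nrow(subjects)
  if (n < 2) abort("Need at least 2 subjects to split.", class = "somnimu_data_error")
  if (ratio <= 0 || ratio >= 1) {
    abort("`ratio` must be strictly between 0 and 1 (both groups non-empty).",
          class = "somnimu_data_error")
  }
  subjects <- tibble::as_tibble(subjects)
  subjects$severity <- severity_class(subjects$ahi)
  target <- round(ratio * n)
  if (target < 1 || target >= n) {
    abort("Split leaves an empty group.", class = "somnimu_data_error")
  }
  strata <- split(seq_len(n), subjects$severity, drop = TRUE)
  exact <- vapply(strata, length, integer(1)) * ratio
  base <- floor(exact)
  shortfall <- target - sum(base)
  if (shortfall > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(shortfall)]] <- base[order_rem[seq_len(shortfall)]] + 1
  } else if (shortfall < 0) {
    order_rem <- order(exact - base)
    take <- order_rem[base[order_rem] > 0][seq_len(-shortfall)]
    base[take] <- base[take] - 1
  }
  train_idx <- withr::with_seed(seed, {
    unlist(purrr::map2(strata, base, function(idx, k) {
      if (k >= length(idx)) idx else sample(idx, k)
    }), use.names = FALSE)
  })
  structure(list(train = subjects[sort(train_idx), ],
                 test = subjects[setdiff(seq_len(n), train_idx), ],
                 ratio = ratio, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test subjects (ratio %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$ratio, x$seed))
  invisible(x)
}

#' @export
tidy.split_plan <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$train, group = "train"),
    dplyr::mutate(x$test, group = "test")
  )
}

model_feature_cols <- function(data) {
  feats <- intersect(somnimu_features(), names(data))
  if (length(feats) == 0) {
    feats <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                     c("epoch", "subject_id"))
  }
  if (length(feats) < 1) abort("No feature columns found.")
  feats
}

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Adds interpolated minority-class samples until the classes are exactly
#' 1:1. Each synthetic sample lies on the segment between a random minority
#' sample and one of its `k` nearest minority neighbours (Euclidean
#' distance in feature space); originals are preserved unchanged.
#'
#' @param data Labelled feature table (`label` factor plus feature columns).
#' @param k Number of minority neighbours (default 5; reduced with a
#'   warning when the minority class has at most `k` members).
#' @param seed Integer seed.
#' @return The balanced tibble; synthetic rows have `.synthetic = TRUE`
#'   recorded in the `n_synthetic` attribute and copy their seed row's
#'   non-feature columns.
#' @export
smote_balance <- function(data, k = 5, seed = 1) {
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  data <- tibble::as_tibble(data)
  counts <- table(data$label)
  counts <- counts[counts > 0]
  if (length(counts) < 2) abort("Need two classes to balance.", class = "somnimu_data_error")
  minority <- names(counts)[which.min(counts)]
  n_syn <- max(counts) - min(counts)
  if (n_syn == 0) return(data)
  feats <- model_feature_cols(data)
  min_rows <- which(data$label == minority)
  n_min <- length(min_rows)
  if (n_min < 2) abort("Minority class needs at least 2 members.", class = "somnimu_data_error")
  if (n_min <= k) {
    warn(sprintf("Minority class has %d members; reducing k to %d.", n_min, n_min - 1))
    k <- n_min - 1
  }
  x <- as.matrix(data[min_rows, feats])
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  syn <- withr::with_seed(seed, {
    i <- sample.int(n_min, n_syn, replace = TRUE)
    j <- nn[cbind(i, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    list(i = i, x = x[i, , drop = FALSE] + u * (x[j, , drop = FALSE] -
                                                  x[i, , drop = FALSE]))
  })
  syn_rows <- data[min_rows[syn$i], ]
  syn_rows[, feats] <- as.data.frame(syn$x)
  syn_rows$label <- factor(minority, levels = levels(data$label))
  out <- dplyr::bind_rows(data, syn_rows)
  attr(out, "n_synthetic") <- n_syn
  out
}

# ---- classifier kinds ------------------------------------------------------

somnimu_model_kinds <- c("logistic_regression", "random_forest",
                         "gradient_boosting", "knn", "mlp")

scale_features <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, pmax(scale, 1e-12), "/")
}

fit_one <- function(kind, x, y, pars, seed) {
  switch(kind,
    logistic_regression = {
      df <- as.data.frame(x); df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = pars$num_trees %||% 300, mtry = pars$mtry,
      seed = seed, num.threads = 1, importance = "impurity"),
    gradient_boosting = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = pars$max_depth,
                      eta = pars$eta, nthread = 1),
        data = dtrain, nrounds = pars$nrounds, verbose = 0)
    },
    knn = list(x = as.matrix(x), y = y, k = pars$k),
    mlp = {
      set.seed(seed)
      nnet::nnet(x = as.matrix(x), y = as.integer(y) - 1L,
                 size = pars$size, decay = pars$decay, maxit = 250,
                 entropy = TRUE, trace = FALSE, MaxNWts = 5000)
    }
  )
}

predict_prob <- function(kind, fit, x) {
  switch(kind,
    logistic_regression = as.numeric(predict(fit, newdata = as.data.frame(x),
                                             type = "response")),
    random_forest = {
      pr <- predict(fit, data = x, num.threads = 1)$predictions
      as.numeric(pr[, 2])
    },
    gradient_boosting = as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))),
    knn = {
      cl <- class::knn(train = fit$x, test = as.matrix(x), cl = fit$y,
                       k = fit$k, prob = TRUE)
      p_win <- attr(cl, "prob")
      ifelse(cl == levels(fit$y)[2], p_win, 1 - p_win)
    },
    mlp = as.numeric(predict(fit, as.matrix(x)))
  )
}

default_grid <- function(kind, p) {
  switch(kind,
    logistic_regression = tibble::tibble(.dummy = 1),
    random_forest = tibble::tibble(mtry = unique(pmin(p, c(2, max(2, floor(sqrt(p))), 8)))),
    gradient_boosting = tidyr::expand_grid(max_depth = c(2, 4),
                                           nrounds = c(100, 300), eta = 0.1),
    knn = tibble::tibble(k = c(5, 11, 21)),
    mlp = tidyr::expand_grid(size = c(4, 8), decay = c(0.01, 0.1))
  )
}

auc_safe <- function(truth, prob) {
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob,
                                 levels = c("RE_negative", "RE_positive"),
                                 direction = "<", quiet = TRUE)))
}

cv_auc <- function(kind, x, y, pars, seed, folds = 5) {
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  aucs <- vapply(seq_len(folds), function(fd) {
    tr <- fold_id != fd
    fit <- fit_one(kind, x[tr, , drop = FALSE], y[tr], pars, seed + fd)
    auc_safe(y[!tr], predict_prob(kind, fit, x[!tr, , drop = FALSE]))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Train a respiratory-event classifier
#'
#' Fits one of five probabilistic classifiers on a (typically
#' SMOTE-balanced) epoch feature table: logistic regression, random forest,
#' gradient boosting, k-nearest neighbours, or a single-hidden-layer
#' perceptron. When `tune = TRUE` a small hyperparameter grid is scored by
#' 5-fold cross-validated AUC inside the training data; results are
#' reproducible under `seed`.
#'
#' @param data Labelled feature table (`label` plus the features of
#'   [somnimu_features()]).
#' @param kind One of `"logistic_regression"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"knn"`, `"mlp"`.
#' @param seed Integer seed.
#' @param tune Tune over the default grid (`TRUE`) or fit the first grid row
#'   directly.
#' @param threshold Probability threshold used for class predictions
#'   (default 0.5).
#' @return An `re_model` object; see [predict.re_model()],
#'   [evaluate_epochs()], [tidy.re_model()].
#' @export
train_re_model <- function(data, kind = somnimu_model_kinds, seed = 1,
                           tune = TRUE, threshold = 0.5) {
  kind <- match.arg(kind, somnimu_model_kinds)
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  feats <- model_feature_cols(data)
  x_raw <- as.matrix(tibble::as_tibble(data)[, feats])
  y <- factor(data$label, levels = c("RE_negative", "RE_positive"))
  if (length(unique(y)) < 2) abort("Training data has a single class.",
                                   class = "somnimu_data_error")
  center <- colMeans(x_raw)
  scl <- apply(x_raw, 2, sd)
  x <- if (kind %in% c("knn", "mlp")) scale_features(x_raw, center, scl) else x_raw
  grid <- default_grid(kind, length(feats))
  if (tune && nrow(grid) > 1) {
    grid$cv_auc <- vapply(seq_len(nrow(grid)), function(i) {
      cv_auc(kind, x, y, as.list(grid[i, ]), seed)
    }, numeric(1))
    best <- as.list(grid[which.max(grid$cv_auc), ])
  } else {
    best <- as.list(grid[1, ])
    grid$cv_auc <- NA_real_
  }
  fit <- fit_one(kind, x, y, best, seed)
  structure(list(kind = kind, fit = fit, features = feats,
                 center = center, scale = scl,
                 tuning = grid, best = best,
                 threshold = threshold, seed = seed, n_train = nrow(x)),
            class = "re_model")
}

#' @export
print.re_model <- function(x, ...) {
  pars <- x$best[setdiff(names(x$best), c(".dummy", "cv_auc"))]
  cat(sprintf("<re_model> %s trained on %d epochs (%d features)%s\n",
              x$kind, x$n_train, length(x$features),
              if (length(pars)) paste0("; ", paste(names(pars), unlist(pars),
                                                   sep = " = ", collapse = ", "))
              else ""))
  invisible(x)
}

#' Predict respiratory-event probabilities or classes
#'
#' @param object An `re_model`.
#' @param newdata Feature table with the model's feature columns.
#' @param type `"prob"` for the probability of `RE_positive`, `"class"` for
#'   the thresholded factor.
#' @param ... Unused.
#' @return Numeric vector (`"prob"`) or factor (`"class"`).
#' @export
predict.re_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(tibble::as_tibble(newdata)[, object$features])
  if (object$kind %in% c("knn", "mlp")) {
    x <- scale_features(x, object$center, object$scale)
  }
  prob <- predict_prob(object$kind, object$fit, x)
  if (type == "prob") return(prob)
  factor(ifelse(prob >= object$threshold, "RE_positive", "RE_negative"),
         levels = c("RE_negative", "RE_positive"))
}

#' Per-epoch classification metrics
#'
#' Confusion-matrix metrics at a probability threshold, plus the
#' threshold-free AUC: accuracy, sensitivity, specificity, positive and
#' negative predictive accuracy (PPA / NPA) and F1
#' (`2 * ppa * sensitivity / (ppa + sensitivity)`).
#'
#' @param truth Factor of true labels (`RE_negative` / `RE_positive`).
#' @param prob Predicted probabilities of `RE_positive`.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble with `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppa`, `npa`, `f1`, `threshold` and the confusion counts.
#' @export
epoch_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- factor(truth, levels = c("RE_negative", "RE_positive"))
  pred_pos <- prob >= threshold
  tp <- sum(pred_pos & truth == "RE_positive")
  fp <- sum(pred_pos & truth == "RE_negative")
  fn <- sum(!pred_pos & truth == "RE_positive")
  tn <- sum(!pred_pos & truth == "RE_negative")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppa <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npa <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppa) && !is.na(sens) && ppa + sens > 0) {
    2 * ppa * sens / (ppa + sens)
  } else NA_real_
  auc <- auc_safe(truth, prob)
  if (is.na(auc)) warn("AUC undefined: evaluation set has a single class.")
  tibble::tibble(auc = auc, accuracy = (tp + tn) / length(truth),
                 sensitivity = sens, specificity = spec,
                 ppa = ppa, npa = npa, f1 = f1, threshold = threshold,
                 tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Evaluate a fitted model on labelled epochs
#'
#' @param model An `re_model`.
#' @param data Labelled feature table.
#' @param threshold Probability threshold (defaults to the model's).
#' @return One-row metric tibble; see [epoch_metrics()].
#' @export
evaluate_epochs <- function(model, data, threshold = model$threshold) {
  epoch_metrics(data$label, predict(model, data, type = "prob"), threshold)
}

#' Respiratory event index from per-epoch predictions
#'
#' REI is the hourly rate of predicted RE-positive epochs over the analysed
#' duration (whole epochs times 30 s; no sleep staging is performed).
#'
#' @param predictions Logical vector, or factor with level `RE_positive`,
#'   one per epoch.
#' @param grid Epoch grid the predictions align to.
#' @return Events per hour.
#' @export
compute_rei <- function(predictions, grid) {
  if (is.factor(predictions) || is.character(predictions)) {
    predictions <- predictions == "RE_positive"
  }
  if (length(predictions) != grid$n_epochs) {
    abort("One prediction per epoch required.", class = "somnimu_data_error")
  }
  hours <- grid$n_epochs * grid$epoch_length / 3600
  if (hours <= 0) abort("Zero analysed duration.", class = "somnimu_data_error")
  sum(predictions) / hours
}

#' Per-subject REI from a pooled feature table
#'
#' Applies the model to every epoch and summarises per subject: epochs
#' analysed, predicted positives, and the REI.
#'
#' @param model An `re_model`.
#' @param data Feature table with `subject_id` (and the feature columns).
#' @param epoch_length Epoch length in seconds.
#' @return Tibble with `subject_id`, `n_epochs`, `n_positive`, `rei`.
#' @export
rei_by_subject <- function(model, data, epoch_length = 30) {
  data$.pred <- predict(model, data, type = "class")
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_epochs = dplyr::n(),
                     n_positive = sum(.data$.pred == "RE_positive"),
                     .groups = "drop") |>
    dplyr::mutate(rei = .data$n_positive / (.data$n_epochs * epoch_length / 3600))
}

#' Per-subject severity agreement between REI and AHI
#'
#' Pearson correlation between the estimated REI and the reference AHI,
#' plus screening sensitivity/specificity at the moderate (15/h) and severe
#' (30/h) cutoffs (REI >= cutoff predicting AHI >= cutoff), and the severity
#' confusion table at the 5/15/30 cutoffs.
#'
#' @param subjects Tibble with columns `rei` and `ahi` (one row per
#'   subject).
#' @param cutoffs Screening cutoffs in events/hour (default 15 and 30).
#' @return A `subject_eval`: list with `r`, `n`, `cutoffs` (tibble),
#'   `confusion` (table) and the input `data`.
#' @export
evaluate_subjects <- function(subjects, cutoffs = c(15, 30)) {
  if (nrow(subjects) < 3) abort("Need at least 3 subjects.", class = "somnimu_data_error")
  r <- if (sd(subjects$rei) == 0 || sd(subjects$ahi) == 0) {
    warn("Correlation undefined: zero variance.")
    NA_real_
  } else {
    cor(subjects$rei, subjects$ahi)
  }
  cut_tbl <- purrr::map_dfr(cutoffs, function(cc) {
    truth <- subjects$ahi >= cc
    pred <- subjects$rei >= cc
    tibble::tibble(
      cutoff = cc,
      sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
      specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_
    )
  })
  structure(list(r = r, n = nrow(subjects), cutoffs = cut_tbl,
                 confusion = table(predicted = severity_class(subjects$rei),
                                   truth = severity_class(subjects$ahi)),
                 data = tibble::as_tibble(subjects)),
            class = "subject_eval")
}

#' @export
print.subject_eval <- function(x, ...) {
  cat(sprintf("<subject_eval> n = %d, Pearson r(REI, AHI) = %.3f\n", x$n, x$r))
  print(x$cutoffs)
  invisible(x)
}

#' @export
tidy.subject_eval <- function(x, ...) x$cutoffs

#' @export
glance.subject_eval <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n)
}

#' Recursive feature elimination with a naive Bayes scorer
#'
#' Features are ranked by single-feature ROC AUC and eliminated lowest
#' first; each subset size is scored by the accuracy of a Gaussian naive
#' Bayes classifier over bootstrap resamples (fit on the bootstrap sample,
#' evaluated on the out-of-bag rows, 25 repetitions). The best subset is the
#' smallest one attaining the maximum mean accuracy.
#'
#' @param data Labelled feature table.
#' @param seed Integer seed.
#' @param reps Bootstrap repetitions (25).
#' @return An `rfe_result`: list with `profile` (tibble of subset size,
#'   mean accuracy, SE and the feature set), `selected` (character vector)
#'   and `ranking`.
#' @export
rfe_select <- function(data, seed = 1, reps = 25) {
  feats <- model_feature_cols(data)
  if (length(feats) < 2) abort("Need at least 2 features.", class = "somnimu_data_error")
  y <- factor(data$label, levels = c("RE_negative", "RE_positive"))
  if (length(unique(y)) < 2) abort("Single-class data.", class = "somnimu_data_error")
  x <- tibble::as_tibble(data)[, feats]
  ranking <- vapply(feats, function(f) {
    a <- auc_safe(y, x[[f]])
    abs(a - 0.5)
  }, numeric(1))
  order_feats <- feats[order(ranking, decreasing = TRUE)]
  profile <- withr::with_seed(seed, {
    purrr::map_dfr(rev(seq_along(order_feats)), function(kk) {
      sub <- order_feats[seq_len(kk)]
      df <- as.data.frame(x[, sub, drop = FALSE])
      accs <- vapply(seq_len(reps), function(rr) {
        idx <- sample.int(nrow(df), replace = TRUE)
        oob <- setdiff(seq_len(nrow(df)), unique(idx))
        if (length(oob) == 0 || length(unique(y[idx])) < 2) return(NA_real_)
        nb <- e1071::naiveBayes(df[idx, , drop = FALSE], y[idx])
        mean(predict(nb, df[oob, , drop = FALSE]) == y[oob])
      }, numeric(1))
      tibble::tibble(k = kk, accuracy = mean(accs, na.rm = TRUE),
                     se = sd(accs, na.rm = TRUE) / sqrt(sum(!is.na(accs))),
                     features = list(sub))
    })
  })
  best_acc <- max(profile$accuracy)
  best_k <- min(profile$k[profile$accuracy >= best_acc])
  structure(list(profile = dplyr::arrange(profile, .data$k),
                 selected = order_feats[seq_len(best_k)],
                 ranking = sort(ranking, decreasing = TRUE)),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> best subset: %d features (accuracy %.3f)\n",
              length(x$selected), max(x$profile$accuracy)))
  invisible(x)
}

#' Feature importance of a fitted random forest, scaled to 0-100
#'
#' Impurity importance of the random-forest model rescaled so the most
#' influential feature scores 100.
#'
#' @param model An `re_model` of kind `random_forest`.
#' @return Tibble with `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "re_model") || model$kind != "random_forest") {
    abort("Feature importance is defined for random-forest models.")
  }
  imp <- ranger::importance(model$fit)
  imp <- 100 * imp / max(imp)
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
tidy.re_model <- function(x, ...) {
  switch(x$kind,
    logistic_regression = {
      cf <- summary(x$fit)$coefficients
      tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                     std_error = cf[, 2], statistic = cf[, 3],
                     p_value = cf[, 4])
    },
    random_forest = feature_importance(x),
    tibble::as_tibble(x$tuning)
  )
}

#' @export
glance.re_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_train = x$n_train,
                 n_features = length(x$features),
                 cv_auc = if ("cv_auc" %in% names(x$tuning)) {
                   suppressWarnings(max(x$tuning$cv_auc, na.rm = TRUE))
                 } else NA_real_,
                 threshold = x$threshold, seed = x$seed)
}
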