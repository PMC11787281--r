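# Toy labelled feature table: first `k_inf` features carry class signal,
# the rest are noise.
toy_table <- function(n = 300, p = 6, k_inf = 2, shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.4)
    x <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(k_inf)) x[, j] <- x[, j] + shift * y
    tbl <- tibble::as_tibble(as.data.frame(x))
    names(tbl) <- paste0("f", seq_len(p))
    tbl$label <- factor(ifelse(y == 1, "RE_positive", "RE_negative"),
                        levels = c("RE_negative", "RE_positive"))
    tbl$subject_id <- "toy"
    tbl
  })
}

test_that("severity classes follow the 5/15/30 cutoffs", {
  expect_equal(as.character(severity_class(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 80))),
               c("normal", "normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
})

test_that("subject splitting is stratified, sized and reproducible", {
  withr::local_seed(5)
  subjects <- tibble::tibble(subject_id = sprintf("P%02d", 1:61),
                             ahi = c(runif(16, 0, 5), runif(16, 5, 15),
                                     runif(15, 15, 30), runif(14, 30, 70)))
  plan <- split_subjects(subjects, ratio = 0.67, seed = 3)
  expect_equal(nrow(plan$train), 41)
  expect_equal(nrow(plan$test), 20)
  expect_length(intersect(plan$train$subject_id, plan$test$subject_id), 0)
  # severity proportions preserved within one subject per class
  tr_tab <- table(plan$train$severity)
  all_tab <- table(severity_class(subjects$ahi))
  expect_true(all(abs(tr_tab - 0.67 * all_tab) <= 1))
  # reproducible
  plan2 <- split_subjects(subjects, ratio = 0.67, seed = 3)
  expect_identical(plan$train$subject_id, plan2$train$subject_id)
  # degenerate requests
  expect_error(split_subjects(subjects, ratio = 1), class = "somnimu_data_error")
  expect_error(split_subjects(subjects[1, ]), class = "somnimu_data_error")
})

test_that("SMOTE balances to exactly 1:1 with convex synthetic points", {
  withr::local_seed(9)
  # minority points on the line x2 = 2 x1: synthetic points must stay on it
  n_min <- 25; n_maj <- 100
  tbl <- tibble::tibble(
    f1 = c(rnorm(n_maj, 5), rnorm(n_min)),
    label = factor(rep(c("RE_negative", "RE_positive"), c(n_maj, n_min)),
                   levels = c("RE_negative", "RE_positive"))
  )
  tbl$f2 <- ifelse(tbl$label == "RE_positive", 2 * tbl$f1, rnorm(n_maj + n_min, 5))
  bal <- smote_balance(tbl, seed = 4)
  expect_equal(unname(table(bal$label)["RE_positive"]),
               unname(table(bal$label)["RE_negative"]))
  syn <- bal[-seq_len(nrow(tbl)), ]
  expect_true(all(abs(syn$f2 - 2 * syn$f1) < 1e-9))
  rng <- range(tbl$f1[tbl$label == "RE_positive"])
  expect_true(all(syn$f1 >= rng[1] - 1e-9 & syn$f1 <= rng[2] + 1e-9))
  # originals preserved
  expect_equal(bal[seq_len(nrow(tbl)), names(tbl)], tbl, ignore_attr = TRUE)
  # already balanced -> unchanged
  eq <- tbl[c(1:25, 101:125), ]
  expect_identical(smote_balance(eq, seed = 1), tibble::as_tibble(eq))
})

test_that("all five classifier kinds separate a separable table", {
  tbl <- toy_table(n = 240, p = 4, k_inf = 1, shift = 6, seed = 2)
  for (kind in c("logistic_regression", "random_forest", "gradient_boosting",
                 "knn", "mlp")) {
    m <- train_re_model(tbl, kind, seed = 11, tune = FALSE)
    auc <- evaluate_epochs(m, tbl)$auc
    expect_gte(auc, 0.95)
  }
})

test_that("label-shuffled data yields chance-level held-out AUC", {
  tbl <- toy_table(n = 400, p = 5, k_inf = 2, seed = 6)
  tbl$label <- withr::with_seed(8, sample(tbl$label))
  tr <- tbl[1:200, ]; te <- tbl[201:400, ]
  m <- train_re_model(tr, "random_forest", seed = 12, tune = FALSE)
  expect_lt(abs(evaluate_epochs(m, te)$auc - 0.5), 0.12)
})

test_that("random-forest training is deterministic under a seed", {
  tbl <- toy_table(seed = 3)
  m1 <- train_re_model(tbl, "random_forest", seed = 21, tune = FALSE)
  m2 <- train_re_model(tbl, "random_forest", seed = 21, tune = FALSE)
  expect_identical(predict(m1, tbl), predict(m2, tbl))
})

test_that("epoch metrics reproduce confusion-matrix arithmetic", {
  truth <- factor(rep(c("RE_positive", "RE_negative"), c(40, 160)),
                  levels = c("RE_negative", "RE_positive"))
  prob <- c(rep(1, 30), rep(0, 10),   # TP 30, FN 10
            rep(1, 20), rep(0, 140))  # FP 20, TN 140
  m <- epoch_metrics(truth, prob)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.875)
  expect_equal(m$ppa, 0.6)
  expect_equal(m$npa, 140 / 150, tolerance = 1e-3)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-9)

  perfect <- epoch_metrics(truth, as.numeric(truth == "RE_positive"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)

  allneg <- epoch_metrics(truth, rep(0, 200))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
})

test_that("REI is positives per analysed hour", {
  grid8h <- toy_grid(960)
  expect_equal(compute_rei(rep(c(TRUE, FALSE), c(120, 840)), grid8h), 15)
  expect_equal(compute_rei(rep(FALSE, 960), grid8h), 0)
  expect_equal(compute_rei(rep(TRUE, 960), grid8h), 120)
  expect_error(compute_rei(rep(TRUE, 10), grid8h), class = "somnimu_data_error")
})

test_that("subject-level agreement handles identity and shifted REI", {
  subj <- tibble::tibble(subject_id = letters[1:5],
                         ahi = c(3, 10, 14, 20, 40))
  ev_id <- evaluate_subjects(dplyr::mutate(subj, rei = ahi))
  expect_equal(ev_id$r, 1)
  expect_equal(ev_id$cutoffs$sensitivity, c(1, 1))
  expect_equal(ev_id$cutoffs$specificity, c(1, 1))

  ev_sh <- evaluate_subjects(dplyr::mutate(subj, rei = ahi + 2))
  expect_equal(ev_sh$r, 1)
  # 14 + 2 crosses the 15 cutoff: one false positive among three negatives
  expect_equal(ev_sh$cutoffs$sensitivity, c(1, 1))
  expect_equal(ev_sh$cutoffs$specificity, c(2 / 3, 1))

  expect_error(evaluate_subjects(subj[1:2, ]), class = "somnimu_data_error")
})

test_that("RFE eliminates noise before informative features", {
  tbl <- toy_table(n = 400, p = 8, k_inf = 3, shift = 1.2, seed = 14)
  res <- rfe_select(tbl, seed = 15, reps = 10)
  expect_equal(nrow(res$profile), 8)
  # the single-feature AUC ranking puts the informative three on top
  expect_setequal(names(res$ranking)[1:3], c("f1", "f2", "f3"))
  expect_true(all(c("f1", "f2", "f3") %in% res$selected))
  expect_true(all(diff(res$profile$k) == 1))
})

test_that("random-forest importance is scaled to 100 and finds the signal", {
  tbl <- toy_table(n = 300, p = 5, k_inf = 1, shift = 3, seed = 16)
  m <- train_re_model(tbl, "random_forest", seed = 17, tune = FALSE)
  imp <- feature_importance(m)
  expect_equal(max(imp$importance), 100)
  expect_equal(imp$feature[1], "f1")
  expect_true(all(imp$importance >= 0 & imp$importance <= 100))
  # column order of the input does not change the scores
  tbl2 <- tbl[, c(paste0("f", 5:1), "label", "subject_id")]
  m2 <- train_re_model(tbl2, "random_forest", seed = 17, tune = FALSE)
  imp2 <- feature_importance(m2)
  expect_equal(imp2[order(imp2$feature), ]$importance,
               imp[order(imp$feature), ]$importance, tolerance = 0.35)
  # defined only for the random forest
  lg <- train_re_model(tbl, "logistic_regression", seed = 1, tune = FALSE)
  expect_error(feature_importance(lg))
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  tbl <- toy_table(seed = 19)
  lg <- train_re_model(tbl, "logistic_regression", seed = 1, tune = FALSE)
  td <- tidy(lg)
  expect_true(all(c("term", "estimate", "p_value") %in% names(td)))
  rf <- train_re_model(tbl, "random_forest", seed = 1, tune = FALSE)
  expect_true(all(c("feature", "importance") %in% names(tidy(rf))))
  gl <- glance(rf)
  expect_equal(gl$kind, "random_forest")
  expect_equal(gl$n_train, nrow(tbl))
})
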