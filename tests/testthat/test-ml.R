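test_that("stratified folds partition rows and balance classes", {
  set.seed(1)
  y <- rep(c(0L, 1L), c(50, 33))
  f <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(tabulate(f, 10), rep(c(9, 8), c(3, 7)))   # all rows, once
  glob <- mean(y)
  for (k in 1:10) {
    ratio <- mean(y[f == k])
    nk <- sum(f == k)
    # within one sample of the global class ratio
    expect_lte(abs(sum(y[f == k]) - glob * nk), 1)
  }
  # the assignment depends only on its own seed
  expect_identical(stratified_folds(y, 10, seed = 3), f)
  expect_false(identical(stratified_folds(y, 10, seed = 4), f))
  expect_error(stratified_folds(y, 100), "exceeds")
})

test_that("rank AUC matches an established implementation", {
  set.seed(7)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  expect_equal(mssignal:::auc_score(y, s),
               as.numeric(suppressMessages(pROC::auc(y, s))))
  expect_equal(mssignal:::auc_score(c(0, 1), c(0.1, 0.9)), 1)
  expect_equal(mssignal:::auc_score(c(0, 1), c(0.9, 0.1)), 0)
})

test_that("a separable feature gives near-perfect repeated-CV metrics", {
  df <- make_ml_table(n = 80, informative = 1, effect = 8)
  b <- repeated_cv(df, "I_MS", "RF", k = 10, seeds = 3)
  s <- setNames(b$summary$mean, b$summary$metric)
  expect_gte(s[["accuracy"]], 99)
  expect_gte(s[["aucroc"]], 0.99)
  expect_equal(b$n, 80)
})

test_that("repeated CV is deterministic and its metrics match the confusion", {
  df <- make_ml_table(n = 60, effect = 1)
  b1 <- repeated_cv(df, "I_MS", "RF", k = 5, seeds = 4)
  b2 <- repeated_cv(df, "I_MS", "RF", k = 5, seeds = 4)
  expect_identical(b1$per_seed, b2$per_seed)
  ps <- b1$per_seed
  expect_equal(ps$accuracy,
               100 * (ps$TP + ps$TN) / (ps$TP + ps$TN + ps$FP + ps$FN))
  expect_equal(ps$sensitivity, 100 * ps$TP / (ps$TP + ps$FN))
  expect_equal(ps$specificity, 100 * ps$TN / (ps$TN + ps$FP))
  expect_equal(ps$TP + ps$TN + ps$FP + ps$FN, rep(60, 4))  # every row tested
})

test_that("every model family trains, scores and stays in range", {
  df <- make_ml_table(n = 60, effect = 3)
  for (m in c("RF", "GB", "ADAB", "SVM", "KNN", "MLP")) {
    b <- repeated_cv(df, "I_MS", m, k = 5, seeds = 2)
    s <- setNames(b$summary$mean, b$summary$metric)
    expect_true(all(s[c("accuracy", "sensitivity", "specificity")] >= 0 &
                      s[c("accuracy", "sensitivity", "specificity")] <= 100),
                info = m)
    expect_gte(s[["aucroc"]], 0.8)      # clearly separable problem
  }
  expect_error(repeated_cv(df, "I_MS", "LDA"))
  df1 <- df; df1$I_MS <- 1L
  expect_error(repeated_cv(df1, "I_MS", "RF"), "single class")
  expect_error(repeated_cv(df, "I_MS", "RF", k = 100), "exceeds")
})

test_that("permuted labels give chance-level accuracy", {
  df <- make_ml_table(n = 80, effect = 3, seed = 42)
  set.seed(17)
  df$I_MS <- sample(df$I_MS)
  b <- repeated_cv(df, "I_MS", "KNN", k = 10, seeds = 10)
  s <- b$summary
  acc <- s$mean[s$metric == "accuracy"]; sd_acc <- s$sd[s$metric == "accuracy"]
  majority <- 100 * max(mean(df$I_MS), 1 - mean(df$I_MS))
  expect_lte(acc, majority + 3 * sd_acc)    # no spurious learned signal
  auc <- s$mean[s$metric == "aucroc"]
  expect_gte(auc, 0.3); expect_lte(auc, 0.7)
})

test_that("random-forest importance recovers a planted signal and sums to 100", {
  df <- make_ml_table(n = 150, p = 19, informative = 1, effect = 2, seed = 5)
  imp <- rf_importance(df, "I_MS", seeds = 5)
  expect_equal(sum(imp$importance), 100, tolerance = 0.1)
  expect_equal(imp$feature[1], feature_names()[1])
  expect_gte(imp$importance[1], 3 * imp$importance[2])
  expect_equal(imp$rank, seq_len(19))
})

test_that("a duplicated informative column shares its importance", {
  df <- make_ml_table(n = 150, p = 10, informative = 1, effect = 2, seed = 6)
  imp1 <- rf_importance(df, "I_MS", seeds = 5,
                        features = feature_names()[1:10])
  base <- imp1$importance[imp1$feature == feature_names()[1]]
  df2 <- df
  df2$dup <- df2[[feature_names()[1]]]
  imp2 <- rf_importance(df2, "I_MS", seeds = 5,
                        features = c(feature_names()[1:10], "dup"))
  pair <- sum(imp2$importance[imp2$feature %in% c(feature_names()[1], "dup")])
  expect_equal(pair, base, tolerance = 0.2 * base)
})

test_that("rows with missing features are dropped listwise and counted", {
  df <- make_ml_table(n = 60, effect = 4)
  df[1:5, feature_names()[1]] <- NA
  b <- repeated_cv(df, "I_MS", "RF", k = 5, seeds = 2)
  expect_equal(b$n, 55)
  expect_equal(b$dropped_rows, 5)
})

test_that("the full benchmark grid has the expected shape and flags a best model", {
  df <- make_ml_table(n = 60, effect = 2, seed = 20)
  df$I_PV <- df$I_MS
  df$I_NM <- as.integer(ifelse(runif(60) < 0.15, 1 - df$I_MS, df$I_MS))
  rep <- benchmark_all(df, labels = c("I_PV", "I_NM", "I_MS"),
                       models = c("RF", "KNN"), k = 5, seeds = 2)
  expect_equal(nrow(rep$metrics), 3 * 2 * 4)    # index x model x metric
  expect_equal(sort(unique(rep$metrics$metric)),
               sort(c("accuracy", "sensitivity", "specificity", "aucroc")))
  for (lab in c("I_PV", "I_NM", "I_MS")) {
    best <- unique(rep$metrics$model[rep$metrics$index == lab &
                                       rep$metrics$best])
    expect_length(best, 1)
    expect_s3_class(rep$importance[[lab]], "importance_report")
  }
})
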