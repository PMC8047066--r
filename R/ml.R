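#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals its members to folds in turn,
#' so every fold's class ratio is within one sample of the global ratio
#' and both classes appear in every test fold whenever `k` does not exceed
#' the minority count.
#'
#' @param y Binary label vector (0/1).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer fold id in `1..k` per observation.
#' @export
stratified_folds <- function(y, k = 10, seed = 1L) {
  n <- length(y)
  if (k > n) stop("k exceeds the number of observations")
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cl in unique(sort(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)        # stagger classes across folds
  }
  fold
}

ml_models <- function() c("RF", "GB", "ADAB", "SVM", "KNN", "MLP")

# Standardize by training-set statistics (constant columns left unscaled).
std_fit <- function(X) {
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

# AdaBoost.M1 with depth-1 rpart stumps (no boosting-of-trees package is
# part of the stack, and the algorithm is ~30 lines).  The continuous
# score is the signed weighted-vote margin.
adaboost_fit <- function(X, y, n_rounds = 100, maxdepth = 1) {
  df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
  w <- rep(1 / nrow(df), nrow(df))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w * nrow(df), method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {          # fall back to the prior
    return(structure(list(stumps = list(), alphas = 0,
                          prior = mean(y)), class = "adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, prior = mean(y)),
            class = "adaboost")
}

#' @export
predict.adaboost <- function(object, X, ...) {
  if (!length(object$stumps))
    return(rep(object$prior - 0.5, nrow(X)))
  votes <- vapply(object$stumps, function(s) {
    p <- as.integer(as.character(predict(s, data.frame(X), type = "class")))
    2 * p - 1
  }, numeric(nrow(X)))
  as.numeric(matrix(votes, nrow = nrow(X)) %*% object$alphas) /
    sum(object$alphas)
}

# Train on (Xtr, ytr), return continuous scores for Xte oriented so that
# larger means more likely class 1.  Every model's RNG is seeded here so
# repeated runs are bit-identical.
train_score <- function(model, Xtr, ytr, Xte, seed) {
  set.seed(seed)
  yf <- factor(ytr, levels = c(0, 1))
  switch(model,
    RF = {
      fit <- randomForest::randomForest(Xtr, yf, ntree = 100)
      predict(fit, Xte, type = "prob")[, "1"]
    },
    GB = {
      fit <- xgboost::xgboost(Xtr, yf, nrounds = 100, verbosity = 0,
                              max_depth = 3, learning_rate = 0.1,
                              nthreads = 1)
      as.numeric(predict(fit, Xte))   # probability of class "1"
    },
    ADAB = {
      fit <- adaboost_fit(Xtr, ytr)
      predict(fit, Xte)
    },
    SVM = {
      s <- std_fit(Xtr)
      fit <- e1071::svm(std_apply(Xtr, s), yf, kernel = "radial",
                        scale = FALSE)
      dv <- attr(predict(fit, std_apply(Xte, s), decision.values = TRUE),
                 "decision.values")
      # orient decision values toward class "1"
      if (startsWith(colnames(dv)[1], "1")) as.numeric(dv)
      else -as.numeric(dv)
    },
    KNN = {
      s <- std_fit(Xtr)
      pr <- class::knn(std_apply(Xtr, s), std_apply(Xte, s), yf, k = 5,
                       prob = TRUE)
      frac <- attr(pr, "prob")            # vote share of the winning class
      ifelse(pr == "1", frac, 1 - frac)
    },
    MLP = {
      s <- std_fit(Xtr)
      fit <- nnet::nnet(std_apply(Xtr, s), ytr, size = 32, decay = 1e-3,
                        maxit = 200, entropy = TRUE, trace = FALSE,
                        MaxNWts = 5000)
      as.numeric(predict(fit, std_apply(Xte, s)))
    },
    stop("unknown model: ", model))
}

score_threshold <- function(model) {
  switch(model, RF = , GB = , KNN = , MLP = 0.5, SVM = , ADAB = 0)
}

# Rank-based AUC of scores for binary labels (class 1 positive).
auc_score <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(y, pred) {
  tp <- sum(y == 1 & pred == 1); tn <- sum(y == 0 & pred == 0)
  fp <- sum(y == 0 & pred == 1); fn <- sum(y == 1 & pred == 0)
  c(accuracy = 100 * (tp + tn) / length(y),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    TP = tp, TN = tn, FP = fp, FN = fn)
}

prepare_xy <- function(cohort, label, features) {
  cohort <- as.data.frame(cohort)
  miss <- setdiff(c(features, label), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(cohort[features])
  y <- cohort[[label]]
  keep <- stats::complete.cases(X) & !is.na(y)
  list(X = X[keep, , drop = FALSE], y = as.integer(y[keep]),
       dropped = sum(!keep))
}

#' Repeated stratified 10-fold cross-validation of one classifier
#'
#' For each seed, the cohort is split into `k` stratified folds; each fold
#' is predicted by a model trained on the other `k - 1`; the out-of-fold
#' predictions are pooled into one confusion matrix and one ROC per seed.
#' Accuracy, sensitivity and specificity (class 1 positive, in percent)
#' and AUCROC are then averaged over seeds, with their SD.  Rows with any
#' missing feature are dropped listwise (count reported).
#'
#' @param cohort Data frame with feature and label columns.
#' @param label Name of a binary 0/1 column with both classes present.
#' @param model One of `"RF"`, `"GB"`, `"ADAB"`, `"SVM"`, `"KNN"`,
#'   `"MLP"`.
#' @param k Folds (default 10).
#' @param seeds Either a count (default 10; seeds derived from
#'   `base_seed`) or an explicit integer vector of seeds.
#' @param features Feature columns (default the 19 biometric features).
#' @param base_seed Root of the derived seed sequence.
#' @return Object of class `bench_result`: `summary` (mean and sd of the
#'   four metrics), `per_seed` (one row per seed, incl. pooled confusion
#'   counts), `model`, `label`, `n`, `dropped_rows`, `folds`.
#' @export
repeated_cv <- function(cohort, label, model = "RF", k = 10, seeds = 10,
                        features = feature_names(), base_seed = 2024L) {
  model <- match.arg(model, ml_models())
  d <- prepare_xy(cohort, label, features)
  if (length(unique(d$y)) < 2) stop("label '", label, "' has a single class")
  if (k > length(d$y)) stop("k exceeds the number of usable rows")
  if (length(seeds) == 1) seeds <- base_seed + seq_len(seeds)
  per_seed <- lapply(seeds, function(s) {
    fold <- stratified_folds(d$y, k, seed = s)
    score <- numeric(length(d$y))
    for (f in seq_len(k)) {
      te <- fold == f
      score[te] <- train_score(model, d$X[!te, , drop = FALSE], d$y[!te],
                               d$X[te, , drop = FALSE],
                               seed = derive_seed(s, model, label, f))
    }
    pred <- as.integer(score > score_threshold(model))
    c(seed = s, confusion_metrics(d$y, pred), aucroc = auc_score(d$y, score))
  })
  per_seed <- as.data.frame(do.call(rbind, per_seed))
  met <- c("accuracy", "sensitivity", "specificity", "aucroc")
  summary <- data.frame(metric = met,
                        mean = colMeans(per_seed[met]),
                        sd = apply(per_seed[met], 2, stats::sd),
                        row.names = NULL)
  structure(list(summary = summary, per_seed = per_seed, model = model,
                 label = label, n = length(d$y), dropped_rows = d$dropped,
                 folds = k),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> %s on %s (n = %d, %d-fold x %d seeds%s)\n",
              x$model, x$label, x$n, x$folds, nrow(x$per_seed),
              if (x$dropped_rows) paste0(", ", x$dropped_rows, " rows dropped")
              else ""))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Random-forest feature importance, normalized to percent
#'
#' Trains one 100-tree forest per seed on the full usable table, averages
#' the mean-decrease-in-impurity (Gini) importances across seeds and
#' rescales them to sum to 100.
#'
#' @inheritParams repeated_cv
#' @return Data frame of class `importance_report`: `feature`,
#'   `importance` (percent, sums to 100), `rank`, sorted by rank.
#' @export
rf_importance <- function(cohort, label, seeds = 10,
                          features = feature_names(), base_seed = 2024L) {
  d <- prepare_xy(cohort, label, features)
  if (length(unique(d$y)) < 2) stop("label '", label, "' has a single class")
  if (length(seeds) == 1) seeds <- base_seed + seq_len(seeds)
  yf <- factor(d$y, levels = c(0, 1))
  imp <- vapply(seeds, function(s) {
    set.seed(derive_seed(s, "rfimp", label))
    fit <- randomForest::randomForest(d$X, yf, ntree = 100,
                                      importance = FALSE)
    fit$importance[, "MeanDecreaseGini"]
  }, numeric(ncol(d$X)))
  m <- rowMeans(imp)
  pct <- 100 * m / sum(m)
  out <- data.frame(feature = names(pct), importance = pct,
                    row.names = NULL)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Benchmark all six classifier families on the composite indexes
#'
#' Runs [repeated_cv()] for every (index, model) combination, flags the
#' best model per index by mean AUCROC, and attaches the random-forest
#' importance ranking for each index.
#'
#' @inheritParams repeated_cv
#' @param labels Index columns to classify (default the three composite
#'   indexes).
#' @param models Model set (default all six).
#' @return Object of class `benchmark_report`: `metrics` (one row per
#'   index x model x metric: mean, sd, best flag), `importance` (named
#'   list of [rf_importance()] tables), `labels`, `models`.
#' @export
benchmark_all <- function(cohort, labels = c("I_PV", "I_NM", "I_MS"),
                          models = ml_models(), k = 10, seeds = 10,
                          features = feature_names(), base_seed = 2024L) {
  grid <- list()
  for (lab in labels) for (mo in models) {
    b <- repeated_cv(cohort, lab, mo, k = k, seeds = seeds,
                     features = features, base_seed = base_seed)
    s <- b$summary
    grid[[length(grid) + 1L]] <- data.frame(index = lab, model = mo,
                                            metric = s$metric,
                                            mean = s$mean, sd = s$sd)
  }
  metrics <- do.call(rbind, grid)
  metrics$best <- FALSE
  for (lab in labels) {
    au <- metrics[metrics$index == lab & metrics$metric == "aucroc", ]
    best <- au$model[which.max(au$mean)]
    metrics$best[metrics$index == lab & metrics$model == best] <- TRUE
  }
  importance <- lapply(stats::setNames(labels, labels), function(lab)
    rf_importance(cohort, lab, seeds = seeds, features = features,
                  base_seed = base_seed))
  structure(list(metrics = metrics, importance = importance,
                 labels = labels, models = models),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  for (lab in x$labels) {
    cat(lab, ":\n")
    sub <- x$metrics[x$metrics$index == lab, ]
    wide <- stats::reshape(sub[c("model", "metric", "mean")],
                           idvar = "model", timevar = "metric",
                           direction = "wide")
    names(wide) <- sub("^mean\\.", "", names(wide))
    wide$best <- ifelse(wide$model %in% sub$model[sub$best], "*", "")
    print(format(wide, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
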