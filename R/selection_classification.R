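feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "clip_id", "label"))
}

label_factor <- function(labels) {
  factor(labels, levels = c("typical", "delayed"))
}

#' Screen features by one-way ANOVA across the two label groups
#'
#' Each feature is tested with a classic one-way ANOVA (equal-variance
#' F test); features with p < `alpha` are retained, in original column
#' order. Raw p values are used for selection (no multiplicity
#' correction); Benjamini-Hochberg adjusted p values are attached as a
#' supplementary attribute for inspection.
#'
#' Degenerate columns are resolved analytically: zero between-group
#' variance gives F = 0 (p = 1, never retained); zero within-group
#' variance with distinct group means gives F -> infinity (p = 0,
#' retained).
#'
#' @param table Feature `data.frame` (as from [feature_table()]) with a
#'   `label` column, or a plain numeric matrix/data.frame plus `labels`.
#' @param labels Optional label vector when `table` has no label column.
#' @param alpha Significance level, default 0.05.
#' @return Character vector of retained feature names, with attributes
#'   `p_values` and `f_statistics` (named, all features) and `p_adjusted`
#'   (BH).
#' @export
anova_filter <- function(table, labels = NULL, alpha = 0.05) {
  table <- as.data.frame(table, check.names = FALSE)
  if (is.null(labels)) labels <- table$label
  g <- factor(labels)
  if (nlevels(g) < 2) stop("anova_filter needs two label groups")
  if (any(tabulate(g) < 2)) stop("each label group needs >= 2 rows")
  feats <- feature_columns(table)
  res <- vapply(feats, function(f) {
    v <- table[[f]]
    ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - mean(v))^2))
    ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
    if (ssw <= 0) return(if (ssb > 0) c(Inf, 0) else c(0, 1))
    if (ssb <= 0) return(c(0, 1))
    ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
    c(unname(ow$statistic), ow$p.value)
  }, numeric(2))
  p <- res[2, ]
  sel <- feats[p < alpha]
  attr(sel, "p_values") <- p
  attr(sel, "f_statistics") <- res[1, ]
  attr(sel, "p_adjusted") <- stats::p.adjust(p, method = "BH")
  sel
}

#' Oversample the minority class to a target count
#'
#' Minority rows are duplicated by seeded sampling with replacement until
#' the minority count equals `target_count`; when the target is an exact
#' integer multiple of the minority size each row is replicated the same
#' number of times. Majority rows are untouched and keep their order.
#'
#' @param table Feature `data.frame` with a `label` column.
#' @param target_count Desired minority row count; defaults to three
#'   times the minority size (e.g. 26 minority clips -> 78).
#' @param seed Integer seed for the remainder draw.
#' @return The augmented table (majority rows first, then minority).
#' @export
oversample_minority <- function(table, target_count = NULL, seed = 1L) {
  g <- factor(table$label)
  counts <- table(g)
  if (any(counts == 0) || nlevels(g) < 2) stop("empty minority class")
  minority <- names(counts)[which.min(counts)]
  m <- min(counts)
  if (is.null(target_count)) target_count <- 3L * m
  if (target_count < m) stop("target_count below current minority size")
  if (target_count == m) return(table)
  min_rows <- which(table$label == minority)
  full <- target_count %/% m
  rem <- target_count %% m
  extra <- if (rem > 0) {
    local_seed(seed)
    sample(min_rows, rem, replace = TRUE)
  } else integer(0)
  idx <- c(which(table$label != minority),
           rep(min_rows, times = full), extra)
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reseed the session RNG; all stochastic steps route through this so a
# top-level seed fully determines the run.
local_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Uses the population (divide-by-n) standard deviation. Zero-variance
#' columns map to 0. When `center`/`scale` are supplied (e.g. fitted on a
#' training fold) they are applied instead of being re-estimated, so held
#' -out data can be transformed without leakage.
#'
#' @param table Feature `data.frame` (metadata columns pass through).
#' @param center,scale Optional named vectors of per-feature location and
#'   scale to apply.
#' @return The standardized table with attributes `center` and `scale`.
#' @export
standardize_features <- function(table, center = NULL, scale = NULL) {
  feats <- feature_columns(table)
  m <- as.matrix(table[, feats, drop = FALSE])
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  }
  z <- sweep(m, 2, center[feats])
  s <- scale[feats]
  pos <- s > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, s[pos], "/")
  z[, !pos] <- 0
  out <- table
  out[, feats] <- z
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

stratified_folds <- function(labels, n_folds, seed) {
  g <- factor(labels)
  if (any(tabulate(g) < n_folds))
    stop("n_folds exceeds the size of a class (fold without both classes)")
  fold <- integer(length(labels))
  local_seed(seed)
  for (lv in levels(g)) {
    idx <- sample(which(g == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

fit_classifier <- function(model_name, x, y) {
  switch(model_name,
    random_forest = randomForest::randomForest(x = x, y = y),
    svm = e1071::svm(x = x, y = y, probability = TRUE),
    logistic_regression = {
      df <- as.data.frame(x); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y == "delayed"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eval_metric = "logloss", nthread = 1),
                         data = dtrain, nrounds = 100, verbose = 0)
    },
    stop("unknown model_name '", model_name, "'")
  )
}

# Probability of the "delayed" class for held-out rows.
predict_prob <- function(model_name, fit, x) {
  switch(model_name,
    random_forest = stats::predict(fit, x, type = "prob")[, "delayed"],
    svm = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      pr[, "delayed"]
    },
    logistic_regression =
      suppressWarnings(stats::predict(fit, as.data.frame(x), type = "response")),
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))
  )
}

# Support-weighted and macro classification metrics for one fold.
fold_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- label_factor(truth)
  if (nlevels(droplevels(truth)) < 2)
    stop("fold without both classes; reduce n_folds")
  pred <- factor(ifelse(prob >= threshold, "delayed", "typical"),
                 levels = levels(truth))
  per_class <- t(vapply(levels(truth), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1, support = sum(truth == cl))
  }, numeric(4)))
  w <- per_class[, "support"] / sum(per_class[, "support"])
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob,
    levels = c("typical", "delayed"), direction = "<", quiet = TRUE)))
  list(
    accuracy = mean(pred == truth),
    weighted = c(precision = sum(w * per_class[, "precision"]),
                 recall = sum(w * per_class[, "recall"]),
                 f1 = sum(w * per_class[, "f1"]),
                 auc = auc),
    macro = c(precision = mean(per_class[, "precision"]),
              recall = mean(per_class[, "recall"]),
              f1 = mean(per_class[, "f1"]),
              auc = auc),
    per_class = per_class,
    n = length(truth)
  )
}

#' Stratified cross-validated evaluation of one classifier
#'
#' Seeded stratified k-fold split; per fold the named classifier is fit
#' on the training rows and scored on the held-out rows. Reports per-fold
#' and support-weighted-average accuracy, recall, precision, F1 and AUC
#' (one-vs-rest, support-weighted over the two classes; for a binary task
#' the two one-vs-rest AUCs coincide). Macro averages are included
#' alongside.
#'
#' @param table Standardized feature `data.frame` with labels.
#' @param model_name One of `"random_forest"`, `"xgboost"`, `"svm"`,
#'   `"logistic_regression"`.
#' @param n_folds Number of folds, default 5; must not exceed the
#'   minority class size.
#' @param seed Integer seed controlling the fold split and any model
#'   randomness.
#' @return A `cv_report` list: `model_name`, `per_fold` data.frame,
#'   `weighted_avg`, `macro_avg`, `n_folds`, `seed`.
#' @export
crossval_evaluate <- function(table, model_name, n_folds = 5, seed = 1L) {
  feats <- feature_columns(table)
  y <- label_factor(table$label)
  x <- as.matrix(table[, feats, drop = FALSE])
  fold <- stratified_folds(y, n_folds, seed)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    local_seed(seed + f)
    fit <- fit_classifier(model_name, x[tr, , drop = FALSE], droplevels(y[tr]))
    prob <- predict_prob(model_name, fit, x[te, , drop = FALSE])
    per_fold[[f]] <- fold_metrics(y[te], prob)
  }
  summarize_cv(model_name, per_fold, n_folds, seed)
}

summarize_cv <- function(model_name, per_fold, n_folds, seed) {
  ns <- vapply(per_fold, `[[`, numeric(1), "n")
  w <- ns / sum(ns)
  pull <- function(kind, metric) vapply(per_fold, function(pf)
    if (metric == "accuracy") pf$accuracy else pf[[kind]][[metric]], numeric(1))
  weighted_avg <- c(
    accuracy = sum(w * pull("weighted", "accuracy")),
    recall = sum(w * pull("weighted", "recall")),
    precision = sum(w * pull("weighted", "precision")),
    f1 = sum(w * pull("weighted", "f1")),
    auc = sum(w * pull("weighted", "auc"))
  )
  macro_avg <- c(
    accuracy = mean(pull("macro", "accuracy")),
    recall = mean(pull("macro", "recall")),
    precision = mean(pull("macro", "precision")),
    f1 = mean(pull("macro", "f1")),
    auc = mean(pull("macro", "auc"))
  )
  pf_df <- data.frame(
    fold = seq_len(n_folds), n = ns,
    accuracy = pull("weighted", "accuracy"),
    recall = pull("weighted", "recall"),
    precision = pull("weighted", "precision"),
    f1 = pull("weighted", "f1"),
    auc = pull("weighted", "auc")
  )
  structure(list(model_name = model_name, per_fold = pf_df,
                 weighted_avg = weighted_avg, macro_avg = macro_avg,
                 per_fold_detail = per_fold,
                 n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s  (%d-fold, seed %d)\n",
              x$model_name, x$n_folds, x$seed))
  cat("  weighted avg:",
      paste(sprintf("%s=%.3f", names(x$weighted_avg), x$weighted_avg),
            collapse = "  "), "\n")
  invisible(x)
}

#' Screen, balance, standardize and cross-validate all four classifiers
#'
#' Runs the modeling stack: ANOVA feature screening, minority
#' oversampling, standardization and stratified cross-validation for
#' random forest, XGBoost, SVM and logistic regression, producing a
#' model-by-metric comparison.
#'
#' Two orderings are supported. The default applies screening,
#' oversampling and standardization to the full table before splitting
#' (the conventional pipeline order in this application area; note that
#' duplicated minority rows then span fold boundaries). With
#' `leakage_safe = TRUE` all three steps are fit inside each training
#' fold only and applied to the held-out fold — the methodologically
#' clean variant whose metrics estimate generalization.
#'
#' @param table Feature `data.frame` with labels.
#' @param models Character vector of model ids.
#' @param alpha ANOVA significance level, default 0.05.
#' @param target_count Minority target for oversampling (default 3x the
#'   minority size).
#' @param n_folds Folds, default 5.
#' @param seed Integer seed.
#' @param leakage_safe Fit screening/oversampling/standardization within
#'   training folds only.
#' @return List with `reports` (one `cv_report` per model), `comparison`
#'   (models x weighted metrics data.frame), `selected_features`, and the
#'   echoed `config`.
#' @export
run_pipeline <- function(table,
                         models = c("random_forest", "xgboost", "svm",
                                    "logistic_regression"),
                         alpha = 0.05, target_count = NULL, n_folds = 5,
                         seed = 1L, leakage_safe = FALSE) {
  if (!leakage_safe) {
    sel <- anova_filter(table, alpha = alpha)
    keep <- c(intersect(names(table), c("subject_id", "clip_id", "label")), sel)
    tab <- table[, keep, drop = FALSE]
    tab <- oversample_minority(tab, target_count, seed)
    tab <- standardize_features(tab)
    reports <- lapply(models, function(mn)
      crossval_evaluate(tab, mn, n_folds, seed))
  } else {
    sel <- NULL
    reports <- lapply(models, function(mn)
      crossval_leakage_safe(table, mn, alpha, target_count, n_folds, seed))
    sel <- attr(reports[[1]], "selected_union")
  }
  names(reports) <- models
  comparison <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(as.list(r$weighted_avg))))
  comparison <- cbind(model = models, comparison)
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison,
       selected_features = sel,
       config = list(models = models, alpha = alpha,
                     target_count = target_count, n_folds = n_folds,
                     seed = seed, leakage_safe = leakage_safe))
}

# Leakage-safe CV: screening, oversampling and standardization are fit on
# each training fold and only applied to its held-out fold.
crossval_leakage_safe <- function(table, model_name, alpha, target_count,
                                  n_folds, seed) {
  y <- label_factor(table$label)
  fold <- stratified_folds(y, n_folds, seed)
  per_fold <- vector("list", n_folds)
  sel_union <- character(0)
  for (f in seq_len(n_folds)) {
    tr_tab <- table[fold != f, , drop = FALSE]
    te_tab <- table[fold == f, , drop = FALSE]
    sel <- anova_filter(tr_tab, alpha = alpha)
    if (!length(sel)) {
      # no feature survives screening in this fold: fall back to the
      # full catalog so the fold still yields predictions
      sel <- feature_columns(tr_tab)
    }
    sel_union <- union(sel_union, sel)
    keep <- c(intersect(names(table), c("subject_id", "clip_id", "label")), sel)
    tr_tab <- oversample_minority(tr_tab[, keep, drop = FALSE],
                                  target_count, seed + f)
    tr_tab <- standardize_features(tr_tab)
    te_tab <- standardize_features(te_tab[, keep, drop = FALSE],
                                   center = attr(tr_tab, "center"),
                                   scale = attr(tr_tab, "scale"))
    local_seed(seed + f)
    fit <- fit_classifier(model_name,
                          as.matrix(tr_tab[, sel, drop = FALSE]),
                          droplevels(label_factor(tr_tab$label)))
    prob <- predict_prob(model_name, fit,
                         as.matrix(te_tab[, sel, drop = FALSE]))
    per_fold[[f]] <- fold_metrics(te_tab$label, prob)
  }
  rep <- summarize_cv(model_name, per_fold, n_folds, seed)
  attr(rep, "selected_union") <- sel_union
  rep
}
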