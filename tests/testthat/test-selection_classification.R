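test_that("per-feature ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(12)
  for (rep in 1:25) {
    tab <- toy_feature_table(n_typ = sample(5:15, 1), n_del = sample(5:15, 1),
                             k = 6, k_informative = 2, effect = runif(1, 0, 2),
                             seed = sample.int(1e6, 1))
    g <- factor(tab$label)
    sel <- anova_filter(tab, alpha = 0.05)
    p <- attr(sel, "p_values")
    for (f in sprintf("f%02d", 1:6)) {
      tt <- t.test(tab[[f]] ~ g, var.equal = TRUE)
      expect_equal(unname(p[f]), tt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("ANOVA screening handles degenerate and boundary columns", {
  tab <- toy_feature_table(10, 10, k = 4, k_informative = 0)
  tab$f01 <- 1                                   # identical in both groups
  tab$f02 <- rep(c(0, 5), each = 10)             # zero within-group variance
  sel <- anova_filter(tab, alpha = 0.05)
  expect_false("f01" %in% sel)
  expect_true("f02" %in% sel)
  expect_equal(unname(attr(sel, "p_values")["f02"]), 0)
  expect_error(anova_filter(tab[tab$label == "typical", ]), "two label groups")
  # selection invariant to row order and feature scaling
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  tab2$f03 <- tab2$f03 * 1000 + 5
  expect_identical(as.character(anova_filter(tab2)), as.character(sel))
})

test_that("minority oversampling reproduces the 26 -> 78 exact-triplication case", {
  tab <- toy_feature_table(n_typ = 83, n_del = 26, k = 3)
  out <- oversample_minority(tab, target_count = 78, seed = 5)
  expect_equal(sum(out$label == "delayed"), 78)
  expect_equal(sum(out$label == "typical"), 83)
  counts <- table(out$clip_id[out$label == "delayed"])
  expect_true(all(counts == 3))                  # exact 3x replication
  # no-op when the target equals the current minority count
  expect_identical(oversample_minority(tab, 26, seed = 5), tab)
  # seeded determinism for non-multiple targets
  a <- oversample_minority(tab, 40, seed = 9)
  b <- oversample_minority(tab, 40, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$label == "delayed"), 40)
  expect_error(oversample_minority(tab, 10), "below current minority")
})

test_that("standardization centers and scales by the population convention", {
  tab <- data.frame(label = c("typical", "typical", "delayed"),
                    f1 = c(1, 2, 3), f2 = c(7, 7, 7))
  st <- standardize_features(tab)
  expect_equal(st$f1, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(st$f2, c(0, 0, 0))
  # idempotence on the transformed table
  st2 <- standardize_features(st)
  expect_equal(st2$f1, st$f1, tolerance = 1e-12)
  # applying frozen parameters to new data
  new <- data.frame(label = "typical", f1 = 4, f2 = 7)
  ap <- standardize_features(new, center = attr(st, "center"),
                             scale = attr(st, "scale"))
  expect_equal(ap$f1, (4 - 2) / sqrt(2 / 3), tolerance = 1e-9)
})

test_that("cross-validation is deterministic and metric identities hold", {
  tab <- toy_feature_table(n_typ = 20, n_del = 15, k = 8, k_informative = 3,
                           effect = 4)
  r1 <- crossval_evaluate(tab, "logistic_regression", n_folds = 5, seed = 42)
  r2 <- crossval_evaluate(tab, "logistic_regression", n_folds = 5, seed = 42)
  expect_equal(r1$weighted_avg, r2$weighted_avg, tolerance = 1e-12)
  expect_equal(nrow(r1$per_fold), 5)
  expect_true(all(unlist(r1$weighted_avg) >= 0 & unlist(r1$weighted_avg) <= 1))
  # per-class F1 identity in every fold
  for (pf in r1$per_fold_detail) {
    pc <- pf$per_class
    for (cl in rownames(pc)) {
      pr <- pc[cl, "precision"]; rc <- pc[cl, "recall"]
      f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
      expect_equal(unname(pc[cl, "f1"]), f1, tolerance = 1e-12)
    }
  }
  expect_error(crossval_evaluate(tab, "boosted_trees"), "unknown model_name")
  expect_error(crossval_evaluate(tab, "svm", n_folds = 20), "n_folds")
})

test_that("weighted and macro metrics coincide on balanced classes", {
  tab <- toy_feature_table(n_typ = 16, n_del = 16, k = 6, k_informative = 2,
                           effect = 2.5)
  r <- crossval_evaluate(tab, "random_forest", n_folds = 4, seed = 3)
  expect_equal(unname(r$weighted_avg["recall"]), unname(r$macro_avg["recall"]),
               tolerance = 1e-9)
  expect_equal(unname(r$weighted_avg["precision"]),
               unname(r$macro_avg["precision"]), tolerance = 1e-9)
})

test_that("a strongly separated table is classified nearly perfectly by all models", {
  tab <- toy_feature_table(n_typ = 25, n_del = 15, k = 10, k_informative = 4,
                           effect = 6, seed = 1)
  tab <- standardize_features(tab)
  for (mn in c("random_forest", "xgboost", "svm", "logistic_regression")) {
    r <- crossval_evaluate(tab, mn, n_folds = 5, seed = 7)
    expect_gte(r$weighted_avg["f1"], 0.95)
    expect_gte(r$weighted_avg["auc"], 0.95)
  }
})

test_that("permuted labels drive weighted accuracy to chance on average", {
  set.seed(55)
  accs <- replicate(10, {
    tab <- toy_feature_table(n_typ = 30, n_del = 30, k = 8, k_informative = 0,
                             seed = sample.int(1e6, 1))
    tab$label <- sample(tab$label)
    r <- crossval_evaluate(tab, "logistic_regression", n_folds = 5,
                           seed = sample.int(1e6, 1))
    unname(r$weighted_avg["accuracy"])
  })
  # the permutation-mean sits inside the single-run 95% binomial band
  # around 0.5 (finite-sample CV is slightly pessimistic under the null,
  # so the mean lands just below 0.5, never meaningfully above it)
  band <- 1.96 * sqrt(0.25 / 60)
  expect_gte(mean(accs), 0.5 - band)
  expect_lte(mean(accs), 0.5 + band)
})

test_that("run_pipeline produces the four-model comparison in both modes", {
  tab <- toy_feature_table(n_typ = 24, n_del = 10, k = 12, k_informative = 4,
                           effect = 5)
  for (safe in c(FALSE, TRUE)) {
    res <- run_pipeline(tab, n_folds = 5, seed = 4, leakage_safe = safe)
    expect_named(res$reports, c("random_forest", "xgboost", "svm",
                                "logistic_regression"))
    expect_equal(nrow(res$comparison), 4)
    expect_true(all(c("accuracy", "recall", "precision", "f1", "auc")
                    %in% names(res$comparison)))
    expect_gte(res$reports$random_forest$weighted_avg["f1"], 0.9)
    expect_true(all(res$selected_features %in% sprintf("f%02d", 1:12)))
  }
  # determinism end to end
  a <- run_pipeline(tab, n_folds = 5, seed = 4)
  b <- run_pipeline(tab, n_folds = 5, seed = 4)
  expect_equal(a$comparison, b$comparison, tolerance = 1e-12)
})
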