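test_that("metric identities hold exactly for every confusion outcome", {
  set.seed(91)
  for (i in 1:20) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (cnt[1] + cnt[4] == 0 || cnt[1] + cnt[2] == 0) next
    m <- classification_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m[["accuracy"]], (cnt[1] + cnt[3]) / sum(cnt))
    expect_equal(m[["recall"]], cnt[1] / (cnt[1] + cnt[4]))
    expect_equal(m[["precision"]], cnt[1] / (cnt[1] + cnt[2]))
    expect_equal(m[["f1"]],
                 2 * m[["precision"]] * m[["recall"]] /
                   (m[["precision"]] + m[["recall"]]))
  }
})

test_that("all backends separate well-separated cohorts under LOOCV", {
  tab <- make_feature_table(n_per_group = 29, d = 3, k = 5, p = 10, seed = 2)
  for (m in c("logistic", "rf", "xgb")) {
    rep <- loocv_classify(tab, m, "all", seed = 5)
    expect_gte(rep$metrics[["accuracy"]], 0.90)
    expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, nrow(tab))
  }
})

test_that("permuted labels give chance-level LOOCV accuracy", {
  set.seed(97)
  acc <- replicate(25, {
    tab <- make_feature_table(n_per_group = 15, d = 0, k = 0, p = 5,
                              seed = sample.int(1e6, 1))
    loocv_classify(tab, "logistic", "all", seed = 1)$metrics[["accuracy"]]
  })
  # LOOCV on null data is slightly anti-conservative (the held-out subject
  # opposes the training majority), so allow a one-sided dip below 0.5
  expect_lt(abs(mean(acc) - 0.5), 0.12)
})

test_that("per-fold significant-subset selection runs without test-fold leakage", {
  tab <- make_feature_table(n_per_group = 15, d = 3, k = 3, p = 8, seed = 4)
  rep <- loocv_classify(tab, "logistic", "significant", seed = 3)
  expect_gte(rep$metrics[["accuracy"]], 0.90)
  # every fold selected its features from its own training rows
  expect_length(rep$selected_per_fold, nrow(tab))
  expect_true(all(lengths(rep$selected_per_fold) >= 2))
})

test_that("out-of-fold selection cannot beat nested selection on null data", {
  # On pure-noise features, selecting "significant" indicators on the full
  # table before cross-validation overfits; nesting the selection inside the
  # folds must not yield higher apparent accuracy than the nested procedure.
  set.seed(111)
  nested <- numeric(10); unnested <- numeric(10)
  for (i in 1:10) {
    tab <- make_feature_table(n_per_group = 12, d = 0, k = 0, p = 12,
                              seed = 1000 + i)
    nested[i] <- loocv_classify(tab, "logistic", "significant",
                                alpha = 0.4, seed = 1)$metrics[["accuracy"]]
    # un-nested: select on the full table, then LOOCV on that fixed subset
    bg <- between_group(tab)
    keep <- bg$indicator[bg$p_value < 0.4]
    if (length(keep) < 2) keep <- bg$indicator[order(bg$p_value)][1:2]
    tab_sel <- tab[, c("subject_id", "group", "hand", keep)]
    unnested[i] <- loocv_classify(tab_sel, "logistic", "all",
                                  seed = 1)$metrics[["accuracy"]]
  }
  expect_gte(mean(unnested), mean(nested))
})

test_that("attribution ranks a dominant feature first and a noise feature last", {
  tab <- make_feature_table(n_per_group = 20, d = 4, k = 1, p = 6, seed = 6)
  ind <- intersect(indicator_names(), names(tab))
  fit <- fit_model(as.matrix(tab[, ind]), tab$group, "xgb", seed = 1)
  at <- attribute(fit, tab)
  expect_equal(at$summary$indicator[1], ind[1])
  expect_gte(at$summary$mean_abs[1] / sum(at$summary$mean_abs), 0.9)

  # appended pure-noise feature ranks last in most seeds (every other
  # feature carries signal)
  last_rank <- vapply(1:20, function(s) {
    tb <- make_feature_table(n_per_group = 50, d = 1.5, k = 8, p = 8,
                             seed = 200 + s)
    set.seed(s)
    tb$ZZZ_noise <- rnorm(nrow(tb))
    feats <- c(intersect(indicator_names(), names(tb)), "ZZZ_noise")
    f <- fit_model(as.matrix(tb[, feats]), tb$group, "xgb", seed = s)
    a <- attribute(f, tb)
    a$summary$rank[a$summary$indicator == "ZZZ_noise"]
  }, numeric(1))
  expect_gte(mean(last_rank == 9), 0.9)   # dead last in >= 90% of seeds
})

test_that("tree attributions plus base value reproduce the model margin", {
  tab <- make_feature_table(n_per_group = 20, d = 2, k = 3, p = 8, seed = 8)
  ind <- intersect(indicator_names(), names(tab))
  fit <- fit_model(as.matrix(tab[, ind]), tab$group, "xgb", seed = 2)
  at <- attribute(fit, tab)
  marg <- predict(fit$fit, xgboost::xgb.DMatrix(at$feature_values),
                  outputmargin = TRUE)
  expect_lt(max(abs(rowSums(at$values) + at$base_value - marg)), 1e-4)
  expect_setequal(at$summary$rank, seq_along(ind))
})

test_that("linear attribution follows coefficient times centered value", {
  tab <- make_feature_table(n_per_group = 25, d = 2, k = 2, p = 5, seed = 10)
  ind <- intersect(indicator_names(), names(tab))
  fit <- fit_model(as.matrix(tab[, ind]), tab$group, "logistic")
  at <- attribute(fit, tab)
  beta <- as.matrix(coef(fit$fit))[-1, 1]
  X <- as.matrix(tab[, ind])
  expect_equal(at$values[, 1], (X[, 1] - mean(X[, 1])) * beta[1],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(attribute(fit_model(X, tab$group, "rf"), tab), "backends")
})
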