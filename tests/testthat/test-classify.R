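test_that("fold assignment is participant-wise, stratified and stable", {
  fm <- toy_feature_matrix(n_per = 14, n_win = 3, seed = 1)
  folds <- assign_folds(fm, k = 10, seed = 17)
  expect_length(folds, 28)
  sizes <- as.integer(sort(table(folds)))
  expect_equal(sizes, c(2L, 2L, rep(3L, 8)))
  # every window of a participant shares its fold
  per_row <- folds[fm$participant_id]
  expect_true(all(tapply(per_row, fm$participant_id,
                         function(v) length(unique(v))) == 1))
  # both conditions in every training set
  cond_of <- setNames(fm$condition[!duplicated(fm$participant_id)],
                      fm$participant_id[!duplicated(fm$participant_id)])
  for (f in unique(folds)) {
    train <- names(folds)[folds != f]
    expect_setequal(unique(cond_of[train]), c("GamePlay", "GameWatch"))
  }
  expect_identical(folds, assign_folds(fm, k = 10, seed = 17))
  expect_false(identical(folds, assign_folds(fm, k = 10, seed = 18)))
  expect_error(assign_folds(fm, k = 1), "k must be")
  expect_error(assign_folds(fm[fm$participant_id %in%
                                 c("play01", "watch01"), ], k = 10),
               "more folds")
})

test_that("a perfectly separating feature is classified perfectly", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 25, seed = 2,
                           informative = "bpm")
  folds <- assign_folds(fm, k = 4, seed = 1)
  expect_equal(cross_validate(fm, "bpm", folds)$accuracy, 1)
  expect_equal(cross_validate(fm, feature_set("full"), folds)$accuracy, 1)
})

test_that("pooled accuracy equals correct windows over total windows", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 8, seed = 5)
  folds <- assign_folds(fm, k = 3, seed = 2)
  rep <- cross_validate(fm, feature_set("full"), folds)
  expect_equal(rep$n_windows, nrow(fm))
  sizes <- table(folds[fm$participant_id])
  expect_equal(rep$accuracy,
               sum(rep$per_fold * as.numeric(sizes)) / sum(sizes),
               tolerance = 1e-12)
})

test_that("accuracy is invariant to column order and affine rescaling", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 8, seed = 7,
                           informative = "HF time sam")
  set.seed(3)
  for (f in feature_names()[1:10]) fm[[f]] <- fm[[f]] + rnorm(nrow(fm))
  folds <- assign_folds(fm, k = 4, seed = 9)
  a1 <- cross_validate(fm, feature_set("full"), folds)$accuracy
  a2 <- cross_validate(fm, rev(feature_set("full")), folds)$accuracy
  expect_equal(a1, a2)
  fm2 <- fm
  fm2$bpm <- 1000 * fm2$bpm - 55
  a3 <- cross_validate(fm2, feature_set("full"), folds)$accuracy
  expect_equal(a1, a3)
})

test_that("held-out windows never shape their own fold's preprocessing", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 8, seed = 13,
                           informative = "bpm")
  folds <- assign_folds(fm, k = 4, seed = 4)
  base <- cross_validate(fm, feature_set("full"), folds,
                         return_predictions = TRUE)
  # corrupt every window of one held-out participant except its first:
  # if imputation/standardisation used test-fold data, the surviving
  # window's probability would shift; fold-local preprocessing leaves it
  # bit-identical
  victim <- names(folds)[1]
  rows <- which(fm$participant_id == victim)
  keep_row <- rows[1]
  fm2 <- fm
  for (f in feature_names()) {
    fm2[[f]][setdiff(rows, keep_row)] <- 1e6
  }
  pert <- cross_validate(fm2, feature_set("full"), folds,
                         return_predictions = TRUE)
  expect_identical(base$predictions$prob[keep_row],
                   pert$predictions$prob[keep_row])
})

test_that("degenerate training folds are refused", {
  fm <- toy_feature_matrix(n_per = 2, n_win = 4, seed = 1)
  # both play participants in fold 0: training for fold 0 is watch-only
  folds2 <- setNames(c(0L, 0L, 1L, 1L), c("play01", "play02",
                                          "watch01", "watch02"))
  expect_error(cross_validate(fm, "bpm", folds2), "degenerate fold")
})

test_that("ablation suite uses the printed feature-set sizes on shared folds", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 6, seed = 21)
  folds <- assign_folds(fm, k = 4, seed = 6)
  reps <- ablation_suite(fm, folds)
  expect_equal(vapply(reps, function(r) r$n_features, numeric(1)),
               c(full = 80, wo_emg = 63, wo_emg_eda = 51))
  expect_equal(vapply(reps, function(r) r$n_windows, numeric(1)),
               rep(nrow(fm), 3), ignore_attr = TRUE)
})

test_that("ablation removes the signal only when its modality is dropped", {
  # condition signal injected only into EDA features
  fm <- toy_feature_matrix(n_per = 8, n_win = 6, seed = 23)
  set.seed(24)
  eda_cols <- names(feature_modalities())[feature_modalities() == "EDA"]
  for (f in eda_cols) {
    fm[[f]] <- ifelse(fm$condition == "GamePlay", 0.8, -0.8) +
      rnorm(nrow(fm))
  }
  folds <- assign_folds(fm, k = 4, seed = 8)
  reps <- ablation_suite(fm, folds)
  expect_gt(reps$wo_emg$accuracy, reps$wo_emg_eda$accuracy)
})

test_that("single-feature screen ranks an oracle feature first", {
  fm <- toy_feature_matrix(n_per = 6, n_win = 6, seed = 31,
                           informative = "pwr TP")
  set.seed(32)
  fm$`pwr TP` <- fm$`pwr TP` + 0.2 * rnorm(nrow(fm))
  fm$`val mean` <- 3  # constant
  folds <- assign_folds(fm, k = 4, seed = 3)
  scr <- single_feature_screen(fm, folds)
  expect_equal(scr$feature[1], "pwr TP")
  expect_equal(scr$accuracy[1], 1)
  expect_lt(scr$p_fdr[scr$feature == "pwr TP"], 1e-6)
  # a feature identical to the label still classifies perfectly and its
  # likelihood-ratio p collapses to zero
  fm$bpm <- ifelse(fm$condition == "GamePlay", 1, 0)
  scr2 <- single_feature_screen(fm, folds)
  expect_equal(scr2$accuracy[scr2$feature == "bpm"], 1)
  expect_lt(scr2$p[scr2$feature == "bpm"], 1e-12)
  expect_equal(scr$flag[scr$feature == "val mean"], "constant")
  expect_true(all(diff(scr$accuracy[!is.na(scr$accuracy)]) <= 1e-12))
  top <- single_feature_screen(fm, folds, top_n = 5)
  expect_equal(nrow(top), 5)
})

test_that("label-shuffled nulls classify at chance", {
  fm <- toy_feature_matrix(n_per = 8, n_win = 10, seed = 41)
  folds <- assign_folds(fm, k = 4, seed = 5)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    fm2 <- fm
    fm2$condition <- sample(fm2$condition)
    cross_validate(fm2, feature_set("full"), folds)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})
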