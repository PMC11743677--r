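# small synthetic feature matrices for the CV machinery tests
make_fm <- function(n_subj_s = 12, n_subj_p = 11, epochs = 4, n_feat = 30,
                    shift = 0, seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("S%02d", seq_len(n_subj_s)), sprintf("P%02d", seq_len(n_subj_p)))
  lab <- c(rep("SMCI", n_subj_s), rep("PMCI", n_subj_p))
  rows <- do.call(rbind, lapply(seq_along(subj), function(i) {
    m <- matrix(rnorm(epochs * n_feat), epochs, n_feat)
    if (lab[i] == "PMCI") m[, 1:5] <- m[, 1:5] + shift
    m
  }))
  colnames(rows) <- sprintf("f%03d", seq_len(n_feat))
  feature_matrix(rows, rep(subj, each = epochs), rep(lab, each = epochs),
                 rep(seq_len(epochs), length(subj)))
}

test_that("subject-level folds are stratified, disjoint, and deterministic", {
  fm <- make_fm(65, 42, epochs = 2)
  plan <- subject_kfold(fm, k = 10, seed = 3)
  sizes_s <- vapply(plan, function(f) sum(startsWith(f, "S")), 0L)
  sizes_p <- vapply(plan, function(f) sum(startsWith(f, "P")), 0L)
  expect_true(all(sizes_s %in% 6:7))
  expect_true(all(sizes_p %in% 4:5))
  expect_identical(sum(sizes_s), 65L)
  expect_identical(sum(sizes_p), 42L)
  expect_false(anyDuplicated(unlist(plan)) > 0)
  expect_identical(plan, subject_kfold(fm, k = 10, seed = 3))
  expect_true(audit_leakage(fm, plan))
  expect_error(subject_kfold(make_fm(12, 5), k = 10), "fewer than k")
})

test_that("vectorized selection p-values agree with t.test and wilcox.test", {
  fm <- make_fm(10, 10, epochs = 3, n_feat = 12, seed = 5)
  mask <- select_features(fm, alpha = 0.05)
  p_t <- attr(mask, "p_t"); p_w <- attr(mask, "p_w")
  g1 <- fm$labels == "SMCI"; g2 <- fm$labels == "PMCI"
  for (j in seq_len(12)) {
    ref_t <- t.test(fm$values[g1, j], fm$values[g2, j])$p.value
    ref_w <- wilcox.test(fm$values[g1, j], fm$values[g2, j],
                         exact = FALSE, correct = TRUE)$p.value
    expect_equal(unname(p_t[j]), ref_t, tolerance = 1e-10)
    expect_equal(unname(p_w[j]), ref_w, tolerance = 1e-10)
  }
})

test_that("selection keeps strongly shifted features, drops constants, errors on one class", {
  fm <- make_fm(20, 20, epochs = 10, n_feat = 30, shift = 2, seed = 6)
  fm$values <- cbind(fm$values, const = rep(1, nrow(fm$values)))
  mask <- select_features(fm)
  expect_true(all(mask[1:5]))
  expect_false(mask["const"])
  # 2-SD shift with 400 rows per class: retained in essentially every draw
  hits <- vapply(1:50, function(i) {
    f <- make_fm(20, 20, epochs = 10, n_feat = 6, shift = 2, seed = 100 + i)
    all(select_features(f)[1:5])
  }, logical(1))
  expect_gt(mean(hits), 0.99)
  one_class <- fm$labels == "SMCI"
  expect_error(select_features(eegmci:::.subset_fm(fm, one_class)), "both classes")
})

test_that("null-feature retention stays within the either-test union-bound band", {
  # iid Gaussian features, no group effect: per-feature retention probability
  # lies between alpha (perfect test correlation) and 2*alpha - alpha^2
  # (independent tests); Monte-Carlo over many features
  set.seed(7)
  n_feat <- 800
  x <- matrix(rnorm(200 * n_feat), 200, n_feat)
  colnames(x) <- sprintf("f%04d", seq_len(n_feat))
  fm <- feature_matrix(x, sprintf("s%03d", rep(1:100, each = 2)),
                       rep(c("SMCI", "PMCI"), each = 100))
  rate <- mean(select_features(fm, alpha = 0.05))
  expect_gte(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / n_feat))
  expect_lte(rate, 0.0975 + 2.5 * sqrt(0.0975 * 0.9025 / n_feat))
})

test_that("the fitted transform reaches 95% variance with the minimal rank", {
  set.seed(8)
  # rank-2 data: 10 columns spanned by 2 independent factors
  z <- matrix(rnorm(400), 200, 2)
  x <- z %*% matrix(rnorm(20), 2, 10)
  colnames(x) <- sprintf("f%02d", 1:10)
  fm <- feature_matrix(x, sprintf("s%03d", 1:200),
                       rep(c("SMCI", "PMCI"), each = 100))
  model <- fit_transform(fm, rep(TRUE, 10))
  expect_identical(model$k95, 2L)
  # isotropic data: every component explains ~10%, so k95 = 10
  xi <- matrix(rnorm(5000 * 10), 5000, 10)
  colnames(xi) <- sprintf("g%02d", 1:10)
  fmi <- feature_matrix(xi, sprintf("s%04d", 1:5000),
                        rep(c("SMCI", "PMCI"), each = 2500))
  expect_identical(fit_transform(fmi, rep(TRUE, 10))$k95, 10L)
  # training scores are centered
  tr <- apply_transform(model, fm)
  expect_lt(max(abs(colMeans(tr))), 1e-8)
  expect_error(fit_transform(fm, rep(FALSE, 20)), "relax alpha")
})

test_that("the transform is a function of the training rows only", {
  fm <- make_fm(15, 15, epochs = 3, shift = 1, seed = 9)
  plan <- subject_kfold(fm, k = 5, seed = 9)
  is_test <- fm$subject_ids %in% plan[[1]]
  train <- eegmci:::.subset_fm(fm, !is_test)
  mask <- select_features(train)
  model <- fit_transform(train, mask)
  # scrambling the held-out rows must not change the fitted parameters
  fm2 <- fm
  fm2$values[is_test, ] <- fm2$values[is_test, sample(ncol(fm2$values))]
  train2 <- eegmci:::.subset_fm(fm2, !is_test)
  mask2 <- select_features(train2)
  model2 <- fit_transform(train2, mask2)
  expect_identical(mask, mask2)
  expect_identical(model$rotation, model2$rotation)
  expect_identical(model$mean, model2$mean)
})

test_that("all eight classifiers solve linearly separable blobs and reject bad names", {
  set.seed(10)
  n <- 60
  tr_x <- rbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2) + 6, n, 2))
  tr_y <- factor(rep(c("SMCI", "PMCI"), each = n), levels = c("SMCI", "PMCI"))
  te_x <- rbind(matrix(rnorm(20 * 2), 20, 2), matrix(rnorm(20 * 2) + 6, 20, 2))
  te_y <- rep(c("SMCI", "PMCI"), each = 20)
  for (cl in classifier_names) {
    pred <- train_and_predict(cl, tr_x, tr_y, te_x, seed = 11)
    expect_identical(as.character(pred$labels), te_y)
    expect_equal(auc_rank(pred$scores, te_y), 1)
  }
  expect_error(train_and_predict("MLP", tr_x, tr_y, te_x), "valid names")
  # 1-nearest-neighbour reproduces its own training labels
  knn_self <- train_and_predict("KNN", tr_x, tr_y, tr_x)
  expect_identical(as.character(knn_self$labels), as.character(tr_y))
})

test_that("confusion metrics evaluate their defining formulas exactly", {
  pred <- c(rep("PMCI", 40), rep("SMCI", 2), rep("PMCI", 5), rep("SMCI", 60))
  truth <- c(rep("PMCI", 42), rep("SMCI", 65))
  m <- confusion_metrics(pred, truth)
  expect_identical(c(m$TP, m$FN, m$FP, m$TN), c(40L, 2L, 5L, 60L))
  expect_equal(m$ACC, 100 / 107)
  expect_equal(m$SEN, 40 / 42)
  expect_equal(m$SPE, 60 / 65)
  expect_equal(m$PPV, 40 / 45)
  expect_equal(m$F1, 80 / 87)
  # identities
  expect_equal(m$ACC * (m$M + m$N), m$TP + m$TN)
  expect_equal(m$F1, 2 / (1 / m$PPV + 1 / m$SEN))
  perfect <- confusion_metrics(truth, truth)
  expect_true(all(unlist(perfect[c("ACC", "SEN", "SPE", "PPV", "F1")]) == 1))
  allneg <- confusion_metrics(rep("SMCI", 107), truth)
  expect_equal(allneg$SEN, 0)
  expect_true(is.na(allneg$PPV))
  expect_error(confusion_metrics(pred[1:5], truth), "length")
})

test_that("rank AUC equals the concordance oracle, including ties", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.6),
                        c("PMCI", "PMCI", "SMCI", "SMCI")), 1)
  expect_equal(auc_rank(c(0.9, 0.6, 0.8, 0.7),
                        c("PMCI", "PMCI", "SMCI", "SMCI")), 0.5)
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    scores <- round(runif(n1 + n2), 1)          # coarse grid forces ties
    truth <- c(rep("PMCI", n1), rep("SMCI", n2))
    expect_equal(auc_rank(scores, truth), auc_brute(scores, truth),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(1:4, rep("PMCI", 4))))
})

test_that("cross-validation recovers a strong effect and permuted labels destroy it", {
  fm <- make_fm(15, 15, epochs = 4, shift = 2.5, seed = 13)
  plan <- subject_kfold(fm, k = 5, seed = 13)
  rep_lda <- run_cv(fm, plan, classifier = "LDA", seed = 13)
  expect_gt(rep_lda$summary$mean[rep_lda$summary$metric == "AUC"], 0.9)
  expect_identical(nrow(rep_lda$folds), 5L)
  # permuted labels: accuracy near the majority-class rate
  set.seed(14)
  subj <- unique(fm$subject_ids)
  perm <- setNames(sample(fm$labels[!duplicated(fm$subject_ids)]), subj)
  fm_perm <- feature_matrix(fm$values, fm$subject_ids,
                            as.character(perm[fm$subject_ids]), fm$epoch_index)
  plan_p <- subject_kfold(fm_perm, k = 5, seed = 14)
  rep_p <- run_cv(fm_perm, plan_p, classifier = "LDA", alpha = 0.2, seed = 14)
  acc <- rep_p$summary$mean[rep_p$summary$metric == "ACC"]
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("cohort statistics reproduce demographic t and chi-square values", {
  demo <- amci_demographics()
  stats <- cohort_statistics(demo$continuous, demo$categorical,
                             demo$n_smci, demo$n_pmci)
  get <- function(v) stats$statistic[stats$variable == v]
  expect_lt(abs(get("age") - 0.40), 0.01)
  expect_lt(abs(get("gender") - 2.49), 0.01)
  expect_lt(abs(get("amci_type") - 0.01), 0.01)
  expect_lt(abs(get("diabetes") - 0.63), 0.01)
  expect_lt(abs(get("hypertension") - 0.73), 0.01)
  expect_lt(abs(get("education") - 0.03), 0.01)
  # identical groups give null statistics
  expect_equal(t_from_summary(5, 1, 30, 5, 1, 30)$t, 0)
  expect_equal(chisq_from_counts(rbind(c(10, 20), c(10, 20)))$chisq, 0)
  expect_error(t_from_summary(5, 1, 1, 5, 1, 30), "n >= 2")
})

test_that("group-difference maps order features by evidence and honour top_n", {
  fm <- make_fm(15, 15, epochs = 4, shift = 2, seed = 15)
  gdm <- group_difference_map(fm)
  expect_identical(nrow(gdm), ncol(fm$values))
  expect_false(is.unsorted(gdm$p))
  expect_true(all(sprintf("f%03d", 1:5) %in% gdm$feature[1:8]))
  top <- group_difference_map(fm, top_n = 15)
  expect_identical(nrow(top), 15L)
})
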