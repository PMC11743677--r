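#' Subject-level stratified k-fold plan
#'
#' Partitions the subject IDs (not rows) into k folds, stratified by group,
#' so no subject's epochs can span training and test sets. Deterministic
#' given `seed`.
#'
#' @param fm a `feature_matrix`
#' @param k number of folds (default 10)
#' @param seed integer seed
#' @return a `fold_plan`: list of k character vectors of held-out subject IDs
#' @export
subject_kfold <- function(fm, k = 10L, seed = 1L) {
  subj <- fm$subject_ids[!duplicated(fm$subject_ids)]
  lab <- fm$labels[!duplicated(fm$subject_ids)]
  folds <- vector("list", k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (g in levels(lab)) {
    ids <- subj[lab == g]
    if (length(ids) < k)
      stop("class ", g, " has fewer than k = ", k, " subjects")
    ids <- sample(ids)
    asg <- rep(seq_len(k), length.out = length(ids))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ids[asg == f])
  }
  structure(folds, class = "fold_plan")
}

# vectorized Welch two-sample t-test p-values over feature columns
.t_pvalues <- function(x, g1, g2) {
  m1 <- colMeans(x[g1, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(x[g2, , drop = FALSE], na.rm = TRUE)
  v1 <- apply(x[g1, , drop = FALSE], 2L, var, na.rm = TRUE)
  v2 <- apply(x[g2, , drop = FALSE], 2L, var, na.rm = TRUE)
  n1 <- colSums(!is.na(x[g1, , drop = FALSE]))
  n2 <- colSums(!is.na(x[g2, , drop = FALSE]))
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  ifelse(is.finite(p), p, 1)
}

# vectorized Wilcoxon rank-sum p-values (normal approximation with tie
# correction and continuity correction, as stats::wilcox.test uses for
# large samples)
.wilcox_pvalues <- function(x, g1, g2) {
  apply(x, 2L, function(col) {
    a <- col[g1]; b <- col[g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2L || n2 < 2L) return(1)
    r <- rank(c(a, b))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2      # Mann-Whitney U
    mu <- n1 * n2 / 2
    nt <- table(r)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
}

#' Univariate feature selection on training rows
#'
#' Computes a Welch two-sample t-test and a Wilcoxon rank-sum test per
#' feature on the training rows. Under the default `"either"` rule a feature
#' is retained iff `min(p_t, p_w) < alpha`; `"both"` requires both p-values
#' below `alpha`. Constant and all-missing features are always dropped.
#'
#' @param fm a `feature_matrix` (training rows only)
#' @param alpha significance level (default 0.05)
#' @param rule `"either"` or `"both"`
#' @return logical mask over feature columns, with attributes `p_t`, `p_w`
#' @export
select_features <- function(fm, alpha = 0.05, rule = c("either", "both")) {
  rule <- match.arg(rule)
  g1 <- fm$labels == "SMCI"; g2 <- fm$labels == "PMCI"
  if (!any(g1) || !any(g2)) stop("training rows must contain both classes")
  x <- fm$values
  p_t <- .t_pvalues(x, g1, g2)
  p_w <- .wilcox_pvalues(x, g1, g2)
  sds <- apply(x, 2L, sd, na.rm = TRUE)
  nonconst <- is.finite(sds) & sds > 0
  mask <- if (rule == "either") pmin(p_t, p_w) < alpha else pmax(p_t, p_w) < alpha
  mask <- mask & nonconst
  mask[is.na(mask)] <- FALSE
  attr(mask, "p_t") <- p_t
  attr(mask, "p_w") <- p_w
  mask
}

#' Fit the train-fold transform (imputation, standardization, PCA)
#'
#' All parameters are estimated from the training rows only: per-feature
#' training medians (for imputing missing values), training mean/SD
#' (z-scoring), and a PCA basis truncated at the smallest number of
#' components whose cumulative explained variance reaches `var_target`.
#' Component sign convention: the largest-magnitude loading is positive.
#'
#' @param fm training `feature_matrix`
#' @param mask logical feature mask from [select_features]
#' @param var_target cumulative explained-variance target (default 0.95)
#' @return a `transform_model`
#' @export
fit_transform <- function(fm, mask, var_target = 0.95) {
  if (!any(mask)) stop("empty feature mask: relax alpha or the selection rule")
  x <- fm$values[, mask, drop = FALSE]
  med <- apply(x, 2L, median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  sv <- svd(z)
  ev <- sv$d^2 / sum(sv$d^2)
  k95 <- which(cumsum(ev) >= var_target - 1e-12)[1L]
  rot <- sv$v[, seq_len(k95), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, `*`)
  structure(list(mask = mask, medians = med, mean = mu, sd = sdv,
                 rotation = rot, k95 = k95, explained = ev,
                 cum_explained = cumsum(ev)[k95]),
            class = "transform_model")
}

#' Apply a fitted transform to new rows
#'
#' Uses only the stored training parameters (no refitting).
#'
#' @param model a `transform_model`
#' @param fm a `feature_matrix`
#' @return rows x k95 numeric matrix of principal-component scores
#' @export
apply_transform <- function(model, fm) {
  x <- fm$values[, model$mask, drop = FALSE]
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- model$medians[j]
  z <- sweep(sweep(x, 2L, model$mean), 2L, model$sd, `/`)
  z %*% model$rotation
}

.subset_fm <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$subject_ids[rows],
                 fm$labels[rows], fm$epoch_index[rows])
}

#' Leakage-safe subject-level cross-validation
#'
#' For each fold: feature selection, imputation, standardization and PCA are
#' fitted on the training subjects only, then applied to the held-out
#' subjects; the classifier is trained and evaluated; metrics are reported
#' per fold and as mean +/- SD across folds.
#'
#' @param fm a `feature_matrix`
#' @param plan a `fold_plan` from [subject_kfold]
#' @param classifier one or more of [classifier_names]; the per-fold
#'   transforms are fitted once and shared across classifiers
#' @param alpha selection level (default 0.05)
#' @param rule selection rule (see [select_features])
#' @param var_target PCA cumulative-variance target
#' @param seed seed forwarded to stochastic classifiers
#' @return a `cv_report` (single classifier): list with `folds` (per-fold
#'   metrics data.frame), `summary` (mean and SD per metric), and a `log` of
#'   per-fold selection counts and PCA dimensions; for several classifiers,
#'   a named list of `cv_report`s
#' @export
run_cv <- function(fm, plan, classifier = "KNN", alpha = 0.05,
                   rule = "either", var_target = 0.95, seed = 1L) {
  metrics <- c("ACC", "AUC", "SEN", "SPE", "PPV", "F1")
  fold_rows <- lapply(classifier, function(cl) list())
  names(fold_rows) <- classifier
  log <- list()
  for (f in seq_along(plan)) {
    test_subj <- plan[[f]]
    is_test <- fm$subject_ids %in% test_subj
    train <- .subset_fm(fm, !is_test)
    test <- .subset_fm(fm, is_test)
    mask <- select_features(train, alpha = alpha, rule = rule)
    model <- fit_transform(train, mask, var_target = var_target)
    tr_x <- apply_transform(model, train)
    te_x <- apply_transform(model, test)
    two_class <- nlevels(droplevels(test$labels)) == 2L
    if (!two_class)
      warning("fold ", f, " test set contains a single class; AUC missing")
    for (cl in classifier) {
      pred <- train_and_predict(cl, tr_x, train$labels, te_x, seed = seed + f)
      cm <- confusion_metrics(pred$labels, test$labels)
      auc <- if (two_class) auc_rank(pred$scores, test$labels) else NA_real_
      fold_rows[[cl]][[f]] <- data.frame(
        fold = f, ACC = cm$ACC, AUC = auc, SEN = cm$SEN,
        SPE = cm$SPE, PPV = cm$PPV, F1 = cm$F1,
        TP = cm$TP, FN = cm$FN, FP = cm$FP, TN = cm$TN)
    }
    log[[f]] <- list(fold = f, n_selected = sum(mask), k95 = model$k95,
                     cum_explained = model$cum_explained,
                     test_subjects = test_subj)
  }
  reports <- lapply(classifier, function(cl) {
    folds <- do.call(rbind, fold_rows[[cl]])
    summ <- data.frame(metric = metrics,
                       mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE), 0),
                       sd = vapply(metrics, function(m) sd(folds[[m]], na.rm = TRUE), 0))
    structure(list(classifier = cl, folds = folds, summary = summ,
                   log = log, seed = seed),
              class = "cv_report")
  })
  names(reports) <- classifier
  if (length(reports) == 1L) reports[[1L]] else reports
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds\n", x$classifier, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %6.2f +/- %5.2f %%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  invisible(x)
}

#' Subject-based classification of whole segments
#'
#' Extracts one feature vector per subject from the whole (e.g. 20-s)
#' preprocessed signal and runs the same subject-level CV machinery.
#'
#' @param cohort list of `eeg_recording`s
#' @param config a `preprocess_config`
#' @param classifier,k,alpha,rule,var_target,seed as in [run_cv]
#' @param families feature families to extract
#' @return a `cv_report`
#' @export
subject_mode_run <- function(cohort, config = preprocess_config(),
                             classifier = "KNN", k = 10L, alpha = 0.05,
                             rule = "either", var_target = 0.95, seed = 1L,
                             families = c("spectral", "nonlinear", "connectivity")) {
  if (length(cohort) < 2L) stop("cross-validation undefined for a single subject")
  tabs <- extract_features(cohort, config, mode = "subject", families = families)
  fm <- assemble_features(tabs)
  plan <- subject_kfold(fm, k = k, seed = seed)
  run_cv(fm, plan, classifier = classifier, alpha = alpha, rule = rule,
         var_target = var_target, seed = seed)
}

#' Group-difference map (Wilcoxon rank-sum per feature)
#'
#' Per-feature two-sample Wilcoxon rank-sum p-values between SMCI and PMCI
#' rows, for one feature family/prefix, organised by the channel (or channel
#' pair) parsed from the feature name.
#'
#' @param fm a `feature_matrix`
#' @param prefix feature-name prefix, e.g. `"ratio1"`, `"se_s2"`,
#'   `"pli_full"`; `NULL` for all features
#' @param top_n optionally return only the `top_n` smallest p-values
#' @return data.frame with `feature`, `channel`, `p`, sorted ascending by `p`
#' @export
group_difference_map <- function(fm, prefix = NULL, top_n = NULL) {
  g1 <- fm$labels == "SMCI"; g2 <- fm$labels == "PMCI"
  if (!any(g1) || !any(g2)) stop("both groups must be present")
  cols <- colnames(fm$values)
  if (!is.null(prefix)) cols <- cols[startsWith(cols, paste0(prefix, "__"))]
  if (!length(cols)) stop("no features match prefix '", prefix, "'")
  p <- .wilcox_pvalues(fm$values[, cols, drop = FALSE], g1, g2)
  out <- data.frame(feature = cols,
                    channel = sub("^.*__", "", cols),
                    p = as.numeric(p), row.names = NULL)
  out <- out[order(out$p), ]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Leakage audit of a fold plan
#'
#' Checks that the fold test sets partition the subjects and that no subject
#' appears in both the training and test rows of any fold.
#'
#' @param fm a `feature_matrix`
#' @param plan a `fold_plan`
#' @return `TRUE` (invisibly); stops with a message on violation
#' @export
audit_leakage <- function(fm, plan) {
  all_subj <- unique(fm$subject_ids)
  test_all <- unlist(plan)
  if (anyDuplicated(test_all)) stop("leakage audit failed: subject in two folds")
  if (!setequal(test_all, all_subj)) stop("leakage audit failed: folds do not partition subjects")
  for (f in seq_along(plan)) {
    tr <- unique(fm$subject_ids[!(fm$subject_ids %in% plan[[f]])])
    if (length(intersect(tr, plan[[f]])))
      stop("leakage audit failed: subject spans train and test in fold ", f)
  }
  invisible(TRUE)
}
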