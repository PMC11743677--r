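#' Names of the eight supported classifiers
#' @export
classifier_names <- c("SVM", "DT", "NB", "LDA", "ADA", "KNN", "RF", "LogReg")

#' Train a classifier and predict on a test set
#'
#' Fits one of the eight classifiers on the (reduced) training matrix with
#' library defaults and returns per-row continuous scores (higher = more
#' PMCI-like) and hard labels for the test rows.
#'
#' @param classifier one of [classifier_names]
#' @param train_x,train_y training rows (matrix) and labels (factor)
#' @param test_x test rows
#' @param seed integer seed for the stochastic learners (RF)
#' @return list with `scores` (numeric) and `labels` (factor SMCI/PMCI)
#' @export
train_and_predict <- function(classifier, train_x, train_y, test_x, seed = 1L) {
  if (!classifier %in% classifier_names)
    stop("unknown classifier '", classifier, "'; valid names: ",
         paste(classifier_names, collapse = ", "))
  train_y <- factor(as.character(train_y), levels = c("SMCI", "PMCI"))
  if (nlevels(droplevels(train_y)) < 2L) stop("training rows contain a single class")
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  colnames(train_x) <- colnames(test_x) <- paste0("pc", seq_len(ncol(train_x)))
  dtr <- data.frame(train_x, y = train_y)
  dte <- data.frame(test_x)

  scores <- switch(
    classifier,
    SVM = {
      fit <- e1071::svm(y ~ ., data = dtr, kernel = "radial")
      pr <- predict(fit, dte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient so that higher = PMCI (svm orders by training label occurrence)
      sc <- if (grepl("^PMCI/", colnames(dv)[1L])) as.numeric(dv) else -as.numeric(dv)
      attr(sc, "hard_labels") <- factor(as.character(pr), levels = c("SMCI", "PMCI"))
      sc
    },
    DT = {
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class")
      predict(fit, dte, type = "prob")[, "PMCI"]
    },
    NB = {
      fit <- e1071::naiveBayes(y ~ ., data = dtr)
      predict(fit, dte, type = "raw")[, "PMCI"]
    },
    LDA = {
      fit <- MASS::lda(y ~ ., data = dtr)
      predict(fit, dte)$posterior[, "PMCI"]
    },
    ADA = .adaboost_score(train_x, train_y, test_x),
    KNN = {
      pr <- class::knn(train_x, test_x, train_y, k = 1L, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "PMCI", p, 1 - p)
    },
    RF = {
      set.seed(seed)
      fit <- randomForest::randomForest(train_x, train_y)
      predict(fit, test_x, type = "prob")[, "PMCI"]
    },
    LogReg = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dtr, family = stats::binomial()))
      suppressWarnings(as.numeric(predict(fit, dte, type = "response")))
    })
  labels <- attr(scores, "hard_labels")
  if (is.null(labels)) {
    labels <- factor(ifelse(scores > 0.5, "PMCI", "SMCI"),
                     levels = c("SMCI", "PMCI"))
  }
  list(scores = as.numeric(scores), labels = labels)
}

# AdaBoost.M1 over depth-1 rpart stumps; returns the real-valued ensemble
# margin rescaled to (0, 1) via the logistic link so 0.5 is the decision
# boundary like the probability-scoring classifiers.
.adaboost_score <- function(train_x, train_y, test_x, n_rounds = 50L) {
  n <- nrow(train_x)
  w <- rep(1 / n, n)
  y_num <- ifelse(train_y == "PMCI", 1, -1)
  dtr <- data.frame(train_x)
  dte <- data.frame(test_x)
  agg <- numeric(nrow(test_x))
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(train_y ~ ., data = cbind(dtr, train_y = train_y),
                        weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                       minsplit = 2L, xval = 0L))
    pred_tr <- ifelse(predict(fit, dtr, type = "class") == "PMCI", 1, -1)
    err <- sum(w * (pred_tr != y_num))
    if (err <= 0) {            # perfect stump: dominate and stop
      agg <- agg + 10 * ifelse(predict(fit, dte, type = "class") == "PMCI", 1, -1)
      break
    }
    if (err >= 0.5) break      # no better than chance: stop boosting
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y_num * pred_tr)
    w <- w / sum(w)
    agg <- agg + alpha * ifelse(predict(fit, dte, type = "class") == "PMCI", 1, -1)
  }
  1 / (1 + exp(-2 * agg))
}
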