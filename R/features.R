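#' Assemble a feature matrix from per-family feature tables
#'
#' Column-wise join of feature tables keyed by `(subject_id, epoch_index)`.
#' Each table is a data.frame with columns `subject_id`, `epoch_index`,
#' `group`, then features. Rows with more than `max_missing` missing feature
#' values are dropped (and reported); remaining missing values stay `NA` and
#' are median-imputed from training folds at transform time.
#'
#' @param ... two or more feature tables (or a single list of them)
#' @param max_missing maximum tolerated fraction of missing features per row
#' @return a `feature_matrix`: list with `values` (rows x features matrix),
#'   `subject_ids`, `epoch_index`, `labels` (factor SMCI/PMCI, PMCI positive)
#' @export
assemble_features <- function(..., max_missing = 0.2) {
  tabs <- list(...)
  if (length(tabs) == 1L && !is.data.frame(tabs[[1L]])) tabs <- tabs[[1L]]
  stopifnot(length(tabs) >= 1L)
  key <- function(t) paste(t$subject_id, t$epoch_index, sep = "@")
  k0 <- key(tabs[[1L]])
  if (anyDuplicated(k0)) stop("duplicate (subject_id, epoch_index) keys")
  for (t in tabs[-1L]) {
    kt <- key(t)
    bad <- c(setdiff(k0, kt), setdiff(kt, k0))
    if (length(bad))
      stop("feature tables disagree on keys: ", paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
  }
  meta <- tabs[[1L]][c("subject_id", "epoch_index", "group")]
  blocks <- lapply(tabs, function(t) {
    t <- t[match(k0, key(t)), , drop = FALSE]
    as.matrix(t[setdiff(names(t), c("subject_id", "epoch_index", "group"))])
  })
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values))) stop("duplicate feature names across tables")
  frac_na <- rowMeans(is.na(values))
  keep <- frac_na <= max_missing
  if (any(!keep))
    message(sum(!keep), " row(s) dropped for > ", max_missing * 100, "% missing features")
  feature_matrix(values[keep, , drop = FALSE], meta$subject_id[keep],
                 meta$group[keep], meta$epoch_index[keep])
}

#' Feature matrix container
#'
#' @param values rows x named-features numeric matrix
#' @param subject_ids character per row
#' @param labels per-row group label (`"SMCI"`/`"PMCI"`); PMCI is the
#'   positive class
#' @param epoch_index integer per row
#' @return a `feature_matrix`
#' @export
feature_matrix <- function(values, subject_ids, labels, epoch_index = NULL) {
  values <- as.matrix(values)
  stopifnot(length(subject_ids) == nrow(values), length(labels) == nrow(values))
  labels <- factor(as.character(labels), levels = c("SMCI", "PMCI"))
  for (s in unique(subject_ids)) {
    if (length(unique(labels[subject_ids == s])) > 1L)
      stop("subject ", s, " appears with more than one label")
  }
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 labels = labels,
                 epoch_index = if (is.null(epoch_index)) rep(1L, nrow(values)) else epoch_index),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features; %d subjects (%d SMCI, %d PMCI)\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject_ids)),
              sum(x$labels[!duplicated(x$subject_ids)] == "SMCI"),
              sum(x$labels[!duplicated(x$subject_ids)] == "PMCI")))
  invisible(x)
}

#' Extract feature tables from a cohort of recordings
#'
#' Runs the preprocessing chain on every recording and extracts the selected
#' feature families per epoch (`mode = "epoch"`) or once per subject from the
#' whole segment (`mode = "subject"`, Welch windows of 2 s).
#'
#' @param cohort list of `eeg_recording`s
#' @param config a `preprocess_config`
#' @param mode `"epoch"` (2-s epochs) or `"subject"` (whole segment)
#' @param families subset of `c("spectral", "nonlinear", "connectivity")`
#' @param verbose print progress every 10 subjects
#' @return named list of data.frames (one per family), each keyed by
#'   `subject_id`, `epoch_index`, `group`
#' @export
extract_features <- function(cohort, config = preprocess_config(),
                             mode = c("epoch", "subject"),
                             families = c("spectral", "nonlinear", "connectivity"),
                             verbose = FALSE) {
  mode <- match.arg(mode)
  families <- match.arg(families, several.ok = TRUE)
  win <- if (mode == "epoch") 1 else 2
  rows <- vector("list", length(cohort))
  for (si in seq_along(cohort)) {
    rec <- preprocess(cohort[[si]], config)
    eps <- if (mode == "epoch") segment_epochs(rec, config) else list(
      structure(list(subject_id = rec$subject_id, group = rec$group,
                     epoch_index = 1L, channel_names = rec$channel_names,
                     fs = rec$fs, data = rec$data), class = "eeg_epoch"))
    rows[[si]] <- lapply(eps, function(ep) {
      fam <- list()
      if ("spectral" %in% families)
        fam$spectral <- spectral_features(ep, window_sec = win)
      if ("nonlinear" %in% families)
        fam$nonlinear <- nonlinear_features(ep)
      if ("connectivity" %in% families)
        fam$connectivity <- connectivity_features(ep, window_sec = win)
      list(subject_id = ep$subject_id, group = ep$group,
           epoch_index = ep$epoch_index, fam = fam)
    })
    if (verbose && si %% 10L == 0L)
      message("extracted features for ", si, "/", length(cohort), " subjects")
  }
  rows <- do.call(c, rows)
  out <- list()
  for (f in families) {
    mat <- do.call(rbind, lapply(rows, function(r) r$fam[[f]]))
    df <- data.frame(subject_id = vapply(rows, `[[`, "", "subject_id"),
                     epoch_index = vapply(rows, `[[`, 0L, "epoch_index"),
                     group = vapply(rows, `[[`, "", "group"),
                     stringsAsFactors = FALSE)
    out[[f]] <- cbind(df, as.data.frame(mat))
  }
  out
}
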