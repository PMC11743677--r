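#' Two-sample t statistic from summary statistics
#'
#' Pooled-variance two-sample t-test computed from per-group mean, SD and n
#' (the form used for demographic tables).
#'
#' @param mean1,sd1,n1 group 1 summary
#' @param mean2,sd2,n2 group 2 summary
#' @return list with `t`, `df`, `p`
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square statistic from a contingency table
#'
#' Pearson chi-square WITHOUT continuity correction.
#'
#' @param counts matrix of counts (groups x categories)
#' @return list with `chisq`, `df`, `p`
#' @export
chisq_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("empty contingency table")
  exp_ <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_ == 0)) stop("degenerate margin in contingency table")
  chisq <- sum((counts - exp_)^2 / exp_)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Demographic cohort statistics
#'
#' Reproduces the statistics column of a demographic characteristics table:
#' pooled-variance t-tests for continuous variables given as
#' `(mean, sd, n)` per group, and Pearson chi-square (no continuity
#' correction) for categorical variables given as contingency counts.
#'
#' @param continuous named list; each element a list with `smci = c(mean,
#'   sd)`, `pmci = c(mean, sd)` (n taken from `n_smci`/`n_pmci`)
#' @param categorical named list of count matrices (rows SMCI, PMCI)
#' @param n_smci,n_pmci group sizes for the continuous variables
#' @return data.frame with `variable`, `type`, `statistic`, `df`, `p`
#' @export
cohort_statistics <- function(continuous = list(), categorical = list(),
                              n_smci = 65, n_pmci = 42) {
  rows <- list()
  for (v in names(continuous)) {
    e <- continuous[[v]]
    r <- t_from_summary(e$smci[1], e$smci[2], n_smci, e$pmci[1], e$pmci[2], n_pmci)
    rows[[length(rows) + 1L]] <- data.frame(variable = v, type = "t",
                                            statistic = r$t, df = r$df, p = r$p)
  }
  for (v in names(categorical)) {
    r <- chisq_from_counts(categorical[[v]])
    rows[[length(rows) + 1L]] <- data.frame(variable = v, type = "chisq",
                                            statistic = r$chisq, df = r$df, p = r$p)
  }
  do.call(rbind, rows)
}

#' Demographics of the study cohort
#'
#' The printed demographic summaries of the 65 SMCI / 42 PMCI cohort (age,
#' MMSE and MoCA scores as mean/SD; gender, aMCI type, diabetes,
#' hypertension and education level as counts), in the input form expected
#' by [cohort_statistics].
#'
#' @return list with elements `continuous`, `categorical`, `n_smci`, `n_pmci`
#' @export
amci_demographics <- function() {
  list(
    continuous = list(
      age  = list(smci = c(68.85, 8.76), pmci = c(68.17, 8.08)),
      mmse = list(smci = c(23.58, 2.87), pmci = c(23.55, 2.47)),
      moca = list(smci = c(19.31, 3.36), pmci = c(18.52, 3.01))),
    categorical = list(
      gender       = rbind(SMCI = c(male = 24, female = 41), PMCI = c(22, 20)),
      amci_type    = rbind(SMCI = c(single = 27, multiple = 38), PMCI = c(17, 25)),
      diabetes     = rbind(SMCI = c(yes = 25, no = 40), PMCI = c(13, 29)),
      hypertension = rbind(SMCI = c(yes = 41, no = 24), PMCI = c(23, 19)),
      education    = rbind(SMCI = c(primary = 10, secondary = 49, higher = 6),
                           PMCI = c(6, 32, 4))),
    n_smci = 65, n_pmci = 42)
}
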