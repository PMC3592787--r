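# Validation statistics for algorithm-vs-chart-review comparison: the
# confusion matrix (algorithm labels on rows, gold-standard labels on
# columns), observed and per-category agreement, and Cohen's kappa with a
# large-sample confidence interval.

#' Cross-tabulate algorithm labels against gold-standard labels
#'
#' @param pred,gold labels by patient: either named character vectors
#'   (names = patient ids) or data frames with columns `patient_id` and
#'   `label`.  The two id sets must be identical.
#' @param labels ordered character vector of category names (>= 2); every
#'   observed label must appear in it.
#' @return a `cardio_confusion` object: fields `labels`, `counts` (square
#'   integer matrix, rows = algorithm, columns = gold), `n`.
#' @export
confusion_matrix <- function(pred, gold, labels) {
  pred <- as_label_vector(pred, "pred")
  gold <- as_label_vector(gold, "gold")
  if (length(pred) == 0L) stop("empty inputs")
  if (length(labels) < 2L) stop("need at least 2 labels")
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (!setequal(names(pred), names(gold)) ||
      length(pred) != length(gold))
    stop("pred and gold must cover identical patient_id sets")
  gold <- gold[names(pred)]
  bad <- setdiff(unique(c(pred, gold)), labels)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(pred, levels = labels), factor(gold, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(algorithm = labels, gold = labels))
  structure(list(labels = labels, counts = counts, n = sum(counts)),
            class = "cardio_confusion")
}

as_label_vector <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("patient_id", "label") %in% names(x)))
      stop(what, " data frame needs patient_id and label columns")
    v <- stats::setNames(as.character(x$label), as.character(x$patient_id))
  } else {
    v <- as.character(x)
    names(v) <- names(x)
  }
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    stop(what, " labels must be named by patient_id")
  if (anyDuplicated(names(v))) stop("duplicate patient_id in ", what)
  v
}

#' Build a confusion matrix directly from a count table
#'
#' For reconstructing published agreement tables where only the counts are
#' known (no per-patient labels).
#'
#' @param counts square non-negative integer matrix; rows = algorithm,
#'   columns = gold.
#' @param labels category names; defaults to `rownames(counts)`.
#' @return a `cardio_confusion` object.
#' @export
confusion_from_counts <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(counts)))
  if (length(labels) < 2L) stop("need at least 2 labels")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(algorithm = labels, gold = labels))
  structure(list(labels = labels, counts = counts, n = sum(counts)),
            class = "cardio_confusion")
}

#' Observed (overall) agreement
#'
#' Proportion of cases on the diagonal: the fraction where the algorithm
#' and the reviewers assigned the same category.
#'
#' @param m a `cardio_confusion`.
#' @return proportion in \[0, 1\].
#' @export
observed_agreement <- function(m) {
  stopifnot(inherits(m, "cardio_confusion"))
  if (m$n < 1L) stop("empty confusion matrix")
  sum(diag(m$counts)) / m$n
}

kappa_components <- function(m) {
  n <- m$n
  p_o <- sum(diag(m$counts)) / n
  p_e <- sum(rowSums(m$counts) * colSums(m$counts)) / n^2
  list(n = n, p_o = p_o, p_e = p_e)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement and `p_e` the expected agreement under marginal
#' independence.  In the degenerate single-category case (`p_e = 1` with
#' perfect agreement) kappa is defined as exactly 1.
#'
#' @param m a `cardio_confusion` with `n >= 2`.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(m) {
  stopifnot(inherits(m, "cardio_confusion"))
  if (m$n < 2L) stop("kappa requires n >= 2")
  k <- kappa_components(m)
  if (k$p_e == 1) {
    if (k$p_o == 1) return(1)
    stop("kappa undefined: expected agreement is 1 with imperfect observed agreement")
  }
  (k$p_o - k$p_e) / (1 - k$p_e)
}

#' Confidence interval for Cohen's kappa
#'
#' Default is Cohen's large-sample standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` with a normal quantile;
#' endpoints are truncated to \[-1, 1\].  `method = "fleiss"` uses the
#' Fleiss-Cohen-Everitt asymptotic variance instead.
#'
#' @param m a `cardio_confusion` with `n >= 2`.
#' @param level confidence level in (0, 1); default 0.95.
#' @param method `"cohen"` (default) or `"fleiss"`.
#' @return numeric vector `c(low, high)`.
#' @export
kappa_ci <- function(m, level = 0.95, method = c("cohen", "fleiss")) {
  stopifnot(inherits(m, "cardio_confusion"))
  method <- match.arg(method)
  if (m$n < 2L) stop("CI requires n >= 2")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  k <- kappa_components(m)
  if (k$p_e == 1 && k$p_o < 1) stop("CI undefined: expected agreement is 1")
  kap <- cohens_kappa(m)
  se <- if (k$p_e == 1) 0 else switch(method,
    cohen = sqrt(k$p_o * (1 - k$p_o) / (k$n * (1 - k$p_e)^2)),
    fleiss = sqrt(fleiss_variance(m, kap, k)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(-1, kap - z * se)
  hi <- min(1, kap + z * se)
  c(low = lo, high = hi)
}

# Fleiss, Cohen & Everitt (1969) asymptotic variance of unweighted kappa.
fleiss_variance <- function(m, kap, k) {
  p <- m$counts / k$n
  pi_ <- rowSums(p); p_j <- colSums(p)
  a <- sum(diag(p) * (1 - (pi_ + p_j) * (1 - kap))^2)
  b <- 0
  for (i in seq_along(pi_)) for (j in seq_along(p_j))
    if (i != j) b <- b + p[i, j] * (p_j[i] + pi_[j])^2
  b <- (1 - kap)^2 * b
  cc <- (kap - k$p_e * (1 - kap))^2
  (a + b - cc) / (k$n * (1 - k$p_e)^2)
}

#' Per-category agreement
#'
#' Diagonal count over a marginal total for each category.  The default
#' basis, `"algorithm_rows"`, divides by the number of cases the algorithm
#' assigned to the category (the convention used when agreement is quoted
#' per computer-identified case); `"gold_columns"` divides by the
#' reviewers' totals instead.
#'
#' @param m a `cardio_confusion`.
#' @param basis `"algorithm_rows"` (default) or `"gold_columns"`.
#' @return data frame with columns `label`, `concordant`, `total`,
#'   `proportion` (`NA` when the denominator is zero — undefined, not 0).
#' @export
per_category_agreement <- function(m, basis = c("algorithm_rows", "gold_columns")) {
  stopifnot(inherits(m, "cardio_confusion"))
  if (m$n < 1L) stop("empty confusion matrix")
  basis <- match.arg(basis)
  tot <- if (basis == "algorithm_rows") rowSums(m$counts) else colSums(m$counts)
  conc <- diag(m$counts)
  data.frame(label = m$labels, concordant = as.integer(conc),
             total = as.integer(tot),
             proportion = ifelse(tot > 0, conc / tot, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full validation report against gold-standard labels
#'
#' @inheritParams confusion_matrix
#' @param level confidence level for the kappa interval.
#' @param ci_method passed to [kappa_ci()].
#' @return an `agreement_report`: list with `matrix` (the
#'   `cardio_confusion`), `n`, `observed_agreement`, `per_category`,
#'   `kappa`, `ci_low`, `ci_high`, `level`.
#' @export
validation_report <- function(pred, gold, labels, level = 0.95,
                              ci_method = c("cohen", "fleiss")) {
  m <- confusion_matrix(pred, gold, labels)
  report_from_matrix(m, level, match.arg(ci_method))
}

#' @rdname validation_report
#' @param m a `cardio_confusion` (alternative entry point when only counts
#'   are available).
#' @export
report_from_matrix <- function(m, level = 0.95, ci_method = c("cohen", "fleiss")) {
  stopifnot(inherits(m, "cardio_confusion"))
  ci <- kappa_ci(m, level, match.arg(ci_method))
  structure(list(matrix = m, n = m$n,
                 observed_agreement = observed_agreement(m),
                 per_category = per_category_agreement(m),
                 kappa = cohens_kappa(m),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 level = level),
            class = "agreement_report")
}

#' @export
print.cardio_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d; rows = algorithm, columns = gold)\n", x$n))
  print(x$counts)
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d)\n", x$n))
  cat(sprintf("  Observed agreement: %.1f%% (%d/%d)\n",
              100 * x$observed_agreement, sum(diag(x$matrix$counts)), x$n))
  cat(sprintf("  Cohen's kappa: %.2f (%.0f%% CI, %.2f-%.2f)\n",
              x$kappa, 100 * x$level, x$ci_low, x$ci_high))
  cat("  Per-category agreement (algorithm-row basis):\n")
  pc <- x$per_category
  for (i in seq_len(nrow(pc)))
    cat(sprintf("    %-22s %s\n", pc$label[i],
                if (is.na(pc$proportion[i])) "undefined (no cases)"
                else sprintf("%.0f%% (%d/%d)", 100 * pc$proportion[i],
                             pc$concordant[i], pc$total[i])))
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) object
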