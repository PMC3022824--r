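#' Confusion counts for binary case-control prediction
#'
#' Cases (label 1) are the positive class: `tp` counts cases predicted case,
#' `fn` cases predicted control, `tn` controls predicted control, `fp`
#' controls predicted case.
#'
#' @param y_true,y_pred equal-length binary vectors (1 = case, 0 = control).
#' @return A list of class `confusion_counts` with fields `tp`, `fn`, `tn`,
#'   `fp`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (anyNA(y_true) || anyNA(y_pred) ||
      !all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stop("labels must be binary 0/1 with no missing values")
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L)),
            class = "confusion_counts")
}

sensitivity_of <- function(cc) cc$tp / (cc$tp + cc$fn)
specificity_of <- function(cc) cc$tn / (cc$tn + cc$fp)

#' Harmonic mean of sensitivity and specificity (HMSS)
#'
#' `HMSS = 2 * se * sp / (se + sp)`; invariant to the case:control ratio and
#' hence suited to imbalanced cohorts. By convention HMSS is 0 when
#' `se + sp = 0` (the harmonic mean's limit).
#'
#' @param cc a [confusion()] object (both true classes must be represented).
#' @return HMSS in `[0, 1]`.
#' @export
hmss <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$tp + cc$fn == 0L || cc$tn + cc$fp == 0L)
    stop("HMSS undefined: a true class is absent from y_true")
  se <- sensitivity_of(cc); sp <- specificity_of(cc)
  if (se + sp == 0) return(0)
  2 * se * sp / (se + sp)
}

#' Total and group-wise classification accuracy
#'
#' `total_accuracy` is `(tp + tn) / n`; `group_accuracy` is the accuracy
#' within one true class: sensitivity for cases, specificity for controls.
#'
#' @param cc a [confusion()] object.
#' @param group `"cases"` or `"controls"`.
#' @return A rate in `[0, 1]`.
#' @export
total_accuracy <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  (cc$tp + cc$tn) / (cc$tp + cc$fn + cc$tn + cc$fp)
}

#' @rdname total_accuracy
#' @export
group_accuracy <- function(cc, group = c("cases", "controls")) {
  stopifnot(inherits(cc, "confusion_counts"))
  group <- match.arg(group)
  n <- if (group == "cases") cc$tp + cc$fn else cc$tn + cc$fp
  if (n == 0L) stop(sprintf("no %s in y_true: group accuracy undefined", group))
  if (group == "cases") sensitivity_of(cc) else specificity_of(cc)
}

#' Ready-made statistics for [bootstrap_ci()]
#'
#' Each takes `(y_true, y_pred)` and returns one rate.
#' @param y_true,y_pred binary vectors.
#' @export
stat_hmss <- function(y_true, y_pred) hmss(confusion(y_true, y_pred))

#' @rdname stat_hmss
#' @export
stat_total_accuracy <- function(y_true, y_pred) total_accuracy(confusion(y_true, y_pred))

#' @rdname stat_hmss
#' @export
stat_case_accuracy <- function(y_true, y_pred) group_accuracy(confusion(y_true, y_pred), "cases")

#' @rdname stat_hmss
#' @export
stat_control_accuracy <- function(y_true, y_pred) group_accuracy(confusion(y_true, y_pred), "controls")

#' Stratified bootstrap percentile confidence interval for a rate statistic
#'
#' The classifier is frozen: resampling acts on the `(y_true, y_pred)` pairs.
#' Cases and controls are resampled with replacement separately, preserving
#' the class counts, so sensitivity, specificity and HMSS are defined on
#' every resample. The interval is the percentile interval of the resampled
#' statistics at `(1-level)/2` and `1-(1-level)/2`, using linearly
#' interpolated order statistics (quantile type 7).
#'
#' @param y_true,y_pred binary vectors; both classes must appear in `y_true`.
#' @param statistic function `(y_true, y_pred) -> numeric(1)`, e.g.
#'   [stat_hmss()].
#' @param n_boot number of bootstrap iterations (default 200).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the result is reproducible given it.
#' @return A list of class `metric_result`: `point`, `boot_mean`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(y_true, y_pred, statistic = stat_hmss,
                         n_boot = 200L, level = 0.95, seed = 1L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  idx_case <- which(y_true == 1L); idx_ctrl <- which(y_true == 0L)
  if (!length(idx_case) || !length(idx_ctrl))
    stop("both classes must be present in y_true")
  point <- statistic(y_true, y_pred)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vals <- numeric(n_boot)
  n1 <- length(idx_case); n0 <- length(idx_ctrl)
  for (b in seq_len(n_boot)) {
    i <- c(idx_case[sample.int(n1, n1, replace = TRUE)],
           idx_ctrl[sample.int(n0, n0, replace = TRUE)])
    vals[b] <- statistic(y_true[i], y_pred[i])
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(point = point, boot_mean = mean(vals),
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%.3f(%.3f, %.3f-%.3f)  [point(boot mean, 95%% CI), B=%d]\n",
              x$point, x$boot_mean, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Genotypic chi-square association test for one SNP
#'
#' Pearson chi-square (no continuity correction) on the 2 x r contingency
#' table of case-control label by genotype category, where r is the number
#' of genotype categories actually observed (all-zero columns are dropped);
#' degrees of freedom r - 1. A monomorphic SNP (r = 1) yields statistic 0
#' and p = 1.
#'
#' @param g complete (imputed) genotype column, codes in `{0, 1, 2}`.
#' @param labels per-sample 1/0 labels.
#' @return A list of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `table`.
#' @export
chi_square_test <- function(g, labels) {
  g <- as.integer(g); labels <- as.integer(labels)
  if (anyNA(g)) stop("genotype column must be complete (impute first)")
  if (length(g) != length(labels)) stop("length mismatch")
  tab <- rbind(cases = tabulate(g[labels == 1L] + 1L, 3L),
               controls = tabulate(g[labels == 0L] + 1L, 3L))
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  r <- ncol(tab)
  if (r <= 1L)
    return(structure(list(statistic = 0, df = 0L, p_value = 1, table = tab),
                     class = "chisq_result"))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- r - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 table = tab),
            class = "chisq_result")
}

#' Per-SNP chi-square association scan
#'
#' Applies [chi_square_test()] to every SNP of a complete genotype matrix.
#'
#' @param G a complete [genotype_matrix()].
#' @param labels per-sample 1/0 labels.
#' @return Data frame: `snp_id`, `chromosome`, `statistic`, `df`, `p_value`.
#' @export
chi_square_scan <- function(G, labels) {
  stopifnot(inherits(G, "genotype_matrix"))
  res <- lapply(seq_along(G$snp_ids), function(j)
    chi_square_test(G$codes[, j], labels))
  data.frame(snp_id = G$snp_ids,
             chromosome = G$chromosomes,
             statistic = vapply(res, `[[`, 0, "statistic"),
             df = vapply(res, function(x) as.integer(x$df), 0L),
             p_value = vapply(res, `[[`, 0, "p_value"),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`. At the genome-wide scale of 451,724 SNPs and
#'   `alpha = 0.05` this is 1.11e-7 to three significant figures.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
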