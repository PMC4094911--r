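#' Derive per-subject longitudinal index quantities
#'
#' For every subject with both a baseline and a 12-month index, computes the
#' annual rate of change (`index_m12 - index_baseline`; the raw 12-month
#' difference, not divided by an exact inter-scan interval) and the average
#' index (`(index_baseline + index_m12)/2`), and labels the pattern of
#' atrophy from the average index (AD-like iff average > 0.5). Subjects
#' missing a timepoint are excluded with a message.
#'
#' @param indices data.frame with `subject_id`, `timepoint`
#'   (`"baseline"`/`"m12"`) and `index` (e.g. from [compute_index()]).
#' @return data.frame `subject_id`, `index_baseline`, `index_m12`,
#'   `annual_rate`, `average_index`, `pattern`.
#' @export
derive_longitudinal <- function(indices) {
  stopifnot(all(c("subject_id", "timepoint", "index") %in% names(indices)))
  if (anyDuplicated(indices[, c("subject_id", "timepoint")])) {
    stop("duplicate subject x timepoint rows")
  }
  base <- indices[indices$timepoint == "baseline", c("subject_id", "index")]
  m12 <- indices[indices$timepoint == "m12", c("subject_id", "index")]
  names(base)[2] <- "index_baseline"
  names(m12)[2] <- "index_m12"
  out <- merge(base, m12, by = "subject_id")
  n_dropped <- length(unique(indices$subject_id)) - nrow(out)
  if (n_dropped > 0L) {
    message(n_dropped, " subject(s) missing a timepoint were excluded")
  }
  if (nrow(out) == 0L) stop("no subject has both timepoints")
  out$annual_rate <- out$index_m12 - out$index_baseline
  out$average_index <- (out$index_baseline + out$index_m12) / 2
  out$pattern <- pattern_label(out$average_index)
  out
}

#' Descriptive summary of a set of values
#'
#' Mean, SD, median, min, max and quartiles (type-7 quantiles). A
#' single-value group gets SD 0 with `sd_degenerate = TRUE`.
#'
#' @param values numeric vector (non-empty).
#' @return one-row data.frame `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `q1`, `q3`, `sd_degenerate`.
#' @export
descriptive_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || all(is.na(values))) stop("empty group")
  degenerate <- length(values) < 2L
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(values), mean = mean(values),
             sd = if (degenerate) 0 else stats::sd(values),
             median = q[2], min = min(values), max = max(values),
             q1 = q[1], q3 = q[3], sd_degenerate = degenerate)
}

#' Summarise a value by group
#'
#' Applies [descriptive_summary()] within each level of `group`; groups are
#' disjoint and exhaust the sample by construction.
#'
#' @param values numeric vector.
#' @param group factor-like vector of the same length.
#' @return data.frame, one row per group.
#' @export
group_summary <- function(values, group) {
  stopifnot(length(values) == length(group))
  parts <- split(as.numeric(values), group)
  out <- do.call(rbind, lapply(parts, descriptive_summary))
  out <- cbind(group = names(parts), out)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Exact enumeration when both groups are small (total n <= 20) and there
#' are no ties; otherwise the normal approximation with tie correction
#' (no continuity correction, so the U statistic maps exactly onto the
#' empirical AUC of the pooled values: `U/(n1*n2) = AUC`).
#'
#' @param a,b numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`
#'   (alternative about a relative to b).
#' @return data.frame `test`, `n_a`, `n_b`, `statistic` (U for a), `auc`
#'   (`U/(n_a n_b)`), `p_value`, `exact`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = use_exact,
                       correct = FALSE))
  u <- unname(wt$statistic)
  data.frame(test = "Mann-Whitney", n_a = length(a), n_b = length(b),
             statistic = u, auc = u / (length(a) * length(b)),
             p_value = wt$p.value, exact = use_exact,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rho with average ranks for ties; p-value by the exact small-sample
#' distribution (n <= 10, no ties) or the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return data.frame `n`, `rho`, `p_value`.
#' @export
rank_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 10L && !ties))
  data.frame(n = length(x), rho = unname(ct$estimate),
             p_value = ct$p.value)
}

#' Paired baseline-to-12-month change tests
#'
#' Reports both the paired t-test and the Wilcoxon signed-rank test on the
#' 12-month minus baseline differences (the two conventions used for
#' matched-pair comparisons in this setting).
#'
#' @param baseline,m12 paired numeric vectors (same subjects, same order).
#' @param alternative `"two.sided"`, `"greater"` (m12 > baseline) or
#'   `"less"`.
#' @return data.frame with one row per test: `test`, `n`, `statistic`,
#'   `p_value`.
#' @export
paired_change_test <- function(baseline, m12,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  baseline <- as.numeric(baseline); m12 <- as.numeric(m12)
  if (length(baseline) != length(m12)) stop("unpaired input")
  if (length(baseline) < 2L) stop("need at least 2 pairs")
  d <- m12 - baseline
  if (all(d == 0)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
    wt <- list(statistic = c(V = 0), p.value = 1)
  } else {
    tt <- stats::t.test(m12, baseline, paired = TRUE,
                        alternative = alternative)
    wt <- suppressWarnings(
      stats::wilcox.test(m12, baseline, paired = TRUE,
                         alternative = alternative,
                         exact = length(d) <= 25L && !anyDuplicated(abs(d))))
  }
  rbind(
    data.frame(test = "paired-t", n = length(d),
               statistic = unname(tt$statistic), p_value = tt$p.value),
    data.frame(test = "signed-rank", n = length(d),
               statistic = unname(wt$statistic), p_value = wt$p.value))
}

#' One-way ANOVA of annual rates across diagnostic groups
#'
#' Tests whether the mean annual rate of index change differs across
#' diagnostic groups.
#'
#' @param rates numeric vector of annual rates.
#' @param group diagnostic group per subject.
#' @return data.frame `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
rate_anova <- function(rates, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  fit <- stats::aov(rates ~ group)
  s <- summary(fit)[[1]]
  data.frame(f_statistic = s[["F value"]][1], df1 = s[["Df"]][1],
             df2 = s[["Df"]][2], p_value = s[["Pr(>F)"]][1])
}

#' APOE e4 stratification of the MCI sample on standardised averages
#'
#' For MCI subjects with both timepoints, averages the index and each
#' cognitive score over baseline and 12 months, z-scores each variable over
#' the MCI sample (mean 0, SD 1), and compares e4 carriers with
#' non-carriers by rank-sum test.
#'
#' @param longit data.frame from [derive_longitudinal()] restricted to MCI
#'   subjects, carrying `average_index`.
#' @param meta metadata with `subject_id`, `apoe_e4`, and per-timepoint
#'   cognitive scores `mmse`, `cdr_sob`, `adas1` (plus `timepoint`).
#' @return list with `z` (per-subject z-scored averages and carrier flag)
#'   and `tests` (one rank-sum row per variable).
#' @export
apoe_stratification <- function(longit, meta) {
  cogs <- c("mmse", "cdr_sob", "adas1")
  base <- meta[meta$timepoint == "baseline",
               c("subject_id", "apoe_e4", cogs)]
  m12 <- meta[meta$timepoint == "m12", c("subject_id", cogs)]
  names(m12)[-1] <- paste0(names(m12)[-1], "_m12")
  df <- merge(merge(longit, base, by = "subject_id"), m12, by = "subject_id")
  if (nrow(df) == 0L) stop("no MCI subject with both timepoints")
  if (length(unique(df$apoe_e4)) < 2L) stop("an APOE stratum is empty")
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  z <- data.frame(subject_id = df$subject_id, apoe_e4 = df$apoe_e4)
  z$index <- zscore(df$average_index)
  for (v in cogs) z[[v]] <- zscore((df[[v]] + df[[paste0(v, "_m12")]]) / 2)
  tests <- do.call(rbind, lapply(c("index", cogs), function(v) {
    res <- rank_sum_test(z[[v]][z$apoe_e4 == 1], z[[v]][z$apoe_e4 == 0])
    cbind(variable = v, res)
  }))
  list(z = z, tests = tests)
}
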