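#' Confusion counts for the AD-like / CTL-like decision
#'
#' Counts of subjects labelled AD-like or CTL-like among the true positives
#' (AD, or MCI converters) and true negatives (CTL, or MCI non-converters).
#'
#' @param ad_like_pos,ctl_like_pos counts among the positive group.
#' @param ad_like_neg,ctl_like_neg counts among the negative group.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(ad_like_pos = 0L, ctl_like_pos = 0L,
                             ad_like_neg = 0L, ctl_like_neg = 0L) {
  counts <- c(ad_like_pos, ctl_like_pos, ad_like_neg, ctl_like_neg)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(ad_like_pos = as.integer(ad_like_pos),
                 ctl_like_pos = as.integer(ctl_like_pos),
                 ad_like_neg = as.integer(ad_like_neg),
                 ctl_like_neg = as.integer(ctl_like_neg)),
            class = "confusion_counts")
}

# Half-up rounding to integer: 84.5 -> 85 (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

#' Sensitivity from confusion counts, in integer percent
#'
#' `100 * ad_like_pos / (ad_like_pos + ctl_like_pos)`, rounded half-up to an
#' integer percentage.
#'
#' @param counts a [confusion_counts()] object.
#' @return integer percent.
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_pos <- counts$ad_like_pos + counts$ctl_like_pos
  if (n_pos == 0L) stop("positive group is empty")
  as.integer(round_half_up(100 * counts$ad_like_pos / n_pos))
}

#' Specificity from confusion counts, in integer percent
#'
#' `100 * ctl_like_neg / (ad_like_neg + ctl_like_neg)`, rounded half-up.
#'
#' @param counts a [confusion_counts()] object.
#' @return integer percent.
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_neg <- counts$ad_like_neg + counts$ctl_like_neg
  if (n_neg == 0L) stop("negative group is empty")
  as.integer(round_half_up(100 * counts$ctl_like_neg / n_neg))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct index value as a threshold, accumulating
#' sensitivity and 1-specificity; the AUC is the trapezoidal area, which
#' with tied values equals the tie-corrected pair-counting statistic
#' `U/(n1*n2)`. The standard error uses the Hanley-McNeil formula.
#'
#' @param values numeric index values (higher = more positive-like).
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive class.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `fpr` (1-specificity), `auc`, `auc_se`.
#' @export
empirical_auc <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  l <- labels[ord]
  n1 <- sum(l)
  n2 <- sum(!l)
  # group tied values so each distinct threshold yields one ROC point
  grp_end <- which(!duplicated(v, fromLast = TRUE))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  sens <- c(0, tp / n1)
  fpr <- c(0, fp / n2)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  structure(list(thresholds = c(Inf, v[grp_end]), sensitivity = sens,
                 fpr = fpr, auc = auc, auc_se = auc_se),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.3f +/- %.3f (%d points)\n",
              x$auc, x$auc_se, length(x$thresholds)))
  invisible(x)
}

# One report row: counts + sens/spec/AUC for a positive vs negative contrast.
.report_block <- function(dataset, pos_name, neg_name, idx_pos, idx_neg,
                          threshold = 0.5) {
  lab_pos <- pattern_label(idx_pos, threshold)
  lab_neg <- pattern_label(idx_neg, threshold)
  counts <- confusion_counts(sum(lab_pos == "AD-like"),
                             sum(lab_pos == "CTL-like"),
                             sum(lab_neg == "AD-like"),
                             sum(lab_neg == "CTL-like"))
  roc <- empirical_auc(c(idx_pos, idx_neg),
                       rep(c(TRUE, FALSE), c(length(idx_pos), length(idx_neg))))
  data.frame(dataset = dataset,
             group = c(pos_name, neg_name),
             ad_like = c(counts$ad_like_pos, counts$ad_like_neg),
             ctl_like = c(counts$ctl_like_pos, counts$ctl_like_neg),
             sensitivity = c(sensitivity(counts), NA_integer_),
             specificity = c(specificity(counts), NA_integer_),
             auc = c(roc$auc, NA_real_),
             auc_se = c(roc$auc_se, NA_real_),
             stringsAsFactors = FALSE)
}

#' Classification and conversion-prediction report
#'
#' Emits the Table-5-shaped performance summary of the AD-vs-CTL model:
#' per timepoint, AD vs CTL confusion counts with sensitivity, specificity
#' and empirical AUC, and MCI-c vs MCI-nc prediction metrics, where
#' converter status comes from the follow-up diagnosis. Baseline AD/CTL
#' metrics use out-of-fold cross-validated indices when `cv_index` is
#' supplied (the training-honest estimate); follow-up rows and all MCI rows
#' always use direct application of the final model.
#'
#' @param indices data.frame from [compute_index()] for every
#'   subject x timepoint (direct model application).
#' @param meta per-subject metadata (`subject_id`, `dx`, `mci_status`);
#'   one row per subject or per subject x timepoint.
#' @param cv_index optional data.frame `subject_id`, `index` of out-of-fold
#'   CV indices for the baseline training subjects.
#' @param threshold AD-like decision cut (default 0.5).
#' @return data.frame report, one row per group per dataset block.
#' @export
classification_report <- function(indices, meta, cv_index = NULL,
                                  threshold = 0.5) {
  meta <- unique(meta[, intersect(c("subject_id", "dx", "mci_status"),
                                  names(meta))])
  if (anyDuplicated(meta$subject_id)) {
    stop("metadata is not unique per subject")
  }
  df <- merge(indices, meta, by = "subject_id", all.x = TRUE)
  if (any(is.na(df$dx))) {
    stop("unjoinable rows: no metadata for ",
         paste(unique(df$subject_id[is.na(df$dx)]), collapse = ", "))
  }
  pick <- function(tp, dx, status = NULL) {
    sel <- df$timepoint == tp & df$dx == dx
    if (!is.null(status)) sel <- sel & !is.na(df$mci_status) &
        df$mci_status == status
    df$index[sel]
  }
  blocks <- list()
  base_ad <- pick("baseline", "AD")
  base_ctl <- pick("baseline", "CTL")
  if (!is.null(cv_index)) {
    cvdf <- merge(cv_index, meta, by = "subject_id")
    blocks[[length(blocks) + 1L]] <-
      .report_block("baseline_cv", "AD", "CTL",
                    cvdf$index[cvdf$dx == "AD"],
                    cvdf$index[cvdf$dx == "CTL"], threshold)
  } else if (length(base_ad) && length(base_ctl)) {
    blocks[[length(blocks) + 1L]] <-
      .report_block("baseline", "AD", "CTL", base_ad, base_ctl, threshold)
  }
  if (length(pick("baseline", "MCI", "c")) &&
      length(pick("baseline", "MCI", "nc"))) {
    blocks[[length(blocks) + 1L]] <-
      .report_block("baseline", "MCI-c", "MCI-nc",
                    pick("baseline", "MCI", "c"),
                    pick("baseline", "MCI", "nc"), threshold)
  }
  if (length(pick("m12", "AD")) && length(pick("m12", "CTL"))) {
    blocks[[length(blocks) + 1L]] <-
      .report_block("m12", "AD", "CTL",
                    pick("m12", "AD"), pick("m12", "CTL"), threshold)
  }
  if (length(pick("m12", "MCI", "c")) && length(pick("m12", "MCI", "nc"))) {
    blocks[[length(blocks) + 1L]] <-
      .report_block("m12", "MCI-c", "MCI-nc",
                    pick("m12", "MCI", "c"), pick("m12", "MCI", "nc"),
                    threshold)
  }
  do.call(rbind, blocks)
}
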