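test_that("sensitivity/specificity follow the confusion-count formulas", {
  # published worked examples: 100/19 of 119 AD -> 84; 8/71 of 79 CTL -> 90
  expect_equal(sensitivity(confusion_counts(100, 19, 10, 100)), 84L)
  expect_equal(specificity(confusion_counts(100, 19, 10, 100)), 91L)
  expect_equal(sensitivity(confusion_counts(50, 12, 8, 71)), 81L)
  expect_equal(specificity(confusion_counts(50, 12, 8, 71)), 90L)
  expect_equal(specificity(confusion_counts(0, 0, 32, 28)), 47L)

  # degenerate decisions
  expect_equal(sensitivity(confusion_counts(0, 10, 0, 10)), 0L)
  expect_equal(specificity(confusion_counts(0, 10, 0, 10)), 100L)
  expect_error(sensitivity(confusion_counts(0, 0, 1, 1)), "empty")
  expect_error(specificity(confusion_counts(1, 1, 0, 0)), "empty")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")

  # half-up rounding at the .5 boundary (base round() would give 84)
  expect_equal(sensitivity(confusion_counts(169, 31, 0, 1)), 85L)
})

test_that("sensitivity and its false-negative complement sum to 100", {
  withr::with_seed(7L, {
    for (i in 1:20) {
      tp <- sample(0:50, 1); fn <- sample(1:50, 1)
      sens_raw <- 100 * (tp + 1) / (tp + 1 + fn)
      if (isTRUE(all.equal(sens_raw %% 1, 0.5))) next  # .5 boundary rounds up twice
      counts <- confusion_counts(tp + 1L, fn, 0L, 1L)
      expect_equal(sensitivity(counts) + floor(100 - sens_raw + 0.5), 100L)
    }
  })
})

test_that("empirical AUC matches the brute-force pair-counting oracle", {
  expect_equal(empirical_auc(c(1, 2, 3, 10, 11, 12),
                             c(0, 0, 0, 1, 1, 1))$auc, 1)
  withr::with_seed(2024L, {
    for (i in 1:100) {
      n <- sample(6:20, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      values <- sample(1:6, n, replace = TRUE)  # many ties
      roc <- empirical_auc(values, labels)
      expect_equal(roc$auc, auc_bruteforce(values, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(empirical_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant to strictly monotone transforms", {
  withr::with_seed(31L, {
    values <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
  })
  a0 <- empirical_auc(values, labels)$auc
  expect_equal(empirical_auc(exp(values), labels)$auc, a0)
  expect_equal(empirical_auc(values^3, labels)$auc, a0)
})

test_that("null and structured ROC behave as expected", {
  withr::with_seed(5L, {
    values <- rnorm(2000)
    labels <- rbinom(2000, 1, 0.5)
  })
  roc <- empirical_auc(values, labels)
  expect_lt(abs(roc$auc - 0.5), 0.05)
  # curve monotone in both coordinates, SE positive
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_gt(roc$auc_se, 0)
})

test_that("classification report mirrors the Table-5 layout", {
  meta <- data.frame(
    subject_id = sprintf("S%02d", 1:12),
    dx = rep(c("AD", "CTL", "MCI", "MCI"), each = 3),
    mci_status = rep(c(NA, NA, "c", "nc"), each = 3),
    stringsAsFactors = FALSE)
  idx <- data.frame(
    subject_id = rep(meta$subject_id, 2),
    timepoint = rep(c("baseline", "m12"), each = 12),
    index = c(# baseline: AD 0.9 0.9 0.3 | CTL 0.2 0.2 0.8 | MCI-c 0.9 0.9 0.2 | MCI-nc 0.2 0.2 0.9
              0.9, 0.9, 0.3, 0.2, 0.2, 0.8, 0.9, 0.9, 0.2, 0.2, 0.2, 0.9,
              # m12: everyone a bit higher
              0.95, 0.95, 0.4, 0.3, 0.3, 0.9, 0.95, 0.95, 0.3, 0.3, 0.3, 0.95),
    stringsAsFactors = FALSE)
  rep <- classification_report(idx, meta)
  base_ad <- rep[rep$dataset == "baseline" & rep$group == "AD", ]
  expect_equal(base_ad$ad_like, 2L)
  expect_equal(base_ad$ctl_like, 1L)
  expect_equal(base_ad$sensitivity, 67L)  # 2/3 half-up
  base_mcic <- rep[rep$dataset == "baseline" & rep$group == "MCI-c", ]
  expect_equal(base_mcic$sensitivity, 67L)
  expect_equal(base_mcic$specificity, 67L)  # metrics sit on the positive row
  base_mcinc <- rep[rep$dataset == "baseline" & rep$group == "MCI-nc", ]
  expect_equal(base_mcinc$ad_like, 1L)
  expect_equal(base_mcinc$ctl_like, 2L)
  expect_setequal(unique(rep$dataset), c("baseline", "m12"))

  # all-CTL-like degenerate labelling
  idx0 <- idx
  idx0$index <- 0.1
  rep0 <- classification_report(idx0, meta)
  expect_true(all(rep0$sensitivity == 0L, na.rm = TRUE))
  expect_true(all(rep0$specificity == 100L, na.rm = TRUE))

  # unjoinable rows are an error
  expect_error(classification_report(idx, meta[-1, ]), "unjoinable")

  # cv_index replaces the baseline AD/CTL block with out-of-fold values
  cvi <- data.frame(subject_id = meta$subject_id[1:6],
                    index = c(0.9, 0.3, 0.3, 0.2, 0.2, 0.2))
  rep_cv <- classification_report(idx, meta, cv_index = cvi)
  cv_ad <- rep_cv[rep_cv$dataset == "baseline_cv" & rep_cv$group == "AD", ]
  expect_equal(cv_ad$sensitivity, 33L)
})

test_that("report (sens, spec) at 0.5 is a point on the stored ROC curve", {
  withr::with_seed(77L, {
    idx_pos <- rnorm(30, 0.8, 0.3)
    idx_neg <- rnorm(30, 0.2, 0.3)
  })
  lab <- rep(c(TRUE, FALSE), each = 30)
  roc <- empirical_auc(c(idx_pos, idx_neg), lab)
  sens_at_cut <- mean(idx_pos > 0.5)
  fpr_at_cut <- mean(idx_neg > 0.5)
  hit <- any(abs(roc$sensitivity - sens_at_cut) < 1e-12 &
               abs(roc$fpr - fpr_at_cut) < 1e-12)
  expect_true(hit)
})
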