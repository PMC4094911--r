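test_that("longitudinal identities hold and the pattern uses the average", {
  idx <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    timepoint = rep(c("baseline", "m12"), 3),
    index = c(0.70, 0.86, 0.5, 0.5, -0.13, -0.03))
  lg <- derive_longitudinal(idx)
  a <- lg[lg$subject_id == "a", ]
  expect_equal(a$annual_rate, 0.16)
  expect_equal(a$average_index, 0.78)
  expect_equal(a$pattern, "AD-like")
  b <- lg[lg$subject_id == "b", ]
  expect_equal(b$annual_rate, 0)
  expect_equal(b$pattern, "CTL-like")  # 0.5 exactly is CTL-like
  c_ <- lg[lg$subject_id == "c", ]
  expect_equal(c_$average_index, -0.08)
  expect_equal(c_$pattern, "CTL-like")

  # missing timepoint excluded with a message; duplicates are an error
  idx_miss <- rbind(idx, data.frame(subject_id = "d", timepoint = "baseline",
                                    index = 1))
  expect_message(derive_longitudinal(idx_miss), "1 subject")
  expect_error(derive_longitudinal(rbind(idx, idx[1, ])), "duplicate")
})

test_that("identities hold to machine precision on a generated cohort", {
  co <- generate_cohort(small_spec(seed = 23L))
  tr <- training_subset(co$data)
  m <- fit_hierarchical(tr$table, tr$y, n_ortho = 1L, n_ortho_top = 0L)
  lg <- suppressMessages(derive_longitudinal(compute_index(m, co$data)))
  expect_identical(lg$annual_rate, lg$index_m12 - lg$index_baseline)
  expect_identical(lg$average_index, (lg$index_baseline + lg$index_m12) / 2)
  expect_identical(lg$pattern, ifelse(lg$average_index > 0.5,
                                      "AD-like", "CTL-like"))
  # pattern stratification is a partition
  expect_equal(sum(lg$pattern == "AD-like") + sum(lg$pattern == "CTL-like"),
               nrow(lg))
})

test_that("descriptive summaries report the documented statistics", {
  s <- descriptive_summary(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$min, 1)
  expect_equal(s$max, 4)
  expect_equal(s$mean, 2.5)
  s1 <- descriptive_summary(5)
  expect_equal(s1$sd, 0)
  expect_true(s1$sd_degenerate)
  expect_error(descriptive_summary(numeric(0)), "empty")
  withr::with_seed(9L, {
    for (i in 1:10) {
      s <- descriptive_summary(rnorm(sample(3:30, 1)))
      expect_true(s$q1 <= s$median && s$median <= s$q3)
    }
  })
  g <- group_summary(c(1, 2, 10, 20), c("a", "a", "b", "b"))
  expect_equal(g$group, c("a", "b"))
  expect_equal(g$mean, c(1.5, 15))
})

test_that("rank-sum test matches exact enumeration and the AUC identity", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mw_exact_p_enum(c(1, 2, 3), c(4, 5, 6)))

  same <- rank_sum_test(c(1, 3, 5), c(1, 3, 5))
  expect_gte(same$p_value, 0.99)

  # U/(n1 n2) equals the empirical AUC on random inputs
  withr::with_seed(15L, {
    for (i in 1:20) {
      a <- sample(1:8, sample(4:12, 1), replace = TRUE)
      b <- sample(1:8, sample(4:12, 1), replace = TRUE)
      res <- rank_sum_test(a, b)
      auc <- empirical_auc(c(a, b),
                           rep(c(TRUE, FALSE), c(length(a), length(b))))$auc
      expect_equal(res$auc, auc, tolerance = 1e-12)
    }
  })
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Spearman correlation matches hand-computed values", {
  expect_equal(rank_correlation(1:10, 1:10)$rho, 1)
  expect_equal(rank_correlation(1:10, 10:1)$rho, -1)
  # Sum d^2 = 4 over n = 4: rho = 1 - 6*4/(4*15) = 0.6
  res <- rank_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 1 - 6 * 4 / (4 * 15))
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:2, 1:2), "3")
})

test_that("paired change tests behave at the documented edge cases", {
  # n = 5 uniform positive shift: one-sided exact signed-rank p = 1/32
  base <- c(1, 2, 3, 4, 5)
  res <- paired_change_test(base, base + c(0.5, 0.6, 0.7, 0.8, 0.9),
                            alternative = "greater")
  sr <- res[res$test == "signed-rank", ]
  expect_equal(sr$p_value, 1 / 32)

  same <- paired_change_test(base, base)
  expect_equal(same$statistic[same$test == "paired-t"], 0)
  expect_equal(same$p_value[same$test == "paired-t"], 1)
  expect_error(paired_change_test(1:3, 1:2), "unpaired")
  expect_error(paired_change_test(1, 2), "at least 2")
})

test_that("a planted decline is detected with high power", {
  # 12-month shift +0.16 with noise SD 0.05 at n = 62, alpha = 0.003
  reject <- withr::with_seed(2025L, vapply(1:100, function(i) {
    b <- rnorm(62, 0.7, 0.29)
    m <- b + 0.16 + rnorm(62, 0, 0.05)
    res <- paired_change_test(b, m, alternative = "greater")
    res$p_value[res$test == "paired-t"] < 0.003
  }, logical(1)))
  expect_gte(mean(reject), 0.95)
})

test_that("rate ANOVA distinguishes groups with different mean rates", {
  withr::with_seed(12L, {
    rates <- c(rnorm(60, 0.16, 0.1), rnorm(70, 0.07, 0.1),
               rnorm(80, 0.10, 0.1))
    grp <- rep(c("AD", "MCI", "CTL"), c(60, 70, 80))
  })
  res <- rate_anova(rates, grp)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$df1, 2)
  expect_error(rate_anova(rates, rep("AD", length(rates))), "2 groups")
})

test_that("APOE stratification z-scores and detects a planted effect", {
  make_mci <- function(seed, effect) {
    withr::with_seed(seed, {
      n <- 60L
      carrier <- rbinom(n, 1, 0.4)
      sev <- rnorm(n, 0.5, 0.2) + effect * carrier
      idx_b <- sev + rnorm(n, 0, 0.1)
      idx_m <- sev + 0.08 + rnorm(n, 0, 0.1)
      meta <- rbind(
        data.frame(subject_id = sprintf("M%02d", 1:n), timepoint = "baseline",
                   apoe_e4 = carrier, mmse = 27 - 2 * sev + rnorm(n, 0, 1),
                   cdr_sob = 1 + 2 * sev + rnorm(n, 0, 0.5),
                   adas1 = 5 + sev + rnorm(n, 0, 0.8)),
        data.frame(subject_id = sprintf("M%02d", 1:n), timepoint = "m12",
                   apoe_e4 = carrier, mmse = 26.5 - 2 * sev + rnorm(n, 0, 1),
                   cdr_sob = 1.4 + 2 * sev + rnorm(n, 0, 0.5),
                   adas1 = 5.2 + sev + rnorm(n, 0, 0.8)))
      idx <- data.frame(subject_id = rep(sprintf("M%02d", 1:n), 2),
                        timepoint = rep(c("baseline", "m12"), each = n),
                        index = c(idx_b, idx_m))
    })
    longit <- derive_longitudinal(idx)
    apoe_stratification(longit, meta)
  }
  res <- make_mci(1L, 0.5)
  # z-scored variables have mean 0, SD 1 over the MCI sample
  expect_lt(abs(mean(res$z$index)), 1e-12)
  expect_equal(stats::sd(res$z$index), 1)
  expect_equal(colMeans(res$z[c("mmse", "cdr_sob", "adas1")]),
               c(mmse = 0, cdr_sob = 0, adas1 = 0), tolerance = 1e-12)

  # planted +0.5 SD carrier effect: carrier median above non-carrier in >= 9/10 seeds
  wins <- vapply(1:10, function(s) {
    z <- make_mci(100L + s, 0.5)$z
    stats::median(z$index[z$apoe_e4 == 1]) >
      stats::median(z$index[z$apoe_e4 == 0])
  }, logical(1))
  expect_gte(sum(wins), 9L)

  # an empty stratum is an error
  longit0 <- derive_longitudinal(data.frame(
    subject_id = rep(c("x", "y"), each = 2),
    timepoint = rep(c("baseline", "m12"), 2), index = c(0.3, 0.4, 0.5, 0.6)))
  meta0 <- data.frame(subject_id = rep(c("x", "y"), 2),
                      timepoint = rep(c("baseline", "m12"), each = 2),
                      apoe_e4 = 1, mmse = 27, cdr_sob = 1, adas1 = 5)
  expect_error(apoe_stratification(longit0, meta0), "stratum")
})
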