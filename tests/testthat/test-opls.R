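test_that("OPLS with no orthogonal filtering reduces to one-component PLS1", {
  prob <- random_problem(seed = 31L)
  fit <- fit_opls(prob$X, prob$y, n_ortho = 0L)
  expect_equal(fit$fitted, pls1_nipals_fitted(prob$X, prob$y, 1L),
               tolerance = 1e-10)
})

test_that("OPLS(k ortho) training predictions equal PLS1(k+1) (oracle)", {
  for (seed in 1:6) {
    for (k in 0:3) {
      prob <- random_problem(n = 30L, p = 10L, seed = 300L + seed)
      fit <- fit_opls(prob$X, prob$y, n_ortho = k)
      expect_equal(fit$fitted, pls1_nipals_fitted(prob$X, prob$y, k + 1L),
                   tolerance = 1e-6,
                   label = sprintf("seed %d, k = %d", seed, k))
    }
  }
})

test_that("orthogonal components carry no class information", {
  for (seed in c(41L, 42L)) {
    prob <- random_problem(seed = seed)
    fit <- fit_opls(prob$X, prob$y, n_ortho = 3L)
    expect_equal(sqrt(sum(fit$w^2)), 1)
    for (i in seq_len(fit$n_ortho)) {
      expect_lt(abs(stats::cor(fit$ortho_scores[, i], prob$y)), 1e-8)
      expect_lt(abs(sum(fit$w * fit$W_o[, i])), 1e-8)
      expect_equal(sqrt(sum(fit$W_o[, i]^2)), 1)
    }
    # score vectors pairwise orthogonal (after centring)
    S <- cbind(fit$scores, fit$ortho_scores)
    Sc <- scale(S, scale = FALSE)
    G <- crossprod(Sc)
    expect_true(all(abs(G[upper.tri(G)]) < 1e-6))
  }
})

test_that("prediction is consistent and affine in the documented way", {
  prob <- random_problem(seed = 55L)
  fit <- fit_opls(prob$X, prob$y, n_ortho = 2L)
  # training rows reproduce training fitted values exactly
  expect_equal(predict(fit, prob$X), fit$fitted)
  # the grand mean (row of zeros) predicts y_mean when n_ortho = 0
  fit0 <- fit_opls(prob$X, prob$y, n_ortho = 0L)
  expect_equal(predict(fit0, matrix(0, 1, ncol(prob$X))), fit0$y_mean)
  # class centroids order correctly
  cen_ad <- colMeans(prob$X[prob$y == 1, ])
  cen_ctl <- colMeans(prob$X[prob$y == 0, ])
  expect_gt(predict(fit, rbind(cen_ad)), predict(fit, rbind(cen_ctl)))
  expect_error(predict(fit, matrix(0, 1, 3)), "mismatch")
})

test_that("degenerate fits are rejected", {
  prob <- random_problem(seed = 66L)
  expect_error(fit_opls(prob$X, rep(1, nrow(prob$X))), "single class")
  expect_error(fit_opls(prob$X, prob$y, n_ortho = 10L), "n_ortho")
  expect_error(fit_opls(prob$X[1:4, 1:3], c(0, 1, 0, 1), n_ortho = 3L),
               "n_ortho")
})

test_that("cross-validation satisfies the Q2 conventions", {
  prob <- random_problem(n = 42L, p = 8L, seed = 77L, signal = 3)
  cv <- cross_validate(prob$X, prob$y, n_ortho = 1L, k_folds = 7L, seed = 5L)
  # every subject in exactly one test fold, folds stratified
  expect_equal(sort(unique(cv$fold_assignment)), 1:7)
  expect_length(cv$fold_assignment, length(prob$y))
  for (k in 1:7) {
    expect_true(all(c(0, 1) %in% prob$y[cv$fold_assignment != k]))
  }
  # identity q2 = 1 - press/ssy, ssy the centred class-code variation
  expect_identical(cv$q2y, 1 - cv$press / cv$ssy)
  expect_equal(cv$ssy, sum((prob$y - mean(prob$y))^2))
  # strong signal: high q2; perfect predictions would give exactly 1,
  # mean predictions exactly 0
  expect_gt(cv$q2y, 0.5)
  expect_equal(1 - sum((prob$y - mean(prob$y))^2) / cv$ssy, 0)

  # determinism of the fold assignment
  cv2 <- cross_validate(prob$X, prob$y, n_ortho = 1L, k_folds = 7L, seed = 5L)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$q2y, cv2$q2y)

  # Q2 invariant to relabelling the classes 0 <-> 1
  cv_flip <- cross_validate(prob$X, 1 - prob$y, n_ortho = 1L, k_folds = 7L,
                            seed = 5L)
  expect_equal(cv_flip$q2y, cv$q2y, tolerance = 1e-10)
})

test_that("q2_significant applies the strict 0.05 rule", {
  expect_false(q2_significant(0.05))
  expect_true(q2_significant(0.051))
  expect_false(q2_significant(-0.3))
})

test_that("permuting class labels destroys Q2", {
  prob <- random_problem(n = 60L, p = 20L, seed = 88L, signal = 2)
  q2_perm <- withr::with_seed(99L, vapply(1:30, function(i) {
    cross_validate(prob$X, sample(prob$y), n_ortho = 0L, k_folds = 7L,
                   seed = i)$q2y
  }, numeric(1)))
  expect_lt(stats::median(q2_perm), 0.05)
  # while the true labelling is clearly significant
  expect_gt(cross_validate(prob$X, prob$y, n_ortho = 0L, k_folds = 7L,
                           seed = 1L)$q2y, 0.05)
})

test_that("variable importance finds a planted single-feature effect", {
  withr::with_seed(123L, {
    n <- 80L
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 15L), n, 15L,
                dimnames = list(NULL, paste0("f", 1:15)))
    X[, 7] <- X[, 7] + 2.5 * y
    X <- scale(X)
  })
  fit <- fit_opls(X, y, n_ortho = 1L)
  imp <- variable_importance(fit)
  expect_equal(imp$feature[1], "f7")
  expect_equal(imp$rank, seq_len(15L))
})

test_that("select_n_ortho picks a count in range and follows forward rule", {
  prob <- random_problem(n = 50L, p = 12L, seed = 101L, signal = 2)
  sel <- select_n_ortho(prob$X, prob$y, k_folds = 5L, seed = 3L,
                        max_ortho = 3L, scale = FALSE)
  expect_true(sel$n_ortho %in% 0:3)
  # the chosen k is the last strict improvement along the path
  path <- sel$q2y_path
  if (sel$n_ortho > 0L) {
    expect_true(all(diff(path[seq_len(sel$n_ortho + 1L)]) > 0))
  }
})
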