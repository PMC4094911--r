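#' Fit a two-class OPLS model (single predictive component)
#'
#' Orthogonal projections to latent structures for a single binary response.
#' The algorithm is the single-y O-PLS recursion: the predictive weight is
#' `w = X'y / ||X'y||`; each orthogonal component is extracted by taking the
#' loading of the current predictive score, removing its projection on `w`,
#' renormalising to get the orthogonal weight, and deflating `X` by the
#' resulting orthogonal score/loading pair. After `n_ortho` deflations a
#' single predictive component is fit on the filtered matrix, with an inner
#' regression scalar `b` mapping the predictive score to the class code.
#'
#' For a single response, deflation leaves `X'y` (and hence `w`) unchanged up
#' to scale, and the model's training predictions equal those of a
#' `(n_ortho + 1)`-component PLS1 regression on the same data — orthogonal
#' filtering redistributes, but never adds, predictive information.
#'
#' @param X numeric matrix, column-autoscaled (centred, unit variance).
#' @param y numeric vector of class codes, exactly two distinct values
#'   (canonically CTL = 0, AD = 1).
#' @param n_ortho number of orthogonal components (0 or more).
#' @param feature_names optional column names to store with the model.
#' @return object of class `opls` with fields `w`, `p` (predictive weight /
#'   loading), `b`, `y_mean`, `W_o`, `P_o` (p x n_ortho matrices), `n_ortho`,
#'   `r2y`, `fitted`, `scores` (training predictive score), `ortho_scores`,
#'   `features`. `q2y` is `NA` until filled by [cross_validate()].
#' @export
fit_opls <- function(X, y, n_ortho = 0L, feature_names = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2L) stop("y holds a single class; two classes required")
  if (length(unique(y)) > 2L) stop("y must be two-valued class codes")
  n_ortho <- as.integer(n_ortho)
  if (n_ortho < 0L) stop("n_ortho must be >= 0")
  if (n_ortho >= min(dim(X))) stop("n_ortho too large for the rank of X")

  y_mean <- mean(y)
  yc <- y - y_mean
  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X'y is numerically zero; no predictive direction")
  w <- w / nw

  p_dim <- ncol(X)
  W_o <- matrix(numeric(0), nrow = p_dim, ncol = 0L)
  P_o <- matrix(numeric(0), nrow = p_dim, ncol = 0L)
  T_o <- matrix(numeric(0), nrow = nrow(X), ncol = 0L)
  Xd <- X
  for (i in seq_len(n_ortho)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) {
      stop("n_ortho too large: no orthogonal variation left after ",
           i - 1L, " component(s)")
    }
    w_o <- w_o / nwo
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }

  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  fitted <- y_mean + b * t
  r2y <- 1 - sum((yc - b * t)^2) / sum(yc^2)

  structure(list(w = w, p = p, b = b, y_mean = y_mean,
                 W_o = W_o, P_o = P_o, n_ortho = n_ortho,
                 r2y = r2y, q2y = NA_real_,
                 fitted = fitted, scores = t, ortho_scores = T_o,
                 features = feature_names),
            class = "opls")
}

#' Predict the response for new observations
#'
#' Removes the orthogonal variation from each new row using the stored
#' orthogonal weight/loading pairs, projects the filtered row onto the
#' predictive weight, and maps the score through the inner regression:
#' `y_hat = y_mean + b * t`. The output is an unbounded real value.
#'
#' @param object fitted `opls` model.
#' @param newdata numeric matrix scaled with the *training*
#'   scaling parameters (same columns as the training matrix).
#' @param ... unused.
#' @return numeric vector of predicted class values.
#' @export
predict.opls <- function(object, newdata, ...) {
  sc <- opls_scores(object, newdata)
  unname(drop(object$y_mean + object$b * sc[, 1L]))
}

#' Compute predictive and orthogonal scores for new observations
#'
#' Applies the same orthogonal-filtering recursion used in training, so for
#' the training matrix the returned scores equal the stored training scores
#' exactly. Used by the hierarchical model, whose top level consumes block
#' scores.
#'
#' @param model fitted `opls` model.
#' @param X numeric matrix on the training-scaled feature space.
#' @return matrix with column 1 = predictive score `t_pred`, then one column
#'   per orthogonal component (`t_ortho1`, ...).
#' @export
opls_scores <- function(model, X) {
  stopifnot(inherits(model, "opls"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(model$w)) {
    stop("column count mismatch: model has ", length(model$w),
         " features, newdata has ", ncol(X))
  }
  n_o <- model$n_ortho
  T_o <- matrix(0, nrow = nrow(X), ncol = n_o)
  for (i in seq_len(n_o)) {
    t_o <- drop(X %*% model$W_o[, i])
    X <- X - tcrossprod(t_o, model$P_o[, i])
    T_o[, i] <- t_o
  }
  t <- drop(X %*% model$w)
  out <- cbind(t_pred = t, T_o)
  if (n_o > 0L) colnames(out) <- c("t_pred", paste0("t_ortho", seq_len(n_o)))
  out
}

#' Stratified k-fold cross-validation with Q2(Y)
#'
#' Folds are stratified by class and assigned deterministically from `seed`.
#' For each fold the autoscaler and the OPLS model are re-fit on the training
#' split only (no leakage), and held-out rows are predicted with the frozen
#' fold scaler. Pooled out-of-fold predictions give
#' `PRESS = sum((y - y_hat)^2)` and `Q2(Y) = 1 - PRESS/SSY` with
#' `SSY = sum((y - mean(y))^2)`, the total variation of the centred class
#' codes — so the mean predictor scores exactly 0.
#'
#' @param X numeric matrix of *unscaled* (but ICV-normalised, if applicable)
#'   features; per-fold autoscaling is internal. Set `scale = FALSE` if `X`
#'   is already scaled and per-fold re-scaling is not wanted.
#' @param y two-valued class codes.
#' @param n_ortho orthogonal component count passed to [fit_opls()].
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param scale re-fit the autoscaler inside each fold (default TRUE).
#' @return object of class `cv_result`: `fold_assignment`, `y_actual`,
#'   `y_predicted`, `press`, `ssy`, `q2y`.
#' @export
cross_validate <- function(X, y, n_ortho = 0L, k_folds = 7L, seed = 1L,
                           scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  k_folds <- as.integer(k_folds)
  if (k_folds < 2L) stop("k_folds must be >= 2")
  folds <- stratified_folds(y, k_folds, seed)
  y_pred <- rep(NA_real_, length(y))
  for (k in seq_len(k_folds)) {
    test <- folds == k
    if (length(unique(y[!test])) < 2L) {
      stop("training split for fold ", k, " lacks both classes")
    }
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (scale) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, stats::sd)
      if (any(sdv <= 0)) stop("constant feature inside fold ", k)
      Xtr <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sdv, "/")
      Xte <- sweep(sweep(Xte, 2L, mu, "-"), 2L, sdv, "/")
    }
    fit <- fit_opls(Xtr, y[!test], n_ortho = n_ortho)
    y_pred[test] <- predict(fit, Xte)
  }
  press <- sum((y - y_pred)^2)
  ssy <- sum((y - mean(y))^2)
  structure(list(fold_assignment = folds, y_actual = y, y_predicted = y_pred,
                 press = press, ssy = ssy, q2y = 1 - press / ssy),
            class = "cv_result")
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled under the seed and dealt round-robin across folds.
stratified_folds <- function(y, k_folds, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  folds
}

#' Is a cross-validated Q2(Y) value significant?
#'
#' Convention: Q2(Y) values strictly greater than 0.05 are regarded as
#' statistically significant evidence of class separation.
#'
#' @param q2y numeric.
#' @return logical.
#' @export
q2_significant <- function(q2y) {
  !is.na(q2y) & q2y > 0.05
}

#' Select the number of orthogonal components by forward CV
#'
#' Starting at 0 orthogonal components, one more is added while it increases
#' the cross-validated Q2(Y) (evaluated on the training set only), up to
#' `max_ortho`.
#'
#' @inheritParams cross_validate
#' @param max_ortho upper bound on orthogonal components (default 5).
#' @return list with `n_ortho` (the selected count) and `q2y_path` (Q2 for
#'   0..k components examined).
#' @export
select_n_ortho <- function(X, y, k_folds = 7L, seed = 1L, max_ortho = 5L,
                           scale = TRUE) {
  q2_path <- cross_validate(X, y, n_ortho = 0L, k_folds = k_folds,
                            seed = seed, scale = scale)$q2y
  best <- 0L
  for (k in seq_len(max_ortho)) {
    q2k <- tryCatch(
      cross_validate(X, y, n_ortho = k, k_folds = k_folds,
                     seed = seed, scale = scale)$q2y,
      error = function(e) -Inf)
    q2_path <- c(q2_path, q2k)
    if (q2k > q2_path[best + 1L]) best <- k else break
  }
  list(n_ortho = best, q2y_path = q2_path)
}

#' Rank features by discriminative importance
#'
#' Features are ranked by the absolute value of their predictive loading
#' `|p|`: the contribution of each (autoscaled) feature to the single
#' class-separating component.
#'
#' @param model fitted `opls` model (or hierarchical index model).
#' @param ... unused.
#' @return data.frame `feature`, `score`, `rank`, sorted by decreasing score.
#' @export
variable_importance <- function(model, ...) UseMethod("variable_importance")

#' @export
variable_importance.opls <- function(model, ...) {
  sc <- abs(model$p)
  feats <- model$features
  if (is.null(feats)) feats <- paste0("x", seq_along(sc))
  out <- data.frame(feature = feats, score = sc, stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.opls <- function(x, ...) {
  cat("OPLS model: 1 predictive +", x$n_ortho, "orthogonal component(s) on",
      length(x$w), "features\n")
  cat(sprintf("  R2Y = %.3f; Q2Y = %s\n", x$r2y,
              ifelse(is.na(x$q2y), "not cross-validated",
                     sprintf("%.3f", x$q2y))))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  k <- length(unique(x$fold_assignment))
  cat(sprintf("%d-fold CV: PRESS = %.4f, SSY = %.4f, Q2(Y) = %.4f (%s)\n",
              k, x$press, x$ssy, x$q2y,
              ifelse(q2_significant(x$q2y), "significant", "not significant")))
  invisible(x)
}
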