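#' Fit the two-block hierarchical severity-index model
#'
#' Cortical thickness measures and (ICV-normalised) subcortical volumes are
#' modelled separately: one OPLS discriminant model per block. The scores of
#' the two block models are pooled, autoscaled, and fed to a top-level OPLS
#' model whose predicted class value is the per-subject severity index. All
#' scaling parameters are frozen from the training set.
#'
#' Which block outputs feed the top model is configurable: `"all"` (default)
#' passes the predictive score plus every orthogonal score of each block;
#' `"predictive"` passes the two predictive scores only.
#'
#' @param train MorphometryTable of baseline AD and CTL subjects only (raw
#'   or ICV-normalised; must contain the 57 canonical features and `icv`).
#' @param y class codes, CTL = 0 and AD = 1.
#' @param n_ortho `"auto"` (forward CV selection per block, 0..`max_ortho`)
#'   or a fixed integer used for both blocks.
#' @param n_ortho_top same, for the top model.
#' @param block_scores `"all"` or `"predictive"`.
#' @param k_folds folds for the auto selection CV.
#' @param max_ortho cap for auto selection.
#' @param seed seed for the auto-selection fold assignment.
#' @return object of class `hier_index_model`: `scaler` (feature
#'   autoscaling), `thickness_block`, `volume_block`, `score_names`,
#'   `score_scaler` (mean/sd of the pooled block scores),
#'   `top_model`, `partition`, `config`.
#' @export
fit_hierarchical <- function(train, y, n_ortho = "auto", n_ortho_top = "auto",
                             block_scores = c("all", "predictive"),
                             k_folds = 7L, max_ortho = 5L, seed = 1L) {
  block_scores <- match.arg(block_scores)
  y <- as.numeric(y)
  if ("dx" %in% names(train) && !all(train$dx %in% c("AD", "CTL"))) {
    stop("training table contains non-AD/CTL rows (e.g. MCI); ",
         "the discriminant is trained on baseline AD vs CTL only")
  }
  if ("timepoint" %in% names(train) && !all(train$timepoint == "baseline")) {
    stop("training table contains follow-up rows; train on baseline only")
  }
  th <- thickness_features()
  vol <- volume_features()
  missing <- setdiff(c(th, vol), names(train))
  if (length(missing)) {
    stop("training table does not match the canonical feature partition; ",
         "missing: ", paste(missing, collapse = ", "))
  }
  scaler <- fit_scaler(train, provenance = "baseline AD vs CTL training set")
  Xs <- apply_scaler(scaler, train)

  fit_block <- function(cols, tag, seed_off) {
    Xb <- Xs[, cols, drop = FALSE]
    k <- if (identical(n_ortho, "auto")) {
      select_n_ortho(Xb, y, k_folds = k_folds, seed = seed + seed_off,
                     max_ortho = max_ortho, scale = FALSE)$n_ortho
    } else as.integer(n_ortho)
    fit_opls(Xb, y, n_ortho = k, feature_names = cols)
  }
  th_model <- fit_block(th, "thickness", 101L)
  vol_model <- fit_block(vol, "volume", 202L)

  S <- cbind(block_score_matrix(th_model, Xs[, th, drop = FALSE],
                                "thickness", block_scores),
             block_score_matrix(vol_model, Xs[, vol, drop = FALSE],
                                "volume", block_scores))
  s_mean <- colMeans(S)
  s_sd <- apply(S, 2L, stats::sd)
  if (any(s_sd <= 0)) stop("degenerate block score (zero variance)")
  Ss <- sweep(sweep(S, 2L, s_mean, "-"), 2L, s_sd, "/")

  k_top <- if (identical(n_ortho_top, "auto")) {
    max_top <- max(0L, min(as.integer(max_ortho), ncol(Ss) - 1L))
    if (max_top > 0L) {
      select_n_ortho(Ss, y, k_folds = k_folds, seed = seed + 303L,
                     max_ortho = max_top, scale = FALSE)$n_ortho
    } else 0L
  } else as.integer(n_ortho_top)
  top <- fit_opls(Ss, y, n_ortho = k_top, feature_names = colnames(Ss))

  structure(list(scaler = scaler,
                 thickness_block = th_model, volume_block = vol_model,
                 score_names = colnames(S),
                 score_scaler = list(mean = s_mean, sd = s_sd),
                 top_model = top,
                 partition = list(thickness = th, volume = vol),
                 config = list(block_scores = block_scores,
                               n_ortho = n_ortho, n_ortho_top = n_ortho_top,
                               k_folds = k_folds, max_ortho = max_ortho,
                               seed = seed)),
            class = "hier_index_model")
}

block_score_matrix <- function(model, Xb, tag, block_scores) {
  S <- opls_scores(model, Xb)
  if (block_scores == "predictive") S <- S[, 1L, drop = FALSE]
  colnames(S) <- paste0(tag, "_", c("t_pred",
                                    paste0("t_ortho",
                                           seq_len(ncol(S) - 1L)))[seq_len(ncol(S))])
  S
}

# Index for rows already on the training-scaled 57-feature space.
.index_from_scaled <- function(model, Xs) {
  th <- model$partition$thickness
  vol <- model$partition$volume
  S <- cbind(block_score_matrix(model$thickness_block,
                                Xs[, th, drop = FALSE], "thickness",
                                model$config$block_scores),
             block_score_matrix(model$volume_block,
                                Xs[, vol, drop = FALSE], "volume",
                                model$config$block_scores))
  Ss <- sweep(sweep(S, 2L, model$score_scaler$mean, "-"),
              2L, model$score_scaler$sd, "/")
  predict(model$top_model, Ss)
}

#' Compute the severity index for every row of a morphometry table
#'
#' ICV-normalises, applies the frozen training scaler, pushes each row
#' through both block models and the top model; the index is the top model's
#' predicted class value — close to 1 for AD-like and 0 for CTL-like
#' morphometry, unbounded and deliberately not clipped. Rows with index
#' strictly above 0.5 are labelled `AD-like`, all others `CTL-like`.
#'
#' @param model a `hier_index_model`.
#' @param table morphometry data.frame with the 57 features and `icv`
#'   (`subject_id`/`timepoint` carried through when present).
#' @return data.frame `subject_id`, `timepoint`, `index`, `pattern`.
#' @export
compute_index <- function(model, table) {
  stopifnot(inherits(model, "hier_index_model"))
  Xs <- apply_scaler(model$scaler, table)
  idx <- .index_from_scaled(model, Xs)
  data.frame(
    subject_id = if ("subject_id" %in% names(table)) table$subject_id
                 else sprintf("row%04d", seq_len(nrow(table))),
    timepoint = if ("timepoint" %in% names(table)) table$timepoint
                else NA_character_,
    index = idx,
    pattern = pattern_label(idx),
    stringsAsFactors = FALSE)
}

#' Label an index value as AD-like or CTL-like
#'
#' Strictly above the 0.5 cut is AD-like; 0.5 itself is CTL-like.
#'
#' @param index numeric vector of index values.
#' @param threshold decision cut (default 0.5).
#' @return character vector, `"AD-like"` / `"CTL-like"`.
#' @export
pattern_label <- function(index, threshold = 0.5) {
  ifelse(index > threshold, "AD-like", "CTL-like")
}

#' Per-feature coefficients of the fitted hierarchical index
#'
#' The whole hierarchy is linear in the autoscaled features, so the index is
#' an affine function `index = c0 + sum_j beta_j x_j`. The coefficients are
#' extracted exactly by pushing the identity basis through the model.
#'
#' @param object a `hier_index_model`.
#' @param ... unused.
#' @return named numeric vector `beta` over the 57 features, with attribute
#'   `intercept`.
#' @export
coef.hier_index_model <- function(object, ...) {
  feats <- object$scaler$features
  p <- length(feats)
  base <- .index_from_scaled(object, matrix(0, 1L, p,
                                            dimnames = list(NULL, feats)))
  I <- diag(p)
  colnames(I) <- feats
  beta <- .index_from_scaled(object, I) - base
  names(beta) <- feats
  attr(beta, "intercept") <- base
  beta
}

#' @export
#' @describeIn variable_importance hierarchical model: per-feature importance
#'   propagates the class-separating direction only — each feature's absolute
#'   predictive loading within its block, weighted by the top model's
#'   absolute predictive loading on that block's predictive score (the
#'   block's orthogonal scores carry no class information by construction
#'   and are excluded). For the exact linear map of the index on the
#'   features, including orthogonal filtering, see [coef.hier_index_model()].
variable_importance.hier_index_model <- function(model, ...) {
  top_p <- stats::setNames(abs(model$top_model$p), model$top_model$features)
  block_weight <- c(thickness = unname(top_p["thickness_t_pred"]),
                    volume = unname(top_p["volume_t_pred"]))
  score <- c(abs(model$thickness_block$p) * block_weight["thickness"],
             abs(model$volume_block$p) * block_weight["volume"])
  out <- data.frame(feature = c(model$partition$thickness,
                                model$partition$volume),
                    score = unname(score), stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cross-validate the full hierarchical pipeline
#'
#' Stratified k-fold CV in which the complete hierarchy — feature scaler,
#' both block models (with their configured orthogonal-component policy) and
#' the top model — is re-fit on each training split, avoiding any leakage of
#' test-set scaling or score statistics. Pooled out-of-fold indices give
#' PRESS, SSY and Q2(Y) under the same conventions as [cross_validate()].
#'
#' @param train training MorphometryTable (baseline AD and CTL rows).
#' @param y class codes CTL = 0, AD = 1.
#' @param k_folds number of folds (default 7).
#' @param seed fold-assignment seed.
#' @param ... passed to [fit_hierarchical()] for each fold (e.g. `n_ortho`).
#' @return a `cv_result` whose `y_predicted` are out-of-fold indices.
#' @export
cross_validate_hierarchical <- function(train, y, k_folds = 7L, seed = 1L,
                                        ...) {
  y <- as.numeric(y)
  folds <- stratified_folds(y, k_folds, seed)
  y_pred <- rep(NA_real_, length(y))
  for (k in seq_len(k_folds)) {
    test <- folds == k
    if (length(unique(y[!test])) < 2L) {
      stop("training split for fold ", k, " lacks both classes")
    }
    fit <- fit_hierarchical(train[!test, , drop = FALSE], y[!test],
                            seed = seed + k, ...)
    y_pred[test] <- compute_index(fit, train[test, , drop = FALSE])$index
  }
  press <- sum((y - y_pred)^2)
  ssy <- sum((y - mean(y))^2)
  structure(list(fold_assignment = folds, y_actual = y, y_predicted = y_pred,
                 press = press, ssy = ssy, q2y = 1 - press / ssy),
            class = "cv_result")
}

#' @export
print.hier_index_model <- function(x, ...) {
  cat("Hierarchical severity-index model\n")
  cat("  thickness block:", length(x$partition$thickness), "features,",
      x$thickness_block$n_ortho, "orthogonal component(s)\n")
  cat("  volume block:   ", length(x$partition$volume), "features,",
      x$volume_block$n_ortho, "orthogonal component(s)\n")
  cat("  top model:", length(x$score_names), "block scores (",
      x$config$block_scores, "),", x$top_model$n_ortho,
      "orthogonal component(s)\n")
  invisible(x)
}
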