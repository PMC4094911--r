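#' Average left/right hemisphere measures into bilateral features
#'
#' FreeSurfer reports paired structures once per hemisphere (here as
#' `lh_<feature>` / `rh_<feature>` columns) and midline structures once.
#' Paired features are replaced by their arithmetic mean; midline features
#' pass through unchanged. Non-feature columns (ids, metadata, `icv`) pass
#' through untouched.
#'
#' @param raw data.frame with `lh_`/`rh_` columns for every paired feature
#'   and plain columns for midline features.
#' @return data.frame with the 57 canonical bilateral feature columns.
#' @export
average_hemispheres <- function(raw) {
  stopifnot(is.data.frame(raw))
  reg <- feature_registry()
  out <- raw[, setdiff(names(raw), c(paste0("lh_", reg$feature),
                                     paste0("rh_", reg$feature),
                                     reg$feature)), drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    f <- reg$feature[i]
    if (reg$paired[i]) {
      lh <- paste0("lh_", f); rh <- paste0("rh_", f)
      missing <- c(lh, rh)[!c(lh, rh) %in% names(raw)]
      if (length(missing)) {
        stop("missing hemisphere column(s) for paired feature '", f, "': ",
             paste(missing, collapse = ", "))
      }
      out[[f]] <- (raw[[lh]] + raw[[rh]]) / 2
    } else {
      if (!f %in% names(raw)) stop("missing midline feature column '", f, "'")
      out[[f]] <- raw[[f]]
    }
  }
  out
}

#' Normalise volumetric features by intracranial volume
#'
#' Each of the 23 volume features is divided by the subject's estimated
#' intracranial volume (`icv`, mm^3), yielding dimensionless fractions;
#' cortical thickness features are left untouched. Normalisation is
#' idempotent per table: a table already flagged as normalised is returned
#' as-is.
#'
#' @param table morphometry data.frame containing the 57 features and `icv`.
#' @return the table with volume columns replaced by volume/ICV and attribute
#'   `icv_normalised = TRUE`.
#' @export
normalize_icv <- function(table) {
  if (isTRUE(attr(table, "icv_normalised"))) return(table)
  if (!"icv" %in% names(table)) stop("column 'icv' is absent")
  if (any(!is.finite(table$icv)) || any(table$icv <= 0)) {
    stop("icv must be positive and finite for every row")
  }
  for (f in volume_features()) {
    if (!f %in% names(table)) stop("missing volume feature '", f, "'")
    table[[f]] <- table[[f]] / table$icv
  }
  attr(table, "icv_normalised") <- TRUE
  table
}

#' Fit frozen autoscaling parameters on a training table
#'
#' Computes per-feature mean and sample SD (n-1 denominator) after ICV
#' normalisation. These training statistics are frozen: [apply_scaler()]
#' re-applies them to any new table and never re-estimates.
#'
#' @param train morphometry data.frame (ICV-normalised or raw; raw tables are
#'   normalised internally first).
#' @param provenance free-text tag recording what the training set was.
#' @return object of class `scaling_params` with fields `features`, `mean`,
#'   `sd`, `icv_normalised` (the volume feature names), `provenance`.
#' @export
fit_scaler <- function(train, provenance = "training") {
  train <- normalize_icv(train)
  feats <- feature_names()
  missing <- setdiff(feats, names(train))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  if (nrow(train) < 2L) stop("need at least 2 rows to fit a scaler")
  X <- as.matrix(train[, feats, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    stop("constant feature(s): ",
         paste(feats[sdv <= 0 | !is.finite(sdv)], collapse = ", "))
  }
  structure(list(features = feats, mean = mu, sd = sdv,
                 icv_normalised = volume_features(),
                 provenance = provenance),
            class = "scaling_params")
}

#' Apply frozen scaling parameters
#'
#' Returns `(x - mean)/sd` per feature using the training statistics stored
#' in `params`. The input table is ICV-normalised first if it has not been
#' already. The feature set must match the training feature set exactly.
#'
#' @param params a `scaling_params` object from [fit_scaler()].
#' @param table morphometry data.frame.
#' @return numeric matrix (rows = table rows, columns = training features).
#' @export
apply_scaler <- function(params, table) {
  stopifnot(inherits(params, "scaling_params"))
  table <- normalize_icv(table)
  have <- intersect(names(table), feature_names())
  extra <- setdiff(have, params$features)
  missing <- setdiff(params$features, names(table))
  if (length(missing) || length(extra)) {
    stop("feature-set mismatch; missing: {",
         paste(missing, collapse = ", "), "}; unexpected: {",
         paste(extra, collapse = ", "), "}")
  }
  X <- as.matrix(table[, params$features, drop = FALSE])
  sweep(sweep(X, 2L, params$mean, "-"), 2L, params$sd, "/")
}

#' Invert frozen scaling
#'
#' Back-transforms a scaled matrix to the ICV-normalised feature scale:
#' `x * sd + mean`.
#'
#' @param params a `scaling_params` object.
#' @param X scaled numeric matrix with the training feature columns.
#' @return matrix on the ICV-normalised scale.
#' @export
invert_scaler <- function(params, X) {
  stopifnot(inherits(params, "scaling_params"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$features)) stop("column count mismatch")
  sweep(sweep(X, 2L, params$sd, "*"), 2L, params$mean, "+")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("Frozen autoscaling over", length(x$features), "features (",
      length(x$icv_normalised), "ICV-normalised volumes );",
      "provenance:", x$provenance, "\n")
  invisible(x)
}
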