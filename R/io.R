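#' Read a morphometry TSV into a validated, canonically-ordered table
#'
#' The file must carry `subject_id`, `timepoint`, the 57 canonical feature
#' columns and `icv`; metadata columns (`dx`, `mci_status`, `apoe_e4`,
#' `age`, `mmse`, `cdr_sob`, `adas1`) are optional. Column order in the file
#' is irrelevant: the table is returned in canonical order. Errors name
#' missing/unknown feature columns, duplicated subject x timepoint rows,
#' non-numeric feature values and unknown diagnosis codes.
#'
#' @param path TSV path.
#' @return data.frame in canonical column order.
#' @export
read_morphometry <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_morphometry(raw, context = path)
}

#' @rdname read_morphometry
#' @param table in-memory data.frame to validate instead of a file.
#' @param context label used in error messages.
#' @export
validate_morphometry <- function(table, context = "morphometry table") {
  feats <- feature_names()
  required <- c("subject_id", "timepoint", feats, "icv")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop(context, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  known <- c(required, .meta_columns)
  unknown <- setdiff(names(table), known)
  if (length(unknown)) {
    stop(context, ": unknown column(s): ", paste(unknown, collapse = ", "))
  }
  for (f in c(feats, "icv")) {
    if (!is.numeric(table[[f]])) {
      stop(context, ": non-numeric values in feature column '", f, "'")
    }
  }
  if (anyDuplicated(table[, c("subject_id", "timepoint")])) {
    stop(context, ": duplicated subject x timepoint rows")
  }
  bad_tp <- setdiff(unique(table$timepoint), .timepoints)
  if (length(bad_tp)) {
    stop(context, ": unknown timepoint label(s): ",
         paste(bad_tp, collapse = ", "))
  }
  if ("dx" %in% names(table)) {
    bad_dx <- setdiff(unique(table$dx), c("AD", "MCI", "CTL"))
    if (length(bad_dx)) {
      stop(context, ": unknown diagnosis code(s): ",
           paste(bad_dx, collapse = ", "))
    }
  }
  ord <- c("subject_id", "timepoint",
           intersect(.meta_columns, names(table)), feats, "icv")
  table[, unique(ord), drop = FALSE]
}

#' Write a morphometry table (or a synthetic cohort) as TSV
#'
#' @param table data.frame or `synthetic_cohort`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_morphometry <- function(table, path) {
  if (inherits(table, "synthetic_cohort")) table <- table$data
  table <- validate_morphometry(table, context = "table to write")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a fitted hierarchical index model as JSON
#'
#' All weights, loadings, scaling statistics and configuration are written
#' as JSON arrays at full double precision; [read_index_model()] restores a
#' model whose predictions match the original to numerical precision.
#'
#' @param model a `hier_index_model`.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_index_model <- function(model, path) {
  stopifnot(inherits(model, "hier_index_model"))
  ser_opls <- function(m) {
    list(w = unname(m$w), p = unname(m$p), b = m$b, y_mean = m$y_mean,
         W_o = unname(as.matrix(m$W_o)), P_o = unname(as.matrix(m$P_o)),
         n_ortho = m$n_ortho, r2y = m$r2y, q2y = m$q2y,
         features = m$features)
  }
  payload <- list(
    format = "adindex-hier-model",
    version = 1L,
    scaler = list(features = model$scaler$features,
                  mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd),
                  icv_normalised = model$scaler$icv_normalised,
                  provenance = model$scaler$provenance),
    thickness_block = ser_opls(model$thickness_block),
    volume_block = ser_opls(model$volume_block),
    score_names = model$score_names,
    score_scaler = list(mean = unname(model$score_scaler$mean),
                        sd = unname(model$score_scaler$sd)),
    top_model = ser_opls(model$top_model),
    config = model$config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "adindex-hier-model")) {
    stop("not an adindex model file: ", path)
  }
  de_opls <- function(m) {
    p_dim <- length(m$w)
    W_o <- matrix(as.numeric(m$W_o), nrow = p_dim)
    P_o <- matrix(as.numeric(m$P_o), nrow = p_dim)
    structure(list(w = as.numeric(m$w), p = as.numeric(m$p), b = m$b,
                   y_mean = m$y_mean, W_o = W_o, P_o = P_o,
                   n_ortho = as.integer(m$n_ortho), r2y = m$r2y,
                   q2y = if (is.null(m$q2y)) NA_real_ else m$q2y,
                   fitted = NULL, scores = NULL, ortho_scores = NULL,
                   features = m$features),
              class = "opls")
  }
  scaler <- structure(list(features = payload$scaler$features,
                           mean = stats::setNames(payload$scaler$mean,
                                                  payload$scaler$features),
                           sd = stats::setNames(payload$scaler$sd,
                                                payload$scaler$features),
                           icv_normalised = payload$scaler$icv_normalised,
                           provenance = payload$scaler$provenance),
                      class = "scaling_params")
  structure(list(scaler = scaler,
                 thickness_block = de_opls(payload$thickness_block),
                 volume_block = de_opls(payload$volume_block),
                 score_names = payload$score_names,
                 score_scaler = list(
                   mean = stats::setNames(payload$score_scaler$mean,
                                          payload$score_names),
                   sd = stats::setNames(payload$score_scaler$sd,
                                        payload$score_names)),
                 top_model = de_opls(payload$top_model),
                 partition = list(thickness = thickness_features(),
                                  volume = volume_features()),
                 config = payload$config),
            class = "hier_index_model")
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults of
#' [run_pipeline()].
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("input_tsv", "cohort", "k_folds", "n_ortho", "n_ortho_top",
             "block_scores", "threshold", "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}
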