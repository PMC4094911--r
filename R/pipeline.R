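#' Run the full severity-index pipeline
#'
#' Orchestrates the analysis end-to-end in the canonical order:
#' (1) obtain a cohort table (generate synthetically from `config$cohort`,
#' or read `config$input_tsv`); (2) preprocess and fit the hierarchical
#' AD-vs-CTL model on baseline AD/CTL rows only — any attempt to train on
#' MCI rows is a hard error; (3) cross-validate the full hierarchy;
#' (4) compute the index for every subject x timepoint; (5) emit the
#' Table-5-style classification/prediction report; (6) derive longitudinal
#' quantities and group comparisons. All artifacts are written under
#' `config$output_dir` together with a machine-readable run manifest.
#'
#' @param config named list (see [read_run_config()]): either `cohort` (a
#'   list of [cohort_spec()] arguments) or `input_tsv`; plus optional
#'   `k_folds` (7), `n_ortho` ("auto"), `n_ortho_top` ("auto"),
#'   `block_scores` ("all"), `threshold` (0.5), `seed` (1), `output_dir`.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with `data`, `model`, `cv`, `indices`, `report`,
#'   `longitudinal`, `comparisons`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  k_folds <- config$k_folds %||% 7L
  n_ortho <- config$n_ortho %||% "auto"
  n_ortho_top <- config$n_ortho_top %||% "auto"
  block_scores <- config$block_scores %||% "all"
  threshold <- config$threshold %||% 0.5
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% tempfile("adindex_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)

  # stage 1: data
  if (!is.null(config$input_tsv)) {
    say("reading cohort from ", config$input_tsv)
    data <- read_morphometry(config$input_tsv)
  } else {
    spec_args <- config$cohort %||% list()
    if (is.null(spec_args$seed)) spec_args$seed <- seed
    spec <- do.call(cohort_spec, spec_args)
    say("generating synthetic cohort (seed ", spec$seed, ")")
    data <- generate_cohort(spec)$data
    write_morphometry(data, file.path(out_dir, "cohort.tsv"))
  }
  if (!"dx" %in% names(data)) stop("stage data: cohort table lacks 'dx'")

  # stage 2: training subset and model
  train <- training_subset(data)
  n_mci_train <- sum(train$table$dx == "MCI")
  if (n_mci_train > 0L) {
    stop("stage fit: ", n_mci_train, " MCI row(s) in the training set; ",
         "training is baseline AD vs CTL only")
  }
  say("training rows: ", sum(train$y == 1), " AD vs ",
      sum(train$y == 0), " CTL")
  model <- fit_hierarchical(train$table, train$y, n_ortho = n_ortho,
                            n_ortho_top = n_ortho_top,
                            block_scores = block_scores,
                            k_folds = k_folds, seed = seed)
  write_index_model(model, file.path(out_dir, "model.json"))

  # stage 3: cross-validation of the full hierarchy
  say("cross-validating (", k_folds, " folds)")
  cv <- cross_validate_hierarchical(train$table, train$y, k_folds = k_folds,
                                    seed = seed, n_ortho = n_ortho,
                                    n_ortho_top = n_ortho_top,
                                    block_scores = block_scores)
  model$top_model$q2y <- cv$q2y
  say(sprintf("Q2(Y) = %.3f (%s)", cv$q2y,
              ifelse(q2_significant(cv$q2y), "significant",
                     "not significant")))

  # stage 4: index for every subject x timepoint
  indices <- compute_index(model, data)
  utils::write.table(indices, file.path(out_dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage 5: classification / prediction report
  meta <- unique(data[, intersect(c("subject_id", "dx", "mci_status"),
                                  names(data))])
  cv_index <- data.frame(subject_id = train$table$subject_id,
                         index = cv$y_predicted)
  report <- classification_report(indices, meta, cv_index = cv_index,
                                  threshold = threshold)
  utils::write.table(report, file.path(out_dir, "classification_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 6: longitudinal analysis
  longit <- suppressMessages(derive_longitudinal(indices))
  longit <- merge(longit, meta, by = "subject_id")
  utils::write.table(longit, file.path(out_dir, "longitudinal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparisons <- list(
    summary = group_summary(longit$average_index, longit$dx),
    rate_anova = rate_anova(longit$annual_rate, longit$dx))
  mci <- longit[longit$dx == "MCI", ]
  if (nrow(mci) > 1L && "apoe_e4" %in% names(data) &&
      length(unique(data$apoe_e4[data$dx == "MCI"])) > 1L) {
    comparisons$apoe <- tryCatch(
      apoe_stratification(mci, data[data$dx == "MCI", ])$tests,
      error = function(e) NULL)
  }
  utils::write.table(comparisons$summary,
                     file.path(out_dir, "group_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # manifest: config hash + seeds + versions, enough to re-execute the run
  cfg_norm <- list(cohort = config$cohort, input_tsv = config$input_tsv,
                   k_folds = k_folds, n_ortho = n_ortho,
                   n_ortho_top = n_ortho_top, block_scores = block_scores,
                   threshold = threshold, seed = seed)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_norm, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "adindex",
    package_version = as.character(utils::packageVersion("adindex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg_norm,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    n_rows = nrow(data),
    n_train = length(train$y),
    q2y = cv$q2y)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("artifacts written to ", out_dir)

  invisible(list(data = data, model = model, cv = cv, indices = indices,
                 report = report, longitudinal = longit,
                 comparisons = comparisons, manifest = manifest,
                 output_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
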