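#' Pipeline configuration
#'
#' Bundles every stage setting of the simulate/decompose/select/
#' featurize/classify pipeline. When `input` is `NULL` the synthetic
#' generator supplies the dataset; otherwise segments are read from disk.
#'
#' @param decomposer `"emd"`, `"eemd"`, `"dwt"` or `"raw"`.
#' @param sift a [sift_config()].
#' @param generator a [generator_config()].
#' @param selection_k number of IMFs chosen by the histogram consensus.
#' @param feature_groups subset of `c("time", "spectral", "nonlinear")`.
#' @param classifiers subset of the four supported classifier names.
#' @param cv_folds number of cross-validation folds.
#' @param seed master seed; generator, EEMD noise and fold assignment
#'   seeds all derive from it.
#' @param input optional input path for [read_segments()].
#' @param input_format `"delimited"` or `"edf"`.
#' @param output_dir directory for the report bundle (`NULL` = don't
#'   write files).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(decomposer = c("emd", "eemd", "dwt", "raw"),
                            sift = NULL, generator = NULL, selection_k = 3,
                            feature_groups = c("time", "spectral", "nonlinear"),
                            classifiers = c("svm", "knn", "naive_bayes",
                                            "logistic_regression"),
                            cv_folds = 5, seed = 1, input = NULL,
                            input_format = "delimited", output_dir = NULL) {
  decomposer <- match.arg(decomposer)
  feature_groups <- match.arg(feature_groups,
                              c("time", "spectral", "nonlinear"),
                              several.ok = TRUE)
  classifiers <- match.arg(classifiers,
                           c("svm", "knn", "naive_bayes",
                             "logistic_regression"), several.ok = TRUE)
  seed <- as.integer(seed)
  structure(list(decomposer = decomposer,
                 sift = sift %||% sift_config(seed = child_seed(seed, 2)),
                 generator = generator %||%
                   generator_config(seed = child_seed(seed, 1)),
                 selection_k = as.integer(selection_k),
                 feature_groups = feature_groups, classifiers = classifiers,
                 cv_folds = as.integer(cv_folds), seed = seed,
                 input = input, input_format = input_format,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Chains the stages: obtain segments (synthetic or from disk),
#' decompose each one (EMD/EEMD; skipped for the DWT and raw paths),
#' build the ranking matrix and select IMFs by histogram consensus,
#' assemble one feature table per requested feature group (plus the
#' combined concatenation when more than one group is requested), and
#' cross-validate every configured classifier on every table. When
#' `config$output_dir` is set, the ranking matrix, selection histogram,
#' feature tables, cross-validation results and a run log are written
#' there as delimited text and JSON.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list) with elements `segments` (count),
#'   `selection`, `feature_tables`, `cv_results` (nested by feature
#'   group then classifier) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  segments <- if (is.null(config$input)) generate_dataset(config$generator)
    else read_segments(config$input, config$input_format)

  selection <- NULL
  decomps <- NULL
  if (config$decomposer %in% c("emd", "eemd")) {
    dec_fun <- if (config$decomposer == "emd") emd else eemd
    decomps <- lapply(segments, function(s)
      dec_fun(as.vector(s$data[1, ]), config$sift))
    rm_ <- build_ranking_matrix(segments, config$decomposer, config$sift,
                                decompositions = decomps)
    selection <- consensus_select(rm_, k = config$selection_k)
  } else rm_ <- NULL

  comp_kind <- switch(config$decomposer, emd = "imf", eemd = "imf",
                      dwt = "dwt", raw = "raw")
  groups <- config$feature_groups
  tables <- lapply(groups, function(g)
    build_feature_table(segments, comp_kind, g, decompositions = decomps,
                        selected = if (is.null(selection)) 1:3
                                   else selection$selected))
  names(tables) <- groups
  if (length(groups) > 1) {
    comb <- tables[[1]]
    for (g in groups[-1]) {
      stopifnot(identical(comb$labels, tables[[g]]$labels))
      comb$values <- cbind(comb$values, tables[[g]]$values)
      comb$feature_names <- c(comb$feature_names, tables[[g]]$feature_names)
    }
    tables$combined <- comb
  }

  cv_results <- lapply(tables, function(tb) {
    res <- lapply(config$classifiers, function(cl)
      cross_validate(tb, cl, folds = config$cv_folds,
                     seed = child_seed(config$seed, 3)))
    names(res) <- config$classifiers
    res
  })

  report <- list(segments = length(segments), ranking_matrix = rm_,
                 selection = selection, feature_tables = tables,
                 cv_results = cv_results, config = config)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$ranking_matrix)) {
    rm_ <- report$ranking_matrix
    utils::write.table(cbind(rm_$row_meta, rm_$rows),
                       file.path(dir, "ranking_matrix.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(histogram = as.list(report$selection$histogram),
                              selected = report$selection$selected),
                         file.path(dir, "selection.json"), auto_unbox = TRUE)
  }
  for (g in names(report$feature_tables)) {
    tb <- report$feature_tables[[g]]
    df <- data.frame(tb$row_meta, label = tb$labels, tb$values,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("features_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summ <- lapply(report$cv_results, function(by_clf)
    lapply(by_clf, function(r)
      c(as.list(round(r$mean_metrics, 4)), folds = r$folds)))
  jsonlite::write_json(summ, file.path(dir, "cv_results.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(sprintf("decomposer: %s", report$config$decomposer),
           sprintf("seed: %d", report$config$seed),
           sprintf("segments: %d", report$segments),
           sprintf("feature groups: %s",
                   paste(report$config$feature_groups, collapse = ", ")),
           sprintf("classifiers: %s",
                   paste(report$config$classifiers, collapse = ", ")),
           sprintf("cv folds: %d", report$config$cv_folds),
           sprintf("sift: max_imfs=%d max_sift_iterations=%d sd_threshold=%g ensemble_size=%d noise_fraction=%g",
                   report$config$sift$max_imfs,
                   report$config$sift$max_sift_iterations,
                   report$config$sift$sd_threshold,
                   report$config$sift$ensemble_size,
                   report$config$sift$noise_fraction),
           sprintf("dropped rows: %s",
                   paste(vapply(report$feature_tables,
                                function(tb) length(tb$dropped), 0L),
                         collapse = ", ")))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
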