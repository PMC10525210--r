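#' Classifier-wise results table
#'
#' One row per (feature matrix, selector) prediction vector, in pipeline
#' order, with cross-validated accuracy in percent (2 decimals) and the best
#' row flagged — the layout of a classifier-wise results table.
#'
#' @param fit An `asnet` object.
#' @param path Optional CSV output path.
#' @return Data frame: `no`, `backbone`, `layer`, `selector`, `accuracy`, `best`.
#' @export
classifier_table <- function(fit, path = NULL) {
  if (length(fit$predictions) == 0L) stop("empty result")
  ids <- names(fit$predictions)
  parts <- strsplit(ids, "+", fixed = TRUE)
  src <- vapply(parts, `[`, character(1), 1L)
  sel <- vapply(parts, `[`, character(1), 2L)
  has_layer <- grepl("/", src, fixed = TRUE)
  df <- data.frame(
    no = seq_along(ids),
    backbone = ifelse(has_layer, sub("/.*$", "", src), src),
    layer = ifelse(has_layer, sub("^.*/", "", src), ""),
    selector = sel,
    accuracy = round_half_up(
      100 * vapply(fit$predictions, function(p) p$accuracy, numeric(1)), 2),
    best = ids == fit$best_id,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Performance metric panel table
#'
#' Overall accuracy with per-class recall, precision, and F1 for the selected
#' best outcome, percentages rounded half-up to 2 decimals.
#'
#' @inheritParams classifier_table
#' @return Data frame: `class`, `accuracy`, `recall`, `precision`, `f1`.
#' @export
class_metrics_table <- function(fit, path = NULL) {
  if (is.null(fit$metrics)) stop("empty result")
  pc <- fit$metrics$per_class
  df <- data.frame(class = pc$class, accuracy = fit$metrics$accuracy,
                   recall = pc$recall, precision = pc$precision, f1 = pc$f1,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Write the machine-readable result report
#'
#' JSON containing the structural counts, every candidate's accuracy, the
#' best outcome id, the confusion matrix, the metric panel, and the resolved
#' configuration (full provenance; no timestamps, so identical runs give
#' byte-identical reports).
#'
#' @inheritParams classifier_table
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(fit, path) {
  cfg <- fit$config
  report <- list(
    counts = pipeline_counts(fit),
    best_candidate = fit$best_id,
    accuracy = round_half_up(100 * fit$accuracy, 2),
    confusion = unclass(fit$confusion),
    classes = lapply(seq_len(nrow(fit$metrics$per_class)), function(i) {
      pc <- fit$metrics$per_class
      list(name = pc$class[i], recall = pc$recall[i],
           precision = pc$precision[i], f1 = pc$f1[i])
    }),
    candidates = candidate_table(fit),
    config = list(selectors = cfg$selectors, k = cfg$k,
                  cv = unclass(cfg$cv), r_min = cfg$r_min, r_max = cfg$r_max,
                  pool = cfg$pool, selection_mode = cfg$selection_mode,
                  extractor = cfg$extractor, seed = cfg$seed)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the pipeline end-to-end and write reports
#'
#' Convenience orchestrator: fits [asnet()] on a dataset directory (read via
#' [load_manifest()]) or on prepared feature matrices, then writes the JSON
#' report plus the classifier-wise and metric-panel CSVs to `out_dir`.
#'
#' @param data Directory of class subfolders, an `asnet_manifest`, a list of
#'   feature matrices, or a single matrix.
#' @param out_dir Output directory (created if needed).
#' @param y Class codes when `data` is not a manifest/directory.
#' @param ... Passed to [asnet()].
#' @return The `asnet` fit, invisibly; files `report.json`,
#'   `classifier_wise.csv`, `metrics.csv` appear in `out_dir`.
#' @export
run_pipeline <- function(data, out_dir, y = NULL, ...) {
  if (is.character(data) && length(data) == 1L) data <- load_manifest(data)
  fit <- asnet(data, y = y, ...)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  write_report_json(fit, file.path(out_dir, "report.json"))
  classifier_table(fit, file.path(out_dir, "classifier_wise.csv"))
  class_metrics_table(fit, file.path(out_dir, "metrics.csv"))
  invisible(fit)
}
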