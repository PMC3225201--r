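# Output writers for fitted models: plain-text CSV matrices plus a JSON
# metadata file, deterministic so repeated runs are byte-identical.

write_matrix_csv <- function(M, path, rowname_col = "sample_id") {
  df <- data.frame(rownames(M) %||% seq_len(nrow(M)), M,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- rowname_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the outputs of a fitted fusion model
#'
#' Writes `scores.csv` (global PC scores of the training samples),
#' `loadings.csv` (super-loadings of the concatenated-score PCA),
#' `weights_<block>.csv` (back-projected global weights per original
#' variable), `confusion.csv` and `accuracy` inside `metrics.json` when a
#' test set exists, and `model.json` with the model metadata (configuration,
#' split, per-block selected variables and PLS settings).
#'
#' @param model a `fusion_model`.
#' @param study the aligned study (needed to evaluate the test set).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_fusion_outputs <- function(model, study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(model$global$scores, file.path(dir, "scores.csv"))
  write_matrix_csv(model$global$loadings, file.path(dir, "loadings.csv"),
                   rowname_col = "score_column")
  for (bid in names(model$blocks))
    write_matrix_csv(global_weights(model, bid),
                     file.path(dir, paste0("weights_", bid, ".csv")),
                     rowname_col = "variable_id")
  metrics <- list(r_global = model$r_global,
                  explained_variance = model$global$explained_variance,
                  n_train = length(model$train_ids),
                  n_test = length(model$test_ids))
  if (length(model$test_ids)) {
    ev <- evaluate(model, study)
    metrics$test_accuracy <- ev$accuracy
    utils::write.csv(as.data.frame.matrix(ev$confusion),
                     file.path(dir, "confusion.csv"), quote = FALSE)
  }
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  meta <- list(
    class_levels = model$class_levels,
    train_ids = model$train_ids, test_ids = model$test_ids,
    config = unclass(model$config),
    blocks = lapply(model$blocks, function(bm) list(
      block_id = bm$block_id, normalize = bm$normalize,
      scale = bm$scaling$method, n_pls = bm$ecva$n_pls,
      n_variables = length(bm$ecva$selected_variables),
      selected_variables = bm$ecva$selected_variables,
      eigen_ratios = bm$ecva$eigen_ratios)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialize an eCVA model to plain-text files
#'
#' `<stem>_W.csv`, `<stem>_T.csv`, `<stem>_group_means.csv` and
#' `<stem>.json` (metadata: selected variables, PLS component count,
#' scaling statistics).
#'
#' @param model an `ecva_model`.
#' @param stem path stem for the output files.
#' @return `stem`, invisibly.
#' @export
write_ecva <- function(model, stem) {
  write_matrix_csv(model$W, paste0(stem, "_W.csv"), rowname_col = "variable_id")
  write_matrix_csv(model$T, paste0(stem, "_T.csv"))
  write_matrix_csv(model$group_means, paste0(stem, "_group_means.csv"),
                   rowname_col = "class")
  meta <- list(n_pls = model$n_pls, g = model$g,
               selected_variables = model$selected_variables,
               eigen_ratios = model$eigen_ratios,
               scaling = if (!is.null(model$scaling)) list(
                 method = model$scaling$method,
                 column_means = model$scaling$column_means,
                 column_sds = model$scaling$column_sds,
                 dropped_variables = model$scaling$dropped_variables))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}
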