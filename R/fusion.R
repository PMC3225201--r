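# Mid-level fusion pipeline: Kennard-Stone test split, per-block eCVA,
# concatenation of the canonical-variate scores, missing-value PCA on the
# concatenated scores, nearest-centroid (PCDA-like) classification.

#' Configuration for the fusion pipeline
#'
#' Per-block settings (`normalize`, `scale`, `n_pls`, `n_pls_grid`, `top_k`)
#' are recycled across blocks when given as scalars.
#'
#' @param test_fraction fraction of samples set aside as a Kennard-Stone
#'   test set (default 0.20; 0 disables the split, e.g. for the final
#'   interpretation refit on all samples).
#' @param normalize per-block row normalization: `"none"` or `"integral"`
#'   (constant-sum, for NMR-like blocks).
#' @param scale per-block column scaling method (default `"vast"`).
#' @param n_pls per-block inner PLS component count, used when
#'   `n_pls_grid` is NULL.
#' @param n_pls_grid per-block candidate grids for [select_pls_components()]
#'   (list to differ per block). When non-NULL the count is picked per
#'   block by the inner cross-validation, which is advisable when no
#'   reasonable count is known; NULL (default) uses `n_pls` directly.
#' @param top_k optional per-block variable screen size (NA = no screen);
#'   see [select_top_k_and_refit()].
#' @param r_global number of global PCs retained (default g - 1, resolved
#'   at fit time when NULL).
#' @param classifier `"nearest_centroid_mahalanobis"` (pooled within-class
#'   covariance, the closest deterministic reading of PCDA) or
#'   `"nearest_centroid_euclidean"`.
#' @param stratified stratify the Kennard-Stone split by class (default
#'   TRUE, so every class appears in the test set).
#' @param global_tol,global_max_iter convergence settings for the
#'   missing-value PCA of the concatenated scores. Looser than the
#'   [fit_pca_missing()] defaults because samples observed in only one
#'   block leave their score-space position partly underdetermined, where
#'   the imputation contracts slowly; at 1e-7 the retained model is stable
#'   to far below the classification scale.
#' @param seed recorded for provenance; the pipeline itself is
#'   deterministic given the data and configuration.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(test_fraction = 0.20,
                          normalize = "none",
                          scale = "vast",
                          n_pls = 8L,
                          n_pls_grid = NULL,
                          top_k = NA_integer_,
                          r_global = NULL,
                          classifier = c("nearest_centroid_mahalanobis",
                                         "nearest_centroid_euclidean"),
                          stratified = TRUE,
                          global_tol = 1e-7,
                          global_max_iter = 5000L,
                          seed = NULL) {
  classifier <- match.arg(classifier)
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must be in [0, 1)")
  if (!is.null(r_global) && r_global < 1L) stop("r_global must be >= 1")
  structure(list(test_fraction = test_fraction, normalize = normalize,
                 scale = scale, n_pls = n_pls, n_pls_grid = n_pls_grid,
                 top_k = top_k, r_global = r_global, classifier = classifier,
                 stratified = stratified, global_tol = global_tol,
                 global_max_iter = global_max_iter, seed = seed),
            class = "fusion_config")
}

per_block <- function(value, b, n_blocks) {
  if (is.list(value)) return(value[[((b - 1L) %% length(value)) + 1L]])
  rep_len(value, n_blocks)[b]
}

#' Kennard-Stone representative subset split
#'
#' Classic max-min selection on Euclidean distances: seed with the two
#' mutually farthest points, then repeatedly add the point whose minimal
#' distance to the already-selected set is largest. The selected,
#' space-covering points form the TEST set (they are representative of the
#' whole set); everything else trains. Deterministic given the input order:
#' ties go to the lowest row index.
#'
#' @param X representation matrix, rows named by sample id.
#' @param labels class per row (used when `stratified = TRUE`).
#' @param fraction test fraction in [0, 1); the test set has
#'   `round(fraction * n)` samples (per class when stratified).
#' @param stratified run the selection separately per class (default TRUE).
#' @return list with character vectors `train` and `test`.
#' @export
kennard_stone_split <- function(X, labels = NULL, fraction = 0.20,
                                stratified = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(n))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  ks_pick <- function(D, size) {
    m <- nrow(D)
    if (size <= 0L) return(integer(0))
    if (size >= m) return(seq_len(m))
    # farthest pair; ties -> lexicographically lowest (i, j)
    best <- c(1L, 2L); bestd <- -Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
    sel <- if (size == 1L) best[1L] else best
    while (length(sel) < size) {
      cand <- setdiff(seq_len(m), sel)
      mind <- apply(D[cand, sel, drop = FALSE], 1L, min)
      sel <- c(sel, cand[which.max(mind)])
    }
    sel
  }
  if (stratified) {
    if (is.null(labels)) stop("labels required for a stratified split")
    labels <- check_labels(labels, n)
    test_idx <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      size <- round(fraction * length(idx))
      if (fraction > 0 && size < 1L)
        warning("class ", cl, " contributes no test samples at fraction ",
                fraction)
      D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
      test_idx <- c(test_idx, idx[ks_pick(D, size)])
    }
  } else {
    size <- round(fraction * n)
    D <- as.matrix(stats::dist(X))
    test_idx <- ks_pick(D, size)
  }
  test_idx <- sort(test_idx)
  list(train = ids[setdiff(seq_len(n), test_idx)], test = ids[test_idx])
}

# normalize + scale the raw values of one block with a fitted block model
transform_block <- function(bm, values) {
  if (bm$normalize == "integral") values <- integral_normalize(values)
  apply_scaling(bm$scaling, values)
}

#' Fit the mid-level fusion model
#'
#' For each block: take its training samples (samples absent from the block
#' are simply excluded from that block's model), apply the configured row
#' normalization and column scaling, fit eCVA (optionally preceded by the
#' top-k variable screen). The per-block canonical-variate scores are then
#' concatenated into an n_train x sum_b(g-1) matrix with missing cells where
#' a sample was not measured by a block, analysed by [fit_pca_missing()],
#' and a nearest-centroid classifier is set up in the retained global PC
#' space. All statistics derive from training samples only.
#'
#' @param study an [align_blocks()] result.
#' @param config a [fusion_config()].
#' @param split optional fixed list(train, test) of sample ids, overriding
#'   the Kennard-Stone split (used, e.g., to audit leakage).
#' @return A `fusion_model` holding the per-block models, the global
#'   `pca_model`, class centroids, pooled within-class score covariance,
#'   the split and the configuration.
#' @export
fit_fusion <- function(study, config = fusion_config(), split = NULL) {
  stopifnot(inherits(study, "aligned_study"))
  labels <- study$labels
  g <- nlevels(labels)
  nb <- length(study$blocks)
  block_ids <- names(study$blocks)
  if (is.null(split)) {
    if (config$test_fraction > 0) {
      rep_ <- ks_representation(study)
      split <- kennard_stone_split(rep_, labels[rownames(rep_)],
                                   fraction = config$test_fraction,
                                   stratified = config$stratified)
      # samples absent from some block never enter the representation;
      # they always train
      split$train <- setdiff(study$sample_ids, split$test)
    } else {
      split <- list(train = study$sample_ids, test = character(0))
    }
  }
  train_ids <- split$train
  r_global <- config$r_global %||% (g - 1L)

  blocks <- vector("list", nb)
  names(blocks) <- block_ids
  for (b in seq_len(nb)) {
    bid <- block_ids[b]
    present <- train_ids[study$presence[train_ids, bid]]
    lab_b <- droplevels(labels[present])
    if (nlevels(lab_b) < g)
      stop("class ", paste(setdiff(levels(labels), levels(lab_b)), collapse = ", "),
           " has no training samples in block '", bid, "'")
    if (length(present) == 0L) stop("no training samples in block '", bid, "'")
    Xb <- block_values(study, bid, present)
    norm_b <- per_block(config$normalize, b, nb)
    if (norm_b == "integral") Xb <- integral_normalize(Xb)
    scale_b <- per_block(config$scale, b, nb)
    grid_b <- if (is.null(config$n_pls_grid)) NULL else per_block(config$n_pls_grid, b, nb)
    topk_b <- per_block(config$top_k, b, nb)
    sc <- fit_scaling(Xb, scale_b)
    Xs <- apply_scaling(sc, Xb)
    n_pls <- if (!is.null(grid_b)) {
      select_pls_components(Xs, labels[present], grid_b)$n_pls
    } else per_block(config$n_pls, b, nb)
    model <- if (!is.na(topk_b) && topk_b < ncol(Xb)) {
      select_top_k_and_refit(Xb, labels[present], k = topk_b,
                             n_pls = n_pls, scale = scale_b)
    } else {
      fit_ecva(Xs, labels[present], n_pls = n_pls, scaling = sc)
    }
    blocks[[b]] <- list(block_id = bid, normalize = norm_b, ecva = model,
                        scaling = model$scaling, train_samples = present)
  }

  ncv <- vapply(blocks, function(bm) ncol(bm$ecva$W), integer(1L))
  col_block <- rep(block_ids, ncv)
  concat <- matrix(NA_real_, length(train_ids), sum(ncv),
                   dimnames = list(train_ids,
                                   paste(col_block,
                                         unlist(lapply(ncv, seq_len)), sep = ".CV")))
  off <- 0L
  for (b in seq_len(nb)) {
    bm <- blocks[[b]]
    concat[bm$train_samples, off + seq_len(ncv[b])] <- bm$ecva$T
    off <- off + ncv[b]
  }
  if (r_global > min(length(train_ids) - 1L, ncol(concat)))
    stop("r_global too large for the concatenated score matrix")
  # canonical-variate convention: unit-norm direction vectors leave the
  # score columns on arbitrary, block-dependent scales, so each column is
  # standardized to unit pooled within-class SD (training samples only)
  # before the global PCA; otherwise the PCA follows whichever platform's
  # scores happen to be largest rather than the class structure
  lab_tr <- labels[train_ids]
  score_scale <- vapply(seq_len(ncol(concat)), function(j) {
    x <- concat[, j]
    obs <- !is.na(x)
    cm <- tapply(x[obs], lab_tr[obs], mean)
    sqrt(sum((x[obs] - cm[as.character(lab_tr[obs])])^2) /
           max(sum(obs) - g, 1L))
  }, numeric(1L))
  score_scale[score_scale < .Machine$double.eps] <- 1
  concat <- sweep(concat, 2L, score_scale, "/")
  global <- fit_pca_missing(concat, r = r_global, tol = config$global_tol,
                            max_iter = config$global_max_iter)

  scores <- global$scores
  centroids <- group_means_of(scores, lab_tr)
  centered <- scores - centroids[lab_tr, , drop = FALSE]
  S_pooled <- crossprod(centered) / (length(train_ids) - g)
  structure(list(blocks = blocks, concat_scores = concat,
                 col_block = col_block, score_scale = score_scale,
                 global = global,
                 centroids = centroids, S_pooled = S_pooled,
                 class_levels = levels(labels), g = g, r_global = r_global,
                 config = config, train_ids = train_ids, test_ids = split$test),
            class = "fusion_model")
}

# Kennard-Stone representation space: concatenated per-block autoscaled
# data, restricted to samples present in every block (other samples always
# train)
ks_representation <- function(study) {
  complete <- study$sample_ids[rowSums(study$presence) == ncol(study$presence)]
  if (length(complete) < 3L)
    stop("fewer than 3 samples present in all blocks; cannot form a split")
  do.call(cbind, lapply(names(study$blocks), function(bid) {
    X <- block_values(study, bid, complete)
    apply_scaling(fit_scaling(X, "autoscale"), X)
  }))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("fusion_model: ", length(x$blocks), " blocks, ", x$g, " classes, ",
      length(x$train_ids), " training / ", length(x$test_ids),
      " test samples\n", sep = "")
  cat("global PCs: ", x$r_global, " (",
      paste(sprintf("%.1f%%", 100 * x$global$explained_variance), collapse = ", "),
      " of concatenated-score variance)\n", sep = "")
  invisible(x)
}

# per-sample concatenated eCVA score vector (NA for absent blocks)
fused_score_vector <- function(model, study, id) {
  out <- rep(NA_real_, length(model$col_block))
  off <- 0L
  for (bm in model$blocks) {
    ncv_b <- ncol(bm$ecva$W)
    if (study$presence[id, bm$block_id]) {
      x <- block_values(study, bm$block_id, id)
      out[off + seq_len(ncv_b)] <- project_ecva(bm$ecva, transform_block(bm, x))
    }
    off <- off + ncv_b
  }
  out / model$score_scale
}

#' Classify samples with a fitted fusion model
#'
#' Each sample is scaled with the stored per-block models, projected through
#' every block it was measured in, assembled into a (possibly incomplete)
#' concatenated score vector, projected into the global PC space
#' (least-squares on the observed coordinates when a block is absent), and
#' assigned the class of the nearest centroid — Mahalanobis with the pooled
#' within-class covariance by default. Ties go to the lowest class index.
#'
#' @param model a `fusion_model`.
#' @param study the aligned study holding the samples' raw values.
#' @param ids sample ids to classify (default: the model's test set).
#' @return named character vector of predicted class labels.
#' @export
classify <- function(model, study, ids = model$test_ids) {
  UseMethod("classify")
}

#' @export
classify.fusion_model <- function(model, study, ids = model$test_ids) {
  if (!length(ids)) stop("no samples to classify")
  absent <- ids[rowSums(study$presence[ids, , drop = FALSE]) == 0L]
  if (length(absent))
    stop("sample present in no block: ", paste(absent, collapse = ", "))
  Sinv <- if (model$config$classifier == "nearest_centroid_mahalanobis") {
    solve(model$S_pooled)
  } else diag(model$r_global)
  cen <- model$centroids
  pred <- vapply(ids, function(id) {
    v <- fused_score_vector(model, study, id)
    t_ <- project_pca(model$global, v)
    d2 <- vapply(seq_len(nrow(cen)), function(k) {
      dlt <- t_ - cen[k, ]
      drop(crossprod(dlt, Sinv %*% dlt))
    }, numeric(1L))
    model$class_levels[which.min(d2)]   # first minimum -> lowest class index
  }, character(1L))
  stats::setNames(pred, ids)
}

#' Evaluate predictions on a labelled test set
#'
#' @param model a fitted model with a `classify()` method.
#' @param study the aligned study.
#' @param ids samples to evaluate (default: the model's test set).
#' @return list with `accuracy` and the g x g `confusion` matrix (rows =
#'   true class, columns = predicted).
#' @export
evaluate <- function(model, study, ids = model$test_ids) {
  if (!length(ids)) stop("empty test set")
  pred <- classify(model, study, ids)
  truth <- factor(study$labels[ids], levels = model$class_levels)
  pred <- factor(pred, levels = model$class_levels)
  confusion <- table(truth = truth, predicted = pred)
  list(accuracy = sum(diag(confusion)) / length(ids),
       confusion = unclass(confusion))
}

#' Low-level fusion baseline
#'
#' Concatenates the per-block scaled feature tables directly (missing cells
#' where a sample is absent from a block) and analyses the result with
#' missing-value PCA plus the same nearest-centroid classifier. Provided as
#' the comparison point that motivates mid-level fusion.
#'
#' @inheritParams fit_fusion
#' @return a `lowlevel_model` with a `classify()` method.
#' @export
fit_lowlevel <- function(study, config = fusion_config(scale = "autoscale"),
                         split = NULL) {
  stopifnot(inherits(study, "aligned_study"))
  labels <- study$labels
  g <- nlevels(labels)
  nb <- length(study$blocks)
  block_ids <- names(study$blocks)
  if (is.null(split)) {
    if (config$test_fraction > 0) {
      rep_ <- ks_representation(study)
      split <- kennard_stone_split(rep_, labels[rownames(rep_)],
                                   fraction = config$test_fraction,
                                   stratified = config$stratified)
      # samples absent from some block never enter the representation;
      # they always train
      split$train <- setdiff(study$sample_ids, split$test)
    } else split <- list(train = study$sample_ids, test = character(0))
  }
  train_ids <- split$train
  r_global <- config$r_global %||% (g - 1L)
  blocks <- vector("list", nb); names(blocks) <- block_ids
  pieces <- vector("list", nb)
  for (b in seq_len(nb)) {
    bid <- block_ids[b]
    present <- train_ids[study$presence[train_ids, bid]]
    Xb <- block_values(study, bid, present)
    norm_b <- per_block(config$normalize, b, nb)
    if (norm_b == "integral") Xb <- integral_normalize(Xb)
    sc <- fit_scaling(Xb, per_block(config$scale, b, nb))
    blocks[[b]] <- list(block_id = bid, normalize = norm_b, scaling = sc)
    piece <- matrix(NA_real_, length(train_ids), length(sc$variable_ids),
                    dimnames = list(train_ids, paste(bid, sc$variable_ids, sep = ".")))
    piece[present, ] <- apply_scaling(sc, Xb)
    pieces[[b]] <- piece
  }
  concat <- do.call(cbind, pieces)
  global <- fit_pca_missing(concat, r = r_global, tol = config$global_tol,
                            max_iter = config$global_max_iter)
  scores <- global$scores
  lab_tr <- labels[train_ids]
  centroids <- group_means_of(scores, lab_tr)
  centered <- scores - centroids[lab_tr, , drop = FALSE]
  S_pooled <- crossprod(centered) / (length(train_ids) - g)
  structure(list(blocks = blocks, global = global, centroids = centroids,
                 S_pooled = S_pooled, class_levels = levels(labels), g = g,
                 r_global = r_global, config = config,
                 train_ids = train_ids, test_ids = split$test),
            class = "lowlevel_model")
}

#' @export
classify.lowlevel_model <- function(model, study, ids = model$test_ids) {
  if (!length(ids)) stop("no samples to classify")
  Sinv <- if (model$config$classifier == "nearest_centroid_mahalanobis") {
    solve(model$S_pooled)
  } else diag(model$r_global)
  cen <- model$centroids
  pred <- vapply(ids, function(id) {
    v <- unlist(lapply(model$blocks, function(bm) {
      if (study$presence[id, bm$block_id]) {
        x <- block_values(study, bm$block_id, id)
        drop(transform_block(bm, x))
      } else rep(NA_real_, length(bm$scaling$variable_ids))
    }), use.names = FALSE)
    t_ <- project_pca(model$global, v)
    d2 <- vapply(seq_len(nrow(cen)), function(k) {
      dlt <- t_ - cen[k, ]
      drop(crossprod(dlt, Sinv %*% dlt))
    }, numeric(1L))
    model$class_levels[which.min(d2)]
  }, character(1L))
  stats::setNames(pred, ids)
}
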