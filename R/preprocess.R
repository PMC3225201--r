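#' Integral (constant-sum) normalization
#'
#' Rescales every sample row so that its entries sum to `total`, removing
#' dilution differences between samples. Standard for binned NMR spectra.
#'
#' @param block an [omics_block()], or a plain numeric matrix.
#' @param total target row sum (default 100).
#' @return object of the same kind with normalized rows.
#' @export
integral_normalize <- function(block, total = 100) {
  X <- if (inherits(block, "omics_block")) block$values else as.matrix(block)
  rs <- rowSums(X)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("row sum <= 0 for sample ",
         paste(rownames(X)[bad] %||% bad, collapse = ", "),
         "; cannot integral-normalize")
  Xn <- X * (total / rs)
  if (inherits(block, "omics_block")) {
    block$values <- Xn
    block
  } else Xn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a column scaling model on training data
#'
#' Supported methods: `mean_center` (x - mu), `autoscale` ((x - mu)/sigma),
#' `pareto` ((x - mu)/sqrt(sigma)) and `vast` (autoscaling weighted by the
#' mean-to-SD ratio, ((x - mu)/sigma) * (mu/sigma)), which down-weights
#' unstable variables. Standard deviations use the unbiased n-1 denominator.
#' Zero-variance columns are dropped with a warning and recorded in the
#' model; they carry no discriminant information and break autoscale/vast.
#'
#' @param X training matrix (>= 2 rows), columns named by variable id.
#' @param method one of `"mean_center"`, `"autoscale"`, `"pareto"`, `"vast"`.
#' @return A `scaling_model` with `method`, `column_means`, `column_sds`,
#'   `variable_ids` (retained) and `dropped_variables`.
#' @export
fit_scaling <- function(X, method = c("vast", "autoscale", "pareto", "mean_center")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 training rows to fit scaling")
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) stop("all columns have zero variance")
  dropped <- colnames(X)[!keep] %||% which(!keep)
  if (any(!keep))
    warning(sum(!keep), " zero-variance column(s) dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  if (method == "vast" && any(mu[keep] <= 0))
    warning("vast scaling with non-positive column means: ",
            sum(mu[keep] <= 0), " column(s) get non-positive weights")
  structure(list(method = method,
                 column_means = mu[keep],
                 column_sds = sd_[keep],
                 variable_ids = colnames(X)[keep],
                 dropped_variables = if (any(!keep)) dropped else character(0)),
            class = "scaling_model")
}

#' Apply a fitted scaling model
#'
#' Uses the stored training means and SDs; never recomputes statistics on
#' new data, so test samples are transformed exactly like training samples.
#'
#' @param model a `scaling_model` from [fit_scaling()].
#' @param X matrix to transform; must contain the model's retained columns
#'   (extra columns, e.g. ones dropped at fit time, are ignored).
#' @return transformed matrix restricted to the retained columns.
#' @export
apply_scaling <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$variable_ids) && !is.null(colnames(X))) {
    miss <- setdiff(model$variable_ids, colnames(X))
    if (length(miss))
      stop("missing variables: ", paste(utils::head(miss, 5L), collapse = ", "))
    X <- X[, model$variable_ids, drop = FALSE]
  }
  mu <- model$column_means
  sd_ <- model$column_sds
  Xc <- sweep(X, 2L, mu, "-")
  switch(model$method,
         mean_center = Xc,
         autoscale   = sweep(Xc, 2L, sd_, "/"),
         pareto      = sweep(Xc, 2L, sqrt(sd_), "/"),
         vast        = sweep(sweep(Xc, 2L, sd_, "/"), 2L, mu / sd_, "*"))
}

#' Invert a scaling transform
#'
#' @param model a `scaling_model`.
#' @param Xs scaled matrix over the model's retained columns.
#' @return matrix on the original measurement scale.
#' @export
invert_scaling <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  mu <- model$column_means
  sd_ <- model$column_sds
  Xc <- switch(model$method,
               mean_center = Xs,
               autoscale   = sweep(Xs, 2L, sd_, "*"),
               pareto      = sweep(Xs, 2L, sqrt(sd_), "*"),
               vast        = sweep(sweep(Xs, 2L, mu / sd_, "/"), 2L, sd_, "*"))
  sweep(Xc, 2L, mu, "+")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat("scaling_model: ", x$method, ", ", length(x$column_means),
      " variables retained", sep = "")
  if (length(x$dropped_variables))
    cat(", ", length(x$dropped_variables), " dropped", sep = "")
  cat("\n")
  invisible(x)
}
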