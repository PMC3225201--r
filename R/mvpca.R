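# PCA for complete and incomplete matrices. Missing cells are filled by
# iterative model-based imputation: fit a rank-r PCA to the current
# completion, replace the missing cells by the model reconstruction, repeat
# until the estimates stop changing. Observed cells are never modified.

#' Principal component analysis of a complete matrix
#'
#' Column-mean-centered SVD. Loadings columns are orthonormal and sign-fixed
#' (largest-magnitude entry positive); scores * t(loadings) is the best
#' rank-r approximation of the centered matrix.
#'
#' @param X complete n x q numeric matrix.
#' @param r number of components, at most `min(n - 1, q)`.
#' @return A `pca_model` with `loadings` (q x r), `scores` (n x r),
#'   `column_means`, `explained_variance` (fractions of total variance) and
#'   `sdev` (score standard deviations).
#' @export
fit_pca <- function(X, r) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X has missing cells; use fit_pca_missing()")
  n <- nrow(X); q <- ncol(X)
  if (r < 1L || r > min(n - 1L, q))
    stop("r must be in 1..min(n-1, q) = 1..", min(n - 1L, q))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc, nu = r, nv = r)
  P <- fix_signs(sv$v)
  # keep scores consistent with the flipped loadings
  scores <- Xc %*% P
  tot <- sum(sv$d^2)
  ev <- if (tot > 0) sv$d[seq_len(r)]^2 / tot else rep(0, r)
  dimnames(P) <- list(colnames(X), paste0("PC", seq_len(r)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(r)))
  structure(list(loadings = P, scores = scores, column_means = mu,
                 explained_variance = ev,
                 sdev = sv$d[seq_len(r)] / sqrt(max(n - 1L, 1L)),
                 imputed_values = NULL, n_iterations = 0L, converged = TRUE),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " variables, ", ncol(x$loadings), " components (",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      ")\n", sep = "")
  if (!is.null(x$imputed_values))
    cat("  ", nrow(x$imputed_values), " missing cells imputed in ",
        x$n_iterations, " iterations (converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' PCA of a matrix with missing cells by iterative imputation
#'
#' Missing cells are initialized with the observed column means, then the
#' loop \{re-center on the current column means; rank-r SVD; replace the
#' missing cells with the rank-r reconstruction\} runs until the relative
#' Frobenius-norm change of the missing-cell estimates drops below `tol`.
#' The rank-r reconstruction error over the observed cells is nonincreasing
#' across iterations, and the observed cells themselves are never altered.
#'
#' @param X n x q matrix, `NA` marking missing cells; every row and column
#'   must have at least one observed cell.
#' @param r number of components.
#' @param tol relative convergence threshold (default 1e-9).
#' @param max_iter iteration cap (default 1000); if reached, the model is
#'   returned with `converged = FALSE` and a warning.
#' @return A `pca_model` as in [fit_pca()], plus `imputed_values` (data
#'   frame of row, col, value for the originally missing cells),
#'   `n_iterations`, `converged` and `obs_rss` (per-iteration observed-cell
#'   reconstruction sums of squares).
#' @export
fit_pca_missing <- function(X, r, tol = 1e-9, max_iter = 1000L) {
  X <- as.matrix(X)
  miss <- is.na(X)
  if (!any(miss)) {
    m <- fit_pca(X, r)
    m$imputed_values <- data.frame(row = integer(0), col = integer(0),
                                   value = numeric(0))
    m$obs_rss <- numeric(0)
    return(m)
  }
  if (any(rowSums(!miss) == 0L)) stop("a row is fully missing")
  if (any(colSums(!miss) == 0L)) stop("a column is fully missing")
  n <- nrow(X); q <- ncol(X)
  if (r < 1L || r > min(n - 1L, q))
    stop("r must be in 1..min(n-1, q) = 1..", min(n - 1L, q))
  Xf <- X
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(q)) Xf[miss[, j], j] <- cm[j]
  est_old <- Xf[miss]
  obs_rss <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- colMeans(Xf)
    Xc <- sweep(Xf, 2L, mu, "-")
    sv <- svd(Xc, nu = r, nv = r)
    rec <- sweep(sv$u %*% (sv$d[seq_len(r)] * t(sv$v)), 2L, mu, "+")
    obs_rss <- c(obs_rss, sum((X[!miss] - rec[!miss])^2))
    Xf[miss] <- rec[miss]
    est_new <- Xf[miss]
    delta <- sqrt(sum((est_new - est_old)^2)) /
      max(sqrt(sum(est_old^2)), .Machine$double.eps)
    est_old <- est_new
    if (delta <= tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("missing-value PCA did not converge in ", max_iter, " iterations")
  # final decomposition of the completed matrix
  mu <- colMeans(Xf)
  Xc <- sweep(Xf, 2L, mu, "-")
  sv <- svd(Xc, nu = r, nv = r)
  P <- fix_signs(sv$v)
  scores <- Xc %*% P
  tot <- sum(sv$d^2)
  idx <- which(miss, arr.ind = TRUE)
  dimnames(P) <- list(colnames(X), paste0("PC", seq_len(r)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(r)))
  structure(list(loadings = P, scores = scores, column_means = mu,
                 explained_variance = if (tot > 0) sv$d[seq_len(r)]^2 / tot else rep(0, r),
                 sdev = sv$d[seq_len(r)] / sqrt(max(n - 1L, 1L)),
                 imputed_values = data.frame(row = idx[, 1L], col = idx[, 2L],
                                             value = Xf[miss]),
                 n_iterations = it, converged = converged, obs_rss = obs_rss),
            class = "pca_model")
}

#' Project a (possibly incomplete) sample into a PCA score space
#'
#' Complete samples are projected as (x - mu) P. For a sample with missing
#' entries the score is the least-squares solution over the observed
#' coordinates, t = argmin ||x_obs - mu_obs - P_obs t||^2, which requires at
#' least r observed entries.
#'
#' @param model a `pca_model`.
#' @param x_new numeric vector of length q (NA = missing), or an n x q
#'   matrix of such rows.
#' @return r-vector score, or an n x r score matrix for matrix input.
#' @export
project_pca <- function(model, x_new) {
  P <- model$loadings
  mu <- model$column_means
  r <- ncol(P)
  one <- function(x) {
    obs <- !is.na(x)
    if (sum(obs) < r)
      stop("fewer than r = ", r, " observed entries; cannot project")
    if (all(obs)) return(drop(crossprod(P, x - mu)))
    Po <- P[obs, , drop = FALSE]
    drop(solve(crossprod(Po), crossprod(Po, x[obs] - mu[obs])))
  }
  if (is.matrix(x_new)) {
    out <- t(apply(x_new, 1L, one))
    if (r == 1L) out <- matrix(out, ncol = 1L, dimnames = list(rownames(x_new), NULL))
    colnames(out) <- colnames(P)
    out
  } else one(as.numeric(x_new))
}

#' PCA-distance outlier screen
#'
#' Classical-PCA analogue of the robust distance-distance diagnostic: each
#' sample gets a score distance (Mahalanobis distance in the r-dimensional
#' score space) and an orthogonal distance (norm of its residual off the PC
#' plane). Cutoffs: sqrt of the chi-square `quantile` for the squared score
#' distance; for the orthogonal distance a Wilson-Hilferty-style normal
#' approximation of the OD^(2/3) distribution. Exploratory only - nothing in
#' the fusion pipeline removes samples automatically.
#'
#' @param X complete n x q matrix.
#' @param r number of components for the screen.
#' @param quantile cutoff level in (0, 1), default 0.975.
#' @return data frame `sample_id, score_distance, orthogonal_distance,
#'   flagged` with the cutoffs attached as attributes.
#' @export
detect_outliers <- function(X, r, quantile = 0.975) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  X <- as.matrix(X)
  m <- fit_pca(X, r)
  lam <- m$sdev^2
  sd2 <- rowSums(sweep(m$scores^2, 2L, pmax(lam, .Machine$double.eps), "/"))
  resid <- sweep(X, 2L, m$column_means, "-") - m$scores %*% t(m$loadings)
  od <- sqrt(rowSums(resid^2))
  sd_cut <- sqrt(stats::qchisq(quantile, df = r))
  z <- od^(2 / 3)
  od_cut <- (mean(z) + stats::sd(z) * stats::qnorm(quantile))^(3 / 2)
  score_distance <- sqrt(sd2)
  flagged <- score_distance > sd_cut | od > od_cut
  out <- data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
                    score_distance = score_distance,
                    orthogonal_distance = od,
                    flagged = flagged, row.names = NULL)
  attr(out, "score_cutoff") <- sd_cut
  attr(out, "orthogonal_cutoff") <- od_cut
  out
}
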