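# Extended Canonical Variates Analysis: Fisher-style discriminant directions
# for p >> n data, obtained by recasting the generalized eigenproblem
# S_within w = lambda^-1 S_between w as the regression S_within B = Y (Y =
# group-mean differences) and solving it with a deflation-based PLS2 fit.

# PLS2 without centering: we are solving the matrix equation X B = Y in a
# regularized fashion, not modelling sampled rows, so no intercept is
# wanted. Each weight vector is the dominant left singular vector of the
# deflated cross-product X'Y — the fixed point of the NIPALS inner loop,
# computed directly so the result is deterministic and fast. With
# ncomp = rank(X) the coefficients converge to the least-squares (here:
# exact) solution.
nipals_pls2 <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  stopifnot(nrow(Y) == n, ncomp >= 1L)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); C <- matrix(0, m, ncomp)
  Tm <- matrix(0, n, ncomp)
  # the deflated X is never formed: with X_a = X - T P' the cross-product
  # deflates by rank-1 updates, M_{a+1} = M_a - (t't) p c', and scores /
  # loadings of the deflated matrix follow from the stored T, P
  M <- crossprod(X, Y)
  Ya <- Y
  h <- 0L
  for (a in seq_len(ncomp)) {
    if (max(abs(M)) < 1e-300) break           # X or Y exhausted
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    t_ <- drop(X %*% w)
    if (h > 0L)
      t_ <- t_ - Tm[, 1:h, drop = FALSE] %*% crossprod(P[, 1:h, drop = FALSE], w)
    t_ <- drop(t_)
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps) break       # X exhausted
    p_ <- drop(crossprod(X, t_))
    if (h > 0L)
      p_ <- p_ - P[, 1:h, drop = FALSE] %*% crossprod(Tm[, 1:h, drop = FALSE], t_)
    p_ <- drop(p_) / tt
    cc <- drop(crossprod(Ya, t_)) / tt
    Ya <- Ya - tcrossprod(t_, cc)
    M <- M - tt * tcrossprod(p_, cc)
    h <- a
    W[, a] <- w; P[, a] <- p_; C[, a] <- cc; Tm[, a] <- t_
  }
  if (h == 0L) stop("PLS could not extract any component")
  W <- W[, 1:h, drop = FALSE]; P <- P[, 1:h, drop = FALSE]
  C <- C[, 1:h, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  list(B = B, ncomp = h)
}

# sign convention: flip each column so its largest-magnitude entry is
# positive; makes directions reproducible across linear-algebra backends
fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

check_labels <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length does not match rows of X")
  labels <- droplevels(labels)
  labels
}

#' Pooled within-group covariance matrix
#'
#' Scatter of the samples around their own group means, pooled over groups
#' and divided by (n - g). The discriminant directions are invariant to this
#' divisor convention.
#'
#' @param X n x p numeric matrix.
#' @param labels class per row (coerced to factor).
#' @return symmetric p x p matrix.
#' @export
within_covariance <- function(X, labels) {
  X <- as.matrix(X)
  labels <- check_labels(labels, nrow(X))
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("every class needs >= 2 samples (singleton: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "), ")")
  n <- nrow(X); g <- nlevels(labels)
  if (n <= g) stop("need n > g samples")
  Xc <- X - group_means_of(X, labels)[labels, , drop = FALSE]
  crossprod(Xc) / (n - g)
}

#' Between-group covariance matrix
#'
#' Covariance of the group means around the grand mean, weighted by group
#' size and divided by (g - 1); rank at most g - 1.
#'
#' @inheritParams within_covariance
#' @return symmetric p x p matrix.
#' @export
between_covariance <- function(X, labels) {
  X <- as.matrix(X)
  labels <- check_labels(labels, nrow(X))
  g <- nlevels(labels)
  if (g < 2L) stop("need at least two classes")
  gm <- group_means_of(X, labels)
  overall <- colMeans(X)
  D <- sweep(gm, 2L, overall, "-")
  n_i <- as.numeric(table(labels))
  crossprod(D * sqrt(n_i)) / (g - 1)
}

group_means_of <- function(X, labels) {
  gm <- rowsum(X, labels) / as.numeric(table(labels))
  gm[levels(labels), , drop = FALSE]
}

#' Fit an extended Canonical Variates Analysis model
#'
#' Builds the regression problem whose predictor matrix is the pooled
#' within-group covariance (p x p) and whose target matrix Y holds all
#' pairwise group-mean differences, solves it with an uncentered NIPALS PLS2
#' fit of `n_pls` components, and takes the canonical directions W as the
#' first g-1 left singular vectors of the coefficient matrix B (unit norm,
#' sign-fixed). The PLS step regularizes the implicit inversion of the
#' within-group covariance, which is what makes the method usable when
#' variables far outnumber samples. Scores are T = (X - overall mean) W.
#'
#' @param X scaled training matrix (apply [fit_scaling()] first; the
#'   fitted `scaling_model` can be attached via `scaling` for bookkeeping).
#' @param labels class per row.
#' @param n_pls number of inner PLS components, at most `min(n - 1, p)`.
#' @param scaling optional `scaling_model` stored in the result.
#' @return An `ecva_model` with canonical directions `W` (p x (g-1)), scores
#'   `T`, `S_within`, target matrix `Y_targets`, coefficients `B`, group and
#'   overall means, per-direction between/within variance ratios
#'   `eigen_ratios`, `n_pls` and `selected_variables`.
#' @export
fit_ecva <- function(X, labels, n_pls, scaling = NULL) {
  X <- as.matrix(X)
  labels <- check_labels(labels, nrow(X))
  n <- nrow(X); p <- ncol(X); g <- nlevels(labels)
  if (n_pls < 1L || n_pls > min(n - 1L, p))
    stop("n_pls must be in 1..min(n-1, p) = 1..", min(n - 1L, p))
  Sw <- within_covariance(X, labels)
  gm <- group_means_of(X, labels)
  overall <- colMeans(X)
  pairs <- utils::combn(g, 2L)
  Y <- apply(pairs, 2L, function(ij) gm[ij[1L], ] - gm[ij[2L], ])
  Y <- matrix(Y, nrow = p)
  if (max(abs(Y)) < 1e-12 * max(1, max(abs(gm))))
    stop("no between-group signal: all group means equal")
  pls <- nipals_pls2(Sw, Y, ncomp = n_pls)
  ncv <- min(p, g - 1L)
  sv <- svd(pls$B, nu = ncv, nv = 0L)
  W <- fix_signs(sv$u[, seq_len(ncv), drop = FALSE])
  rownames(W) <- colnames(X)
  colnames(W) <- paste0("CV", seq_len(ncv))
  scores <- sweep(X, 2L, overall, "-") %*% W
  Sb <- between_covariance(X, labels)
  ratios <- vapply(seq_len(ncv), function(a) {
    w <- W[, a]
    bw <- drop(crossprod(w, Sb %*% w))
    ww <- drop(crossprod(w, Sw %*% w))
    if (ww < .Machine$double.eps) Inf else bw / ww
  }, numeric(1L))
  structure(list(W = W, T = scores, S_within = Sw, Y_targets = Y, B = pls$B,
                 n_pls = pls$ncomp, group_means = gm, overall_mean = overall,
                 labels = labels, scaling = scaling,
                 selected_variables = colnames(X),
                 eigen_ratios = ratios, g = g),
            class = "ecva_model")
}

#' @export
print.ecva_model <- function(x, ...) {
  cat("ecva_model: ", nrow(x$W), " variables, ", x$g, " groups, ",
      ncol(x$W), " canonical variates, ", x$n_pls, " PLS components\n",
      "between/within ratios: ", paste(signif(x$eigen_ratios, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project new samples onto canonical variates
#'
#' @param model an `ecva_model`.
#' @param X_new matrix over the model's retained variables, already
#'   transformed with the model's scaling.
#' @return n_new x (g-1) score matrix.
#' @export
project_ecva <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  vars <- rownames(model$W)
  if (!is.null(vars) && !is.null(colnames(X_new))) {
    miss <- setdiff(vars, colnames(X_new))
    if (length(miss))
      stop("missing variables: ", paste(utils::head(miss, 5L), collapse = ", "))
    X_new <- X_new[, vars, drop = FALSE]
  } else if (ncol(X_new) != nrow(model$W)) {
    stop("X_new has ", ncol(X_new), " variables; model expects ", nrow(model$W))
  }
  sweep(X_new, 2L, model$overall_mean, "-") %*% model$W
}

# stratified venetian-blinds fold assignment: within each class (input
# order) samples are dealt to folds 1..k cyclically
venetian_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Choose the inner PLS component count by cross-validation
#'
#' Stratified venetian-blinds cross-validation: for each candidate count,
#' refit the model on the training folds and classify held-out samples by
#' the nearest class centroid (Euclidean) in canonical-variate space. The
#' count with the fewest misclassifications wins; ties go to the smallest
#' count. If the requested fold count would leave fewer than two samples of
#' some class in a training split, the fold count is reduced with a warning.
#'
#' @param X scaled training matrix.
#' @param labels class per row.
#' @param grid candidate component counts.
#' @param folds number of cross-validation splits (default 7).
#' @return list with `n_pls` (chosen count) and `cv_errors` (named
#'   misclassification counts per candidate).
#' @export
select_pls_components <- function(X, labels, grid, folds = 7L) {
  X <- as.matrix(X)
  labels <- check_labels(labels, nrow(X))
  if (!length(grid)) stop("empty candidate grid")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1L) || any(grid > min(nrow(X) - 1L, ncol(X))))
    stop("grid values must be valid n_pls for fit_ecva")
  if (length(grid) == 1L)
    return(list(n_pls = grid, cv_errors = stats::setNames(NA_real_, grid)))
  cnt <- table(labels)
  k <- min(as.integer(folds), max(cnt))   # no empty folds
  # training split must keep >= 2 samples of every class
  while (k >= 2L && any(cnt - ceiling(cnt / k) < 2L)) k <- k - 1L
  if (k < 2L) stop("cannot form cross-validation folds with >= 2 samples per class in training")
  if (k != folds) warning("fold count reduced to ", k)
  fold <- venetian_folds(labels, k)
  errs <- stats::setNames(numeric(length(grid)), grid)
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ltr <- droplevels(labels[tr])
    Xte <- X[!tr, , drop = FALSE]; lte <- labels[!tr]
    for (i in seq_along(grid)) {
      m <- fit_ecva(Xtr, ltr, n_pls = grid[i])
      # score columns are standardized to unit pooled within-class SD so
      # the Euclidean centroid rule is not dominated by whichever
      # canonical variate happens to carry the largest (often
      # non-discriminant) variance
      wsd <- sqrt(colSums((m$T - group_means_of(m$T, ltr)[ltr, , drop = FALSE])^2) /
                    max(nrow(Xtr) - nlevels(ltr), 1L))
      wsd[wsd < .Machine$double.eps] <- 1
      cen <- sweep(group_means_of(m$T, ltr), 2L, wsd, "/")
      sc <- sweep(project_ecva(m, Xte), 2L, wsd, "/")
      pred <- levels(ltr)[apply(sc, 1L, function(t_)
        which.min(colSums((t(cen) - t_)^2)))]
      errs[i] <- errs[i] + sum(pred != as.character(lte))
    }
  }
  best <- grid[which.min(errs)]   # which.min takes the first (smallest) tie
  list(n_pls = best, cv_errors = errs)
}

#' Variable screening: keep the top-k most important variables and refit
#'
#' Fits eCVA on all variables, ranks them by the Euclidean norm of their row
#' of W (their length over the g-1 canonical directions), keeps the `k`
#' highest, then refits both the scaling and the eCVA model on the reduced
#' table. Used to shrink a very wide block (e.g. thousands of peptides) to a
#' size comparable with the other platform before fusion.
#'
#' @param X raw (unscaled) training matrix.
#' @param labels class per row.
#' @param k number of variables to retain.
#' @param n_pls inner PLS component count used for both fits.
#' @param scale scaling method (see [fit_scaling()]).
#' @return the refitted `ecva_model`; `selected_variables` records the
#'   retained ids and `scaling` the re-fitted scaling model.
#' @export
select_top_k_and_refit <- function(X, labels, k, n_pls, scale = "vast") {
  X <- as.matrix(X)
  if (k <= 0L) stop("k must be positive")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sc0 <- fit_scaling(X, scale)
  m0 <- fit_ecva(apply_scaling(sc0, X), labels, n_pls = n_pls)
  imp <- sqrt(rowSums(m0$W^2))
  k <- min(k, length(imp))
  keep <- rownames(m0$W)[order(imp, decreasing = TRUE)][seq_len(k)]  # stable: ties -> lowest index
  keep <- keep[order(match(keep, rownames(m0$W)))]  # back to original column order
  X2 <- X[, keep, drop = FALSE]
  sc1 <- fit_scaling(X2, scale)
  fit_ecva(apply_scaling(sc1, X2), labels, n_pls = min(n_pls, ncol(X2)),
           scaling = sc1)
}
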