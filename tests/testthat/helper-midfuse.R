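# shared fixtures: all data are generated in code at test time

# small two-block study for module-level tests (fast to fit)
tiny_sim <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_per_class = 8L, p = c(120L, 40L),
               n_discriminant = list(c(8L, 4L), c(4L, 2L)),
               n_missing = c(2L, 2L), peptides_per_protein = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_study(do.call(simulation_config, args))
}

# labelled Gaussian classes with a mean shift along given directions
gauss_classes <- function(n_per, p, shifts, sd = 1) {
  g <- length(shifts)
  X <- matrix(stats::rnorm(g * n_per * p, sd = sd), g * n_per, p)
  lab <- rep(seq_len(g), each = n_per)
  for (i in seq_len(g)) X[lab == i, ] <- sweep(X[lab == i, , drop = FALSE],
                                               2, shifts[[i]], "+")
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, labels = lab)
}

# orthonormal bases -> largest principal angle (radians)
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  d <- svd(crossprod(qa, qb))$d
  max(acos(pmin(1, d)))
}

# reference discriminant subspace from the dense generalized eigenproblem
eigen_cva_subspace <- function(X, labels, ncv) {
  Sw <- within_covariance(X, labels)
  Sb <- between_covariance(X, labels)
  ev <- eigen(solve(Sw) %*% Sb)
  Re(ev$vectors[, seq_len(ncv), drop = FALSE])
}
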