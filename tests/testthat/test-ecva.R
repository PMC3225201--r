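test_that("within/between covariance match hand sums and a loop oracle", {
  # one group, symmetric about its mean: scatter / (n - g)... needs n > g,
  # so use the printed two-sample example with an extra duplicated pair
  X1 <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  W1 <- within_covariance(X1, rep(1, 4))
  expect_equal(W1, rbind(c(4 / 3, 0), c(0, 0)))
  # pairwise-identical samples within each group -> zero scatter
  X2 <- rbind(c(1, 2), c(1, 2), c(5, 1), c(5, 1))
  expect_equal(within_covariance(X2, c(1, 1, 2, 2)), matrix(0, 2, 2))
  # two groups of 2 with means (1,0), (-1,0): S_b = ((4,0),(0,0))
  X3 <- rbind(c(2, 0), c(0, 0), c(-2, 0), c(0, 0))
  expect_equal(between_covariance(X3, c(1, 1, 2, 2)), rbind(c(4, 0), c(0, 0)))
  # equal group means -> zero between matrix
  expect_equal(between_covariance(X2[c(1, 3, 1, 3), ], c(1, 1, 2, 2)),
               matrix(0, 2, 2))

  # brute-force double-loop oracles on random data
  set.seed(11)
  X <- matrix(rnorm(8 * 3), 8, 3)
  lab <- rep(1:2, each = 4)
  Sw_loop <- matrix(0, 3, 3)
  for (i in 1:2) {
    xi <- X[lab == i, , drop = FALSE]
    mi <- colMeans(xi)
    for (j in seq_len(nrow(xi)))
      Sw_loop <- Sw_loop + tcrossprod(xi[j, ] - mi)
  }
  expect_equal(within_covariance(X, lab), Sw_loop / (8 - 2))

  X9 <- matrix(rnorm(9 * 4), 9, 4)
  lab9 <- rep(1:3, each = 3)
  xbar <- colMeans(X9)
  Sb_loop <- matrix(0, 4, 4)
  for (i in 1:3) {
    mi <- colMeans(X9[lab9 == i, ])
    Sb_loop <- Sb_loop + 3 * tcrossprod(mi - xbar)
  }
  Sb <- between_covariance(X9, lab9)
  expect_equal(Sb, Sb_loop / 2)
  expect_lte(qr(Sb)$rank, 2)
  # symmetry to machine precision
  expect_identical(Sb, t(Sb))
  Sw9 <- within_covariance(X9, lab9)
  expect_identical(Sw9, t(Sw9))
  # errors: singleton class, single group between
  expect_error(within_covariance(X, c(1, rep(2, 7))), "singleton")
  expect_error(between_covariance(X, rep(1, 8)), "two classes")
})

test_that("full-rank eCVA matches the dense eigenproblem solution", {
  set.seed(42)
  gc <- gauss_classes(10, 5, list(c(2, 0, 0, 0, 0), c(0, 0, 0, 0, 0),
                                  c(0, -2, 0, 0, 0)))
  m <- fit_ecva(gc$X, gc$labels, n_pls = 5)
  V <- eigen_cva_subspace(gc$X, gc$labels, 2)
  expect_lt(max_principal_angle(V, m$W), 1e-6)
  expect_equal(ncol(m$T), 2L)              # min(p, g-1) score columns
  expect_equal(unname(sqrt(colSums(m$W^2))), c(1, 1))  # unit-norm directions
})

test_that("two-class direction follows S_w^{-1} (mean difference)", {
  set.seed(5)
  gc <- gauss_classes(60, 4, list(c(1, 2, 0, -1), c(0, 0, 0, 0)))
  m <- fit_ecva(gc$X, gc$labels, n_pls = 4)
  d <- colMeans(gc$X[gc$labels == 1, ]) - colMeans(gc$X[gc$labels == 2, ])
  w_ref <- solve(within_covariance(gc$X, gc$labels), d)
  cosine <- abs(sum(m$W[, 1] * w_ref)) / sqrt(sum(w_ref^2))
  expect_gte(cosine, 0.999)
})

test_that("directions are invariant to the covariance divisor convention", {
  set.seed(8)
  gc <- gauss_classes(8, 4, list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(-1, -1, 0, 0)))
  m <- fit_ecva(gc$X, gc$labels, n_pls = 4)
  # same PLS solve with the biased-divisor within matrix: scaling the
  # predictor rescales B but not its column space
  Sw_alt <- m$S_within * (nrow(gc$X) - 3) / nrow(gc$X)
  B_alt <- midfuse:::nipals_pls2(Sw_alt, m$Y_targets, 4)$B
  W_alt <- midfuse:::fix_signs(svd(B_alt, nu = 2, nv = 0)$u)
  expect_lt(max_principal_angle(m$W, W_alt), 1e-8)
})

test_that("degenerate class structure is detected", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30, 4)
  lab <- rep(1:3, each = 10)
  # identical means for groups 1 and 2 by construction
  X[lab == 3, 1] <- X[lab == 3, 1] + 10
  gm <- colMeans(X[lab == 1, ])
  X[lab == 2, ] <- sweep(X[lab == 2, ], 2,
                         colMeans(X[lab == 2, ]) - gm, "-")
  m <- fit_ecva(X, lab, n_pls = 4)
  expect_lt(min(m$eigen_ratios), 0.15 * max(m$eigen_ratios))
  cen <- rowsum(m$T, lab) / 10
  d12 <- sqrt(sum((cen[1, ] - cen[2, ])^2))
  d13 <- sqrt(sum((cen[1, ] - cen[3, ])^2))
  expect_lt(d12, 0.05 * d13)
  # all group means equal -> no between-group signal
  Xeq <- X
  for (i in 1:3) Xeq[lab == i, ] <- sweep(Xeq[lab == i, ], 2,
                                          colMeans(Xeq[lab == i, ]) - gm, "-")
  expect_error(fit_ecva(Xeq, lab, n_pls = 2), "no between-group signal")
  expect_error(fit_ecva(X, lab, n_pls = 0), "n_pls")
  expect_error(fit_ecva(X, lab, n_pls = 40), "n_pls")
})

test_that("projection is consistent with training scores and centering", {
  set.seed(9)
  gc <- gauss_classes(7, 6, list(rep(1, 6), rep(-1, 6), rep(0, 6)))
  m <- fit_ecva(gc$X, gc$labels, n_pls = 5)
  expect_equal(project_ecva(m, gc$X), m$T)
  expect_equal(unname(drop(project_ecva(m, matrix(m$overall_mean, 1)))),
               c(0, 0))
  # a sample at group 1's mean lands on its score centroid
  cen1 <- colMeans(m$T[gc$labels == 1, ])
  expect_equal(unname(drop(project_ecva(m, matrix(m$group_means[1, ], 1)))),
               unname(cen1))
  expect_error(project_ecva(m, gc$X[, 1:3]), "variables")
})

test_that("scaling the data leaves the discriminant directions unchanged", {
  set.seed(10)
  gc <- gauss_classes(8, 5, list(c(2, 0, 0, 0, 0), c(0, 2, 0, 0, 0),
                                 c(0, 0, 0, 0, 0)))
  m1 <- fit_ecva(gc$X, gc$labels, n_pls = 4)
  m3 <- fit_ecva(3 * gc$X, gc$labels, n_pls = 4)
  expect_equal(m3$W, m1$W, tolerance = 1e-8)
  expect_equal(m3$T, 3 * m1$T, tolerance = 1e-8)
})

test_that("inner-CV component selection obeys its contract", {
  set.seed(12)
  # strong rank-1 class signal: every candidate classifies perfectly, so
  # the tie-break must return the smallest count
  gc <- gauss_classes(14, 10, list(c(10, rep(0, 9)), c(-10, rep(0, 9))))
  sel <- select_pls_components(gc$X, gc$labels, grid = 1:5)
  expect_equal(sel$n_pls, 1L)
  expect_true(all(sel$cv_errors == sel$cv_errors[1]))
  # single candidate: returned without cross-validation
  expect_equal(select_pls_components(gc$X, gc$labels, grid = 3)$n_pls, 3L)
  expect_error(select_pls_components(gc$X, gc$labels, grid = integer(0)))
  expect_error(select_pls_components(gc$X, gc$labels, grid = 99))
  # tiny classes force a reduced fold count
  gc2 <- gauss_classes(4, 6, list(rep(2, 6), rep(-2, 6)))
  expect_warning(select_pls_components(gc2$X, gc2$labels, grid = 1:2),
                 "fold count reduced")
})

test_that("top-k screening keeps truly discriminant variables and k=p is a no-op", {
  set.seed(20)
  gc <- gauss_classes(10, 6, list(rep(5, 6), rep(-5, 6)))
  X <- abs(gc$X) + 5   # positive data so vast scaling is well-behaved
  direct <- fit_ecva(apply_scaling(fit_scaling(X, "vast"), X), gc$labels, 4)
  refit <- select_top_k_and_refit(X, gc$labels, k = ncol(X), n_pls = 4)
  expect_equal(refit$W, direct$W)
  expect_error(select_top_k_and_refit(X, gc$labels, k = 0, n_pls = 2), "positive")

  hits <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 40; p <- 10
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    lab <- rep(1:2, each = n / 2)
    X[lab == 1, 1:2] <- X[lab == 1, 1:2] + 3
    m <- select_top_k_and_refit(X, lab, k = 2, n_pls = 10, scale = "autoscale")
    if (setequal(m$selected_variables, c("v1", "v2"))) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})
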