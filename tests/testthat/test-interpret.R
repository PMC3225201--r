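# minimal hand-built fusion model: one block, identity directions and
# identity global loadings, so every quantity is checkable by hand
fake_fusion <- function(W = diag(2), P = diag(2),
                        centroids = rbind(G1 = c(2, 0), G2 = c(-2, 0))) {
  rownames(W) <- paste0("v", seq_len(nrow(W)))
  structure(list(
    blocks = list(A = list(block_id = "A",
                           ecva = list(W = W, selected_variables = rownames(W)))),
    col_block = rep("A", ncol(W)),
    global = list(loadings = P),
    centroids = centroids,
    class_levels = rownames(centroids),
    r_global = ncol(P)), class = "fusion_model")
}

test_that("global weights are the W x P product", {
  fm <- fake_fusion()
  expect_equal(unname(global_weights(fm, "A")), diag(2))
  expect_error(global_weights(fm, "nope"), "unknown block")
  # random small case against an explicit multiply
  set.seed(1)
  W <- matrix(rnorm(10), 5, 2)
  P <- matrix(rnorm(4), 2, 2)
  fm2 <- fake_fusion(W = W, P = P)
  manual <- matrix(0, 5, 2)
  for (i in 1:5) for (j in 1:2)
    manual[i, j] <- sum(W[i, ] * P[, j])
  expect_equal(unname(global_weights(fm2, "A")), manual)
})

test_that("group importance projects on the class-centroid direction", {
  fm <- fake_fusion()
  imp <- group_importance(fm, "G1")
  # v1's weight row equals the G1 direction -> importance 1; v2 orthogonal -> 0
  expect_equal(imp$importance[imp$variable_id == "v1"], 1)
  expect_equal(imp$importance[imp$variable_id == "v2"], 0)
  expect_equal(sum(abs(imp$importance) == 1), 1L)  # unique maximum
  expect_equal(imp$direction[imp$variable_id == "v1"], "up")
  # the same variable is down-regulated for the opposite group
  imp2 <- group_importance(fm, "G2")
  expect_equal(imp2$importance[imp2$variable_id == "v1"], -1)
  expect_error(group_importance(fm, "G9"), "unknown class")
  fm0 <- fake_fusion(centroids = rbind(G1 = c(0, 0), G2 = c(1, 0)))
  expect_error(group_importance(fm0, "G1"), "indistinguishable")
})

test_that("peptide roll-up follows the >= 3 same-sign rule", {
  tab <- data.frame(
    variable_id = paste0("p", 1:9),
    block_id = "A",
    raw = 0,
    importance = c(0.5, 0.7, 0.6,      # PROT1: three up peptides
                   0.5, -0.7,          # PROT2: only two peptides
                   0.5, 0.6, 0.7, -0.9),  # PROT3: 3 up vs 1 down
    direction = "up")
  map <- data.frame(variable_id = paste0("p", 1:9),
                    protein_accession = rep(c("PROT1", "PROT2", "PROT3"),
                                            c(3, 2, 4)))
  out <- aggregate_peptides(tab, map)
  expect_setequal(out$protein_accession, c("PROT1", "PROT3"))
  expect_equal(out$importance[out$protein_accession == "PROT1"], 0.6)
  # dissenting peptide excluded from the average
  expect_equal(out$importance[out$protein_accession == "PROT3"], 0.6)
  expect_equal(out$n_peptides[out$protein_accession == "PROT3"], 3L)
  # sign tie: no majority behaviour -> omitted
  tie <- data.frame(variable_id = paste0("q", 1:4), block_id = "A", raw = 0,
                    importance = c(0.5, 0.6, -0.5, -0.6), direction = "up")
  tmap <- data.frame(variable_id = paste0("q", 1:4),
                     protein_accession = "TIE")
  expect_equal(nrow(aggregate_peptides(tie, tmap, min_peptides = 2)), 0L)
  # duplicate mapping is a hard error
  badmap <- rbind(map, data.frame(variable_id = "p1",
                                  protein_accession = "OTHER"))
  expect_error(aggregate_peptides(tab, badmap), "more than one protein")
  expect_error(aggregate_peptides(tab, map, min_peptides = 0), "min_peptides")
})

# small two-block study with known correlation structure
corr_study <- function() {
  set.seed(42)
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  x <- rnorm(n)
  A <- cbind(a1 = x, a2 = 2 * x + 1, a3 = -x, a4 = rnorm(n),
             a5 = rep(3, n))            # constant within every class
  B <- cbind(b1 = x + rnorm(n, sd = 2), b2 = rnorm(n))
  rownames(A) <- rownames(B) <- ids
  labels <- setNames(rep(c("G1", "G2"), each = 6), ids)
  st <- align_blocks(list(omics_block(A, "A"), omics_block(B, "B")), labels)
  list(study = st,
       vars = list(A = colnames(A), B = colnames(B)))
}

test_that("class-conditional correlations match the textbook formula", {
  cs <- corr_study()
  co <- class_correlations(cs$vars, cs$study, "G1")
  expect_equal(co$r["a1", "a2"], 1)       # y = 2x + 1
  expect_equal(co$r["a1", "a3"], -1)      # y = -x
  expect_true(co$degenerate["a5"])
  expect_equal(co$r["a5", "a1"], 0)       # constant -> flagged zero
  expect_equal(diag(co$r), setNames(rep(1, 7), colnames(co$r)))
  expect_identical(co$r, t(co$r))
  # two-pass formula oracle on the same samples
  members <- names(cs$study$labels)[cs$study$labels == "G1"]
  x1 <- cs$study$blocks$A$values[members, "a1"]
  y1 <- cs$study$blocks$B$values[members, "b1"]
  r_manual <- sum((x1 - mean(x1)) * (y1 - mean(y1))) /
    ((length(x1) - 1) * sd(x1) * sd(y1))
  expect_equal(co$r["a1", "b1"], r_manual, tolerance = 1e-12)
})

test_that("pairs with too few shared samples are recorded as missing", {
  cs <- corr_study()
  # drop block B for all but two G1 samples
  Bv <- cs$study$blocks$B$values
  keep <- c(rownames(Bv)[1:2], rownames(Bv)[7:12])
  B2 <- omics_block(Bv[keep, ], "B")
  st2 <- align_blocks(list(cs$study$blocks$A, B2), cs$study$labels)
  co <- class_correlations(cs$vars, st2, "G1")
  expect_true(is.na(co$r["a1", "b1"]))    # 2 shared samples < 3
  expect_false(is.na(co$r["a1", "a2"]))
})

test_that("network edges require |r| strictly above the threshold", {
  C <- diag(3)
  dimnames(C) <- list(c("x", "y", "z"), c("x", "y", "z"))
  C["x", "y"] <- C["y", "x"] <- 0.8       # exactly at threshold: no edge
  C["x", "z"] <- C["z", "x"] <- -0.85
  co <- list(r = C, blocks = setNames(rep("A", 3), colnames(C)),
             class = "G1")
  net <- build_network(list(co), threshold = 0.8, important = "x")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$var_a, "x")
  expect_equal(net$edges$var_b, "z")
  expect_equal(net$edges$r, -0.85)
  expect_true(net$nodes$important[net$nodes$id == "x"])
  expect_error(build_network(list(co), threshold = 1.5), "threshold")
})

test_that("network edge set equals a brute-force scan over pairs and classes", {
  cs <- corr_study()
  cos <- lapply(c("G1", "G2"), function(cl)
    class_correlations(cs$vars, cs$study, cl))
  net <- build_network(cos, threshold = 0.6)
  count <- 0L
  for (co in cos) {
    vars <- colnames(co$r)
    for (i in seq_along(vars)) for (j in seq_along(vars)) {
      if (i < j && !is.na(co$r[i, j]) && abs(co$r[i, j]) > 0.6)
        count <- count + 1L
    }
  }
  expect_equal(nrow(net$edges), count)
  expect_true(all(net$edges$var_a < net$edges$var_b))
})

test_that("subnetwork extraction is a bounded breadth-first expansion", {
  edges <- data.frame(var_a = c("a", "b", "c"), var_b = c("b", "c", "d"),
                      class = "G1", r = 0.9)
  nodes <- data.frame(id = c("a", "b", "c", "d", "e"), block = "A",
                      important = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, threshold = 0.8),
                   class = "correlation_network")
  sub <- extract_subnetwork(net, "a", layers = 2)
  expect_setequal(sub$nodes$id, c("a", "b", "c"))
  expect_equal(nrow(sub$edges), 2L)
  # isolated seed stays alone
  sub_e <- extract_subnetwork(net, "e", layers = 2)
  expect_equal(sub_e$nodes$id, "e")
  expect_equal(nrow(sub_e$edges), 0L)
  # enough layers saturate the connected component
  sub_all <- extract_subnetwork(net, "a", layers = 10)
  expect_setequal(sub_all$nodes$id, c("a", "b", "c", "d"))
  # monotone in layers
  s1 <- extract_subnetwork(net, "a", layers = 1)
  expect_true(all(s1$nodes$id %in% sub$nodes$id))
  expect_error(extract_subnetwork(net, "zz"), "unknown seed")
})

test_that("DOT export is deterministic and styled by class", {
  nodes <- data.frame(id = c("m1", "p1"), block = c("B", "A"),
                      important = c(FALSE, TRUE))
  edges <- data.frame(var_a = "m1", var_b = "p1", class = "disease", r = 0.9)
  net <- structure(list(nodes = nodes, edges = edges, threshold = 0.8),
                   class = "correlation_network")
  dot <- export_dot(net, reference_class = "control")
  expect_match(dot, "\"p1\" \\[shape=box\\]")
  expect_match(dot, "\"m1\" \\[shape=ellipse\\]")
  expect_equal(lengths(regmatches(dot, gregexpr("style=dotted", dot))), 1L)
  # reference-class edges are solid
  edges2 <- rbind(edges, data.frame(var_a = "m1", var_b = "p1",
                                    class = "control", r = 0.82))
  net2 <- structure(list(nodes = nodes, edges = edges2, threshold = 0.8),
                    class = "correlation_network")
  dot2 <- export_dot(net2, reference_class = "control")
  expect_match(dot2, "style=solid")
  # empty network is still valid DOT
  net0 <- structure(list(nodes = nodes[0, ], edges = edges[0, ],
                         threshold = 0.8), class = "correlation_network")
  expect_equal(export_dot(net0), "graph correlation_network {\n}\n")
  # parse back node/edge statements and compare counts
  lines <- strsplit(dot2, "\n")[[1]]
  expect_equal(sum(grepl("\\[shape=", lines)), nrow(nodes))
  expect_equal(sum(grepl(" -- ", lines)), nrow(edges2))
})
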