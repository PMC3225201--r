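# Interpretation layer: back-projection of the global PCA loadings through
# each block's canonical directions to variable-level weights, group-wise
# importance with joint max-1 normalization, peptide-to-protein roll-up,
# and class-conditional Pearson correlation networks.

# rows of the global loading matrix belonging to one block's score columns
block_loading_rows <- function(fusion, block_id) {
  fusion$global$loadings[fusion$col_block == block_id, , drop = FALSE]
}

#' Back-project global loadings to one block's original variables
#'
#' The weight of each original variable in the global model is the product
#' of the block's canonical directions W (p_b x (g-1)) with the global PCA
#' loading rows belonging to that block's score columns ((g-1) x r_global).
#'
#' @param fusion a `fusion_model`.
#' @param block_id which block.
#' @return p_b x r_global matrix, rows named by the block's selected
#'   variables.
#' @export
global_weights <- function(fusion, block_id) {
  if (!block_id %in% names(fusion$blocks))
    stop("unknown block '", block_id, "'")
  bm <- fusion$blocks[[block_id]]
  bm$ecva$W %*% block_loading_rows(fusion, block_id)
}

#' Variable importance for discriminating one group
#'
#' Projects every variable's global-weight row onto the unit vector pointing
#' from the origin (the grand mean) to the target class's centroid in the
#' retained PC space. All blocks are normalized jointly so that the largest
#' absolute importance is 1. A positive value means the variable is
#' up-regulated in the target group, negative down-regulated.
#'
#' @param fusion a `fusion_model`.
#' @param target_class class label (or index into the class levels).
#' @return an `importance_table` data frame with columns `variable_id`,
#'   `block_id`, `raw`, `importance` and `direction` (`"up"`/`"down"`),
#'   sorted by decreasing absolute importance.
#' @export
group_importance <- function(fusion, target_class) {
  if (is.numeric(target_class)) target_class <- fusion$class_levels[target_class]
  if (!target_class %in% fusion$class_levels)
    stop("unknown class '", target_class, "'")
  cen <- fusion$centroids[target_class, ]
  nc <- sqrt(sum(cen^2))
  if (nc < 1e-12)
    stop("group '", target_class, "' indistinguishable from the grand mean")
  d <- cen / nc
  tabs <- lapply(names(fusion$blocks), function(bid) {
    gw <- global_weights(fusion, bid)
    data.frame(variable_id = rownames(gw), block_id = bid,
               raw = drop(gw %*% d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  mx <- max(abs(out$raw))
  if (mx < .Machine$double.eps) stop("all importances are zero")
  out$importance <- out$raw / mx
  out$direction <- ifelse(out$importance >= 0, "up", "down")
  out <- out[order(-abs(out$importance), out$block_id, out$variable_id), ]
  rownames(out) <- NULL
  attr(out, "target_class") <- target_class
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Roll peptide importances up to proteins
#'
#' A protein is reported only when at least `min_peptides` of its peptides
#' behave similarly, i.e. agree on the sign of their importance (same
#' up/down regulation in the target group). The protein importance is the
#' mean over those majority-sign peptides; dissenting peptides are excluded
#' from the average. Proteins with a sign tie among their peptides are
#' omitted (no majority behaviour).
#'
#' @param table an `importance_table` from [group_importance()].
#' @param map data frame `variable_id, protein_accession` (each variable
#'   maps to at most one protein).
#' @param min_peptides minimum number of agreeing peptides (default 3).
#' @return data frame `protein_accession, n_peptides, importance, direction`
#'   sorted by decreasing absolute importance.
#' @export
aggregate_peptides <- function(table, map, min_peptides = 3L) {
  if (min_peptides < 1L) stop("min_peptides must be >= 1")
  if (anyDuplicated(map$variable_id))
    stop("a variable_id maps to more than one protein accession")
  tab <- merge(as.data.frame(table), map, by = "variable_id")
  out <- do.call(rbind, lapply(split(tab, tab$protein_accession), function(d) {
    pos <- d$importance > 0
    neg <- d$importance < 0
    n_pos <- sum(pos); n_neg <- sum(neg)
    if (n_pos == n_neg) return(NULL)             # no majority behaviour
    keep <- if (n_pos > n_neg) pos else neg
    if (sum(keep) < min_peptides) return(NULL)
    data.frame(protein_accession = d$protein_accession[1L],
               n_peptides = sum(keep),
               importance = mean(d$importance[keep]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(protein_accession = character(0),
                      n_peptides = integer(0), importance = numeric(0),
                      direction = character(0)))
  out$direction <- ifelse(out$importance >= 0, "up", "down")
  out <- out[order(-abs(out$importance), out$protein_accession), ]
  rownames(out) <- NULL
  out
}

#' Class-conditional Pearson correlations over selected variables
#'
#' For one class, computes all pairwise Pearson correlations between the
#' variables selected by each block's model, using only the samples of that
#' class that are present in every block a pair involves (pairwise-complete
#' deletion). Pairs with fewer than 3 usable samples are recorded as
#' missing; a variable that is constant within the class yields r = 0 for
#' its pairs and is flagged as degenerate, so node sets stay comparable
#' across classes.
#'
#' @param fusion a `fusion_model` (defines the selected variables per
#'   block), or a named list mapping block ids to variable-id vectors.
#' @param study the aligned study with the raw values.
#' @param class class label.
#' @return list with `r` (correlation matrix, NA = not computable), `n`
#'   (complete-pair counts), `degenerate` (logical per variable), `blocks`
#'   (block of each variable) and `class`.
#' @export
class_correlations <- function(fusion, study, class) {
  if (!class %in% levels(study$labels)) stop("unknown class '", class, "'")
  var_sets <- if (inherits(fusion, "fusion_model")) {
    lapply(fusion$blocks, function(bm) bm$ecva$selected_variables)
  } else as.list(fusion)
  members <- names(study$labels)[study$labels == class]
  cols <- lapply(names(var_sets), function(bid) {
    vars <- var_sets[[bid]]
    present <- members[study$presence[members, bid]]
    M <- matrix(NA_real_, length(members), length(vars),
                dimnames = list(members, vars))
    M[present, ] <- block_values(study, bid, present)[, vars, drop = FALSE]
    M
  })
  M <- do.call(cbind, cols)
  blocks <- rep(names(var_sets), vapply(cols, ncol, integer(1L)))
  nvar <- ncol(M)
  cnt <- crossprod(!is.na(M)) * 1
  sds <- apply(M, 2L, stats::sd, na.rm = TRUE)
  degen <- !is.na(sds) & sds == 0
  C <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  C[degen, ] <- 0; C[, degen] <- 0
  diag(C) <- 1
  C[cnt < 3L] <- NA_real_   # too few complete pairs beats everything
  names(blocks) <- colnames(M)
  list(r = C, n = cnt, degenerate = stats::setNames(degen, colnames(M)),
       blocks = blocks, class = class)
}

#' Build a class-conditional correlation network
#'
#' One edge per variable pair and class whenever |r| strictly exceeds the
#' threshold. Nodes are the union of the selected variables, annotated with
#' their block and with an importance flag taken from `important`.
#'
#' @param cors list of [class_correlations()] results (one per class).
#' @param threshold absolute-correlation threshold in (0, 1); the edge rule
#'   is strict (`|r| > threshold`), so r equal to the threshold yields no
#'   edge. Default 0.8.
#' @param important variable ids to flag as important (e.g. the top of an
#'   [group_importance()] table).
#' @return a `correlation_network` with data frames `nodes` (`id`, `block`,
#'   `important`) and `edges` (`var_a`, `var_b`, `class`, `r`; `var_a <
#'   var_b` lexicographically).
#' @export
build_network <- function(cors, threshold = 0.8, important = character(0)) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!is.null(cors$r)) cors <- list(cors)
  ids <- unique(unlist(lapply(cors, function(co) colnames(co$r))))
  blocks <- unlist(lapply(cors, function(co) co$blocks))
  blocks <- blocks[!duplicated(names(blocks))]
  nodes <- data.frame(id = sort(ids),
                      block = as.character(blocks[sort(ids)]),
                      important = sort(ids) %in% important,
                      stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(cors, function(co) {
    C <- co$r
    idx <- which(upper.tri(C) & !is.na(C) & abs(C) > threshold, arr.ind = TRUE)
    if (!nrow(idx))
      return(data.frame(var_a = character(0), var_b = character(0),
                        class = character(0), r = numeric(0)))
    a <- colnames(C)[idx[, 1L]]; b <- colnames(C)[idx[, 2L]]
    swap <- a > b
    data.frame(var_a = ifelse(swap, b, a), var_b = ifelse(swap, a, b),
               class = co$class, r = C[idx], stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$var_a, edges$var_b, edges$class), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|r| > ", x$threshold, ")", sep = "")
  if (nrow(x$edges))
    cat(" across classes ", paste(unique(x$edges$class), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Extract the neighbourhood of seed variables
#'
#' Breadth-first expansion: keeps every node within `layers` steps of any
#' seed, where edges of any class count for adjacency, together with the
#' induced edges (class annotations preserved). The default of two layers
#' gives the seed's correlates and their correlates.
#'
#' @param net a `correlation_network`.
#' @param seeds variable ids present in the network.
#' @param layers expansion depth (default 2).
#' @return the induced `correlation_network`.
#' @export
extract_subnetwork <- function(net, seeds, layers = 2L) {
  if (layers < 1L) stop("layers must be >= 1")
  unknown <- setdiff(seeds, net$nodes$id)
  if (length(unknown))
    stop("unknown seed: ", paste(unknown, collapse = ", "))
  adj <- rbind(as.matrix(net$edges[, c("var_a", "var_b")]),
               as.matrix(net$edges[, c("var_b", "var_a")]))
  frontier <- unique(seeds)
  keep <- frontier
  for (l in seq_len(layers)) {
    if (!length(frontier)) break
    nxt <- setdiff(unique(adj[adj[, 1L] %in% frontier, 2L]), keep)
    keep <- c(keep, nxt)
    frontier <- nxt
  }
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$var_a %in% keep & net$edges$var_b %in% keep, ,
                     drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = net$threshold),
            class = "correlation_network")
}

#' Export a correlation network as Graphviz DOT text
#'
#' One node statement per variable — `shape=box` for variables flagged
#' important, `shape=ellipse` otherwise — and one edge statement per (pair,
#' class). Edges of the reference class (e.g. healthy controls) are drawn
#' solid; other classes get dotted/dashed styles in class order. Node and
#' edge statements are ordered lexicographically so the output is
#' deterministic.
#'
#' @param net a `correlation_network`.
#' @param reference_class class drawn with solid edges (default: the first
#'   class occurring in the edge set, alphabetically).
#' @param styles optional named character vector class -> DOT line style.
#' @return a single DOT string (also see [write_dot()]).
#' @export
export_dot <- function(net, reference_class = NULL, styles = NULL) {
  classes <- sort(unique(net$edges$class))
  if (is.null(reference_class)) reference_class <- classes[1L]
  if (is.null(styles)) {
    others <- setdiff(classes, reference_class)
    styles <- c(stats::setNames(rep("solid", length(reference_class)), reference_class),
                stats::setNames(rep(c("dotted", "dashed"), length.out = length(others)),
                                others))
  }
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c("graph correlation_network {")
  nodes <- net$nodes[order(net$nodes$id), , drop = FALSE]
  if (nrow(nodes)) {
    shape <- ifelse(nodes$important, "box", "ellipse")
    lines <- c(lines, sprintf("  %s [shape=%s];", q(nodes$id), shape))
  }
  edges <- net$edges[order(net$edges$var_a, net$edges$var_b, net$edges$class), ,
                     drop = FALSE]
  if (nrow(edges)) {
    st <- styles[edges$class]
    st[is.na(st)] <- "dashed"
    lines <- c(lines, sprintf("  %s -- %s [style=%s, label=\"%.2f\"];",
                              q(edges$var_a), q(edges$var_b), st, edges$r))
  }
  lines <- c(lines, "}")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a network to a DOT file
#'
#' @inheritParams export_dot
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(net, path, reference_class = NULL, styles = NULL) {
  writeLines(export_dot(net, reference_class, styles), path, sep = "")
  invisible(path)
}

#' Write a network edge list to CSV
#'
#' @param net a `correlation_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an importance table to CSV
#'
#' @param table an `importance_table` (or protein-level table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
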