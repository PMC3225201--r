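# Seeded generator of two-block studies with the structure the fusion
# method assumes: a wide proteomics-like block with a two-batch nuisance
# effect, a narrow metabolomics-like block, correlated background through
# shared latent factors, planted class-discriminant variables of known
# identity and sign, and a few samples missing per block.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a three-group animal study (healthy control G1,
#' treatment control G2, disease G3; 15 subjects per group) profiled on two
#' platforms: a wide peptide-level block (2000 variables, a two-batch
#' offset on part of the variables) and a 153-bin spectral block. Both
#' blocks carry both biological contrasts — a disease axis (G3 against the
#' two controls) and a control-split axis (G1 against G2) — with more
#' variables devoted to the disease axis in the wide block and to the
#' control split in the narrow one, so each platform classifies far above
#' chance yet imperfectly and fusing them helps. For a sharply
#' complementary design give each block a single one-vs-rest contrast
#' (e.g. `class_contrast = list(c(-0.5, -0.5, 1), c(1, -0.5, -0.5))`), so
#' that neither platform alone can resolve all three groups.
#'
#' Discriminant variables come in co-regulated modules: the variables of
#' one contrast share a within-class latent factor along their effect
#' signs, because analytes responding to a biological process covary
#' within groups as well as shifting between them. This within-group
#' collinearity along the effect direction is realistic for omics data and
#' is also the regime a PLS-regularized inversion of the within-group
#' covariance is designed for; with mutually independent variables no
#' covariance-range method can localize the effect.
#'
#' @param g number of classes.
#' @param n_per_class samples per class.
#' @param p per-block variable counts.
#' @param block_ids per-block names.
#' @param class_contrast per-block matrix (contrast groups x g) of
#'   class-mean profiles; a plain vector is taken as a single contrast.
#' @param n_discriminant per-block integer vector: planted variables per
#'   contrast group.
#' @param effect_size per-block vector: effect per contrast group in
#'   within-class SD units (applied as effect * contrast[class] * a random
#'   per-variable sign).
#' @param n_latent,latent_scale shared latent factors inducing
#'   multicollinear background correlation across all variables.
#' @param module_scale within-class SD of the co-regulation factor shared
#'   by each contrast group's planted variables.
#' @param batch_block index of the block carrying the batch offset (NA =
#'   none); `batch_fraction` of samples are offset by `batch_offset` SD
#'   units on `batch_var_fraction` of the variables.
#' @param n_missing per-block count of samples dropped from the block.
#' @param noise_sd independent Gaussian noise SD (relative share; the
#'   stochastic within-class part of every variable is normalized to unit
#'   SD, so `noise_sd`, `latent_scale` and `module_scale` set variance
#'   shares while effects stay in SD units exactly).
#' @param baseline_range variable baselines are drawn uniformly from this
#'   range (in within-class SD units). Each variable's whole signal is
#'   scaled in proportion to its baseline, i.e. measurement precision is
#'   relative to intensity as in spectral and abundance data, so
#'   mean-to-SD ratios are comparable across variables — the regime in
#'   which vast scaling is stable.
#' @param peptides_per_protein grouping of block-1 variables into parent
#'   proteins for the roll-up map (0 = no map).
#' @param seed random seed; the generator is deterministic given the seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(g = 3L, n_per_class = 15L,
                              p = c(2000L, 153L),
                              block_ids = c("prot", "metab"),
                              class_contrast = list(
                                rbind(c(-0.5, -0.5, 1), c(1, -1, 0)),
                                rbind(c(1, -1, 0), c(-0.5, -0.5, 1))),
                              n_discriminant = list(c(30L, 10L),
                                                    c(10L, 5L)),
                              effect_size = list(c(1.2, 1.2),
                                                 c(1.2, 1.2)),
                              n_latent = 3L, latent_scale = 0.5,
                              module_scale = 1.0,
                              batch_block = 1L, batch_fraction = 0.5,
                              batch_offset = 1.0, batch_var_fraction = 0.2,
                              n_missing = c(3L, 5L),
                              noise_sd = 0.5,
                              baseline_range = c(10, 30),
                              peptides_per_protein = 4L,
                              seed = 1L) {
  nb <- length(p)
  class_contrast <- lapply(class_contrast, function(ct) {
    if (is.null(dim(ct))) ct <- matrix(ct, nrow = 1L)
    ct
  })
  if (!is.list(n_discriminant)) n_discriminant <- as.list(n_discriminant)
  if (!is.list(effect_size)) effect_size <- as.list(effect_size)
  stopifnot(g >= 2L, n_per_class >= 2L, all(p >= 1L),
            length(block_ids) == nb, length(class_contrast) == nb,
            length(n_discriminant) == nb, length(effect_size) == nb,
            all(vapply(class_contrast, ncol, integer(1L)) == g),
            all(vapply(seq_len(nb), function(b)
              length(n_discriminant[[b]]) == nrow(class_contrast[[b]]) &&
              length(effect_size[[b]]) == nrow(class_contrast[[b]]),
              logical(1L))),
            all(vapply(n_discriminant, sum, numeric(1L)) <= p),
            all(n_missing < n_per_class))
  structure(list(g = g, n_per_class = n_per_class, p = p,
                 block_ids = block_ids, n_discriminant = n_discriminant,
                 effect_size = effect_size, class_contrast = class_contrast,
                 n_latent = n_latent, latent_scale = latent_scale,
                 module_scale = module_scale,
                 batch_block = batch_block, batch_fraction = batch_fraction,
                 batch_offset = batch_offset,
                 batch_var_fraction = batch_var_fraction,
                 n_missing = n_missing, noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 peptides_per_protein = peptides_per_protein, seed = seed),
            class = "simulation_config")
}

#' Simulate a multi-block study with known ground truth
#'
#' Each block is built as planted class-mean contrasts + latent-factor
#' background + per-contrast co-regulation modules + independent Gaussian
#' noise (the stochastic part normalized to unit within-class SD per
#' variable), plus an optional batch offset; variables are then placed on
#' intensity scales via their baselines and the configured number of
#' samples is dropped from each block. Deterministic for a given seed.
#'
#' @param config a [simulation_config()].
#' @return list with `study` (an [align_blocks()] result) and `truth`
#'   (class labels, batch labels, per-block data frames of planted
#'   variables with their signs, home class and expected importance sign,
#'   latent factor scores, per-block missing sample ids).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- config$g
  n <- g * config$n_per_class
  nb <- length(config$p)
  sample_ids <- sprintf("s%02d", seq_len(n))
  labels <- stats::setNames(rep(paste0("G", seq_len(g)),
                                each = config$n_per_class), sample_ids)
  cls <- rep(seq_len(g), each = config$n_per_class)
  batch <- stats::setNames(
    ifelse(seq_len(n) %in% sample(n, round(config$batch_fraction * n)),
           "B2", "B1"), sample_ids)
  Z <- matrix(stats::rnorm(n * config$n_latent), n, config$n_latent)

  blocks <- vector("list", nb)
  truth_vars <- vector("list", nb)
  missing_ids <- vector("list", nb)
  names(truth_vars) <- names(missing_ids) <- config$block_ids
  for (b in seq_len(nb)) {
    p_b <- config$p[b]
    var_ids <- if (b == 1L) sprintf("pep%04d", seq_len(p_b))
               else sprintf("bin%03d", seq_len(p_b))
    contrasts <- config$class_contrast[[b]]
    counts <- config$n_discriminant[[b]]
    effects <- config$effect_size[[b]]
    ppp <- if (b == 1L) config$peptides_per_protein else 0L
    if (ppp > 0L && sum(counts) > 0L) {
      # differential proteins contribute whole groups of concordant
      # peptides: plant protein-by-protein with one sign per protein
      n_prot <- ceiling(counts / ppp)
      prots <- sample(ceiling(p_b / ppp), sum(n_prot))
      grp <- integer(0); disc_all <- integer(0); signs <- numeric(0)
      off <- 0L
      for (cg in seq_along(counts)) {
        idx <- integer(0)
        for (pr in prots[off + seq_len(n_prot[cg])])
          idx <- c(idx, intersect((pr - 1L) * ppp + seq_len(ppp), seq_len(p_b)))
        idx <- idx[seq_len(min(counts[cg], length(idx)))]
        sgn_pr <- stats::setNames(sample(c(-1, 1), n_prot[cg], replace = TRUE),
                                  prots[off + seq_len(n_prot[cg])])
        disc_all <- c(disc_all, idx)
        grp <- c(grp, rep(cg, length(idx)))
        signs <- c(signs, unname(sgn_pr[as.character(ceiling(idx / ppp))]))
        off <- off + n_prot[cg]
      }
      ord <- order(disc_all)
      disc_all <- disc_all[ord]; grp <- grp[ord]; signs <- signs[ord]
    } else {
      disc_all <- sort(sample(p_b, sum(counts)))
      grp <- if (sum(counts) > 0)
        rep(seq_along(counts), counts)[order(sample(sum(counts)))] else integer(0)
      signs <- sample(c(-1, 1), sum(counts), replace = TRUE)
    }
    mu_cls <- matrix(0, g, p_b)
    for (cg in seq_along(counts)) {
      idx <- disc_all[grp == cg]
      if (!length(idx)) next
      mu_cls[, idx] <- effects[cg] * outer(contrasts[cg, ], signs[grp == cg])
    }
    L <- matrix(stats::rnorm(p_b * config$n_latent, sd = config$latent_scale),
                p_b, config$n_latent)
    S <- tcrossprod(Z, L) +
      matrix(stats::rnorm(n * p_b, sd = config$noise_sd), n, p_b)
    var_within <- rowSums(L^2) + config$noise_sd^2
    if (config$module_scale > 0) {
      for (cg in seq_along(counts)) {
        idx <- disc_all[grp == cg]
        if (!length(idx)) next
        f <- stats::rnorm(n, sd = config$module_scale)
        S[, idx] <- S[, idx] + outer(f, signs[grp == cg])
        var_within[idx] <- var_within[idx] + config$module_scale^2
      }
    }
    S <- sweep(S, 2L, sqrt(var_within), "/")
    X <- mu_cls[cls, , drop = FALSE] + S
    if (!is.na(config$batch_block) && b == config$batch_block) {
      bvars <- sample(p_b, round(config$batch_var_fraction * p_b))
      X[batch == "B2", bvars] <- X[batch == "B2", bvars] +
        config$batch_offset
    }
    # intensity realism: per-variable baseline, precision proportional to
    # intensity
    baseline <- stats::runif(p_b, config$baseline_range[1L],
                             config$baseline_range[2L])
    X <- sweep(X, 2L, baseline / mean(config$baseline_range), "*")
    X <- sweep(X, 2L, baseline, "+")
    dimnames(X) <- list(sample_ids, var_ids)
    drop_ids <- if (config$n_missing[b] > 0L) {
      # spread exclusions over classes, as instrument losses tend to be
      picks <- character(0)
      pool <- split(sample_ids, cls)
      ci <- rep_len(seq_len(g), config$n_missing[b])
      for (k in seq_len(config$n_missing[b])) {
        cand <- setdiff(pool[[ci[k]]], picks)
        picks <- c(picks, sample(cand, 1L))
      }
      picks
    } else character(0)
    keep <- setdiff(sample_ids, drop_ids)
    meta <- if (b == 1L && config$peptides_per_protein > 0L) {
      data.frame(variable_id = var_ids,
                 protein_accession = sprintf("PROT%04d",
                   ceiling(seq_len(p_b) / config$peptides_per_protein)),
                 stringsAsFactors = FALSE)
    } else NULL
    blocks[[b]] <- omics_block(X[keep, , drop = FALSE],
                               block_id = config$block_ids[b],
                               variable_meta = meta)
    home <- apply(abs(contrasts), 1L, which.max)
    truth_vars[[b]] <- if (sum(counts) == 0L) {
      data.frame(variable_id = character(0), contrast_group = integer(0),
                 effect = numeric(0), sign = numeric(0),
                 home_class = character(0), expected_sign = numeric(0),
                 stringsAsFactors = FALSE)
    } else data.frame(
      variable_id = var_ids[disc_all],
      contrast_group = grp,
      effect = effects[grp],
      sign = signs,
      home_class = paste0("G", home[grp]),
      expected_sign = signs * sign(contrasts[cbind(grp, home[grp])]),
      stringsAsFactors = FALSE)
    missing_ids[[b]] <- drop_ids
  }
  study <- align_blocks(blocks, labels)
  truth <- list(labels = labels, batch = batch,
                discriminant = truth_vars, latent_scores = Z,
                missing = missing_ids)
  list(study = study, truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits one CSV per block, a labels CSV, a peptide-to-protein TSV for any
#' block carrying variable metadata, and the ground truth as JSON.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- sim$study
  for (b in study$blocks) {
    write_block(b, file.path(dir, paste0(b$block_id, ".csv")))
    if (!is.null(b$variable_meta))
      utils::write.table(b$variable_meta,
                         file.path(dir, paste0(b$block_id, "_map.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(sample_id = names(study$labels),
                              class = as.character(study$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(sim$truth))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
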