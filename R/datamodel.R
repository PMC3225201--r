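#' Construct an omics feature block
#'
#' An `omics_block` holds one platform's samples-by-variables table together
#' with sample and variable identifiers and optional variable metadata
#' (e.g. a peptide-to-protein map). All downstream preprocessing is explicit;
#' the stored values are kept exactly as given.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param block_id short name for the platform (e.g. `"prot"`, `"metab"`).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param variable_ids character vector of unique variable identifiers;
#'   defaults to `colnames(values)`.
#' @param variable_meta optional data frame with columns `variable_id` and
#'   `protein_accession` mapping each variable to at most one parent feature.
#' @return An object of class `omics_block` with fields `block_id`,
#'   `sample_ids`, `variable_ids`, `values` and `variable_meta`.
#' @export
omics_block <- function(values, block_id, sample_ids = rownames(values),
                        variable_ids = colnames(values), variable_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) stop("sample_ids are required (rownames or argument)")
  if (is.null(variable_ids)) stop("variable_ids are required (colnames or argument)")
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("block '", block_id, "' must have at least one sample and one variable")
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(variable_ids) != ncol(values))
    stop("length(variable_ids) != ncol(values)")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id ", paste(unique(dup), collapse = ", "),
         " in block '", block_id, "'")
  dupv <- variable_ids[duplicated(variable_ids)]
  if (length(dupv))
    stop("duplicate variable id ", paste(unique(dupv), collapse = ", "),
         " in block '", block_id, "'")
  if (any(!is.finite(values)))
    stop("non-finite values in block '", block_id, "'")
  dimnames(values) <- list(sample_ids, variable_ids)
  if (!is.null(variable_meta)) {
    variable_meta <- as.data.frame(variable_meta, stringsAsFactors = FALSE)
    if (!all(c("variable_id", "protein_accession") %in% names(variable_meta)))
      stop("variable_meta needs columns 'variable_id' and 'protein_accession'")
    if (anyDuplicated(variable_meta$variable_id))
      stop("a variable_id maps to more than one protein accession")
  }
  structure(list(block_id = as.character(block_id)[1L],
                 sample_ids = sample_ids,
                 variable_ids = variable_ids,
                 values = values,
                 variable_meta = variable_meta),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat("omics_block '", x$block_id, "': ", length(x$sample_ids), " samples x ",
      length(x$variable_ids), " variables\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

.sniff_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a feature table from CSV/TSV
#'
#' Expects samples in rows: the first column holds the sample id, the header
#' row the variable ids. The whole body must be numeric; an absent sample is
#' simply not listed (no blank rows).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated unless `sep` is given.
#' @param block_id name for the resulting block.
#' @param sep field separator override.
#' @param variable_meta optional variable metadata passed to [omics_block()].
#' @return An [omics_block()].
#' @export
read_block <- function(path, block_id, sep = NULL, variable_meta = NULL) {
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed feature table: ", path)
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sample id ", unique(dup)[1L], " in ", path)
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) == 0L && anyNA(num))
    bad <- which(is.na(num), arr.ind = TRUE)
  if (length(bad) && nrow(bad) > 0L)
    stop("non-numeric cell at sample '", ids[bad[1L, 1L]], "', variable '",
         colnames(num)[bad[1L, 2L]], "' in ", path)
  rownames(num) <- ids
  omics_block(num, block_id = block_id, variable_meta = variable_meta)
}

#' Write a feature table to CSV/TSV
#'
#' Inverse of [read_block()]: a `sample_id` first column, variables as the
#' remaining columns. Full `digits = 17` precision so a write/read round trip
#' reproduces the values exactly.
#'
#' @param block an [omics_block()].
#' @param path output path; extension selects the separator as in
#'   [read_block()].
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  sep <- .sniff_sep(path)
  body <- apply(block$values, 2L, function(x) sprintf("%.17g", x))
  if (length(block$sample_ids) == 1L) body <- matrix(body, nrow = 1L)
  df <- data.frame(sample_id = block$sample_ids, body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", block$variable_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' @param path two-column CSV `sample_id,class`.
#' @return named character vector of class labels, names = sample ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label table needs columns sample_id,class")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read a peptide-to-protein map
#'
#' @param path two-column TSV `variable_id,protein_accession`.
#' @return data frame with those two columns; errors if any variable maps to
#'   more than one protein.
#' @export
read_peptide_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          colClasses = "character", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("variable_id", "protein_accession")
  if (anyDuplicated(df$variable_id))
    stop("a variable_id maps to more than one protein accession")
  df
}

#' Align multiple blocks on the union of their samples
#'
#' Builds an `aligned_study`: the sorted union of all blocks' sample ids, a
#' class label per sample, and a presence mask saying which sample was
#' measured in which block. The union (not the intersection) is kept so that
#' samples measured on only some platforms still enter the second fusion
#' layer. Matching is by exact, case-sensitive string id.
#'
#' @param blocks list of [omics_block()] objects (unique `block_id`s).
#' @param labels named vector mapping every sample id occurring in any block
#'   to its class.
#' @return An object of class `aligned_study` with fields `sample_ids`,
#'   `labels` (factor, named by sample), `blocks` (named list) and `presence`
#'   (n x n_blocks logical matrix).
#' @export
align_blocks <- function(blocks, labels) {
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  if (length(blocks) < 1L) stop("need at least one block")
  ids <- unname(vapply(blocks, function(b) b$block_id, character(1L)))
  if (anyDuplicated(ids)) stop("duplicate block_id")
  names(blocks) <- ids
  all_samples <- sort(unique(unlist(lapply(blocks, `[[`, "sample_ids"))))
  missing_lab <- setdiff(all_samples, names(labels))
  if (length(missing_lab))
    stop("samples without a label: ", paste(missing_lab, collapse = ", "))
  lab <- factor(as.character(labels[all_samples]))
  names(lab) <- all_samples
  if (nlevels(lab) < 2L) stop("need at least two classes")
  presence <- vapply(blocks, function(b) all_samples %in% b$sample_ids,
                     logical(length(all_samples)))
  presence <- matrix(presence, nrow = length(all_samples),
                     dimnames = list(all_samples, ids))
  for (b in ids) {
    present_classes <- unique(lab[presence[, b]])
    absent <- setdiff(levels(lab), as.character(present_classes))
    if (length(absent))
      warning("class ", paste(absent, collapse = ", "),
              " has no samples in block '", b, "'")
  }
  structure(list(sample_ids = all_samples, labels = lab,
                 blocks = blocks, presence = presence),
            class = "aligned_study")
}

#' @export
print.aligned_study <- function(x, ...) {
  cat("aligned_study: ", length(x$sample_ids), " samples, ",
      nlevels(x$labels), " classes, ", length(x$blocks), " blocks\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
summary.aligned_study <- function(object, ...) {
  # per-class per-block sample counts
  out <- sapply(names(object$blocks), function(b)
    tapply(object$presence[, b], object$labels, sum))
  out <- matrix(as.integer(out), nrow = nlevels(object$labels),
                dimnames = list(levels(object$labels), names(object$blocks)))
  out
}

# values of one block restricted to the given samples (must all be present)
block_values <- function(study, block_id, sample_ids) {
  b <- study$blocks[[block_id]]
  stopifnot(all(sample_ids %in% b$sample_ids))
  b$values[sample_ids, , drop = FALSE]
}
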