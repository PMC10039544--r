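#' Two-trait expression dataset
#'
#' Container for a genes x samples expression matrix together with a
#' sample-trait table holding exactly two categorical traits. The first
#' trait is the primary axis (typically disease status); the second is the
#' secondary trait (region, timepoint, age, ...). The trait order is always
#' declared by the caller, never inferred from the data.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Log2-scale after
#'   normalization.
#' @param traits data.frame with one row per sample (rownames = sample
#'   ids) containing at least the two trait columns.
#' @param trait_names character(2): names of the primary and secondary
#'   trait columns, in that order.
#' @param gene_lengths optional named numeric vector of per-gene lengths
#'   in bp (needed only for RPKM normalization).
#' @param check_levels if TRUE (the default for a full dataset) require
#'   at least two levels per trait; design-level subsets set this FALSE.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(values, traits, trait_names,
                               gene_lengths = NULL, check_levels = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA/NaN")
  if (length(trait_names) != 2L)
    stop("exactly two trait names are required")
  missing_tr <- setdiff(trait_names, colnames(traits))
  if (length(missing_tr))
    stop("trait column(s) absent from traits table: ",
         paste(missing_tr, collapse = ", "))
  absent <- setdiff(colnames(values), rownames(traits))
  if (length(absent))
    stop("sample(s) in matrix missing from traits: ",
         paste(absent, collapse = ", "))
  traits <- traits[colnames(values), trait_names, drop = FALSE]
  for (tn in trait_names) {
    traits[[tn]] <- as.character(traits[[tn]])
    if (anyNA(traits[[tn]]) || any(traits[[tn]] == ""))
      stop("missing level for trait '", tn, "'")
    if (check_levels && length(unique(traits[[tn]])) < 2L)
      stop("trait '", tn, "' has fewer than 2 levels")
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(values)]
    if (anyNA(gene_lengths) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive and cover every gene")
  }
  structure(list(values = values, traits = traits,
                 trait_names = trait_names, gene_lengths = gene_lengths),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  for (tn in x$trait_names) {
    tab <- table(x$traits[[tn]])
    cat(sprintf("  %s: %s\n", tn,
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Load a two-trait expression dataset from delimited files
#'
#' The expression file has genes in rows, the first column gene ids and a
#' header row of sample ids. The traits file has columns
#' \code{sample_id}, one column per trait. Samples present in the traits
#' file but not in the matrix are dropped with a warning; samples in the
#' matrix that the traits file does not cover are an error.
#'
#' @param matrix_path path to expression TSV/CSV.
#' @param traits_path path to sample-trait TSV/CSV.
#' @param trait1,trait2 column names of the primary and secondary trait.
#' @param gene_lengths_path optional two-column TSV/CSV (gene_id,
#'   length_bp) enabling RPKM normalization.
#' @return an \code{\link{expression_dataset}}.
#' @export
load_expression <- function(matrix_path, traits_path, trait1, trait2,
                            gene_lengths_path = NULL) {
  em <- .read_table_auto(matrix_path)
  gene_ids <- as.character(em[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  values <- as.matrix(em[, -1, drop = FALSE])
  rownames(values) <- gene_ids
  tr <- .read_table_auto(traits_path)
  if (!"sample_id" %in% colnames(tr))
    stop("traits file must have a 'sample_id' column")
  sid <- as.character(tr$sample_id)
  if (anyDuplicated(sid))
    stop("duplicate sample id(s) in traits file: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  rownames(tr) <- sid
  extra <- setdiff(sid, colnames(values))
  if (length(extra))
    warning("dropping ", length(extra),
            " sample(s) absent from expression matrix: ",
            paste(extra, collapse = ", "))
  absent <- setdiff(colnames(values), sid)
  if (length(absent))
    stop("sample(s) in matrix missing from traits file: ",
         paste(absent, collapse = ", "))
  gl <- NULL
  if (!is.null(gene_lengths_path)) {
    glt <- .read_table_auto(gene_lengths_path)
    gl <- stats::setNames(as.numeric(glt[[2]]), as.character(glt[[1]]))
  }
  expression_dataset(values, tr, c(trait1, trait2), gene_lengths = gl)
}

#' RPKM + log2 normalization of a count matrix
#'
#' \code{out[g, s] = log2(count[g, s] / (length_kb[g] *
#' libsize_millions[s]) + pseudocount)}, with library sizes taken as the
#' column sums of the count matrix.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @param gene_lengths per-gene length in bp (named vector aligned by
#'   rownames when named).
#' @param pseudocount added to the RPKM before log2; default 1 so that a
#'   zero count maps to 0.
#' @return matrix of log2(RPKM + pseudocount).
#' @export
normalize_counts <- function(counts, gene_lengths, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(gene_lengths)) stop("gene_lengths required for RPKM")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || anyNA(gene_lengths))
    stop("gene_lengths must cover every gene")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  lib <- colSums(counts) / 1e6
  if (any(lib == 0)) stop("library size zero for sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  rpkm <- sweep(counts / (gene_lengths / 1e3), 2, lib, "/")
  log2(rpkm + pseudocount)
}

#' Normalize an expression_dataset in place
#'
#' Optionally removes genes whose count sum is below \code{min_count_sum}
#' before RPKM + log2 transformation. With \code{method = "none"} the
#' values are returned untouched (pre-normalized input).
#'
#' @param ds an \code{\link{expression_dataset}} holding raw counts.
#' @param method "rpkm_log2" or "none".
#' @param pseudocount see \code{\link{normalize_counts}}.
#' @param min_count_sum drop genes with total count below this (default 0,
#'   i.e. off).
#' @return the normalized dataset.
#' @export
normalize_dataset <- function(ds, method = c("rpkm_log2", "none"),
                              pseudocount = 1, min_count_sum = 0) {
  method <- match.arg(method)
  if (method == "none") return(ds)
  keep <- rowSums(ds$values) >= min_count_sum
  if (!all(keep))
    message("dropping ", sum(!keep), " gene(s) with count sum < ",
            min_count_sum)
  gl <- ds$gene_lengths
  if (is.null(gl)) stop("gene_lengths required for RPKM normalization")
  vals <- normalize_counts(ds$values[keep, , drop = FALSE], gl[keep],
                           pseudocount = pseudocount)
  expression_dataset(vals, ds$traits, ds$trait_names,
                     gene_lengths = gl[keep])
}

.design_level <- function(level, trait_name, condition, dataset) {
  structure(list(level = as.integer(level), trait_name = trait_name,
                 condition = condition, dataset = dataset),
            class = "design_level")
}

#' @export
print.design_level <- function(x, ...) {
  lbl <- if (x$level == 1L) "combined"
         else sprintf("%s = %s", x$trait_name, x$condition)
  cat(sprintf("design_level %d (%s): %d genes x %d samples\n", x$level,
              lbl, nrow(x$dataset$values), ncol(x$dataset$values)))
  invisible(x)
}

#' Split a dataset into the three network design levels
#'
#' Level 1 is the combined dataset; level 2 holds one subset per level of
#' the primary trait; level 3 one subset per level of the secondary trait.
#' Every subset keeps all genes. Subsets with fewer than 12 samples are
#' flagged with a warning (correlation-based networks lose power below
#' roughly a dozen samples per condition); subsets with fewer than 3
#' samples additionally get their own warning but are still produced.
#'
#' @param ds an \code{\link{expression_dataset}} with >= 2 levels per trait.
#' @return named list of \code{design_level} objects: \code{combined}
#'   first, then the level-2 subsets, then the level-3 subsets, conditions
#'   in order of first appearance in the traits table.
#' @export
split_by_design <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  for (tn in ds$trait_names)
    if (length(unique(ds$traits[[tn]])) < 2L)
      stop("trait '", tn, "' has fewer than 2 levels")
  out <- list(combined = .design_level(1L, NA_character_, "", ds))
  for (li in c(2L, 3L)) {
    tn <- ds$trait_names[li - 1L]
    for (cond in unique(ds$traits[[tn]])) {
      keep <- ds$traits[[tn]] == cond
      sub <- expression_dataset(ds$values[, keep, drop = FALSE],
                                ds$traits[keep, , drop = FALSE],
                                ds$trait_names,
                                gene_lengths = ds$gene_lengths,
                                check_levels = FALSE)
      n <- sum(keep)
      if (n < 3)
        warning("subset '", cond, "' has fewer than 3 samples (", n, ")")
      else if (n < 12)
        warning("subset '", cond, "' has fewer than 12 samples (", n,
                "); network estimates will be noisy")
      nm <- if (cond %in% names(out)) paste(tn, cond, sep = "=") else cond
      out[[nm]] <- .design_level(li, tn, cond, sub)
    }
  }
  out
}
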