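# Observed preservation statistics for one gene set. Density statistics
# are computed in the test data; connectivity statistics correlate the
# reference and test versions of kIM, kME and the within-set correlation
# structure.
.pres_stats <- function(genes, ref_expr, test_expr, params) {
  xr <- ref_expr[genes, , drop = FALSE]
  xt <- test_expr[genes, , drop = FALSE]
  ok <- .row_sds(xr) > 0 & .row_sds(xt) > 0
  xr <- xr[ok, , drop = FALSE]; xt <- xt[ok, , drop = FALSE]
  m <- nrow(xr)
  if (m < 3) return(rep(NA_real_, 7))
  cr <- stats::cor(t(xr)); ct <- stats::cor(t(xt))
  at <- if (params$network_type == "unsigned") abs(ct)^params$power
        else ((1 + ct) / 2)^params$power
  ar <- if (params$network_type == "unsigned") abs(cr)^params$power
        else ((1 + cr) / 2)^params$power
  ut <- upper.tri(ct)
  me_t <- module_eigengenes(xt, rep(1L, m))
  me_r <- module_eigengenes(xr, rep(1L, m))
  kme_t <- stats::cor(t(xt), me_t$scores[, 1])
  kme_r <- stats::cor(t(xr), me_r$scores[, 1])
  kim_t <- rowSums(at) - 1
  kim_r <- rowSums(ar) - 1
  c(mean_cor = mean(abs(ct[ut])),
    mean_adj = mean(at[ut]),
    prop_var = unname(me_t$explained_variance[1]),
    mean_kme = mean(abs(kme_t)),
    cor_kim = stats::cor(kim_r, kim_t),
    cor_kme = stats::cor(kme_r, kme_t),
    cor_cor = stats::cor(cr[ut], ct[ut]))
}

.z_category <- function(z) {
  # boundary values sit in the lower category
  ifelse(z <= 2, "not_preserved", ifelse(z <= 10, "weak", "strong"))
}

.z_score012 <- function(z) ifelse(z <= 2, 0L, ifelse(z <= 10, 1L, 2L))

#' Preservation category and ordinal score of a Zsummary value
#'
#' Zsummary <= 2: "not_preserved" (score 0); 2 < Zsummary <= 10: "weak"
#' (score 1); Zsummary > 10: "strong" (score 2). Boundary values fall in
#' the lower category.
#'
#' @param z Zsummary value(s).
#' @return data.frame with z, category, score.
#' @export
preservation_category <- function(z) {
  data.frame(z = z, category = .z_category(z), score = .z_score012(z))
}

#' Module preservation Zsummary of a reference network in test data
#'
#' For each non-grey module of the reference network, four density
#' statistics (mean within-module |cor| in the test data, mean adjacency,
#' proportion of variance explained by the test eigengene, mean |kME|)
#' and three connectivity statistics (correlation between reference and
#' test of kIM, of kME, and of the vectorized within-module correlation
#' matrices) are compared against a permutation null obtained by drawing
#' \code{n_label_perm} random gene sets of the same size from the genes
#' shared between reference and test. Each statistic is standardized to
#' \code{Z = (obs - mean_null) / sd_null}; \code{z_density} is the median
#' of the density Zs, \code{z_connectivity} the median of the
#' connectivity Zs, and \code{z_summary} their mean. Modules sharing
#' fewer than half their genes with the test data are skipped with a
#' warning. Zsummary <= 2 is "not_preserved", 2-10 "weak", > 10 "strong".
#'
#' @param reference a \code{co_network}.
#' @param test_expr genes x samples matrix of the test condition.
#' @param n_label_perm permutations of the module labels (default 100).
#' @param seed RNG seed; per-module streams are derived from it so module
#'   order does not matter.
#' @return \code{preservation_result}: data.frame with module, size,
#'   observed statistics, z_density, z_connectivity, z_summary, category.
#' @export
preservation_zsummary <- function(reference, test_expr, n_label_perm = 100,
                                  seed = 1) {
  stopifnot(inherits(reference, "co_network"))
  ref_expr <- reference$expr
  universe <- intersect(rownames(ref_expr), rownames(test_expr))
  mods <- sort(unique(reference$assignments[reference$assignments > 0]))
  stat_names <- c("mean_cor", "mean_adj", "prop_var", "mean_kme",
                  "cor_kim", "cor_kme", "cor_cor")
  rows <- list()
  for (m in mods) {
    genes <- module_genes(reference, m)
    shared <- intersect(genes, universe)
    if (length(shared) < length(genes) / 2) {
      warning("module ", .qualified_name(reference, m),
              " shares < 50% of its genes with the test data; skipped")
      next
    }
    obs <- .pres_stats(shared, ref_expr, test_expr, reference$params)
    set.seed(seed + m)
    null <- matrix(NA_real_, n_label_perm, 7)
    for (p in seq_len(n_label_perm)) {
      rg <- sample(universe, length(shared))
      null[p, ] <- .pres_stats(rg, ref_expr, test_expr, reference$params)
    }
    mu <- colMeans(null, na.rm = TRUE)
    sdv <- apply(null, 2, stats::sd, na.rm = TRUE)
    z <- (obs - mu) / sdv
    if (any(sdv == 0, na.rm = TRUE)) {
      warning("null sd of zero for module ", m, "; affected Z set to 0")
      z[sdv == 0] <- 0
    }
    zd <- stats::median(z[1:4], na.rm = TRUE)
    zc <- stats::median(z[5:7], na.rm = TRUE)
    zs <- mean(c(zd, zc))
    row <- data.frame(module = .qualified_name(reference, m),
                      size = length(shared), t(obs),
                      z_density = zd, z_connectivity = zc, z_summary = zs,
                      category = .z_category(zs), stringsAsFactors = FALSE)
    colnames(row)[3:9] <- stat_names
    rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), size = integer(0),
               z_density = numeric(0), z_connectivity = numeric(0),
               z_summary = numeric(0), category = character(0))
  rownames(out) <- NULL
  class(out) <- c("preservation_result", "data.frame")
  out
}

#' Exact one-tailed permutation p-value
#'
#' The proportion of null preservation scores lower than or equal to the
#' observed score, with no +1 correction (39 of 2000 null scores at or
#' below the observed value gives exactly 0.0195). A p of 0 carries a
#' \code{note} attribute "< 1/N".
#'
#' @param null_scores numeric vector of null scores (>= 1).
#' @param observed observed score.
#' @return the p-value.
#' @export
p_from_null <- function(null_scores, observed) {
  null_scores <- null_scores[!is.na(null_scores)]
  if (!length(null_scores)) stop("at least one null score is required")
  p <- sum(null_scores <= observed) / length(null_scores)
  if (p == 0) attr(p, "note") <- sprintf("< %g", 1 / length(null_scores))
  p
}

#' Phenotype-permutation test of trait-specific preservation
#'
#' Tests whether an observed Zsummary is lower than expected when the
#' primary-trait labels carry no information. Each permutation randomly
#' reassigns the primary-trait labels to samples (preserving the original
#' group sizes), builds a network on the randomized reference subset,
#' removes single-sample-driven modules, assesses preservation of the
#' surviving modules in the randomized test subset, and records the
#' Zsummary of the module whose size is closest to the module of
#' interest (ties broken toward the smaller module). Permutations
#' yielding no surviving module are excluded from the null with a logged
#' count. The p-value is the exact proportion of null scores at or below
#' the observed score.
#'
#' @param ds the full \code{\link{expression_dataset}}.
#' @param reference_level level of the primary trait defining the
#'   reference group (e.g. "disease").
#' @param module_size size of the module of interest (genes).
#' @param observed the module's observed Zsummary.
#' @param n_permutations number of label permutations.
#' @param seed global seed; per-permutation seeds are derived from it.
#' @param net_params \code{\link{network_parameters}} for the randomized
#'   networks.
#' @param filter_params outlier-module filter settings.
#' @param n_label_perm label permutations inside each Zsummary
#'   computation (reduced relative to the observed run for tractability).
#' @return \code{permutation_null}: list with observed, null_scores,
#'   matched_sizes, p_value, n_permutations, n_excluded, seed.
#' @export
phenotype_permutation_test <- function(ds, reference_level, module_size,
                                       observed, n_permutations = 100,
                                       seed = 1,
                                       net_params = network_parameters(),
                                       filter_params = filter_parameters(),
                                       n_label_perm = 30) {
  stopifnot(inherits(ds, "expression_dataset"))
  labels <- ds$traits[[ds$trait_names[1]]]
  if (!reference_level %in% labels)
    stop("reference_level '", reference_level, "' not a level of trait ",
         ds$trait_names[1])
  n_ref <- sum(labels == reference_level)
  n <- ncol(ds$values)
  null_scores <- rep(NA_real_, n_permutations)
  matched_sizes <- rep(NA_integer_, n_permutations)
  seed0 <- (seed %% 100000L) * 10000L
  for (i in seq_len(n_permutations)) {
    set.seed(seed0 + i)
    idx <- sample.int(n)
    ref_idx <- idx[seq_len(n_ref)]
    test_idx <- idx[-seq_len(n_ref)]
    net <- suppressWarnings(
      detect_modules(ds$values[, ref_idx, drop = FALSE], net_params))
    if (!any(net$assignments > 0)) next
    net <- filter_network(net, filter_params)$network
    if (!any(net$assignments > 0)) next
    pres <- suppressWarnings(
      preservation_zsummary(net, ds$values[, test_idx, drop = FALSE],
                            n_label_perm = n_label_perm,
                            seed = seed0 + i))
    if (!nrow(pres)) next
    gap <- abs(pres$size - module_size)
    pick <- which(gap == min(gap))
    if (length(pick) > 1) pick <- pick[which.min(pres$size[pick])]
    null_scores[i] <- pres$z_summary[pick]
    matched_sizes[i] <- pres$size[pick]
  }
  excluded <- sum(is.na(null_scores))
  if (excluded)
    message(excluded, " permutation(s) yielded no eligible module and ",
            "were excluded from the null")
  ok <- !is.na(null_scores)
  structure(list(observed = observed, null_scores = null_scores[ok],
                 matched_sizes = matched_sizes[ok],
                 p_value = p_from_null(null_scores[ok], observed),
                 n_permutations = n_permutations, n_excluded = excluded,
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(paste0("permutation_null: observed Zsummary %.3g, %d null ",
                     "scores (range %.3g..%.3g), p = %.4g\n"),
              x$observed, length(x$null_scores), min(x$null_scores),
              max(x$null_scores), x$p_value))
  invisible(x)
}

#' Select the size-matched module from a null network
#'
#' Utility exposing the size-matching rule of the permutation test: the
#' module whose size is closest to the target, ties broken toward the
#' smaller module.
#'
#' @param sizes integer module sizes.
#' @param target size of the module of interest.
#' @return index into \code{sizes}.
#' @export
closest_size_match <- function(sizes, target) {
  gap <- abs(sizes - target)
  pick <- which(gap == min(gap))
  if (length(pick) > 1) {
    message("size-matching tie; choosing the smaller module")
    pick <- pick[which.min(sizes[pick])]
  }
  pick
}

#' Preservation accuracy under test-set subsampling
#'
#' Establishes ground-truth preservation categories (0: Zsummary <= 2,
#' 1: 2 < Zsummary <= 10, 2: Zsummary > 10) at the full test-set size,
#' then repeatedly subsamples the test set to each requested size,
#' recomputes per-module Zsummary, and reports the fraction of modules
#' whose category matches the ground truth.
#'
#' @param reference a \code{co_network}.
#' @param test_expr full test genes x samples matrix.
#' @param sizes sample sizes to evaluate (each <= ncol(test_expr)).
#' @param n_reps subsample replicates per size.
#' @param seed RNG seed.
#' @param n_label_perm label permutations per Zsummary computation.
#' @return data.frame size, rep, accuracy.
#' @export
subsample_accuracy <- function(reference, test_expr, sizes, n_reps = 20,
                               seed = 1, n_label_perm = 30) {
  if (any(sizes > ncol(test_expr)))
    stop("requested size exceeds the available ", ncol(test_expr),
         " test samples")
  ground <- suppressWarnings(
    preservation_zsummary(reference, test_expr,
                          n_label_perm = n_label_perm, seed = seed))
  truth <- stats::setNames(.z_score012(ground$z_summary), ground$module)
  out <- expand.grid(size = sizes, rep = seq_len(n_reps),
                     KEEP.OUT.ATTRS = FALSE)
  out$accuracy <- NA_real_
  seed0 <- (seed %% 1000000L) * 1000L
  for (k in seq_len(nrow(out))) {
    set.seed(seed0 + k)
    cols <- sample(ncol(test_expr), out$size[k])
    pres <- suppressWarnings(
      preservation_zsummary(reference, test_expr[, cols, drop = FALSE],
                            n_label_perm = n_label_perm,
                            seed = seed0 + k))
    if (!nrow(pres)) next
    sc <- .z_score012(pres$z_summary)
    out$accuracy[k] <- mean(sc == truth[pres$module])
  }
  out
}
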