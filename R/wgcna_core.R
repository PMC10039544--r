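#' Network construction parameters
#'
#' @param power soft-threshold exponent beta (>= 1) applied to the
#'   correlation-based similarity.
#' @param network_type "unsigned" (|r|^beta) or "signed"
#'   (((1 + r)/2)^beta).
#' @param min_module_size smallest cluster kept as a module; smaller
#'   clusters go to the grey (unassigned, label 0) pool.
#' @param merge_cut_height modules whose eigengenes cluster within this
#'   height on the 1 - cor(ME) dissimilarity are merged iteratively; 0
#'   disables merging.
#' @param max_block_size genes handled in a single TOM block; larger
#'   inputs are pre-partitioned by k-means on eigen-features.
#' @param deep_split 0-4; higher values split more aggressively (lower
#'   cluster-cohesion requirement).
#' @param correlation only "pearson" is supported.
#' @return a \code{network_parameters} object.
#' @export
network_parameters <- function(power = 6, network_type = c("unsigned", "signed"),
                               min_module_size = 30, merge_cut_height = 0.15,
                               max_block_size = 5000, deep_split = 2,
                               correlation = "pearson") {
  network_type <- match.arg(network_type)
  stopifnot(power >= 1, min_module_size >= 2,
            merge_cut_height >= 0, merge_cut_height <= 1,
            deep_split %in% 0:4, identical(correlation, "pearson"),
            max_block_size >= 2)
  structure(list(power = power, network_type = network_type,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 max_block_size = as.integer(max_block_size),
                 deep_split = as.integer(deep_split),
                 correlation = correlation),
            class = "network_parameters")
}

.row_sds <- function(x) {
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
}

#' Weighted adjacency from expression
#'
#' Unsigned: \code{a_ij = |cor(x_i, x_j)|^beta}; signed:
#' \code{a_ij = ((1 + cor)/2)^beta}. The diagonal is 1.
#'
#' @param expr genes x samples matrix with >= 3 samples and no
#'   zero-variance genes.
#' @param params a \code{\link{network_parameters}} object.
#' @return symmetric genes x genes matrix with entries in [0, 1].
#' @export
adjacency <- function(expr, params = network_parameters()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  sds <- .row_sds(expr)
  if (any(sds == 0))
    stop("zero-variance gene(s) must be filtered upstream: ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  a <- if (params$network_type == "unsigned") abs(r)^params$power
       else ((1 + r) / 2)^params$power
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)} with \code{k_i = sum_{u != i} a_iu};
#' \code{TOM_ii = 1}.
#'
#' @param adj symmetric adjacency in [0, 1] with unit diagonal.
#' @return symmetric TOM with unit diagonal, entries in [0, 1].
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || max(abs(adj - t(adj))) > 1e-8)
    stop("adjacency must be symmetric")
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12) ||
      max(abs(diag(adj) - 1)) > 1e-12)
    stop("adjacency entries must lie in [0, 1] with unit diagonal")
  k <- rowSums(adj) - 1
  num <- adj %*% adj - adj          # sum_{u != i,j} a_iu a_uj + a_ij
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- num / denom
  tom <- (tom + t(tom)) / 2
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# Mean within- and cross-cluster dissimilarity for a logical index.
.cohesion <- function(d, idx) {
  s <- sum(idx)
  n <- nrow(d)
  if (s < 2 || s >= n) return(0)
  within <- sum(d[idx, idx]) / (s * (s - 1))
  cross <- sum(d[idx, ]) - sum(d[idx, idx])
  cross <- cross / (s * (n - s))
  if (cross <= 0) return(0)
  1 - within / cross
}

# Mean within-cluster |correlation| for a logical index.
.mean_within_cor <- function(abs_cor, idx) {
  s <- sum(idx)
  if (s < 2) return(0)
  (sum(abs_cor[idx, idx]) - s) / (s * (s - 1))
}

# One pass of the adaptive cut: rescale dissimilarities affinely so that
# the tightest pairs sit near 0 regardless of the absolute TOM scale, then
# scan static cut heights and keep the cut yielding the most clusters that
# are eligible as modules. A cluster is eligible when it is (a) large
# enough, (b) cohesive (mean within-cluster dissimilarity well below its
# mean dissimilarity to the rest), and (c) genuinely co-expressed: its
# mean within-cluster |cor| must exceed a multiple of the null
# expectation E|r| = sqrt(2/pi)/sqrt(n_samples - 1), which screens out
# chance-correlation clusters that hierarchical clustering always yields
# on noise. deep_split relaxes both bars.
.cut_once <- function(d, abs_cor, cor_min, min_size, deep_split) {
  sep_min <- c(0.5, 0.4, 0.3, 0.2, 0.12)[deep_split + 1L]
  n <- nrow(d)
  off <- d[upper.tri(d)]
  lo <- stats::quantile(off, 0.005, names = FALSE, type = 7)
  hi <- max(off)
  if (hi - lo <= 0) return(rep(0L, n))
  dr <- (d - lo) / (hi - lo)
  hc <- stats::hclust(stats::as.dist(dr), method = "average")
  hts <- sort(unique(hc$height))
  hts <- hts[hts > 0]
  if (length(hts) > 128)
    hts <- unique(stats::quantile(hts, seq(0, 1, length.out = 128),
                                  names = FALSE, type = 1))
  if (!length(hts)) return(rep(0L, n))
  cuts <- stats::cutree(hc, h = hts)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  best <- list(count = 0L, genes = 0L, labels = rep(0L, n))
  for (j in seq_len(ncol(cuts))) {
    lab <- cuts[, j]
    tab <- tabulate(lab)
    big <- which(tab >= min_size & tab < n)
    if (!length(big)) next
    elig <- big[vapply(big, function(k) {
      idx <- lab == k
      .mean_within_cor(abs_cor, idx) >= cor_min &&
        .cohesion(dr, idx) >= sep_min
    }, logical(1))]
    if (!length(elig)) next
    cnt <- length(elig)
    gns <- sum(tab[elig])
    if (cnt > best$count || (cnt == best$count && gns > best$genes)) {
      keep <- rep(0L, n)
      for (i in seq_along(elig)) keep[lab == elig[i]] <- i
      best <- list(count = cnt, genes = gns, labels = keep)
    }
  }
  best$labels
}

# Multi-scale cut: modules whose internal dissimilarities live at very
# different absolute scales (e.g. a condition-specific module diluted in
# the combined network) cannot be captured by one static cut, so detected
# clusters are peeled off and the remainder is re-rescaled and re-cut
# until no further eligible cluster emerges.
.cut_modules <- function(d, abs_cor, n_samples, min_size, deep_split,
                         max_rounds = 10L) {
  n <- nrow(d)
  r0 <- sqrt(2 / pi) / sqrt(n_samples - 1)
  cor_min <- min(c(2.5, 2.25, 2, 1.75, 1.5)[deep_split + 1L] * r0, 0.6)
  labels <- rep(0L, n)
  remaining <- seq_len(n)
  offset <- 0L
  for (round in seq_len(max_rounds)) {
    if (length(remaining) < min_size) break
    lab <- .cut_once(d[remaining, remaining, drop = FALSE],
                     abs_cor[remaining, remaining, drop = FALSE],
                     cor_min, min_size, deep_split)
    if (max(lab) == 0L) break
    labels[remaining[lab > 0L]] <- lab[lab > 0L] + offset
    offset <- offset + max(lab)
    remaining <- remaining[lab == 0L]
  }
  labels
}

# Trim weakly connected genes from each detected cluster: genes whose
# |kME| falls below half the cluster's median |kME| are released to grey
# (they are typically noise genes swept up by the tree cut). A cluster
# that drops below min_size afterwards is dissolved entirely, so
# min_module_size applies to the coherent core, not the padded branch.
.prune_by_kme <- function(expr, labels, min_size) {
  for (m in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == m)
    me <- module_eigengenes(expr[idx, , drop = FALSE],
                            rep(1L, length(idx)))
    kme <- abs(stats::cor(t(expr[idx, , drop = FALSE]), me$scores[, 1]))
    thr <- 0.5 * stats::median(kme)
    drop <- kme < thr
    if (any(drop)) labels[idx[drop]] <- 0L
    if (sum(labels == m) < min_size) labels[labels == m] <- 0L
  }
  labels
}

# Iteratively merge modules whose eigengenes are closer than cut_height on
# the 1 - cor(ME) dissimilarity. Returns the relabeled assignment vector.
.merge_close_modules <- function(expr, labels, cut_height) {
  if (cut_height <= 0) return(labels)
  for (iter in 1:10) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, labels)$scores
    dis <- 1 - stats::cor(me)
    grp <- stats::cutree(stats::hclust(stats::as.dist(dis), "average"),
                         h = cut_height)
    if (max(grp) == length(mods)) break
    new <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      new[labels %in% members] <- min(members)
    }
    labels <- new
  }
  labels
}

# Relabel modules 1..K by decreasing size (stable: ties keep old order).
.relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Detect co-expression modules in one design level
#'
#' Builds the weighted adjacency and topological overlap matrix, clusters
#' genes by average-linkage on 1 - TOM, cuts the tree with an adaptive
#' scan (see package vignette), sends clusters below
#' \code{min_module_size} to grey, optionally merges modules with
#' correlated eigengenes, and relabels modules 1..K by decreasing size.
#' Zero-variance genes are dropped from the analysis with a message.
#'
#' @param x genes x samples matrix, \code{expression_dataset}, or
#'   \code{design_level}.
#' @param params a \code{\link{network_parameters}} object.
#' @param name_prefix nomenclature prefix stored on the network (see
#'   \code{\link{assign_module_names}}).
#' @return a \code{co_network} object with fields \code{assignments}
#'   (named integer vector, 0 = grey), \code{dendro}, \code{dendro_order},
#'   \code{eigengenes}, \code{kme}, \code{kim}, \code{params},
#'   \code{design}, \code{module_names}.
#' @export
detect_modules <- function(x, params = network_parameters(),
                           name_prefix = "") {
  design <- NULL
  if (inherits(x, "design_level")) { design <- x; expr <- x$dataset$values }
  else if (inherits(x, "expression_dataset")) expr <- x$values
  else expr <- as.matrix(x)
  if (ncol(expr) < 4) stop("at least 4 samples are required")
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%05d", seq_len(nrow(expr)))
  sds <- .row_sds(expr)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0),
            " zero-variance gene(s) from this network")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) > params$max_block_size) {
    blocks <- .preblock(expr, params$max_block_size)
  } else blocks <- list(seq_len(nrow(expr)))
  labels <- integer(nrow(expr))
  names(labels) <- rownames(expr)
  dendro <- NULL
  dendro_order <- integer(0)
  offset <- 0L
  for (b in blocks) {
    eb <- expr[b, , drop = FALSE]
    adj <- adjacency(eb, params)
    abs_r <- abs(stats::cor(t(eb)))
    tom <- topological_overlap(adj)
    d <- 1 - tom
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    lab <- .cut_modules(d, abs_r, ncol(eb), params$min_module_size,
                        params$deep_split)
    lab[lab > 0] <- lab[lab > 0] + offset
    offset <- offset + max(0L, max(lab))
    labels[b] <- lab
    if (is.null(dendro)) dendro <- hc          # kept for the first block
    dendro_order <- c(dendro_order, b[hc$order])
  }
  labels <- .prune_by_kme(expr, labels, params$min_module_size)
  labels <- .merge_close_modules(expr, labels, params$merge_cut_height)
  labels <- .relabel_by_size(labels)
  if (!any(labels > 0)) warning("no modules detected; all genes are grey")
  me <- if (any(labels > 0)) module_eigengenes(expr, labels) else
    list(scores = matrix(0, ncol(expr), 0,
                         dimnames = list(colnames(expr), NULL)),
         explained_variance = numeric(0))
  kme <- if (ncol(me$scores)) module_kme(expr, me) else
    matrix(0, nrow(expr), 0, dimnames = list(rownames(expr), NULL))
  adj_full <- if (length(blocks) == 1L) adjacency(expr, params) else NULL
  kim <- if (!is.null(adj_full)) intramodular_connectivity(adj_full, labels)
         else .blockwise_kim(expr, labels, params)
  mods <- sort(unique(labels[labels > 0]))
  module_names <- stats::setNames(paste0("M", mods), as.character(mods))
  structure(list(params = params, assignments = labels, dendro = dendro,
                 dendro_order = dendro_order, eigengenes = me, kme = kme,
                 kim = kim, design = design, name_prefix = name_prefix,
                 module_names = module_names, expr = expr),
            class = "co_network")
}

# k-means on gene eigen-features (first right singular vectors of the
# standardized matrix) to pre-partition very large gene sets into blocks;
# an approximation of single-block construction, deterministic.
.preblock <- function(expr, max_block_size) {
  xs <- (expr - rowMeans(expr)) / .row_sds(expr)
  npc <- min(10L, ncol(expr) - 1L)
  sv <- svd(xs, nu = npc, nv = 0)
  feat <- sv$u %*% diag(sv$d[seq_len(npc)], npc)
  k <- ceiling(nrow(expr) / max_block_size)
  set.seed(20260101L)  # block layout must not depend on caller RNG state
  km <- stats::kmeans(feat, centers = k, nstart = 5, iter.max = 50)
  split(seq_len(nrow(expr)), km$cluster)
}

.blockwise_kim <- function(expr, labels, params) {
  kim <- rep(NA_real_, length(labels))
  names(kim) <- names(labels)
  for (m in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == m)
    if (length(idx) == 1L) { kim[idx] <- 0; next }
    a <- adjacency(expr[idx, , drop = FALSE], params)
    kim[idx] <- rowSums(a) - 1
  }
  kim
}

#' @export
print.co_network <- function(x, ...) {
  tab <- table(x$assignments[x$assignments > 0])
  cat(sprintf("co_network: %d genes, %d modules (%d grey), power %.3g %s\n",
              length(x$assignments), length(tab), sum(x$assignments == 0),
              x$params$power, x$params$network_type))
  if (length(tab))
    cat("  module sizes:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Genes assigned to one module of a network
#' @param net a \code{co_network}.
#' @param module integer module label (> 0).
#' @return character vector of gene ids.
#' @export
module_genes <- function(net, module) {
  names(net$assignments)[net$assignments == module]
}

#' Module eigengenes (first principal component per module)
#'
#' Genes are standardized across samples; the eigengene is the first right
#' singular vector of the standardized genes x samples block (unit
#' Euclidean norm), with its sign aligned so that its correlation with the
#' module's mean standardized expression profile is non-negative.
#'
#' @param expr genes x samples matrix.
#' @param assignments per-gene integer labels (0 = grey, excluded).
#' @return list with \code{scores} (samples x modules matrix, columns
#'   \code{M<k>}) and \code{explained_variance} (proportion of the
#'   module's standardized variance captured by the first component).
#' @export
module_eigengenes <- function(expr, assignments) {
  expr <- as.matrix(expr)
  mods <- sort(unique(assignments[assignments > 0]))
  scores <- matrix(NA_real_, ncol(expr), length(mods),
                   dimnames = list(colnames(expr), paste0("M", mods)))
  ev <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    idx <- which(assignments == mods[i])
    if (length(idx) == 1L)
      warning("module ", mods[i], " has a single gene")
    xm <- expr[idx, , drop = FALSE]
    sds <- .row_sds(xm)
    if (any(sds == 0)) {
      warning("module ", mods[i], ": ", sum(sds == 0),
              " zero-variance gene(s) excluded from the eigengene")
      xm <- xm[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    xs <- (xm - rowMeans(xm)) / sds
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (sum(v * colMeans(xs)) < 0) v <- -v
    scores[, i] <- v
    ev[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(scores = scores, explained_variance = ev)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' eigengene.
#'
#' @param expr genes x samples matrix.
#' @param me result of \code{\link{module_eigengenes}}.
#' @return genes x modules matrix in [-1, 1].
#' @export
module_kme <- function(expr, me) {
  stats::cor(t(as.matrix(expr)), me$scores)
}

#' Intramodular connectivity (kIM)
#'
#' Sum of a gene's adjacency to the other genes of its own module. Grey
#' genes get NA; singleton modules get 0.
#'
#' @param adj genes x genes adjacency.
#' @param assignments per-gene integer labels (0 = grey).
#' @return named numeric vector.
#' @export
intramodular_connectivity <- function(adj, assignments) {
  kim <- rep(NA_real_, length(assignments))
  names(kim) <- rownames(adj)
  for (m in sort(unique(assignments[assignments > 0]))) {
    idx <- which(assignments == m)
    if (length(idx) == 1L) { kim[idx] <- 0; next }
    kim[idx] <- rowSums(adj[idx, idx, drop = FALSE]) - 1
  }
  kim
}

#' Soft-threshold scale-free fit report
#'
#' Reports the scale-free topology fit index R^2 (regression of
#' log10 p(k) on log10 k over connectivity bins) and mean connectivity
#' for each candidate power. Purely diagnostic: nothing in the package
#' ever auto-selects a power from it.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate soft thresholds.
#' @param params base parameters (network type is taken from here).
#' @param n_breaks histogram bins for the degree distribution.
#' @return data.frame with power, fit_r2, mean_k.
#' @export
soft_threshold_fit <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                               params = network_parameters(),
                               n_breaks = 10) {
  out <- data.frame(power = powers, fit_r2 = NA_real_, mean_k = NA_real_)
  r <- stats::cor(t(as.matrix(expr)))
  base <- if (params$network_type == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- 0
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    out$mean_k[i] <- mean(k)
    brk <- seq(min(k), max(k), length.out = n_breaks + 1)
    cut_k <- cut(k, brk, include.lowest = TRUE)
    dk <- tapply(k, cut_k, mean)
    pk <- as.numeric(table(cut_k)) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(ok) > 2)
      out$fit_r2[i] <- summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
  }
  out
}
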