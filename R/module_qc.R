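#' Outlier-module filter parameters
#'
#' @param variance_threshold a module is an outlier when the sample
#'   variance of its (unit-norm) eigengene falls below this after removing
#'   the sample with the largest absolute eigengene value. Default 0.02.
#' @return a \code{filter_parameters} object.
#' @export
filter_parameters <- function(variance_threshold = 0.02) {
  stopifnot(variance_threshold > 0)
  structure(list(variance_threshold = variance_threshold),
            class = "filter_parameters")
}

#' Flag a module driven by a single sample
#'
#' Removes the sample with the largest absolute eigengene value and
#' computes the sample variance (n - 1 denominator) of the remainder; the
#' module is flagged as an outlier when that residual variance falls below
#' the threshold. Because the eigengene has unit Euclidean norm, a module
#' whose signal is concentrated in one sample leaves almost no variance
#' once that sample is removed. Ties for the largest |ME| are broken by
#' sample order (first wins) and reported with a message.
#'
#' @param eigengene per-sample eigengene vector (>= 3 samples).
#' @param params a \code{\link{filter_parameters}} object.
#' @return list: \code{outlier} (logical), \code{removed_sample},
#'   \code{residual_variance}.
#' @export
is_outlier_module <- function(eigengene, params = filter_parameters()) {
  if (length(eigengene) < 3) stop("at least 3 samples are required")
  a <- abs(eigengene)
  top <- which(a == max(a))
  if (length(top) > 1)
    message("tie for largest |eigengene|; removing the first by sample order")
  top <- top[1]
  v <- stats::var(eigengene[-top])
  list(outlier = v < params$variance_threshold,
       removed_sample = if (!is.null(names(eigengene))) names(eigengene)[top]
                        else top,
       residual_variance = v)
}

#' Remove single-sample-driven modules from a network
#'
#' Genes of flagged modules are reassigned to grey, the surviving modules
#' are relabeled 1..K by decreasing size, and eigengenes / kME are
#' recomputed for the relabeled network.
#'
#' @param net a \code{co_network}.
#' @param params a \code{\link{filter_parameters}} object.
#' @return list: \code{network} (filtered \code{co_network}) and
#'   \code{removed} (data.frame module, size, removed_sample,
#'   residual_variance).
#' @export
filter_network <- function(net, params = filter_parameters()) {
  stopifnot(inherits(net, "co_network"))
  me <- net$eigengenes$scores
  removed <- data.frame(module = character(0), size = integer(0),
                        removed_sample = character(0),
                        residual_variance = numeric(0))
  mods <- sort(unique(net$assignments[net$assignments > 0]))
  drop <- integer(0)
  for (m in mods) {
    res <- is_outlier_module(me[, paste0("M", m)], params)
    if (res$outlier) {
      drop <- c(drop, m)
      removed <- rbind(removed, data.frame(
        module = net$module_names[[as.character(m)]],
        size = sum(net$assignments == m),
        removed_sample = as.character(res$removed_sample),
        residual_variance = res$residual_variance))
    }
  }
  if (!length(drop)) return(list(network = net, removed = removed))
  labels <- net$assignments
  labels[labels %in% drop] <- 0L
  labels <- .relabel_by_size(labels)
  out <- net
  out$assignments <- labels
  if (any(labels > 0)) {
    out$eigengenes <- module_eigengenes(net$expr, labels)
    out$kme <- module_kme(net$expr, out$eigengenes)
  } else {
    out$eigengenes <- list(scores = me[, 0, drop = FALSE],
                           explained_variance = numeric(0))
    out$kme <- net$kme[, 0, drop = FALSE]
  }
  out$kim <- .blockwise_kim(net$expr, labels, net$params)
  keep <- sort(unique(labels[labels > 0]))
  out$module_names <- stats::setNames(paste0("M", keep), as.character(keep))
  list(network = out, removed = removed)
}
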