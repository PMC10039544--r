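#' Gene flow between consecutive networks (sankey table)
#'
#' For each consecutive pair of networks (e.g. timepoint networks in
#' temporal order), edges connect each non-grey module of the earlier
#' network to each non-grey module of the later network, weighted by the
#' number of shared genes; zero-gene edges are omitted and grey genes
#' never contribute. Each edge carries the hypergeometric overlap
#' p-value over the genes shared by the two networks.
#'
#' @param networks ordered named list of >= 2 \code{co_network}s.
#' @return \code{flow_table}: list with \code{networks} (names in
#'   order), \code{nodes} (data.frame network, module, size) and
#'   \code{edges} (data.frame from_network, to_network, module_from,
#'   module_to, n_genes, p_hyper).
#' @export
flow_table <- function(networks) {
  if (length(networks) < 2) stop("at least 2 networks are required")
  nms <- names(networks)
  if (is.null(nms)) nms <- paste0("net", seq_along(networks))
  nodes <- do.call(rbind, lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    mods <- sort(unique(net$assignments[net$assignments > 0]))
    if (!length(mods)) return(NULL)
    data.frame(network = nms[i],
               module = vapply(mods, function(m) .qualified_name(net, m), ""),
               size = vapply(mods, function(m) sum(net$assignments == m),
                             integer(1)), stringsAsFactors = FALSE)
  }))
  edges <- NULL
  for (i in seq_len(length(networks) - 1)) {
    a <- networks[[i]]; b <- networks[[i + 1]]
    shared <- intersect(.analyzed_genes(a), .analyzed_genes(b))
    la <- a$assignments[shared]; lb <- b$assignments[shared]
    for (ma in sort(unique(la[la > 0]))) {
      in_a <- la == ma
      for (mb in sort(unique(lb[lb > 0]))) {
        ng <- sum(in_a & lb == mb)
        if (ng == 0) next
        p <- hypergeometric_overlap(ng, sum(in_a), sum(lb == mb),
                                    length(shared))
        edges <- rbind(edges, data.frame(
          from_network = nms[i], to_network = nms[i + 1],
          module_from = .qualified_name(a, ma),
          module_to = .qualified_name(b, mb),
          n_genes = ng, p_hyper = p, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(edges))
    edges <- data.frame(from_network = character(0),
                        to_network = character(0),
                        module_from = character(0),
                        module_to = character(0),
                        n_genes = integer(0), p_hyper = numeric(0))
  structure(list(networks = nms, nodes = nodes, edges = edges),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("flow_table: %d networks, %d nodes, %d edges\n",
              length(x$networks), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a flow table as sankey-ready JSON
#'
#' @param ft a \code{\link{flow_table}}.
#' @param path output JSON path.
#' @export
write_flow_json <- function(ft, path) {
  nodes <- ft$nodes
  nodes$id <- paste(nodes$network, nodes$module, sep = ":")
  links <- data.frame(
    source = paste(ft$edges$from_network, ft$edges$module_from, sep = ":"),
    target = paste(ft$edges$to_network, ft$edges$module_to, sep = ":"),
    value = ft$edges$n_genes, p_hyper = ft$edges$p_hyper)
  jsonlite::write_json(list(networks = ft$networks, nodes = nodes,
                            links = links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Track a module's genes across dendrogram leaf orders (TOM flow)
#'
#' Records, for every gene of the focus module, its leaf position in
#' each network's topological-overlap clustering tree, and summarizes
#' per network a dispersion score: the mean pairwise leaf distance of
#' the tracked genes divided by its expectation under random placement
#' ((G + 1)/3 for G leaves). A score near 1 means the genes are
#' interspersed across the tree; well below 1 means they cluster
#' together.
#'
#' @param networks ordered named list of \code{co_network}s.
#' @param focus_network name (in \code{networks}) of the network the
#'   focus module belongs to.
#' @param focus_module qualified module name (e.g. "8m-1").
#' @return \code{tom_flow_track}: list with \code{tracks} (data.frame
#'   gene, network, leaf_position; NA when the gene is absent),
#'   \code{dispersion} (named per-network score), \code{focus}.
#' @export
tom_flow <- function(networks, focus_network, focus_module) {
  nms <- names(networks)
  if (!focus_network %in% nms) stop("unknown focus network")
  fnet <- networks[[focus_network]]
  lab <- match(focus_module, fnet$module_names)
  if (is.na(lab))
    stop("focus module '", focus_module, "' not found in ", focus_network)
  lab <- as.integer(names(fnet$module_names)[lab])
  genes <- module_genes(fnet, lab)
  tracks <- NULL
  dispersion <- stats::setNames(rep(NA_real_, length(nms)), nms)
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    gene_ids <- names(net$assignments)
    pos <- stats::setNames(rep(NA_integer_, length(genes)), genes)
    leaf <- stats::setNames(seq_along(net$dendro_order),
                            gene_ids[net$dendro_order])
    hit <- intersect(genes, names(leaf))
    pos[hit] <- leaf[hit]
    tracks <- rbind(tracks, data.frame(gene = genes, network = nms[i],
                                       leaf_position = unname(pos),
                                       stringsAsFactors = FALSE))
    pp <- pos[!is.na(pos)]
    if (length(pp) >= 2) {
      G <- length(gene_ids)
      obs <- mean(stats::dist(pp))
      dispersion[i] <- obs / ((G + 1) / 3)
    }
  }
  structure(list(tracks = tracks, dispersion = dispersion,
                 focus = focus_module, focus_network = focus_network),
            class = "tom_flow_track")
}

#' @export
print.tom_flow_track <- function(x, ...) {
  cat(sprintf("tom_flow_track: %s (%s), %d genes\n", x$focus,
              x$focus_network, length(unique(x$tracks$gene))))
  cat("  dispersion:",
      paste(sprintf("%s=%.2f", names(x$dispersion), x$dispersion),
            collapse = ", "), "\n")
  invisible(x)
}
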