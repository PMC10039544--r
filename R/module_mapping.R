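#' Upper-tail hypergeometric overlap p-value
#'
#' \code{P(X >= n_overlap)} for X ~ Hypergeometric drawing \code{n_b}
#' genes from a universe of \code{n_universe} genes of which \code{n_a}
#' belong to module A. Computed in log space so that overlaps with
#' p ~ 1e-306 remain finite.
#'
#' @param n_overlap shared genes.
#' @param n_a,n_b module sizes.
#' @param n_universe genes present in both networks.
#' @param log10p if TRUE return log10(p) instead of p.
#' @return p-value in (0, 1] (or its log10).
#' @export
hypergeometric_overlap <- function(n_overlap, n_a, n_b, n_universe,
                                   log10p = FALSE) {
  if (any(n_overlap < 0 | n_a < 0 | n_b < 0 | n_universe < 1 |
          n_a > n_universe | n_b > n_universe |
          n_overlap > pmin(n_a, n_b) |
          n_overlap < pmax(0, n_a + n_b - n_universe)))
    stop("impossible hypergeometric configuration")
  lp <- stats::phyper(n_overlap - 1, n_a, n_universe - n_a, n_b,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

.qualified_name <- function(net, module) {
  nm <- net$module_names[[as.character(module)]]
  if (is.null(nm)) paste0("M", module) else nm
}

.analyzed_genes <- function(net) names(net$assignments)

#' Map the modules of two networks by hypergeometric member overlap
#'
#' The gene universe is the intersection of the genes analyzed (including
#' grey) in the two networks; modules are the non-grey labels. FDR is
#' Benjamini-Hochberg across all module pairs of the table. The
#' comparison category is \code{cross-design} when the two networks share
#' underlying samples (gene overlap confounded, mapping use only) and
#' \code{between-design} when the sample sets are disjoint.
#'
#' @param net_a,net_b \code{co_network} objects sharing >= 1 gene.
#' @return an \code{overlap_table}: list with \code{records} (data.frame
#'   module_a, module_b, n_a, n_b, n_overlap, n_universe, p_hyper, fdr,
#'   category) and \code{best_match} (per module of A: partner in B with
#'   the smallest p; ties broken by larger overlap then lower label).
#' @export
map_modules <- function(net_a, net_b) {
  universe <- intersect(.analyzed_genes(net_a), .analyzed_genes(net_b))
  if (!length(universe)) stop("the two networks share no genes")
  sa <- if (!is.null(net_a$design)) colnames(net_a$design$dataset$values)
        else colnames(net_a$expr)
  sb <- if (!is.null(net_b$design)) colnames(net_b$design$dataset$values)
        else colnames(net_b$expr)
  category <- if (length(intersect(sa, sb))) "cross-design"
              else "between-design"
  la <- net_a$assignments[universe]
  lb <- net_b$assignments[universe]
  mods_a <- sort(unique(la[la > 0]))
  mods_b <- sort(unique(lb[lb > 0]))
  if (!length(mods_a) || !length(mods_b))
    return(structure(list(records = data.frame(), best_match = data.frame(),
                          category = category), class = "overlap_table"))
  cross <- table(factor(la, levels = mods_a), factor(lb, levels = mods_b))
  rec <- expand.grid(a = mods_a, b = mods_b, KEEP.OUT.ATTRS = FALSE)
  rec$n_a <- as.integer(table(factor(la, levels = mods_a))[as.character(rec$a)])
  rec$n_b <- as.integer(table(factor(lb, levels = mods_b))[as.character(rec$b)])
  rec$n_overlap <- as.integer(cross[cbind(as.character(rec$a),
                                          as.character(rec$b))])
  rec$n_universe <- length(universe)
  rec$p_hyper <- hypergeometric_overlap(rec$n_overlap, rec$n_a, rec$n_b,
                                        rec$n_universe)
  rec$fdr <- stats::p.adjust(rec$p_hyper, method = "BH")
  records <- data.frame(
    module_a = vapply(rec$a, function(m) .qualified_name(net_a, m), ""),
    module_b = vapply(rec$b, function(m) .qualified_name(net_b, m), ""),
    label_a = rec$a, label_b = rec$b,
    n_a = rec$n_a, n_b = rec$n_b, n_overlap = rec$n_overlap,
    n_universe = rec$n_universe, p_hyper = rec$p_hyper, fdr = rec$fdr,
    category = category, stringsAsFactors = FALSE)
  best <- do.call(rbind, lapply(split(records, records$label_a), function(g) {
    g <- g[order(g$p_hyper, -g$n_overlap, g$label_b), ]
    g[1, ]
  }))
  rownames(best) <- NULL
  structure(list(records = records, best_match = best, category = category),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("overlap_table (%s): %d module pairs, %d with FDR < 0.05\n",
              x$category, nrow(x$records),
              if (nrow(x$records)) sum(x$records$fdr < 0.05) else 0L))
  invisible(x)
}

#' Assign design-level nomenclature to a list of networks
#'
#' Combined-network modules are named \code{M<k>}; primary-trait (level 2)
#' networks get a one-letter prefix before the M (by default the
#' lower-cased first character of the condition, configurable, mirroring
#' the d-/c- convention for disease/control); secondary-trait (level 3)
#' networks use \code{<condition>-<k>}.
#'
#' @param networks named list of \code{co_network} objects built from
#'   \code{design_level}s.
#' @param level2_prefixes optional named character vector mapping a
#'   level-2 condition to its prefix (e.g. \code{c(disease = "d",
#'   wildtype = "c")}).
#' @return the list of networks with \code{module_names} and
#'   \code{name_prefix} set.
#' @export
assign_module_names <- function(networks, level2_prefixes = NULL) {
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    lvl <- if (!is.null(net$design)) net$design$level else 1L
    cond <- if (!is.null(net$design)) net$design$condition else ""
    mods <- sort(unique(net$assignments[net$assignments > 0]))
    nms <- if (lvl == 1L) paste0("M", mods)
    else if (lvl == 2L) {
      pref <- if (!is.null(level2_prefixes) && cond %in% names(level2_prefixes))
        level2_prefixes[[cond]] else tolower(substr(cond, 1, 1))
      paste0(pref, "M", mods)
    } else paste0(cond, "-", mods)
    net$module_names <- stats::setNames(nms, as.character(mods))
    net$name_prefix <- if (lvl == 1L) "" else
      if (lvl == 2L) sub("M[0-9]+$", "", nms[1]) else paste0(cond, "-")
    networks[[i]] <- net
  }
  networks
}

#' Correspondence graph around a focus module
#'
#' Builds a serializable node/edge list where nodes are all modules of
#' all networks grouped by design level and edges connect the focus
#' module to every module of the other networks, weighted by
#' \code{-log10(p_hyper)} capped at 320.
#'
#' @param networks named list of \code{co_network}s.
#' @param tables list of \code{overlap_table}s as produced by
#'   \code{\link{map_all_modules}} (named "A|B").
#' @param focus qualified name of the focus module (e.g. "dM15").
#' @param fdr_edges if TRUE only edges with FDR < 0.05 get a nonzero
#'   weight flag \code{significant}.
#' @return list with \code{nodes} (data.frame network, level, module,
#'   size) and \code{edges} (data.frame from, to, weight, p_hyper, fdr,
#'   significant).
#' @export
build_trace_graph <- function(networks, tables, focus, fdr_edges = TRUE) {
  nodes <- do.call(rbind, lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    mods <- sort(unique(net$assignments[net$assignments > 0]))
    if (!length(mods)) return(NULL)
    data.frame(network = nm,
               level = if (!is.null(net$design)) net$design$level else 1L,
               module = vapply(mods, function(m) .qualified_name(net, m), ""),
               size = vapply(mods, function(m) sum(net$assignments == m),
                             integer(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes) || !focus %in% nodes$module)
    stop("focus module '", focus, "' not found in any network")
  edges <- NULL
  for (tb in tables) {
    r <- tb$records
    if (!nrow(r)) next
    hit <- r[r$module_a == focus | r$module_b == focus, , drop = FALSE]
    if (!nrow(hit)) next
    other <- ifelse(hit$module_a == focus, hit$module_b, hit$module_a)
    edges <- rbind(edges, data.frame(
      from = focus, to = other,
      weight = pmin(-log10(hit$p_hyper), 320),
      p_hyper = hit$p_hyper, fdr = hit$fdr,
      significant = hit$fdr < 0.05, stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), p_hyper = numeric(0),
                        fdr = numeric(0), significant = logical(0))
  list(nodes = nodes, edges = edges, focus = focus)
}

#' Map every pair of networks
#'
#' @param networks named list of \code{co_network}s.
#' @return named list ("A|B") of \code{overlap_table}s for all unordered
#'   network pairs.
#' @export
map_all_modules <- function(networks) {
  nms <- names(networks)
  out <- list()
  if (length(nms) < 2) return(out)
  for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
    key <- paste(nms[i], nms[j], sep = "|")
    out[[key]] <- map_modules(networks[[nms[i]]], networks[[nms[j]]])
  }
  out
}

#' Hypergeometric enrichment of user gene sets in network modules
#'
#' Gene sets are intersected with the network's analyzed genes; sets with
#' no expressed member are dropped with a warning. FDR is BH across all
#' module x set tests.
#'
#' @param net a \code{co_network}.
#' @param gene_sets named list of character vectors of gene ids.
#' @return data.frame module, set, n_module, n_set, n_overlap,
#'   n_universe, p_hyper, fdr.
#' @export
gene_set_overlap <- function(net, gene_sets) {
  universe <- .analyzed_genes(net)
  gene_sets <- lapply(gene_sets, intersect, y = universe)
  empty <- names(gene_sets)[lengths(gene_sets) == 0]
  if (length(empty)) {
    warning("dropping gene set(s) with no expressed member: ",
            paste(empty, collapse = ", "))
    gene_sets <- gene_sets[lengths(gene_sets) > 0]
  }
  mods <- sort(unique(net$assignments[net$assignments > 0]))
  if (!length(mods) || !length(gene_sets))
    return(data.frame(module = character(0), set = character(0),
                      n_module = integer(0), n_set = integer(0),
                      n_overlap = integer(0), n_universe = integer(0),
                      p_hyper = numeric(0), fdr = numeric(0)))
  out <- do.call(rbind, lapply(mods, function(m) {
    mg <- module_genes(net, m)
    do.call(rbind, lapply(names(gene_sets), function(sn) {
      gs <- gene_sets[[sn]]
      data.frame(module = .qualified_name(net, m), set = sn,
                 n_module = length(mg), n_set = length(gs),
                 n_overlap = length(intersect(mg, gs)),
                 n_universe = length(universe), stringsAsFactors = FALSE)
    }))
  }))
  out$p_hyper <- hypergeometric_overlap(out$n_overlap, out$n_module,
                                        out$n_set, out$n_universe)
  out$fdr <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' @param path GMT (set name, description, genes...) or a two-column
#'   delimited file (set_name, gene_id).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t")
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[[`, "", 1))
  } else {
    df <- .read_table_auto(path)
    split(as.character(df[[2]]), as.character(df[[1]]))
  }
}
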