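#' Factorial ANOVA of one module eigengene on the two traits
#'
#' Fits \code{eigengene ~ trait1 + trait2 + trait1:trait2} and tests each
#' term with Type-II sums of squares (robust to the unbalanced group
#' sizes typical of disease designs; for balanced data this coincides
#' with the classical decomposition). When the trait1 x trait2 cross has
#' empty cells, the interaction is dropped with a warning and its entries
#' are NA.
#'
#' @param me per-sample eigengene vector.
#' @param trait1,trait2 per-sample categorical vectors.
#' @return one-row data.frame with f_trait1, p_trait1, f_trait2,
#'   p_trait2, f_interaction, p_interaction.
#' @export
eigengene_anova <- function(me, trait1, trait2) {
  t1 <- droplevels(factor(trait1))
  t2 <- droplevels(factor(trait2))
  stopifnot(length(me) == length(t1), length(me) == length(t2))
  if (nlevels(t1) < 2 || nlevels(t2) < 2)
    stop("both traits need at least 2 levels")
  has_interaction <- all(table(t1, t2) > 0)
  if (!has_interaction) {
    warning("empty cells in the trait cross; interaction term dropped")
    fit <- stats::lm(me ~ t1 + t2)
  } else fit <- stats::lm(me ~ t1 * t2)
  if (stats::df.residual(fit) < 1)
    stop("no residual degrees of freedom")
  aov2 <- car::Anova(fit, type = 2)
  g <- function(term) {
    if (!term %in% rownames(aov2)) return(c(NA_real_, NA_real_))
    c(aov2[term, "F value"], aov2[term, "Pr(>F)"])
  }
  a <- g("t1"); b <- g("t2"); i <- g("t1:t2")
  data.frame(f_trait1 = a[1], p_trait1 = a[2],
             f_trait2 = b[1], p_trait2 = b[2],
             f_interaction = i[1], p_interaction = i[2])
}

#' PERMANOVA of one module's expression on the two traits
#'
#' Standardizes the module's genes across samples, computes Euclidean
#' distances between sample profiles and partitions them by
#' \code{trait1 * trait2} with permutational MANOVA (Anderson's pseudo-F
#' via \code{vegan::adonis2}). The permutation p-value uses the +1
#' convention (the observed statistic counts as one permutation), so
#' p >= 1/(1 + n_perm) always.
#'
#' @param module_expr genes x samples block of the module.
#' @param trait1,trait2 per-sample categorical vectors.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed controlling the permutations.
#' @return data.frame with term, pseudo_f, p.
#' @export
eigengene_permanova <- function(module_expr, trait1, trait2,
                                n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  x <- as.matrix(module_expr)
  sds <- .row_sds(x)
  x <- x[sds > 0, , drop = FALSE]
  xs <- (x - rowMeans(x)) / .row_sds(x)
  d <- stats::dist(t(xs))
  df <- data.frame(t1 = factor(trait1), t2 = factor(trait2))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ t1 * t2, data = df, permutations = n_perm,
                        by = "terms")
  terms <- c("t1", "t2", "t1:t2")
  keep <- terms[terms %in% rownames(fit)]
  data.frame(term = c("trait1", "trait2", "interaction")[match(keep, terms)],
             pseudo_f = fit[keep, "F"], p = fit[keep, "Pr(>F)"],
             row.names = NULL)
}

#' Trait association for every module of a network
#'
#' Runs \code{\link{eigengene_anova}} (and optionally
#' \code{\link{eigengene_permanova}}) per non-grey module, then applies
#' Benjamini-Hochberg FDR across modules separately within each term.
#'
#' @param net a \code{co_network} built from a design level that carries
#'   both traits (normally the combined network).
#' @param method "anova", "permanova", or "both".
#' @param n_perm,seed PERMANOVA settings.
#' @return data.frame with one row per module: F, p and fdr for the
#'   trait1, trait2 and interaction terms (plus permanova columns when
#'   requested).
#' @export
associate_all <- function(net, method = c("anova", "permanova", "both"),
                          n_perm = 999, seed = 1) {
  method <- match.arg(method)
  if (is.null(net$design))
    stop("network carries no design; build it from a design_level")
  ds <- net$design$dataset
  t1 <- ds$traits[[ds$trait_names[1]]]
  t2 <- ds$traits[[ds$trait_names[2]]]
  mods <- sort(unique(net$assignments[net$assignments > 0]))
  if (!length(mods))
    return(data.frame(module = character(0)))
  rows <- lapply(mods, function(m) {
    out <- data.frame(module = .qualified_name(net, m),
                      size = sum(net$assignments == m))
    if (method %in% c("anova", "both"))
      out <- cbind(out, eigengene_anova(net$eigengenes$scores[, paste0("M", m)],
                                        t1, t2))
    if (method %in% c("permanova", "both")) {
      pm <- eigengene_permanova(net$expr[net$assignments == m, , drop = FALSE],
                                t1, t2, n_perm = n_perm, seed = seed + m)
      wide <- stats::setNames(
        as.list(c(pm$pseudo_f, pm$p)),
        c(paste0("permanova_f_", pm$term), paste0("permanova_p_", pm$term)))
      out <- cbind(out, as.data.frame(wide))
    }
    out
  })
  tab <- do.call(rbind, rows)
  for (term in c("trait1", "trait2", "interaction")) {
    pc <- paste0("p_", term)
    if (pc %in% colnames(tab))
      tab[[paste0("fdr_", term)]] <- stats::p.adjust(tab[[pc]], method = "BH")
  }
  tab
}
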