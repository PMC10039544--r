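# Vectorized Fisher r-to-z comparison of two correlations.
.fisher_z <- function(r1, n1, r2, n2) {
  clip <- abs(r1) > 0.999999 | abs(r2) > 0.999999
  if (any(clip))
    warning(sum(clip), " correlation(s) at |r| ~ 1 clipped to 0.999999")
  r1 <- pmin(pmax(r1, -0.999999), 0.999999)
  r2 <- pmin(pmax(r2, -0.999999), 0.999999)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Fisher z test of differential co-expression for one gene pair
#'
#' Compares the Pearson correlation of a gene pair between two
#' conditions: \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) +
#' 1/(n2 - 3))}, with a two-sided normal p-value. Positive z means
#' higher co-expression in condition 1.
#'
#' @param xa_cond1,xb_cond1 expression of genes a and b in condition 1
#'   (>= 4 samples).
#' @param xa_cond2,xb_cond2 expression in condition 2 (>= 4 samples).
#' @return one-row data.frame: r_cond1, r_cond2, n_cond1, n_cond2, z, p,
#'   direction.
#' @export
fisher_z_test <- function(xa_cond1, xb_cond1, xa_cond2, xb_cond2) {
  n1 <- length(xa_cond1); n2 <- length(xa_cond2)
  if (length(xb_cond1) != n1 || length(xb_cond2) != n2)
    stop("gene vectors must have matching lengths per condition")
  if (n1 <= 3 || n2 <= 3)
    stop("at least 4 samples per condition are required")
  r1 <- stats::cor(xa_cond1, xb_cond1)
  r2 <- stats::cor(xa_cond2, xb_cond2)
  fz <- .fisher_z(r1, n1, r2, n2)
  data.frame(r_cond1 = r1, r_cond2 = r2, n_cond1 = n1, n_cond2 = n2,
             z = fz$z, p = fz$p,
             direction = ifelse(fz$z >= 0, "higher_in_cond1",
                                "higher_in_cond2"),
             stringsAsFactors = FALSE)
}

#' Differential co-expression of all gene pairs of a module
#'
#' Tests every one of the C(m, 2) pairs of module genes between two
#' conditions with the Fisher z test and applies Benjamini-Hochberg FDR
#' across the pairs.
#'
#' @param genes character vector of module gene ids (all must be present
#'   in both matrices).
#' @param expr_cond1,expr_cond2 genes x samples matrices for the two
#'   conditions.
#' @return list: \code{records} (data.frame gene_a, gene_b, r_cond1,
#'   r_cond2, z, p, fdr, direction) and \code{summary} (n_pairs,
#'   n_significant at FDR < 0.05, frac_higher_cond1 among significant
#'   pairs).
#' @export
module_pairs_dc <- function(genes, expr_cond1, expr_cond2) {
  miss <- setdiff(genes, intersect(rownames(expr_cond1),
                                   rownames(expr_cond2)))
  if (length(miss))
    stop("module gene(s) absent from a condition matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(genes) < 2) stop("at least 2 genes are required")
  x1 <- expr_cond1[genes, , drop = FALSE]
  x2 <- expr_cond2[genes, , drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 <= 3 || n2 <= 3)
    stop("at least 4 samples per condition are required")
  c1 <- stats::cor(t(x1)); c2 <- stats::cor(t(x2))
  ut <- which(upper.tri(c1), arr.ind = TRUE)
  fz <- .fisher_z(c1[ut], n1, c2[ut], n2)
  records <- data.frame(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                        r_cond1 = c1[ut], r_cond2 = c2[ut],
                        n_cond1 = n1, n_cond2 = n2,
                        z = fz$z, p = fz$p,
                        fdr = stats::p.adjust(fz$p, method = "BH"),
                        direction = ifelse(fz$z >= 0, "higher_in_cond1",
                                           "higher_in_cond2"),
                        stringsAsFactors = FALSE)
  sig <- records$fdr < 0.05
  list(records = records,
       summary = list(n_pairs = nrow(records), n_significant = sum(sig),
                      frac_higher_cond1 = if (any(sig))
                        mean(records$direction[sig] == "higher_in_cond1")
                      else NA_real_),
       cor_cond1 = c1, cor_cond2 = c2)
}
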