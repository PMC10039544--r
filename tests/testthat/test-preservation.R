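test_that("planted modules self-preserve and destroyed structure scores near zero", {
  gen <- generate_dataset(
    list(module_spec(80, 0.95), module_spec(80, 0.95)),
    n_noise_genes = 340, trait2_levels = c("A", "B"),
    samples_per_cell = rbind(disease = c(10L, 10L),
                             wildtype = c(8L, 8L)), seed = 101)
  dis <- gen$dataset$traits$status == "disease"
  ref_data <- gen$dataset$values[, dis]
  net <- detect_modules(ref_data, fx_reduced_params())

  # test data = reference data: every planted module is strongly
  # preserved; the connectivity statistics are degenerate (identically 1
  # for every gene set) so their null sd is 0 and their Z drops to 0
  self <- suppressWarnings(
    preservation_zsummary(net, ref_data, n_label_perm = 50, seed = 3))
  expect_true(all(self$z_summary > 10))
  expect_true(all(self$category == "strong"))
  expect_true(all(self$z_connectivity == 0))
  expect_warning(
    preservation_zsummary(net, ref_data, n_label_perm = 10, seed = 3),
    "sd of zero")

  # shuffling each gene's samples independently destroys co-expression
  set.seed(19)
  shuf <- t(apply(ref_data, 1, sample))
  colnames(shuf) <- colnames(ref_data)
  dest <- suppressWarnings(
    preservation_zsummary(net, shuf, n_label_perm = 50, seed = 3))
  expect_gte(mean(abs(dest$z_summary) < 2), 0.9)
})

test_that("Zsummary is reproducible and responds monotonically to loading", {
  rp <- fx_reduced_pres()
  gen <- fx_reduced()
  dis <- gen$dataset$traits$status == "disease"
  wt_data <- gen$dataset$values[, !dis]
  p1 <- suppressWarnings(
    preservation_zsummary(rp$net, wt_data, n_label_perm = 25, seed = 11))
  p2 <- suppressWarnings(
    preservation_zsummary(rp$net, wt_data, n_label_perm = 25, seed = 11))
  expect_equal(p1$z_summary, p2$z_summary, tolerance = 1e-12)

  # stronger planted loadings never reduce the preserved module's score
  zs <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(lam) {
    g <- generate_dataset(list(module_spec(60, lam)), 120,
                          samples_per_cell = 8, seed = 202)
    d2 <- g$dataset$traits$status == "disease"
    nn <- suppressWarnings(detect_modules(
      g$dataset$values[, d2],
      network_parameters(power = 6, min_module_size = 40)))
    if (!any(nn$assignments > 0)) return(NA_real_)
    pr <- suppressWarnings(preservation_zsummary(
      nn, g$dataset$values[, !d2], n_label_perm = 30, seed = 5))
    max(pr$z_summary)
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_gte(length(zs), 3)
  expect_gt(cor(seq_along(zs), zs, method = "spearman"), 0)
  expect_gt(zs[length(zs)], zs[1])
})

test_that("preservation categories follow the 2/10 boundaries", {
  pc <- preservation_category(c(1.5, 5, 15, 2, 10, 9.16))
  expect_equal(pc$score, c(0L, 1L, 2L, 0L, 1L, 1L))
  expect_equal(pc$category,
               c("not_preserved", "weak", "strong",
                 "not_preserved", "weak", "weak"))
})

test_that("p_from_null is exact counting", {
  # 39 of 2000 null scores at or below the observed score
  null <- c(seq(-5, length.out = 39, by = 0.1), seq(10, 60, length.out = 1961))
  expect_equal(as.numeric(p_from_null(null, 9.16)), 39 / 2000)
  expect_identical(as.numeric(p_from_null(null, 9.16)), 0.0195)

  # property: matches direct counting for random vectors
  set.seed(44)
  for (i in 1:20) {
    ns <- rnorm(sample(5:200, 1))
    ob <- rnorm(1)
    expect_equal(as.numeric(p_from_null(ns, ob)), mean(ns <= ob))
  }

  # observed below all null scores: p = 0 with a "< 1/N" annotation
  p0 <- p_from_null(1:10, 0)
  expect_equal(as.numeric(p0), 0)
  expect_match(attr(p0, "note"), "< 0.1")
  expect_equal(as.numeric(p_from_null(1:10, 11)), 1)
  expect_error(p_from_null(numeric(0), 1), "at least one")
})

test_that("size matching picks the closest module, ties to the smaller", {
  sizes <- c(225L, 260L, 290L, 310L, 340L, 366L)
  expect_equal(sizes[closest_size_match(sizes, 303)], 310L)
  expect_equal(sizes[closest_size_match(sizes, 300)], 290L)
  expect_message(pick <- closest_size_match(c(100L, 110L), 105L), "tie")
  expect_equal(pick, 1L)
})

test_that("phenotype permutation test separates disease-specific from shared modules", {
  rp <- fx_reduced_pres()
  gen <- fx_reduced()
  ds <- gen$dataset
  pres <- rp$pres
  i_dis <- which(rp$majority == 1)   # disease-only planted module
  i_all <- which(rp$majority == 2)   # always-active planted module
  expect_lt(pres$z_summary[i_dis], 2)
  expect_gt(pres$z_summary[i_all], 10)

  pt <- fx_permtest()
  expect_lte(pt$positive$p_value, 0.05)
  expect_equal(length(pt$positive$null_scores) + pt$positive$n_excluded,
               50L)
  expect_true(all(pt$positive$matched_sizes > 0))
  expect_gte(pt$negative$p_value, 0.2)
})

test_that("subsampling accuracy degrades as the test set shrinks", {
  rp <- fx_reduced_pres()
  gen <- fx_reduced()
  dis <- gen$dataset$traits$status == "disease"
  wt_data <- gen$dataset$values[, !dis]
  acc <- subsample_accuracy(rp$net, wt_data, sizes = c(16, 10, 5),
                            n_reps = 5, seed = 2, n_label_perm = 25)
  m <- tapply(acc$accuracy, acc$size, mean, na.rm = TRUE)
  # full test set reproduces the ground-truth categories
  expect_gte(m["16"], 0.95)
  # shrinking the test set cannot systematically help
  expect_gte(m["16"] + 0.05, m["5"])
  expect_error(subsample_accuracy(rp$net, wt_data, sizes = 20),
               "exceeds")
})
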