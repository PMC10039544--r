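test_that("hypergeometric overlap p matches tail enumeration", {
  expect_equal(hypergeometric_overlap(0, 5, 5, 20), 1)

  # all 5 drawn from the 5 specials: p = 1 / C(20, 5)
  expect_equal(hypergeometric_overlap(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)

  # independent oracle: log-space pmf-tail summation via lchoose
  tail_oracle <- function(k, K, n, N) {
    kk <- k:min(K, n)
    lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
    m <- max(lp)
    m + log(sum(exp(lp - m)))
  }
  set.seed(77)
  for (rep in 1:50) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    rng <- max(0, K + n - N):min(K, n)
    k <- rng[sample.int(length(rng), 1)]
    lp <- hypergeometric_overlap(k, K, n, N, log10p = TRUE) * log(10)
    o <- tail_oracle(k, K, n, N)
    # 1e-10 relative in log space, floored absolutely for log p ~ 0
    expect_lte(abs(lp - o), 1e-10 * max(1, abs(o)))
  }

  # non-increasing in the overlap at fixed margins
  ps <- sapply(0:10, hypergeometric_overlap, n_a = 10, n_b = 15,
               n_universe = 40)
  expect_true(all(diff(ps) <= 1e-15))

  # extreme overlaps stay finite in log space
  expect_lt(hypergeometric_overlap(1000, 1000, 1000, 20000,
                                   log10p = TRUE), -300)

  expect_error(hypergeometric_overlap(6, 5, 5, 20), "impossible")
})

test_that("mapping a network to itself recovers the identity", {
  net <- fx_eae_networks()$disease
  tab <- map_modules(net, net)
  expect_s3_class(tab, "overlap_table")
  expect_equal(tab$category, "cross-design")
  for (i in seq_len(nrow(tab$best_match))) {
    bm <- tab$best_match[i, ]
    expect_equal(bm$module_a, bm$module_b)
    expect_equal(bm$n_overlap, bm$n_a)
    # minimum p within the module's row
    row_p <- tab$records$p_hyper[tab$records$module_a == bm$module_a]
    expect_equal(bm$p_hyper, min(row_p))
  }
  # overlap counts for one reference module never exceed its size
  for (a in unique(tab$records$module_a)) {
    r <- tab$records[tab$records$module_a == a, ]
    expect_lte(sum(r$n_overlap), r$n_a[1])
  }
})

test_that("independent random modules rarely yield significant overlaps", {
  genes <- sprintf("g%04d", 1:600)
  hits <- 0L
  for (s in 1:60) {
    set.seed(400 + s)
    la <- setNames(integer(600), genes)
    lb <- setNames(integer(600), genes)
    la[sample(600, 300)] <- rep(1:2, each = 150)
    lb[sample(600, 300)] <- rep(1:2, each = 150)
    tab <- map_modules(fake_network(la, paste0("a", 1:6)),
                       fake_network(lb, paste0("b", 1:6)))
    if (any(tab$records$fdr < 0.05)) hits <- hits + 1L
  }
  # false-positive runs stay near the nominal BH rate (~5% of runs)
  expect_lte(hits / 60, 0.15)
})

test_that("between-design mapping recovers the shared planted module", {
  nets <- fx_eae_networks()
  gen <- fx_eae()
  tr <- gen$truth$module
  tab <- map_modules(nets$disease, nets$wildtype)
  expect_equal(tab$category, "between-design")
  maj_d <- fx_majority(nets$disease, tr)
  maj_w <- fx_majority(nets$wildtype, tr)
  # the always-active module is the reciprocal best match
  d_always <- nets$disease$module_names[[as.character(which(maj_d == 2))]]
  w_always <- nets$wildtype$module_names[[as.character(which(maj_w == 2))]]
  bm <- tab$best_match
  expect_equal(bm$module_b[bm$module_a == d_always], w_always)
  expect_lt(bm$fdr[bm$module_a == d_always], 1e-10)
  rev_tab <- map_modules(nets$wildtype, nets$disease)
  expect_equal(rev_tab$best_match$module_b[
    rev_tab$best_match$module_a == w_always], d_always)
  # hypergeometric symmetry: p identical under table direction swap
  r1 <- tab$records[tab$records$module_a == d_always &
                    tab$records$module_b == w_always, ]
  r2 <- rev_tab$records[rev_tab$records$module_a == w_always &
                        rev_tab$records$module_b == d_always, ]
  expect_equal(r1$p_hyper, r2$p_hyper, tolerance = 1e-12)
})

test_that("BH FDR keeps the p-value ordering", {
  nets <- fx_eae_networks()
  tab <- map_modules(nets$disease, nets$combined)
  expect_true(all(tab$records$fdr >= tab$records$p_hyper))
  # fdr is non-decreasing when records are sorted by p
  expect_true(all(diff(tab$records$fdr[order(tab$records$p_hyper)]) >=
                  -1e-15))
})

test_that("nomenclature follows the M / prefix-M / condition-dash scheme", {
  genes <- sprintf("g%03d", 1:160)
  lab <- setNames(rep(c(0L, 13L), c(60, 100)), genes)
  combined <- fake_network(lab)
  l2 <- fake_network(setNames(rep(c(0L, 15L), c(60, 100)), genes),
                     level = 2L, condition = "disease",
                     trait_name = "status")
  l2c <- fake_network(setNames(rep(c(0L, 15L), c(60, 100)), genes),
                      level = 2L, condition = "control",
                      trait_name = "status")
  l3 <- fake_network(setNames(rep(c(0L, 1L), c(60, 100)), genes),
                     level = 3L, condition = "8m", trait_name = "age")
  nets <- assign_module_names(list(a = combined, b = l2, bc = l2c, c = l3))
  expect_equal(unname(nets$a$module_names), "M13")
  expect_equal(unname(nets$b$module_names), "dM15")
  expect_equal(unname(nets$bc$module_names), "cM15")
  expect_equal(unname(nets$c$module_names), "8m-1")
  # explicit prefix map overrides the first-letter default
  nets2 <- assign_module_names(list(b = l2c),
                               level2_prefixes = c(control = "w"))
  expect_equal(unname(nets2$b$module_names), "wM15")
})

test_that("the trace graph stars out from the focus module", {
  nets <- fx_eae_networks()
  gen <- fx_eae()
  maj_d <- fx_majority(nets$disease, gen$truth$module)
  d_only <- nets$disease$module_names[[as.character(which(maj_d == 1))]]
  tables <- map_all_modules(nets)
  gr <- build_trace_graph(nets, tables, d_only)
  expect_true(all(gr$edges$from == d_only))
  expect_true(all(gr$edges$weight <= 320))
  expect_equal(gr$edges$weight, pmin(-log10(gr$edges$p_hyper), 320))
  # disease-only module: strong edge to its combined counterpart, no
  # significant edge to any wildtype module
  to_comb <- gr$edges[gr$edges$to %in% nets$combined$module_names, ]
  expect_true(any(to_comb$significant))
  to_wt <- gr$edges[gr$edges$to %in% nets$wildtype$module_names, ]
  expect_true(all(!to_wt$significant))
  expect_error(build_trace_graph(nets, tables, "nonesuch"), "not found")
})

test_that("gene-set enrichment drops unexpressed sets and finds planted ones", {
  net <- fx_eae_networks()$disease
  gen <- fx_eae()
  tr <- gen$truth$module
  maj <- fx_majority(net, tr)
  d_lab <- which(maj == 1)
  mg <- module_genes(net, d_lab)

  # a set equal to a module: overlap = module size, minimal p in its row
  res <- gene_set_overlap(net, list(self = mg))
  row <- res[res$module == net$module_names[[as.character(d_lab)]], ]
  expect_equal(row$n_overlap, length(mg))
  expect_equal(row$p_hyper, min(res$p_hyper))

  # 37-member marker set with one gene absent: tested size is 36
  set.seed(99)
  markers <- c(sample(mg, 36), "not_a_gene")
  res2 <- gene_set_overlap(net, list(markers = markers))
  expect_equal(unique(res2$n_set), 36L)

  # a fully unexpressed set is dropped with a warning
  expect_warning(gene_set_overlap(net, list(gone = c("x1", "x2"))),
                 "no expressed member")

  # random 36-gene sets are null
  hits <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    rs <- sample(names(net$assignments), 36)
    rr <- gene_set_overlap(net, list(rand = rs))
    if (any(rr$fdr < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})
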