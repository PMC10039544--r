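test_that("adjacency applies soft thresholding to Pearson correlation", {
  # two genes with an exact correlation of 0.8 / -0.8
  pr <- exact_cor_pair(0.8, 12)
  e <- rbind(a = pr$x, b = pr$y)
  a2 <- adjacency(e, network_parameters(power = 2))
  expect_equal(a2["a", "b"], 0.64, tolerance = 1e-12)
  e_neg <- rbind(a = pr$x, b = -pr$y)
  expect_equal(adjacency(e_neg, network_parameters(power = 2))["a", "b"],
               0.64, tolerance = 1e-12)
  s2 <- adjacency(e_neg, network_parameters(power = 2,
                                            network_type = "signed"))
  expect_equal(s2["a", "b"], ((1 - 0.8) / 2)^2, tolerance = 1e-12)

  # beta = 1 reproduces |cor| against a brute-force pairwise oracle
  set.seed(5)
  x <- matrix(rnorm(60), 10, 6)
  rownames(x) <- paste0("g", 1:10)
  a1 <- adjacency(x, network_parameters(power = 1))
  oracle <- matrix(1, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- if (i == j) 1 else abs(cor(x[i, ], x[j, ]))
  expect_equal(unname(a1), oracle, tolerance = 1e-12)

  # zero-variance genes are a hard error
  xz <- x; xz[3, ] <- 5
  expect_error(adjacency(xz, network_parameters()), "zero-variance")
})

test_that("topological overlap matches hand-evaluated cases", {
  clique <- matrix(1, 3, 3)
  expect_equal(topological_overlap(clique), matrix(1, 3, 3))

  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  tom <- topological_overlap(a)
  # (0 + 0.5) / (min(0.5, 0.5) + 1 - 0.5) = 0.5
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(tom[1, 3], 0)

  expect_equal(topological_overlap(diag(4)), diag(4))
})

test_that("TOM is symmetric with unit diagonal and entries in [0,1]", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    r <- cor(matrix(rnorm(n * 8), 8, n))
    a <- abs(r)^sample(1:6, 1)
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_equal(tom, t(tom))
    expect_equal(diag(tom), rep(1, n))
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("module detection recovers planted structure and rejects noise", {
  # two orthogonal planted factors, strong loadings
  specs <- list(module_spec(150, 0.95), module_spec(150, 0.95))
  gen <- generate_dataset(specs, n_noise_genes = 200,
                          samples_per_cell = 10, seed = 42)
  net <- detect_modules(gen$dataset$values,
                        network_parameters(power = 6,
                                           min_module_size = 50,
                                           merge_cut_height = 0))
  mods <- sort(unique(net$assignments[net$assignments > 0]))
  expect_length(mods, 2L)
  tr <- gen$truth$module
  for (pm in 1:2) {
    planted <- names(tr)[tr == pm]
    lab <- net$assignments[planted]
    expect_gte(max(table(lab[lab > 0])) / length(planted), 0.95)
  }

  # pure noise: >= 90% grey
  set.seed(9)
  noise <- matrix(rnorm(500 * 30), 500, 30)
  nn <- suppressWarnings(detect_modules(noise, network_parameters()))
  expect_gte(mean(nn$assignments == 0), 0.9)

  # a planted module below min_module_size stays grey
  g80 <- generate_dataset(list(module_spec(80, 0.95)), 150,
                          samples_per_cell = 10, seed = 13)
  n80 <- suppressWarnings(
    detect_modules(g80$dataset$values,
                   network_parameters(power = 6, min_module_size = 100)))
  planted <- names(g80$truth$module)[g80$truth$module == 1]
  expect_true(all(n80$assignments[planted] == 0))

  # fewer than 4 samples is a hard error
  expect_error(detect_modules(matrix(rnorm(30), 10, 3)), "4 samples")
})

test_that("module detection is deterministic", {
  gen <- generate_dataset(list(module_spec(60, 0.9)), 100,
                          samples_per_cell = 6, seed = 8)
  p <- network_parameters(power = 6, min_module_size = 30)
  n1 <- detect_modules(gen$dataset$values, p)
  n2 <- detect_modules(gen$dataset$values, p)
  expect_identical(n1$assignments, n2$assignments)
  expect_identical(n1$dendro_order, n2$dendro_order)
})

test_that("eigengenes are unit-norm first PCs with aligned sign", {
  # rank-1 block: identical genes -> explained variance 1
  x <- matrix(rep(rnorm(8), each = 5), 5, 8, byrow = FALSE)
  x <- rbind(x[1, ], x[1, ], x[1, ])
  rownames(x) <- paste0("g", 1:3)
  me <- module_eigengenes(x, rep(1L, 3))
  expect_equal(unname(me$explained_variance), 1, tolerance = 1e-12)
  expect_equal(sum(me$scores[, 1]^2), 1, tolerance = 1e-12)

  # invariance (up to sign already fixed by alignment) to gene order
  set.seed(31)
  y <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  me1 <- module_eigengenes(y, rep(1L, 20))
  me2 <- module_eigengenes(y[sample(20), ], rep(1L, 20))
  expect_equal(me1$scores, me2$scores, tolerance = 1e-9)

  # matches a dense covariance eigendecomposition oracle
  ys <- t(scale(t(y)))
  ev <- eigen(crossprod(ys), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v * colMeans(ys)) < 0) v <- -v
  expect_equal(unname(me1$scores[, 1]), v, tolerance = 1e-9)
  expect_equal(unname(me1$explained_variance),
               ev$values[1] / sum(ev$values), tolerance = 1e-11)

  # single-gene module: standardized, unit-normalized, with a warning
  expect_warning(m1 <- module_eigengenes(y[1, , drop = FALSE], 1L),
                 "single gene")
  g <- unname(scale(y[1, ])[, 1])
  expect_equal(unname(m1$scores[, 1]), g / sqrt(sum(g^2)),
               tolerance = 1e-12)
})

test_that("kME behaves as module-membership correlation", {
  gen <- generate_dataset(list(module_spec(50, 0.9)), 100,
                          samples_per_cell = 10, seed = 17)
  net <- detect_modules(gen$dataset$values,
                        network_parameters(power = 6, min_module_size = 30))
  expect_true(all(net$kme >= -1 & net$kme <= 1))
  # the top-kME gene of the planted module is a planted member
  tr <- gen$truth$module
  m <- fx_majority(net, tr)
  col <- which(m == 1)[1]
  top <- rownames(net$kme)[which.max(abs(net$kme[, col]))]
  expect_equal(unname(tr[top]), 1L)

  # kME of a gene with its own single-gene eigengene is 1
  x <- gen$dataset$values[1:3, ]
  me <- suppressWarnings(module_eigengenes(x[1, , drop = FALSE], 1L))
  expect_equal(unname(module_kme(x, me)[1, 1]), 1, tolerance = 1e-9)
})

test_that("intramodular connectivity equals within-module row sums", {
  a <- matrix(1, 3, 3)
  rownames(a) <- colnames(a) <- paste0("g", 1:3)
  expect_equal(unname(intramodular_connectivity(a, rep(1L, 3))),
               rep(2, 3))
  # singleton module
  expect_equal(unname(intramodular_connectivity(a[1, 1, drop = FALSE],
                                                1L)), 0)
  # random adjacency against a brute-force oracle; grey gets NA
  set.seed(6)
  r <- abs(cor(matrix(rnorm(80), 10, 8)))
  diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("g", 1:8)
  lab <- c(1L, 1L, 1L, 2L, 2L, 2L, 0L, 0L)
  kim <- intramodular_connectivity(r, lab)
  for (i in 1:6) {
    same <- setdiff(which(lab == lab[i]), i)
    expect_equal(unname(kim[i]), sum(r[i, same]), tolerance = 1e-12)
  }
  expect_true(all(is.na(kim[7:8])))
})

test_that("hub strength replicates across independent draws of the generator", {
  # graded per-gene loadings create genuine hubs whose kIM ranking should
  # be stable across independent sample draws
  p <- network_parameters(power = 6, min_module_size = 50)
  lam <- seq(0.5, 0.95, length.out = 150)
  specs <- list(module_spec(150, lam), module_spec(150, lam))
  kims <- lapply(c(301, 302), function(sd) {
    gen <- generate_dataset(specs, n_noise_genes = 200,
                            samples_per_cell = 10, seed = sd)
    adj <- adjacency(gen$dataset$values, p)
    intramodular_connectivity(adj, unname(gen$truth$module))
  })
  for (pm in 1:2) {
    idx <- 1:150 + (pm - 1) * 150
    expect_gt(cor(kims[[1]][idx], kims[[2]][idx]), 0.8)
  }
})
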