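# Shared fixtures, memoized across test files. Networks for the canned
# two-trait fixture take ~10 s to build, so they are computed once.
.fx <- new.env(parent = emptyenv())

fx_eae <- function() {
  if (is.null(.fx$eae)) .fx$eae <- eae_like_fixture(seed = 1)
  .fx$eae
}

# Unfiltered networks for the combined / disease / wildtype levels.
fx_eae_networks <- function() {
  if (is.null(.fx$eae_nets)) {
    gen <- fx_eae()
    lv <- suppressWarnings(split_by_design(gen$dataset))
    p <- eae_like_parameters()
    nets <- list(combined = detect_modules(lv$combined, p),
                 disease = detect_modules(lv$disease, p),
                 wildtype = detect_modules(lv$wildtype, p))
    .fx$eae_levels <- lv
    .fx$eae_nets <- assign_module_names(nets)
  }
  .fx$eae_nets
}

fx_eae_levels <- function() {
  fx_eae_networks()
  .fx$eae_levels
}

# Majority planted id per module of a network (0 = noise-dominated).
fx_majority <- function(net, truth) {
  mods <- sort(unique(net$assignments[net$assignments > 0]))
  vapply(mods, function(m) {
    tt <- table(truth[module_genes(net, m)])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}

# Reduced two-trait fixture for permutation-test checks: 500 genes,
# 20 disease / 16 wildtype over two regions, one disease-only and one
# always-active planted module.
fx_reduced <- function() {
  if (is.null(.fx$reduced)) {
    spc <- rbind(disease = c(10L, 10L), wildtype = c(8L, 8L))
    specs <- list(
      disease_only = module_spec(80, 0.9,
                                 active_in = cbind("disease", c("A", "B"))),
      always = module_spec(80, 0.9, active_in = "all"))
    .fx$reduced <- generate_dataset(specs, n_noise_genes = 340,
                                    trait2_levels = c("A", "B"),
                                    samples_per_cell = spc, seed = 101)
  }
  .fx$reduced
}

fx_reduced_params <- function() {
  network_parameters(power = 12, min_module_size = 50, merge_cut_height = 0)
}

# Disease-network + observed wildtype preservation for the reduced
# fixture (used by the permutation-test and subsampling tests).
fx_reduced_pres <- function() {
  if (is.null(.fx$reduced_pres)) {
    gen <- fx_reduced()
    ds <- gen$dataset
    dis <- ds$traits$status == "disease"
    net <- detect_modules(ds$values[, dis], fx_reduced_params())
    pres <- suppressWarnings(preservation_zsummary(
      net, ds$values[, !dis], n_label_perm = 50, seed = 7))
    .fx$reduced_pres <- list(net = net, pres = pres,
                             majority = fx_majority(net, gen$truth$module))
  }
  .fx$reduced_pres
}

# Phenotype-permutation controls on the reduced fixture (50 label
# permutations, ~40 s), shared between the preservation and acceptance
# tests.
fx_permtest <- function() {
  if (is.null(.fx$permtest)) {
    rp <- fx_reduced_pres()
    ds <- fx_reduced()$dataset
    pres <- rp$pres
    i_dis <- which(rp$majority == 1)
    i_all <- which(rp$majority == 2)
    pos <- suppressMessages(phenotype_permutation_test(
      ds, "disease", module_size = pres$size[i_dis],
      observed = pres$z_summary[i_dis], n_permutations = 50, seed = 1,
      net_params = fx_reduced_params(), n_label_perm = 30))
    neg <- suppressMessages(phenotype_permutation_test(
      ds, "disease", module_size = pres$size[i_all],
      observed = pres$z_summary[i_all], n_permutations = 50, seed = 1,
      net_params = fx_reduced_params(), n_label_perm = 30))
    .fx$permtest <- list(positive = pos, negative = neg)
  }
  .fx$permtest
}

# Minimal stand-in network for mapping/dynamics tests that only exercise
# module-membership bookkeeping (assignments, names, sample identity).
fake_network <- function(assignments, samples = paste0("s", 1:4),
                         level = 1L, condition = "", trait_name = NA) {
  mods <- sort(unique(assignments[assignments > 0]))
  expr <- matrix(0, length(assignments), length(samples),
                 dimnames = list(names(assignments), samples))
  design <- if (level > 1L || nzchar(condition))
    structure(list(level = level, trait_name = trait_name,
                   condition = condition,
                   dataset = list(values = expr)),
              class = "design_level") else NULL
  structure(list(params = network_parameters(),
                 assignments = assignments,
                 dendro = NULL,
                 dendro_order = seq_along(assignments),
                 eigengenes = list(scores = matrix(0, length(samples), 0),
                                   explained_variance = numeric(0)),
                 kme = NULL, kim = NULL, design = design,
                 name_prefix = "",
                 module_names = stats::setNames(paste0("M", mods),
                                                as.character(mods)),
                 expr = expr),
            class = "co_network")
}

# Two vectors with an exact Pearson correlation r, length n.
exact_cor_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  u <- (u - mean(u)) / stats::sd(u)
  v <- stats::residuals(stats::lm(v ~ u))
  v <- (v - mean(v)) / stats::sd(v)
  list(x = u, y = r * u + sqrt(1 - r^2) * v)
}
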