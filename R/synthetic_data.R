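#' Specify one planted co-expression module
#'
#' Genes of a planted module follow a single-factor model in the sample
#' cells where the module is active: \code{x_gs = loading * f_s +
#' sqrt(1 - loading^2) * e_gs + mean_shift(cell)}, with \code{f_s} a
#' per-module latent factor drawn N(0, 1) per sample and \code{e_gs}
#' N(0, noise_sd^2). In inactive cells the gene is pure noise. The
#' expected within-module correlation in an active cell is
#' \code{loading^2}.
#'
#' @param n_genes module size.
#' @param loading factor loading in (0, 1); either a scalar shared by all
#'   module genes or a per-gene vector of length \code{n_genes} (graded
#'   loadings create genuine hub genes).
#' @param active_in "all", or a data.frame/matrix with columns
#'   (trait1 level, trait2 level) listing the active cells.
#' @param mean_shift optional named numeric vector of per-cell additive
#'   shifts, names "level1:level2".
#' @param spike_sample optional sample index (after generation order) to
#'   which +10 is added on all module genes, emulating a single-sample
#'   outlier module.
#' @return a \code{module_spec} list.
#' @export
module_spec <- function(n_genes, loading, active_in = "all",
                        mean_shift = NULL, spike_sample = NULL) {
  stopifnot(n_genes >= 1, all(loading > 0), all(loading < 1),
            length(loading) %in% c(1L, n_genes))
  if (!identical(active_in, "all")) {
    active_in <- as.matrix(active_in)
    if (ncol(active_in) != 2 || nrow(active_in) < 1)
      stop("active_in must be 'all' or a 2-column cell table")
  }
  structure(list(n_genes = as.integer(n_genes), loading = loading,
                 active_in = active_in, mean_shift = mean_shift,
                 spike_sample = spike_sample), class = "module_spec")
}

#' Generate a two-trait expression dataset with known ground truth
#'
#' Samples are laid out cell by cell (trait1 level varying slowest).
#' Module genes come first in the matrix, then noise genes.
#'
#' @param module_specs list of \code{\link{module_spec}} objects.
#' @param n_noise_genes pure-noise genes appended after the module genes.
#' @param trait1_levels,trait2_levels level names of the two traits.
#' @param samples_per_cell scalar, or matrix (rows = trait1 levels,
#'   columns = trait2 levels) of cell sample counts; every cell needs
#'   >= 4 samples.
#' @param noise_sd standard deviation of the idiosyncratic noise.
#' @param seed RNG seed; generation is bit-identical for a fixed seed.
#' @param trait_names names of the two trait columns.
#' @return list with \code{dataset} (an
#'   \code{\link{expression_dataset}}) and \code{truth} (list:
#'   \code{module} per-gene planted id with 0 = noise, \code{specs},
#'   \code{seed}).
#' @export
generate_dataset <- function(module_specs, n_noise_genes,
                             trait1_levels = c("disease", "wildtype"),
                             trait2_levels = c("A", "B"),
                             samples_per_cell = 5, noise_sd = 1,
                             seed = 1,
                             trait_names = c("status", "condition")) {
  if (length(samples_per_cell) == 1L)
    samples_per_cell <- matrix(samples_per_cell, length(trait1_levels),
                               length(trait2_levels))
  samples_per_cell <- as.matrix(samples_per_cell)
  dimnames(samples_per_cell) <- list(trait1_levels, trait2_levels)
  if (any(samples_per_cell < 4))
    stop("every cell needs at least 4 samples")
  t1 <- character(0); t2 <- character(0)
  for (l1 in trait1_levels) for (l2 in trait2_levels) {
    n <- samples_per_cell[l1, l2]
    t1 <- c(t1, rep(l1, n)); t2 <- c(t2, rep(l2, n))
  }
  n_samples <- length(t1)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  traits <- data.frame(t1, t2, row.names = sample_ids)
  colnames(traits) <- trait_names

  n_mod_genes <- sum(vapply(module_specs, `[[`, integer(1), "n_genes"))
  n_genes <- n_mod_genes + n_noise_genes
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  set.seed(seed)
  values <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  truth <- integer(n_genes)
  row0 <- 0L
  for (m in seq_along(module_specs)) {
    sp <- module_specs[[m]]
    rows <- row0 + seq_len(sp$n_genes)
    row0 <- row0 + sp$n_genes
    truth[rows] <- m
    f <- stats::rnorm(n_samples)
    active <- if (identical(sp$active_in, "all")) rep(TRUE, n_samples)
    else {
      act <- rep(FALSE, n_samples)
      for (i in seq_len(nrow(sp$active_in)))
        act <- act | (t1 == sp$active_in[i, 1] & t2 == sp$active_in[i, 2])
      act
    }
    if (!any(active)) stop("module ", m, " active in no sample cell")
    lam <- sp$loading
    for (s in which(active))
      values[rows, s] <- lam * f[s] +
        sqrt(1 - lam^2) * values[rows, s]
    if (!is.null(sp$mean_shift)) {
      cell <- paste(t1, t2, sep = ":")
      for (cl in names(sp$mean_shift))
        values[rows, cell == cl] <- values[rows, cell == cl] +
          sp$mean_shift[[cl]]
    }
    if (!is.null(sp$spike_sample))
      values[rows, sp$spike_sample] <- values[rows, sp$spike_sample] + 10
  }
  ds <- expression_dataset(values, traits, trait_names)
  list(dataset = ds,
       truth = list(module = stats::setNames(truth, gene_ids),
                    specs = module_specs, seed = seed))
}

#' Canned two-trait fixture with a disease-specific module
#'
#' Emulates the structure of a two-group (20 disease vs 16 wildtype)
#' design crossed with four anatomical regions: one 150-gene module
#' co-expressed only in the disease samples, one 150-gene module active
#' everywhere, one 100-gene single-sample spike module, and 1600 noise
#' genes (2000 genes total). Loadings of 0.9 give an expected
#' within-module correlation of 0.81 in active cells.
#'
#' @param seed RNG seed.
#' @return see \code{\link{generate_dataset}}.
#' @export
eae_like_fixture <- function(seed = 1) {
  regions <- c("ctx", "cb", "hc", "sc")
  spc <- rbind(disease = rep(5L, 4), wildtype = rep(4L, 4))
  colnames(spc) <- regions
  disease_cells <- cbind("disease", regions)
  specs <- list(
    disease_only = module_spec(150, 0.9, active_in = disease_cells),
    always = module_spec(150, 0.9, active_in = "all"),
    spike = module_spec(100, 0.1, active_in = "all", spike_sample = 1L))
  generate_dataset(specs, n_noise_genes = 1600,
                   trait1_levels = c("disease", "wildtype"),
                   trait2_levels = regions, samples_per_cell = spc,
                   noise_sd = 1, seed = seed,
                   trait_names = c("status", "region"))
}

#' Network parameters matching the fixture's intended analysis
#'
#' Soft power 12, minimum module size 100, merge cut height 0 (no
#' merging), unsigned — the configuration under which the canned fixture
#' is analyzed throughout the package's examples and tests.
#' @return a \code{\link{network_parameters}} object.
#' @export
eae_like_parameters <- function() {
  network_parameters(power = 12, min_module_size = 100,
                     merge_cut_height = 0)
}

#' Write a generated dataset to the standard delimited files
#'
#' @param gen result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (expression, traits, truth).
#' @export
write_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen$dataset
  expr_path <- file.path(dir, "expression.tsv")
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  traits_path <- file.path(dir, "traits.tsv")
  tdf <- data.frame(sample_id = rownames(ds$traits), ds$traits,
                    check.names = FALSE)
  utils::write.table(tdf, traits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(data.frame(gene_id = names(gen$truth$module),
                                module = gen$truth$module),
                     truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = expr_path, traits = traits_path,
              truth = truth_path))
}
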