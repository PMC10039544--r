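#' Validate a pipeline configuration
#'
#' A config is a named list (typically parsed from YAML): \code{input}
#' (expression, traits, optional gene_lengths paths — or
#' \code{simulate: eae_like}), \code{trait1}, \code{trait2},
#' \code{normalize} (logical; RPKM + log2), \code{min_count_sum},
#' \code{drop_samples} (explicit sample drop-list), \code{network}
#' (power, network_type, min_module_size, merge_cut_height,
#' max_block_size, deep_split), \code{filter} (variance_threshold),
#' \code{association} (method: anova/permanova/both, n_perm),
#' \code{preservation} (n_label_perm, permutation_test: enabled,
#' n_permutations, reference_level, module), \code{seed}, \code{output}.
#'
#' @param config named list.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.null(config$input))
    stop("config error: 'input' is required")
  simulate <- !is.null(config$input$simulate)
  if (!simulate) {
    for (f in c("expression", "traits"))
      if (is.null(config$input[[f]]))
        stop("config error: input$", f, " is required")
    if (is.null(config$trait1) || is.null(config$trait2))
      stop("config error: trait1 and trait2 must be declared ",
           "(trait order is never inferred)")
  }
  config$normalize <- isTRUE(config$normalize)
  config$min_count_sum <- config$min_count_sum %||% 0
  config$seed <- as.integer(config$seed %||% 1L)
  np <- config$network %||% list()
  config$net_params <- network_parameters(
    power = np$power %||% 6,
    network_type = np$network_type %||% "unsigned",
    min_module_size = np$min_module_size %||% 30,
    merge_cut_height = np$merge_cut_height %||% 0.15,
    max_block_size = np$max_block_size %||% 5000,
    deep_split = np$deep_split %||% 2)
  config$filter_params <- filter_parameters(
    (config$filter %||% list())$variance_threshold %||% 0.02)
  assoc <- config$association %||% list()
  config$assoc_method <- assoc$method %||% "anova"
  config$assoc_n_perm <- assoc$n_perm %||% 999
  pres <- config$preservation %||% list()
  config$pres_n_label_perm <- pres$n_label_perm %||% 100
  config$permtest <- pres$permutation_test %||% list(enabled = FALSE)
  if (is.null(config$output)) stop("config error: 'output' is required")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-stage seeds derived deterministically from the global seed so that
# stages are individually rerunnable.
.stage_seed <- function(seed, stage) {
  (seed * 131L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full multi-level workflow from a config
#'
#' Executes: load/simulate -> (normalize) -> split into design levels ->
#' construct all networks -> filter outlier modules -> assign
#' nomenclature -> map all module pairs -> trait association on the
#' combined network -> within-level preservation (levels 2 and 3) ->
#' module dynamics over the level-3 networks -> optional
#' phenotype-permutation test. All tables are written under the output
#' directory together with a machine-readable summary JSON, the echoed
#' config, and a log.
#'
#' @param config named list or path to a YAML file.
#' @return invisibly, the summary list (also written as summary.json).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  yaml::write_yaml(config[setdiff(names(config),
                                  c("net_params", "filter_params"))],
                   file.path(out_dir, "config_echo.yaml"))
  logf("multinet %s, R %s, seed %d",
       as.character(utils::packageVersion("multinet")),
       paste(R.version$major, R.version$minor, sep = "."), config$seed)

  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$input$simulate)) {
      gen <- eae_like_fixture(seed = .stage_seed(config$seed, "simulate"))
      ds <- gen$dataset
      write_dataset(gen, file.path(out_dir, "simulated"))
      logf("simulated dataset: %d genes x %d samples", nrow(ds$values),
           ncol(ds$values))
    } else {
      ds <- load_expression(config$input$expression, config$input$traits,
                            config$trait1, config$trait2,
                            gene_lengths_path = config$input$gene_lengths)
      logf("loaded %d genes x %d samples", nrow(ds$values), ncol(ds$values))
    }
    if (!is.null(config$drop_samples)) {
      keep <- !colnames(ds$values) %in% config$drop_samples
      ds <- expression_dataset(ds$values[, keep, drop = FALSE],
                               ds$traits[keep, , drop = FALSE],
                               ds$trait_names, ds$gene_lengths)
      logf("dropped %d sample(s) by config", sum(!keep))
    }
    if (config$normalize) {
      stage <- "normalize"
      ds <- normalize_dataset(ds, "rpkm_log2",
                              min_count_sum = config$min_count_sum)
      logf("normalized (RPKM + log2)")
    }

    stage <- "split"
    levels_list <- split_by_design(ds)
    logf("design levels: %s", paste(names(levels_list), collapse = ", "))

    stage <- "construct"
    networks <- list()
    removed_all <- NULL
    for (nm in names(levels_list)) {
      net <- detect_modules(levels_list[[nm]], config$net_params)
      fl <- filter_network(net, config$filter_params)
      networks[[nm]] <- fl$network
      if (nrow(fl$removed)) {
        fl$removed$network <- nm
        removed_all <- rbind(removed_all, fl$removed)
      }
      logf("network %s: %d modules (%d removed as outlier-driven)", nm,
           length(unique(networks[[nm]]$assignments[
             networks[[nm]]$assignments > 0])), nrow(fl$removed))
    }
    networks <- assign_module_names(networks, config$level2_prefixes)
    for (nm in names(networks)) {
      net <- networks[[nm]]
      .write_tsv(data.frame(gene_id = names(net$assignments),
                            module_label = net$assignments,
                            module_name = ifelse(
                              net$assignments > 0,
                              net$module_names[as.character(net$assignments)],
                              "grey")),
                 file.path(out_dir, paste0("assignments_", nm, ".tsv")))
      if (ncol(net$eigengenes$scores))
        .write_tsv(data.frame(sample_id = rownames(net$eigengenes$scores),
                              net$eigengenes$scores, check.names = FALSE),
                   file.path(out_dir, paste0("eigengenes_", nm, ".tsv")))
      jsonlite::write_json(net$params[names(net$params)],
                           file.path(out_dir, paste0("params_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(removed_all))
      .write_tsv(removed_all, file.path(out_dir, "outlier_modules.tsv"))

    stage <- "map"
    tables <- map_all_modules(networks)
    all_rec <- do.call(rbind, lapply(names(tables), function(k) {
      r <- tables[[k]]$records
      if (nrow(r)) cbind(pair = k, r) else NULL
    }))
    if (!is.null(all_rec))
      .write_tsv(all_rec, file.path(out_dir, "module_overlaps.tsv"))
    logf("mapped %d network pairs", length(tables))

    stage <- "associate"
    assoc <- associate_all(networks$combined, method = config$assoc_method,
                           n_perm = config$assoc_n_perm,
                           seed = .stage_seed(config$seed, "associate"))
    .write_tsv(assoc, file.path(out_dir, "trait_association.tsv"))
    logf("trait association: %d modules", nrow(assoc))

    stage <- "preserve"
    pres_rows <- NULL
    lvl <- vapply(networks, function(n)
      if (is.null(n$design)) 1L else n$design$level, integer(1))
    for (L in c(2L, 3L)) {
      nms <- names(networks)[lvl == L]
      for (ref in nms) for (test in setdiff(nms, ref)) {
        pres <- suppressWarnings(preservation_zsummary(
          networks[[ref]],
          levels_list[[test]]$dataset$values,
          n_label_perm = config$pres_n_label_perm,
          seed = .stage_seed(config$seed, paste0("pres", ref, test))))
        if (nrow(pres))
          pres_rows <- rbind(pres_rows,
                             cbind(reference = ref, test = test, pres))
      }
    }
    if (!is.null(pres_rows))
      .write_tsv(pres_rows, file.path(out_dir, "preservation.tsv"))
    logf("preservation: %d (reference, test, module) rows",
         if (is.null(pres_rows)) 0L else nrow(pres_rows))

    stage <- "dynamics"
    l3 <- names(networks)[lvl == 3L]
    flow <- NULL
    if (length(l3) >= 2) {
      flow <- flow_table(networks[l3])
      write_flow_json(flow, file.path(out_dir, "flow_table.json"))
      logf("dynamics: %d flow edges across %d networks",
           nrow(flow$edges), length(l3))
    }

    stage <- "permtest"
    ptest <- NULL
    if (isTRUE(config$permtest$enabled)) {
      lowest <- pres_rows[which.min(pres_rows$z_summary), ]
      target_mod <- config$permtest$module %||% lowest$module
      target_row <- pres_rows[pres_rows$module == target_mod, ][1, ]
      ptest <- phenotype_permutation_test(
        ds, reference_level = config$permtest$reference_level %||%
          ds$traits[[ds$trait_names[1]]][1],
        module_size = target_row$size, observed = target_row$z_summary,
        n_permutations = config$permtest$n_permutations %||% 100,
        seed = .stage_seed(config$seed, "permtest"),
        net_params = config$net_params,
        filter_params = config$filter_params,
        n_label_perm = config$permtest$n_label_perm %||% 30)
      jsonlite::write_json(
        list(module = target_mod, observed = ptest$observed,
             null_scores = ptest$null_scores,
             matched_sizes = ptest$matched_sizes,
             p_value = ptest$p_value, seed = ptest$seed),
        file.path(out_dir, "permutation_test.json"),
        auto_unbox = TRUE, digits = NA)
      logf("permutation test: module %s p = %.4g", target_mod,
           ptest$p_value)
    }

    summary <- list(
      schema_version = "1.0",
      seed = config$seed,
      n_genes = nrow(ds$values), n_samples = ncol(ds$values),
      networks = lapply(networks, function(n) list(
        modules = length(unique(n$assignments[n$assignments > 0])),
        grey = sum(n$assignments == 0))),
      lowest_preservation = if (!is.null(pres_rows)) {
        r <- pres_rows[which.min(pres_rows$z_summary), ]
        list(module = r$module, reference = r$reference, test = r$test,
             z_summary = r$z_summary, category = r$category)
      },
      top_trait1_association = if (nrow(assoc) && "fdr_trait1" %in%
                                   colnames(assoc)) {
        r <- assoc[which.min(assoc$fdr_trait1), ]
        list(module = r$module, fdr = r$fdr_trait1)
      },
      permutation_test = if (!is.null(ptest))
        list(p_value = ptest$p_value,
             n_null = length(ptest$null_scores)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("done")
    summary
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
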