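# Pipeline orchestration: run every stage in order and write diff-able
# reports.  Outputs are a pure function of (inputs, config, seed).

write_tsv_report <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: network construction and module detection on the
#' primary cohort; module preservation against the external cohort;
#' functional/cell-type enrichment; localization (deconvolution of the
#' bulk mixtures plus eigengene-covariate association); drug panel
#' susceptibility scoring; and the directional interaction analysis of
#' the configured signature pair.  Writes `modules.tsv`,
#' `eigengenes.tsv`, `preservation.tsv`, `enrichment.tsv`,
#' `localization.tsv`, `osm.tsv`, `interaction.json` and `run_log.yaml`
#' (seed and all resolved parameters) into `outdir`.  Re-running with the
#' same configuration and seed reproduces every file byte for byte.
#'
#' @param config A `pipeline_config` from [default_config()] or
#'   [read_pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = "coexdrug_run") {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- "inputs"
  result <- tryCatch({
    inputs <- load_pipeline_inputs(config, seed)

    stage <- "network"
    expr <- filter_genes(inputs$expr)
    if (identical(config$network$power, "auto")) {
      sft <- pick_soft_threshold(expr, config$network$powers,
                                 config$network$r2_target,
                                 config$network$mode,
                                 config$network$method)
      power <- sft$power
    } else {
      power <- config$network$power
      sft <- NULL
    }
    adj <- build_adjacency(expr, power, config$network$mode,
                           config$network$method)
    tom <- topological_overlap(adj)
    modules <- detect_modules(tom, config$network$min_module_size,
                              config$network$cut_height)
    modules <- merge_close_modules(expr, modules,
                                   config$network$merge_corr)
    eig <- compute_eigengenes(expr, modules)
    kme <- module_membership(expr, eig)
    own_kme <- ifelse(modules == "grey", NA_real_,
                      kme[cbind(names(modules),
                                ifelse(modules == "grey",
                                       colnames(kme)[1L], modules))])
    write_tsv_report(data.frame(gene = names(modules),
                                module = unname(modules),
                                kme = unname(own_kme)),
                     file.path(outdir, "modules.tsv"))
    eig_df <- data.frame(module = rownames(eig), eig, check.names = FALSE)
    write_tsv_report(eig_df, file.path(outdir, "eigengenes.tsv"))

    stage <- "preservation"
    pres <- module_preservation(expr, inputs$external, modules,
                                n_perm = config$preservation$n_perm,
                                seed = stage_seed(seed, "preserve"))
    pres$replicable <- pres$evaluable & !is.na(pres$z_summary) &
      pres$z_summary >= config$preservation$z_threshold
    write_tsv_report(pres, file.path(outdir, "preservation.tsv"))

    stage <- "enrichment"
    library <- c(inputs$gene_sets, inputs$markers)
    enr <- enrich_modules(modules, library,
                          universe = rownames(expr),
                          alpha = config$enrichment$alpha,
                          or_threshold = config$enrichment$or_threshold)
    write_tsv_report(enr, file.path(outdir, "enrichment.tsv"))

    stage <- "localization"
    props <- deconvolve(inputs$mixtures, inputs$signature_matrix)
    covars <- inputs$covariates
    shared <- intersect(rownames(props), rownames(covars))
    covars <- cbind(covars[shared, , drop = FALSE],
                    props[shared, , drop = FALSE])
    assoc <- correlate_eigengene_covariate(eig, covars,
                                           fdr = config$association$fdr)
    write_tsv_report(assoc, file.path(outdir, "localization.tsv"))

    stage <- "osm"
    panel <- inputs$signatures[config$osm$panel]
    if (any(vapply(panel, is.null, logical(1L)))) {
      stop("panel drug(s) absent from the signature set: ",
           paste(setdiff(config$osm$panel, names(inputs$signatures)),
                 collapse = ", "))
    }
    osm <- susceptibility_metric(modules, panel,
                                 universe = rownames(expr),
                                 top_fraction = config$osm$top_fraction,
                                 aggregation = config$osm$aggregation)
    write_tsv_report(osm, file.path(outdir, "osm.tsv"))

    stage <- "interaction"
    sig_a <- inputs$signatures[[config$interaction$sig_a]]
    sig_b <- inputs$signatures[[config$interaction$sig_b]]
    if (is.null(sig_a) || is.null(sig_b)) {
      stop("interaction signature(s) absent from the signature set")
    }
    top_a <- drug_response_geneset(sig_a, config$interaction$top_fraction)
    top_b <- drug_response_geneset(sig_b, config$interaction$top_fraction)
    report <- build_interaction_report(
      sig_a[top_a], sig_b[top_b], universe = rownames(expr),
      min_overlap = config$interaction$min_overlap,
      alpha = config$enrichment$alpha,
      or_threshold = config$enrichment$or_threshold)
    write_interaction_report(report, file.path(outdir, "interaction.json"))

    log <- list(seed = seed, chosen_power = as.integer(power),
                parameters = prune_nulls(unclass(config)))
    yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))

    list(modules = modules, eigengenes = eig, kme = kme,
         soft_threshold = sft, preservation = pres, enrichment = enr,
         proportions = props, association = assoc, osm = osm,
         interaction = report, power = power)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

prune_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, prune_nulls)
  x[!vapply(x, is.null, logical(1L))]
}

# Resolve pipeline inputs: simulate everything with ground truth, or read
# every file named in the config.
load_pipeline_inputs <- function(config, seed) {
  if (isTRUE(config$inputs$simulate)) {
    s <- config$simulate
    study <- simulate_study(seed = seed, n_genes = s$n_genes,
                            n_samples = s$n_samples,
                            n_modules = s$n_modules,
                            module_size = s$module_size,
                            noise_sd = s$noise_sd,
                            n_external = s$n_external)
    truth_sets <- split(names(study$truth$module),
                        study$truth$module)
    truth_sets <- truth_sets[setdiff(names(truth_sets), "grey")]
    names(truth_sets) <- paste0("planted_", names(truth_sets))
    sigs <- c(study$panel[], list(
      morphine_analog = study$sig_opioid,
      ici_analog = study$sig_ici,
      ketamine_analog = study$sig_ketamine))
    list(expr = study$expr, external = study$external,
         gene_sets = truth_sets, markers = study$marker_sets,
         signature_matrix = study$signature_matrix,
         mixtures = study$mixtures$expr,
         covariates = matrix(study$phenotype,
                             dimnames = list(names(study$phenotype),
                                             "phenotype")),
         signatures = sigs, truth = study$truth)
  } else {
    inp <- config$inputs
    list(expr = read_expression_matrix(inp$expression),
         external = read_expression_matrix(inp$external),
         gene_sets = read_gmt(inp$gene_sets),
         markers = read_gmt(inp$markers),
         signature_matrix = read_expression_matrix(inp$signature_matrix),
         mixtures = read_expression_matrix(inp$expression),
         covariates = read_covariates(inp$covariates),
         signatures = read_drug_signatures(inp$drug_signatures),
         truth = NULL)
  }
}
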