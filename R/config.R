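# Pipeline configuration: defaults, YAML loading, strict validation.

#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration.  With
#' `inputs$simulate = TRUE` (the default) the pipeline generates all its
#' inputs from the synthetic study generator; otherwise every path under
#' `inputs` must point to an existing file.
#'
#' @param seed Master integer seed.
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    inputs = list(
      simulate = TRUE,
      expression = NULL,          # genes x samples TSV
      external = NULL,            # external cohort TSV
      gene_sets = NULL,           # GMT library for functional enrichment
      markers = NULL,             # GMT library of cell-type marker sets
      signature_matrix = NULL,    # cell-type signature TSV
      covariates = NULL,          # per-sample covariate TSV
      drug_signatures = NULL      # long-format signature TSV
    ),
    simulate = list(
      n_genes = 1300, n_samples = 200, n_modules = 5, module_size = 60,
      noise_sd = 1, n_external = 160
    ),
    network = list(
      power = "auto", powers = 1:20, r2_target = 0.8, mode = "unsigned",
      method = "pearson", min_module_size = 30, cut_height = 0.998,
      merge_corr = 0.75
    ),
    preservation = list(n_perm = 200, z_threshold = 2),
    enrichment = list(alpha = 0.05, or_threshold = 1),
    association = list(fdr = 0.1),
    osm = list(top_fraction = 0.05, aggregation = "stouffer",
               panel = c("opioid1", "opioid2", "opioid3", "opioid4")),
    interaction = list(sig_a = "morphine_analog", sig_b = "ici_analog",
                       min_overlap = 2, top_fraction = 0.05)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merged <- merge_config(unclass(cfg), user, prefix = "")
  cfg <- structure(merged, class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

merge_config <- function(base, override, prefix) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (key in names(override)) {
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(prefix, key, "."))
    } else {
      base[key] <- list(override[[key]])
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks every numeric parameter against its documented range and, in
#' file-input mode, that every input path exists.
#'
#' @param config A `pipeline_config`.
#' @return The config, invisibly; errors on the first violation.
#' @export
validate_pipeline_config <- function(config) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  net <- config$network
  chk(identical(net$power, "auto") ||
        (is.numeric(net$power) && net$power >= 1),
      "network.power must be 'auto' or >= 1")
  chk(all(net$powers >= 1), "network.powers must be >= 1")
  chk(net$r2_target > 0 && net$r2_target <= 1,
      "network.r2_target must be in (0, 1]")
  chk(net$min_module_size >= 3, "network.min_module_size must be >= 3")
  chk(net$cut_height > 0 && net$cut_height <= 1,
      "network.cut_height must be in (0, 1]")
  chk(net$merge_corr > 0 && net$merge_corr < 1,
      "network.merge_corr must be in (0, 1)")
  chk(net$mode %in% c("unsigned", "signed"),
      "network.mode must be unsigned or signed")
  chk(config$preservation$n_perm >= 10, "preservation.n_perm must be >= 10")
  chk(config$preservation$z_threshold > 0,
      "preservation.z_threshold must be > 0")
  chk(config$enrichment$alpha > 0 && config$enrichment$alpha < 1,
      "enrichment.alpha must be in (0, 1)")
  chk(config$enrichment$or_threshold >= 0,
      "enrichment.or_threshold must be >= 0")
  chk(config$association$fdr > 0 && config$association$fdr < 1,
      "association.fdr must be in (0, 1)")
  chk(config$osm$top_fraction > 0 && config$osm$top_fraction < 0.5,
      "osm.top_fraction must be in (0, 0.5)")
  chk(config$osm$aggregation %in% c("stouffer", "mean", "max"),
      "osm.aggregation must be stouffer, mean or max")
  chk(config$interaction$min_overlap >= 2,
      "interaction.min_overlap must be >= 2")
  chk(config$interaction$top_fraction > 0 &&
        config$interaction$top_fraction < 0.5,
      "interaction.top_fraction must be in (0, 0.5)")
  if (!isTRUE(config$inputs$simulate)) {
    paths <- config$inputs[setdiff(names(config$inputs), "simulate")]
    for (nm in names(paths)) {
      chk(!is.null(paths[[nm]]) && file.exists(paths[[nm]]),
          paste0("inputs.", nm, " must be an existing file"))
    }
  }
  invisible(config)
}
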