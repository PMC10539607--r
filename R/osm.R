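# Drug susceptibility metric: how strongly each module is enriched among
# the top-responsive genes of each drug in a perturbation panel, combined
# across the panel into a single per-module susceptibility score.  Run on a
# panel of opioid receptor modulators this is the opioid susceptibility
# metric (OSM).

#' Top-responsive gene set of a drug signature
#'
#' The `ceiling(top_fraction * n)` genes with the largest absolute effect
#' scores (direction-agnostic); ties at the boundary are broken by gene ID.
#'
#' @param signature Named numeric vector of signed per-gene scores.
#' @param top_fraction Fraction of genes kept, in (0, 0.5).
#' @return Character vector of gene IDs.
#' @export
drug_response_geneset <- function(signature, top_fraction = 0.05) {
  if (length(signature) == 0L) stop("empty signature")
  if (top_fraction <= 0 || top_fraction >= 0.5) {
    stop("top_fraction must be in (0, 0.5)")
  }
  n_keep <- ceiling(top_fraction * length(signature))
  ord <- order(-abs(signature), names(signature))
  names(signature)[ord][seq_len(n_keep)]
}

#' Per-(module, drug) overlap enrichment z-scores
#'
#' For each non-grey module and each drug gene set, the one-sided Fisher
#' overlap p-value within the universe is converted to
#' `z = qnorm(1 - p)`, with p clipped to `[1e-15, 1 - 1e-15]` before
#' inversion.
#'
#' @param modules Named character vector gene -> label.
#' @param drug_sets Named list: drug -> gene set.
#' @param universe Background genes (drug sets are intersected with it).
#' @return data.frame with columns `module`, `drug`, `z`.
#' @export
network_drug_zscores <- function(modules, drug_sets,
                                 universe = names(modules)) {
  labs <- setdiff(unique(modules), "grey")
  sizes <- vapply(labs, function(l) sum(modules == l), integer(1L))
  labs <- labs[order(-sizes, labs)]
  rows <- list()
  for (l in labs) {
    genes <- intersect(names(modules)[modules == l], universe)
    if (length(genes) < 3L) {
      warning("module ", l, " has fewer than 3 universe genes; omitted")
      next
    }
    for (d in names(drug_sets)) {
      res <- suppressWarnings(
        fisher_overlap(genes, drug_sets[[d]], universe))
      p <- min(max(res$p_value, 1e-15), 1 - 1e-15)
      # Phi^-1(1 - p) evaluated as -Phi^-1(p) to keep tail precision
      rows[[length(rows) + 1L]] <- data.frame(
        module = l, drug = d, z = -stats::qnorm(p),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no evaluable modules")
  do.call(rbind, rows)
}

#' Combine per-drug enrichment z-scores into susceptibility scores
#'
#' The raw score per module is the Stouffer combination
#' `sum_d z / sqrt(n_drugs)` (alternatives: plain mean or max of z); the
#' scaled score standardizes the raw scores to mean 0 and unit standard
#' deviation across evaluable modules.
#'
#' @param z_table data.frame from [network_drug_zscores()].
#' @param aggregation `"stouffer"` (default), `"mean"` or `"max"`.
#' @return data.frame sorted by scaled score descending: `module`, one
#'   `z_<drug>` column per drug, `raw_osm`, `scaled_osm`.
#' @export
osm_scores <- function(z_table, aggregation = c("stouffer", "mean", "max")) {
  aggregation <- match.arg(aggregation)
  drugs <- sort(unique(z_table$drug))
  mods <- unique(z_table$module)
  if (length(drugs) < 2L) stop("need at least 2 drugs")
  if (length(mods) < 2L) stop("need at least 2 modules to scale scores")
  Z <- matrix(NA_real_, length(mods), length(drugs),
              dimnames = list(mods, drugs))
  Z[cbind(z_table$module, z_table$drug)] <- z_table$z
  if (anyNA(Z)) stop("incomplete (module, drug) z table")
  raw <- switch(aggregation,
    stouffer = rowSums(Z) / sqrt(length(drugs)),
    mean = rowMeans(Z),
    max = apply(Z, 1L, max))
  if (stats::sd(raw) == 0) {
    scaled <- rep(0, length(raw))
  } else {
    scaled <- (raw - mean(raw)) / stats::sd(raw)
  }
  out <- data.frame(module = mods, Z, raw_osm = raw, scaled_osm = scaled,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[seq_along(drugs) + 1L] <- paste0("z_", drugs)
  out <- out[order(-out$scaled_osm, out$module), ]
  rownames(out) <- NULL
  out
}

#' Full susceptibility scoring of modules against a drug panel
#'
#' Thresholds every signature into its top-responsive gene set, computes
#' the per-(module, drug) enrichment z table and combines it into raw and
#' scaled susceptibility scores.
#'
#' @param modules Named character vector gene -> label.
#' @param signatures A `drug_signature_set` (named list of score vectors).
#' @param universe Background genes.
#' @param top_fraction Per-signature thresholding fraction.
#' @param aggregation Passed to [osm_scores()].
#' @return The [osm_scores()] table.
#' @export
susceptibility_metric <- function(modules, signatures,
                                  universe = names(modules),
                                  top_fraction = 0.05,
                                  aggregation = "stouffer") {
  sets <- lapply(signatures, drug_response_geneset,
                 top_fraction = top_fraction)
  z <- network_drug_zscores(modules, sets, universe)
  osm_scores(z, aggregation)
}
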