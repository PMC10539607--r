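# Synthetic data with recorded ground truth.
#
# Every generator follows the same latent single-factor model: a module is a
# set of genes sharing one latent factor (the future eigengene), each gene
# loading on it with a coefficient in [0, 1].  Hubs are the high-loading
# genes.  This makes within-module correlations available in closed form,
# cor(i, j) = l_i * l_j / sqrt((l_i^2 + s^2) (l_j^2 + s^2)),
# which the test suite uses as an oracle.

#' Simulate a primary cohort with planted coexpression modules
#'
#' Genes in module m have expression `loading_g * factor_m + N(0, noise_sd)`,
#' with a hub tier and a bulk tier of loadings: the first `n_hubs` genes of
#' each module load at `hub_loading`, the remaining genes decrease linearly
#' from `bulk_loading` to `min_loading`.  The tier gap keeps the hubs
#' statistically identifiable from gene-eigengene correlations at realistic
#' sample sizes, which a smooth loading ramp does not.  Background genes are
#' pure noise; module factors are independent standard normals across
#' samples.
#'
#' @param n_genes Total number of genes (modules + background).
#' @param n_samples Number of samples.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module.
#' @param noise_sd Standard deviation of the additive gene-level noise.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @param hub_loading,min_loading Loading range within a module.
#' @param n_hubs Number of hub-tier genes per module.
#' @param bulk_loading Loading of the first bulk-tier gene (the gap below
#'   `hub_loading` is what makes hubs identifiable).
#' @return A list with `expr` (genes x samples matrix) and `truth`, a
#'   `coexdrug_truth` object recording per-gene module labels (`"M1"`, ...,
#'   with `NA_character_`-free `"background"` coded as label `"grey"`),
#'   loadings, the factor matrix and the generator parameters.
#' @export
simulate_cohort <- function(n_genes = 1300, n_samples = 200, n_modules = 5,
                            module_size = 60, noise_sd = 1, seed = 1,
                            hub_loading = 1, min_loading = 0.4,
                            n_hubs = 3, bulk_loading = 0.7) {
  if (n_modules * module_size > n_genes) {
    stop("infeasible sizes: n_modules * module_size exceeds n_genes")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  set.seed(as.integer(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  module_names <- paste0("M", seq_len(n_modules))
  module <- c(rep(module_names, each = module_size),
              rep("grey", n_genes - n_modules * module_size))
  names(module) <- genes
  loading <- rep(0, n_genes)
  names(loading) <- genes
  n_hubs <- min(n_hubs, module_size)
  per_mod <- c(rep(hub_loading, n_hubs),
               if (module_size > n_hubs) {
                 seq(bulk_loading, min_loading,
                     length.out = module_size - n_hubs)
               })
  loading[module != "grey"] <- rep(per_mod, n_modules)
  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples,
                    dimnames = list(module_names, samples))
  expr <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                 n_genes, n_samples, dimnames = list(genes, samples))
  for (m in module_names) {
    idx <- which(module == m)
    expr[idx, ] <- expr[idx, ] + loading[idx] %o% factors[m, ]
  }
  truth <- structure(list(
    genes = genes, samples = samples, module = module, loading = loading,
    factors = factors, noise_sd = noise_sd, n_modules = n_modules,
    module_size = module_size, hub_loading = hub_loading,
    min_loading = min_loading, n_hubs = n_hubs, seed = as.integer(seed)
  ), class = "coexdrug_truth")
  list(expr = expr, truth = truth)
}

#' Simulate an external validation cohort
#'
#' Preserved modules reuse the reference cohort's gene loadings with freshly
#' drawn factors; genes of non-preserved modules lose their structure and
#' become pure background noise.
#'
#' @param truth A `coexdrug_truth` from [simulate_cohort()].
#' @param preserved_labels Character vector of module labels to preserve
#'   (subset of the planted labels).
#' @param n_samples Number of samples in the external cohort.
#' @param seed Integer seed.
#' @return Expression matrix genes x samples (same genes as the reference).
#' @export
simulate_external_cohort <- function(truth, preserved_labels, n_samples,
                                     seed = 1) {
  stopifnot(inherits(truth, "coexdrug_truth"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  planted <- rownames(truth$factors)
  unknown <- setdiff(preserved_labels, planted)
  if (length(unknown) > 0L) {
    stop("unknown module label(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n_genes <- length(truth$genes)
  samples <- sprintf("t%03d", seq_len(n_samples))
  factors <- matrix(stats::rnorm(length(planted) * n_samples),
                    length(planted), n_samples,
                    dimnames = list(planted, samples))
  expr <- matrix(stats::rnorm(n_genes * n_samples, sd = truth$noise_sd),
                 n_genes, n_samples, dimnames = list(truth$genes, samples))
  for (m in intersect(planted, preserved_labels)) {
    idx <- which(truth$module == m)
    expr[idx, ] <- expr[idx, ] + truth$loading[idx] %o% factors[m, ]
  }
  expr
}

#' Simulate a panel of drug-response signatures
#'
#' Each drug produces a signed per-gene effect score over the whole gene
#' universe: a random `frac_affected` subset of its target module's genes
#' scores `N(direction * effect_size, background_sd)`, every other gene
#' `N(0, background_sd)`.  Opposing pairs (same module, directions +1/-1)
#' and a neutral drug on a disjoint module are expressed through the
#' `drugs` table.
#'
#' @param truth A `coexdrug_truth`.
#' @param drugs data.frame with columns `name`, `module` (target label),
#'   `direction` (+1 or -1), `effect_size` (> 0 scale of the planted effect;
#'   0 gives pure background), `frac_affected` in (0, 1].
#' @param background_sd Noise scale of unaffected genes' scores.
#' @param seed Integer seed.
#' @return A `drug_signature_set` with an `"affected"` attribute listing the
#'   planted responsive genes per drug.
#' @export
simulate_drug_panel <- function(truth, drugs, background_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "coexdrug_truth"), is.data.frame(drugs))
  needed <- c("name", "module", "direction", "effect_size", "frac_affected")
  if (!all(needed %in% colnames(drugs))) {
    stop("drugs table needs columns: ", paste(needed, collapse = ", "))
  }
  planted <- rownames(truth$factors)
  unknown <- setdiff(drugs$module, planted)
  if (length(unknown) > 0L) {
    stop("unknown target module(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!drugs$direction %in% c(-1, 1))) stop("direction must be +1 or -1")
  if (any(drugs$effect_size < 0)) stop("effect_size must be >= 0")
  if (any(drugs$frac_affected <= 0 | drugs$frac_affected > 1)) {
    stop("frac_affected must be in (0, 1]")
  }
  set.seed(as.integer(seed))
  n_genes <- length(truth$genes)
  out <- vector("list", nrow(drugs))
  names(out) <- drugs$name
  affected <- vector("list", nrow(drugs))
  names(affected) <- drugs$name
  for (i in seq_len(nrow(drugs))) {
    score <- stats::rnorm(n_genes, mean = 0, sd = background_sd)
    names(score) <- truth$genes
    target <- truth$genes[truth$module == drugs$module[i]]
    n_hit <- ceiling(drugs$frac_affected[i] * length(target))
    hit <- sort(sample(target, n_hit))
    score[hit] <- stats::rnorm(n_hit,
                               mean = drugs$direction[i] * drugs$effect_size[i],
                               sd = background_sd)
    out[[i]] <- score
    affected[[i]] <- hit
  }
  attr(out, "affected") <- affected
  class(out) <- "drug_signature_set"
  out
}

#' Build a synthetic cell-type signature matrix
#'
#' Each cell type gets a disjoint block of marker genes expressed at
#' `high` in that type and `low` elsewhere; non-marker signature genes sit
#' at `low` everywhere with small deterministic jitter so columns are
#' linearly independent.
#'
#' @param marker_sets Named list: cell type -> character vector of marker
#'   genes (disjoint).
#' @param high,low Expression of a marker in its own type / elsewhere.
#' @param seed Integer seed for the jitter.
#' @return Numeric matrix, signature genes x cell types.
#' @export
make_signature_matrix <- function(marker_sets, high = 5, low = 0.5, seed = 1) {
  genes <- unlist(marker_sets, use.names = FALSE)
  if (anyDuplicated(genes)) stop("marker sets must be disjoint")
  set.seed(as.integer(seed))
  S <- matrix(low, length(genes), length(marker_sets),
              dimnames = list(genes, names(marker_sets)))
  for (ct in names(marker_sets)) S[marker_sets[[ct]], ct] <- high
  S + matrix(abs(stats::rnorm(length(S), sd = 0.05)), nrow(S))
}

#' Simulate bulk mixtures from a signature matrix
#'
#' Per sample, cell-type proportions are drawn from a Dirichlet
#' distribution and the bulk profile is `S p + N(0, noise_sd)`.
#'
#' @param signature_matrix Genes x cell types, full column rank.
#' @param n_samples Number of mixtures.
#' @param dirichlet_alpha Concentration vector (recycled to the number of
#'   cell types).
#' @param noise_sd Additive noise standard deviation (0 allowed).
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples) and `proportions`
#'   (samples x cell types, rows summing to 1).
#' @export
simulate_mixtures <- function(signature_matrix, n_samples,
                              dirichlet_alpha = 2, noise_sd = 0.1, seed = 1) {
  S <- as.matrix(signature_matrix)
  if (qr(S)$rank < ncol(S)) stop("signature matrix is rank deficient")
  k <- ncol(S)
  alpha <- rep_len(dirichlet_alpha, k)
  set.seed(as.integer(seed))
  P <- t(vapply(seq_len(n_samples), function(i) {
    g <- stats::rgamma(k, shape = alpha, rate = 1)
    g / sum(g)
  }, numeric(k)))
  dimnames(P) <- list(sprintf("mix%03d", seq_len(n_samples)), colnames(S))
  expr <- S %*% t(P)
  if (noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                          nrow(expr))
  }
  dimnames(expr) <- list(rownames(S), rownames(P))
  list(expr = expr, proportions = P)
}

#' Simulate a continuous phenotype driven by selected modules
#'
#' The phenotype (a fraction in [0, 1], modelled on a stromal
#' tumor-infiltrating lymphocyte burden) is an affine rescaling of
#' `sum(beta * factor_m) + N(0, noise_sd)`, clipped to [0, 1].
#'
#' @param truth A `coexdrug_truth`.
#' @param driver_modules Character vector of planted module labels driving
#'   the phenotype (may be empty for a pure-noise phenotype).
#' @param beta Effect size per driver module.
#' @param noise_sd Phenotype noise standard deviation.
#' @param seed Integer seed.
#' @param center,scale Affine map applied before clipping.
#' @return Named numeric vector over samples, values in [0, 1].
#' @export
simulate_phenotype <- function(truth, driver_modules, beta = 1,
                               noise_sd = 0.5, seed = 1,
                               center = 0.5, scale = 0.15) {
  stopifnot(inherits(truth, "coexdrug_truth"))
  planted <- rownames(truth$factors)
  unknown <- setdiff(driver_modules, planted)
  if (length(unknown) > 0L) {
    stop("unknown driver module(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n <- length(truth$samples)
  raw <- stats::rnorm(n, sd = noise_sd)
  for (m in driver_modules) raw <- raw + beta * truth$factors[m, ]
  phen <- pmin(pmax(center + scale * raw, 0), 1)
  names(phen) <- truth$samples
  phen
}

#' Simulate the full synthetic study
#'
#' One call builds every input the pipeline consumes, with ground truth:
#' a primary cohort with planted modules, an external cohort preserving a
#' subset of them, a module-driven phenotype, cell-type mixtures whose
#' first cell type is tied to the first module (its markers are that
#' module's hub genes and its true proportion is the module's factor),
#' a drug panel targeting the first module, an opposing
#' morphine-analog/ICI-analog signature pair on that module, and a neutral
#' ketamine-analog signature on a disjoint module.
#'
#' @param seed Integer master seed; each component draws from its own
#'   deterministic substream.
#' @param n_genes,n_samples,n_modules,module_size,noise_sd Primary cohort
#'   dimensions (defaults: 5 modules x 60 genes + 1000 background genes,
#'   200 samples, unit noise).
#' @param n_external External cohort size.
#' @param preserved Labels of modules preserved externally; by default all
#'   but the last planted module (which is destroyed).
#' @param n_celltypes Number of cell types in the signature matrix.
#' @param markers_per_type Markers per cell type.
#' @param panel_effect,panel_frac Effect size and affected fraction of the
#'   drug panel and directional signatures.
#' @param phenotype_beta,phenotype_noise Phenotype generator parameters.
#' @return List with components `expr`, `truth`, `external`, `phenotype`,
#'   `signature_matrix`, `mixtures` (cohort-aligned bulk for deconvolution,
#'   with true `proportions`), `panel` (drug_signature_set of 4 opioid
#'   analogs), `sig_opioid`, `sig_ici`, `sig_ketamine`, `marker_sets`.
#' @export
simulate_study <- function(seed = 1, n_genes = 1300, n_samples = 200,
                           n_modules = 5, module_size = 60, noise_sd = 1,
                           n_external = 160, preserved = NULL,
                           n_celltypes = 4, markers_per_type = 30,
                           panel_effect = 2, panel_frac = 0.8,
                           phenotype_beta = 1, phenotype_noise = 0.5) {
  seed <- as.integer(seed)
  if (is.null(preserved)) {
    preserved <- paste0("M", seq_len(max(1L, n_modules - 1L)))
  }
  cohort <- simulate_cohort(n_genes, n_samples, n_modules, module_size,
                            noise_sd, seed = stage_seed(seed, "simulate"))
  truth <- cohort$truth
  external <- simulate_external_cohort(truth, preserved, n_external,
                                       seed = stage_seed(seed, "external"))
  truth$preserved <- stats::setNames(
    rownames(truth$factors) %in% preserved, rownames(truth$factors))
  phenotype <- simulate_phenotype(truth, driver_modules = "M1",
                                  beta = phenotype_beta,
                                  noise_sd = phenotype_noise,
                                  seed = stage_seed(seed, "phenotype"))
  truth$phenotype_drivers <- "M1"

  # Cell types: type 1 markers are module M1's hub genes; the remaining
  # types mark disjoint background genes.
  m1_genes <- truth$genes[truth$module == "M1"]
  bg_genes <- truth$genes[truth$module == "grey"]
  marker_sets <- list(CT1 = m1_genes[seq_len(markers_per_type)])
  for (ct in seq_len(n_celltypes - 1L)) {
    idx <- (ct - 1L) * markers_per_type + seq_len(markers_per_type)
    marker_sets[[paste0("CT", ct + 1L)]] <- bg_genes[idx]
  }
  sig_mat <- make_signature_matrix(marker_sets,
                                   seed = stage_seed(seed, "mixtures"))
  # Cohort-aligned mixtures: cell type 1's true proportion follows module
  # M1's factor (rank-preserving logistic squash), so the module eigengene
  # and the deconvolved CT1 proportion are associated by construction.
  set.seed(stage_seed(seed, "mixtures"))
  k <- length(marker_sets)
  raw <- matrix(stats::rgamma(n_samples * k, shape = 2, rate = 1),
                n_samples, k)
  raw[, 1L] <- 2 * stats::plogis(truth$factors["M1", ]) + 0.05
  P <- raw / rowSums(raw)
  dimnames(P) <- list(truth$samples, names(marker_sets))
  mix_expr <- sig_mat %*% t(P) +
    matrix(stats::rnorm(nrow(sig_mat) * n_samples, sd = 0.1), nrow(sig_mat))
  dimnames(mix_expr) <- list(rownames(sig_mat), truth$samples)
  truth$proportions <- P

  panel_tab <- data.frame(
    name = paste0("opioid", 1:4), module = "M1",
    direction = c(1, -1, 1, -1), effect_size = panel_effect,
    frac_affected = panel_frac, stringsAsFactors = FALSE)
  panel <- simulate_drug_panel(truth, panel_tab,
                               seed = stage_seed(seed, "drugs"))
  pair_tab <- data.frame(
    name = c("morphine_analog", "ici_analog", "ketamine_analog"),
    module = c("M1", "M1", "M2"), direction = c(-1, 1, 1),
    effect_size = panel_effect, frac_affected = panel_frac,
    stringsAsFactors = FALSE)
  pair <- simulate_drug_panel(truth, pair_tab,
                              seed = stage_seed(seed, "interact"))
  truth$drug_targets <- rbind(panel_tab, pair_tab)

  list(expr = cohort$expr, truth = truth, external = external,
       phenotype = phenotype, signature_matrix = sig_mat,
       mixtures = list(expr = mix_expr, proportions = P),
       panel = panel, sig_opioid = pair[["morphine_analog"]],
       sig_ici = pair[["ici_analog"]],
       sig_ketamine = pair[["ketamine_analog"]],
       marker_sets = marker_sets)
}

#' Ground-truth module labels as an assignment vector
#'
#' @param truth A `coexdrug_truth`.
#' @return Named character vector gene -> label (`"grey"` for background).
#' @export
truth_module_labels <- function(truth) {
  stopifnot(inherits(truth, "coexdrug_truth"))
  truth$module
}
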