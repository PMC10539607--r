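# Module preservation in an external cohort: permutation Z statistics for
# module density and connectivity.

# Mean off-diagonal |cor| among a gene set in one cohort.
module_density <- function(expr, genes) {
  C <- abs(stats::cor(t(expr[genes, , drop = FALSE])))
  mean(C[upper.tri(C)])
}

# Permutation Z with a guard for a point-mass null: when the two cohorts
# are copies, the connectivity statistic is identically 1 under every
# permutation, so an observed value equal to the null mass scores 0;
# a genuinely degenerate null away from the observation is an error.
perm_z <- function(obs, perm, label) {
  mu <- mean(perm)
  s <- stats::sd(perm)
  if (!is.finite(s) || s < 1e-10) {
    if (is.finite(s) && abs(obs - mu) < 1e-8) return(0)
    stop("degenerate permutation null (zero spread) for module ", label)
  }
  (obs - mu) / s
}

# Intramodular connectivity of each gene: sum of |cor| to its co-members.
intramodular_connectivity <- function(expr, genes) {
  C <- abs(stats::cor(t(expr[genes, , drop = FALSE])))
  diag(C) <- 0
  rowSums(C)
}

#' Permutation test of module preservation in an external cohort
#'
#' For each module, two statistics are computed in the test cohort: the
#' density (mean off-diagonal absolute correlation among the module's
#' genes) and the connectivity pattern (Pearson correlation between the
#' genes' intramodular connectivities in the reference vs test cohort).
#' Each is converted to a Z score against `n_perm` random gene sets of the
#' same size drawn from the unassigned (`"grey"`) genes shared by both
#' cohorts — the null asks whether the module looks different from a
#' random set of non-module genes.  Drawing from all other genes instead
#' would contaminate the null with the remaining modules' coexpression
#' and bias Z downward; when too few unassigned genes exist, the pool
#' widens to all shared genes outside the module under test, with a
#' warning.  `Z_summary` is the mean of the two Z scores.
#'
#' @param ref_expr,test_expr Genes x samples matrices (gene overlap must
#'   cover at least half of each module).
#' @param modules Named character vector gene -> label from the reference
#'   cohort.
#' @param n_perm Number of permutations (>= 10; default 200).
#' @param seed Integer seed for the permutation draws.
#' @param only Optional character vector restricting which modules are
#'   evaluated (the full assignment still defines the permutation pool).
#' @return data.frame with one row per non-grey module: `module`, `size`,
#'   `evaluable`, `density`, `z_density`, `z_connectivity`, `z_summary`.
#' @export
module_preservation <- function(ref_expr, test_expr, modules, n_perm = 200,
                                seed = 1, only = NULL) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  shared <- intersect(rownames(ref_expr), rownames(test_expr))
  if (length(shared) < 10L) stop("cohorts share too few genes")
  set.seed(as.integer(seed))
  labs <- setdiff(unique(modules), "grey")
  if (!is.null(only)) labs <- intersect(labs, only)
  # size order for stable output
  sizes <- vapply(labs, function(l) sum(modules == l), integer(1L))
  labs <- labs[order(-sizes, labs)]
  rows <- lapply(labs, function(l) {
    genes <- intersect(names(modules)[modules == l], shared)
    full <- sum(modules == l)
    if (length(genes) < 3L) {
      return(data.frame(module = l, size = full, evaluable = FALSE,
                        density = NA_real_, z_density = NA_real_,
                        z_connectivity = NA_real_, z_summary = NA_real_))
    }
    if (length(genes) < 0.5 * full) {
      stop("module ", l, " has < 50% gene overlap between cohorts")
    }
    obs_dens <- module_density(test_expr, genes)
    obs_conn <- stats::cor(intramodular_connectivity(ref_expr, genes),
                           intramodular_connectivity(test_expr, genes))
    pool <- intersect(names(modules)[modules == "grey"], shared)
    pool <- union(pool, setdiff(shared, names(modules)))
    if (length(pool) < length(genes)) {
      pool <- setdiff(shared, genes)
      warning("too few unassigned genes; permutation pool widened to all ",
              "genes outside module ", l)
    }
    if (length(pool) < length(genes)) {
      warning("permutation pool smaller than module ", l,
              "; flagged not evaluable")
      return(data.frame(module = l, size = full, evaluable = FALSE,
                        density = obs_dens, z_density = NA_real_,
                        z_connectivity = NA_real_, z_summary = NA_real_))
    }
    perm <- vapply(seq_len(n_perm), function(i) {
      rnd <- sample(pool, length(genes))
      c(dens = module_density(test_expr, rnd),
        conn = stats::cor(intramodular_connectivity(ref_expr, rnd),
                          intramodular_connectivity(test_expr, rnd)))
    }, numeric(2L))
    z_d <- perm_z(obs_dens, perm["dens", ], l)
    z_c <- perm_z(obs_conn, perm["conn", ], l)
    data.frame(module = l, size = full, evaluable = TRUE,
               density = obs_dens, z_density = z_d, z_connectivity = z_c,
               z_summary = (z_d + z_c) / 2)
  })
  do.call(rbind, rows)
}

#' Modules passing the preservation threshold
#'
#' @param result data.frame from [module_preservation()].
#' @param z_threshold Positive Z_summary cutoff (default 2).
#' @return Character vector of replicable module labels (never `"grey"`).
#' @export
replicable_modules <- function(result, z_threshold = 2) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  ok <- result$evaluable & is.finite(result$z_summary) &
    result$z_summary >= z_threshold & result$module != "grey"
  result$module[ok]
}
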