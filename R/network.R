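# Weighted coexpression network construction and module detection.

cor_matrix <- function(expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene: ", rownames(expr)[which(v == 0)[1L]])
  }
  C <- stats::cor(t(expr), method = method)
  if (any(!is.finite(C))) stop("non-finite correlation encountered")
  C
}

#' Build a weighted coexpression adjacency matrix
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^power`; signed:
#' `a_ij = ((1 + cor) / 2)^power`.  The diagonal is 1.
#'
#' @param expr Genes x samples expression matrix (log scale).
#' @param power Soft-threshold power (>= 1).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @param method Correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return Symmetric genes x genes matrix with entries in [0, 1].
#' @export
build_adjacency <- function(expr, power, mode = c("unsigned", "signed"),
                            method = "pearson") {
  mode <- match.arg(mode)
  if (power < 1) stop("power must be >= 1")
  C <- cor_matrix(expr, method)
  A <- if (mode == "unsigned") abs(C)^power else ((1 + C) / 2)^power
  diag(A) <- 1
  A
}

#' Pick a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the adjacency is built, connectivities
#' `k_i = sum_{j != i} a_ij` are computed, and k is discretized into 10
#' equal-count (quantile) bins.  The scale-free fit is the R-squared of the
#' regression `log10(density(k)) ~ log10(mean k)` over bins, where the
#' density is the bin's probability mass divided by its width; the fit
#' index is signed (negated when the slope is positive, since an
#' increasing degree density contradicts scale-free topology).  The
#' chosen power is the smallest whose signed fit reaches `r2_target`, or
#' the argmax of the signed fit if none does.
#'
#' @param expr Genes x samples matrix (>= 20 genes, >= 10 samples).
#' @param powers Integer grid of candidate powers.
#' @param r2_target Target scale-free fit R-squared.
#' @param mode,method Passed to the adjacency construction.
#' @return List with `table` (data.frame: power, r_squared, slope, fit,
#'   mean_connectivity) and `power` (the chosen value).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8,
                                mode = "unsigned", method = "pearson") {
  if (nrow(expr) < 20L) stop("need at least 20 genes")
  if (ncol(expr) < 10L) stop("need at least 10 samples")
  if (any(powers < 1) || any(powers != round(powers))) {
    stop("powers must be positive integers")
  }
  C <- cor_matrix(expr, method)
  base <- if (mode == "unsigned") abs(C) else (1 + C) / 2
  diag(base) <- 0
  fits <- vapply(powers, function(p) {
    A <- base^p
    k <- rowSums(A)
    c(scale_free_fit(k), meank = mean(k))
  }, numeric(4L))
  # signed fit index: a positive log-log slope is not scale-free topology,
  # so its fit is negated before applying the selection rule
  tab <- data.frame(power = powers, r_squared = fits["r2", ],
                    slope = fits["slope", ], fit = fits["fit", ],
                    mean_connectivity = fits["meank", ])
  hit <- which(tab$fit >= r2_target)
  chosen <- if (length(hit) > 0L) {
    tab$power[min(hit)]
  } else {
    tab$power[which.max(tab$fit)]
  }
  list(table = tab, power = chosen, r2_target = r2_target)
}

# Scale-free fit from a connectivity vector: quantile bins (duplicate
# edges merged), empirical density per bin regressed on mean k, log-log.
# Returns the raw R^2, the slope, and the signed fit index (R^2 negated
# for an increasing degree density, which contradicts a power law).
scale_free_fit <- function(k, n_bins = 10L) {
  br <- unique(stats::quantile(k, seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  if (length(br) < 4L) {
    stop("fewer distinct connectivity values than 3 bins")
  }
  bin <- cut(k, br, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  count <- tapply(k, bin, length)
  width <- diff(br)
  dens <- (count / length(k)) / width
  keep <- is.finite(mean_k) & mean_k > 0 & dens > 0
  if (sum(keep) < 3L) stop("fewer than 3 usable connectivity bins")
  fit <- stats::lm(log10(dens[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  c(r2 = r2, slope = slope, fit = ifelse(slope < 0, r2, -r2))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`.
#'
#' @param adjacency Symmetric matrix with unit diagonal, entries in [0, 1].
#' @return Symmetric TOM with entries in [0, 1] and unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(A < -1e-12) || any(A > 1 + 1e-12)) {
    stop("adjacency entries must lie in [0, 1]")
  }
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A              # diag(A) = 0 makes this sum over u != i, j
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at an absolute height `cut_height` on the dissimilarity scale;
#' clusters smaller than `min_module_size` become `"grey"`, the rest are
#' labeled by decreasing size from the fixed color palette.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Minimum genes per retained module (>= 3).
#' @param cut_height Static cut height in (0, 1]; default 0.998.
#' @return Named character vector gene -> module label; attribute
#'   `"dendrogram"` carries the hclust tree.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.998) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  tab <- table(cl)
  keep <- names(tab)[tab >= min_module_size]
  ids <- integer(length(cl))
  for (i in seq_along(keep)) ids[cl == as.integer(keep[i])] <- i
  labels <- label_by_size(ids)
  names(labels) <- rownames(tom)
  attr(labels, "dendrogram") <- tree
  labels
}

#' Module eigengenes
#'
#' Per non-grey module, the first principal component of the
#' gene-standardized submatrix across samples, scaled to unit variance and
#' oriented so its mean correlation with the module's genes is
#' non-negative.
#'
#' @param expr Genes x samples matrix.
#' @param modules Named character vector gene -> label.
#' @return Matrix modules x samples with attribute `"var_explained"`
#'   (named numeric, fraction of variance captured by the component).
#' @export
compute_eigengenes <- function(expr, modules) {
  labs <- setdiff(unique(modules), "grey")
  if (length(labs) == 0L) stop("no non-grey modules")
  sizes <- vapply(labs, function(l) sum(modules == l), integer(1L))
  if (any(sizes < 2L)) {
    stop("module with fewer than 2 genes: ", labs[which(sizes < 2L)[1L]])
  }
  labs <- labs[order(-sizes, labs)]
  n <- ncol(expr)
  me <- matrix(NA_real_, length(labs), n,
               dimnames = list(labs, colnames(expr)))
  ve <- stats::setNames(numeric(length(labs)), labs)
  for (l in labs) {
    sub <- expr[names(modules)[modules == l], , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    e <- e / stats::sd(e)
    gene_cor <- stats::cor(t(z), e)
    if (mean(gene_cor) < 0) e <- -e
    me[l, ] <- e
    ve[l] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- ve
  me
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene with each module eigengene.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Modules x samples matrix.
#' @return Genes x modules matrix of correlations in [-1, 1].
#' @export
module_membership <- function(expr, eigengenes) {
  if (ncol(expr) != ncol(eigengenes)) stop("sample dimensions differ")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene: ", rownames(expr)[which(v == 0)[1L]])
  }
  kme <- stats::cor(t(expr), t(eigengenes))
  dimnames(kme) <- list(rownames(expr), rownames(eigengenes))
  kme
}

#' Hub genes per module
#'
#' Ranks each module's own genes by kME (descending, ties broken
#' lexicographically by gene ID) and returns either the top `top_n` genes
#' or all genes with kME >= `kme_min`.
#'
#' @param kme Genes x modules kME matrix.
#' @param modules Named character vector gene -> label.
#' @param top_n Number of hubs to return per module (default rule).
#' @param kme_min Alternative threshold rule in (0, 1); overrides `top_n`
#'   when non-NULL.
#' @return Named list module -> ordered character vector of hub genes.
#' @export
hub_genes <- function(kme, modules, top_n = 5, kme_min = NULL) {
  if (!is.null(kme_min) && (kme_min <= 0 || kme_min >= 1)) {
    stop("kme_min must be in (0, 1)")
  }
  if (is.null(kme_min) && top_n < 1) stop("top_n must be >= 1")
  out <- list()
  for (l in colnames(kme)) {
    genes <- names(modules)[modules == l]
    if (length(genes) == 0L) {
      warning("module ", l, " is empty; skipped")
      next
    }
    score <- kme[genes, l]
    ord <- order(-score, genes)
    ranked <- genes[ord]
    out[[l]] <- if (is.null(kme_min)) {
      utils::head(ranked, top_n)
    } else {
      ranked[score[ord] >= kme_min]
    }
  }
  out
}

#' Merge modules with highly correlated eigengenes
#'
#' Single-linkage components of the graph connecting modules whose
#' eigengene correlation exceeds `merge_corr` are merged; labels are then
#' reassigned by size.  Applying the operation to its own output changes
#' nothing.
#'
#' @param expr Genes x samples matrix.
#' @param modules Named character vector gene -> label.
#' @param merge_corr Correlation threshold in (0, 1).
#' @return Updated module assignment.
#' @export
merge_close_modules <- function(expr, modules, merge_corr = 0.75) {
  if (merge_corr <= 0 || merge_corr >= 1) stop("merge_corr must be in (0, 1)")
  labs <- setdiff(unique(modules), "grey")
  if (length(labs) < 2L) return(modules)
  me <- compute_eigengenes(expr, modules)
  C <- stats::cor(t(me))
  # single-linkage components over the |labs| module graph
  comp <- seq_along(labs)
  names(comp) <- rownames(C)
  repeat {
    changed <- FALSE
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i < j && C[i, j] > merge_corr && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids <- integer(length(modules))
  names(ids) <- names(modules)
  for (idx in seq_along(labs)) {
    ids[modules == rownames(C)[idx]] <- comp[idx]
  }
  out <- label_by_size(ids)
  names(out) <- names(modules)
  out
}

#' Drop low-information genes before network construction
#'
#' Removes zero-variance genes and optionally keeps only the `top_n` most
#' variable genes.
#'
#' @param expr Genes x samples matrix.
#' @param top_n Optional cap on the number of genes kept (by variance).
#' @return Filtered expression matrix.
#' @export
filter_genes <- function(expr, top_n = NULL) {
  v <- apply(expr, 1L, stats::var)
  expr <- expr[v > 0, , drop = FALSE]
  if (!is.null(top_n) && nrow(expr) > top_n) {
    v <- v[v > 0]
    expr <- expr[order(-v)[seq_len(top_n)], , drop = FALSE]
  }
  expr
}
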