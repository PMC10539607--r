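# Cell-type localization of modules: bulk deconvolution against a
# signature matrix, eigengene-covariate association, and marker-set
# overlap.

#' Deconvolve bulk expression into cell-type proportions
#'
#' Per sample, solves the nonnegative least-squares problem
#' `min || S p - b ||_2` subject to `p >= 0` over the genes shared by the
#' bulk matrix and the signature matrix, then renormalizes `p` to sum 1.
#' This is a deterministic constrained least-squares deconvolver with the
#' usual signature-based contract (estimated fractions on the simplex).
#'
#' @param bulk Genes x samples expression matrix.
#' @param signature_matrix Signature genes x cell types matrix, full
#'   column rank on the shared genes; shared genes must cover at least
#'   half of the signature rows.
#' @return Samples x cell types matrix, rows on the unit simplex.
#' @export
deconvolve <- function(bulk, signature_matrix) {
  S <- as.matrix(signature_matrix)
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) == 0L) stop("no genes shared with the signature matrix")
  if (length(shared) < 0.5 * nrow(S)) {
    stop("bulk matrix covers < 50% of signature genes")
  }
  S <- S[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) {
    stop("signature matrix is rank deficient on the shared genes")
  }
  B <- bulk[shared, , drop = FALSE]
  P <- t(vapply(seq_len(ncol(B)), function(j) {
    p <- pracma::lsqnonneg(S, B[, j])$x
    tot <- sum(p)
    if (tot <= 0) {
      warning("all-zero solution for sample ", colnames(B)[j],
              "; falling back to uniform proportions")
      rep(1 / ncol(S), ncol(S))
    } else {
      p / tot
    }
  }, numeric(ncol(S))))
  dimnames(P) <- list(colnames(B), colnames(S))
  P
}

#' Associate module eigengenes with sample covariates
#'
#' Spearman correlation (average ranks on ties) of every eigengene with
#' every covariate over the shared samples, with BH correction across the
#' full table.
#'
#' @param eigengenes Modules x samples matrix.
#' @param covariates Samples x covariates numeric matrix (e.g. a
#'   phenotype, or deconvolved cell-type proportions).
#' @param fdr BH significance threshold on q (default 0.1).
#' @return data.frame with columns `module`, `covariate`, `rho`,
#'   `p_value`, `q_value`, `significant`, sorted by q then p.
#' @export
correlate_eigengene_covariate <- function(eigengenes, covariates, fdr = 0.1) {
  cov <- as.matrix(covariates)
  shared <- intersect(colnames(eigengenes), rownames(cov))
  if (length(shared) < 10L) stop("fewer than 10 shared samples")
  me <- eigengenes[, shared, drop = FALSE]
  cov <- cov[shared, , drop = FALSE]
  rows <- list()
  for (m in rownames(me)) {
    for (v in colnames(cov)) {
      y <- cov[, v]
      if (stats::sd(y) == 0) {
        warning("constant covariate ", v, "; dropped")
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(me[m, ], y, method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, covariate = v, rho = unname(ct$estimate),
        p_value = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no usable covariates")
  tab <- do.call(rbind, rows)
  tab$q_value <- bh_adjust(tab$p_value)
  tab$significant <- tab$q_value < fdr
  tab <- tab[order(tab$q_value, tab$p_value, tab$module, tab$covariate), ]
  rownames(tab) <- NULL
  tab
}

#' Cell-type specificity of modules by marker-set overlap
#'
#' Fisher overlap of each module with each cell-type marker set; a module
#' is called specific to a cell type when `p < alpha` and
#' `odds_ratio > or_threshold` (raw p, not q — a deliberately different
#' rule from the FDR-based association calls).
#'
#' @inheritParams enrich_modules
#' @param marker_library Named list: cell type -> marker gene set.
#' @return data.frame with the [enrich_modules()] schema.
#' @export
celltype_specificity <- function(modules, marker_library,
                                 universe = names(modules), alpha = 0.05,
                                 or_threshold = 1) {
  enrich_modules(modules, marker_library, universe, alpha, or_threshold)
}
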