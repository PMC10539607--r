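# Directional interaction of two drug-response signatures: overlap
# enrichment, sign discordance on the shared genes, and a two-sample
# Kolmogorov-Smirnov comparison of the two effect-score distributions.

#' Overlap of two signatures' gene memberships
#'
#' Membership is every gene present in a signature (callers pre-filter to
#' differentially expressed genes, e.g. with [drug_response_geneset()]).
#' The overlap is tested for enrichment with the one-sided Fisher test
#' (flag rule: p < alpha and odds ratio > or_threshold).
#'
#' @param sig_a,sig_b Named numeric score vectors.
#' @param universe Background genes.
#' @param alpha,or_threshold Significance rule.
#' @return List with `genes` (sorted overlap IDs) and `enrichment`
#'   (one-row data.frame from [fisher_overlap()]).
#' @export
signature_overlap <- function(sig_a, sig_b, universe, alpha = 0.05,
                              or_threshold = 1) {
  if (length(universe) == 0L) stop("empty universe")
  a_genes <- intersect(names(sig_a), universe)
  b_genes <- intersect(names(sig_b), universe)
  res <- suppressWarnings(
    fisher_overlap(a_genes, b_genes, universe, alpha, or_threshold))
  list(genes = sort(intersect(a_genes, b_genes)), enrichment = res)
}

#' Sign discordance of two signatures on their shared genes
#'
#' Classifies each overlap gene by the signs of its two scores and
#' reports: the fraction of B-up genes down-regulated by A, the fraction
#' of B-down genes up-regulated by A, the two concordant complements, and
#' the overall discordance (fraction of genes with opposite signs).
#' Zero scores form their own category, counted but excluded from the
#' fractions.
#'
#' @param sig_a,sig_b Named numeric score vectors.
#' @param overlap_genes Genes scored in both signatures.
#' @return List: `n_overlap`, `n_zero`, `overall_discordance`,
#'   `frac_b_up_a_down`, `frac_b_up_a_up`, `frac_b_down_a_up`,
#'   `frac_b_down_a_down`.
#' @export
directional_discordance <- function(sig_a, sig_b, overlap_genes) {
  miss <- setdiff(overlap_genes,
                  intersect(names(sig_a), names(sig_b)))
  if (length(miss) > 0L) {
    stop("overlap gene missing a score: ", miss[1L])
  }
  sa <- sign(sig_a[overlap_genes])
  sb <- sign(sig_b[overlap_genes])
  nz <- sa != 0 & sb != 0
  n_zero <- sum(!nz)
  sa <- sa[nz]
  sb <- sb[nz]
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  b_up <- sum(sb > 0)
  b_down <- sum(sb < 0)
  list(
    n_overlap = length(overlap_genes),
    n_zero = n_zero,
    overall_discordance = frac(sum(sa * sb < 0), length(sa)),
    frac_b_up_a_down = frac(sum(sb > 0 & sa < 0), b_up),
    frac_b_up_a_up = frac(sum(sb > 0 & sa > 0), b_up),
    frac_b_down_a_up = frac(sum(sb < 0 & sa > 0), b_down),
    frac_b_down_a_down = frac(sum(sb < 0 & sa < 0), b_down)
  )
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |F_x(t) - F_y(t)|` evaluated exactly over the pooled sorted
#' values; the p-value comes from the asymptotic Kolmogorov distribution
#' via [ks_asymptotic_pvalue()].
#'
#' @param x,y Numeric samples of length >= 2, finite values.
#' @return List with `D`, `p_value`, `n`, `m`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations")
  }
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1L))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1L))
  D <- max(abs(fx - fy))
  list(D = D, p_value = ks_asymptotic_pvalue(D, length(x), length(y)),
       n = length(x), m = length(y))
}

#' Asymptotic two-sided Kolmogorov-Smirnov p-value
#'
#' With `lambda = sqrt(n m / (n + m)) * D`, the p-value is
#' `2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)`, truncated once terms
#' drop below 1e-18 and clamped to [0, 1].
#'
#' @param D KS statistic in [0, 1].
#' @param n,m Sample sizes (>= 1).
#' @return p-value in [0, 1].
#' @export
ks_asymptotic_pvalue <- function(D, n, m) {
  if (!all(is.finite(c(D, n, m)))) stop("inputs must be finite")
  if (D < 0 || D > 1) stop("D must lie in [0, 1]")
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  lambda <- sqrt(n * m / (n + m)) * D
  if (lambda == 0) return(1)
  total <- 0
  for (k in 1:1000) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-18) break
  }
  min(max(2 * total, 0), 1)
}

#' Full directional interaction report for two signatures
#'
#' Runs overlap enrichment, sign discordance, and the two-sample KS
#' comparison of the two score vectors restricted to the overlap genes
#' (treated as two unpaired samples of equal size), and collects the
#' per-gene paired effect table for scatter plotting.  When fewer than
#' `min_overlap` genes are shared, the KS and discordance components are
#' `NULL` and only the overlap statistics are reported.
#'
#' @param sig_a,sig_b Named numeric score vectors (pre-filtered to each
#'   signature's differentially expressed genes).
#' @param universe Background genes.
#' @param min_overlap Minimum overlap size for the directional components
#'   (default 2).
#' @param alpha,or_threshold Overlap significance rule.
#' @return List of class `interaction_report`: `overlap_genes`,
#'   `n_overlap`, `enrichment` (named list of counts/odds ratio/p/flag),
#'   `discordance`, `ks` (list with D, p_value, n, m) and `effects`
#'   (data.frame gene, score_a, score_b).
#' @export
build_interaction_report <- function(sig_a, sig_b, universe,
                                     min_overlap = 2, alpha = 0.05,
                                     or_threshold = 1) {
  ov <- signature_overlap(sig_a, sig_b, universe, alpha, or_threshold)
  genes <- ov$genes
  enr <- as.list(ov$enrichment)
  report <- list(
    overlap_genes = genes,
    n_overlap = length(genes),
    enrichment = enr,
    discordance = NULL,
    ks = NULL,
    effects = data.frame(gene = genes,
                         score_a = unname(sig_a[genes]),
                         score_b = unname(sig_b[genes]),
                         stringsAsFactors = FALSE)
  )
  if (length(genes) >= max(2L, min_overlap)) {
    report$discordance <- directional_discordance(sig_a, sig_b, genes)
    report$ks <- ks_two_sample(unname(sig_a[genes]), unname(sig_b[genes]))
  }
  class(report) <- "interaction_report"
  report
}

#' Serialize an interaction report to JSON
#'
#' @param report An `interaction_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an interaction report back from JSON
#'
#' @param path Path written by [write_interaction_report()].
#' @return List with the `interaction_report` fields.
#' @export
read_interaction_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "interaction_report"
  rep
}
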