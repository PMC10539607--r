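# One-sided Fisher overlap testing with Benjamini-Hochberg correction: the
# engine behind functional annotation, cell-type specificity and drug
# signature overlap calls.

#' One-sided Fisher overlap test of two gene sets
#'
#' Tests whether `set_a` and `set_b` share more genes than expected by
#' chance within `universe`.  The p-value is the hypergeometric upper tail
#' `P(X >= a)` with population `|universe|`, successes `|A|` and draws
#' `|B|`; the odds ratio is the raw cross-product ratio `(a d) / (b c)`
#' (`Inf` when `b c = 0` and `a d > 0`).
#'
#' @param set_a,set_b Character vectors of gene IDs; genes outside the
#'   universe are dropped (their count is recorded in attribute
#'   `"n_dropped"`).
#' @param universe Character vector, the background gene population.
#' @param alpha Significance level on the raw p (default 0.05).
#' @param or_threshold Minimum odds ratio for the significance flag
#'   (default 1).
#' @param haldane If TRUE, add 0.5 to every cell before the odds ratio
#'   (never done silently).
#' @param two_sided If TRUE, report the two-sided Fisher p instead of the
#'   enrichment tail.
#' @return One-row data.frame: `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `significant`.
#' @export
fisher_overlap <- function(set_a, set_b, universe, alpha = 0.05,
                           or_threshold = 1, haldane = FALSE,
                           two_sided = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  a_in <- unique(set_a)
  b_in <- unique(set_b)
  A <- intersect(a_in, universe)
  B <- intersect(b_in, universe)
  n_dropped <- (length(a_in) - length(A)) + (length(b_in) - length(B))
  if (n_dropped > 0L) {
    warning(n_dropped, " gene(s) outside the universe were dropped")
  }
  N <- length(universe)
  a <- length(intersect(A, B))
  b <- length(A) - a
  cc <- length(B) - a
  d <- N - a - b - cc
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else if (b * cc == 0) {
    if (a * d > 0) Inf else if (a == 0 || d == 0) 0 else NaN
  } else {
    (a * d) / (b * cc)
  }
  p <- if (two_sided) {
    stats::fisher.test(matrix(c(a, b, cc, d), 2L))$p.value
  } else {
    stats::phyper(a - 1L, length(A), N - length(A), length(B),
                  lower.tail = FALSE)
  }
  out <- data.frame(a = a, b = b, c = cc, d = d, odds_ratio = or,
                    p_value = p,
                    significant = (p < alpha) && is.finite(p) &&
                      (isTRUE(or > or_threshold)))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; values are returned in input
#' order and never fall below the raw p.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Enrich modules against a gene-set library
#'
#' One Fisher overlap test per (non-grey module, library set); BH
#' correction is applied across the whole table, which constitutes one
#' testing family per call.
#'
#' @param modules Named character vector gene -> label.
#' @param library Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background genes; defaults to the genes carrying module
#'   labels.
#' @param alpha,or_threshold Significance rule on raw p and odds ratio.
#' @return data.frame sorted by q then p with columns `module`, `set`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`, `significant`.
#' @export
enrich_modules <- function(modules, library, universe = names(modules),
                           alpha = 0.05, or_threshold = 1) {
  labs <- setdiff(unique(modules), "grey")
  sizes <- vapply(labs, function(l) sum(modules == l), integer(1L))
  labs <- labs[order(-sizes, labs)]
  rows <- list()
  for (l in labs) {
    genes <- names(modules)[modules == l]
    for (s in names(library)) {
      res <- suppressWarnings(
        fisher_overlap(genes, library[[s]], universe, alpha, or_threshold))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(module = l, set = s, stringsAsFactors = FALSE), res)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q_value <- bh_adjust(tab$p_value)
  or_ok <- !is.na(tab$odds_ratio) & tab$odds_ratio > or_threshold
  tab$significant <- tab$p_value < alpha & or_ok
  tab <- tab[order(tab$q_value, tab$p_value, tab$module, tab$set), ]
  rownames(tab) <- NULL
  tab[, c("module", "set", "a", "b", "c", "d", "odds_ratio",
          "p_value", "q_value", "significant")]
}
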