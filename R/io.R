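#' Read a gene expression matrix from TSV
#'
#' Expression values are assumed to be on a log scale, complete (no missing
#' values) and tab-separated with a mandatory header row.  The first column
#' carries gene identifiers when `genes_in = "rows"`, or sample identifiers
#' when `genes_in = "columns"`; the matrix is always oriented genes x samples
#' internally.
#'
#' @param path Path to a TSV file.
#' @param genes_in Either `"rows"` (default) or `"columns"`.
#' @return Numeric matrix, genes in rows, samples in columns, dimnames set.
#' @export
read_expression_matrix <- function(path, genes_in = c("rows", "columns")) {
  genes_in <- match.arg(genes_in)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file has an empty body: ", path)
  }
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate identifier in expression file: ", dup[1L])
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value in expression file at row %d, column '%s'",
                 bad[["row"]], colnames(raw)[-1L][bad[["col"]]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(raw)[-1L]
  if (genes_in == "columns") num <- t(num)
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are serialized with enough
#' digits for a lossless double round trip.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param id_column Header name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, id_column = "gene") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  body <- apply(expr, 2L, format_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(expr))
  df <- data.frame(rownames(expr), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set library in GMT format
#'
#' One set per line: name, description, then one gene per field, all
#' tab-separated.  Duplicate genes within a line are removed; duplicate set
#' names and lines with fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("GMT line %d has no genes", i))
    nms[i] <- fields[1L]
    desc[i] <- fields[2L]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in GMT: ", nms[duplicated(nms)][1L])
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set library in GMT format
#'
#' @param library Named list of character vectors, optionally carrying a
#'   `"descriptions"` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  desc <- attr(library, "descriptions") %||%
    stats::setNames(rep("na", length(library)), names(library))
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", library[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a panel of drug-response signatures
#'
#' Long-format TSV with columns `gene`, `drug`, `score` (signed real effect,
#' positive = up-regulated by the drug) and optionally `pvalue`.  Each
#' (gene, drug) pair must be unique.
#'
#' @param path Path to a TSV file.
#' @return A `drug_signature_set`: named list (one element per drug) of named
#'   numeric score vectors; a parallel `"pvalues"` attribute holds p-value
#'   vectors when present.
#' @export
read_drug_signatures <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  required <- c("gene", "drug", "score")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("drug signature file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$gene, df$drug, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (gene, drug) pair: (%s, %s)", bad$gene, bad$drug))
  }
  suppressWarnings(score <- as.numeric(df$score))
  if (anyNA(score)) {
    i <- which(is.na(score))[1L]
    stop(sprintf("non-numeric score at line %d (gene %s, drug %s)",
                 i + 1L, df$gene[i], df$drug[i]))
  }
  has_p <- "pvalue" %in% colnames(df)
  sigs <- split(seq_len(nrow(df)), df$drug)
  out <- lapply(sigs, function(idx) stats::setNames(score[idx], df$gene[idx]))
  if (has_p) {
    suppressWarnings(pv <- as.numeric(df$pvalue))
    attr(out, "pvalues") <-
      lapply(sigs, function(idx) stats::setNames(pv[idx], df$gene[idx]))
  }
  class(out) <- "drug_signature_set"
  out
}

#' Write a panel of drug-response signatures
#'
#' Inverse of [read_drug_signatures()].
#'
#' @param signatures A `drug_signature_set` or plain named list of named
#'   numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_signatures <- function(signatures, path) {
  rows <- lapply(names(signatures), function(d) {
    s <- signatures[[d]]
    data.frame(gene = names(s), drug = d, score = format_num(unname(s)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample covariate table
#'
#' TSV with a `sample` identifier column and one numeric column per
#' covariate.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, samples x covariates, rownames = sample IDs.
#' @export
read_covariates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!"sample" %in% colnames(df)) {
    stop("covariate file must have a 'sample' column")
  }
  ids <- as.character(df$sample)
  if (anyDuplicated(ids)) stop("duplicate sample ID in covariate file")
  m <- as.matrix(df[, setdiff(colnames(df), "sample"), drop = FALSE])
  if (!is.numeric(m)) stop("covariate columns must be numeric")
  rownames(m) <- ids
  m
}
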