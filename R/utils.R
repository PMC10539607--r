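# Internal helpers shared across stages.

#' Module color palette
#'
#' Fixed palette used to name detected modules by decreasing size, in the
#' convention of weighted coexpression analysis ("turquoise" is always the
#' largest module). `"grey"` is reserved for unassigned genes and never
#' appears in the palette.
#'
#' @return Character vector of color names.
#' @export
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

# Label clusters by decreasing size from the palette; sizes beyond the
# palette get synthetic "module<N>" names.  `labels` is an integer vector
# with 0 meaning unassigned.
label_by_size <- function(cluster_ids) {
  stopifnot(is.numeric(cluster_ids))
  out <- rep("grey", length(cluster_ids))
  assigned <- cluster_ids != 0
  if (any(assigned)) {
    tab <- sort(table(cluster_ids[assigned]), decreasing = TRUE)
    pal <- module_palette()
    nm <- names(tab)
    for (i in seq_along(nm)) {
      color <- if (i <= length(pal)) pal[i] else paste0("module", i)
      out[cluster_ids == as.numeric(nm[i])] <- color
    }
  }
  names(out) <- names(cluster_ids)
  out
}

# Deterministic per-stage seed substream.  Each pipeline stage draws its own
# seed from the master seed so stages can be re-run in isolation and still
# reproduce the full run.  Offsets are fixed per stage name.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, external = 211L, drugs = 307L,
               mixtures = 401L, phenotype = 503L, network = 601L,
               preserve = 701L, enrich = 809L, localize = 907L,
               osm = 1009L, interact = 1103L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage name: ", stage)
  }
  (as.integer(seed) * 1181L + offsets[[stage]]) %% 2147483587L
}

# Stable numeric formatting for TSV reports: enough digits for a lossless
# double round trip, byte-identical across runs.
format_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
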