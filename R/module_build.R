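# Construction of fixed-size marker-anchored transcript modules: Pearson
# correlation of each marker against all genes of a reference panel, top-k
# selection, and size-matched random gene sets as a permutation control.

#' Correlate a marker gene against every gene of a panel
#'
#' Pearson correlation of the marker's expression row with every gene that has
#' nonzero variance, ranked descending. The marker correlates 1 with itself
#' and therefore ranks first (ties broken by gene id).
#'
#' @param expr gene x sample expression matrix.
#' @param marker marker gene id, present in `expr`.
#' @return data.frame with columns `gene`, `r`, sorted by descending `r`,
#'   then ascending gene id.
#' @export
correlate_marker <- function(expr, marker) {
  if (!marker %in% rownames(expr)) stopf("marker '%s' not in matrix", marker)
  if (ncol(expr) < 3) stopf("need at least 3 samples to correlate")
  v <- expr[marker, ]
  if (stats::sd(v) == 0) stopf("marker '%s' has zero variance", marker)
  sds <- apply(expr, 1, stats::sd)
  keep <- sds > 0
  r <- as.vector(stats::cor(v, t(expr[keep, , drop = FALSE])))
  out <- data.frame(gene = rownames(expr)[keep], r = r,
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$gene), , drop = FALSE]
}

#' Build one marker-anchored module
#'
#' Takes the `module_size` genes most positively correlated with the marker
#' (the marker itself included at r = 1); negatively correlated transcripts
#' are never recruited preferentially — only the positive end of the ranking
#' is used. Rank ties are broken by ascending gene id, so the construction is
#' deterministic.
#'
#' @param expr gene x sample expression matrix.
#' @param marker marker gene id.
#' @param module_size module size (default 100).
#' @return object of class `gene_module`: list with `marker`, `members`
#'   (length `module_size`), `correlations` (descending).
#' @export
build_module <- function(expr, marker, module_size = 100) {
  ranked <- correlate_marker(expr, marker)
  if (nrow(ranked) < module_size) {
    stopf("only %d genes with defined correlation; %d more needed for a %d-gene module",
          nrow(ranked), module_size - nrow(ranked), module_size)
  }
  top <- ranked[seq_len(module_size), ]
  structure(list(marker = marker, members = top$gene, correlations = top$r),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %s.mod: %d genes, r in [%.3f, %.3f]\n",
              x$marker, length(x$members), min(x$correlations),
              max(x$correlations)))
  invisible(x)
}

#' Build modules for a list of markers
#'
#' One module per marker found in the matrix; absent markers are skipped with
#' a warning. Modules are named `<MARKER>.mod`.
#'
#' @param expr gene x sample expression matrix.
#' @param markers character vector of marker gene ids.
#' @param module_size module size (default 100).
#' @return object of class `module_collection`.
#' @export
build_all_modules <- function(expr, markers, module_size = 100) {
  if (length(markers) == 0) stopf("no markers supplied")
  missing <- setdiff(markers, rownames(expr))
  if (length(missing) > 0) {
    warnf("skipping %d marker(s) absent from the matrix: %s",
          length(missing), paste(utils::head(missing, 5), collapse = ", "))
  }
  markers <- intersect(markers, rownames(expr))
  if (length(markers) == 0) stopf("all markers missing from the matrix")
  mods <- lapply(markers, build_module, expr = expr, module_size = module_size)
  names(mods) <- paste0(markers, ".mod")
  module_collection(mods, provenance = "derived")
}

#' Construct a module collection
#'
#' @param modules named list of `gene_module` objects (or plain member lists
#'   for random sets).
#' @param provenance `"derived"` or `"random"`.
#' @return object of class `module_collection`.
#' @export
module_collection <- function(modules, provenance = c("derived", "random")) {
  provenance <- match.arg(provenance)
  if (anyDuplicated(names(modules))) stopf("module names must be unique")
  structure(modules, class = "module_collection", provenance = provenance)
}

#' @export
print.module_collection <- function(x, ...) {
  sizes <- vapply(x, function(m) length(module_members(m)), 0L)
  cat(sprintf("<module_collection> %d %s modules (sizes %d-%d), %d distinct genes\n",
              length(x), attr(x, "provenance"), min(sizes), max(sizes),
              length(unique(unlist(lapply(x, module_members))))))
  invisible(x)
}

#' Member genes of a module
#' @param m a `gene_module` or a plain character vector.
#' @return character vector of gene ids.
#' @export
module_members <- function(m) {
  if (inherits(m, "gene_module")) m$members else as.character(m)
}

#' Draw size-matched random gene sets
#'
#' `n_sets` sets of `set_size` distinct genes, each drawn uniformly from the
#' universe; sets are drawn independently, so genes recur across sets
#' (sampling with substitution across sets), but never within one.
#'
#' @param universe character vector of candidate gene ids.
#' @param n_sets number of sets (default 526, matching the derived
#'   collection).
#' @param set_size genes per set (default 100).
#' @param seed RNG seed.
#' @return `module_collection` with provenance `"random"`; sets are named
#'   `rand001`, `rand002`, ...
#' @export
random_gene_sets <- function(universe, n_sets = 526, set_size = 100, seed = 1) {
  universe <- unique(as.character(universe))
  if (length(universe) < set_size) {
    stopf("universe (%d genes) smaller than set_size (%d)",
          length(universe), set_size)
  }
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  })
  names(sets) <- sprintf("rand%03d", seq_len(n_sets))
  module_collection(sets, provenance = "random")
}

#' Serialize a module collection as GMT
#'
#' The description field carries the marker and the min/median member
#' correlation for derived modules.
#'
#' @param collection `module_collection`.
#' @param path output path.
#' @export
write_modules_gmt <- function(collection, path) {
  desc <- vapply(collection, function(m) {
    if (inherits(m, "gene_module")) {
      sprintf("marker=%s;min_r=%.4f;median_r=%.4f", m$marker,
              min(m$correlations), stats::median(m$correlations))
    } else "random"
  }, "")
  sets <- lapply(collection, module_members)
  names(sets) <- names(collection)
  write_gmt(sets, path, descriptions = desc)
}
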