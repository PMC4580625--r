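# Module clustering and annotation: pairwise overlap fractions, Ward
# clustering of the overlap table with a silhouette-selected cut, and
# hypergeometric enrichment against reference gene-set collections with
# Benjamini-Hochberg correction.

#' Fraction of gene overlap between two equal-size modules
#'
#' @param a,b `gene_module` objects or character vectors of equal size.
#' @return `|A intersect B| / module_size`, in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  ga <- module_members(a); gb <- module_members(b)
  if (length(ga) != length(gb)) {
    stopf("overlap fraction requires equal-size modules (%d vs %d)",
          length(ga), length(gb))
  }
  length(intersect(ga, gb)) / length(ga)
}

#' Pairwise overlap matrix of a module collection
#'
#' Symmetric with unit diagonal; entry (i, j) is the fraction of shared genes.
#'
#' @param collection `module_collection` of equal-size modules.
#' @return numeric matrix, module names on both dimensions.
#' @export
overlap_matrix <- function(collection) {
  members <- lapply(collection, module_members)
  sizes <- lengths(members)
  if (length(unique(sizes)) != 1) stopf("modules must share one size")
  genes <- unique(unlist(members))
  # indicator matrix: crossprod gives all pairwise intersection counts at once
  ind <- vapply(members, function(m) as.numeric(genes %in% m),
                numeric(length(genes)))
  ov <- crossprod(ind) / sizes[1]
  dimnames(ov) <- list(names(collection), names(collection))
  stopifnot(isSymmetric(ov), all(abs(diag(ov) - 1) < 1e-12))
  ov
}

#' Cluster modules on their overlap matrix
#'
#' Agglomerative Ward clustering on distance `1 - overlap`. With `k = "auto"`
#' the tree is cut at every k in `2..k_max` and the cut maximizing the mean
#' silhouette width is kept; ties go to the smaller k. Deterministic given
#' the input.
#'
#' @param overlap overlap matrix from [overlap_matrix()].
#' @param k fixed number of clusters, or `"auto"`.
#' @param k_max largest k scanned when `k = "auto"` (default 30).
#' @return list of class `module_clusters`: `cluster` (named integer vector,
#'   ids contiguous from 1), `n_clusters`, `hclust` (the linkage record),
#'   `silhouette` (mean widths per scanned k, when auto).
#' @export
cluster_modules <- function(overlap, k = "auto", k_max = 30) {
  n <- nrow(overlap)
  d <- stats::as.dist(1 - overlap)
  hc <- stats::hclust(d, method = "ward.D")
  sil_by_k <- NULL
  if (identical(k, "auto")) {
    ks <- if (n >= 3) seq(2L, min(k_max, n - 1L)) else integer(0)
    if (length(ks) == 0) {
      k <- 1L
    } else {
      sil_by_k <- vapply(ks, function(kk) {
        cl <- stats::cutree(hc, k = kk)
        mean(cluster::silhouette(cl, d)[, "sil_width"])
      }, 0)
      k <- ks[which.max(sil_by_k)]
      names(sil_by_k) <- ks
    }
  } else {
    k <- as.integer(k)
    if (k > n) stopf("k (%d) exceeds the number of modules (%d)", k, n)
  }
  raw <- stats::cutree(hc, k = k)
  # relabel so cluster ids are contiguous from 1 in first-appearance order
  cl <- match(raw, unique(raw))
  names(cl) <- rownames(overlap)
  structure(list(cluster = cl, n_clusters = max(cl), hclust = hc,
                 silhouette = sil_by_k),
            class = "module_clusters")
}

#' @export
print.module_clusters <- function(x, ...) {
  cat(sprintf("<module_clusters> %d modules in %d clusters\n",
              length(x$cluster), x$n_clusters))
  invisible(x)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `|module intersect set|` annotated genes
#' when `|module|` genes are drawn without replacement from the universe.
#' Both the module and the annotation set are first intersected with the
#' universe.
#'
#' @param module character vector of gene ids.
#' @param set annotation gene set.
#' @param universe background gene ids (non-empty).
#' @return `P(X >= k)` in `(0, 1]`.
#' @export
hypergeom_enrichment <- function(module, set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  module <- intersect(unique(module), universe)
  set <- intersect(unique(set), universe)
  k <- length(intersect(module, set))
  stats::phyper(k - 1, length(set), length(universe) - length(set),
                length(module), lower.tail = FALSE)
}

#' Annotate a module collection against reference gene-set collections
#'
#' Hypergeometric enrichment of every (module, reference set) pair;
#' Benjamini-Hochberg FDR applied within each reference collection. The top
#' term of a module in a collection is the minimum-FDR set at FDR < 0.05
#' (ties broken by set name), else `"NS"`. Each cluster's summary term is the
#' top term occurring most often among its member modules (ties: smallest
#' FDR, then name) — a deterministic stand-in for expert-assigned summary
#' labels.
#'
#' @param collection `module_collection`.
#' @param refs named list of gene-set collections (each from [read_gmt()] or
#'   a named list of character vectors).
#' @param universe background gene universe (typically all genes of the
#'   reference panel the modules were built from).
#' @param clusters optional `module_clusters`; enables summary terms.
#' @param fdr_cutoff significance cut-off on the BH FDR (default 0.05).
#' @return list of class `annotation_result`: `tests` (long data.frame:
#'   collection, module, set, k, set_size, module_size, p, fdr), `top_terms`
#'   (module x collection data.frame), `cluster_terms` (per-cluster summary),
#'   `universe_size`.
#' @export
annotate_collection <- function(collection, refs, universe, clusters = NULL,
                                fdr_cutoff = 0.05) {
  if (length(refs) == 0) stopf("no reference collections supplied")
  if (is.null(names(refs))) names(refs) <- sprintf("ref%d", seq_along(refs))
  universe <- unique(universe)
  members <- lapply(collection, function(m) intersect(module_members(m), universe))
  tests <- do.call(rbind, lapply(names(refs), function(rn) {
    sets <- lapply(refs[[rn]], function(s) intersect(unique(s), universe))
    grid <- expand.grid(module = names(collection), set = names(sets),
                        stringsAsFactors = FALSE)
    grid$collection <- rn
    grid$k <- mapply(function(m, s) length(intersect(members[[m]], sets[[s]])),
                     grid$module, grid$set)
    grid$set_size <- lengths(sets)[grid$set]
    grid$module_size <- lengths(members)[grid$module]
    grid$p <- stats::phyper(grid$k - 1, grid$set_size,
                            length(universe) - grid$set_size,
                            grid$module_size, lower.tail = FALSE)
    grid$fdr <- stats::p.adjust(grid$p, method = "BH")
    grid
  }))
  tests <- tests[, c("collection", "module", "set", "k", "set_size",
                     "module_size", "p", "fdr")]
  top <- expand.grid(module = names(collection), collection = names(refs),
                     stringsAsFactors = FALSE)
  pick <- mapply(function(m, rn) {
    sub <- tests[tests$module == m & tests$collection == rn &
                   tests$fdr < fdr_cutoff, ]
    if (nrow(sub) == 0) return(c("NS", NA_real_))
    sub <- sub[order(sub$fdr, sub$set), ]
    c(sub$set[1], sub$fdr[1])
  }, top$module, top$collection)
  top$term <- pick[1, ]
  top$fdr <- suppressWarnings(as.numeric(pick[2, ]))
  cluster_terms <- NULL
  if (!is.null(clusters)) {
    cluster_terms <- data.frame(cluster = seq_len(clusters$n_clusters),
                                summary_term = NA_character_,
                                stringsAsFactors = FALSE)
    for (cl in cluster_terms$cluster) {
      mods <- names(clusters$cluster)[clusters$cluster == cl]
      cand <- top[top$module %in% mods & top$term != "NS", ]
      if (nrow(cand) == 0) { cluster_terms$summary_term[cl] <- "NS"; next }
      freq <- sort(table(cand$term), decreasing = TRUE)
      best <- names(freq)[freq == max(freq)]
      if (length(best) > 1) {
        sub <- cand[cand$term %in% best, ]
        sub <- sub[order(sub$fdr, sub$term), ]
        best <- sub$term[1]
      }
      cluster_terms$summary_term[cl] <- best
    }
  }
  structure(list(tests = tests, top_terms = top,
                 cluster_terms = cluster_terms,
                 universe_size = length(universe)),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  sig <- sum(x$top_terms$term != "NS")
  cat(sprintf("<annotation_result> %d tests over %d modules x %d collections; %d module/collection top terms at FDR < 0.05\n",
              nrow(x$tests), length(unique(x$tests$module)),
              length(unique(x$tests$collection)), sig))
  invisible(x)
}
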