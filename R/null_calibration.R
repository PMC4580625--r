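# Permutation nulls and significance tallies: random equal-sized sample
# partitions, random gene sets (see random_gene_sets), expected-by-chance
# counts, BH FDR per cohort, cluster counting among significant modules,
# and the per-cohort summary table.

#' Random equal-sized hi/lo sample partitions
#'
#' Each permutation assigns floor(n/2) samples to `lo` and ceiling(n/2) to
#' `hi` uniformly at random (hi takes the extra sample at odd n).
#'
#' @param samples character vector of sample ids (>= 4).
#' @param n_perm number of partitions.
#' @param seed RNG seed.
#' @return logical matrix samples x n_perm (TRUE = hi), usable directly with
#'   [logrank_many()]; convert with [as_partition_list()] for the per-object
#'   interface.
#' @export
random_sample_partitions <- function(samples, n_perm = 1000, seed = 1) {
  n <- length(samples)
  if (n < 4) stopf("need at least 4 samples")
  n_hi <- ceiling(n / 2)
  hi <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      x <- logical(n); x[sample.int(n, n_hi)] <- TRUE; x
    }, logical(n))
  })
  rownames(hi) <- samples
  colnames(hi) <- sprintf("random:%d", seq_len(n_perm))
  hi
}

#' Convert a partition membership matrix to a list of partitions
#' @param hi logical matrix from [random_sample_partitions()].
#' @return list of `partition` objects.
#' @export
as_partition_list <- function(hi) {
  lapply(seq_len(ncol(hi)), function(j) {
    lab <- ifelse(hi[, j], "hi", "lo")
    names(lab) <- rownames(hi)
    structure(list(labels = lab, origin = colnames(hi)[j], score = NULL),
              class = "partition")
  })
}

#' Log-rank p-values of random sample partitions on one cohort
#'
#' The empirical null of the screening procedure: survival is fixed, group
#' labels are random.
#'
#' @param clinical clinical data.frame.
#' @param n_perm number of random partitions (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of p-values, one per partition.
#' @export
null_partition_pvalues <- function(clinical, n_perm = 1000, seed = 1) {
  validate_clinical(clinical)
  hi <- random_sample_partitions(clinical$sample, n_perm, seed)
  logrank_many(clinical$time, clinical$event, hi)$p
}

#' Tally significance counts against expected-by-chance
#'
#' @param p numeric p-values (one permutation family, e.g. the random
#'   partitions of one cohort).
#' @param thresholds significance thresholds (default 1e-3 and 5e-3).
#' @return data.frame: `threshold`, `count` (p < threshold), `n_tests`,
#'   `expected` (`n_tests * threshold`).
#' @export
null_counts <- function(p, thresholds = c(1e-3, 5e-3)) {
  if (length(p) == 0) stopf("no p-values supplied")
  data.frame(threshold = thresholds,
             count = vapply(thresholds, function(a) sum(p < a, na.rm = TRUE), 0),
             n_tests = length(p),
             expected = length(p) * thresholds)
}

#' Cluster counting among significant modules
#'
#' Builds a graph on the significant modules with an edge wherever the
#' pairwise gene overlap exceeds the threshold, and counts connected
#' components — the number of distinct module clusters represented, guarding
#' against double-counting near-identical modules.
#'
#' @param significant character vector of module names.
#' @param overlap overlap matrix containing them.
#' @param threshold overlap fraction above which modules are linked
#'   (default 0.25).
#' @return integer component count.
#' @export
count_significant_clusters <- function(significant, overlap, threshold = 0.25) {
  if (length(significant) == 0) return(0L)
  missing <- setdiff(significant, rownames(overlap))
  if (length(missing) > 0) {
    stopf("module(s) not in overlap matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- overlap[significant, significant, drop = FALSE]
  adj <- sub > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::count_components(g)
}

#' Retain survival themes supported by more than one module
#'
#' A theme is trustworthy when at least two significant modules share a
#' cluster, or at least two significant modules from different clusters share
#' a summary annotation term; singleton hits are reported as unsupported.
#'
#' @param significant character vector of significant module names.
#' @param clusters `module_clusters`.
#' @param annotations `annotation_result` (its `cluster_terms` supply each
#'   module's summary term through its cluster).
#' @return data.frame: `module`, `cluster`, `summary_term`, `supported`,
#'   `support` (`"cluster"`, `"annotation"`, `"both"` or `""`).
#' @export
theme_filter <- function(significant, clusters, annotations) {
  if (length(significant) == 0) {
    return(data.frame(module = character(0), cluster = integer(0),
                      summary_term = character(0), supported = logical(0),
                      support = character(0), stringsAsFactors = FALSE))
  }
  cl <- clusters$cluster[significant]
  terms <- annotations$cluster_terms$summary_term[cl]
  by_cluster <- table(cl)
  term_ok <- !is.na(terms) & terms != "NS"
  by_term <- table(terms[term_ok])
  cluster_support <- as.vector(by_cluster[as.character(cl)]) >= 2
  term_support <- term_ok & as.vector(by_term[terms]) >= 2 & !cluster_support
  # annotation support requires the sharing modules to sit in different clusters
  for (i in which(term_ok)) {
    same_term <- which(term_ok & terms == terms[i])
    term_support[i] <- length(unique(cl[same_term])) >= 2 && length(same_term) >= 2
  }
  support <- ifelse(cluster_support & term_support, "both",
                    ifelse(cluster_support, "cluster",
                           ifelse(term_support, "annotation", "")))
  data.frame(module = significant, cluster = as.integer(cl),
             summary_term = ifelse(is.na(terms), "NS", terms),
             supported = support != "", support = support,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR per cohort
#'
#' BH step-up within each cohort across its module p-values; reports, per
#' cohort, the FDR attained at the largest p-value below each cutoff, and
#' the median of those FDRs across cohorts.
#'
#' @param screen_res `screen_matrix` (or any data.frame with `cohort`,
#'   `p_value`).
#' @param cutoffs p-value cutoffs of interest (default 1e-3, 5e-3).
#' @return list: `per_cohort` (cohort x cutoff FDR data.frame), `median_fdr`
#'   (named by cutoff).
#' @export
bh_fdr_per_cohort <- function(screen_res, cutoffs = c(1e-3, 5e-3)) {
  d <- screen_res[!is.na(screen_res$p_value), , drop = FALSE]
  if (nrow(d) == 0) stopf("no p-values to adjust")
  per <- do.call(rbind, lapply(split(d, d$cohort), function(s) {
    fdr <- stats::p.adjust(s$p_value, method = "BH")
    row <- data.frame(cohort = s$cohort[1], stringsAsFactors = FALSE)
    for (ct in cutoffs) {
      below <- s$p_value <= ct
      row[[paste0("fdr_at_", format(ct))]] <-
        if (any(below)) fdr[below][which.max(s$p_value[below])] else NA_real_
    }
    row
  }))
  rownames(per) <- NULL
  med <- vapply(cutoffs, function(ct) {
    stats::median(per[[paste0("fdr_at_", format(ct))]], na.rm = TRUE)
  }, 0)
  names(med) <- vapply(cutoffs, format, "")
  list(per_cohort = per, median_fdr = med)
}

#' Per-cohort summary of module, random-gene-set and random-partition tallies
#'
#' One row per cohort: counts of significant module partitions, random gene
#' sets and random sample partitions at each threshold, the number of module
#' clusters represented among significant modules (>25% overlap rule), a
#' representative top module, and its annotation.
#'
#' @param module_screen `screen_matrix` of the derived modules.
#' @param random_screen `screen_matrix` of the random gene sets (same
#'   cohorts).
#' @param null_partition_p named list: cohort -> p-values from
#'   [null_partition_pvalues()].
#' @param overlap overlap matrix of the derived modules.
#' @param clusters `module_clusters` of the derived modules.
#' @param annotations optional `annotation_result` for top-module terms.
#' @param thresholds significance thresholds (default 1e-3, 5e-3).
#' @return data.frame of class `cohort_summary`, one row per cohort.
#' @export
cohort_summary_table <- function(module_screen, random_screen,
                                 null_partition_p, overlap, clusters,
                                 annotations = NULL,
                                 thresholds = c(1e-3, 5e-3)) {
  cohorts <- unique(module_screen$cohort)
  rows <- lapply(cohorts, function(cn) {
    ms <- module_screen[module_screen$cohort == cn & !module_screen$skipped, ]
    rs <- random_screen[random_screen$cohort == cn & !random_screen$skipped, ]
    np <- null_partition_p[[cn]]
    row <- data.frame(cohort = cn, stringsAsFactors = FALSE)
    for (a in thresholds) {
      tag <- gsub("-", "m", format(a, scientific = TRUE))
      row[[paste0("random_samples_", tag)]] <-
        if (is.null(np)) NA_integer_ else sum(np < a)
      row[[paste0("random_gene_sets_", tag)]] <- sum(rs$p_value < a)
      row[[paste0("modules_", tag)]] <- sum(ms$p_value < a)
      row[[paste0("clusters_", tag)]] <- count_significant_clusters(
        ms$module[ms$p_value < a], overlap)
    }
    sig <- ms[ms$p_value < max(thresholds), ]
    if (nrow(sig) > 0) {
      top <- sig$module[which.min(sig$p_value)]
      row$top_module <- top
      row$top_module_p <- min(sig$p_value)
      if (!is.null(annotations)) {
        cl <- clusters$cluster[top]
        row$top_module_annotation <-
          annotations$cluster_terms$summary_term[cl]
      }
    } else {
      row$top_module <- "NA"; row$top_module_p <- NA_real_
      if (!is.null(annotations)) row$top_module_annotation <- "NA"
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}
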