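# Per-gene hi/lo comparisons of copy-number, expression or protein tables:
# Wilcoxon rank-sum scans ordered along the genome (Manhattan view), random
# -partition controls, peak-region calling, and targeted feature contrasts.

#' Two-sided Wilcoxon rank-sum test between two value groups
#'
#' Exact distribution when both groups have at most 10 values and there are
#' no ties; otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction.
#'
#' @param values_hi,values_lo numeric vectors (both non-empty).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_two_group <- function(values_hi, values_lo) {
  if (length(values_hi) == 0 || length(values_lo) == 0) {
    stopf("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(values_hi, values_lo)) > 0
  use_exact <- length(values_hi) <= 10 && length(values_lo) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(values_hi, values_lo, exact = use_exact,
                       correct = TRUE))
  p <- res$p.value
  # zero rank variance (e.g. both groups constant): statistic at its null
  # center, no evidence either way
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

order_by_genome <- function(positions) {
  order(chrom_rank(normalize_chrom(positions$chrom)), positions$start,
        positions$gene)
}

#' Genome-ordered per-gene scan of a hi/lo partition
#'
#' Wilcoxon rank-sum p-value, group medians and the lo - hi median difference
#' for every gene of a copy-number, expression or protein table, ordered by
#' (chromosome 1..22,X,Y, start, gene id). Genes without a position are
#' scanned but flagged and sorted last.
#'
#' @param table gene x sample numeric matrix.
#' @param partition `partition` over (a subset of) the table's samples.
#' @param positions gene position data.frame (`gene`, `chrom`, `start`).
#' @return data.frame of class `gene_scan`: `gene`, `chrom`, `start`, `p`,
#'   `median_hi`, `median_lo`, `diff` (lo - hi), `positioned`.
#' @export
scan_partition <- function(table, partition, positions = NULL) {
  lab <- partition$labels
  common <- intersect(colnames(table), names(lab))
  if (length(common) == 0) stopf("partition and table share no samples")
  lab <- lab[common]
  hi <- table[, common[lab == "hi"], drop = FALSE]
  lo <- table[, common[lab == "lo"], drop = FALSE]
  if (ncol(hi) == 0 || ncol(lo) == 0) stopf("one partition side is empty")
  genes <- rownames(table)
  p <- vapply(seq_along(genes), function(i) {
    wilcoxon_two_group(hi[i, ], lo[i, ])
  }, 0)
  med_hi <- apply(hi, 1, stats::median)
  med_lo <- apply(lo, 1, stats::median)
  out <- data.frame(gene = genes, chrom = NA_character_, start = NA_real_,
                    p = p, median_hi = med_hi, median_lo = med_lo,
                    diff = med_lo - med_hi, positioned = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(positions)) {
    validate_positions(positions)
    idx <- match(out$gene, positions$gene)
    out$chrom <- normalize_chrom(positions$chrom)[idx]
    out$start <- positions$start[idx]
    out$positioned <- !is.na(idx)
  }
  pos <- out[out$positioned, , drop = FALSE]
  pos <- pos[order(chrom_rank(pos$chrom), pos$start, pos$gene), , drop = FALSE]
  out <- rbind(pos, out[!out$positioned, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("gene_scan", "data.frame")
  attr(out, "origin") <- partition$origin
  out
}

#' Maximal runs of contiguous significant genes
#'
#' The scan's formal notion of a Manhattan "peak": at least `min_run`
#' consecutive positioned genes (in genome order, within one chromosome) with
#' `p < alpha`.
#'
#' @param scan `gene_scan`.
#' @param alpha significance cut-off (default 1e-3).
#' @param min_run minimum run length (default 3).
#' @return data.frame: `chrom`, `start`, `end`, `n_genes`, `min_p`,
#'   `first_gene`, `last_gene`.
#' @export
peak_regions <- function(scan, alpha = 1e-3, min_run = 3) {
  s <- scan[scan$positioned, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_genes = integer(0),
                      min_p = numeric(0), first_gene = character(0),
                      last_gene = character(0), stringsAsFactors = FALSE)
  if (nrow(s) == 0) return(empty)
  sig <- s$p < alpha
  runs <- rle(paste(s$chrom, sig))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- grepl("TRUE$", runs$values) & runs$lengths >= min_run
  if (!any(keep)) return(empty)
  do.call(rbind, lapply(which(keep), function(i) {
    block <- s[starts[i]:ends[i], ]
    data.frame(chrom = block$chrom[1], start = min(block$start),
               end = max(block$start), n_genes = nrow(block),
               min_p = min(block$p), first_gene = block$gene[1],
               last_gene = block$gene[nrow(block)], stringsAsFactors = FALSE)
  }))
}

#' Contrast a module-partition scan with random-partition scans
#'
#' Runs [scan_partition()] for the module partition and for `n_random`
#' random equal-sized partitions of the same samples, tallies genes below
#' `alpha` in each scan, and calls peak regions for the module scan.
#'
#' @param table gene x sample numeric matrix.
#' @param module_partition `partition`.
#' @param positions gene position table.
#' @param n_random number of random control partitions (>= 1).
#' @param seed RNG seed for the random partitions.
#' @param alpha significance cut-off (default 1e-3).
#' @param min_run minimum peak run length (default 3).
#' @return list of class `scan_comparison`: `module_scan`, `random_scans`
#'   (list), `counts` (data.frame scan/count), `peaks`, `alpha`.
#' @export
compare_to_random <- function(table, module_partition, positions,
                              n_random = 1, seed = 1, alpha = 1e-3,
                              min_run = 3) {
  if (n_random < 1) stopf("n_random must be >= 1")
  mod_scan <- scan_partition(table, module_partition, positions)
  samples <- intersect(colnames(table), names(module_partition$labels))
  hi <- random_sample_partitions(samples, n_random, seed)
  rand_scans <- lapply(as_partition_list(hi), function(p) {
    scan_partition(table, p, positions)
  })
  counts <- data.frame(
    scan = c("module", sprintf("random%d", seq_len(n_random))),
    count = c(sum(mod_scan$p < alpha),
              vapply(rand_scans, function(s) sum(s$p < alpha), 0)),
    n_genes = nrow(mod_scan))
  structure(list(module_scan = mod_scan, random_scans = rand_scans,
                 counts = counts,
                 peaks = peak_regions(mod_scan, alpha, min_run),
                 alpha = alpha),
            class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat(sprintf("<scan_comparison> %d genes at p < %g: module %d vs random %s; %d peak region(s)\n",
              x$counts$n_genes[1], x$alpha, x$counts$count[1],
              paste(x$counts$count[-1], collapse = "/"), nrow(x$peaks)))
  invisible(x)
}

#' Targeted hi/lo comparison of selected features
#'
#' Per-feature group medians and Wilcoxon p for chosen genes or proteins
#' (e.g. immune checkpoint ligands, chemokine receptors, or an RPPA protein).
#' Missing features are reported, not fatal.
#'
#' @param table gene/protein x sample numeric matrix.
#' @param partition `partition`.
#' @param features character vector of row ids.
#' @return data.frame: `feature`, `median_hi`, `median_lo`, `diff` (lo - hi),
#'   `p`; attribute `missing` lists absent features.
#' @export
group_compare_features <- function(table, partition, features) {
  missing <- setdiff(features, rownames(table))
  features <- intersect(features, rownames(table))
  if (length(features) == 0) stopf("all requested features are missing")
  if (length(missing) > 0) {
    message(sprintf("features not in table: %s", paste(missing, collapse = ", ")))
  }
  sub <- scan_partition(table[features, , drop = FALSE], partition,
                        positions = NULL)
  out <- data.frame(feature = sub$gene, median_hi = sub$median_hi,
                    median_lo = sub$median_lo, diff = sub$diff, p = sub$p,
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  out
}

#' Manhattan plot of a genome-ordered scan
#'
#' @param scan `gene_scan` (optionally a second one as `overlay`, drawn in a
#'   contrasting color, e.g. a random-partition control).
#' @param overlay optional second `gene_scan`.
#' @param alpha dashed significance line (default 1e-3).
#' @param main title.
#' @export
plot_manhattan <- function(scan, overlay = NULL, alpha = 1e-3,
                           main = "copy-number scan") {
  s <- scan[scan$positioned, ]
  x <- seq_len(nrow(s))
  graphics::plot(x, -log10(s$p), pch = 16, cex = 0.5,
                 col = ifelse(chrom_rank(s$chrom) %% 2 == 0, "firebrick",
                              "firebrick3"),
                 xlab = "genes in genome order", ylab = "-log10 p",
                 main = main)
  if (!is.null(overlay)) {
    o <- overlay[overlay$positioned, ]
    graphics::points(seq_len(nrow(o)), -log10(o$p), pch = 16, cex = 0.4,
                     col = "cadetblue")
  }
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(NULL)
}
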