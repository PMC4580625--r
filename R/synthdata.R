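# Synthetic reference panels, tumor cohorts and copy-number tables with
# planted ground truth, emulating the statistical assumptions of the
# screening pipeline: marker-anchored coexpression blocks, an immune
# infiltrate that modulates both block-gene expression and survival under a
# proportional-hazards model, and a contiguous copy-number loss enriched in
# low-infiltrate samples.

#' Generate a reference panel of purified immune-cell expression profiles
#'
#' Each signature block shares a latent per-sample factor: member genes are
#' `mu + sqrt(rho) * z + sqrt(1 - rho) * noise_sd * eps`, giving a pairwise
#' within-block correlation of about `rho` at `noise_sd = 1` and tending to 1
#' as `noise_sd` tends to 0. One designated marker per block carries a higher
#' loading than the other members, so it is the natural anchor gene.
#' Background genes are independent noise. Values are shifted to a baseline
#' of 6 and clipped at 0 to respect the log2(RPM + 1) scale.
#'
#' @param n_blocks number of planted signature blocks (cell types).
#' @param genes_per_block genes per block, marker included (>= 100 so that a
#'   100-gene module can be filled from within one block).
#' @param n_background_genes independent noise genes.
#' @param n_samples panel size (>= 10).
#' @param within_block_corr target pairwise correlation within a block, in
#'   (0, 1).
#' @param noise_sd standard deviation multiplier of the member-specific noise.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param module_size intended downstream module size; a warning is raised
#'   when blocks are smaller than it.
#' @return list with `expr` (matrix), `markers` (character), `truth` (list
#'   recording block membership, markers, and the seed).
#' @export
generate_reference_panel <- function(n_blocks = 5, genes_per_block = 100,
                                     n_background_genes = 1000,
                                     n_samples = 336,
                                     within_block_corr = 0.6, noise_sd = 1,
                                     seed = 1, module_size = 100) {
  if (n_samples < 10) stopf("n_samples must be >= 10")
  if (within_block_corr <= 0 || within_block_corr >= 1) {
    stopf("within_block_corr must lie in (0, 1)")
  }
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (genes_per_block < module_size) {
    warnf("genes_per_block (%d) < module_size (%d): modules will exhaust their block and recruit background genes",
          genes_per_block, module_size)
  }
  with_seed(seed, {
    rho <- within_block_corr
    rho_marker <- (1 + rho) / 2   # marker gets the strongest loading
    mu <- 6                       # typical log2(RPM+1) baseline
    block_names <- sprintf("BLK%d", seq_len(n_blocks))
    gene_ids <- character(0)
    cell_type <- character(0)
    markers <- character(0)
    rows <- vector("list", n_blocks + 1L)
    for (b in seq_len(n_blocks)) {
      z <- stats::rnorm(n_samples)
      ids <- c(sprintf("MK%d", b),
               sprintf("B%dG%03d", b, seq_len(genes_per_block - 1L)))
      r <- c(rho_marker, rep(rho, genes_per_block - 1L))
      loading <- sqrt(r)
      noise <- sqrt(1 - r) * noise_sd
      e <- matrix(stats::rnorm(genes_per_block * n_samples),
                  nrow = genes_per_block)
      rows[[b]] <- mu + loading %o% z + noise * e
      gene_ids <- c(gene_ids, ids)
      cell_type <- c(cell_type, rep(block_names[b], genes_per_block))
      markers <- c(markers, ids[1])
    }
    if (n_background_genes > 0) {
      rows[[n_blocks + 1L]] <-
        mu + noise_sd * matrix(stats::rnorm(n_background_genes * n_samples),
                               nrow = n_background_genes)
      gene_ids <- c(gene_ids, sprintf("BGG%04d", seq_len(n_background_genes)))
      cell_type <- c(cell_type, rep("background", n_background_genes))
    }
    expr <- pmax(do.call(rbind, rows), 0)
    rownames(expr) <- gene_ids
    colnames(expr) <- sprintf("REF%03d", seq_len(n_samples))
    truth <- list(cell_type_of_gene = stats::setNames(cell_type, gene_ids),
                  marker_of_block = stats::setNames(markers, block_names),
                  within_block_corr = within_block_corr,
                  noise_sd = noise_sd, seed = seed)
    validate_matrix(expr)
    list(expr = expr, markers = markers, truth = truth)
  })
}

#' Generate a tumor cohort with an infiltrate-driven survival effect
#'
#' Each tumor sample draws an immune-infiltrate fraction `f ~ Uniform(0, 1)`.
#' Block genes gain `infiltrate_slope * f` on the log2 scale (keeping the
#' median module score monotone in `f`); background genes stay independent
#' noise. Death times are exponential under proportional hazards,
#' `h = baseline_hazard * exp(beta * 1[f > median(f)])`, censored by the
#' minimum of an independent exponential and an administrative cutoff
#' (the "date of last visit").
#'
#' @param n_samples cohort size.
#' @param reference_truth `truth` element from [generate_reference_panel()];
#'   fixes the gene universe and block structure.
#' @param beta log hazard ratio of the high- vs low-infiltrate half; negative
#'   means high infiltrate is protective (melanoma-like), positive deleterious
#'   (bladder-like), 0 is the null.
#' @param baseline_hazard events per day for the low-infiltrate group.
#' @param censor_rate rate of the independent censoring process (events/day);
#'   0 disables it.
#' @param admin_censor_days administrative follow-up cutoff in days.
#' @param infiltrate_slope log2 expression units gained by block genes as `f`
#'   goes from 0 to 1.
#' @param noise_sd residual expression noise.
#' @param seed RNG seed.
#' @return list with `expr`, `clinical`, `truth` (adds `infiltrate_fraction`,
#'   `hazard_log_ratio`, and the true hi/lo labels).
#' @export
generate_tumor_cohort <- function(n_samples = 300, reference_truth,
                                  beta = 0, baseline_hazard = 1 / 1000,
                                  censor_rate = 1 / 2000,
                                  admin_censor_days = 3650,
                                  infiltrate_slope = 2, noise_sd = 1,
                                  seed = 1) {
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (censor_rate < 0) stopf("censor_rate must be >= 0")
  if (admin_censor_days <= 0) stopf("admin_censor_days must be positive")
  cell_type <- reference_truth$cell_type_of_gene
  with_seed(seed, {
    genes <- names(cell_type)
    f <- stats::runif(n_samples)
    in_block <- cell_type != "background"
    mu <- 6
    expr <- mu + noise_sd * matrix(stats::rnorm(length(genes) * n_samples),
                                   nrow = length(genes))
    # infiltrate raises all immune block genes linearly on the log2 scale
    expr[in_block, ] <- expr[in_block, ] +
      matrix(infiltrate_slope * f, nrow = sum(in_block), ncol = n_samples,
             byrow = TRUE)
    expr <- pmax(expr, 0)
    rownames(expr) <- genes
    colnames(expr) <- sprintf("TUM%04d", seq_len(n_samples))
    hi <- f > stats::median(f)
    hazard <- baseline_hazard * exp(beta * as.numeric(hi))
    death <- stats::rexp(n_samples, rate = hazard)
    cens <- if (censor_rate > 0) stats::rexp(n_samples, rate = censor_rate) else Inf
    cens <- pmin(cens, admin_censor_days)
    clinical <- data.frame(sample = colnames(expr),
                           time = pmin(death, cens),
                           event = as.numeric(death <= cens),
                           stringsAsFactors = FALSE)
    truth <- reference_truth
    truth$infiltrate_fraction <- stats::setNames(f, colnames(expr))
    truth$hazard_log_ratio <- beta
    truth$true_hi <- stats::setNames(hi, colnames(expr))
    truth$cohort_seed <- seed
    validate_matrix(expr)
    validate_clinical(clinical)
    list(expr = expr, clinical = clinical, truth = truth)
  })
}

#' Generate gene-level copy-number profiles with a planted contiguous loss
#'
#' Background copy number is Normal(0, `noise_sd`) around the diploid-neutral
#' log2-ratio of 0. A contiguous run of `region_span` genes is shifted down by
#' `loss_depth` in carrier samples. Carriers are drawn preferentially from the
#' cohort's low-infiltrate half (probability `p_loss_lo` there, `p_loss_hi` in
#' the high half), emulating a deletion enriched in immune-poor tumors. Genes
#' are laid out in ascending position order along synthetic chromosomes.
#'
#' @param cohort_truth `truth` from [generate_tumor_cohort()] (supplies the
#'   sample ids and true hi/lo labels).
#' @param n_genes number of scanned genes.
#' @param region_span planted deletion width in genes (< `n_genes`).
#' @param loss_depth copy-number units subtracted in carriers.
#' @param positions_per_chrom genes per synthetic chromosome.
#' @param noise_sd background copy-number standard deviation.
#' @param p_loss_lo,p_loss_hi per-sample carrier probability in the
#'   low/high-infiltrate halves.
#' @param seed RNG seed.
#' @return list with `cnv` (matrix), `positions` (data.frame), `truth`
#'   (adds the planted region and carrier set).
#' @export
generate_cnv_profiles <- function(cohort_truth, n_genes = 400,
                                  region_span = 30, loss_depth = 1,
                                  positions_per_chrom = 100, noise_sd = 0.3,
                                  p_loss_lo = 0.8, p_loss_hi = 0.1,
                                  seed = 1) {
  if (region_span <= 0) stopf("region_span must be positive")
  if (region_span >= n_genes) stopf("region_span must be < n_genes")
  samples <- names(cohort_truth$true_hi)
  if (is.null(samples)) stopf("cohort_truth must come from generate_tumor_cohort()")
  with_seed(seed, {
    n_samples <- length(samples)
    genes <- sprintf("CNG%05d", seq_len(n_genes))
    cnv <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                  nrow = n_genes, dimnames = list(genes, samples))
    # plant the deletion away from the chromosome edges when possible
    start_idx <- if (n_genes > 2 * region_span) {
      sample.int(n_genes - 2 * region_span, 1) + floor(region_span / 2)
    } else {
      sample.int(n_genes - region_span + 1, 1)
    }
    region <- seq(start_idx, length.out = region_span)
    hi <- cohort_truth$true_hi
    p_carrier <- ifelse(hi, p_loss_hi, p_loss_lo)
    carriers <- stats::runif(n_samples) < p_carrier
    cnv[region, carriers] <- cnv[region, carriers] - loss_depth
    n_chrom <- ceiling(n_genes / positions_per_chrom)
    if (n_chrom > 24) stopf("layout needs more than 24 chromosomes")
    chrom <- chrom_levels()[ceiling(seq_len(n_genes) / positions_per_chrom)]
    offset <- (seq_len(n_genes) - 1) %% positions_per_chrom
    positions <- data.frame(gene = genes, chrom = chrom,
                            start = 1e6 + offset * 1e4,
                            stringsAsFactors = FALSE)
    truth <- cohort_truth
    truth$deleted_region <- list(genes = genes[region], index = region)
    truth$loss_carriers <- samples[carriers]
    truth$loss_depth <- loss_depth
    truth$cnv_seed <- seed
    validate_matrix(cnv, "copy-number table", min_value = -Inf)
    validate_positions(positions)
    list(cnv = cnv, positions = positions, truth = truth)
  })
}
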