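# End-to-end orchestration from a single configuration (YAML file or list):
# simulate or load inputs, build and annotate modules, run the survival
# screen with both permutation nulls, and scan copy-number tables, with
# deterministic seeding and provenance headers on every output.

default_config <- function() {
  list(seed = 1, outdir = "immunomod_out", module_size = 100,
       thresholds = c(1e-3, 5e-3), n_permutations = 1000,
       truncate = FALSE, truncate_days = 1825, overlap_threshold = 0.25,
       scan_alpha = 1e-3, n_random_scans = 1)
}

#' Load and validate a run configuration
#'
#' @param config path to a YAML file, or a list. Unset keys fall back to the
#'   defaults: `module_size` 100, `thresholds` 1e-3/5e-3, 1825-day
#'   truncation horizon, overlap threshold 0.25, 1000 permutations.
#' @return validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  cfg <- utils::modifyList(default_config(), config)
  has_sim <- !is.null(cfg$simulate)
  has_inputs <- !is.null(cfg$inputs)
  if (!has_sim && !has_inputs) {
    stopf("config needs either an 'inputs' block or a 'simulate' block")
  }
  if (has_inputs && !has_sim) {
    need <- c("reference", "markers", "expr", "clinical")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss) > 0) stopf("inputs block missing: %s",
                                paste(miss, collapse = ", "))
    absent <- Filter(function(p) !file.exists(cfg$inputs[[p]]), need)
    if (length(absent) > 0) {
      stopf("input file(s) not found: %s",
            paste(unlist(cfg$inputs[absent]), collapse = ", "))
    }
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

provenance_line <- function(cfg) {
  sprintf("#immunomod\tversion=%s\tseed=%s\tconfig_md5=%s",
          as.character(utils::packageVersion("immunomod")),
          cfg$seed, config_hash(cfg))
}

prepend_line <- function(path, line) {
  body <- readLines(path)
  con <- file(path, open = "wb")
  writeLines(c(line, body), con, sep = "\n", useBytes = TRUE)
  close(con)
}

#' Read a pipeline output TSV, skipping provenance header lines
#' @param path file path.
#' @return data.frame.
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

log_stage <- function(log_path, stage, detail) {
  cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              stage, detail), file = log_path, append = TRUE)
}

#' Simulate a full synthetic study and write it to disk
#'
#' Writes `expression_ref.tsv`, `markers.txt`, `expression.tsv`,
#' `clinical.tsv`, `cnv.tsv`, `positions.bed` and `truth.json` (the planted
#' ground truth) into `outdir`.
#'
#' @param config config list/path with a `simulate` block (generator
#'   parameters; all optional) plus `seed` and `outdir`.
#' @return list with the in-memory objects (`reference`, `cohort`, `cnv`).
#' @export
simulate_study <- function(config) {
  cfg <- load_config(config)
  sim <- cfg$simulate %||% list()
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference_panel(
    n_blocks = sim$n_blocks %||% 5,
    genes_per_block = sim$genes_per_block %||% 100,
    n_background_genes = sim$n_background_genes %||% 1000,
    n_samples = sim$n_samples_ref %||% 336,
    within_block_corr = sim$within_block_corr %||% 0.6,
    noise_sd = sim$noise_sd %||% 1,
    seed = sub_seed(cfg$seed, 1),
    module_size = cfg$module_size)
  cohort <- generate_tumor_cohort(
    n_samples = sim$n_samples_tumor %||% 300,
    reference_truth = ref$truth,
    beta = sim$beta %||% -1,
    baseline_hazard = sim$baseline_hazard %||% 1 / 1000,
    censor_rate = sim$censor_rate %||% 1 / 2000,
    admin_censor_days = sim$admin_censor_days %||% 3650,
    infiltrate_slope = sim$infiltrate_slope %||% 2,
    seed = sub_seed(cfg$seed, 2))
  cnv <- generate_cnv_profiles(
    cohort_truth = cohort$truth,
    n_genes = sim$n_cnv_genes %||% 400,
    region_span = sim$region_span %||% 30,
    loss_depth = sim$loss_depth %||% 1,
    positions_per_chrom = sim$positions_per_chrom %||% 100,
    noise_sd = sim$cnv_noise_sd %||% 0.3,
    seed = sub_seed(cfg$seed, 3))
  write_matrix(ref$expr, file.path(cfg$outdir, "expression_ref.tsv"))
  writeLines(ref$markers, file.path(cfg$outdir, "markers.txt"))
  write_matrix(cohort$expr, file.path(cfg$outdir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(cfg$outdir, "clinical.tsv"))
  write_cnv(cnv$cnv, file.path(cfg$outdir, "cnv.tsv"))
  write_positions(cnv$positions, file.path(cfg$outdir, "positions.bed"))
  truth <- cnv$truth
  truth$cell_type_of_gene <- as.list(truth$cell_type_of_gene)
  jsonlite::write_json(truth, file.path(cfg$outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(reference = ref, cohort = cohort, cnv = cnv)
}

pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- simulate_study(cfg)
    list(ref_expr = sim$reference$expr, markers = sim$reference$markers,
         expr = sim$cohort$expr, clinical = sim$cohort$clinical,
         cnv = sim$cnv$cnv, positions = sim$cnv$positions,
         truth = sim$cnv$truth)
  } else {
    inp <- cfg$inputs
    list(ref_expr = read_expression(inp$reference),
         markers = readLines(inp$markers),
         expr = read_expression(inp$expr),
         clinical = read_clinical(inp$clinical),
         cnv = if (!is.null(inp$cnv)) read_cnv(inp$cnv),
         positions = if (!is.null(inp$positions)) read_positions(inp$positions),
         truth = NULL)
  }
}

#' Run the full screening pipeline
#'
#' Stages, in order: input loading (or simulation), module construction,
#' random gene sets, overlap/clustering/annotation, survival screen of both
#' collections, random-partition null, and the per-cohort summary. Outputs
#' (`modules.gmt`, `overlap.tsv`, `clusters.tsv`, `annotations.tsv`,
#' `screen.tsv`, `screen_random.tsv`, `null_summary.tsv`,
#' `cohort_summary.tsv`, `run.log`) carry a provenance header with the
#' package version, seed and config hash; a failed stage aborts with its
#' name and leaves prior outputs in place.
#'
#' @param config YAML path or config list (see [load_config()]).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_screen_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  prov <- provenance_line(cfg)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }
  out <- function(...) file.path(cfg$outdir, ...)
  emit <- function(df, name) {
    write_tsv_lf(df, out(name)); prepend_line(out(name), prov)
  }

  inp <- stage("inputs", pipeline_inputs(cfg))
  log_stage(log_path, "inputs",
            sprintf("reference %d x %d, cohort %d x %d",
                    nrow(inp$ref_expr), ncol(inp$ref_expr),
                    nrow(inp$expr), ncol(inp$expr)))

  modules <- stage("build_modules",
                   build_all_modules(inp$ref_expr, inp$markers,
                                     cfg$module_size))
  write_modules_gmt(modules, out("modules.gmt"))
  log_stage(log_path, "build_modules", sprintf("%d modules", length(modules)))

  rand_sets <- stage("random_gene_sets",
                     random_gene_sets(rownames(inp$ref_expr),
                                      n_sets = length(modules),
                                      set_size = cfg$module_size,
                                      seed = sub_seed(cfg$seed, 4)))

  ov <- stage("overlap", overlap_matrix(modules))
  ov_df <- data.frame(module = rownames(ov), as.data.frame(ov),
                      check.names = FALSE)
  emit(ov_df, "overlap.tsv")
  cl <- stage("cluster", cluster_modules(ov))
  log_stage(log_path, "cluster", sprintf("%d clusters", cl$n_clusters))

  refs <- if (!is.null(cfg$refs)) {
    stats::setNames(lapply(cfg$refs, read_gmt), basename(unlist(cfg$refs)))
  } else if (!is.null(inp$truth)) {
    # annotate against the planted cell-type blocks
    ct <- inp$truth$cell_type_of_gene
    blocks <- split(names(ct), unlist(ct))
    blocks <- blocks[names(blocks) != "background"]
    list(planted_blocks = blocks)
  } else NULL
  ann <- NULL
  if (!is.null(refs)) {
    ann <- stage("annotate",
                 annotate_collection(modules, refs,
                                     universe = rownames(inp$ref_expr),
                                     clusters = cl))
    emit(ann$tests, "annotations.tsv")
  }
  cl_df <- data.frame(module = names(cl$cluster), cluster = cl$cluster,
                      stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    cl_df$summary_term <- ann$cluster_terms$summary_term[cl_df$cluster]
  }
  emit(cl_df, "clusters.tsv")

  scr <- stage("screen",
               screen(inp$expr, inp$clinical, modules, cohort = "cohort1",
                      truncate = isTRUE(cfg$truncate),
                      horizon_days = cfg$truncate_days))
  emit(as.data.frame(scr), "screen.tsv")
  scr_r <- stage("screen_random",
                 screen(inp$expr, inp$clinical, rand_sets,
                        cohort = "cohort1",
                        truncate = isTRUE(cfg$truncate),
                        horizon_days = cfg$truncate_days))
  emit(as.data.frame(scr_r), "screen_random.tsv")
  log_stage(log_path, "screen",
            sprintf("%d module + %d random tests", nrow(scr), nrow(scr_r)))

  null_p <- stage("null_partitions",
                  null_partition_pvalues(inp$clinical,
                                         n_perm = cfg$n_permutations,
                                         seed = sub_seed(cfg$seed, 5)))
  emit(null_counts(null_p, cfg$thresholds), "null_summary.tsv")

  summary_tab <- stage("cohort_summary",
                       cohort_summary_table(scr, scr_r,
                                            list(cohort1 = null_p), ov, cl,
                                            annotations = ann,
                                            thresholds = cfg$thresholds))
  emit(as.data.frame(summary_tab), "cohort_summary.tsv")
  log_stage(log_path, "done", "screen pipeline complete")

  # best module's partition, for the downstream scan
  tested <- scr[!scr$skipped, ]
  if (nrow(tested) > 0) {
    best <- tested$module[which.min(tested$p_value)]
    sc <- module_score(inp$expr, modules[[best]])
    part <- median_partition(sc, origin = paste0("module:", best))
    part_df <- data.frame(sample = names(part$labels), label = part$labels,
                          score = sc[names(part$labels)],
                          stringsAsFactors = FALSE)
    emit(part_df, "best_partition.tsv")
  }
  invisible(list(config = cfg, modules = modules, random_sets = rand_sets,
                 overlap = ov, clusters = cl, annotations = ann,
                 screen = scr, screen_random = scr_r, null_p = null_p,
                 summary = summary_tab, inputs = inp))
}

#' Run the genomic scan pipeline
#'
#' Requires a hi/lo partition: either `partition_file` (TSV: sample, label)
#' or the `best_partition.tsv` written by [run_screen_pipeline()] in the
#' same output directory. Writes `scan.tsv`, `scan_random.tsv` (first random
#' control) and `peaks.tsv`.
#'
#' @param config YAML path or config list; needs `inputs$cnv` and
#'   `inputs$positions` (or a simulate block).
#' @param partition_file optional explicit partition TSV.
#' @return invisibly, the `scan_comparison`.
#' @export
run_scan_pipeline <- function(config, partition_file = NULL) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_line(cfg)
  out <- function(...) file.path(cfg$outdir, ...)
  inp <- pipeline_inputs(cfg)
  if (is.null(inp$cnv) || is.null(inp$positions)) {
    stopf("scan pipeline needs cnv and positions inputs")
  }
  pf <- partition_file %||% out("best_partition.tsv")
  if (!file.exists(pf)) stopf("no partition available: %s", pf)
  pdf_ <- read_pipeline_tsv(pf)
  unknown <- setdiff(pdf_$sample, colnames(inp$cnv))
  if (length(unknown) > 0) {
    stopf("partition has samples absent from the table: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  }
  lab <- stats::setNames(pdf_$label, pdf_$sample)
  part <- structure(list(labels = lab, origin = basename(pf), score = NULL),
                    class = "partition")
  cmp <- compare_to_random(inp$cnv, part, inp$positions,
                           n_random = cfg$n_random_scans,
                           seed = sub_seed(cfg$seed, 6),
                           alpha = cfg$scan_alpha)
  emit <- function(df, name) {
    write_tsv_lf(df, out(name)); prepend_line(out(name), prov)
  }
  emit(as.data.frame(cmp$module_scan), "scan.tsv")
  emit(as.data.frame(cmp$random_scans[[1]]), "scan_random.tsv")
  emit(cmp$counts, "scan_counts.tsv")
  if (nrow(cmp$peaks) > 0) emit(cmp$peaks, "peaks.tsv")
  log_stage(file.path(cfg$outdir, "run.log"), "scan",
            sprintf("%d genes scanned, %d peaks", nrow(cmp$module_scan),
                    nrow(cmp$peaks)))
  invisible(cmp)
}
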