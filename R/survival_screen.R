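# Median-split survival screening: per-sample module scores, hi/lo
# partitions at the cohort median (lo takes ties), two-group log-rank
# tests, Kaplan-Meier curves, Harrell's concordance index, and the
# module x cohort screen.

#' Skip signal for untestable module/cohort pairs
#'
#' Returned instead of a result when a pair cannot be tested (low gene
#' coverage, degenerate partition, no events); never an exception, so the
#' screen records the reason and moves on.
#'
#' @param reason short machine-readable reason.
#' @return object of class `screen_skip`.
#' @export
screen_skip <- function(reason) structure(list(reason = reason),
                                          class = "screen_skip")

#' Per-sample module score
#'
#' The score of a sample is the median expression of the module's genes that
#' are present in the matrix. Pairs with under `min_coverage` of the module
#' present are skipped.
#'
#' @param expr gene x sample expression matrix.
#' @param module `gene_module` or character vector of gene ids.
#' @param min_coverage minimum fraction of module genes required (default
#'   0.5).
#' @return named numeric vector of scores with attribute `genes_used`, or a
#'   [screen_skip()] with reason `"coverage"`.
#' @export
module_score <- function(expr, module, min_coverage = 0.5) {
  genes <- module_members(module)
  present <- intersect(genes, rownames(expr))
  if (length(present) < min_coverage * length(genes)) {
    return(screen_skip("coverage"))
  }
  sub <- expr[present, , drop = FALSE]
  s <- apply(sub, 2, stats::median)
  attr(s, "genes_used") <- present
  s
}

#' Split a cohort at the median score
#'
#' Samples strictly above the cohort median are `hi`; samples at or below it
#' are `lo` (ties go to `lo`). With all scores identical the partition is
#' degenerate (`hi` empty) and a skip is returned.
#'
#' @param score named numeric vector of per-sample scores.
#' @param origin provenance label, e.g. `"module:FLT3LG.mod"` or
#'   `"random:17"`.
#' @return object of class `partition`: `labels` (named character, `"hi"` /
#'   `"lo"`), `origin`, `score`; or a [screen_skip()].
#' @export
median_partition <- function(score, origin = "module") {
  if (length(score) < 4) stopf("need at least 4 samples to partition")
  med <- stats::median(score)
  lab <- ifelse(score > med, "hi", "lo")
  names(lab) <- names(score)
  if (!any(lab == "hi")) return(screen_skip("degenerate"))
  structure(list(labels = lab, origin = origin, score = score),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %s: %d hi / %d lo\n", x$origin,
              sum(x$labels == "hi"), sum(x$labels == "lo")))
  invisible(x)
}

#' Kaplan-Meier survival curve for a sample subset
#'
#' Product-limit estimate via [survival::survfit()]. The curve starts at 1,
#' is non-increasing and right-continuous; censored times do not drop it.
#'
#' @param clinical clinical data.frame (`sample`, `time`, `event`).
#' @param group optional character vector of sample ids; default all.
#' @return data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(clinical, group = NULL) {
  validate_clinical(clinical)
  if (!is.null(group)) {
    clinical <- clinical[clinical$sample %in% group, , drop = FALSE]
  }
  if (nrow(clinical) == 0) stopf("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = clinical)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at given times from a KM curve
#' @param curve `km_curve` from [km_estimate()].
#' @param times numeric times.
#' @return survival probabilities (right-continuous step function, 1 before
#'   the first event).
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$surv[max(i)]
  }, 0)
}

#' Vectorized two-group log-rank tests over many partitions
#'
#' One pass over the event times evaluates the log-rank statistic for every
#' column of a membership matrix, so permutation nulls with thousands of
#' random partitions cost little more than a single test. At each distinct
#' event time the observed-minus-expected hi-group event count and its
#' hypergeometric variance are accumulated; `chisq = (sum O - E)^2 / sum V`,
#' p from a 1-df chi-square.
#'
#' @param time,event numeric vectors (days; 1 = death, 0 = censored).
#' @param hi logical/0-1 matrix, samples x partitions: TRUE = hi group.
#' @return data.frame with one row per partition: `chisq`, `p`, `oe` (sum of
#'   observed minus expected hi events; positive means excess hi deaths).
#' @export
logrank_many <- function(time, event, hi) {
  hi <- as.matrix(hi) * 1
  n <- length(time)
  stopifnot(nrow(hi) == n, length(event) == n)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  g_s <- hi[ord, , drop = FALSE]
  grp <- match(t_s, unique(t_s))          # distinct-time index per row
  m <- max(grp)
  # at-risk counts: reverse cumulative sums down the sorted rows
  at_risk <- apply(g_s[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  first <- !duplicated(grp)
  n_tot <- (n:1)[first]                    # total at risk at each distinct time
  n1 <- at_risk[first, , drop = FALSE]     # hi at risk (m x P)
  d <- as.vector(rowsum(e_s, grp))         # events per distinct time
  d1 <- rowsum(g_s * e_s, grp)             # hi events (m x P)
  keep <- d > 0
  n_tot <- n_tot[keep]; d <- d[keep]
  n1 <- n1[keep, , drop = FALSE]; d1 <- d1[keep, , drop = FALSE]
  frac <- sweep(n1, 1, n_tot, "/")
  oe <- colSums(d1 - sweep(frac, 1, d, "*"))
  vmul <- ifelse(n_tot > 1, d * (n_tot - d) / (n_tot - 1), 0)
  v <- colSums(sweep(frac * (1 - frac), 1, vmul, "*"))
  chisq <- ifelse(v > 0, oe^2 / v, NA_real_)
  data.frame(chisq = chisq,
             p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             oe = oe)
}

#' Two-group log-rank test of a hi/lo partition
#'
#' Standard 1-df log-rank comparing survival of the `hi` and `lo` strata.
#' `direction` is +1 when the hi group has fewer deaths than expected
#' (hi protective), -1 when more, 0 at exact balance.
#'
#' @param clinical clinical data.frame.
#' @param partition `partition` from [median_partition()] (or a
#'   [screen_skip()], which is passed through).
#' @return list of class `survival_test`: `chi_square`, `p_value`, `n_hi`,
#'   `n_lo`, `direction`; or a `screen_skip` (no events / one-sided
#'   partition).
#' @export
logrank_test <- function(clinical, partition) {
  if (inherits(partition, "screen_skip")) return(partition)
  validate_clinical(clinical)
  lab <- partition$labels[match(clinical$sample, names(partition$labels))]
  if (any(is.na(lab))) stopf("partition does not cover all cohort samples")
  if (!any(lab == "hi") || !any(lab == "lo")) return(screen_skip("degenerate"))
  if (sum(clinical$event) == 0) return(screen_skip("no_events"))
  res <- logrank_many(clinical$time, clinical$event,
                      matrix(lab == "hi", ncol = 1))
  if (!is.finite(res$chisq)) return(screen_skip("zero_variance"))
  structure(list(chi_square = res$chisq, p_value = res$p,
                 n_hi = sum(lab == "hi"), n_lo = sum(lab == "lo"),
                 direction = -sign(res$oe)),
            class = "survival_test")
}

#' @export
print.survival_test <- function(x, ...) {
  cat(sprintf("<survival_test> chisq = %.3f (1 df), p = %.3g, n = %d hi / %d lo, hi %s\n",
              x$chi_square, x$p_value, x$n_hi, x$n_lo,
              if (x$direction > 0) "protective" else if (x$direction < 0)
                "deleterious" else "neutral"))
  invisible(x)
}

#' Harrell's concordance index of a risk score
#'
#' Fraction of comparable sample pairs (the smaller observed time carries an
#' event) whose score ordering agrees with their survival ordering, higher
#' score treated as higher risk; score ties count 0.5. Both the raw value and
#' the orientation-free `max(C, 1 - C)` are returned, since a marker can be
#' protective or deleterious.
#'
#' @param score named numeric per-sample score.
#' @param clinical clinical data.frame.
#' @return list of class `concordance_index`: `raw`, `oriented`,
#'   `flipped` (TRUE when `oriented != raw`), `n_pairs`; or a `screen_skip`
#'   when no pair is comparable.
#' @export
concordance_index <- function(score, clinical) {
  validate_clinical(clinical)
  s <- score[match(clinical$sample, names(score))]
  if (any(is.na(s))) stopf("score does not cover all cohort samples")
  time <- clinical$time; event <- clinical$event
  n <- length(s)
  # pair (i, j) comparable when time_i < time_j and subject i died;
  # tied observed times are never comparable
  cmp <- outer(time, time, "<") & (event == 1)
  n_pairs <- sum(cmp)
  if (n_pairs == 0) return(screen_skip("no_comparable_pairs"))
  agree <- sum(cmp & outer(s, s, ">")) + 0.5 * sum(cmp & outer(s, s, "=="))
  raw <- agree / n_pairs
  structure(list(raw = raw, oriented = max(raw, 1 - raw),
                 flipped = raw < 0.5, n_pairs = n_pairs),
            class = "concordance_index")
}

#' Administratively truncate follow-up
#'
#' Times beyond the horizon are set to the horizon and censored, restricting
#' every cohort to a common, fairly short follow-up window.
#'
#' @param clinical clinical data.frame.
#' @param horizon_days truncation horizon (default 1825 days, i.e. 5 years).
#' @return truncated clinical data.frame.
#' @export
truncate_followup <- function(clinical, horizon_days = 1825) {
  validate_clinical(clinical)
  if (horizon_days <= 0) stopf("horizon must be positive")
  over <- clinical$time > horizon_days
  clinical$event[over] <- 0
  clinical$time[over] <- horizon_days
  clinical
}

#' Screen a module collection against one cohort
#'
#' For every module: score the samples, split at the median, log-rank test,
#' and concordance of the continuous score. Untestable pairs are kept with
#' their skip reason.
#'
#' @param expr cohort expression matrix.
#' @param clinical cohort clinical table; samples are intersected with the
#'   matrix (>= 4 required).
#' @param collection `module_collection`.
#' @param cohort cohort label stored in the result.
#' @param truncate truncate follow-up before testing?
#' @param horizon_days truncation horizon (default 1825).
#' @param min_coverage module coverage threshold (default 0.5).
#' @return data.frame of class `screen_matrix`, one row per module:
#'   `cohort`, `module`, `n_hi`, `n_lo`, `chi_square`, `p_value`,
#'   `direction`, `concordance`, `concordance_oriented`, `skipped`,
#'   `reason`.
#' @export
screen <- function(expr, clinical, collection, cohort = "cohort",
                   truncate = FALSE, horizon_days = 1825,
                   min_coverage = 0.5) {
  al <- intersect_samples(expr, clinical)
  expr <- al$expr; clinical <- al$clinical
  if (nrow(clinical) < 4) stopf("cohort has fewer than 4 usable samples")
  if (truncate) clinical <- truncate_followup(clinical, horizon_days)
  rows <- lapply(names(collection), function(mn) {
    out <- data.frame(cohort = cohort, module = mn, n_hi = NA_integer_,
                      n_lo = NA_integer_, chi_square = NA_real_,
                      p_value = NA_real_, direction = NA_real_,
                      concordance = NA_real_, concordance_oriented = NA_real_,
                      skipped = FALSE, reason = "", stringsAsFactors = FALSE)
    s <- module_score(expr, collection[[mn]], min_coverage)
    if (inherits(s, "screen_skip")) {
      out$skipped <- TRUE; out$reason <- s$reason; return(out)
    }
    part <- median_partition(s, origin = paste0("module:", mn))
    lr <- logrank_test(clinical, part)
    if (inherits(lr, "screen_skip")) {
      out$skipped <- TRUE; out$reason <- lr$reason; return(out)
    }
    out$n_hi <- lr$n_hi; out$n_lo <- lr$n_lo
    out$chi_square <- lr$chi_square; out$p_value <- lr$p_value
    out$direction <- lr$direction
    ci <- concordance_index(s, clinical)
    if (!inherits(ci, "screen_skip")) {
      out$concordance <- ci$raw
      out$concordance_oriented <- ci$oriented
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("screen_matrix", "data.frame")
  attr(res, "thresholds") <- c(1e-3, 5e-3)
  res
}

#' Screen a module collection against several cohorts
#'
#' @param cohorts named list; each element a list with `expr` and `clinical`.
#' @param collection `module_collection`.
#' @param ... passed to [screen()].
#' @return stacked `screen_matrix` over all cohorts.
#' @export
screen_cohorts <- function(cohorts, collection, ...) {
  if (is.null(names(cohorts))) names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  res <- do.call(rbind, lapply(names(cohorts), function(cn) {
    screen(cohorts[[cn]]$expr, cohorts[[cn]]$clinical, collection,
           cohort = cn, ...)
  }))
  class(res) <- c("screen_matrix", "data.frame")
  attr(res, "thresholds") <- c(1e-3, 5e-3)
  res
}

#' @export
summary.screen_matrix <- function(object, thresholds = c(1e-3, 5e-3), ...) {
  tested <- object[!object$skipped, , drop = FALSE]
  out <- do.call(rbind, lapply(split(tested, tested$cohort), function(d) {
    data.frame(cohort = d$cohort[1], n_tested = nrow(d),
               n_skipped = sum(object$cohort == d$cohort[1]) - nrow(d),
               sig_1e3 = sum(d$p_value < thresholds[1]),
               sig_5e3 = sum(d$p_value < thresholds[2]),
               mean_concordance_sig =
                 if (any(d$p_value < thresholds[1]))
                   mean(d$concordance_oriented[d$p_value < thresholds[1]],
                        na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d module x cohort tests (%d skipped)\n",
              nrow(x), sum(x$skipped)))
  print(summary(x))
  invisible(x)
}

#' -log10(p) module x cohort matrix for heatmaps
#'
#' @param x `screen_matrix`.
#' @return numeric matrix, modules x cohorts, `-log10(p)`; skipped pairs NA.
#' @export
neglog10_matrix <- function(x) {
  mods <- unique(x$module); cohorts <- unique(x$cohort)
  m <- matrix(NA_real_, length(mods), length(cohorts),
              dimnames = list(mods, cohorts))
  ok <- !x$skipped
  m[cbind(match(x$module[ok], mods), match(x$cohort[ok], cohorts))] <-
    -log10(x$p_value[ok])
  m
}

#' Kaplan-Meier plot of a hi/lo partition
#'
#' @param clinical clinical data.frame.
#' @param partition `partition`.
#' @param main plot title.
#' @param col two colors (lo, hi).
#' @return invisibly, the underlying `survfit` object.
#' @export
plot_km <- function(clinical, partition, main = partition$origin,
                    col = c("steelblue", "firebrick")) {
  validate_clinical(clinical)
  grp <- factor(partition$labels[match(clinical$sample,
                                       names(partition$labels))],
                levels = c("lo", "hi"))
  fit <- survival::survfit(survival::Surv(clinical$time, clinical$event) ~ grp)
  graphics::plot(fit, col = col, xlab = "days", ylab = "survival",
                 main = main, mark.time = TRUE)
  graphics::legend("bottomleft", legend = c("lo", "hi"), col = col, lty = 1,
                   bty = "n")
  invisible(fit)
}
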