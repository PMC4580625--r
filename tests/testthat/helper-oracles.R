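# Independent brute-force oracles used to cross-check the package's
# statistics on small instances, plus tiny fixture builders.

# Log-rank by direct O-E / hypergeometric-variance accumulation over the
# distinct event times (1 df, two groups).
oracle_logrank <- function(time, event, hi) {
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & hi)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & hi)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- oe^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE), oe = oe)
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i]); d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Harrell's C by pair enumeration: comparable when the smaller observed time
# carries an event; higher score = higher risk; score ties 0.5.
oracle_cindex <- function(score, time, event) {
  num <- 0; den <- 0; n <- length(score)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    sm <- if (time[i] < time[j]) i else j
    lg <- if (time[i] < time[j]) j else i
    if (event[sm] == 0) next
    den <- den + 1
    if (score[sm] > score[lg]) num <- num + 1
    else if (score[sm] == score[lg]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Upper-tail hypergeometric by exhaustive enumeration of all equally likely
# draws of |module| genes from the universe.
oracle_hypergeom <- function(module, set, universe) {
  module <- intersect(unique(module), universe)
  set <- intersect(unique(set), universe)
  k_obs <- length(intersect(module, set))
  draws <- combn(length(universe), length(module))
  in_set <- universe %in% set
  hits <- apply(draws, 2, function(ix) sum(in_set[ix]))
  mean(hits >= k_obs)
}

# BH step-up from the formula, with monotonization.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n); out[o] <- pmin(adj, 1)
  out
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled ranks to the first group (no ties allowed).
oracle_wilcoxon <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ws <- combn(n, nx, FUN = sum)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}

# Tiny deterministic expression matrix fixture.
toy_expr <- function(genes = 5, samples = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(genes * samples, 6, 2)), 3), genes,
              dimnames = list(sprintf("G%d", seq_len(genes)),
                              sprintf("S%d", seq_len(samples))))
  m
}

toy_clinical <- function(samples, time, event) {
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

make_partition <- function(samples, hi) {
  lab <- ifelse(samples %in% hi, "hi", "lo")
  names(lab) <- samples
  structure(list(labels = lab, origin = "test", score = NULL),
            class = "partition")
}
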