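# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so generators are pure functions of (parameters, seed) and never
#' perturb the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for the i-th sub-stream of a generator call.
# Kept below 2^31 so it is always a valid R integer seed.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647L)
}

# Canonical chromosome order 1..22, X, Y; "chr" prefixes are stripped on input.
chrom_levels <- function() c(as.character(1:22), "X", "Y")

normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  bad <- setdiff(unique(x), chrom_levels())
  if (length(bad) > 0) {
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

chrom_rank <- function(x) match(x, chrom_levels())

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
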