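# Internal helpers: seeded evaluation, deterministic child seeds, small
# numerical utilities shared across modules.

# Evaluate expr under a local RNG state. seed = NULL leaves the global
# stream untouched (caller-managed randomness).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed plus arbitrary labels, via a
# polynomial rolling hash mod (2^31 - 1). Keeps derived seeds valid 32-bit
# integers and lets any design cell be re-simulated in isolation.
childSeed <- function(seed, ...) {
  p <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% p
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(part), "|"))) {
      h <- (h * 131 + ch) %% p
    }
  }
  as.integer(h %% (p - 1) + 1)
}

# Row-wise minima of a matrix without matrixStats.
rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# All unordered sample pairs of a label vector, as a two-column data.frame
# in canonical (i < j) order.
samplePairs <- function(labels) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 samples to form pairs")
  idx <- utils::combn(n, 2L)
  data.frame(sampleA = labels[idx[1L, ]], sampleB = labels[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# Labelled symmetric matrix -> dist with a metric tag (vegan convention).
asDist <- function(m, metric) {
  if (!isSymmetric(unname(m), tol = 1e-12))
    stop("matrix must be symmetric")
  d <- stats::as.dist(m)
  attr(d, "method") <- metric
  attr(d, "call") <- NULL
  d
}

# dist -> full labelled matrix.
distMatrix <- function(d) as.matrix(d)

checkMode <- function(x, allowed, what) {
  if (!tableMode(x) %in% allowed)
    stop(sprintf("%s requires a table in mode %s (got '%s')", what,
                 paste(sprintf("'%s'", allowed), collapse = " or "),
                 tableMode(x)))
  invisible(TRUE)
}
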