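# Internal helpers: seed derivation, local RNG scoping, orthogonalization.

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based splitting: each (master, index...) combination maps to a
#' fixed integer in `[1, 2^31 - 2]` by integer hashing, so adding subjects,
#' stages or permutations never perturbs the streams of existing ones.
#' All arithmetic stays below 2^53, hence exact in doubles.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (subject number, stage
#'   code, permutation number, ...).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gram-Schmidt orthonormalization of the columns of V (p x k). If p < k only
# the first p columns can be mutually orthogonal; the remainder are
# normalized after projecting out nothing further (documented behaviour for
# very small voxel counts).
gram_schmidt <- function(V) {
  p <- nrow(V); k <- ncol(V)
  for (j in seq_len(k)) {
    v <- V[, j]
    if (j > 1 && j <= p) {
      prev <- V[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate signature vector during orthogonalization")
    V[, j] <- v / nv
  }
  V
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)
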