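#' @include AllClasses.R
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed below 2^31 from a master seed and index.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

# All permutations of 1..n in lexicographic row order (n <= 7 intended).
lexPermutations <- function(n) {
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- lexPermutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
  dimnames(out) <- NULL
  out
}
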