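## internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. A NULL seed runs `expr` under the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# All permutations of 1..n as an n!-row matrix (n <= 8 kept cheap).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(i, rows), sub + (sub >= i))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Normalize rows of a non-negative matrix to sum to one; all-zero rows become
# uniform (they carry no evidence and must stay on the simplex).
row_normalize <- function(M) {
  s <- rowSums(M)
  zero <- s <= 0
  if (any(zero)) {
    M[zero, ] <- 1
    s[zero] <- ncol(M)
  }
  M / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
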