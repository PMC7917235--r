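# Internal unit system: nm (length), kg/mol (molar mass), ps (time),
# kJ/mol (energy). Dynamics converts masses to g/mol so that
# kJ/mol, nm, ps, g/mol form a consistent unit set (1 kJ/mol/(g/mol nm)
# accelerates at exactly 1 nm/ps^2).

.kB <- 0.008314462618      # kJ/mol/K
.kB_SI <- 1.380649e-23     # J/K
.NN_TO_KJMOLNM <- 602.214076  # kJ/mol/nm per nN (1 nN * 1 nm * N_A)

# Run expr with a private, seeded RNG stream; restores global state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Squared Euclidean cross-distances between rows of X (n x 3) and C (m x 3),
# chunked so the n x m matrix never exceeds ~2e7 entries at once when a
# function f(chunkMatrix, rowOffset) consumes it; otherwise returns the full
# matrix.
.crossDist2 <- function(X, C) {
  rx <- rowSums(X^2)
  rc <- rowSums(C^2)
  d2 <- outer(rx, rc, "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# Nearest-center assignment and objective for weighted points, chunked.
# Ties go to the lowest center index (max.col on negated distances with
# ties.method = "first").
.assignNearest <- function(X, w, C, chunk = 2e7) {
  n <- nrow(X); m <- nrow(C)
  rows <- max(1L, floor(chunk / m))
  assign <- integer(n)
  dist2 <- numeric(n)
  rc <- rowSums(C^2)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + rows - 1L)
    Xi <- X[start:end, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), rc, "+") - 2 * tcrossprod(Xi, C)
    a <- max.col(-d2, ties.method = "first")
    assign[start:end] <- a
    dist2[start:end] <- d2[cbind(seq_len(end - start + 1L), a)]
    start <- end + 1L
  }
  dist2[dist2 < 0] <- 0
  list(assign = assign, objective = sum(w * dist2), dist2 = dist2)
}

# x clipped into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
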