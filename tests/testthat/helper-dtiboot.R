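# Shared fixtures: built once per test run.

ovp48 <- buildOverplusScheme(700, 3)     # the simulated protocol: 3 x (1 + 15)
ovp16 <- buildOverplusScheme(700, 1)
uni15 <- buildUniformScheme(15, 700, 3)

randomRotation_ <- dtiboot:::randomRotation

# A rotation whose first column (principal eigenvector) is the given unit
# vector.
rotationWithAxis <- function(g) {
  g <- g / sqrt(sum(g^2))
  a <- if (abs(g[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * g) * g
  u <- u / sqrt(sum(u^2))
  v <- c(g[2L] * u[3L] - g[3L] * u[2L],
         g[3L] * u[1L] - g[1L] * u[3L],
         g[1L] * u[2L] - g[2L] * u[1L])
  cbind(g, u, v, deparse.level = 0)
}

# Exact two-sided Fisher p for a 2 x k table by full enumeration over
# tables with the observed margins (independent oracle for fisherExact).
enumFisherP <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  k <- ncol(tab)
  logProb <- function(row1) {
    sum(lchoose(cs, row1)) - lchoose(sum(cs), rs[1L])
  }
  grid <- expand.grid(lapply(cs, function(m) 0:m))
  keep <- rowSums(grid) == rs[1L]
  grid <- grid[keep, , drop = FALSE]
  lp <- apply(grid, 1L, logProb)
  pObs <- logProb(tab[1L, ])
  sum(exp(lp[lp <= pObs + 1e-7]))
}
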