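# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use (and advance) the caller's RNG stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Uniformly distributed rotation matrix (QR of a Gaussian matrix with sign fix).
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

# Eigenvalues (descending) of the symmetric tensor packed as
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensorEigen <- function(d6) {
  m <- matrix(c(d6[1L], d6[4L], d6[5L],
                d6[4L], d6[2L], d6[6L],
                d6[5L], d6[6L], d6[3L]), 3L, 3L)
  sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

# Truncated-normal draws on [lo, hi) by rejection; fine for the ranges used here.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out >= hi)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] >= hi]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal target is infeasible: mean ",
                             mean, ", sd ", sd, " on [", lo, ", ", hi, ")")
  }
  out
}
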