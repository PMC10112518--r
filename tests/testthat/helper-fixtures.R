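# shared fixtures, built in code at test time

small_panel <- function(n1 = 20, n2 = 20, m = 60, seed = 11, ...) {
  simulate_population_pair(n1 = n1, n2 = n2, m = m, seed = seed, ...)
}

# panel with known per-site frequencies and HWE genotypes (no divergence)
hwe_panel <- function(n = 200, p = c(0.1, 0.3, 0.5, 0.7), seed = 5) {
  set.seed(seed)
  m <- length(p)
  dos <- sapply(p, function(pp) rbinom(n, 2L, pp))
  geno_matrix(dos, pop = rep(c("A", "B"), length.out = n),
              ancestral_is_ref = rep(TRUE, m), freqs = p)
}

# brute-force entry-by-entry GRM oracles (double loop over clones and sites)
oracle_additive <- function(dos, p, w = rep(1, length(p))) {
  n <- nrow(dos)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_along(p))
      s <- s + w[l] * (dos[i, l] - 2 * p[l]) * (dos[j, l] - 2 * p[l])
    G[i, j] <- s
  }
  G / sum(2 * p * (1 - p) * w)
}

oracle_dominance <- function(dos, p, w = rep(1, length(p))) {
  n <- nrow(dos)
  code <- function(x, pp) {
    q <- 1 - pp
    if (x == 0L) -2 * pp^2 else if (x == 1L) 2 * pp * q else -2 * q^2
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_along(p))
      s <- s + w[l] * code(dos[i, l], p[l]) * code(dos[j, l], p[l])
    G[i, j] <- s
  }
  G / sum((2 * p * (1 - p) * w)^2)
}

# Henderson mixed-model-equation solver at fixed variance components:
# independent oracle for BLUE/BLUP recovery, including unobserved levels
mme_solve <- function(y, X, Zs, Ks, sig2s, sig2e) {
  Z <- do.call(cbind, Zs)
  Ginv_blocks <- mapply(function(K, s2) solve(K) / s2, Ks, sig2s,
                        SIMPLIFY = FALSE)
  Ginv <- matrix(0, ncol(Z), ncol(Z))
  off <- 0L
  for (b in Ginv_blocks) {
    ix <- off + seq_len(nrow(b))
    Ginv[ix, ix] <- b
    off <- off + nrow(b)
  }
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + sig2e * Ginv))
  rhs <- rbind(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)[, 1]
  p <- ncol(X)
  list(beta = sol[seq_len(p)], u = sol[-seq_len(p)])
}
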