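# Independent brute-force oracles used across the suite.  These stay
# deliberately naive and separate from the package implementations.

# numerator relationship matrix by the tabular method
tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        aij <- 0
        if (s > 0) aij <- aij + 0.5 * A[j, s]
        if (d > 0) aij <- aij + 0.5 * A[j, d]
        A[i, j] <- A[j, i] <- aij
      }
    }
  }
  A
}

# random topologically-ordered pedigree with n_f founders
random_pedigree <- function(n, n_f = 10, seed = 1) {
  set.seed(seed)
  sex <- rep_len(c("M", "F"), n)
  sire <- dam <- integer(n)
  for (i in (n_f + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    sire[i] <- sample(males, 1L)
    dam[i] <- sample(females, 1L)
  }
  data.frame(animal = as.character(seq_len(n)),
             sire = as.character(sire), dam = as.character(dam),
             sex = sex, stringsAsFactors = FALSE)
}

# Benjamini-Hochberg step-up by direct enumeration
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# HWE chi-square from explicitly formed expected counts
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(nAA, nAB, nBB) - e)^2 / e)
  pchisq(stat, 1, lower.tail = FALSE)
}

# generalized least squares for y = Xb + sum Z_i u_i + e with
# var ratios lambda_i = sigma2_e / sigma2_ui (unit residual variance scale)
gls_oracle <- function(y, X, Zs, Gs, ratios) {
  V <- diag(length(y))
  for (i in seq_along(Zs))
    V <- V + Zs[[i]] %*% Gs[[i]] %*% t(Zs[[i]]) / ratios[i]
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- lapply(seq_along(Zs), function(i)
    as.numeric(Gs[[i]] %*% t(Zs[[i]]) %*% Vi %*% r / ratios[i]))
  list(b = as.numeric(b), u = u)
}

# classical MDS by direct double-centred eigendecomposition
mds_oracle <- function(D, k = 2) {
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  ev <- eigen(B, symmetric = TRUE)
  ev$vectors[, seq_len(k)] %*% diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
}

# align columns of A to B up to sign, return max abs difference
sign_aligned_maxdiff <- function(A, B) {
  for (j in seq_len(ncol(A)))
    if (sum(abs(A[, j] - B[, j])) > sum(abs(A[, j] + B[, j])))
      B[, j] <- -B[, j]
  max(abs(A - B))
}

# small deterministic simulated dataset reused by several files
small_sim <- function(seed = 11, n_snps = 300, n_per_line = 30,
                      n_generations = 4, ...) {
  cfg <- sim_config(n_founders = 2 * n_per_line,
                    n_per_line_per_gen = n_per_line,
                    n_generations = n_generations, n_snps = n_snps,
                    seed = seed, ...)
  f <- simulate_founders(cfg)
  s <- simulate_lines(cfg, f)
  s$config <- cfg
  s
}
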