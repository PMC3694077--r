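test_that("window assignment follows floor division and drops unmapped SNPs", {
  map <- data.frame(snp_id = paste0("s", 1:5),
                    chrom = c("1", "1", "1", "2", "U"),
                    pos_bp = c(999999L, 1000001L, 12L, 500L, 100L),
                    stringsAsFactors = FALSE)
  w <- make_windows(map)
  expect_false(w$assignment[1] == w$assignment[2])  # 1 Mb boundary
  expect_equal(w$assignment[1], w$assignment[3])
  expect_true(is.na(w$assignment[5]))
  expect_equal(nrow(w$windows), 3L)

  # one chromosome entirely inside 1 Mb -> a single window
  m1 <- data.frame(snp_id = paste0("x", 1:10), chrom = "3",
                   pos_bp = as.integer(seq(1, 9e5, length.out = 10)))
  expect_equal(nrow(make_windows(m1)$windows), 1L)

  # random map matches an independent floor-division oracle
  set.seed(61)
  m2 <- data.frame(snp_id = sprintf("r%03d", 1:300),
                   chrom = as.character(sample(1:5, 300, replace = TRUE)),
                   pos_bp = sample.int(8e6, 300))
  m2 <- m2[order(as.integer(m2$chrom), m2$pos_bp), ]
  w2 <- make_windows(m2)
  key <- paste(m2$chrom, (m2$pos_bp - 1) %/% 1e6)
  expect_equal(as.integer(factor(w2$assignment)),
               as.integer(factor(key, levels = unique(key))))
})

test_that("expected window share is 100/n and reports to 2 decimals", {
  expect_equal(round(expected_window_share(2815), 2), 0.04)
  expect_equal(expected_window_share(1), 100)
  expect_equal(expected_window_share(200), 0.5)
  expect_equal(5 * round(expected_window_share(2815), 2), 0.2)
})

test_that("as pi -> 1 no marker enters and fixed effects reduce to OLS", {
  set.seed(71)
  n <- 120; k <- 100
  Z <- encode_centered(matrix(rbinom(n * k, 2, 0.3), n, k))
  X <- cbind(1, rbinom(n, 1, 0.5))
  y <- as.numeric(X %*% c(3, 1) + rnorm(n))
  cfg <- bayesb_config(pi = 1 - 1e-12, n_iter = 2000, burn_in = 500,
                       thin = 5, seed = 2)
  fit <- fit_bayesb(y, X, Z, cfg)
  expect_true(all(fit$var_g == 0))
  expect_true(all(fit$n_included == 0L))
  b_post <- rowMeans(fit$b)
  b_ols <- qr.solve(X, y)
  expect_lt(max(abs(b_post - b_ols)), 0.1)
})

test_that("single-marker posterior mean matches the conjugate closed form", {
  set.seed(72)
  n <- 150
  z <- encode_centered(matrix(rbinom(n, 2, 0.4), n, 1))
  a_true <- 0.05
  y <- as.numeric(z * a_true + rnorm(n, 0, 1))
  y <- y - mean(y)
  # pin the variances with enormous prior df and force inclusion (pi -> 0)
  cfg <- bayesb_config(pi = 1e-9, n_iter = 11000, burn_in = 1000, thin = 1,
                       nu_effect = 1e8, nu_resid = 1e8, expected_h2 = 0.3,
                       seed = 5)
  fit <- fit_bayesb(y, matrix(0, n, 1), z, cfg)
  S_a <- unname(fit$prior_scales["effect"])
  S_e <- unname(fit$prior_scales["residual"])
  ztz <- sum(z^2)
  closed <- sum(z * y) / (ztz + S_e / S_a)
  draws <- vapply(seq_along(fit$sigma2_e), function(s)
    if (length(fit$effect_val[[s]])) fit$effect_val[[s]][1] else 0, 0)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_gt(mean(fit$n_included), 0.99)
  expect_lt(abs(mean(draws) - closed), 4 * mc_se + 1e-8)
})

test_that("residual bookkeeping audit stays at numerical noise", {
  set.seed(73)
  n <- 100; k <- 200
  Z <- encode_centered(matrix(rbinom(n * k, 2, 0.3), n, k))
  y <- as.numeric(Z[, 1] * 0.03 + rnorm(n))
  fit <- fit_bayesb(y, matrix(1, n, 1), Z,
                    bayesb_config(pi = 0.95, n_iter = 4000, burn_in = 500,
                                  thin = 5, seed = 3))
  expect_lt(fit$audit_max, 1e-8)
  expect_equal(length(fit$sigma2_e), (4000 - 500) %/% 5)
})

test_that("null inclusion counts follow the prior mixture", {
  set.seed(74)
  n <- 150; k <- 400
  Z <- encode_centered(matrix(rbinom(n * k, 2, 0.3), n, k))
  y <- rnorm(n)
  pi0 <- 0.99
  fit <- fit_bayesb(y, matrix(1, n, 1), Z,
                    bayesb_config(pi = pi0, n_iter = 3000, burn_in = 500,
                                  thin = 5, expected_h2 = 0.3, seed = 4))
  expected <- k * (1 - pi0)
  band <- 4 * sqrt(k * pi0 * (1 - pi0))
  expect_gt(mean(fit$n_included), expected - band)
  expect_lt(mean(fit$n_included), expected + band)
})

test_that("constant SNP columns are tolerated and zero-variance phenotypes are not", {
  set.seed(75)
  n <- 60
  Z <- cbind(0, encode_centered(matrix(rbinom(n * 20, 2, 0.3), n, 20)))
  y <- rnorm(n)
  fit <- fit_bayesb(y, matrix(1, n, 1), Z,
                    bayesb_config(pi = 0.9, n_iter = 500, burn_in = 100,
                                  thin = 2, seed = 6))
  expect_equal(fit$post_inclusion[1], 0)
  expect_error(fit_bayesb(rep(1, n), matrix(1, n, 1), Z, bayesb_config()),
               "variance")
})

test_that("window summaries recover a planted QTL and respect invariances", {
  set.seed(76)
  n <- 400; k <- 600
  maf <- runif(k, 0.1, 0.5)
  G <- sapply(maf, function(p) rbinom(n, 2, p))
  colnames(G) <- sprintf("q%03d", 1:k)
  map <- data.frame(snp_id = colnames(G),
                    chrom = as.character(rep(1:6, each = 100)),
                    pos_bp = as.integer(rep(seq(1e4, 4.9e6, length.out = 100), 6)),
                    stringsAsFactors = FALSE)
  Z <- encode_centered(G)
  qtl <- 250                                  # chromosome 3 window
  g_true <- Z[, qtl] * 0.08
  y <- as.numeric(g_true + rnorm(n, 0, sd(g_true)))  # ~50% of variance genetic
  fit <- fit_bayesb(y, matrix(1, n, 1), Z,
                    bayesb_config(pi = 0.99, n_iter = 6000, burn_in = 1000,
                                  thin = 5, expected_h2 = 0.5, seed = 7))
  w <- make_windows(map)
  ws <- summarize_windows(fit, w, Z)
  top <- ws[which.max(ws$pct_genetic_variance), ]
  expect_equal(top$window, w$windows$window[w$assignment[qtl]])
  expect_gt(top$ppa, 0.9)
  expect_true(top$candidate)
  # windows never visited by an included SNP report exactly zero
  expect_true(all(ws$ppa[ws$pct_genetic_variance == 0] == 0))

  # candidate calls invariant to SNP order within windows
  perm <- seq_len(k)
  w1 <- which(w$assignment == w$assignment[qtl])
  perm[w1] <- rev(w1)
  ws2 <- summarize_windows(fit, list(assignment = w$assignment[perm],
                                     windows = w$windows), Z[, perm])
  expect_equal(sort(ws2$window[ws2$candidate]), sort(ws$window[ws$candidate]))
})

test_that("chains from different seeds agree and h2 follows the samples", {
  set.seed(77)
  n <- 300; k <- 300
  G <- matrix(rbinom(n * k, 2, 0.3), n, k)
  Z <- encode_centered(G)
  qtl <- sample(k, 5)
  g <- as.numeric(Z[, qtl] %*% rnorm(5, 0, 0.04))
  y <- g + rnorm(n, 0, sd(g))
  mk <- function(seed) fit_bayesb(y, matrix(1, n, 1), Z,
    bayesb_config(pi = 0.98, n_iter = 5000, burn_in = 1000, thin = 4,
                  expected_h2 = 0.5, seed = seed))
  f1 <- mk(1); f2 <- mk(2)
  # identical seed reproduces the chain exactly
  expect_identical(mk(1)$var_g, f1$var_g)
  # Gelman-Rubin on total genetic variance across the two seeds
  m <- cbind(f1$var_g, f2$var_g)
  W <- mean(apply(m, 2, var))
  B <- nrow(m) * var(colMeans(m))
  rhat <- sqrt(((nrow(m) - 1) / nrow(m) * W + B / nrow(m)) / W)
  expect_lt(rhat, 1.1)
  h <- genomic_heritability(f1)
  expect_equal(h$mean, mean(f1$var_g / (f1$var_g + f1$sigma2_e)))
  expect_true(h$lower <= h$mean && h$mean <= h$upper)
  # with the data duplicated the likelihood dominates the prior: the
  # posterior interval straddles the realized marker-captured h2
  f3 <- fit_bayesb(c(y, y), matrix(1, 2 * n, 1), rbind(Z, Z),
                   bayesb_config(pi = 0.98, n_iter = 5000, burn_in = 1000,
                                 thin = 4, expected_h2 = 0.5, seed = 3))
  h3 <- genomic_heritability(f3)
  realized <- var(g) / var(y)
  expect_gte(realized, h3$lower)
  expect_lte(realized, h3$upper)
})
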