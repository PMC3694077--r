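test_that("ADG is the OLS slope of weight on day", {
  expect_equal(compute_adg(c(0, 14), c(40, 54)), 1.0)
  d <- seq(0, 98, 14)
  expect_equal(compute_adg(d, 37 + 0.9 * d), 0.9)
  set.seed(2)
  w <- 40 + 0.85 * d + rnorm(length(d))
  expect_equal(compute_adg(d, w), unname(coef(lm(w ~ d))[2]),
               tolerance = 1e-10)
  # invariant to record order
  o <- sample(seq_along(d))
  expect_equal(compute_adg(d[o], w[o]), compute_adg(d, w))
  expect_error(compute_adg(c(3, 3), c(1, 2)), "distinct")
})

test_that("ADFI is the mean of the quadratic fit over the test days", {
  d <- 0:90
  expect_equal(compute_adfi(d, rep(2.5, 91)), 2.5)
  y <- 1.5 + 0.02 * d - 1e-4 * d^2
  expect_equal(compute_adfi(d, y), mean(1.5 + 0.02 * (0:90) - 1e-4 * (0:90)^2),
               tolerance = 1e-10)
  # 30% of days missing at random: estimate stays close to complete-data value
  set.seed(6)
  yn <- y + rnorm(91, 0, 0.2)
  full <- compute_adfi(d, yn)
  keep <- sort(sample(91, 64))
  expect_lt(abs(compute_adfi(d[keep], yn[keep]) - full), 0.15)
  o <- sample(91)
  expect_equal(compute_adfi(d[o], yn[o]), full)
  expect_error(compute_adfi(c(1, 2), c(1, 2)), "distinct")
})

test_that("A-inverse follows Henderson's rules with inbreeding", {
  # two unrelated founders
  ped2 <- data.frame(animal = c("a", "b"), sire = "0", dam = "0")
  expect_equal(as.matrix(build_a_inverse(ped2)), diag(2),
               ignore_attr = TRUE)
  # sire-dam-offspring trio: textbook values
  trio <- data.frame(animal = c("s", "d", "o"), sire = c("0", "0", "s"),
                     dam = c("0", "0", "d"))
  Ai <- as.matrix(build_a_inverse(trio))
  expect_equal(Ai, matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  # full-sib mating: offspring of full sibs has F = 0.25
  ped_f <- data.frame(animal = c("s", "d", "x", "y", "z"),
                      sire = c("0", "0", "s", "s", "x"),
                      dam = c("0", "0", "d", "d", "y"))
  expect_equal(inbreeding_ml(ped_f), c(0, 0, 0, 0, 0.25))
  # cycle and ordering errors
  expect_error(build_a_inverse(data.frame(animal = "a", sire = "a", dam = "0")),
               "cycle")
  expect_error(build_a_inverse(data.frame(animal = c("a", "b"),
                                          sire = c("b", "0"),
                                          dam = c("0", "0"))),
               "topologically")
})

test_that("A-inverse inverts the tabular A on random 50-animal pedigrees", {
  for (seed in c(1, 2)) {
    ped <- random_pedigree(50, n_f = 8, seed = seed)
    A <- tabular_A(as.integer(ped$sire), as.integer(ped$dam))
    Ai <- as.matrix(build_a_inverse(ped))
    expect_lt(max(abs(A %*% Ai - diag(50))), 1e-8)
  }
})

test_that("MME solutions equal dense GLS and behave in limits", {
  set.seed(31)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  fac <- sample(1:6, n, replace = TRUE)
  Z <- matrix(0, n, 6); Z[cbind(1:n, fac)] <- 1
  u <- rnorm(6, 0, 1)
  y <- X %*% c(2, 0.5, -1) + Z %*% u + rnorm(n, 0, 0.7)
  ratio <- 0.49
  fit <- solve_mme(as.numeric(y), X, list(grp = list(Z = Z, ratio = ratio)))
  orc <- gls_oracle(as.numeric(y), X, list(Z), list(diag(6)), ratio)
  expect_lt(max(abs(fit$b - orc$b)), 1e-8)
  expect_lt(max(abs(fit$u$grp - orc$u[[1]])), 1e-8)

  # ratio -> Inf: random predictions vanish, fixed solutions are OLS
  fit_inf <- solve_mme(as.numeric(y), X, list(grp = list(Z = Z, ratio = 1e12)))
  ols <- qr.solve(X, y)
  expect_lt(max(abs(fit_inf$b - ols)), 1e-4)
  expect_lt(max(abs(fit_inf$u$grp)), 1e-4)

  # duplicated observation splits its residual symmetrically
  X2 <- rbind(X, X[1, ]); Z2 <- rbind(Z, Z[1, ]); y2 <- c(y, y[1])
  f2 <- solve_mme(as.numeric(y2), X2, list(grp = list(Z = Z2, ratio = ratio)))
  expect_equal(f2$residuals[1], f2$residuals[n + 1], tolerance = 1e-10)

  expect_error(solve_mme(as.numeric(y), X[1:10, ],
                         list(g = list(Z = Z, ratio = 1))))
})

test_that("MME with a pedigree effect matches GLS through the A matrix", {
  ped <- random_pedigree(30, n_f = 6, seed = 9)
  A <- tabular_A(as.integer(ped$sire), as.integer(ped$dam))
  Ainv <- build_a_inverse(ped)
  set.seed(10)
  n <- 30
  X <- cbind(1, rnorm(n))
  Z <- diag(n)
  y <- X %*% c(1, 0.3) + t(chol(A + diag(1e-10, n))) %*% rnorm(n) + rnorm(n)
  fit <- solve_mme(as.numeric(y), X,
                   list(animal = list(Z = Z, Ginv = Ainv, ratio = 1)))
  orc <- gls_oracle(as.numeric(y), X, list(Z), list(A), 1)
  expect_lt(max(abs(fit$b - orc$b)), 1e-8)
  expect_lt(max(abs(fit$u$animal - orc$u[[1]])), 1e-8)
})

test_that("RFI strips fixed and covariate effects but keeps genetic deviation", {
  cfg <- sim_config(n_founders = 80, n_per_line_per_gen = 40,
                    n_generations = 4, n_snps = 150, seed = 17)
  s <- simulate_lines(cfg, simulate_founders(cfg))
  r <- simulate_records(cfg, s)
  ph <- derive_phenotypes(r$weights, r$intakes, r$offtest, s$pedigree)
  ph <- compute_rfi(ph, s$pedigree)         # OLS: no random effects
  expect_false(anyNA(ph$RFI))
  cell <- paste(ph$generation, ph$line)
  # cell means are zero with cell intercepts in the model
  expect_lt(max(abs(tapply(ph$RFI, cell, mean))), 1e-8)
  # within each cell RFI is uncorrelated with every centred covariate
  for (cl in unique(cell)) {
    sel <- cell == cl
    for (v in list(ph$onwt - 40, ph$age_on_test - 90, ph$offwt - 115,
                   ph$metamidwt, ph$adga, ph$offbfa)) {
      if (sd(v[sel]) == 0) next
      expect_lt(abs(cor(ph$RFI[sel], v[sel])), 1e-6)
    }
  }
  # RFI still tracks the genetic + residual deviation it is meant to keep
  expect_gt(cor(ph$RFI, r$truth_records$true_rfi), 0.5)
})

test_that("fitted covariate slopes equal the OLS oracle when ratios are zero", {
  cfg <- sim_config(n_founders = 60, n_per_line_per_gen = 30,
                    n_generations = 3, n_snps = 100, seed = 27)
  s <- simulate_lines(cfg, simulate_founders(cfg))
  r <- simulate_records(cfg, s)
  ph <- derive_phenotypes(r$weights, r$intakes, r$offtest, s$pedigree)
  ph2 <- compute_rfi(ph, s$pedigree)
  fit <- attr(ph2, "fit")
  X <- attr(ph2, "design")$X
  ok <- complete.cases(ph[, c("ADFI", "onwt", "offwt", "metamidwt",
                              "adga", "offbfa")])
  b_ols <- qr.coef(qr(X), ph$ADFI[ok])
  b_ols[is.na(b_ols)] <- 0
  keep <- fit$b != 0 & b_ols != 0
  expect_lt(max(abs(fit$b[keep] - b_ols[keep])), 1e-8)
})

test_that("selection reduces LOW-line RFI relative to HIGH at the last generation", {
  cfg <- sim_config(n_founders = 100, n_per_line_per_gen = 50,
                    n_generations = 7, n_snps = 200, h2_target = 0.45,
                    selection_fraction = 0.15,
                    high_line_selection_start_gen = 3, seed = 41)
  s <- simulate_lines(cfg, simulate_founders(cfg))
  r <- simulate_records(cfg, s)
  ph <- derive_phenotypes(r$weights, r$intakes, r$offtest, s$pedigree)
  ph <- compute_rfi(ph, s$pedigree, cell_intercepts = FALSE)
  last <- ph$generation == max(ph$generation)
  expect_lt(mean(ph$RFI[last & ph$line == "LOW"]),
            mean(ph$RFI[last & ph$line == "HIGH"]))
})

test_that("an underpopulated generation-by-line cell is a named error", {
  cfg <- sim_config(n_founders = 60, n_per_line_per_gen = 30,
                    n_generations = 3, n_snps = 100, seed = 29)
  s <- simulate_lines(cfg, simulate_founders(cfg))
  r <- simulate_records(cfg, s)
  ph <- derive_phenotypes(r$weights, r$intakes, r$offtest, s$pedigree)
  ph_small <- ph[c(which(ph$generation < 2), which(ph$generation == 2)[1:3]), ]
  expect_error(compute_rfi(ph_small, s$pedigree), "g2_")
})
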