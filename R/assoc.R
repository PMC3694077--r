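# Single-SNP association on adjusted phenotypes with genomic control,
# plus the stratification diagnostics (IBS similarity, classical MDS,
# Q-Q points).

# median of a 1-df chi-square
CHI2_MEDIAN_1DF <- 0.4549364

#' Adjust a phenotype for the fixed-effect association model
#'
#' OLS residuals of y on sex, pen-by-group and an age-at-on-test
#' covariate with a separate slope for every line-by-parity combination.
#' Line-by-parity cells with fewer than 2 animals are merged into the
#' nearest parity within the line (with a warning) so their slope is
#' estimable.
#'
#' @param y phenotype vector.
#' @param sex,pen_by_group factors (or coercible).
#' @param age_on_test numeric covariate (days).
#' @param line,parity define the slope cells.
#' @return residual vector (mean zero); attribute `fit` holds the lm.
#' @export
adjust_phenotype <- function(y, sex, pen_by_group, age_on_test, line, parity) {
  stopifnot(!anyNA(sex), !anyNA(pen_by_group), !anyNA(age_on_test),
            !anyNA(line), !anyNA(parity))
  parity <- as.integer(as.character(parity))
  cell <- paste(line, parity, sep = "_")
  repeat {
    small <- names(which(table(cell) < 2L))
    if (!length(small)) break
    cl <- small[1L]
    ln <- sub("_[^_]*$", "", cl)
    pr <- as.integer(sub("^.*_", "", cl))
    cand <- sort(unique(parity[line == ln & cell != cl]))
    if (!length(cand))
      stop(sprintf("cannot merge singleton cell %s: no other parity in line", cl))
    nearest <- cand[which.min(abs(cand - pr))]
    warning(sprintf("line-by-parity cell %s has < 2 animals; merged into parity %d",
                    cl, nearest))
    sel <- cell == cl
    parity[sel] <- nearest
    cell[sel] <- paste(ln, nearest, sep = "_")
  }
  d <- data.frame(y = y, sex = factor(sex), pg = factor(pen_by_group),
                  age = age_on_test, cell = factor(cell))
  fit <- if (nlevels(d$cell) > 1L)
    lm(y ~ sex + pg + cell:age, data = d)
  else lm(y ~ sex + pg + age, data = d)
  res <- unname(residuals(fit))
  attr(res, "fit") <- fit
  res
}

#' Single-SNP quantitative association
#'
#' Per SNP, simple regression of the adjusted phenotype on the allele_b
#' dosage over the non-missing individuals: slope, t statistic with
#' n - 2 df, two-sided P, and the 1-df chi-square equivalent of the P
#' value.  Monomorphic SNPs get P = 1 and chi-square 0.
#'
#' @param y_adj adjusted phenotype (finite).
#' @param genotypes allele_b dosage matrix.
#' @return data.frame with snp_id, n, beta, t, p_raw, chi2.
#' @export
single_snp_assoc <- function(y_adj, genotypes) {
  stopifnot(all(is.finite(y_adj)), nrow(genotypes) == length(y_adj))
  G <- genotypes
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  n_j <- colSums(M)
  sum_x <- colSums(G0)
  sum_x2 <- colSums(G0^2)
  sum_y <- as.numeric(crossprod(M, y_adj))
  sum_y2 <- as.numeric(crossprod(M, y_adj^2))
  sum_xy <- as.numeric(crossprod(G0, y_adj))
  sxx <- sum_x2 - sum_x^2 / n_j
  syy <- sum_y2 - sum_y^2 / n_j
  sxy <- sum_xy - sum_x * sum_y / n_j

  beta <- t_stat <- p <- rep(NA_real_, ncol(G))
  poly <- sxx > 0 & n_j > 2
  beta[poly] <- sxy[poly] / sxx[poly]
  sse <- pmax(syy[poly] - sxy[poly]^2 / sxx[poly], 0)
  se <- sqrt(sse / ((n_j[poly] - 2) * sxx[poly]))
  tv <- beta[poly] / se
  tv[se == 0] <- sign(beta[poly][se == 0]) * Inf
  t_stat[poly] <- tv
  p[poly] <- 2 * stats::pt(-abs(tv), df = n_j[poly] - 2)
  p[!poly] <- 1
  chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  chi2[p >= 1] <- 0
  data.frame(snp_id = colnames(G) %||% as.character(seq_len(ncol(G))),
             n = n_j, beta = beta, t = t_stat, p_raw = p, chi2 = chi2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic control of association chi-square statistics
#'
#' lambda = median(chi2) / 0.4549364 (the 1-df chi-square median).  When
#' lambda > 1 all statistics are divided by it; otherwise they are left
#' unchanged (no anti-conservative inflation).  Corrected P values come
#' from the 1-df upper tail.
#'
#' @param chi2 vector of 1-df chi-square statistics (>= 10 SNPs).
#' @return list with `lambda`, `chi2_gc`, `p_gc`.
#' @export
genomic_control <- function(chi2) {
  if (length(chi2) < 10L) stop("genomic control needs >= 10 SNPs")
  lambda <- median(chi2, na.rm = TRUE) / CHI2_MEDIAN_1DF
  chi2_gc <- if (lambda > 1) chi2 / lambda else chi2
  list(lambda = lambda, chi2_gc = chi2_gc,
       p_gc = pchisq(chi2_gc, df = 1, lower.tail = FALSE))
}

#' Adjusted-phenotype association with GC and FDR
#'
#' Convenience wrapper: [adjust_phenotype()], [single_snp_assoc()],
#' [genomic_control()] and [bh_fdr()], with the two significance
#' conventions reported as flags (`sig_gc`: GC-corrected P < 0.01;
#' `sig_fdr`: q < 0.05).
#'
#' @param y phenotype vector.
#' @param genotypes dosage matrix.
#' @param design data.frame with sex, group, pen, age_on_test, line,
#'   parity aligned to rows.
#' @param map optional map for chrom/pos columns.
#' @param gc_alpha,fdr_alpha significance thresholds (defaults 0.01 and
#'   0.05).
#' @return data.frame per SNP with beta, t, p_raw, chi2, p_gc, q and the
#'   flags; attribute `lambda`.
#' @export
run_assoc <- function(y, genotypes, design, map = NULL,
                      gc_alpha = 0.01, fdr_alpha = 0.05) {
  ok <- is.finite(y)
  y_adj <- adjust_phenotype(y[ok], design$sex[ok],
                            paste(design$group[ok], design$pen[ok]),
                            design$age_on_test[ok], design$line[ok],
                            design$parity[ok])
  res <- single_snp_assoc(y_adj, genotypes[ok, , drop = FALSE])
  gc <- genomic_control(res$chi2)
  res$p_gc <- gc$p_gc
  res$q <- bh_fdr(res$p_gc)
  res$sig_gc <- res$p_gc < gc_alpha
  res$sig_fdr <- res$q < fdr_alpha
  if (!is.null(map)) {
    res$chrom <- map$chrom[match(res$snp_id, map$snp_id)]
    res$pos_bp <- map$pos_bp[match(res$snp_id, map$snp_id)]
  }
  attr(res, "lambda") <- gc$lambda
  res
}

#' Identity-by-state similarity and classical MDS
#'
#' IBS(i, j) is the average over co-typed SNPs of the shared-allele
#' fraction (1, 0.5 or 0 for dosage differences 0, 1, 2).  Classical
#' metric scaling of the dissimilarity D = 1 - IBS (double-centred
#' squared distances, eigendecomposition, top-k coordinates scaled by
#' root eigenvalues) gives the stratification coordinates.
#'
#' @param genotypes dosage matrix, n >= 3 rows.
#' @param k number of coordinates (default 2).
#' @return list with `ibs` (n x n) and `coordinates` (n x k, centred).
#' @export
ibs_mds <- function(genotypes, k = 2) {
  n <- nrow(genotypes)
  if (n < 3L) stop("ibs_mds needs at least 3 individuals")
  M <- !is.na(genotypes)
  if (any(rowSums(M) == 0L)) stop("an individual has no called genotypes")
  I0 <- (genotypes == 0L) & M; I1 <- (genotypes == 1L) & M
  I2 <- (genotypes == 2L) & M
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  storage.mode(M) <- "double"
  S <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2) +
    0.5 * (tcrossprod(I0, I1) + tcrossprod(I1, I0) +
             tcrossprod(I1, I2) + tcrossprod(I2, I1))
  denom <- tcrossprod(M)
  if (any(denom == 0)) stop("a pair of individuals shares no called SNPs")
  ibs <- S / denom
  dimnames(ibs) <- list(rownames(genotypes), rownames(genotypes))
  D <- 1 - ibs
  coords <- cmdscale(stats::as.dist(D), k = k)
  list(ibs = ibs, coordinates = coords)
}

#' Q-Q plot coordinates for association P values
#'
#' @param p P values in (0, 1\].
#' @return data.frame with `expected` = -log10((i - 0.5)/m) and
#'   `observed` = -log10 of the sorted P values, both ascending.
#' @export
qq_points <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p)))
}
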