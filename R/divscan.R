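# Drift-controlled between-line allele-frequency divergence scan.
#
# Signed frequency differences (HIGH - LOW) of the fixed allele_b are
# standardized within founder-MAF bins, so that the null variance of the
# difference -- which grows as drift acts harder on rare alleles -- is
# matched within each bin.

#' Founder minor-allele-frequency bin index
#'
#' Five bins partitioning \[0, 0.5\]: \[0, 0.1), \[0.1, 0.2), \[0.2, 0.3),
#' \[0.3, 0.4), \[0.4, 0.5\].
#'
#' @param founder_maf minor-allele frequencies at generation zero.
#' @return integer bin index 0-4.
#' @export
bin_by_founder_maf <- function(founder_maf) {
  if (any(founder_maf < 0 | founder_maf > 0.5 + 1e-12, na.rm = TRUE))
    stop("founder_maf must be a minor-allele frequency in [0, 0.5]")
  b <- pmin(floor(founder_maf / 0.1), 4)
  as.integer(b)
}

#' Negative base-10 log of a P value
#'
#' @param p P values in (0, 1\].
#' @param digits optional rounding for report formatting (the scan tables
#'   print 2 decimals).
#' @export
neg_log10 <- function(p, digits = NULL) {
  if (any(p <= 0)) stop("p must be > 0")
  out <- -log10(p)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Benjamini-Hochberg FDR-adjusted P values
#'
#' Step-up adjustment (via [stats::p.adjust()]): after sorting ascending,
#' q(i) = min over j >= i of m p(j)/j, capped at 1, order restored.
#'
#' @param p P values in \[0, 1\].
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Between-line allele-frequency divergence scan
#'
#' Computes the allele_b frequency per line at the focal generation, the
#' signed difference (HIGH - LOW), bins SNPs by founder minor-allele
#' frequency, and standardizes differences within bins (population mean
#' and SD) into Z scores with two-sided normal P values and BH q values.
#' SNPs in bins with fewer than 2 scoreable SNPs or zero bin SD, or with
#' an undefined line frequency, are flagged (`scored = FALSE`) and carry
#' NA statistics; BH m = number of scored SNPs.
#'
#' @param genotypes allele_b dosage matrix (all generations).
#' @param pedigree design table with animal, generation, line.
#' @param map optional marker map for chrom/pos columns.
#' @param focal_generation generation compared between lines (default 8).
#' @param founder_generation generation defining the MAF bins (default 0).
#' @param lines the two line labels, difference = second minus first.
#' @return data.frame with per-SNP freq_low, freq_high, diff, founder_maf,
#'   bin_index, bin_mean, bin_sd, z, p, neg_log10_p, q, scored.
#' @export
divergence_scan <- function(genotypes, pedigree, map = NULL,
                            focal_generation = 8, founder_generation = 0,
                            lines = c("LOW", "HIGH")) {
  idx <- match(pedigree$animal, rownames(genotypes))
  if (anyNA(idx)) stop("pedigree animals missing from genotype matrix")
  in_low <- pedigree$generation == focal_generation & pedigree$line == lines[1L]
  in_high <- pedigree$generation == focal_generation & pedigree$line == lines[2L]
  if (!any(in_low) || !any(in_high))
    stop("both lines must be present at the focal generation")
  f_low <- allele_frequency(genotypes, idx[in_low])
  f_high <- allele_frequency(genotypes, idx[in_high])
  in_f <- pedigree$generation == founder_generation
  f0 <- allele_frequency(genotypes, idx[in_f])
  founder_maf <- pmin(f0, 1 - f0)

  k <- ncol(genotypes)
  diff <- f_high - f_low
  bin <- rep(NA_integer_, k)
  okm <- !is.na(founder_maf)
  bin[okm] <- bin_by_founder_maf(founder_maf[okm])
  scored <- !is.na(diff) & !is.na(bin)

  bin_mean <- bin_sd <- z <- rep(NA_real_, k)
  for (b in 0:4) {
    sel <- scored & bin == b
    nb <- sum(sel)
    if (nb < 2L) { scored[which(bin == b)] <- FALSE; next }
    m <- mean(diff[sel])
    s <- sqrt(mean((diff[sel] - m)^2))     # population SD
    if (s == 0) { scored[sel] <- FALSE; next }
    bin_mean[sel] <- m; bin_sd[sel] <- s
    z[sel] <- (diff[sel] - m) / s
  }
  p <- q <- rep(NA_real_, k)
  p[scored] <- 2 * pnorm(-abs(z[scored]))
  q[scored] <- bh_fdr(p[scored])
  nl <- rep(NA_real_, k)
  pos <- scored & p > 0
  nl[pos] <- -log10(p[pos])

  out <- data.frame(snp_id = colnames(genotypes) %||% as.character(seq_len(k)),
                    freq_low = f_low, freq_high = f_high, diff = diff,
                    founder_maf = founder_maf, bin_index = bin,
                    bin_mean = bin_mean, bin_sd = bin_sd, z = z, p = p,
                    neg_log10_p = nl, q = q, scored = scored,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    out$chrom <- map$chrom[match(out$snp_id, map$snp_id)]
    out$pos_bp <- map$pos_bp[match(out$snp_id, map$snp_id)]
  }
  rownames(out) <- NULL
  out
}
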