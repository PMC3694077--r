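# Genotype, map and quality-control input/output.
#
# Genotypes are held as a plain integer matrix (individuals x SNPs) of
# allele_b dosages {0, 1, 2} with NA for missing, rownames = sample ids,
# colnames = SNP ids.  The marker map is a data.frame aligned to the
# columns.  allele_b is fixed at load time as the dataset minor allele so
# every downstream frequency refers to one consistent allele per SNP.

CHROM_ORDER <- c(as.character(1:18), "X", "Y", "U")

.chrom_rank <- function(chrom) {
  r <- match(as.character(chrom), CHROM_ORDER)
  r[is.na(r)] <- length(CHROM_ORDER) + 1L
  r
}

#' Sort a marker map by chromosome and physical position
#'
#' Chromosomes order as 1-18, X, Y, then U (unassigned); positions are
#' 1-based base pairs.
#'
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`.
#' @return the map sorted by (chrom, pos_bp), plus an `order` attribute
#'   giving the permutation applied.
#' @keywords internal
sort_marker_map <- function(map) {
  ord <- order(.chrom_rank(map$chrom), map$pos_bp)
  out <- map[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "order") <- ord
  out
}

#' Read PLINK text PED/MAP genotypes
#'
#' Parses whitespace-delimited PLINK PED/MAP files.  Genotype codes count
#' copies of `allele_b`, which is forced to the minor allele in the loaded
#' data (ties broken so that `allele_b` is the lexicographically larger
#' allele).  Missing genotypes are the PLINK `0 0` convention and become
#' `NA`.  The map (and genotype columns) are sorted by (chrom, pos_bp).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (chrom, snp_id, cM, pos_bp).
#' @return list with `genotypes` (integer matrix, n x k), `map`
#'   (data.frame: snp_id, chrom, pos_bp, allele_a, allele_b) and
#'   `sample_ids` (character).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map_raw) < 4L)
    stop("MAP file must have 4 columns (chrom, snp_id, cM, pos_bp)")
  k <- nrow(map_raw)
  map <- data.frame(snp_id = map_raw[[2L]], chrom = map_raw[[1L]],
                    pos_bp = as.integer(map_raw[[4L]]),
                    allele_a = NA_character_, allele_b = NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP ids in MAP file")
  if (any(map$pos_bp < 1L, na.rm = TRUE))
    stop("MAP positions must be >= 1 (1-based base pairs)")

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * k
  bad <- which(vapply(fields, length, 1L) != want)
  if (length(bad))
    stop(sprintf(
      "PED line %d has %d fields; expected %d for %d MAP SNPs",
      bad[1L], length(fields[[bad[1L]]]), want, k))
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  sample_ids <- ped[, 2L]
  al <- ped[, -(1:6), drop = FALSE]

  a1 <- al[, seq(1L, 2L * k, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * k, by = 2L), drop = FALSE]
  codes <- matrix(NA_integer_, n, k)
  allele_a <- character(k)
  allele_b <- character(k)
  for (j in seq_len(k)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop(sprintf("SNP %s has >2 alleles", map$snp_id[j]))
    if (length(alleles) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      # monomorphic: the single observed allele is allele_a, dosage 0
      allele_a[j] <- alleles[1L]; allele_b[j] <- "0"
      cj <- rep(0L, n); cj[miss] <- NA_integer_
      codes[, j] <- cj
      next
    }
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    # minor allele is allele_b; on a tie keep the lexicographically larger
    if (cnt[1L] < cnt[2L]) alleles <- rev(alleles)
    allele_a[j] <- alleles[1L]; allele_b[j] <- alleles[2L]
    cj <- (x1 == alleles[2L]) + (x2 == alleles[2L])
    cj[miss] <- NA_integer_
    codes[, j] <- cj
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  dimnames(codes) <- list(sample_ids, map$snp_id)

  map <- sort_marker_map(map)
  codes <- codes[, attr(map, "order"), drop = FALSE]
  attr(map, "order") <- NULL
  list(genotypes = codes, map = map, sample_ids = sample_ids)
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [read_ped_map()]: codes 0/1/2 become `allele_a allele_a`,
#' `allele_a allele_b`, `allele_b allele_b`; `NA` becomes `0 0`.
#'
#' @param genotypes integer matrix of allele_b dosages (n x k).
#' @param map marker map aligned to the genotype columns.
#' @param ped_path,map_path output paths.
#' @param sample_ids ids written to both FID and IID columns; defaults to
#'   the genotype rownames.
#' @export
write_ped_map <- function(genotypes, map, ped_path, map_path,
                          sample_ids = rownames(genotypes)) {
  stopifnot(ncol(genotypes) == nrow(map))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(genotypes)))
  k <- nrow(map)
  n <- nrow(genotypes)
  write.table(data.frame(map$chrom, map$snp_id, 0L, map$pos_bp),
              map_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  pair <- matrix("0", n, 2L * k)
  for (j in seq_len(k)) {
    cj <- genotypes[, j]
    aa <- map$allele_a[j]; bb <- map$allele_b[j]
    h1 <- ifelse(is.na(cj), "0", ifelse(cj == 2L, bb, aa))
    h2 <- ifelse(is.na(cj), "0", ifelse(cj >= 1L, bb, aa))
    pair[, 2L * j - 1L] <- h1
    pair[, 2L * j] <- h2
  }
  lead <- cbind(sample_ids, sample_ids, "0", "0", "0", "-9")
  out <- cbind(lead, pair)
  writeLines(apply(out, 1L, paste, collapse = " "), ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square P value against the
#' genotype frequencies expected from the observed allele frequency.
#' Monomorphic SNPs return P = 1 by convention.  Vectorised over count
#' triples.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative).
#' @return P value(s) in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be >= 0")
  if (any(n == 0)) stop("all genotype counts are zero")
  p <- (2 * n_AA + n_AB) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAB <- 2 * n * p * q; eBB <- n * q^2
  chisq <- ifelse(p == 0 | p == 1, 0,
                  (n_AA - eAA)^2 / eAA + (n_AB - eAB)^2 / eAB +
                    (n_BB - eBB)^2 / eBB)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Per-SNP quality summaries
#'
#' Computes call rate and HWE P per SNP from the genotype matrix; the
#' intensity-based platform quality score cannot be derived from dosages
#' and is taken as given (default 1).  The HWE subset mask defaults to all
#' individuals.
#'
#' @param genotypes allele_b dosage matrix.
#' @param quality_score numeric vector in \[0, 1\] per SNP, recycled.
#' @param hwe_subset optional logical/integer row subset used for the HWE
#'   test (e.g. founders only).
#' @return data.frame with snp_id, call_rate, quality_score, hwe_p,
#'   monomorphic flag.
#' @export
snp_quality <- function(genotypes, quality_score = 1, hwe_subset = NULL) {
  k <- ncol(genotypes)
  quality_score <- rep_len(quality_score, k)
  if (any(quality_score < 0 | quality_score > 1))
    stop("quality_score must lie in [0, 1]")
  g <- if (is.null(hwe_subset)) genotypes else genotypes[hwe_subset, , drop = FALSE]
  call_rate <- colMeans(!is.na(genotypes))
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  tot <- n0 + n1 + n2
  hwe_p <- rep(1, k)
  ok <- tot > 0
  hwe_p[ok] <- hwe_test(n0[ok], n1[ok], n2[ok])
  mono <- ok & (n1 == 0) & (n0 == 0 | n2 == 0)
  data.frame(snp_id = colnames(genotypes) %||% as.character(seq_len(k)),
             call_rate = call_rate, quality_score = quality_score,
             hwe_p = hwe_p, monomorphic = mono,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SNP quality-control filter
#'
#' Keeps SNPs with call rate strictly above `call_rate_min`, quality score
#' strictly above `quality_min` and HWE P strictly above `hwe_alpha` (all
#' three inequalities strict).  A SNP may fail several criteria; the report
#' counts each.
#'
#' @param genotypes allele_b dosage matrix.
#' @param map marker map aligned to columns (optional).
#' @param quality data.frame as returned by [snp_quality()].
#' @param call_rate_min,quality_min,hwe_alpha thresholds in \[0, 1\].
#' @return list with `genotypes`, `map` (filtered), `keep` (logical per
#'   input SNP) and `report` (counts removed per criterion and overall).
#' @export
qc_filter <- function(genotypes, quality, map = NULL,
                      call_rate_min = 0.80, quality_min = 0.40,
                      hwe_alpha = 1e-4) {
  thr <- c(call_rate_min, quality_min, hwe_alpha)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must lie in [0, 1]")
  stopifnot(nrow(quality) == ncol(genotypes))
  fail_call <- !(quality$call_rate > call_rate_min)
  fail_gc <- !(quality$quality_score > quality_min)
  fail_hwe <- !(quality$hwe_p > hwe_alpha)
  keep <- !(fail_call | fail_gc | fail_hwe)
  report <- list(n_input = ncol(genotypes),
                 n_kept = sum(keep),
                 removed_call_rate = sum(fail_call),
                 removed_quality = sum(fail_gc),
                 removed_hwe = sum(fail_hwe),
                 removed_total = sum(!keep))
  list(genotypes = genotypes[, keep, drop = FALSE],
       map = if (!is.null(map)) {
         m <- map[keep, , drop = FALSE]; rownames(m) <- NULL; m
       },
       keep = keep, report = report)
}

#' Allele_b frequency among non-missing genotypes
#'
#' @param codes dosage vector or matrix (columns = SNPs).
#' @param subset optional logical/integer subset of individuals.
#' @return frequency in \[0, 1\]; `NA` where every genotype in the subset
#'   is missing (undefined frequency).
#' @export
allele_frequency <- function(codes, subset = NULL) {
  if (is.null(dim(codes))) codes <- matrix(codes, ncol = 1L)
  if (!is.null(subset)) codes <- codes[subset, , drop = FALSE]
  if (nrow(codes) == 0L) stop("empty subset")
  nn <- colSums(!is.na(codes))
  f <- colSums(codes, na.rm = TRUE) / (2 * nn)
  f[nn == 0L] <- NA_real_
  if (length(f) == 1L) unname(f) else f
}

#' Centered genotype coding for whole-genome regression
#'
#' Maps dosages 0/1/2 to -scale/0/+scale (default the -10/0/10 coding).
#' Missing genotypes are imputed with the SNP's mean coded value,
#' `scale * (2 * f - 1)` for allele_b frequency f, which preserves
#' allele-frequency expectations.
#'
#' @param genotypes allele_b dosage matrix.
#' @param scale half-range of the coding (default 10).
#' @return numeric matrix of the same shape.
#' @export
encode_centered <- function(genotypes, scale = 10) {
  z <- (genotypes - 1) * scale
  if (anyNA(z)) {
    f <- allele_frequency(genotypes)
    fill <- scale * (2 * f - 1)
    fill[is.na(fill)] <- 0
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- fill[idx[, 2L]]
  }
  z
}
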