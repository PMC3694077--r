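# Forward simulation of the two-line divergent selection design.
#
# Founders are drawn in linkage equilibrium; LD then accumulates through
# drift and selection.  Selection acts by truncation on the simulated
# selection-trait phenotype (the efficiency trait): the LOW line keeps the
# lowest fraction every generation, the HIGH line mates at random until
# `high_line_selection_start_gen` and keeps the highest fraction
# thereafter.  Gametes recombine with Poisson crossover counts per
# chromosome.  Sex chromosomes are simulated autosomally; the map labels
# the last chromosome "X" when n_chroms = 19.

#' Simulation configuration for the divergent-line generator
#'
#' Defaults describe the desk-scale version of the study design: two lines
#' of 80 pigs per generation over 9 generations (G0-G8) from 160 founders,
#' 1,000 SNPs on 18 autosomes plus X, a sparse trait architecture in which
#' 0.5 percent of markers are QTL, heritability 0.4, and truncation
#' selection of the best 20 percent.  The selection trait is simulated on a
#' standardized scale (phenotypic variance 1) and mapped to kg/day by the
#' records layer.
#'
#' @param n_founders founder count (split equally between lines at G0).
#' @param n_per_line_per_gen offspring per line per generation.
#' @param n_generations number of generations including G0 (default 9).
#' @param n_snps,n_chroms,chrom_length_bp marker panel geometry.
#' @param founder_maf_range uniform law for founder minor-allele frequency.
#' @param qtl_fraction fraction of SNPs that are causal (1 - pi).
#' @param qtl_effect_sd raw QTL effect SD before variance calibration.
#' @param h2_target narrow-sense heritability of the selection trait.
#' @param dam_var,pen_var variance of dam and pen-within-group random
#'   effects (phenotypic scale; residual absorbs the remainder).
#' @param selection_fraction fraction of each sex kept as parents.
#' @param high_line_selection_start_gen first generation bred from
#'   upward-selected parents in the HIGH line (default 5).
#' @param sex_effect_sd,pen_group_effect_sd fixed-effect SDs for the
#'   records layer.
#' @param age_slope_sd SD of per-line-by-parity on-test-age slopes.
#' @param recomb_rate_per_bp expected crossovers per bp (1e-8 = 1 cM/Mb).
#' @param test_days,weigh_interval length of test and weighing interval
#'   (days).
#' @param weight_noise_sd,intake_noise_sd measurement noise (kg).
#' @param qc_fail_fraction fraction of SNPs given failing quality scores.
#' @param seed integer seed; every simulate_* call is deterministic in it.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 160, n_per_line_per_gen = 80,
                       n_generations = 9, n_snps = 1000, n_chroms = 19,
                       chrom_length_bp = 5e6,
                       founder_maf_range = c(0.05, 0.5),
                       qtl_fraction = 0.005, qtl_effect_sd = 1,
                       h2_target = 0.4, dam_var = 0.05, pen_var = 0.05,
                       selection_fraction = 0.2,
                       high_line_selection_start_gen = 5,
                       sex_effect_sd = 0.1, pen_group_effect_sd = 0.1,
                       age_slope_sd = 0.002,
                       recomb_rate_per_bp = 1e-8,
                       test_days = 98, weigh_interval = 14,
                       weight_noise_sd = 1.5, intake_noise_sd = 0.3,
                       qc_fail_fraction = 0.02, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$qtl_fraction > 0, cfg$qtl_fraction < 1,
            cfg$h2_target > 0, cfg$h2_target < 1,
            cfg$selection_fraction > 0, cfg$selection_fraction <= 1,
            cfg$h2_target + cfg$dam_var + cfg$pen_var < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder genotypes and a marker map
#'
#' Founder haplotypes are Bernoulli(maf) per SNP in linkage equilibrium;
#' minor-allele frequencies follow the configured uniform law.  Map
#' positions are uniform per chromosome and sorted.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (dosages, founders x SNPs), `map`,
#'   `hap1`/`hap2` (phased 0/1 matrices) and `maf` (the drawn founder
#'   frequencies).
#' @export
simulate_founders <- function(config) {
  if (config$n_snps < config$n_chroms)
    stop("n_snps must be >= n_chroms")
  set.seed(config$seed)
  k <- config$n_snps
  n <- config$n_founders
  chrom_labels <- c(as.character(1:18), "X", "Y")[seq_len(config$n_chroms)]
  chrom <- sort(rep_len(seq_len(config$n_chroms), k))
  pos <- integer(k)
  for (c_i in seq_len(config$n_chroms)) {
    idx <- which(chrom == c_i)
    pos[idx] <- sort(sample.int(config$chrom_length_bp, length(idx)))
  }
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(k)),
                    chrom = chrom_labels[chrom], pos_bp = pos,
                    allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  maf <- runif(k, config$founder_maf_range[1L], config$founder_maf_range[2L])
  hap1 <- matrix(rbinom(n * k, 1L, rep(maf, each = n)), n, k)
  hap2 <- matrix(rbinom(n * k, 1L, rep(maf, each = n)), n, k)
  ids <- sprintf("A%05d", seq_len(n))
  geno <- hap1 + hap2
  dimnames(geno) <- list(ids, map$snp_id)
  dimnames(hap1) <- dimnames(hap2) <- dimnames(geno)
  list(genotypes = geno, map = map, hap1 = hap1, hap2 = hap2, maf = maf)
}

# one recombined gamete from a phased parent; vectorised over SNPs
.meiosis <- function(h1, h2, chrom_id, pos, chrom_len, rate) {
  gam <- h1
  for (c_i in unique(chrom_id)) {
    idx <- which(chrom_id == c_i)
    start <- sample.int(2L, 1L) - 1L
    ncx <- rpois(1L, chrom_len * rate)
    if (ncx > 0L) {
      cx <- sort(runif(ncx, 0, chrom_len))
      seg <- (start + findInterval(pos[idx], cx)) %% 2L
    } else seg <- rep(start, length(idx))
    gam[idx] <- ifelse(seg == 0L, h1[idx], h2[idx])
  }
  gam
}

#' Simulate the divergent selection lines forward from founders
#'
#' @param config a [sim_config()].
#' @param founders output of [simulate_founders()].
#' @return list with `pedigree` (animal, sire, dam, generation, line, sex,
#'   parity, pen, group, age_on_test), `genotypes` (all animals),
#'   `hap1`/`hap2`, `map`, and `truth` (QTL indices and calibrated
#'   effects, true breeding values, dam/pen effects, selection-trait
#'   phenotype, variance components).
#' @export
simulate_lines <- function(config, founders) {
  set.seed(config$seed + 1L)
  k <- config$n_snps
  map <- founders$map
  chrom_id <- match(map$chrom, unique(map$chrom))

  n_qtl <- max(1L, round(config$qtl_fraction * k))
  qtl <- sort(sample.int(k, n_qtl))
  eff_raw <- rnorm(n_qtl, 0, config$qtl_effect_sd)
  bv_raw <- as.numeric(founders$genotypes[, qtl, drop = FALSE] %*% eff_raw)
  v_raw <- var(bv_raw)
  if (v_raw <= 0) stop("degenerate founder genetic variance; add QTL or MAF")
  eff <- eff_raw * sqrt(config$h2_target / v_raw)
  resid_var <- 1 - config$h2_target - config$dam_var - config$pen_var

  n_f <- config$n_founders
  n_gen <- config$n_generations
  n_off <- config$n_per_line_per_gen
  n_total <- n_f + 2L * n_off * (n_gen - 1L)
  hap1 <- matrix(0L, n_total, k)
  hap2 <- matrix(0L, n_total, k)
  hap1[1:n_f, ] <- founders$hap1
  hap2[1:n_f, ] <- founders$hap2

  ped <- data.frame(
    animal = sprintf("A%05d", seq_len(n_total)),
    sire = "0", dam = "0", generation = NA_integer_,
    line = NA_character_, sex = NA_character_, parity = NA_integer_,
    pen = NA_character_, group = NA_character_, age_on_test = NA_integer_,
    stringsAsFactors = FALSE)

  half <- n_f %/% 2L
  ped$generation[1:n_f] <- 0L
  ped$line[1:n_f] <- rep(c("LOW", "HIGH"), c(half, n_f - half))
  ped$sex[1:n_f] <- rep_len(c("M", "F"), n_f)

  bv <- numeric(n_total)
  dam_eff <- numeric(n_total)
  pen_eff <- numeric(n_total)
  pheno <- numeric(n_total)

  assign_env <- function(rows, gen) {
    np <- max(1L, ceiling(length(rows) / 16L))
    pens <- sprintf("P%02d", rep_len(seq_len(np), length(rows)))
    ped$pen[rows] <<- pens
    ped$group[rows] <<- sprintf("G%dg%d", gen, rep_len(1:2, length(rows)))
    ped$parity[rows] <<- rep_len(1:2, length(rows))
    ped$age_on_test[rows] <<- as.integer(round(rnorm(length(rows), 90, 4)))
    key <- paste(ped$group[rows], pens)
    pe <- rnorm(length(unique(key)), 0, sqrt(config$pen_var))
    pen_eff[rows] <<- pe[match(key, unique(key))]
  }

  score <- function(rows) {
    g <- hap1[rows, qtl, drop = FALSE] + hap2[rows, qtl, drop = FALSE]
    bv[rows] <<- as.numeric(g %*% eff)
    pheno[rows] <<- bv[rows] + dam_eff[rows] + pen_eff[rows] +
      rnorm(length(rows), 0, sqrt(resid_var))
  }
  assign_env(1:n_f, 0L)
  score(1:n_f)

  pick_parents <- function(rows, direction) {
    sel <- function(r) {
      ns <- max(2L, round(config$selection_fraction * length(r)))
      if (length(r) < 2L) stop("fewer than 2 candidate parents of a sex")
      if (is.null(direction)) sample(r, min(ns, length(r)))
      else r[order(pheno[r], decreasing = (direction == "high"))][seq_len(min(ns, length(r)))]
    }
    list(sires = sel(rows[ped$sex[rows] == "M"]),
         dams = sel(rows[ped$sex[rows] == "F"]))
  }

  nxt <- n_f
  for (gen in seq_len(n_gen - 1L)) {
    for (line in c("LOW", "HIGH")) {
      prev <- which(ped$generation == gen - 1L & ped$line == line)
      direction <-
        if (config$selection_fraction >= 1) NULL
        else if (line == "LOW") "low"
        else if (gen >= config$high_line_selection_start_gen) "high"
        else NULL
      par <- pick_parents(prev, direction)
      rows <- nxt + seq_len(n_off)
      sires <- sample(par$sires, n_off, replace = TRUE)
      dams <- sample(par$dams, n_off, replace = TRUE)
      for (i in seq_len(n_off)) {
        r <- rows[i]
        hap1[r, ] <- .meiosis(hap1[sires[i], ], hap2[sires[i], ], chrom_id,
                              map$pos_bp, config$chrom_length_bp,
                              config$recomb_rate_per_bp)
        hap2[r, ] <- .meiosis(hap1[dams[i], ], hap2[dams[i], ], chrom_id,
                              map$pos_bp, config$chrom_length_bp,
                              config$recomb_rate_per_bp)
      }
      ped$sire[rows] <- ped$animal[sires]
      ped$dam[rows] <- ped$animal[dams]
      ped$generation[rows] <- gen
      ped$line[rows] <- line
      ped$sex[rows] <- rep_len(c("M", "F"), n_off)
      # litter-mates (same dam) share the dam environmental effect
      de <- rnorm(length(unique(dams)), 0, sqrt(config$dam_var))
      dam_eff[rows] <- de[match(dams, unique(dams))]
      assign_env(rows, gen)
      score(rows)
      nxt <- nxt + n_off
    }
  }

  geno <- hap1 + hap2
  dimnames(geno) <- list(ped$animal, map$snp_id)
  dimnames(hap1) <- dimnames(hap2) <- dimnames(geno)
  truth <- list(qtl_indices = qtl, qtl_effects = eff,
                breeding_values = setNames(bv, ped$animal),
                dam_effects = setNames(dam_eff, ped$animal),
                pen_effects = setNames(pen_eff, ped$animal),
                selection_phenotype = setNames(pheno, ped$animal),
                varcomp = list(genetic = config$h2_target,
                               dam = config$dam_var, pen = config$pen_var,
                               residual = resid_var))
  list(pedigree = ped, genotypes = geno, hap1 = hap1, hap2 = hap2,
       map = map, truth = truth)
}

#' Simulate longitudinal records and off-test traits
#'
#' Body weights follow an individual growth line (about 40 kg at on-test,
#' slope = the animal's true ADG) measured every `weigh_interval` days
#' with noise; daily feed intake is an animal-specific quadratic in day
#' whose level carries the expected intake for growth and maintenance plus
#' the animal's residual feed intake (the selection trait, rescaled to
#' kg/day); BF and LMA are correlated polygenic traits.  Per-SNP platform
#' quality scores are drawn with a configurable failing fraction.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_lines()].
#' @return list with `weights` and `intakes` (long data.frames:
#'   animal, day, value), `offtest` (animal, BF, LMA), `quality_score`
#'   (per SNP), and `truth_records` (true ADG, ADFI level and RFI in
#'   kg/day per animal).
#' @export
simulate_records <- function(config, sim) {
  set.seed(config$seed + 2L)
  ped <- sim$pedigree
  n <- nrow(ped)
  bv_std <- sim$truth$selection_phenotype  # phenotypic scale, var ~ 1
  bvg <- sim$truth$breeding_values

  corr_trait <- function(rho, mu, sdg, sde) {
    g <- rho * bvg / sqrt(config$h2_target) +
      sqrt(max(0, 1 - rho^2)) * rnorm(n)
    mu + sdg * g + rnorm(n, 0, sde)
  }
  adg <- corr_trait(rho = 0.3, mu = 0.90, sdg = 0.06, sde = 0.04)
  bf <- corr_trait(rho = 0.25, mu = 15, sdg = 1.8, sde = 1.2)
  lma <- corr_trait(rho = -0.15, mu = 40, sdg = 2.5, sde = 2.0)
  rfi_kg <- 0.15 * bv_std                      # selection trait in kg/day
  sex_eff <- ifelse(ped$sex == "M", 1, -1) * config$sex_effect_sd
  pg_key <- paste(ped$group, ped$pen)
  pg_lev <- unique(pg_key)
  pg_eff <- rnorm(length(pg_lev), 0, config$pen_group_effect_sd)[match(pg_key, pg_lev)]
  slope_key <- paste(ped$line, ped$parity)
  sl_lev <- unique(slope_key)
  age_slope <- rnorm(length(sl_lev), 0, config$age_slope_sd)[match(slope_key, sl_lev)]
  # expected intake from growth/maintenance + fixed effects + RFI
  adfi_level <- 1.0 + 1.1 * adg + 0.02 * bf + sex_eff + pg_eff +
    age_slope * (ped$age_on_test - 90) + rfi_kg

  days_w <- seq(0, config$test_days, by = config$weigh_interval)
  weights <- data.frame(
    animal = rep(ped$animal, each = length(days_w)),
    day = rep(days_w, n),
    weight_kg = rep(40 + rnorm(n, 0, 1.5), each = length(days_w)) +
      rep(adg, each = length(days_w)) * rep(days_w, n) +
      rnorm(n * length(days_w), 0, config$weight_noise_sd),
    stringsAsFactors = FALSE)

  days_i <- 0:config$test_days
  nd <- length(days_i)
  d_c <- (days_i - config$test_days / 2) / config$test_days
  shape <- 0.4 * d_c - 0.5 * d_c^2              # ramping, concave intake curve
  shape <- shape - mean(shape)                  # level stays interpretable
  intakes <- data.frame(
    animal = rep(ped$animal, each = nd),
    day = rep(days_i, n),
    intake_kg = rep(adfi_level, each = nd) + rep(shape, n) +
      rnorm(n * nd, 0, config$intake_noise_sd),
    stringsAsFactors = FALSE)

  k <- config$n_snps
  failing <- runif(k) < config$qc_fail_fraction
  quality_score <- ifelse(failing, runif(k, 0, 0.40), runif(k, 0.60, 1))

  list(weights = weights, intakes = intakes,
       offtest = data.frame(animal = ped$animal, BF = bf, LMA = lma,
                            stringsAsFactors = FALSE),
       quality_score = quality_score,
       truth_records = data.frame(animal = ped$animal, true_adg = adg,
                                  true_adfi = adfi_level, true_rfi = rfi_kg,
                                  stringsAsFactors = FALSE))
}
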