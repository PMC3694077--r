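# Pipeline orchestration: simulate -> phenotypes -> QC -> divergence scan
# -> BayesB -> single-SNP association, per trait, from one configuration.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param traits subset of RFI, ADFI, ADG, BF, LMA.
#' @param sim a [sim_config()] (its own seed is overridden by the
#'   pipeline's derived stage seed).
#' @param bayesb a [bayesb_config()].
#' @param ratios variance ratios for [compute_rfi()] (NULL = fixed-model
#'   OLS).
#' @param focal_generation,founder_generation scan generations.
#' @param seed global seed; stage seeds derive as
#'   (seed + 10007 * stage_index) mod (2^31 - 1).
#' @export
run_config <- function(out_dir, traits = c("RFI", "ADFI", "ADG", "BF", "LMA"),
                       sim = sim_config(), bayesb = bayesb_config(),
                       ratios = NULL, focal_generation = NULL,
                       founder_generation = 0, seed = 1) {
  known <- c("RFI", "ADFI", "ADG", "BF", "LMA")
  if (length(traits) == 0L) stop("trait list must be non-empty")
  bad <- setdiff(traits, known)
  if (length(bad))
    stop(sprintf("unknown trait(s): %s (choose from %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  structure(as.list(environment())[setdiff(names(formals(run_config)), "known")],
            class = "run_config")
}

#' Derived per-stage seed
#' @keywords internal
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 10007 * stage_index) %% (2^31 - 1))
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small polynomial rolling hash of the serialized configuration (hex)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Simulates the divergent lines, derives phenotypes, applies SNP QC,
#' runs the divergence scan, and runs BayesB window mapping and
#' single-SNP association for each configured trait.  All outputs are
#' TSV/JSON files in `config$out_dir`; a manifest records the seed,
#' configuration hash and thresholds.  Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)

  # stage 1: simulate
  sim_cfg <- config$sim
  sim_cfg$seed <- stage_seed(config$seed, 1L)
  founders <- simulate_founders(sim_cfg)
  sim <- simulate_lines(sim_cfg, founders)
  records <- simulate_records(sim_cfg, sim)
  write_ped_map(sim$genotypes, sim$map, od("genotypes.ped"), od("genotypes.map"))
  .write_tsv(sim$pedigree, od("pedigree.tsv"))
  .write_tsv(records$weights, od("weights.tsv"))
  .write_tsv(records$intakes, od("intakes.tsv"))
  .write_tsv(records$offtest, od("offtest.tsv"))
  jsonlite::write_json(
    list(qtl_indices = sim$truth$qtl_indices,
         qtl_effects = round(sim$truth$qtl_effects, 10),
         varcomp = sim$truth$varcomp),
    od("truth.json"), digits = NA, auto_unbox = TRUE)

  # stage 2: phenotypes
  ph <- derive_phenotypes(records$weights, records$intakes, records$offtest,
                          sim$pedigree)
  ph <- compute_rfi(ph, sim$pedigree, ratios = config$ratios)
  .write_tsv(ph, od("phenotypes.tsv"))

  # stage 3: SNP QC
  qual <- snp_quality(sim$genotypes, quality_score = records$quality_score)
  qc <- qc_filter(sim$genotypes, qual, map = sim$map)
  .write_tsv(qual, od("snp_quality.tsv"))

  # stage 4: divergence scan
  focal <- config$focal_generation %||% (sim_cfg$n_generations - 1L)
  scan <- divergence_scan(qc$genotypes, sim$pedigree, map = qc$map,
                          focal_generation = focal,
                          founder_generation = config$founder_generation)
  .write_tsv(scan, od("divscan.tsv"))

  # stages 5-6: per-trait BayesB and single-SNP association
  Z <- encode_centered(qc$genotypes)
  windows <- make_windows(qc$map)
  cell <- paste(sim$pedigree$line, sim$pedigree$parity, sep = "_")
  Xf <- cbind(`(Intercept)` = 1,
              .incidence(sim$pedigree$sex)[, -1L, drop = FALSE],
              .incidence(paste(sim$pedigree$group, sim$pedigree$pen))[, -1L, drop = FALSE],
              .incidence(cell) * (sim$pedigree$age_on_test - 90))
  bayesb_out <- list(); assoc_out <- list()
  for (ti in seq_along(config$traits)) {
    trait <- config$traits[ti]
    y <- ph[[trait]]
    ok <- is.finite(y)
    bb_cfg <- config$bayesb
    bb_cfg$seed <- stage_seed(config$seed, 10L + ti)
    fit <- fit_bayesb(y[ok], Xf[ok, , drop = FALSE], Z[ok, , drop = FALSE],
                      bb_cfg)
    wsum <- summarize_windows(fit, windows, Z[ok, , drop = FALSE])
    h2 <- genomic_heritability(fit)
    wsum$trait <- trait
    .write_tsv(wsum, od(sprintf("bayesb_windows_%s.tsv", trait)))
    .write_tsv(data.frame(snp_id = colnames(Z),
                          post_inclusion = fit$post_inclusion,
                          post_mean_effect = fit$post_mean_effect),
               od(sprintf("bayesb_snps_%s.tsv", trait)))
    bayesb_out[[trait]] <- list(windows = wsum, h2 = h2)

    ares <- run_assoc(y, qc$genotypes, sim$pedigree, map = qc$map)
    .write_tsv(ares, od(sprintf("assoc_%s.tsv", trait)))
    assoc_out[[trait]] <- ares
  }

  manifest <- list(
    seed = config$seed,
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
    traits = config$traits,
    focal_generation = focal,
    qc = qc$report,
    n_windows = nrow(windows$windows),
    expected_window_pct = expected_window_share(nrow(windows$windows)),
    candidate_threshold_pct = 5 * expected_window_share(nrow(windows$windows)),
    genomic_h2 = lapply(bayesb_out, function(b)
      round(unlist(b$h2[c("mean", "lower", "upper")]), 6)),
    lambda = lapply(assoc_out, function(a) round(attr(a, "lambda"), 6)),
    files = sort(list.files(config$out_dir)))
  jsonlite::write_json(manifest, od("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, records = records, phenotypes = ph, qc = qc,
                 scan = scan, bayesb = bayesb_out, assoc = assoc_out,
                 manifest = manifest))
}
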