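#' Configuration for the paired-tissue eQTL simulator
#'
#' Collects and validates every knob of the synthetic-data generator:
#' panel geometry (LD blocks), study sample sizes, the true cross-tissue
#' sharing fraction, effect sizes, platform differences and the master seed.
#' The returned object fully determines the simulated panel and study pair:
#' the same configuration always reproduces byte-identical data.
#'
#' @param n_genes Number of genes (one expression probe per assayed gene and
#'   platform).
#' @param n_individuals_i,n_individuals_j Sample sizes of study i (discovery,
#'   conventionally the larger) and study j (replication).
#' @param pi_true Fraction of eQTL-bearing genes whose causal cis variant is
#'   identical in both tissues, in `[0,1]`.
#' @param effect_beta Standardized per-allele effect size, either a single
#'   value or `c(mean, sd)` for per-gene normal draws (signs are randomized).
#' @param effect_beta_shared Optional override of `effect_beta` for shared
#'   genes only; used to probe the estimator's effect-size-similarity
#'   assumption. Default `NULL` (same distribution as tissue-specific genes).
#' @param noise_sd Residual standard deviation of expression.
#' @param frac_null Fraction of genes with no eQTL in either tissue
#'   (`beta = 0`), so false-discovery behaviour is exercised.
#' @param n_blocks,snps_per_block LD-block count and variants per block.
#' @param within_block_r2 Target pairwise r-squared of variants in the same
#'   block, in `[0,1]`; variants in different blocks are independent.
#' @param maf_range Length-2 vector: minor-allele-frequency bounds in
#'   `(0, 0.5]` for block founder alleles.
#' @param n_haplotypes Phased haplotypes in the reference panel (2N).
#' @param block_spacing_bp,snp_spacing_bp Base-pair distance between block
#'   centers and between adjacent variants of a block.
#' @param platform_snp_keep_i,platform_snp_keep_j Fractions of panel variants
#'   genotyped by each study's SNP array (independent random subsets).
#' @param probe_overlap_frac Fraction of genes assayed on both expression
#'   platforms; the remainder are split between the two platforms.
#' @param tissue_coupling `"coupled"` (default): every eQTL-bearing gene has
#'   an eQTL in both tissues, shared or tissue-specific. `"independent"`:
#'   each tissue draws its eQTL-bearing gene set independently; only
#'   meaningful (and only allowed) at `pi_true = 0`, where it yields an
#'   independence null for chance-overlap calibration.
#' @param seed Master integer seed; all randomness derives from it.
#'
#' @return An object of class `eqtl_sim_config` (a validated list).
#' @seealso [simulate_haplotype_panel()], [simulate_study_pair()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_individuals_i = 100,
#'                   n_individuals_j = 50, pi_true = 0.3, seed = 1)
#' cfg
sim_config <- function(n_genes = 2000,
                       n_individuals_i = 1000,
                       n_individuals_j = 150,
                       pi_true = 0.2,
                       effect_beta = 0.45,
                       effect_beta_shared = NULL,
                       noise_sd = 1,
                       frac_null = 0.5,
                       n_blocks = 100,
                       snps_per_block = 5,
                       within_block_r2 = 0.9,
                       maf_range = c(0.2, 0.5),
                       n_haplotypes = 2000,
                       block_spacing_bp = 500000,
                       snp_spacing_bp = 2000,
                       platform_snp_keep_i = 0.6,
                       platform_snp_keep_j = 0.6,
                       probe_overlap_frac = 0.7,
                       tissue_coupling = c("coupled", "independent"),
                       seed = 1L) {
  tissue_coupling <- match.arg(tissue_coupling)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_individuals_i = check_count(n_individuals_i, "n_individuals_i", min = 3L),
    n_individuals_j = check_count(n_individuals_j, "n_individuals_j", min = 3L),
    pi_true = check_fraction(pi_true, "pi_true"),
    effect_beta = effect_beta,
    effect_beta_shared = effect_beta_shared,
    noise_sd = noise_sd,
    frac_null = check_fraction(frac_null, "frac_null"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    snps_per_block = check_count(snps_per_block, "snps_per_block"),
    within_block_r2 = check_fraction(within_block_r2, "within_block_r2"),
    maf_range = maf_range,
    n_haplotypes = check_count(n_haplotypes, "n_haplotypes", min = 4L),
    block_spacing_bp = check_count(block_spacing_bp, "block_spacing_bp"),
    snp_spacing_bp = check_count(snp_spacing_bp, "snp_spacing_bp"),
    platform_snp_keep_i = check_fraction(platform_snp_keep_i,
                                         "platform_snp_keep_i", open_left = TRUE),
    platform_snp_keep_j = check_fraction(platform_snp_keep_j,
                                         "platform_snp_keep_j", open_left = TRUE),
    probe_overlap_frac = check_fraction(probe_overlap_frac, "probe_overlap_frac"),
    tissue_coupling = tissue_coupling,
    seed = seed
  )
  if (!is.numeric(cfg$effect_beta) || !length(cfg$effect_beta) %in% 1:2 ||
      any(is.na(cfg$effect_beta)))
    stop_field("effect_beta", "must be a value or c(mean, sd)")
  if (!is.null(cfg$effect_beta_shared) &&
      (!is.numeric(cfg$effect_beta_shared) ||
       !length(cfg$effect_beta_shared) %in% 1:2))
    stop_field("effect_beta_shared", "must be NULL, a value, or c(mean, sd)")
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1L || cfg$noise_sd < 0)
    stop_field("noise_sd", "must be a single non-negative number")
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_field("maf_range", "must be (low, high) within (0, 0.5]")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31 - 1)
    stop_field("seed", "must be a 32-bit integer")
  cfg$seed <- as.integer(seed)
  if (cfg$tissue_coupling == "independent" && cfg$pi_true > 0)
    stop_field("tissue_coupling",
               "'independent' is an independence null and requires pi_true = 0")
  if (cfg$snps_per_block * cfg$snp_spacing_bp >= cfg$block_spacing_bp)
    stop_field("snp_spacing_bp", "block span must be smaller than block spacing")
  class(cfg) <- "eqtl_sim_config"
  cfg
}

#' @export
#' @method print eqtl_sim_config
print.eqtl_sim_config <- function(x, ...) {
  cat("Paired-tissue eQTL simulation configuration\n")
  cat(sprintf("  genes: %d (null fraction %.2f), pi_true = %.2f [%s]\n",
              x$n_genes, x$frac_null, x$pi_true, x$tissue_coupling))
  cat(sprintf("  samples: n_i = %d, n_j = %d; panel: %d haplotypes\n",
              x$n_individuals_i, x$n_individuals_j, x$n_haplotypes))
  cat(sprintf("  LD: %d blocks x %d SNPs, target within-block r2 = %.2f, MAF [%.2f, %.2f]\n",
              x$n_blocks, x$snps_per_block, x$within_block_r2,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  platforms: SNP keep %.2f / %.2f, probe overlap %.2f; seed %d\n",
              x$platform_snp_keep_i, x$platform_snp_keep_j,
              x$probe_overlap_frac, x$seed))
  invisible(x)
}
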