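#' @export
#' @method print raw_study
print.raw_study <- function(x, ...) {
  cat(sprintf("Raw eQTL study '%s' (%s): %d individuals\n",
              x$study_id, x$tissue, x$n_samples))
  cat(sprintf("  genotyped variants: %d; expression probes: %d\n",
              nrow(x$genotypes), nrow(x$expression)))
  invisible(x)
}

# Subset a raw study to a set of individuals (columns); used by the
# subsampling power estimator.
subset_individuals <- function(raw, idx) {
  out <- raw
  out$genotypes <- raw$genotypes[, idx, drop = FALSE]
  out$expression <- raw$expression[, idx, drop = FALSE]
  out$n_samples <- length(idx)
  out
}

draw_beta <- function(spec, n) {
  b <- if (length(spec) == 2L) stats::rnorm(n, spec[1], spec[2]) else rep(spec, n)
  b * sample(c(-1, 1), n, replace = TRUE)
}

# Diploid dosage matrix (variants x individuals) by random pairing of panel
# haplotypes (Hardy-Weinberg, no population structure).
draw_genotypes <- function(panel, n, prefix) {
  nh <- nrow(panel$haplotypes)
  i1 <- sample.int(nh, n, replace = TRUE)
  i2 <- sample.int(nh, n, replace = TRUE)
  g <- t(panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE])
  colnames(g) <- sprintf("%s_ind%04d", prefix, seq_len(n))
  g
}

#' Simulate a pair of eQTL studies with known cross-tissue sharing
#'
#' Builds two raw studies (genotype-dosage and expression matrices on
#' partially overlapping SNP and probe platforms) from one haplotype panel,
#' together with the ground truth the downstream estimators try to recover.
#'
#' Each gene gets a TSS at its home LD-block center and one annotated exon.
#' A fraction `frac_null` of genes carries no eQTL in either tissue. Among
#' eQTL-bearing genes, a fraction `pi_true` is *shared*: the identical causal
#' variant (and effect size) drives expression in both tissues. Non-shared
#' genes are driven by a variant in the home block in tissue i and by an
#' independent variant in an adjacent block (still cis) in tissue j, so their
#' eSNPs never match under LD-proxy comparison. Expression is
#' `beta * dosage(causal) + N(0, noise_sd)`. Each study genotypes only a
#' platform-specific random subset of panel variants and assays a
#' platform-specific probe set with `probe_overlap_frac` of genes in common;
#' the causal dosage itself always comes from the full panel, so a study may
#' well not have genotyped its own causal variant.
#'
#' @param panel A [haplotype_panel()], normally from
#'   [simulate_haplotype_panel()] under the same `config`.
#' @param config An [sim_config()] object.
#' @param study_ids,tissues Length-2 character labels for the two studies.
#' @return A list of class `eqtl_sim_pair` with elements `study_i`,
#'   `study_j` (class `raw_study`), `truth` (data.frame: `gene_id`, `tissue`,
#'   `causal_variant`, `beta`, `shared_flag`, with the shared gene set as
#'   attribute `shared_genes`), `annotation` (list with `genes` and `exons`
#'   data.frames) and `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, n_individuals_i = 60, n_individuals_j = 40,
#'                   n_blocks = 20, n_haplotypes = 200, seed = 11)
#' sim <- simulate_study_pair(simulate_haplotype_panel(cfg), cfg)
#' sim$study_i
simulate_study_pair <- function(panel, config,
                                study_ids = c("study_i", "study_j"),
                                tissues = c("blood", "brain")) {
  if (!inherits(panel, "haplotype_panel"))
    stop("panel must be a haplotype_panel", call. = FALSE)
  if (!inherits(config, "eqtl_sim_config"))
    stop("config must be built by sim_config()", call. = FALSE)
  if (nrow(panel$variants) != config$n_blocks * config$snps_per_block)
    stop("panel is inconsistent with config (variant count mismatch)",
         call. = FALSE)
  set.seed(derive_seed(config$seed, 2L))

  nb <- config$n_blocks
  ng <- config$n_genes
  vt <- panel$variants

  ## --- gene annotation: TSS near the home-block center, one exon per gene
  home <- ((seq_len(ng) - 1L) %% nb) + 1L
  slot <- (seq_len(ng) - 1L) %/% nb
  tss <- home * config$block_spacing_bp + 10000L + slot * 300L
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                      chrom = "1", tss = tss, block = home,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id,
                      exon_id = sprintf("%s_ex1", genes$gene_id),
                      chrom = "1", start = tss, end = tss + 200L,
                      stringsAsFactors = FALSE)

  ## --- gene architecture
  is_null <- stats::runif(ng) < config$frac_null
  if (config$tissue_coupling == "independent") {
    # independence null: each tissue draws its eQTL-bearing genes on its own
    has_i <- stats::runif(ng) >= config$frac_null
    has_j <- stats::runif(ng) >= config$frac_null
    shared <- rep(FALSE, ng)
  } else {
    has_i <- has_j <- !is_null
    shared <- has_i & (stats::runif(ng) < config$pi_true)
  }

  block_variants <- split(seq_len(nrow(vt)), vt$block)
  poly_block <- vapply(block_variants,
                       function(ix) any(!vt$monomorphic[ix]), logical(1))
  pick_variant <- function(b, gene) {
    ix <- block_variants[[b]]
    ix <- ix[!vt$monomorphic[ix]]
    if (length(ix) == 0L)
      stop(sprintf("cis window contains no usable variants for gene %s", gene),
           call. = FALSE)
    if (length(ix) == 1L) ix else sample(ix, 1L)
  }
  # adjacent block (within the cis window by construction: one spacing away)
  alt_block <- function(b) if (b == nb) b - 1L else b + 1L

  causal_i <- causal_j <- rep(NA_integer_, ng)
  for (g in seq_len(ng)) {
    if (shared[g]) {
      causal_i[g] <- causal_j[g] <- pick_variant(home[g], genes$gene_id[g])
    } else {
      if (has_i[g]) causal_i[g] <- pick_variant(home[g], genes$gene_id[g])
      if (has_j[g]) causal_j[g] <- pick_variant(alt_block(home[g]),
                                                genes$gene_id[g])
    }
  }

  beta_i <- beta_j <- rep(0, ng)
  spec_shared <- config$effect_beta_shared %||% config$effect_beta
  bsh <- draw_beta(spec_shared, ng)
  bsp_i <- draw_beta(config$effect_beta, ng)
  bsp_j <- draw_beta(config$effect_beta, ng)
  beta_i[has_i] <- ifelse(shared[has_i], bsh[has_i], bsp_i[has_i])
  beta_j[has_j] <- ifelse(shared[has_j], bsh[has_j], bsp_j[has_j])

  ## --- probe platforms
  n_both <- round(config$probe_overlap_frac * ng)
  both <- sample.int(ng, n_both)
  rest <- setdiff(seq_len(ng), both)
  only_i <- rest[seq_along(rest) %% 2L == 1L]
  only_j <- setdiff(rest, only_i)
  assay_i <- sort(c(both, only_i))
  assay_j <- sort(c(both, only_j))

  make_probes <- function(assay, study_id, offset) {
    data.frame(probe_id = sprintf("%s_pr_%s", study_id, genes$gene_id[assay]),
               gene_id = genes$gene_id[assay],
               chrom = "1",
               start = tss[assay] + offset,
               end = tss[assay] + offset + 50L,
               stringsAsFactors = FALSE)
  }

  make_study <- function(study_id, tissue, n, keep_frac, assay, causal, beta,
                         probe_offset) {
    geno_full <- draw_genotypes(panel, n, study_id)
    mask <- sort(sample.int(nrow(vt), round(keep_frac * nrow(vt))))
    probes <- make_probes(assay, study_id, probe_offset)
    expr <- matrix(stats::rnorm(length(assay) * n, 0, config$noise_sd),
                   nrow = length(assay), ncol = n,
                   dimnames = list(probes$probe_id, colnames(geno_full)))
    hit <- which(!is.na(causal[assay]) & beta[assay] != 0)
    if (length(hit))
      expr[hit, ] <- expr[hit, , drop = FALSE] +
        beta[assay][hit] * geno_full[causal[assay][hit], , drop = FALSE]
    structure(list(study_id = study_id, tissue = tissue,
                   genotypes = geno_full[mask, , drop = FALSE],
                   variants = vt[mask, c("id", "chrom", "pos")],
                   expression = expr, probes = probes, n_samples = n),
              class = "raw_study")
  }

  study_i <- make_study(study_ids[1], tissues[1], config$n_individuals_i,
                        config$platform_snp_keep_i, assay_i, causal_i, beta_i,
                        20L)
  study_j <- make_study(study_ids[2], tissues[2], config$n_individuals_j,
                        config$platform_snp_keep_j, assay_j, causal_j, beta_j,
                        120L)

  truth_rows <- function(tissue, has, causal, beta) {
    idx <- which(has)
    data.frame(gene_id = genes$gene_id[idx],
               tissue = rep(tissue, length(idx)),
               causal_variant = vt$id[causal[idx]], beta = beta[idx],
               shared_flag = shared[idx], stringsAsFactors = FALSE)
  }
  truth <- rbind(truth_rows(tissues[1], has_i, causal_i, beta_i),
                 truth_rows(tissues[2], has_j, causal_j, beta_j))
  attr(truth, "shared_genes") <- genes$gene_id[shared]

  structure(list(study_i = study_i, study_j = study_j, truth = truth,
                 annotation = list(genes = genes[, c("gene_id", "chrom", "tss")],
                                   exons = exons),
                 config = config),
            class = "eqtl_sim_pair")
}

#' @export
#' @method print eqtl_sim_pair
print.eqtl_sim_pair <- function(x, ...) {
  cat("Simulated paired-tissue eQTL data\n")
  print(x$study_i)
  print(x$study_j)
  sh <- attr(x$truth, "shared_genes")
  cat(sprintf("  shared causal variants: %d genes (pi_true = %.2f)\n",
              length(sh), x$config$pi_true))
  invisible(x)
}
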