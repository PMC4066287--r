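#' Fit a cross-study eQTL concordance model
#'
#' The central fitting function of the package. Given two raw studies that
#' share a gene annotation and an LD reference panel, it (1) maps eQTL in
#' each study by cis linear regression at a study-wide FDR, (2) harmonizes
#' the two platforms onto the common gene/exon universe, (3) determines
#' per-gene overlap of the best eSNPs both directly and through LD-proxy
#' sets, (4) summarizes directional raw overlap against its chance
#' expectation, and (5) corrects the raw overlap for the smaller study's
#' power by subsampling the larger study, yielding the power-adjusted
#' overlap fraction.
#'
#' The larger study is used as discovery (`i`) and the smaller as
#' replication (`j`); if the arguments arrive in the other order they are
#' swapped and the swap is recorded in the fit.
#'
#' @param raw_i,raw_j `raw_study` objects (see [simulate_study_pair()]).
#' @param annotation Gene annotation list (`genes`, `exons`).
#' @param panel [haplotype_panel()] LD reference for proxy matching.
#' @param fdr Study-wide FDR level for eQTL calling (default 0.05).
#' @param cis_window_bp Cis window half-width (default 1 Mb).
#' @param r2_threshold,proxy_window_bp Proxy-SNP definition: LD threshold
#'   (default 0.8) and distance window (default 100 kb).
#' @param proxy_criterion Proxy-overlap rule, see [proxy_overlap()].
#' @param power_reps Subsampling replicates for the power estimate.
#' @param power_match Replication criterion inside the power estimator.
#'   The default, `"proxy"`, scores replication with the same eSNP/proxy
#'   rule that defines the raw overlap, so the power entering the
#'   adjustment refers to the same event; `"gene"` (any significant eQTL
#'   for the gene) is the more lenient alternative.
#' @param a_j Chance-significance override; default: replication study's
#'   realized BH cutoff.
#' @param seed Seed for the subsampling draws.
#' @param adjust Set `FALSE` to skip the (comparatively expensive) power
#'   adjustment.
#' @return Object of class `eqtl_concordance` with components `study_i`,
#'   `study_j` (`eqtl_study`), `match_table`, `calls`, `overlap`
#'   (`overlap_result`), `adjustment` (`power_adjustment` or `NULL`) and
#'   `params`. Methods: `print`, `summary`, `coef`, `plot`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 300, n_individuals_i = 300,
#'                   n_individuals_j = 80, n_blocks = 30, n_haplotypes = 400,
#'                   pi_true = 0.3, seed = 5)
#' pan <- simulate_haplotype_panel(cfg)
#' sim <- simulate_study_pair(pan, cfg)
#' fit <- concordance(sim$study_i, sim$study_j, sim$annotation, pan,
#'                    power_reps = 3)
#' fit
#' coef(fit)
concordance <- function(raw_i, raw_j, annotation, panel,
                        fdr = 0.05, cis_window_bp = 1000000,
                        r2_threshold = 0.8, proxy_window_bp = 100000,
                        proxy_criterion = c("intersect", "containment"),
                        power_reps = 20, power_match = c("proxy", "gene"),
                        a_j = NULL, seed = 1, adjust = TRUE) {
  proxy_criterion <- match.arg(proxy_criterion)
  power_match <- match.arg(power_match)
  swapped <- raw_j$n_samples > raw_i$n_samples
  if (swapped) { tmp <- raw_i; raw_i <- raw_j; raw_j <- tmp }

  study_i <- call_eqtls(suppressMessages(cis_scan(raw_i, annotation,
                                                  cis_window_bp)),
                        q = fdr, study_id = raw_i$study_id,
                        tissue = raw_i$tissue, n_samples = raw_i$n_samples)
  study_j <- call_eqtls(suppressMessages(cis_scan(raw_j, annotation,
                                                  cis_window_bp)),
                        q = fdr, study_id = raw_j$study_id,
                        tissue = raw_j$tissue, n_samples = raw_j$n_samples)

  tab <- match_probes_to_genes(raw_i$probes, raw_j$probes, annotation$exons)
  genes_both <- shared_eqtl_genes(study_i, study_j, tab)
  esnps <- unique(c(best_esnp(study_i, genes_both),
                    best_esnp(study_j, genes_both)))
  pm <- build_proxy_map(panel, esnps, r2_threshold, proxy_window_bp)
  calls <- suppressMessages(
    proxy_overlap(study_i, study_j, genes_both, pm, pm, proxy_criterion))
  ov <- overlap_result(study_i, study_j, tab, calls)

  adjustment <- NULL
  if (adjust && !is.na(ov$pi_raw_i_to_j)) {
    adjustment <- adjust_pair(raw_i, study_j, ov$pi_raw_i_to_j, annotation,
                              fdr_i = fdr, a_j = a_j, n_reps = power_reps,
                              seed = seed, cis_window_bp = cis_window_bp,
                              match = power_match, panel = panel,
                              r2_threshold = r2_threshold,
                              window_bp = proxy_window_bp)
  }
  structure(list(study_i = study_i, study_j = study_j, match_table = tab,
                 calls = calls, overlap = ov, adjustment = adjustment,
                 params = list(fdr = fdr, cis_window_bp = cis_window_bp,
                               r2_threshold = r2_threshold,
                               proxy_window_bp = proxy_window_bp,
                               proxy_criterion = proxy_criterion,
                               power_reps = power_reps,
                               power_match = power_match, seed = seed),
                 swapped = swapped),
            class = "eqtl_concordance")
}

#' @export
#' @method print eqtl_concordance
print.eqtl_concordance <- function(x, ...) {
  cat(sprintf("Cross-study eQTL concordance: %s (discovery) vs %s (replication)\n",
              x$study_i$study_id, x$study_j$study_id))
  cat(sprintf("  pi_raw (i->j): %.1f%% proxy, %.1f%% direct; chance %.2f%%\n",
              100 * x$overlap$pi_raw_i_to_j,
              100 * x$overlap$pi_raw_i_to_j_direct,
              100 * x$overlap$chance_expected))
  if (!is.null(x$adjustment))
    cat(sprintf("  pi_adjusted: %.1f%% (power_j = %.2f)\n",
                100 * x$adjustment$pi_adjusted, x$adjustment$power_j))
  cat("Use summary() for the full breakdown.\n")
  invisible(x)
}

#' @export
summary.eqtl_concordance <- function(object, ...) {
  structure(list(fit = object), class = "summary.eqtl_concordance")
}

#' @export
#' @method print summary.eqtl_concordance
print.summary.eqtl_concordance <- function(x, ...) {
  f <- x$fit
  print(f$study_i); print(f$study_j)
  cat("\n"); print(f$overlap)
  if (!is.null(f$adjustment)) { cat("\n"); print(f$adjustment) }
  p <- f$params
  cat(sprintf("\nParameters: FDR %.2f, cis window %s bp, proxies r2 >= %.2f within %s bp (%s)\n",
              p$fdr, format(p$cis_window_bp, big.mark = ","), p$r2_threshold,
              format(p$proxy_window_bp, big.mark = ","), p$proxy_criterion))
  invisible(x)
}

#' @export
coef.eqtl_concordance <- function(object, ...) {
  ov <- object$overlap
  out <- c(pi_raw_i_to_j = ov$pi_raw_i_to_j,
           pi_raw_j_to_i = ov$pi_raw_j_to_i,
           pi_raw_direct_i_to_j = ov$pi_raw_i_to_j_direct,
           chance_expected = ov$chance_expected,
           pi_adjusted = NA_real_, power_j_raw = NA_real_,
           power_j = NA_real_, a_j = NA_real_)
  if (!is.null(object$adjustment)) {
    a <- object$adjustment
    out[c("pi_adjusted", "power_j_raw", "power_j", "a_j")] <-
      c(a$pi_adjusted, a$power_j_raw, a$power_j, a$a_j)
  }
  out
}

#' @export
#' @method plot eqtl_concordance
plot.eqtl_concordance <- function(x, ...) {
  ov <- x$overlap
  vals <- c(chance = 100 * ov$chance_expected,
            direct = 100 * ov$pi_raw_i_to_j_direct,
            proxy = 100 * ov$pi_raw_i_to_j,
            adjusted = if (!is.null(x$adjustment))
              100 * x$adjustment$pi_adjusted else NA_real_)
  vals <- vals[!is.na(vals)]
  graphics::barplot(vals, ylab = "overlap (% of discovery eQTL genes)",
                    main = sprintf("%s vs %s", x$study_i$study_id,
                                   x$study_j$study_id), ...)
  invisible(x)
}
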