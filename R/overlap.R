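#' Raw directional overlap fraction
#'
#' The observed overlap fraction pi_raw in a given direction: the number of
#' overlapping eQTL genes divided by the number of eQTL genes of the
#' *directing* study, both restricted to the harmonized gene universe.
#' Reported in both directions because the two studies rarely have equal
#' power.
#'
#' @param calls Per-gene overlap calls from [proxy_overlap()] or
#'   [direct_esnp_overlap()].
#' @param study_i,study_j `eqtl_study` objects.
#' @param table The [match_probes_to_genes()] universe.
#' @param direction `"i_to_j"`: fraction of study i's eQTL genes overlapping
#'   in j; `"j_to_i"` the converse.
#' @param method Count `"proxy"` or `"direct"` matches.
#' @return A fraction in `[0, 1]`, or `NA` when the directing study has no
#'   eQTL genes in the universe (undefined, not 0).
#' @export
pi_raw <- function(calls, study_i, study_j, table,
                   direction = c("i_to_j", "j_to_i"),
                   method = c("proxy", "direct")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  directing <- if (direction == "i_to_j") study_i else study_j
  denom <- length(intersect(directing$sig_genes, table$gene_id))
  if (denom == 0L) {
    message("pi_raw undefined: directing study has no eQTL genes in the universe")
    return(NA_real_)
  }
  k <- sum(if (method == "proxy") calls$proxy_match else calls$direct_match)
  k / denom
}

#' Chance-expected overlap under the no-sharing null
#'
#' If eQTL occurrence were independent between the two studies, the expected
#' fraction of genes with an eQTL in both is simply the product of the two
#' per-study eQTL proportions (fraction of tested probes with an eQTL). With
#' proportions 0.33 and 0.05 this gives 0.0165, i.e. about 1.6%.
#'
#' @param prop_eqtl_i,prop_eqtl_j Per-study proportions in `[0, 1]`.
#' @return Their product.
#' @export
#' @examples
#' chance_overlap(0.33, 0.05)  # 0.0165
chance_overlap <- function(prop_eqtl_i, prop_eqtl_j) {
  check_fraction(prop_eqtl_i, "prop_eqtl_i")
  check_fraction(prop_eqtl_j, "prop_eqtl_j")
  prop_eqtl_i * prop_eqtl_j
}

#' One-sided enrichment test of observed overlap against chance
#'
#' Upper-tail binomial test: the probability of observing at least
#' `k_overlap` overlapping genes among `n_genes` under the chance rate.
#' The binomial form is a pragmatic choice for a null of independent eQTL
#' occurrence; it is recorded in the result metadata of [overlap_result()].
#'
#' @param k_overlap Observed overlapping gene count.
#' @param n_genes Number of genes at risk (the harmonized universe).
#' @param chance_rate Expected per-gene overlap probability under the null.
#' @return One-sided p-value `P(X >= k)`.
#' @export
overlap_enrichment_test <- function(k_overlap, n_genes, chance_rate) {
  stopifnot(k_overlap >= 0, k_overlap <= n_genes)
  check_fraction(chance_rate, "chance_rate")
  stats::pbinom(k_overlap - 1, size = n_genes, prob = chance_rate,
                lower.tail = FALSE)
}

#' Assemble the pairwise overlap summary
#'
#' Bundles the gene-universe counts, directional raw overlap fractions
#' (proxy and direct), the chance expectation and its enrichment test into
#' one result object. The chance expectation uses each study's eQTL
#' proportion *within the harmonized universe*, and the enrichment test is
#' applied to the gene-level co-occurrence count (genes with an eQTL in both
#' studies), the quantity the independence null actually constrains.
#'
#' @param study_i,study_j `eqtl_study` objects.
#' @param table [match_probes_to_genes()] universe.
#' @param calls Overlap calls from [proxy_overlap()].
#' @return Object of class `overlap_result`.
#' @export
overlap_result <- function(study_i, study_j, table, calls) {
  n_common <- attr(table, "n_common_genes") %||% nrow(table)
  gi <- intersect(study_i$sig_genes, table$gene_id)
  gj <- intersect(study_j$sig_genes, table$gene_id)
  n_shared <- length(intersect(gi, gj))
  prop_i <- length(gi) / n_common
  prop_j <- length(gj) / n_common
  chance <- chance_overlap(prop_i, prop_j)
  res <- list(
    study_i = study_i$study_id, study_j = study_j$study_id,
    n_common_genes = n_common,
    n_genes_eqtl_i = length(gi), n_genes_eqtl_j = length(gj),
    n_shared_eqtl_genes = n_shared,
    n_overlap_direct = sum(calls$direct_match),
    n_overlap_proxy = sum(calls$proxy_match),
    pi_raw_i_to_j = pi_raw(calls, study_i, study_j, table, "i_to_j", "proxy"),
    pi_raw_j_to_i = pi_raw(calls, study_i, study_j, table, "j_to_i", "proxy"),
    pi_raw_i_to_j_direct = pi_raw(calls, study_i, study_j, table, "i_to_j",
                                  "direct"),
    pi_raw_j_to_i_direct = pi_raw(calls, study_i, study_j, table, "j_to_i",
                                  "direct"),
    prop_eqtl_i = prop_i, prop_eqtl_j = prop_j,
    chance_expected = chance,
    enrichment_p = overlap_enrichment_test(n_shared, n_common, chance),
    enrichment_test = "one-sided binomial upper tail on gene-level co-occurrence",
    mean_shared_r2 = mean(calls$best_shared_r2[calls$proxy_match], na.rm = TRUE),
    # Table-style descriptive summaries of the overlapping eQTL
    mean_overlap_snps = if (any(calls$proxy_match) &&
                            !is.null(calls$n_shared_proxies))
      mean(calls$n_shared_proxies[calls$proxy_match]) else NA_real_,
    mean_esnp_distance_kb = {
      ov_genes <- calls$gene_id[calls$proxy_match]
      r <- study_i$records
      d <- abs(r$distance_to_tss[r$gene_id %in% ov_genes])
      if (length(d)) mean(d) / 1000 else NA_real_
    }
  )
  class(res) <- "overlap_result"
  res
}

#' @export
#' @method print overlap_result
print.overlap_result <- function(x, ...) {
  cat(sprintf("eQTL overlap %s vs %s (harmonized universe: %d genes)\n",
              x$study_i, x$study_j, x$n_common_genes))
  cat(sprintf("  eQTL genes: %d (i), %d (j); in both: %d\n",
              x$n_genes_eqtl_i, x$n_genes_eqtl_j, x$n_shared_eqtl_genes))
  cat(sprintf("  overlapping eQTL: %d proxy (%d direct)\n",
              x$n_overlap_proxy, x$n_overlap_direct))
  cat(sprintf("  pi_raw i->j: %.1f%% proxy (%.1f%% direct); j->i: %.1f%% (%.1f%%)\n",
              100 * x$pi_raw_i_to_j, 100 * x$pi_raw_i_to_j_direct,
              100 * x$pi_raw_j_to_i, 100 * x$pi_raw_j_to_i_direct))
  cat(sprintf("  chance expectation %.2f%%; enrichment p = %.3g (%s)\n",
              100 * x$chance_expected, x$enrichment_p, x$enrichment_test))
  invisible(x)
}
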