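make_calls <- function(genes, proxy, direct = rep(FALSE, length(genes))) {
  data.frame(gene_id = genes, esnp_i = "a", esnp_j = "b",
             direct_match = direct, proxy_match = proxy,
             best_shared_r2 = ifelse(proxy, 0.9, NA_real_))
}

test_that("pi_raw divides overlap counts by the directing study's eQTL genes", {
  tab <- structure(data.frame(gene_id = sprintf("g%03d", 1:200)),
                   n_common_genes = 200L)
  si <- mock_study(sprintf("g%03d", 1:100))
  sj <- mock_study(sprintf("g%03d", 51:100))
  calls <- make_calls(sprintf("g%03d", 51:60), proxy = rep(TRUE, 10))
  expect_equal(pi_raw(calls, si, sj, tab, "i_to_j", "proxy"), 0.10)
  expect_equal(pi_raw(calls, si, sj, tab, "j_to_i", "proxy"), 0.20)
  expect_equal(pi_raw(calls, si, sj, tab, "i_to_j", "direct"), 0)
  empty <- mock_study(character(0))
  expect_message(v <- pi_raw(calls, empty, sj, tab, "i_to_j", "proxy"),
                 "undefined")
  expect_true(is.na(v))
})

test_that("identical studies overlap completely under the proxy method", {
  out <- .shared
  fit <- suppressWarnings(concordance(out$sim$study_i, out$sim$study_i,
                                      out$sim$annotation, out$panel,
                                      adjust = FALSE))
  expect_equal(fit$overlap$pi_raw_i_to_j, 1)
  expect_equal(fit$overlap$pi_raw_j_to_i, 1)
  expect_equal(fit$overlap$pi_raw_i_to_j_direct, 1)
})

test_that("chance overlap is the product of the eQTL proportions", {
  expect_equal(chance_overlap(0.33, 0.05), 0.0165)
  expect_equal(chance_overlap(0.4, 0), 0)
  expect_equal(chance_overlap(1, 1), 1)
  expect_error(chance_overlap(1.2, 0.5), "prop_eqtl_i")
  expect_error(chance_overlap(0.5, -0.1), "prop_eqtl_j")
  # symmetric, monotone, bounded by either argument
  expect_equal(chance_overlap(0.2, 0.7), chance_overlap(0.7, 0.2))
  expect_lt(chance_overlap(0.2, 0.3), chance_overlap(0.2, 0.5))
  expect_lte(chance_overlap(0.2, 0.7), 0.2)
})

test_that("the enrichment test is an exact binomial upper tail", {
  expect_equal(overlap_enrichment_test(0, 100, 0.3), 1)
  expect_equal(overlap_enrichment_test(10, 10, 0.5), 2^-10)
  # at the null expectation the p-value hovers near 1/2
  p <- overlap_enrichment_test(3000, 10000, 0.3)
  expect_gt(p, 0.3); expect_lt(p, 0.7)
  expect_error(overlap_enrichment_test(5, 4, 0.1))
})

test_that("enrichment p-values are well calibrated under a binomial null", {
  set.seed(8)
  k <- stats::rbinom(400, 300, 0.12)
  p <- vapply(k, overlap_enrichment_test, numeric(1), n_genes = 300,
              chance_rate = 0.12)
  # discrete upper-tail p-values are stochastically >= uniform
  expect_gte(mean(p), 0.45)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("gene-level co-occurrence matches the chance product when tissues are independent", {
  cfg <- sim_config(n_genes = 3000, pi_true = 0, frac_null = 0.5,
                    tissue_coupling = "independent",
                    n_individuals_i = 400, n_individuals_j = 400,
                    seed = 23L)
  out <- make_sim(cfg)
  fit <- suppressWarnings(concordance(out$sim$study_i, out$sim$study_j,
                                      out$sim$annotation, out$panel,
                                      adjust = FALSE))
  ov <- fit$overlap
  n <- as.numeric(ov$n_common_genes)
  gi <- as.numeric(ov$n_genes_eqtl_i); gj <- as.numeric(ov$n_genes_eqtl_j)
  # conditional on the margins, the overlap count is hypergeometric
  expected <- gi * gj / n
  sd_hyper <- sqrt(gi * gj * (n - gi) * (n - gj) / (n^2 * (n - 1)))
  expect_lt(abs(ov$n_shared_eqtl_genes - expected), 3 * sd_hyper)
  # the proxy-matched overlap is a strict subset of co-occurrence
  expect_lte(ov$n_overlap_proxy, ov$n_shared_eqtl_genes)
  # and the enrichment test finds nothing surprising
  expect_gt(ov$enrichment_p, 0.01)
})

test_that("overlap_result satisfies its count orderings on simulated data", {
  out <- .shared
  fit <- suppressWarnings(concordance(out$sim$study_i, out$sim$study_j,
                                      out$sim$annotation, out$panel,
                                      adjust = FALSE))
  ov <- fit$overlap
  expect_lte(ov$n_overlap_direct, ov$n_overlap_proxy)
  expect_lte(ov$n_overlap_proxy, ov$n_shared_eqtl_genes)
  expect_gte(ov$pi_raw_i_to_j, ov$pi_raw_i_to_j_direct)
  expect_gte(ov$pi_raw_j_to_i, ov$pi_raw_j_to_i_direct)
  expect_output(print(ov), "chance expectation")
})
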