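test_that("identical platforms match every annotated gene", {
  sim <- .shared$sim
  tab <- match_probes_to_genes(sim$study_i$probes, sim$study_i$probes,
                               sim$annotation$exons)
  expect_equal(attr(tab, "n_common_genes"), nrow(sim$study_i$probes))
  expect_true(all(tab$probe_i == tab$probe_j))
})

test_that("matched-gene count tracks the configured probe overlap", {
  cfg <- small_cfg(n_genes = 1000, probe_overlap_frac = 0.5, seed = 19L)
  sim <- make_sim(cfg)$sim
  tab <- match_probes_to_genes(sim$study_i$probes, sim$study_j$probes,
                               sim$annotation$exons)
  expect_lt(abs(attr(tab, "n_common_genes") - 500),
            3 * sqrt(1000 * 0.5 * 0.5))
})

test_that("probes outside exons or spanning several genes are dropped", {
  exons <- data.frame(gene_id = c("g1", "g2"), exon_id = c("e1", "e2"),
                      chrom = "1", start = c(100L, 140L), end = c(200L, 260L))
  probes_i <- data.frame(
    probe_id = c("pi1", "pi2", "pi3"), chrom = "1",
    start = c(110L, 500L, 150L), end = c(160L, 550L, 190L))
  # pi1 only in e1; pi2 in no exon; pi3 inside both e1 and e2 -> ambiguous
  probes_j <- data.frame(probe_id = "pj1", chrom = "1",
                         start = 120L, end = 170L)
  expect_message(tab <- match_probes_to_genes(probes_i, probes_j, exons),
                 "multiple genes")
  expect_equal(tab$gene_id, "g1")
  expect_equal(tab$probe_i, "pi1")
})

test_that("when several probes qualify the smallest span is retained", {
  exons <- data.frame(gene_id = "g1", exon_id = "e1", chrom = "1",
                      start = 0L, end = 1000L)
  probes_i <- data.frame(probe_id = c("wide", "narrow"), chrom = "1",
                         start = c(10L, 20L), end = c(500L, 70L))
  probes_j <- data.frame(probe_id = "pj", chrom = "1", start = 5L, end = 55L)
  tab <- match_probes_to_genes(probes_i, probes_j, exons)
  expect_equal(tab$probe_i, "narrow")
})

test_that("shared eQTL genes are the harmonized intersection", {
  tab <- structure(data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5")),
                   n_common_genes = 5L)
  si <- mock_study(c("g1", "g2", "g3"))
  sj <- mock_study(c("g2", "g3", "g4"))
  expect_setequal(shared_eqtl_genes(si, sj, tab), c("g2", "g3"))
  expect_length(shared_eqtl_genes(mock_study("g1"), mock_study("g9"), tab), 0)
  expect_setequal(shared_eqtl_genes(si, si, tab), c("g1", "g2", "g3"))
})

test_that("direct overlap compares eSNP identifiers gene by gene", {
  si <- mock_study(c("g1", "g2", "g3"), esnps = c("s1", "s2", "s3"))
  sj <- mock_study(c("g1", "g2", "g3"), esnps = c("s1", "sX", "sY"))
  calls <- direct_esnp_overlap(si, sj, c("g1", "g2", "g3"))
  expect_equal(sum(calls$direct_match), 1L)
  expect_true(calls$direct_match[calls$gene_id == "g1"])
  expect_identical(calls$direct_match, calls$proxy_match)
  expect_equal(nrow(direct_esnp_overlap(si, sj, character(0))), 0L)
})

test_that("proxy overlap finds matches that direct comparison misses", {
  # two SNPs in perfect LD but with different ids
  H <- cbind(rep(c(0L, 1L), 50), rep(c(0L, 1L), 50), rbinom(100, 1, 0.4))
  pan <- panel_from_matrix(H, pos = c(1000L, 2000L, 50000L))
  si <- mock_study("g1", esnps = "v01")
  sj <- mock_study("g1", esnps = "v02")
  pm <- build_proxy_map(pan, c("v01", "v02"), 0.8, 1e5)
  calls <- proxy_overlap(si, sj, "g1", pm, pm)
  expect_false(calls$direct_match)
  expect_true(calls$proxy_match)
  expect_equal(calls$best_shared_r2, 1)
  expect_equal(calls$n_shared_proxies, 2L)  # v01 and v02 themselves
  # the containment criterion agrees here (v02 is in proxies(v01))
  calls2 <- proxy_overlap(si, sj, "g1", pm, pm, criterion = "containment")
  expect_true(calls2$proxy_match)
})

test_that("eSNPs in unlinked blocks never proxy-match", {
  set.seed(2)
  H <- cbind(rbinom(200, 1, 0.3), rbinom(200, 1, 0.3))
  pan <- panel_from_matrix(H, pos = c(1000L, 5000L))
  si <- mock_study("g1", esnps = "v01")
  sj <- mock_study("g1", esnps = "v02")
  pm <- build_proxy_map(pan, c("v01", "v02"), 0.8, 1e5)
  calls <- proxy_overlap(si, sj, "g1", pm, pm)
  expect_false(calls$proxy_match)
  expect_true(is.na(calls$best_shared_r2))
})

test_that("direct matches always imply proxy matches on simulated pairs", {
  out <- .shared
  fit <- suppressWarnings(concordance(out$sim$study_i, out$sim$study_j,
                                      out$sim$annotation, out$panel,
                                      adjust = FALSE))
  calls <- fit$calls
  expect_true(all(!calls$direct_match | calls$proxy_match))
  expect_gte(sum(calls$proxy_match), sum(calls$direct_match))
})
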