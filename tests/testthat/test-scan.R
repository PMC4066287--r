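# Assemble a raw_study by hand from explicit matrices.
toy_study <- function(G, E, pos, gene_tss, id = "toy") {
  vn <- sprintf("v%02d", seq_len(nrow(G)))
  pn <- names(gene_tss)
  rownames(G) <- vn
  colnames(G) <- colnames(E) <- sprintf("ind%02d", seq_len(ncol(G)))
  rownames(E) <- paste0("pr_", pn)
  structure(list(study_id = id, tissue = NA,
                 genotypes = G,
                 variants = data.frame(id = vn, chrom = "1", pos = pos),
                 expression = E,
                 probes = data.frame(probe_id = paste0("pr_", pn),
                                     gene_id = pn, chrom = "1",
                                     start = gene_tss, end = gene_tss + 50),
                 n_samples = ncol(G)),
            class = "raw_study")
}
toy_annotation <- function(gene_tss) {
  list(genes = data.frame(gene_id = names(gene_tss), chrom = "1",
                          tss = unname(gene_tss)))
}

test_that("a noiseless linear relation is fit exactly", {
  dos <- matrix(rep(c(0, 1, 2, 1, 0, 2, 1, 2, 0, 1), 1), nrow = 1)
  st <- toy_study(dos, 2 * dos, pos = 500L, gene_tss = c(g1 = 400L))
  rec <- cis_scan(st, toy_annotation(c(g1 = 400L)))
  expect_equal(rec$beta, 2)
  expect_lt(rec$p_value, 1e-12)
})

test_that("the six-point toy dataset matches closed-form OLS", {
  dos <- matrix(c(0, 0, 1, 1, 2, 2), nrow = 1)
  y <- matrix(c(0.1, -0.2, 0.9, 1.1, 2.2, 1.9), nrow = 1)
  st <- toy_study(dos, y, pos = 100L, gene_tss = c(g1 = 100L))
  rec <- cis_scan(st, toy_annotation(c(g1 = 100L)))
  fit <- summary(stats::lm(as.vector(y) ~ as.vector(dos)))$coefficients
  expect_equal(rec$beta, 1.05)
  expect_equal(rec$beta, unname(fit[2, 1]), tolerance = 1e-12)
  expect_equal(rec$t_stat, unname(fit[2, 3]), tolerance = 1e-10)
  expect_equal(rec$p_value, unname(fit[2, 4]), tolerance = 1e-10)
})

test_that("monomorphic variants and zero-variance probes are skipped", {
  G <- rbind(rep(1, 8), c(0, 1, 2, 0, 1, 2, 0, 1))
  E <- rbind(stats::rnorm(8), rep(3, 8))
  st <- toy_study(G, E, pos = c(100L, 200L),
                  gene_tss = c(g1 = 100L, g2 = 150L))
  expect_warning(
    expect_message(rec <- cis_scan(st, toy_annotation(c(g1 = 100L, g2 = 150L))),
                   "monomorphic"),
    "zero-variance")
  expect_true(all(rec$variant_id == "v02"))
  expect_true(all(rec$gene_id == "g1"))
})

test_that("the cis window boundary is inclusive at exactly window_bp", {
  G <- rbind(c(0, 1, 2, 0, 1, 2), c(0, 2, 1, 1, 0, 2))
  E <- matrix(stats::rnorm(6), nrow = 1)
  tss <- 2e6
  st <- toy_study(G, E, pos = c(tss - 1e6, tss - 1e6 - 1),
                  gene_tss = c(g1 = tss))
  rec <- cis_scan(st, toy_annotation(c(g1 = tss)), cis_window_bp = 1e6)
  expect_equal(rec$variant_id, "v01")
  expect_equal(rec$distance_to_tss, -1e6)
})

test_that("slope tests agree with lm() on random small samples", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(5:50, 1)
    x <- stats::rbinom(n, 2, runif(1, 0.2, 0.5))
    if (stats::var(x) == 0) next
    y <- 0.4 * x + stats::rnorm(n)
    st <- toy_study(matrix(x, 1), matrix(y, 1), pos = 100L,
                    gene_tss = c(g1 = 100L))
    rec <- cis_scan(st, toy_annotation(c(g1 = 100L)))
    fit <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(rec$beta, unname(fit[2, 1]), tolerance = 1e-10)
    expect_equal(rec$p_value, unname(fit[2, 4]), tolerance = 1e-8)
  }
})

test_that("missing individual overlap and tiny samples raise errors", {
  st <- toy_study(matrix(c(0, 1, 2, 1), 1), matrix(rnorm(4), 1),
                  pos = 100L, gene_tss = c(g1 = 100L))
  colnames(st$expression) <- paste0("other", 1:4)
  expect_error(cis_scan(st, toy_annotation(c(g1 = 100L))), "overlapping")
  st2 <- toy_study(matrix(c(0, 1), 1), matrix(rnorm(2), 1),
                   pos = 100L, gene_tss = c(g1 = 100L))
  expect_error(cis_scan(st2, toy_annotation(c(g1 = 100L))), "3 individuals")
})

test_that("cis/trans labels follow the inclusive 1 Mb rule", {
  ann <- toy_annotation(c(g1 = 5e6))
  expect_equal(classify_cis_trans("g1", "1", 5e6, ann), "cis")
  expect_equal(classify_cis_trans("g1", "1", 6e6, ann), "cis")       # exactly 1 Mb
  expect_equal(classify_cis_trans("g1", "1", 6e6 + 1, ann), "trans") # 1 Mb + 1
  expect_equal(classify_cis_trans("g1", "2", 5e6, ann), "trans")     # other chrom
  expect_error(classify_cis_trans("gX", "1", 1, ann), "unknown gene")
})

test_that("weighted-Z meta-analysis combines cohorts as specified", {
  expect_equal(weighted_z_meta(1.7, 120), 1.7)
  expect_equal(weighted_z_meta(c(2, 2), c(100, 100)), 2 * sqrt(2),
               tolerance = 1e-6)
  expect_equal(weighted_z_meta(c(2, -2), c(100, 100)), 0)
  expect_error(weighted_z_meta(c(1, 2), 100), "equal length")
  expect_error(weighted_z_meta(c(1, 2), c(100, -5)), "sample sizes")
})

test_that("meta_scan reproduces the weighted-Z combination of per-cohort scans", {
  set.seed(11)
  x1 <- matrix(stats::rbinom(40, 2, 0.4), 1); x2 <- matrix(stats::rbinom(60, 2, 0.4), 1)
  y1 <- 0.8 * x1 + stats::rnorm(40); y2 <- 0.8 * x2 + stats::rnorm(60)
  ann <- toy_annotation(c(g1 = 100L))
  c1 <- toy_study(x1, y1, 100L, c(g1 = 100L), id = "c1")
  c2 <- toy_study(x2, y2, 100L, c(g1 = 100L), id = "c2")
  meta <- meta_scan(list(c1, c2), ann)
  r1 <- cis_scan(c1, ann); r2 <- cis_scan(c2, ann)
  z <- vapply(list(r1, r2), function(r)
    sign(r$beta) * stats::qnorm(r$p_value / 2, lower.tail = FALSE), numeric(1))
  expect_equal(meta$z, weighted_z_meta(z, c(40, 60)), tolerance = 1e-8)
  expect_equal(meta$n, 100)
})
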