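# Shared fixtures built in code: a small simulated study pair for fast unit
# tests, plus independent oracles used across files.

# Unit-test scale: few genes/blocks, strong effects so even n ~ 50 subsamples
# carry signal.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 200, n_individuals_i = 150, n_individuals_j = 60,
         n_blocks = 20, n_haplotypes = 400, effect_beta = 1,
         seed = 101L),
    list(...))
  do.call(sim_config, args)
}

make_sim <- function(cfg) {
  panel <- simulate_haplotype_panel(cfg)
  sim <- simulate_study_pair(panel, cfg)
  list(panel = panel, sim = sim)
}

# cached default small simulation, shared across tests that only read it
.shared <- local({
  cfg <- small_cfg(pi_true = 0.3)
  c(make_sim(cfg), list(cfg = cfg))
})

# --- independent oracles -------------------------------------------------

# Brute-force BH step-up straight from its definition.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  if (!is.finite(k)) return(list(reject = rep(FALSE, m), cutoff = 0))
  list(reject = p <= ps[k], cutoff = ps[k])
}

# LD r2 by direct haplotype-frequency counting on two 0/1 vectors.
r2_oracle <- function(x, y) {
  pa <- mean(x); pb <- mean(y); pab <- mean(x == 1 & y == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Build a tiny panel directly from a haplotype matrix.
panel_from_matrix <- function(H, pos = NULL) {
  v <- data.frame(id = sprintf("v%02d", seq_len(ncol(H))), chrom = "1",
                  pos = pos %||% (seq_len(ncol(H)) * 1000L),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  colnames(H) <- v$id
  haplotype_panel(v, H)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal eqtl_study stand-in for set-logic tests.
mock_study <- function(genes, esnps = NULL, id = "mock", n = 100) {
  if (is.null(esnps))
    esnps <- if (length(genes)) paste0("snp_", genes) else character(0)
  rec <- data.frame(gene_id = genes,
                    variant_id = esnps,
                    p_value = rep(1e-6, length(genes)),
                    distance_to_tss = rep(0, length(genes)),
                    stringsAsFactors = FALSE)
  structure(list(study_id = id, tissue = NA, n_samples = n, records = rec,
                 sig_genes = genes, n_probes_tested = length(genes),
                 n_genes_with_eqtl = length(genes),
                 n_tests = 10 * length(genes), n_sig_pairs = length(genes),
                 fdr_level = 0.05, realized_cutoff = 1e-4),
            class = "eqtl_study")
}
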