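#' Directional raw-overlap matrix for several studies
#'
#' Calls eQTL once per study, then evaluates proxy overlap for every ordered
#' study pair. Entry `[d, r]` is the fraction of discovery study `d`'s eQTL
#' genes (within the pairwise harmonized universe) overlapping in replication
#' study `r`; the diagonal is empty.
#'
#' @param studies Named list of `raw_study` objects sharing `annotation` and
#'   `panel`.
#' @param annotation,panel As in [concordance()].
#' @param fdr,cis_window_bp,r2_threshold,proxy_window_bp As in
#'   [concordance()].
#' @return list with `matrix` (directional proxy pi_raw, `NA` diagonal) and
#'   `pairs`, a long data.frame (`discovery`, `replication`, `pi_raw`,
#'   `pi_raw_direct`, `n_overlap_proxy`, `n_overlap_direct`,
#'   `n_common_genes`).
#' @export
pairwise_overlap <- function(studies, annotation, panel, fdr = 0.05,
                             cis_window_bp = 1000000, r2_threshold = 0.8,
                             proxy_window_bp = 100000) {
  stopifnot(length(studies) >= 2L)
  ids <- vapply(studies, `[[`, character(1), "study_id")
  names(studies) <- ids
  called <- lapply(studies, function(s)
    call_eqtls(suppressMessages(cis_scan(s, annotation, cis_window_bp)),
               q = fdr, study_id = s$study_id, tissue = s$tissue,
               n_samples = s$n_samples))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    sa <- called[[a]]; sb <- called[[b]]
    tab <- match_probes_to_genes(studies[[a]]$probes, studies[[b]]$probes,
                                 annotation$exons)
    genes_both <- shared_eqtl_genes(sa, sb, tab)
    esnps <- unique(c(best_esnp(sa, genes_both), best_esnp(sb, genes_both)))
    pm <- build_proxy_map(panel, esnps, r2_threshold, proxy_window_bp)
    calls <- suppressMessages(proxy_overlap(sa, sb, genes_both, pm, pm))
    for (dir in c("i_to_j", "j_to_i")) {
      d <- if (dir == "i_to_j") a else b
      r <- if (dir == "i_to_j") b else a
      m[d, r] <- pi_raw(calls, sa, sb, tab, dir, "proxy")
      rows[[length(rows) + 1L]] <- data.frame(
        discovery = ids[d], replication = ids[r],
        pi_raw = m[d, r],
        pi_raw_direct = pi_raw(calls, sa, sb, tab, dir, "direct"),
        n_overlap_proxy = sum(calls$proxy_match),
        n_overlap_direct = sum(calls$direct_match),
        n_common_genes = attr(tab, "n_common_genes"),
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = m, pairs = do.call(rbind, rows))
}

#' Mean overlap within versus between study subgroups
#'
#' Groups directional overlap values by whether the two studies carry the
#' same label (e.g. tissue or diagnosis) and reports the two group means —
#' the generic form of "same-region versus different-region" contrasts.
#'
#' @param pairs data.frame from [pairwise_overlap()]`$pairs` (needs
#'   `discovery`, `replication`, `pi_raw`).
#' @param labels Named character vector mapping study id to label.
#' @return list with `same_label` and `different_label` (mean, n_pairs; the
#'   mean is `NA` when a group has no pair).
#' @export
subgroup_overlap <- function(pairs, labels) {
  if (length(unique(c(pairs$discovery, pairs$replication))) < 2L)
    stop("need at least two labelled studies", call. = FALSE)
  miss <- setdiff(unique(c(pairs$discovery, pairs$replication)), names(labels))
  if (length(miss))
    stop(sprintf("missing label(s) for: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  same <- labels[pairs$discovery] == labels[pairs$replication]
  grp <- function(sel) list(
    mean = if (any(sel)) mean(pairs$pi_raw[sel], na.rm = TRUE) else NA_real_,
    n_pairs = sum(sel))
  list(same_label = grp(same), different_label = grp(!same))
}

#' Write a study's called eQTL as a summary TSV
#'
#' One row per eQTL gene (best eSNP), in the tab-delimited layout the rest
#' of the pipeline consumes: study_id, gene_id, probe_id, esnp_id, chrom,
#' pos, tss, distance_bp, beta, p_value, cis_trans, n_samples.
#'
#' @param study An `eqtl_study` from [call_eqtls()].
#' @param annotation Gene annotation list (for the cis/trans label).
#' @param path Output TSV.
#' @param cis_window_bp Window used for the cis/trans label.
#' @return `path`, invisibly.
#' @export
write_eqtl_summary <- function(study, annotation, path,
                               cis_window_bp = 1000000) {
  r <- study$records
  out <- data.frame(study_id = study$study_id, gene_id = r$gene_id,
                    probe_id = r$probe_id, esnp_id = r$variant_id,
                    chrom = r$chrom, pos = r$pos, tss = r$tss,
                    distance_bp = r$distance_to_tss, beta = r$beta,
                    p_value = r$p_value,
                    cis_trans = classify_cis_trans(r$gene_id, r$chrom, r$pos,
                                                   annotation, cis_window_bp),
                    n_samples = study$n_samples, stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(fdr = 0.05, cis_window_bp = 1000000, r2_threshold = 0.8,
       proxy_window_bp = 100000, power_reps = 20, power_match = "gene",
       proxy_criterion = "intersect", seed = 1L, write_fixtures = FALSE)
}

load_raw_study <- function(spec) {
  geno <- read_matrix_tsv(spec$genotypes)
  v <- utils::read.table(spec$variants, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"chrom" %in% names(v)) v$chrom <- "1"  # panel.tsv dialect
  v <- v[match(rownames(geno), v$id), c("id", "chrom", "pos")]
  if (anyNA(v$id))
    stop(sprintf("variants file '%s' is missing genotyped variant ids",
                 spec$variants), call. = FALSE)
  structure(list(study_id = spec$study_id,
                 tissue = spec$tissue %||% NA_character_,
                 genotypes = geno,
                 variants = v,
                 expression = read_matrix_tsv(spec$expression),
                 probes = utils::read.table(spec$probes, header = TRUE,
                                            sep = "\t",
                                            stringsAsFactors = FALSE),
                 n_samples = ncol(geno)),
            class = "raw_study")
}

#' Run the full concordance pipeline from a declarative config
#'
#' Executes simulate (optional) -> map -> harmonize -> overlap -> adjust and
#' writes a report bundle: a pairwise overlap table, a power-adjustment
#' table, a directional overlap matrix when more than two studies are
#' analysed, and a YAML run log with all effective parameters, the seed and
#' the realized per-study FDR cutoffs. Reports are deterministic: rerunning
#' with the same config yields byte-identical files.
#'
#' @param config A list, or path to a YAML file, with entries `output_dir`,
#'   either `simulate` (fields of [sim_config()]) or `inputs` (`panel`,
#'   `panel_format`, `annotation`, and `studies`, a list of per-study file
#'   sets: `study_id`, `tissue`, `genotypes`, `expression`, `probes`,
#'   `variants`), plus optional overrides of `fdr` (0.05),
#'   `cis_window_bp` (1e6), `r2_threshold` (0.8), `proxy_window_bp` (1e5),
#'   `power_reps`, `power_match`, `seed`.
#' @return list with the `eqtl_concordance` fit of the first study pair,
#'   `pairwise` (for >2 studies, else `NULL`), and `reports` (paths),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$output_dir)) stop("config needs 'output_dir'", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    panel <- simulate_haplotype_panel(scfg)
    sim <- simulate_study_pair(panel, scfg)
    studies <- list(sim$study_i, sim$study_j)
    annotation <- sim$annotation
    if (isTRUE(cfg$write_fixtures))
      write_fixture_set(sim, panel, file.path(cfg$output_dir, "fixtures"))
  } else if (!is.null(cfg$inputs)) {
    panel <- read_haplotypes(cfg$inputs$panel,
                             cfg$inputs$panel_format %||% "vcf")
    annotation <- read_gene_annotation(cfg$inputs$annotation)
    studies <- lapply(cfg$inputs$studies, load_raw_study)
  } else stop("config needs either 'simulate' or 'inputs'", call. = FALSE)

  fit <- concordance(studies[[1]], studies[[2]], annotation, panel,
                     fdr = cfg$fdr, cis_window_bp = cfg$cis_window_bp,
                     r2_threshold = cfg$r2_threshold,
                     proxy_window_bp = cfg$proxy_window_bp,
                     proxy_criterion = cfg$proxy_criterion,
                     power_reps = cfg$power_reps,
                     power_match = cfg$power_match, seed = cfg$seed)

  pw <- if (length(studies) > 2L)
    pairwise_overlap(studies, annotation, panel, cfg$fdr, cfg$cis_window_bp,
                     cfg$r2_threshold, cfg$proxy_window_bp) else NULL

  p <- function(f) file.path(cfg$output_dir, f)
  ov <- fit$overlap
  pct <- function(x) round(100 * x, 1)
  reports <- character(0)
  overlap_tab <- data.frame(
    study_i = ov$study_i, study_j = ov$study_j,
    n_common_genes = ov$n_common_genes,
    n_overlap_proxy = ov$n_overlap_proxy,
    n_overlap_direct = ov$n_overlap_direct,
    pct_i_with_overlap_in_j = pct(ov$pi_raw_i_to_j),
    pct_j_with_overlap_in_i = pct(ov$pi_raw_j_to_i),
    pct_i_to_j_direct = pct(ov$pi_raw_i_to_j_direct),
    pct_chance_expected = pct(ov$chance_expected),
    enrichment_p = signif(ov$enrichment_p, 3),
    mean_shared_r2 = round(ov$mean_shared_r2, 3),
    mean_overlap_snps_per_gene = round(ov$mean_overlap_snps, 1),
    mean_esnp_distance_kb = round(ov$mean_esnp_distance_kb, 1))
  reports <- c(reports, write_tsv(overlap_tab, p("overlap_pairs.tsv")))
  for (st in list(fit$study_i, fit$study_j))
    reports <- c(reports,
                 write_eqtl_summary(st, annotation,
                                    p(sprintf("%s_eqtls.tsv", st$study_id)),
                                    cfg$cis_window_bp))
  if (!is.null(fit$adjustment)) {
    a <- fit$adjustment
    adj_tab <- data.frame(study_j = a$study_pair[2], n_j = a$n_j,
                          power_j_raw = round(a$power_j_raw, 3),
                          power_j_raw_se = round(a$power_j_raw_se, 4),
                          power_j = round(a$power_j, 3),
                          pct_pi_adjusted = pct(a$pi_adjusted),
                          pct_pi_raw = pct(a$pi_raw),
                          a_j = signif(a$a_j, 3), fdr_i = a$fdr_i)
    reports <- c(reports, write_tsv(adj_tab, p("adjustment.tsv")))
  }
  if (!is.null(pw)) {
    reports <- c(reports,
                 write_tsv(as.data.frame(round(100 * pw$matrix, 1)),
                           p("pairwise_matrix.tsv"), rownames = TRUE))
  }
  log <- list(package = "eqtloverlap",
              version = as.character(utils::packageVersion("eqtloverlap")),
              seed = cfg$seed,
              parameters = cfg[c("fdr", "cis_window_bp", "r2_threshold",
                                 "proxy_window_bp", "power_reps",
                                 "power_match", "proxy_criterion")],
              simulate = cfg$simulate,
              realized_cutoffs = list(study_i = fit$study_i$realized_cutoff,
                                      study_j = fit$study_j$realized_cutoff))
  yaml::write_yaml(log, p("run_log.yaml"))
  reports <- c(reports, p("run_log.yaml"))
  invisible(list(fit = fit, pairwise = pw, reports = reports, config = cfg))
}
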