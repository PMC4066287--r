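#' Cis-eQTL scan by per-pair linear regression
#'
#' For every (probe, variant) pair with the variant within `cis_window_bp` of
#' the probe's gene TSS (inclusive at the boundary), regresses expression on
#' allele dosage (additive 0/1/2 coding, no covariates) and returns the OLS
#' slope with its two-sided t-test. Variants monomorphic in the sample are
#' skipped (a message reports the count), as are zero-variance probes (with a
#' warning).
#'
#' @param study A `raw_study` (genotypes, variants, expression, probes), as
#'   produced by [simulate_study_pair()] or assembled from
#'   [read_matrix_tsv()] inputs.
#' @param annotation list with a `genes` data.frame (`gene_id`, `chrom`,
#'   `tss`), e.g. from [read_gene_annotation()].
#' @param cis_window_bp Cis window half-width around the TSS (default 1 Mb).
#' @return data.frame of association records: `gene_id`, `probe_id`,
#'   `variant_id`, `chrom`, `pos`, `tss`, `distance_to_tss` (signed
#'   `pos - tss`), `beta`, `se`, `t_stat`, `p_value`, `n`. The number of
#'   probes scanned is attached as attribute `n_probes_tested`.
#' @export
cis_scan <- function(study, annotation, cis_window_bp = 1000000) {
  stopifnot(inherits(study, "raw_study") || is.list(study))
  if (cis_window_bp <= 0) stop("cis_window_bp must be > 0", call. = FALSE)
  G <- study$genotypes
  E <- study$expression
  if (ncol(G) < 3L) stop("need at least 3 individuals", call. = FALSE)
  common <- intersect(colnames(G), colnames(E))
  if (length(common) == 0L)
    stop("no overlapping individuals between genotype and expression matrices",
         call. = FALSE)
  G <- G[, common, drop = FALSE]
  E <- E[, common, drop = FALSE]
  n <- length(common)

  genes <- annotation$genes
  probes <- study$probes
  probes <- probes[probes$probe_id %in% rownames(E), , drop = FALSE]
  tssv <- stats::setNames(genes$tss, genes$gene_id)
  chrv <- stats::setNames(genes$chrom, genes$gene_id)

  V <- study$variants
  n_mono <- 0L
  n_zero_var <- 0L
  by_chrom <- split(seq_len(nrow(V)), V$chrom)
  pos_by_chrom <- lapply(by_chrom, function(ix) V$pos[ix][order(V$pos[ix])])
  idx_by_chrom <- lapply(by_chrom, function(ix) ix[order(V$pos[ix])])

  ptss <- unname(tssv[probes$gene_id])
  pch <- unname(chrv[probes$gene_id])
  plo <- phi <- rep(NA_integer_, nrow(probes))
  for (ch in names(pos_by_chrom)) {
    sel <- which(!is.na(pch) & pch == ch)
    if (!length(sel)) next
    pos <- pos_by_chrom[[ch]]
    plo[sel] <- findInterval(ptss[sel] - cis_window_bp - 0.5, pos) + 1L
    phi[sel] <- findInterval(ptss[sel] + cis_window_bp + 0.5, pos)
  }
  usable <- which(!is.na(plo) & phi >= plo)

  # probes sharing a cis variant range are regressed in one BLAS call
  groups <- split(usable, paste(pch[usable], plo[usable], phi[usable]))
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ks <- groups[[gi]]
    ch <- pch[ks[1]]
    vix <- idx_by_chrom[[ch]][plo[ks[1]]:phi[ks[1]]]
    Y <- E[probes$probe_id[ks], , drop = FALSE]
    yc <- Y - rowMeans(Y)
    syy <- rowSums(yc^2)
    zv <- syy == 0
    n_zero_var <- n_zero_var + sum(zv)
    if (all(zv)) next
    ks <- ks[!zv]; yc <- yc[!zv, , drop = FALSE]; syy <- syy[!zv]
    X <- G[vix, , drop = FALSE]
    xc <- X - rowMeans(X)
    sxx <- rowSums(xc^2)
    ok <- sxx > 0
    n_mono <- n_mono + sum(!ok) * length(ks)
    if (!any(ok)) next
    vix <- vix[ok]; xc <- xc[ok, , drop = FALSE]; sxx <- sxx[ok]
    m <- length(vix); g <- length(ks)
    sxy <- tcrossprod(xc, yc)                   # m x g
    b <- sxy / sxx
    sse <- pmax(matrix(syy, m, g, byrow = TRUE) - sxy^2 / sxx, 0)
    se <- sqrt(sse / (n - 2L) / sxx)
    tt <- ifelse(se > 0, b / se, sign(b) * Inf)
    p <- pmax(2 * stats::pt(-abs(tt), df = n - 2L), 1e-300)
    out[[gi]] <- list(gene_id = rep(probes$gene_id[ks], each = m),
                      probe_id = rep(probes$probe_id[ks], each = m),
                      variant_id = rep.int(V$id[vix], g),
                      chrom = rep(ch, m * g),
                      pos = rep.int(V$pos[vix], g),
                      tss = rep(ptss[ks], each = m),
                      beta = as.vector(b), se = as.vector(se),
                      t_stat = as.vector(tt), p_value = as.vector(p))
  }
  if (n_zero_var > 0)
    warning(sprintf("skipped %d zero-variance expression probe(s)", n_zero_var),
            call. = FALSE)
  if (n_mono > 0)
    message(sprintf("cis_scan: skipped %d monomorphic variant test(s)", n_mono))
  out <- out[!vapply(out, is.null, logical(1))]
  rec <- if (length(out)) {
    data.frame(lapply(stats::setNames(nm = names(out[[1]])), function(f)
      unlist(lapply(out, `[[`, f), use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), probe_id = character(0),
               variant_id = character(0), chrom = character(0),
               pos = integer(0), tss = integer(0), beta = numeric(0),
               se = numeric(0), t_stat = numeric(0), p_value = numeric(0))
  }
  rec$distance_to_tss <- rec$pos - rec$tss
  rec$n <- n
  attr(rec, "n_probes_tested") <- nrow(probes)
  rec
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Returns the rejection flags at FDR level `q` and the realized p-value
#' cutoff: the largest p-value among the rejected hypotheses (0 if none) —
#' i.e. the step-up threshold `p(k)` with `k` the largest index such that
#' `p(k) <= k q / m`.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return list with `reject` (logical vector) and `cutoff`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
bh_fdr <- function(p_values, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must lie in (0, 1)", call. = FALSE)
  if (length(p_values) == 0L)
    return(list(reject = logical(0), cutoff = 0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  reject <- stats::p.adjust(p_values, method = "BH") <= q
  cutoff <- if (any(reject)) max(p_values[reject]) else 0
  list(reject = reject, cutoff = cutoff)
}

#' Call eQTL from association records at a study-wide FDR
#'
#' Applies [bh_fdr()] across all tested gene-SNP pairs of one study
#' (study-wide, not per gene). In `best_per_gene` mode the single most
#' significant record per gene is kept (the gene's eSNP), with ties broken by
#' smaller `|distance_to_tss|`, then lexicographic variant id; in
#' `all_significant` mode every significant record is retained as well.
#'
#' @param records data.frame from [cis_scan()] (or [meta_scan()]).
#' @param q Study-wide FDR level (default 0.05).
#' @param mode `"best_per_gene"` or `"all_significant"`.
#' @param study_id,tissue,n_samples Study metadata carried into the result.
#' @return An object of class `eqtl_study`: list with `records` (best eSNP
#'   per significant gene), `sig_all` (all significant pairs), `sig_genes`,
#'   counts (`n_probes_tested`, `n_genes_with_eqtl`, `n_tests`,
#'   `n_sig_pairs`), `fdr_level`, `realized_cutoff`, and the metadata.
#' @export
call_eqtls <- function(records, q = 0.05,
                       mode = c("best_per_gene", "all_significant"),
                       study_id = "study", tissue = NA_character_,
                       n_samples = if (nrow(records)) records$n[1] else NA_integer_) {
  mode <- match.arg(mode)
  fdr <- bh_fdr(records$p_value, q)
  sig <- records[fdr$reject, , drop = FALSE]
  best <- if (nrow(sig)) {
    ord <- order(sig$gene_id, sig$p_value, abs(sig$distance_to_tss),
                 sig$variant_id)
    s <- sig[ord, , drop = FALSE]
    s[!duplicated(s$gene_id), , drop = FALSE]
  } else sig
  rownames(best) <- NULL
  structure(list(study_id = study_id, tissue = tissue, n_samples = n_samples,
                 records = best,
                 sig_all = if (mode == "all_significant") sig else NULL,
                 sig_genes = unique(best$gene_id),
                 n_probes_tested = attr(records, "n_probes_tested") %||%
                   length(unique(records$probe_id)),
                 n_genes_with_eqtl = length(unique(best$gene_id)),
                 n_tests = nrow(records), n_sig_pairs = nrow(sig),
                 fdr_level = q, realized_cutoff = fdr$cutoff),
            class = "eqtl_study")
}

#' @export
#' @method print eqtl_study
print.eqtl_study <- function(x, ...) {
  cat(sprintf("eQTL study '%s' (%s), n = %s\n", x$study_id, x$tissue,
              x$n_samples))
  cat(sprintf("  %d / %d probes with an eQTL at study-wide FDR %.2f (%.1f%%)\n",
              x$n_genes_with_eqtl, x$n_probes_tested, x$fdr_level,
              100 * x$n_genes_with_eqtl / max(x$n_probes_tested, 1L)))
  cat(sprintf("  %d significant of %d tested pairs; realized p cutoff %.3g\n",
              x$n_sig_pairs, x$n_tests, x$realized_cutoff))
  invisible(x)
}

#' Label associations as cis or trans
#'
#' An association is *cis* when the variant lies on the same chromosome as
#' the gene and within `cis_window_bp` of its TSS (boundary inclusive), and
#' *trans* otherwise.
#'
#' @param gene_id Character vector of gene ids (recycled against the variant
#'   vectors).
#' @param variant_chrom,variant_pos Variant coordinates.
#' @param annotation list with a `genes` data.frame.
#' @param cis_window_bp Window half-width (default 1 Mb).
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(gene_id, variant_chrom, variant_pos,
                               annotation, cis_window_bp = 1000000) {
  genes <- annotation$genes
  m <- match(gene_id, genes$gene_id)
  if (anyNA(m))
    stop(sprintf("unknown gene(s): %s",
                 paste(unique(gene_id[is.na(m)]), collapse = ", ")),
         call. = FALSE)
  ifelse(genes$chrom[m] == variant_chrom &
           abs(variant_pos - genes$tss[m]) <= cis_window_bp, "cis", "trans")
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Combines per-cohort Z-scores as `sum(w_i z_i) / sqrt(sum(w_i^2))` with
#' `w_i = sqrt(n_i)`, the standard weighted-Z combination used by large
#' multi-cohort eQTL discovery analyses.
#'
#' @param z_scores,sample_sizes Equal-length numeric vectors.
#' @return The combined Z-score.
#' @export
#' @examples
#' weighted_z_meta(c(2, 2), c(100, 100))  # 2 * sqrt(2)
weighted_z_meta <- function(z_scores, sample_sizes) {
  if (length(z_scores) != length(sample_sizes))
    stop("z_scores and sample_sizes must have equal length", call. = FALSE)
  if (length(z_scores) < 1L) stop("need at least one cohort", call. = FALSE)
  if (any(sample_sizes <= 0)) stop("sample sizes must be > 0", call. = FALSE)
  w <- sqrt(sample_sizes)
  sum(w * z_scores) / sqrt(sum(w^2))
}

#' Multi-cohort cis scan combined by weighted Z
#'
#' Scans each cohort with [cis_scan()], converts the per-cohort slope tests
#' to signed Z-scores and combines them with [weighted_z_meta()]. Emulates a
#' meta-analytic discovery study; only pairs tested in every cohort are kept.
#'
#' @param cohorts list of `raw_study` objects sharing probe and variant ids.
#' @param annotation,cis_window_bp As in [cis_scan()].
#' @return Association records with meta-analytic `z` and `p_value`
#'   (`beta` is the sample-size-weighted mean slope, `n` the summed size).
#' @export
meta_scan <- function(cohorts, annotation, cis_window_bp = 1000000) {
  scans <- lapply(cohorts, cis_scan, annotation = annotation,
                  cis_window_bp = cis_window_bp)
  key <- function(r) paste(r$probe_id, r$variant_id, sep = "\r")
  keys <- Reduce(intersect, lapply(scans, key))
  scans <- lapply(scans, function(r) {
    r <- r[match(keys, key(r)), , drop = FALSE]
    r$z <- sign(r$beta) * stats::qnorm(pmin(r$p_value, 1) / 2,
                                       lower.tail = FALSE)
    r
  })
  zmat <- matrix(vapply(scans, `[[`, numeric(length(keys)), "z"),
                 nrow = length(keys))
  nvec <- vapply(scans, function(r) r$n[1], numeric(1))
  bmat <- matrix(vapply(scans, `[[`, numeric(length(keys)), "beta"),
                 nrow = length(keys))
  zc <- apply(zmat, 1L, weighted_z_meta, sample_sizes = nvec)
  out <- scans[[1]][, c("gene_id", "probe_id", "variant_id", "chrom", "pos",
                        "tss", "distance_to_tss")]
  out$beta <- as.vector(bmat %*% nvec) / sum(nvec)
  out$z <- zc
  out$t_stat <- zc
  out$p_value <- pmax(2 * stats::pnorm(-abs(zc)), 1e-300)
  out$n <- sum(nvec)
  attr(out, "n_probes_tested") <- length(unique(out$probe_id))
  out
}
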