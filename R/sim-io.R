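write_tsv <- function(df, path, rownames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = TRUE)
  path
}

#' Write a haplotype panel as a minimal phased VCF or a plain TSV
#'
#' The VCF carries one diploid sample per pair of consecutive haplotypes with
#' phased `GT` (`a|b`). The TSV has one row per variant: `id`, `pos`, then one
#' 0/1 column per haplotype.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  v <- panel$variants
  H <- panel$haplotypes
  if (format == "tsv") {
    df <- data.frame(id = v$id, pos = v$pos, t(H), check.names = FALSE)
    colnames(df) <- c("id", "pos", sprintf("hap%04d", seq_len(nrow(H))))
    write_tsv(df, path)
    return(invisible(path))
  }
  if (nrow(H) %% 2L != 0L)
    stop("VCF output needs an even number of haplotypes", call. = FALSE)
  ns <- nrow(H) %/% 2L
  gt <- matrix(sprintf("%d|%d",
                       t(H[seq(1L, 2L * ns, by = 2L), , drop = FALSE]),
                       t(H[seq(2L, 2L * ns, by = 2L), , drop = FALSE])),
               nrow = ncol(H), ncol = ns)
  samples <- sprintf("sample%04d", seq_len(ns))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(v$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(cbind(v$chrom, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS",
                      ".", "GT", gt), 1L, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated study pair to disk as plain-text fixtures
#'
#' Serializes everything downstream stages need: the haplotype panel (VCF and
#' TSV), per-study genotype-dosage and expression matrices, probe tables, the
#' BED-like gene annotation (chrom, tss, gene_id, comma-separated exon
#' intervals) and the ground truth. A manifest with MD5 checksums makes
#' determinism checkable by rerun.
#'
#' @param sim An `eqtl_sim_pair` from [simulate_study_pair()].
#' @param panel The [haplotype_panel()] the pair was simulated from.
#' @param dir Output directory (created if missing).
#' @return data.frame manifest (`file`, `md5`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixture_set <- function(sim, panel, dir) {
  if (!dir.exists(dir) &&
      !suppressWarnings(dir.create(dir, recursive = TRUE)))
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  if (file.access(dir, 2L) != 0L)
    stop(sprintf("directory '%s' is not writable", dir), call. = FALSE)
  p <- function(f) file.path(dir, f)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  add(write_haplotypes(panel, p("panel.vcf"), "vcf"))
  add(write_haplotypes(panel, p("panel.tsv"), "tsv"))

  for (s in list(sim$study_i, sim$study_j)) {
    add(write_tsv(as.data.frame(s$genotypes),
                  p(sprintf("%s_genotypes.tsv", s$study_id)), rownames = TRUE))
    add(write_tsv(as.data.frame(s$expression),
                  p(sprintf("%s_expression.tsv", s$study_id)), rownames = TRUE))
    add(write_tsv(s$probes, p(sprintf("%s_probes.tsv", s$study_id))))
  }

  ex <- sim$annotation$exons
  ivals <- vapply(split(sprintf("%d-%d", ex$start, ex$end), ex$gene_id),
                  paste, character(1), collapse = ",")
  g <- sim$annotation$genes
  bed <- data.frame(chrom = g$chrom, tss_pos = g$tss, gene_id = g$gene_id,
                    exons = unname(ivals[g$gene_id]), stringsAsFactors = FALSE)
  add(write_tsv(bed, p("genes.tsv")))
  add(write_tsv(sim$truth, p("ground_truth.tsv")))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  invisible(manifest)
}

#' Read a BED-like gene annotation written by [write_fixture_set()]
#'
#' @param path TSV with columns chrom, tss_pos, gene_id, exons
#'   (comma-separated `start-end` intervals, 0-based half-open).
#' @return list with `genes` and `exons` data.frames as used throughout the
#'   package.
#' @export
read_gene_annotation <- function(path) {
  bed <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = bed$gene_id, chrom = as.character(bed$chrom),
                      tss = bed$tss_pos, stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
    iv <- strsplit(bed$exons[i], ",", fixed = TRUE)[[1]]
    se <- do.call(rbind, strsplit(iv, "-", fixed = TRUE))
    data.frame(gene_id = bed$gene_id[i],
               exon_id = sprintf("%s_ex%d", bed$gene_id[i], seq_along(iv)),
               chrom = as.character(bed$chrom[i]),
               start = as.integer(se[, 1]), end = as.integer(se[, 2]),
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = ex)
}

#' Read a matrix TSV (variants or probes in rows, individuals in columns)
#' @param path TSV with row names in the first column.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}
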