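#' Match expression probes of two platforms onto a common gene universe
#'
#' Two platforms rarely share probe sets, so genes are matched through the
#' annotation: a gene enters the common universe when *each* platform has at
#' least one probe whose interval is fully contained in the same annotated
#' exon of that gene (0-based half-open coordinates). When several probes of
#' a platform qualify, the one with the smallest genomic span is retained.
#' Probes whose interval falls inside exons of more than one gene are
#' excluded (a message reports the count).
#'
#' @param probes_i,probes_j data.frames with `probe_id`, `chrom`, `start`,
#'   `end` (gene labels, if present, are ignored — matching is positional).
#' @param exon_annotation data.frame with `gene_id`, `exon_id`, `chrom`,
#'   `start`, `end`.
#' @return An object of class `gene_match_table`: data.frame `gene_id`,
#'   `probe_i`, `probe_j`, `exon_id`, with `n_common_genes` as attribute.
#' @export
match_probes_to_genes <- function(probes_i, probes_j, exon_annotation) {
  ex <- exon_annotation
  map_platform <- function(probes) {
    hits <- lapply(seq_len(nrow(probes)), function(k) {
      h <- which(ex$chrom == probes$chrom[k] &
                   ex$start <= probes$start[k] & probes$end[k] <= ex$end)
      h
    })
    ngenes <- vapply(hits, function(h) length(unique(ex$gene_id[h])), integer(1))
    multi <- ngenes > 1L
    if (any(multi))
      message(sprintf("excluded %d probe(s) mapping to multiple genes",
                      sum(multi)))
    keep <- which(ngenes == 1L)
    if (!length(keep))
      return(data.frame(probe_id = character(0), gene_id = character(0),
                        exon_id = character(0), span = integer(0)))
    data.frame(probe_id = probes$probe_id[keep],
               gene_id = ex$gene_id[vapply(hits[keep], `[`, integer(1), 1L)],
               exon_id = ex$exon_id[vapply(hits[keep], `[`, integer(1), 1L)],
               span = probes$end[keep] - probes$start[keep],
               stringsAsFactors = FALSE)
  }
  pick_best <- function(m) {
    m <- m[order(m$gene_id, m$span, m$probe_id), , drop = FALSE]
    m[!duplicated(paste(m$gene_id, m$exon_id)), , drop = FALSE]
  }
  mi <- pick_best(map_platform(probes_i))
  mj <- pick_best(map_platform(probes_j))
  tab <- merge(mi[, c("gene_id", "exon_id", "probe_id")],
               mj[, c("gene_id", "exon_id", "probe_id")],
               by = c("gene_id", "exon_id"),
               suffixes = c("_i", "_j"))
  # one row per gene: if several exons qualify, keep the first
  tab <- tab[order(tab$gene_id, tab$exon_id), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = tab$gene_id, probe_i = tab$probe_id_i,
                    probe_j = tab$probe_id_j, exon_id = tab$exon_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gene_match_table", "data.frame"),
            n_common_genes = nrow(out))
}

#' Genes with a significant eQTL in both studies of a harmonized pair
#'
#' @param study_i,study_j `eqtl_study` objects.
#' @param table A [match_probes_to_genes()] table defining the common gene
#'   universe.
#' @return character vector of gene ids.
#' @export
shared_eqtl_genes <- function(study_i, study_j, table) {
  intersect(table$gene_id, intersect(study_i$sig_genes, study_j$sig_genes))
}

best_esnp <- function(study, genes) {
  r <- study$records
  stats::setNames(r$variant_id, r$gene_id)[genes]
}

#' Direct best-eSNP overlap between two studies
#'
#' For every gene with an eQTL in both studies, compares the two best eSNPs
#' by identifier: `direct_match` is `TRUE` only when both studies report the
#' very same SNP. This is the naive comparison available from published
#' result lists alone and is biased downwards whenever the studies genotyped
#' different SNP arrays.
#'
#' @param study_i,study_j `eqtl_study` objects.
#' @param shared_genes Genes with an eQTL in both studies (from
#'   [shared_eqtl_genes()]); may be empty.
#' @return data.frame of per-gene overlap calls: `gene_id`, `esnp_i`,
#'   `esnp_j`, `direct_match`, `proxy_match` (equal to `direct_match` here,
#'   since a SNP is always its own proxy), `best_shared_r2`.
#' @export
direct_esnp_overlap <- function(study_i, study_j, shared_genes) {
  ei <- best_esnp(study_i, shared_genes)
  ej <- best_esnp(study_j, shared_genes)
  miss <- is.na(ei) | is.na(ej)
  if (any(miss)) {
    warning(sprintf("%d gene(s) missing an eSNP in one study, excluded",
                    sum(miss)), call. = FALSE)
    shared_genes <- shared_genes[!miss]
    ei <- ei[!miss]; ej <- ej[!miss]
  }
  direct <- !is.na(ei) & ei == ej
  data.frame(gene_id = shared_genes, esnp_i = unname(ei), esnp_j = unname(ej),
             direct_match = direct, proxy_match = direct,
             best_shared_r2 = ifelse(direct, 1, NA_real_),
             stringsAsFactors = FALSE)
}

#' LD-proxy overlap between two studies' best eSNPs
#'
#' Upgrades [direct_esnp_overlap()] calls with the proxy-SNP comparison: a
#' gene's eQTL overlaps when the proxy sets of its two eSNPs intersect
#' (`criterion = "intersect"`), or — stricter, for sensitivity analysis —
#' when one eSNP lies inside the other's proxy set
#' (`criterion = "containment"`). `best_shared_r2` records, over shared
#' proxies, the maximum of `min(r2 to eSNP_i, r2 to eSNP_j)`. eSNPs absent
#' from a proxy map are treated as self-only sets (a message is emitted).
#'
#' @param study_i,study_j `eqtl_study` objects.
#' @param shared_genes Genes with an eQTL in both studies.
#' @param proxy_map_i,proxy_map_j [build_proxy_map()] objects built from the
#'   same reference panel.
#' @param criterion Proxy-overlap rule; `"intersect"` is the default.
#' @return data.frame of per-gene overlap calls (see
#'   [direct_esnp_overlap()]), plus `n_shared_proxies`, the size of the
#'   proxy-set intersection (0 when the gene does not overlap).
#' @export
proxy_overlap <- function(study_i, study_j, shared_genes,
                          proxy_map_i, proxy_map_j,
                          criterion = c("intersect", "containment")) {
  criterion <- match.arg(criterion)
  calls <- direct_esnp_overlap(study_i, study_j, shared_genes)
  calls$n_shared_proxies <- ifelse(calls$direct_match, 1L, 0L)
  n_absent <- 0L
  get_set <- function(pm, e) {
    s <- pm[[e]]
    if (is.null(s)) {
      n_absent <<- n_absent + 1L
      s <- data.frame(proxy_id = e, r2 = 1, distance_bp = 0L,
                      stringsAsFactors = FALSE)
    }
    s
  }
  for (k in seq_len(nrow(calls))) {
    si <- get_set(proxy_map_i, calls$esnp_i[k])
    sj <- get_set(proxy_map_j, calls$esnp_j[k])
    if (criterion == "containment") {
      hit <- calls$esnp_j[k] %in% si$proxy_id ||
        calls$esnp_i[k] %in% sj$proxy_id
      calls$proxy_match[k] <- calls$direct_match[k] || hit
      if (hit && !calls$direct_match[k])
        calls$best_shared_r2[k] <- max(si$r2[si$proxy_id == calls$esnp_j[k]],
                                       sj$r2[sj$proxy_id == calls$esnp_i[k]],
                                       -Inf)
      next
    }
    common <- intersect(si$proxy_id, sj$proxy_id)
    if (length(common)) {
      calls$proxy_match[k] <- TRUE
      calls$n_shared_proxies[k] <- length(common)
      calls$best_shared_r2[k] <-
        max(pmin(si$r2[match(common, si$proxy_id)],
                 sj$r2[match(common, sj$proxy_id)]))
    }
  }
  if (n_absent > 0)
    message(sprintf("proxy_overlap: %d eSNP(s) not in proxy map, used self-only sets",
                    n_absent))
  calls
}
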