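#' Construct a haplotype panel object
#'
#' A haplotype panel is the LD substrate of the pipeline: a binary matrix of
#' phased haplotypes (rows) over positioned variants (columns), plus a variant
#' table. Monomorphic columns are flagged rather than dropped, since LD is
#' undefined for them.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (0-based bp),
#'   `ref`, `alt` (and optionally `block` for simulated panels).
#' @param haplotypes integer matrix (haplotypes x variants), entries 0/1;
#'   column names must match `variants$id`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            is.matrix(haplotypes), ncol(haplotypes) == nrow(variants))
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique", call. = FALSE)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  haplotypes <- haplotypes[, ord, drop = FALSE]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("variant positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0/1", call. = FALSE)
  colnames(haplotypes) <- variants$id
  rownames(variants) <- NULL
  freq <- colMeans(haplotypes)
  variants$alt_freq <- unname(freq)
  variants$monomorphic <- freq == 0 | freq == 1
  structure(list(variants = variants, haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
#' @method print haplotype_panel
print.haplotype_panel <- function(x, ...) {
  v <- x$variants
  cat(sprintf("Haplotype panel: %d haplotypes x %d variants (%d monomorphic)\n",
              nrow(x$haplotypes), nrow(v), sum(v$monomorphic)))
  cat(sprintf("  chrom %s, positions %s..%s\n",
              paste(unique(v$chrom), collapse = ","),
              format(min(v$pos), big.mark = ","),
              format(max(v$pos), big.mark = ",")))
  invisible(x)
}

# Per-site flip probability for the copy-with-mutation LD scheme. Each block
# variant is the block founder copied with symmetric flip probability eps;
# two such copies then have correlation
#   rho(eps) = (1-2 eps)^2 p(1-p) / (p'(1-p')),  p' = p + eps(1-2p),
# so eps is solved from rho(eps)^2 = within_block_r2.
flip_prob_for_r2 <- function(r2_target, p) {
  if (r2_target >= 1) return(0)
  if (r2_target <= 0) return(0.5)
  rho <- sqrt(r2_target)
  f <- function(eps) {
    pp <- p + eps * (1 - 2 * p)
    (1 - 2 * eps)^2 * p * (1 - p) / (pp * (1 - pp)) - rho
  }
  stats::uniroot(f, c(0, 0.499999), tol = 1e-12)$root
}

#' Simulate a phased haplotype reference panel with block LD
#'
#' Generates `n_blocks` independent LD blocks of `snps_per_block` variants on
#' a single chromosome. Within a block, every variant is a copy of a block
#' founder haplotype with a per-site flip probability tuned so that the
#' expected pairwise r-squared equals `within_block_r2`; variants in different
#' blocks are independent. Founder allele frequencies are drawn uniformly from
#' `maf_range`. With `within_block_r2 = 1` block members are exact copies;
#' with `within_block_r2 = 0` every variant is drawn independently.
#'
#' @param config An [sim_config()] object.
#' @return A [haplotype_panel()] whose variant table carries a `block` column.
#' @export
#' @examples
#' panel <- simulate_haplotype_panel(sim_config(n_blocks = 4, seed = 7,
#'                                              n_haplotypes = 200))
#' panel
simulate_haplotype_panel <- function(config) {
  if (!inherits(config, "eqtl_sim_config"))
    stop("config must be built by sim_config()", call. = FALSE)
  set.seed(derive_seed(config$seed, 1L))
  nh <- config$n_haplotypes
  nb <- config$n_blocks
  m <- config$snps_per_block
  span <- (m - 1L) * config$snp_spacing_bp
  cols <- vector("list", nb)
  pos <- integer(0)
  block <- integer(0)
  for (b in seq_len(nb)) {
    center <- b * config$block_spacing_bp
    start <- center - span %/% 2L
    pos <- c(pos, start + (seq_len(m) - 1L) * config$snp_spacing_bp)
    block <- c(block, rep.int(b, m))
    p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    if (config$within_block_r2 <= 0) {
      # independent variants: no founder, each site its own frequency
      ps <- stats::runif(m, config$maf_range[1], config$maf_range[2])
      cols[[b]] <- vapply(ps, function(pp) stats::rbinom(nh, 1L, pp),
                          integer(nh))
    } else {
      eps <- flip_prob_for_r2(config$within_block_r2, p)
      founder <- stats::rbinom(nh, 1L, p)
      cols[[b]] <- vapply(seq_len(m), function(s) {
        if (eps == 0) return(founder)
        flip <- stats::rbinom(nh, 1L, eps)
        as.integer(xor(founder, flip))
      }, integer(nh))
    }
  }
  hap <- do.call(cbind, cols)
  storage.mode(hap) <- "integer"
  ids <- sprintf("snp_b%03d_%02d", block, stats::ave(block, block, FUN = seq_along))
  variants <- data.frame(id = ids, chrom = "1", pos = pos,
                         ref = "A", alt = "G", block = block,
                         stringsAsFactors = FALSE)
  colnames(hap) <- ids
  haplotype_panel(variants, hap)
}
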