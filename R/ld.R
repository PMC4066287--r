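#' Read a phased haplotype panel from VCF or TSV
#'
#' VCF records must be phased (`a|b`) and biallelic; unphased or multi-allelic
#' records are skipped with a warning giving the count. The TSV dialect is the
#' one written by [write_haplotypes()]: one row per variant, columns `id`,
#' `pos`, then one 0/1 column per haplotype.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE),
      error = function(e) stop(sprintf("parse error in '%s': %s",
                                       path, conditionMessage(e)), call. = FALSE))
    if (!all(c("id", "pos") %in% names(df)))
      stop(sprintf("parse error in '%s' line 1: need 'id' and 'pos' columns",
                   path), call. = FALSE)
    hap <- t(as.matrix(df[, setdiff(names(df), c("id", "pos")), drop = FALSE]))
    storage.mode(hap) <- "integer"
    variants <- data.frame(id = as.character(df$id), chrom = "1",
                           pos = as.integer(df$pos), ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
    return(haplotype_panel(variants, hap))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  unphased <- apply(gt, 1L, function(r) any(grepl("/", r, fixed = TRUE)))
  keep <- !multi & !unphased
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(sprintf("skipped %d record(s): %d multi-allelic, %d unphased",
                    n_skip, sum(multi), sum(unphased & !multi)), call. = FALSE)
  if (!any(keep))
    stop(sprintf("no usable phased biallelic records in '%s'", path),
         call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alle <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  if (any(lengths(alle) != 2L))
    stop(sprintf("parse error in '%s': non-diploid GT encountered", path),
         call. = FALSE)
  a <- matrix(as.integer(unlist(alle)), ncol = 2L, byrow = TRUE)
  ns <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * ns, ncol = nrow(gt))
  # sample s contributes haplotypes 2s-1 and 2s
  hap[seq(1L, 2L * ns, 2L), ] <- matrix(a[, 1], nrow = ns)
  hap[seq(2L, 2L * ns, 2L), ] <- matrix(a[, 2], nrow = ns)
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]) - 1L,
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  haplotype_panel(variants, hap)
}

#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' Computed from haplotype frequencies as `D^2 / (pA(1-pA) pB(1-pB))` with
#' `D = pAB - pA pB`, where `pAB` is the frequency of the alt-alt haplotype.
#' Symmetric in its arguments; `ld_r2(panel, a, a)` is 1.
#'
#' @param panel A [haplotype_panel()].
#' @param a,b Variant ids present in the panel.
#' @return r-squared in `[0, 1]`.
#' @export
#' @examples
#' pan <- simulate_haplotype_panel(sim_config(n_blocks = 2, n_haplotypes = 100,
#'                                            seed = 3))
#' ids <- pan$variants$id
#' ld_r2(pan, ids[1], ids[2])
ld_r2 <- function(panel, a, b) {
  v <- panel$variants
  for (id in c(a, b))
    if (!id %in% v$id)
      stop(sprintf("variant '%s' not in panel", id), call. = FALSE)
  x <- panel$haplotypes[, a]
  y <- panel$haplotypes[, b]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop(sprintf("LD undefined: variant '%s' is monomorphic",
                 if (pa %in% c(0, 1)) a else b), call. = FALSE)
  d <- mean(x * y) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# r2 of one variant (by column index) against many, vectorised over the
# haplotype matrix; monomorphic partners come back NA.
r2_one_vs_many <- function(H, i, idx) {
  x <- H[, i]
  pa <- mean(x)
  if (pa %in% c(0, 1)) return(rep(NA_real_, length(idx)))
  Y <- H[, idx, drop = FALSE]
  pb <- colMeans(Y)
  d <- colMeans(x * Y) - pa * pb
  out <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  out[pb %in% c(0, 1)] <- NA_real_
  out
}

#' Build a proxy-SNP map for a set of eSNPs
#'
#' For every eSNP, collects the panel variants within `window_bp` (symmetric,
#' inclusive) whose LD with the eSNP reaches `r2_threshold`. The proxy set
#' always contains the eSNP itself with r-squared 1; monomorphic partners are
#' skipped (LD undefined). eSNPs absent from the panel — e.g. platform-private
#' SNPs — degrade to a self-only set with a warning rather than an error.
#'
#' @param panel A [haplotype_panel()].
#' @param esnps Character vector of eSNP ids.
#' @param r2_threshold LD threshold in `(0, 1]`; 0.8 is the conventional
#'   "high LD" choice, 0.5 a common sensitivity setting.
#' @param window_bp Maximum distance from the eSNP, in bp (default 100 kb).
#' @return An object of class `proxy_map`: a named list of data.frames
#'   (`proxy_id`, `r2`, `distance_bp`, ordered by position) with the
#'   thresholds stored as attributes.
#' @export
build_proxy_map <- function(panel, esnps, r2_threshold = 0.8,
                            window_bp = 100000) {
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(window_bp) || window_bp < 0)
    stop("window_bp must be non-negative", call. = FALSE)
  v <- panel$variants
  H <- panel$haplotypes
  esnps <- unique(as.character(esnps))
  missing <- setdiff(esnps, v$id)
  if (length(missing))
    warning(sprintf("%d eSNP(s) absent from panel, kept as self-only proxy sets (e.g. %s)",
                    length(missing), missing[1]), call. = FALSE)
  self_df <- function(id) data.frame(proxy_id = id, r2 = 1, distance_bp = 0L,
                                     stringsAsFactors = FALSE)
  entries <- lapply(esnps, function(e) {
    if (!e %in% v$id) return(self_df(e))
    i <- match(e, v$id)
    cand <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window_bp)
    r2 <- r2_one_vs_many(H, i, cand)
    keep <- !is.na(r2) & r2 >= r2_threshold
    keep[cand == i] <- TRUE  # self is always a proxy
    cand <- cand[keep]; r2 <- r2[keep]
    r2[cand == i] <- 1
    ord <- order(v$pos[cand])
    data.frame(proxy_id = v$id[cand][ord], r2 = r2[ord],
               distance_bp = abs(v$pos[cand] - v$pos[i])[ord],
               stringsAsFactors = FALSE)
  })
  names(entries) <- esnps
  structure(entries, class = "proxy_map",
            r2_threshold = r2_threshold, window_bp = window_bp)
}

#' @export
#' @method print proxy_map
print.proxy_map <- function(x, ...) {
  sizes <- lengths(lapply(unclass(x), `[[`, "proxy_id"))
  cat(sprintf("Proxy map: %d eSNPs (r2 >= %.2f within %s bp); proxies per eSNP: median %d, max %d\n",
              length(x), attr(x, "r2_threshold"),
              format(attr(x, "window_bp"), big.mark = ","),
              as.integer(stats::median(sizes)), max(sizes)))
  invisible(x)
}

#' Serialize a proxy map to TSV (esnp_id, proxy_id, r2, distance_bp)
#' @param pm A `proxy_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proxy_map <- function(pm, path) {
  df <- do.call(rbind, lapply(names(pm), function(e)
    cbind(esnp_id = e, pm[[e]], stringsAsFactors = FALSE)))
  write_tsv(df, path)
  invisible(path)
}
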