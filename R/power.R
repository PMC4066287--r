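#' Correct the raw subsampled power for chance significance and discovery FDR
#'
#' The raw replication proportion from the subsampling procedure mixes true
#' replication with chance significance and false discoveries; the corrected
#' replication power is `(power_j_raw - fdr_i * a_j) / (1 - fdr_i)`.
#'
#' @param power_j_raw Raw replication proportion from
#'   [estimate_power_j_raw()], in `[0, 1]`.
#' @param fdr_i FDR level of the discovery study (default 0.05).
#' @param a_j Chance-significance rate of the replication study.
#' @return Corrected power, clipped to `[0, 1]` with a warning if the inputs
#'   push it outside.
#' @export
#' @examples
#' power_j_from_raw(0.84, fdr_i = 0.05, a_j = 0.01)
power_j_from_raw <- function(power_j_raw, fdr_i = 0.05, a_j = 0) {
  check_fraction(power_j_raw, "power_j_raw")
  check_fraction(a_j, "a_j")
  if (!is.numeric(fdr_i) || length(fdr_i) != 1L || fdr_i < 0 || fdr_i >= 1)
    stop("fdr_i must lie in [0, 1)", call. = FALSE)
  p <- (power_j_raw - fdr_i * a_j) / (1 - fdr_i)
  if (p < 0 || p > 1) {
    warning(sprintf("power_j = %.4f outside [0,1], clipped", p), call. = FALSE)
    p <- min(max(p, 0), 1)
  }
  p
}

#' Power-adjusted overlap estimate
#'
#' Corrects the observed overlap fraction for the replication study's limited
#' power and for chance overlap:
#' `(pi_raw - a_j * (1 - fdr_i)) / (power_j - a_j)`.
#' With full power and no chance significance (`power_j = 1`, `a_j = 0`,
#' `fdr_i = 0`) this reduces to `pi_raw`; with partial power it inflates the
#' raw estimate by `1 / power_j`.
#'
#' @param pi_raw Observed overlap fraction (see [pi_raw()]).
#' @param a_j Chance-significance rate of the replication study.
#' @param fdr_i Discovery-study FDR level.
#' @param power_j Corrected replication power from [power_j_from_raw()];
#'   must exceed `a_j` for the estimate to exist.
#' @return Adjusted overlap fraction, clipped to `[0, 1]` with a warning if
#'   sampling noise pushes it outside.
#' @export
#' @examples
#' pi_adjusted(0.10, a_j = 0, fdr_i = 0, power_j = 0.5)  # 0.20
pi_adjusted <- function(pi_raw, a_j = 0, fdr_i = 0.05, power_j = 1) {
  check_fraction(pi_raw, "pi_raw")
  check_fraction(a_j, "a_j")
  check_fraction(power_j, "power_j")
  if (!is.numeric(fdr_i) || length(fdr_i) != 1L || fdr_i < 0 || fdr_i >= 1)
    stop("fdr_i must lie in [0, 1)", call. = FALSE)
  if (power_j <= a_j)
    stop(sprintf("estimate undefined: power_j (%.4f) must exceed a_j (%.4f)",
                 power_j, a_j), call. = FALSE)
  est <- (pi_raw - a_j * (1 - fdr_i)) / (power_j - a_j)
  if (est < 0 || est > 1) {
    warning(sprintf("pi_adjusted = %.4f outside [0,1], clipped", est),
            call. = FALSE)
    est <- min(max(est, 0), 1)
  }
  est
}

# Does the best eSNP of a gene in scan 1 match the best eSNP in scan 2,
# directly or through panel LD?
esnp_pair_matches <- function(e1, e2, panel, r2_threshold, window_bp) {
  if (e1 == e2) return(TRUE)
  if (is.null(panel)) return(FALSE)
  v <- panel$variants
  i1 <- match(e1, v$id); i2 <- match(e2, v$id)
  if (is.na(i1) || is.na(i2)) return(FALSE)
  if (v$monomorphic[i1] || v$monomorphic[i2]) return(FALSE)
  if (abs(v$pos[i1] - v$pos[i2]) > window_bp) return(FALSE)
  ld_r2(panel, e1, e2) >= r2_threshold
}

#' Estimate raw replication power by subsampling the large study
#'
#' Empirical analogue of "what would the discovery study have found at the
#' replication study's sample size": repeatedly draws two mutually exclusive
#' subsets of `n_j` individuals from the large study, calls eQTL in each at
#' study-wide FDR `fdr`, and records the proportion of the first subset's
#' eQTL genes that are also significant in the second. With
#' `match = "gene"` (default) replication is any significant eQTL for the
#' same gene; `match = "proxy"` additionally requires the two best eSNPs to
#' coincide or be linked at `r2_threshold` within `window_bp` in `panel`.
#'
#' @param raw_i The large study as a `raw_study`.
#' @param annotation Gene annotation list (as in [cis_scan()]).
#' @param n_j Target (replication-study) sample size; needs
#'   `2 * n_j <= n_samples`.
#' @param fdr Study-wide FDR for both subsample scans.
#' @param n_reps Number of subsampling replicates.
#' @param seed Integer seed for the subset draws.
#' @param cis_window_bp Cis window for the subsample scans.
#' @param match Replication criterion, `"gene"` or `"proxy"`.
#' @param panel,r2_threshold,window_bp LD reference for `match = "proxy"`.
#' @return list with `power_j_raw` (mean over replicates), `se`, the
#'   per-replicate values `reps`, and `mean_cutoff_i2` (average realized BH
#'   cutoff of the second subset, an empirical per-test chance rate).
#' @export
estimate_power_j_raw <- function(raw_i, annotation, n_j, fdr = 0.05,
                                 n_reps = 20, seed = 1,
                                 cis_window_bp = 1000000,
                                 match = c("gene", "proxy"),
                                 panel = NULL, r2_threshold = 0.8,
                                 window_bp = 100000) {
  match <- match.arg(match)
  n_reps <- check_count(n_reps, "n_reps")
  n <- raw_i$n_samples
  if (2 * n_j > n)
    stop(sprintf("need 2 * n_j = %d individuals but study has only %d",
                 2 * n_j, n), call. = FALSE)
  if (match == "proxy" && is.null(panel))
    stop("match = 'proxy' requires a haplotype panel", call. = FALSE)
  set.seed(derive_seed(seed, 3L))
  reps <- rep(NA_real_, n_reps)
  cutoffs <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(n)
    s1 <- subset_individuals(raw_i, perm[seq_len(n_j)])
    s2 <- subset_individuals(raw_i, perm[n_j + seq_len(n_j)])
    st1 <- call_eqtls(suppressMessages(cis_scan(s1, annotation, cis_window_bp)),
                      q = fdr, study_id = "i1")
    st2 <- call_eqtls(suppressMessages(cis_scan(s2, annotation, cis_window_bp)),
                      q = fdr, study_id = "i2")
    cutoffs[r] <- st2$realized_cutoff
    g1 <- st1$sig_genes
    if (length(g1) == 0L) next
    if (match == "gene") {
      reps[r] <- mean(g1 %in% st2$sig_genes)
    } else {
      e1 <- best_esnp(st1, g1)
      e2 <- best_esnp(st2, g1)
      hit <- vapply(seq_along(g1), function(k) {
        !is.na(e2[k]) && esnp_pair_matches(e1[[k]], e2[[k]], panel,
                                           r2_threshold, window_bp)
      }, logical(1))
      reps[r] <- mean(hit)
    }
  }
  ok <- !is.na(reps)
  if (!any(ok))
    warning("no subsample yielded any eQTL; power estimate undefined",
            call. = FALSE)
  list(power_j_raw = mean(reps[ok]),
       se = if (sum(ok) > 1) stats::sd(reps[ok]) / sqrt(sum(ok)) else NA_real_,
       reps = reps, mean_cutoff_i2 = mean(cutoffs, na.rm = TRUE),
       n_j = n_j, n_reps = n_reps, match = match)
}

#' Power-adjust the observed overlap for a study pair
#'
#' Chains the full adjustment: [estimate_power_j_raw()] on the large study at
#' the replication study's sample size, [power_j_from_raw()], and
#' [pi_adjusted()]. The chance-significance rate `a_j` defaults to the
#' replication study's realized BH p-value cutoff — the per-test probability
#' of significance absent true sharing — and can be overridden.
#'
#' @param raw_i The large (discovery) study as `raw_study`.
#' @param study_j The replication study's `eqtl_study` (supplies `n_j` and
#'   the default `a_j`).
#' @param pi_raw_value Observed overlap fraction in the i-to-j direction.
#' @param annotation Gene annotation list.
#' @param fdr_i Discovery FDR level.
#' @param a_j Chance-significance rate override (default: realized cutoff of
#'   study j).
#' @param n_reps,seed,cis_window_bp,match,panel,r2_threshold,window_bp Passed
#'   to [estimate_power_j_raw()].
#' @return Object of class `power_adjustment` with all intermediate
#'   quantities.
#' @export
adjust_pair <- function(raw_i, study_j, pi_raw_value, annotation,
                        fdr_i = 0.05, a_j = NULL, n_reps = 20, seed = 1,
                        cis_window_bp = 1000000, match = c("gene", "proxy"),
                        panel = NULL, r2_threshold = 0.8, window_bp = 100000) {
  match <- match.arg(match)
  a_j <- a_j %||% study_j$realized_cutoff
  pw <- estimate_power_j_raw(raw_i, annotation, n_j = study_j$n_samples,
                             fdr = fdr_i, n_reps = n_reps, seed = seed,
                             cis_window_bp = cis_window_bp, match = match,
                             panel = panel, r2_threshold = r2_threshold,
                             window_bp = window_bp)
  power_j <- power_j_from_raw(pw$power_j_raw, fdr_i, a_j)
  structure(list(study_pair = c(raw_i$study_id, study_j$study_id),
                 n_j = study_j$n_samples, fdr_i = fdr_i, a_j = a_j,
                 power_j_raw = pw$power_j_raw, power_j_raw_se = pw$se,
                 power_j = power_j, pi_raw = pi_raw_value,
                 pi_adjusted = pi_adjusted(pi_raw_value, a_j, fdr_i, power_j),
                 n_subsample_reps = n_reps, seed = seed, match = match),
            class = "power_adjustment")
}

#' @export
#' @method print power_adjustment
print.power_adjustment <- function(x, ...) {
  cat(sprintf("Power adjustment %s -> %s (n_j = %d, %d subsample reps, %s match)\n",
              x$study_pair[1], x$study_pair[2], x$n_j, x$n_subsample_reps,
              x$match))
  cat(sprintf("  power_j_raw = %.3f (se %.3f); power_j = %.3f; a_j = %.3g; FDR_i = %.2f\n",
              x$power_j_raw, x$power_j_raw_se, x$power_j, x$a_j, x$fdr_i))
  cat(sprintf("  pi_raw = %.1f%%  ->  pi_adjusted = %.1f%%\n",
              100 * x$pi_raw, 100 * x$pi_adjusted))
  invisible(x)
}
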