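test_that("the power correction follows its closed form", {
  expect_equal(power_j_from_raw(1, 0, 0), 1)
  expect_equal(power_j_from_raw(0.5, 0, 0.2), 0.5)
  expect_equal(power_j_from_raw(0.84, 0.05, 0.01), 0.8395 / 0.95,
               tolerance = 1e-12)
  expect_error(power_j_from_raw(0.5, 1, 0), "fdr_i")
  expect_warning(power_j_from_raw(0.99, 0.05, 0), "clipped")
})

test_that("the adjusted overlap follows its closed form and limits", {
  expect_equal(pi_adjusted(0.10, 0, 0, 1), 0.10)
  expect_equal(pi_adjusted(0.10, 0, 0, 0.5), 0.20)
  expect_equal(pi_adjusted(0.11, 0.01, 0.05, 0.8395 / 0.95),
               (0.11 - 0.01 * 0.95) / (0.8395 / 0.95 - 0.01),
               tolerance = 1e-12)
  expect_equal(pi_adjusted(0.11, 0.01, 0.05, 0.8395 / 0.95), 0.115,
               tolerance = 1e-3)
  expect_error(pi_adjusted(0.1, 0.5, 0.05, 0.4), "must exceed")
  expect_warning(pi_adjusted(0.9, 0, 0.05, 0.5), "clipped")
})

test_that("adjusted overlap decreases in power at fixed raw overlap", {
  vals <- vapply(c(0.4, 0.6, 0.8, 1), function(p)
    pi_adjusted(0.15, 0.001, 0.05, p), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("subsampling needs enough individuals and an LD panel when asked", {
  out <- .shared
  expect_error(estimate_power_j_raw(out$sim$study_i, out$sim$annotation,
                                    n_j = 100, n_reps = 2),
               "2 \\* n_j")
  expect_error(estimate_power_j_raw(out$sim$study_i, out$sim$annotation,
                                    n_j = 50, n_reps = 2, match = "proxy"),
               "panel")
})

test_that("replication power is near one for strong effects and near zero under the null", {
  cfg <- small_cfg(effect_beta = 3, noise_sd = 0.1, frac_null = 0,
                   pi_true = 1, n_individuals_i = 120)
  out <- make_sim(cfg)
  pw <- estimate_power_j_raw(out$sim$study_i, out$sim$annotation, n_j = 50,
                             n_reps = 3, seed = 1)
  expect_gt(pw$power_j_raw, 0.95)

  cfg0 <- small_cfg(frac_null = 1, pi_true = 0, n_genes = 400,
                    n_individuals_i = 120, seed = 3L)
  out0 <- make_sim(cfg0)
  pw0 <- suppressWarnings(
    estimate_power_j_raw(out0$sim$study_i, out0$sim$annotation, n_j = 50,
                         n_reps = 4, seed = 1))
  expect_true(is.nan(pw0$power_j_raw) || pw0$power_j_raw < 0.2)
})

test_that("replication power increases with the subsample size", {
  cfg <- small_cfg(n_individuals_i = 300, n_genes = 400, seed = 17L)
  out <- make_sim(cfg)
  p_small <- estimate_power_j_raw(out$sim$study_i, out$sim$annotation,
                                  n_j = 40, n_reps = 4, seed = 2)
  p_large <- estimate_power_j_raw(out$sim$study_i, out$sim$annotation,
                                  n_j = 140, n_reps = 4, seed = 2)
  expect_gt(p_large$power_j_raw, p_small$power_j_raw)
})

test_that("gene-level and proxy-level replication criteria are ordered", {
  out <- make_sim(small_cfg(n_individuals_i = 200, effect_beta = 1.2,
                            seed = 61L))
  pg <- estimate_power_j_raw(out$sim$study_i, out$sim$annotation, n_j = 80,
                             n_reps = 3, seed = 4)
  pp <- estimate_power_j_raw(out$sim$study_i, out$sim$annotation, n_j = 80,
                             n_reps = 3, seed = 4, match = "proxy",
                             panel = out$panel)
  expect_lte(pp$power_j_raw, pg$power_j_raw + 1e-12)
  expect_gt(pp$power_j_raw, 0)
})

test_that("with a_j = 0 the adjustment chain reduces to its closed form", {
  out <- .shared
  st_j <- call_eqtls(suppressMessages(cis_scan(out$sim$study_j,
                                               out$sim$annotation)),
                     study_id = "j", n_samples = out$sim$study_j$n_samples)
  adj <- suppressWarnings(
    adjust_pair(out$sim$study_i, st_j, pi_raw_value = 0.12,
                annotation = out$sim$annotation, a_j = 0,
                n_reps = 3, seed = 5))
  expect_equal(adj$power_j, min(1, adj$power_j_raw / (1 - adj$fdr_i)))
  expect_equal(adj$pi_adjusted, 0.12 / adj$power_j)
  expect_output(print(adj), "pi_adjusted")
})

test_that("violating effect-size similarity biases the estimate upwards", {
  # shared eQTL get much larger effects than tissue-specific ones, so the
  # subsampled power (a mixture) understates the shared genes' replication
  # probability and the adjusted overlap overshoots pi_true
  res <- vapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 800, pi_true = 0.2, effect_beta = 0.35,
                      effect_beta_shared = 1.5, n_individuals_i = 400,
                      n_individuals_j = 100, seed = 400 + s)
    out <- make_sim(cfg)
    fit <- suppressWarnings(concordance(out$sim$study_i, out$sim$study_j,
                                        out$sim$annotation, out$panel,
                                        power_reps = 3, seed = s))
    fit$adjustment$pi_adjusted
  }, numeric(1))
  expect_gt(mean(res), 0.2)
})
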