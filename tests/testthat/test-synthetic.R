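test_that("synth_network is deterministic and jitter-free at cv = 0", {
  n0 <- synth_network(seed = 5, jitter_cv = 0)
  tmpl <- cowflow:::cow_template_segments()
  expect_equal(n0$segments$diameter_mm, tmpl$diameter_mm)
  n1 <- synth_network(seed = 99, jitter_cv = 0.05)
  n2 <- synth_network(seed = 99, jitter_cv = 0.05)
  expect_identical(n1, n2)
  n3 <- synth_network(seed = 100, jitter_cv = 0.05)
  expect_false(identical(n1$segments$diameter_mm, n3$segments$diameter_mm))
  # complete circle: every region owns at least one outlet
  expect_setequal(unique(unname(n1$outlets)), COW_REGIONS)
  expect_equal(sort(unname(n1$inlets)), c("LICA", "LVA", "RICA", "RVA"))
})

test_that("diameter jitter has the configured coefficient of variation", {
  draws <- vapply(1:1000, function(s)
    synth_network(seed = s, jitter_cv = 0.05)$segments$diameter_mm[1],
    numeric(1))
  cv <- stats::sd(draws) / mean(draws)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("synthetic recordings are reproducible with noiseless option", {
  cfg0 <- cohort_config(cycle_noise_cv = 0, samples_per_cycle = 48)
  rec <- synth_inlet_recording("LICA", "rest", cfg0, seed = 7)
  expect_s3_class(rec, "duplex_recording")
  # zero cycle noise: all cycles identical in values
  expect_equal(rec$cycles[[1]]$values, rec$cycles[[2]]$values)
  expect_equal(rec$cycles[[2]]$values, rec$cycles[[3]]$values)
  rec2 <- synth_inlet_recording("LICA", "rest", cfg0, seed = 7)
  expect_identical(rec, rec2)
})

test_that("poiseuille conversion recovers the drawn flow from a recording", {
  cfg <- cohort_config(cycle_noise_cv = 0, samples_per_cycle = 64)
  rec <- synth_inlet_recording("RICA", "rest", cfg, seed = 3, mean_flow = 250)
  ens <- ensemble_average(rec$cycles, n_points = 64)
  q <- poiseuille_flow(ens, rec$diameter_mm)
  expect_equal(time_average(q), 250, tolerance = 1e-2)
})

test_that("cohort mean tCBF at rest matches the configured flow table", {
  # Monte-Carlo over recordings: recovered tCBF approximates the sum of the
  # configured per-artery means (618.1 mL/min) within 2 standard errors
  cfg <- cohort_config(samples_per_cycle = 48)
  n_mc <- 300
  arteries <- c("LICA", "RICA", "LVA", "RVA")
  tcbf <- vapply(seq_len(n_mc), function(i) {
    flows <- lapply(arteries, function(a) {
      rec <- synth_inlet_recording(a, "rest", cfg, seed = derive_seed(77, i, a))
      poiseuille_flow(ensemble_average(rec$cycles, n_points = 48),
                      rec$diameter_mm)
    })
    total_cbf(flows)
  }, numeric(1))
  se <- sqrt(sum(c(63.3, 74.2, 26.4, 18.3)^2) / n_mc)
  expect_lt(abs(mean(tcbf) - 618.1), 2 * se)
})

test_that("hypercapnia raises every artery's configured mean flow over rest", {
  cfg <- cohort_config()
  expect_true(all(cfg$flow_mean[, "hypercapnia"] > cfg$flow_mean[, "rest"]))
  # exercise is close to rest by comparison
  expect_true(all(abs(cfg$flow_mean[, "exercise"] / cfg$flow_mean[, "rest"] - 1) < 0.25))
})

test_that("uniform TCD bias scales all metrics exactly", {
  ph <- seq(0, 1, length.out = 65)[-65]
  env <- sampled_waveform(40 + 30 * sin(pi * ph)^2, 0.9, "cm/s")
  same <- synth_tcd_envelope(env, 1.0, noise_cv = 0)
  expect_equal(same$values, env$values, tolerance = 1e-14)
  biased <- synth_tcd_envelope(env, 1.6, noise_cv = 0)
  m0 <- unclass(extract_metrics(env))
  m1 <- unclass(extract_metrics(biased))
  expect_equal(m1, 1.6 * m0, tolerance = 1e-12)
})

test_that("diastolic-dominant bias inflates end-diastolic ratio most", {
  ph <- seq(0, 1, length.out = 65)[-65]
  env <- sampled_waveform(40 + 30 * sin(pi * ph)^2, 0.9, "cm/s")  # trough at cycle end
  tcd <- synth_tcd_envelope(env, c(systolic = 1.5, end_diastolic = 1.9),
                            noise_cv = 0)
  m0 <- unclass(extract_metrics(env))
  m1 <- unclass(extract_metrics(tcd))
  ratio <- m1 / m0
  expect_gt(ratio[["end_diastolic"]], ratio[["systolic"]])
  expect_equal(ratio[["systolic"]], 1.5, tolerance = 1e-2)
  expect_equal(ratio[["end_diastolic"]], 1.9, tolerance = 1e-2)
})

test_that("constant within-participant bias makes relative changes agree exactly", {
  ph <- seq(0, 1, length.out = 65)[-65]
  rest <- sampled_waveform(40 + 30 * sin(pi * ph)^2, 0.9, "cm/s")
  stim <- sampled_waveform(55 + 45 * sin(pi * ph)^2, 0.8, "cm/s")
  b <- 1.72
  d_cfd <- relative_change(extract_metrics(rest), extract_metrics(stim))
  d_tcd <- relative_change(
    extract_metrics(synth_tcd_envelope(rest, b, 0)),
    extract_metrics(synth_tcd_envelope(stim, b, 0)))
  expect_equal(unclass(d_cfd), unclass(d_tcd), tolerance = 1e-12)
})

test_that("synth_cohort is deterministic with independent sub-streams", {
  cfg <- cohort_config(n_participants = 3, n_phase = 32,
                       samples_per_cycle = 32, seed = 12)
  c1 <- synth_cohort(cfg)
  c2 <- synth_cohort(cfg)
  expect_identical(c1[[2]]$bias_factors, c2[[2]]$bias_factors)
  expect_identical(c1[[3]]$conditions$rest$tcd, c2[[3]]$conditions$rest$tcd)
  expect_identical(c1[[1]]$drawn_flows, c2[[1]]$drawn_flows)
  # different master seed changes the draws
  c3 <- synth_cohort(cohort_config(n_participants = 3, n_phase = 32,
                                   samples_per_cycle = 32, seed = 13))
  expect_false(identical(c1[[1]]$drawn_flows, c3[[1]]$drawn_flows))
  # sub-streams are keyed by participant index, not by draw order: the
  # first participants of cohorts differing only in size are identical
  c4 <- synth_cohort(cohort_config(n_participants = 4, n_phase = 32,
                                   samples_per_cycle = 32, seed = 12))
  expect_identical(c1[[1]]$drawn_flows, c4[[1]]$drawn_flows)
  expect_identical(c1[[3]]$conditions$rest$cfd, c4[[3]]$conditions$rest$cfd)
})

test_that("generated cohorts satisfy all upstream type invariants", {
  cfg <- cohort_config(n_participants = 3, n_phase = 32,
                       samples_per_cycle = 32, seed = 31)
  coh <- synth_cohort(cfg)
  for (p in coh) {
    expect_s3_class(p$network, "vascular_network")
    for (cd in names(p$recordings)) for (rec in p$recordings[[cd]]) {
      expect_s3_class(rec, "duplex_recording")
      expect_true(all(vapply(rec$cycles, function(cy) all(cy$values >= 0),
                             logical(1))))
    }
    for (cd in names(p$conditions)) {
      m <- unclass(p$conditions[[cd]]$cfd)
      expect_lte(m[["end_diastolic"]], m[["time_averaged"]])
      expect_lte(m[["time_averaged"]], m[["systolic"]])
      expect_gt(p$conditions[[cd]]$tcbf, 0)
    }
  }
  # TCD metrics systematically above CFD by construction
  st <- run_study(coh)
  expect_true(all(st$absolute_distributions$mean_tcd >
                  st$absolute_distributions$mean_cfd))
})
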