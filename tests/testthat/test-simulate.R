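test_that("simulators are byte-identical under a fixed seed", {
  s1 <- simulate_itraq(itraq_sim_spec(n_proteins = 30, n_phosphopeptides = 40, seed = 5))
  s2 <- simulate_itraq(itraq_sim_spec(n_proteins = 30, n_phosphopeptides = 40, seed = 5))
  expect_identical(s1, s2)
  s3 <- simulate_itraq(itraq_sim_spec(n_proteins = 30, n_phosphopeptides = 40, seed = 6))
  expect_false(identical(s1$proteins, s3$proteins))

  t1 <- simulate_tracks(track_sim_spec(n_tracks = 20, seed = 5))
  t2 <- simulate_tracks(track_sim_spec(n_tracks = 20, seed = 5))
  expect_identical(t1, t2)

  g1 <- simulate_growth(c(wt = 1, m = 0.5), seed = 5)
  g2 <- simulate_growth(c(wt = 1, m = 0.5), seed = 5)
  expect_identical(g1, g2)
})

test_that("generated tables pass the consumer validators unchanged", {
  sim <- simulate_itraq(itraq_sim_spec(n_proteins = 40, n_phosphopeptides = 60, seed = 2))
  expect_silent(validate_quant_table(sim$proteins, sim$channel_map, "protein"))
  expect_silent(validate_quant_table(sim$phospho, sim$channel_map, "phosphopeptide"))

  trk <- simulate_tracks(track_sim_spec(n_tracks = 20, seed = 2))
  expect_silent(validate_tracks(trk$tracks))
  expect_true(all(trk$tracks$position_um >= 0 &
    trk$tracks$position_um <= 100))
})

test_that("channel bias is recovered by the normalizer up to common scale", {
  bias <- c(1.5, 0.75, 1.2, 0.8, 1.0, 1.1, 0.9, 1.05)
  spec <- itraq_sim_spec(n_proteins = 2000, n_phosphopeptides = 10,
    channel_bias = bias, peptide_noise_sd = 0.01,
    protein_scatter_sd = 0, regulated_fraction = 0, seed = 9)
  sim <- simulate_itraq(spec)
  fac <- compute_channel_factors(sim$proteins, sim$channel_map)
  # factors proportional to 1/bias
  est <- fac$factor / mean(fac$factor)
  truth <- (1 / bias) / mean(1 / bias)
  expect_equal(est, truth, tolerance = 0.02)
})

test_that("spiked effects and parent-protein flatness shape the truth table", {
  spec <- itraq_sim_spec(n_proteins = 100, n_phosphopeptides = 200,
    regulated_fraction = 0.2, seed = 4)
  sim <- simulate_itraq(spec)
  truth <- sim$truth
  expect_setequal(unique(truth$condition), c("pro11", "pp2Ac1pro22", "pro11pro22"))
  reg <- dplyr::filter(truth, regulated)
  expect_true(all(reg$true_log2fc == spec$effect_size))
  expect_gt(nrow(reg), 0)
  # a regulated fraction of 0 yields an all-null truth table
  null_sim <- simulate_itraq(itraq_sim_spec(n_proteins = 20,
    n_phosphopeptides = 30, regulated_fraction = 0, seed = 4))
  expect_false(any(null_sim$truth$regulated))
})

test_that("noise-free growth assays return the true relative rates exactly", {
  truth <- c(wt = 1, pro45 = 0.494, pro11 = 0.413, gul1 = 0.189)
  growth <- simulate_growth(truth, rep_noise_cv = 0, seed = 1)
  rel <- relative_growth(growth)
  expect_equal(rel$rel_rate[match(names(truth), rel$strain)], unname(truth))
  expect_equal(nrow(growth), length(truth) * 9)  # 3 bio x 3 tech
})

test_that("track simulator honours processive fraction and guarantees ranges", {
  sim <- simulate_tracks(track_sim_spec(n_tracks = 100, processive_fraction = 0.5,
    seed = 8))
  st <- track_stats(sim$tracks)
  joined <- dplyr::inner_join(st, sim$truth, by = c("hypha_id", "track_id", "channel"))
  # analyzer's processivity equals the generator's label
  expect_equal(joined$processive.x, joined$processive.y)
  expect_true(all(joined$range_um[joined$processive.y] >= 5))
  expect_true(all(joined$range_um[!joined$processive.y] < 5))
})

test_that("inhibited mode suppresses processive density", {
  control <- simulate_tracks(track_sim_spec(n_tracks = 100,
    processive_fraction = 0.5, seed = 12))
  treated <- simulate_tracks(track_sim_spec(n_tracks = 100, inhibited = TRUE,
    seed = 13))
  cs <- shuttle_stats(control$tracks, control$observations)
  ts <- shuttle_stats(treated$tracks, treated$observations)
  res <- inhibition_contrast(cs, ts)
  expect_lt(res$ratio, 0.15)
})

test_that("infeasible track specs are rejected", {
  expect_error(track_sim_spec(duration = 3, speed_mean = 0.5, speed_sd = 0.05),
    "duration too short")
  expect_error(track_sim_spec(processive_fraction = 1.5), "processive_fraction")
  expect_error(itraq_sim_spec(regulated_fraction = 2), "regulated_fraction")
  expect_error(itraq_sim_spec(sty_proportions = c(0.5, 0.5, 0.5)), "sty_proportions")
})

test_that("generator-analyzer round trip recovers processive fractions", {
  for (p in c(0.22, 0.5, 0.59)) {
    devs <- vapply(1:3, function(s) {
      sim <- simulate_tracks(track_sim_spec(n_tracks = 800,
        processive_fraction = p, seed = 100 + s))
      est <- shuttle_summary(shuttle_stats(sim$tracks, sim$observations))
      abs(est$percent_processive - p * 100)
    }, numeric(1))
    expect_true(all(devs <= 5), label = paste("fraction", p))
  }
})

test_that("velocities are recovered within 10 percent across the speed range", {
  for (v in c(0.5, 2.5, 5)) {
    dur <- if (v < 1) 80 else 30
    sim <- simulate_tracks(track_sim_spec(n_tracks = 200,
      processive_fraction = 0.6, speed_mean = v, speed_sd = v * 0.1,
      duration = dur, seed = 10))
    est <- shuttle_summary(shuttle_stats(sim$tracks, sim$observations))
    expect_lt(abs(est$mean_velocity_um_s - v) / v, 0.10,
      label = paste("speed", v))
  }
})
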