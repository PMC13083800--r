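test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_units = 10, duration_s = 60, seed = 5)
  expect_identical(generate_poisson_set(cfg)$spikes,
                   generate_poisson_set(cfg)$spikes)
  cfg2 <- synth_config(n_units = 10, duration_s = 60, seed = 5,
                       coupling = coupling_blocks(2, 0.5))
  expect_identical(generate_correlated_set(cfg2)$spikes,
                   generate_correlated_set(cfg2)$spikes)
  cfg3 <- synth_config(n_units = 8, duration_s = 60, seed = 5,
                       burst_spec = burst_spec(5, 0.2))
  expect_identical(generate_bursting_set(cfg3)$set$spikes,
                   generate_bursting_set(cfg3)$set$spikes)
})

test_that("Poisson set hits its target rates", {
  # fixed-rate unit: spike count within the Poisson 99% interval
  s1 <- generate_poisson_set(synth_config(n_units = 1, duration_s = 300,
                                          rate_hz = 1, seed = 8))
  lam <- 300
  expect_gte(length(s1$spikes[[1]]), qpois(0.005, lam))
  expect_lte(length(s1$spikes[[1]]), qpois(0.995, lam))

  # empirical mean log10-rate within 3 SE of mu
  cfg <- synth_config(n_units = 50, duration_s = 300, rate_mu = 0,
                      rate_sigma = 0.25, seed = 9)
  s <- generate_poisson_set(cfg)
  lr <- log10(firing_rates(s))
  se <- cfg$rate_sigma / sqrt(cfg$n_units)
  expect_lt(abs(mean(lr) - cfg$rate_mu), 3 * se + 0.05)

  # empirical per-unit rate near its drawn target at 300 s
  target <- attr(s, "rates_hz")
  emp <- firing_rates(s)
  se_rate <- sqrt(target / 300)
  expect_true(all(abs(emp - target) <= 3.5 * se_rate))
})

test_that("coupling drives STTC monotonically; full coupling gives 1", {
  # coupling 1, zero jitter, equal rates -> identical trains
  s <- generate_correlated_set(
    synth_config(n_units = 2, duration_s = 60, rate_hz = 2,
                 coupling = coupling_groups(list(list(units = 1:2, c = 1))),
                 jitter_sd_s = 0, seed = 3))
  expect_identical(s$spikes[[1]], s$spikes[[2]])
  expect_equal(sttc_pair(s$spikes[[1]], s$spikes[[2]], 0.010, c(0, 60)), 1)

  # mean pair STTC non-decreasing in coupling (averaged over seeds)
  mean_sttc <- function(cpl) {
    mean(vapply(1:6, function(sd) {
      ss <- generate_correlated_set(
        synth_config(n_units = 2, duration_s = 120, rate_hz = 2,
                     coupling = coupling_groups(list(list(units = 1:2,
                                                          c = cpl))),
                     seed = sd))
      sttc_pair(ss$spikes[[1]], ss$spikes[[2]], 0.010, c(0, 120))
    }, numeric(1)))
  }
  curve <- vapply(c(0.1, 0.4, 0.7, 1.0), mean_sttc, numeric(1))
  expect_true(all(diff(curve) > 0))

  # zero coupling: pair indistinguishable from independent Poisson
  s0 <- generate_correlated_set(
    synth_config(n_units = 10, duration_s = 120, rate_hz = 2,
                 coupling = coupling_blocks(2, 0), seed = 4))
  expect_lt(abs(sttc_summary(sttc_matrix(s0))$mean), 0.03)

  expect_error(generate_correlated_set(
    synth_config(n_units = 2, duration_s = 60, rate_hz = c(0.1, 5),
                 coupling = coupling_groups(list(list(units = 1:2, c = 1))),
                 seed = 1)), NA) # parent rate = min rate keeps c=1 feasible
})

test_that("infeasible coupling demand is rejected", {
  # two parents (module + hub/global) can exceed a unit's rate budget
  expect_error(generate_correlated_set(
    synth_config(n_units = 4, duration_s = 60, rate_hz = 1,
                 coupling = coupling_blocks(1, 0.8),
                 hub_spec = list(n_hubs = 2, hub_coupling = 0.8),
                 seed = 1)), "infeasible")
})

test_that("bursting generator plants bursts, backbone and background", {
  cfg <- synth_config(n_units = 12, duration_s = 60, seed = 13,
                      burst_spec = burst_spec(10, 0.2,
                                              background_rate_hz = 0,
                                              backbone = 1:2))
  gb <- generate_bursting_set(cfg)
  expect_equal(nrow(gb$bursts$bursts), 10L)
  expect_identical(gb$backbone, c("u1", "u2"))
  # backbone units emit >= 2 spikes in every burst by construction
  expect_true(all(gb$bursts$participation[, 1:2] >= 2))
  # zero background: every spike lies inside a ground-truth window
  w <- gb$bursts$bursts
  for (t in gb$set$spikes) {
    inside <- rep(FALSE, length(t))
    for (k in seq_len(nrow(w))) {
      inside <- inside | (t >= w$t_start[k] & t < w$t_end[k])
    }
    expect_true(all(inside))
  }
  expect_error(generate_bursting_set(
    synth_config(n_units = 2, duration_s = 1, seed = 1,
                 burst_spec = burst_spec(10, 0.2))), "fit")
})

test_that("development profiles rise (DF) or stay flat (VF) in STTC", {
  mean_by_stage <- function(profile, seed) {
    ser <- generate_development_series(profile, c(25, 40, 55), seed = seed,
                                       n_units = 20, duration_s = 120)
    vapply(ser, function(s) sttc_summary(sttc_matrix(s))$mean, numeric(1))
  }
  df <- rowMeans(vapply(1:5, function(sd) mean_by_stage("DF_like", sd),
                        numeric(3)))
  expect_true(all(diff(df) > 0))
  vf <- rowMeans(vapply(1:5, function(sd) mean_by_stage("VF_like", sd),
                        numeric(3)))
  # flat synchrony: log-mean STTC slope near zero across days 25..55
  slope <- coef(lm(log10(vf) ~ c(25, 40, 55)))[[2]]
  expect_lt(abs(slope), 0.0025)

  # per-stage rates stay log-normal (Shapiro on log rates)
  ser <- generate_development_series("DF_like", c(25, 40, 55), seed = 2,
                                     n_units = 30, duration_s = 120)
  p <- vapply(ser, function(s) {
    shapiro.test(log10(firing_rates(s)))$p.value
  }, numeric(1))
  expect_gte(sum(p > 0.01), 2)

  # metadata carries region and age
  expect_equal(ser[[1]]$metadata$region, "DF")
  expect_equal(vapply(ser, function(s) s$metadata$age_days, integer(1)),
               c(25L, 40L, 55L))
})
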