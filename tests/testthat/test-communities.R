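fake_partition <- function(membership) {
  structure(list(membership = membership,
                 n_modules = length(unique(membership)),
                 modularity_Q = NA_real_, resolution = 1, seed = 1L),
            class = "community_partition")
}

test_that("Louvain recovers disconnected cliques with Q = 0.5", {
  g <- fg_from_adj(two_cliques_adj(5))
  p <- louvain_partition(g, seed = 3)
  expect_equal(p$n_modules, 2L)
  expect_equal(p$modularity_Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(p$membership[1:5])), 1L)
  expect_equal(length(unique(p$membership[6:10])), 1L)
  expect_false(p$membership[1] == p$membership[6])
})

test_that("a complete graph stays one module and Q matches the formula", {
  adj <- matrix(1L, 6, 6)
  diag(adj) <- 0L
  p <- louvain_partition(fg_from_adj(adj), seed = 1)
  expect_equal(p$n_modules, 1L)

  set.seed(13)
  for (i in 1:10) {
    a <- random_gnp_adj(12, 0.4)
    w <- a * matrix(runif(144, 0.1, 1), 12)
    w <- (w + t(w)) / 2
    g <- fg_from_adj(a, weights = ifelse(a > 0, w, NA_real_))
    p <- louvain_partition(g, seed = i)
    expect_equal(p$modularity_Q,
                 modularity_direct(w, unname(p$membership)),
                 tolerance = 1e-12)
    # never below the all-singleton partition
    singleton_q <- modularity_direct(w, seq_len(12))
    expect_gte(p$modularity_Q, singleton_q)
  }
})

test_that("edgeless graphs yield singleton modules with a warning", {
  expect_warning(p <- louvain_partition(fg_from_adj(matrix(0L, 4, 4))),
                 "no edges")
  expect_equal(p$n_modules, 4L)
  expect_equal(p$modularity_Q, 0)
})

test_that("partitions are seed-deterministic and relabeling-invariant", {
  set.seed(29)
  adj <- random_gnp_adj(16, 0.3)
  ids <- paste0("n", 1:16)
  g1 <- fg_from_adj(adj, ids = ids)
  p1 <- louvain_partition(g1, seed = 7)
  expect_identical(p1$membership, louvain_partition(g1, seed = 7)$membership)
  perm <- sample(16)
  g2 <- fg_from_adj(adj[perm, perm], ids = ids[perm])
  p2 <- louvain_partition(g2, seed = 7)
  common <- sort(ids)
  expect_equal(ari(p1$membership[common], p2$membership[common]), 1)
})

# --- module-level burst dynamics fixtures ------------------------------

# n_units split into two modules; each burst is a Gaussian packet of
# spikes around its center; `centers_by_module` gives per-module burst
# centers (NA = module silent in that burst).
module_burst_fixture <- function(centers_a, centers_b, n_per_module = 8,
                                 sd_s = 0.03, spikes_per_unit = 4,
                                 duration = NULL, seed = 1) {
  set.seed(seed)
  duration <- duration %||% (max(c(centers_a, centers_b), na.rm = TRUE) + 1)
  mk <- function(centers) {
    lapply(seq_len(n_per_module), function(i) {
      t <- unlist(lapply(centers[!is.na(centers)], function(cc) {
        rnorm(spikes_per_unit, cc, sd_s)
      }))
      sort(pmin(pmax(t, 0), duration - 1e-6))
    })
  }
  spikes <- c(mk(centers_a), mk(centers_b))
  names(spikes) <- paste0("u", seq_along(spikes))
  s <- spike_train_set(spikes, t_end = duration)
  membership <- setNames(rep(1:2, each = n_per_module), names(spikes))
  list(s = s, partition = fake_partition(membership))
}

test_that("globally synchronized modules show high burst correlations", {
  centers <- seq(2, 20, by = 2)
  fx <- module_burst_fixture(centers, centers, seed = 11)
  b <- detect_network_bursts(fx$s)
  expect_gte(nrow(b$bursts), 2)
  mbc <- module_burst_correlation(fx$partition, fx$s, b)
  expect_equal(nrow(mbc$pairs), 1L)  # 2 modules -> 1 pair
  expect_gt(mbc$mean, 0.9)
})

test_that("modules bursting in disjoint windows anticorrelate", {
  centers <- seq(2, 20, by = 2)
  odd <- centers[c(TRUE, FALSE)]
  even <- centers[c(FALSE, TRUE)]
  fx <- module_burst_fixture(odd, even, seed = 12)
  b <- detect_network_bursts(fx$s)
  mbc <- module_burst_correlation(fx$partition, fx$s, b)
  expect_lte(mbc$mean, 0)
})

test_that("module-pair accounting excludes self pairs", {
  centers <- seq(2, 12, by = 2)
  fx <- module_burst_fixture(centers, centers, seed = 13)
  membership <- fx$partition$membership
  membership[1:4] <- 3L  # three modules
  b <- detect_network_bursts(fx$s)
  mbc <- module_burst_correlation(fake_partition(membership), fx$s, b)
  expect_equal(nrow(mbc$pairs), 3L)  # 3 choose 2
  expect_warning(
    module_burst_correlation(fake_partition(setNames(rep(1, n_units(fx$s)),
                                                     names(membership))),
                             fx$s, b), "fewer than 2 modules")
})

test_that("burst timing spreads recover scripted lags and jitter", {
  # identical modules: zero lag, zero spread
  centers <- seq(2, 20, by = 2) + 0.005
  n_per <- 8
  mk_exact <- function(centers) {
    lapply(seq_len(n_per), function(i) centers)
  }
  spikes <- c(mk_exact(centers), mk_exact(centers + 0.030))
  names(spikes) <- paste0("u", seq_along(spikes))
  s <- spike_train_set(spikes, t_end = 21)
  part <- fake_partition(setNames(rep(1:2, each = n_per), names(spikes)))
  b <- structure(list(
    bursts = data.frame(t_start = centers - 0.2, t_peak = centers,
                        t_end = centers + 0.2),
    participation = NULL, params = burst_params(),
    unit_ids = names(spikes)), class = "burst_set")
  tv <- burst_timing_variability(part, s, b)
  expect_equal(tv$spread_ms, c(0, 0), tolerance = 1e-9)
  expect_equal(tv$mean_lag_ms, c(0, 30), tolerance = 1e-6)

  # jittered module: recovered spread near the planted 20 ms SD
  sds <- vapply(1:10, function(sd) {
    set.seed(100 + sd)
    centers <- seq(2, 60, by = 2) + 0.005
    jit <- pmin(pmax(rnorm(length(centers), 0, 0.020), -0.15), 0.15)
    spikes <- c(mk_exact(centers),
                lapply(seq_len(n_per), function(i) centers + jit))
    names(spikes) <- paste0("u", seq_along(spikes))
    s <- spike_train_set(spikes, t_end = 62)
    b <- structure(list(
      bursts = data.frame(t_start = centers - 0.25, t_peak = centers,
                          t_end = centers + 0.25),
      participation = NULL, params = burst_params(),
      unit_ids = names(spikes)), class = "burst_set")
    part <- fake_partition(setNames(rep(1:2, each = n_per), names(spikes)))
    burst_timing_variability(part, s, b)$spread_ms[2]
  }, numeric(1))
  expect_gte(mean(sds), 14)
  expect_lte(mean(sds), 26)
})

test_that("modules silent in most bursts are flagged", {
  centers <- seq(2, 20, by = 2) + 0.005
  n_per <- 6
  spikes <- c(lapply(seq_len(n_per), function(i) centers),
              lapply(seq_len(n_per), function(i) centers[1:2]))
  names(spikes) <- paste0("u", seq_along(spikes))
  s <- spike_train_set(spikes, t_end = 21)
  part <- fake_partition(setNames(rep(1:2, each = n_per), names(spikes)))
  b <- structure(list(
    bursts = data.frame(t_start = centers - 0.2, t_peak = centers,
                        t_end = centers + 0.2),
    participation = NULL, params = burst_params(),
    unit_ids = names(spikes)), class = "burst_set")
  tv <- burst_timing_variability(part, s, b)
  expect_false(tv$flagged[1])
  expect_true(tv$flagged[2])
  expect_equal(tv$n_bursts_used[2], 2L)
})
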