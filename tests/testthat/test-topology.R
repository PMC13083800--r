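complete_adj <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

test_that("clustering coefficient matches closed forms", {
  expect_equal(clustering_coefficient(fg_from_adj(complete_adj(5))), 1.0)
  # ring lattice with k neighbors: C = 3(k-2) / (4(k-1))
  expect_equal(clustering_coefficient(fg_from_adj(ring_lattice(20, 4))),
               3 * (4 - 2) / (4 * (4 - 1)))
  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1L
  expect_equal(clustering_coefficient(fg_from_adj(star)), 0.0)
})

test_that("path length is exact on small graphs and reports coverage", {
  expect_equal(as.numeric(path_length(fg_from_adj(complete_adj(4)))), 1.0)
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  expect_equal(as.numeric(path_length(fg_from_adj(path3))), 4 / 3)
  # two disconnected dyads: L within the largest component, coverage 1/2
  dyads <- matrix(0L, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1L
  L <- path_length(fg_from_adj(dyads))
  expect_equal(as.numeric(L), 1.0)
  expect_equal(attr(L, "coverage"), 0.5)
  expect_warning(L0 <- path_length(fg_from_adj(matrix(0L, 3, 3))),
                 "no edges")
  expect_true(is.na(L0))
})

test_that("degree-preserving references keep degrees and are seeded", {
  g <- fg_from_adj(ring_lattice(30, 4))
  r1 <- random_reference(g, n_rand = 3, seed = 5)
  r2 <- random_reference(g, n_rand = 3, seed = 5)
  expect_identical(r1, r2)
  # complete graph cannot be rewired into anything else
  rc <- random_reference(fg_from_adj(complete_adj(6)), n_rand = 2, seed = 1)
  expect_equal(rc$C_rand, 1.0)
  expect_equal(rc$L_rand, 1.0)
  # a large sparse lattice loses its clustering under rewiring
  big <- fg_from_adj(ring_lattice(100, 4))
  rr <- random_reference(big, n_rand = 5, seed = 2)
  expect_gt(clustering_coefficient(big) / rr$C_rand, 5)
})

test_that("small-world index calibrates on random and lattice graphs", {
  expect_equal(small_world_index(fg_from_adj(complete_adj(6)), n_rand = 2,
                                 seed = 1)$S, 1.0)
  set.seed(31)
  S_er <- small_world_index(fg_from_adj(random_gnp_adj(100, 0.1)),
                            n_rand = 20, seed = 3)$S
  expect_gt(S_er, 0.8)
  expect_lt(S_er, 1.2)
  ws <- igraph::sample_smallworld(1, 100, 3, 0.1)
  expect_gt(small_world_index(ws, n_rand = 20, seed = 4)$S, 1.5)
})

test_that("k-core numbers match the brute-force pruning oracle", {
  # triangle plus pendant: cores 2,2,2 and 1
  tri <- matrix(0L, 4, 4)
  tri[1, 2] <- tri[2, 1] <- tri[2, 3] <- tri[3, 2] <- tri[1, 3] <-
    tri[3, 1] <- tri[1, 4] <- tri[4, 1] <- 1L
  kc <- kcore_decomposition(fg_from_adj(tri))
  expect_equal(unname(kc$core_number), c(2, 2, 2, 1))
  expect_equal(unname(kc$core_label), c("core", "core", "core", "periphery"))

  expect_equal(unname(kcore_decomposition(fg_from_adj(matrix(0L, 4, 4)))$
                        core_number), rep(0, 4))
  expect_equal(unname(kcore_decomposition(fg_from_adj(complete_adj(6)))$
                        core_number), rep(5, 6))

  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    adj <- random_gnp_adj(n, runif(1, 0.2, 0.7))
    expect_equal(unname(kcore_decomposition(fg_from_adj(adj))$core_number),
                 kcore_oracle(adj))
  }
})

test_that("core-periphery density equals exhaustive pair enumeration", {
  # triangle core {1,2,3}, periphery {4,5}, single cross edge 1-4 -> 1/6
  adj <- matrix(0L, 5, 5)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(1, 4))) {
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1L
  }
  g <- fg_from_adj(adj)
  labs <- setNames(c("core", "core", "core", "periphery", "periphery"),
                   g$unit_ids)
  expect_equal(core_periphery_density(g, labs), 1 / 6)

  adj[1, 4] <- adj[4, 1] <- 0L
  expect_equal(core_periphery_density(fg_from_adj(adj), labs), 0.0)
  adj2 <- adj
  adj2[1:3, 4:5] <- 1L
  adj2[4:5, 1:3] <- 1L
  expect_equal(core_periphery_density(fg_from_adj(adj2), labs), 1.0)

  # exhaustive enumeration oracle on random graphs with random labels
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    adj <- random_gnp_adj(n, 0.4)
    g <- fg_from_adj(adj)
    labs <- setNames(sample(c("core", "periphery"), n, replace = TRUE),
                     g$unit_ids)
    if (length(unique(labs)) < 2) next
    cross <- 0
    for (a in which(labs == "core")) {
      for (b in which(labs == "periphery")) cross <- cross + adj[a, b]
    }
    expect_equal(core_periphery_density(g, labs),
                 cross / (sum(labs == "core") * sum(labs == "periphery")))
  }

  expect_warning(
    d <- core_periphery_density(fg_from_adj(complete_adj(4)),
                                setNames(rep("core", 4), paste0("u", 1:4))),
    "empty")
  expect_true(is.na(d))
})

test_that("hubness is maximal at a star center and vanishes on a cycle", {
  star <- matrix(0L, 10, 10)
  star[1, 2:10] <- star[2:10, 1] <- 1L
  h <- hubness_scores(fg_from_adj(star))
  expect_equal(h$scores$unit_id[which.max(h$scores$hubness)], "u1")
  expect_true("u1" %in% h$hubs)

  cyc <- ring_lattice(8, 2)
  w <- capture_warnings(hc <- hubness_scores(fg_from_adj(cyc)))
  expect_true(all(grepl("zero variance", w)))
  expect_length(w, 4L)  # all four centralities are constant on a cycle
  expect_equal(hc$scores$hubness, rep(0, 8))
})

test_that("a planted hub unit is recovered in the detected hub set", {
  hits <- vapply(1:10, function(sd) {
    cfg <- synth_config(n_units = 20, duration_s = 120, rate_hz = 1.5,
                        coupling = coupling_blocks(4, 0.35, 0.10),
                        hub_spec = list(n_hubs = 1, hub_coupling = 0.6),
                        seed = sd)
    s <- generate_correlated_set(cfg)
    m <- sttc_matrix(s)
    nd <- null_distribution(s, cfg = surrogate_config(n_surrogates = 15,
                                                      seed = sd + 50))
    g <- build_graph(m, nd)
    "u1" %in% hubness_scores(g, hub_fraction = 0.1)$hubs
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("topology metrics are invariant under node relabeling", {
  set.seed(47)
  adj <- random_gnp_adj(12, 0.35)
  g1 <- fg_from_adj(adj, ids = paste0("a", 1:12))
  perm <- sample(12)
  g2 <- fg_from_adj(adj[perm, perm], ids = paste0("a", 1:12)[perm])
  expect_equal(clustering_coefficient(g1), clustering_coefficient(g2))
  expect_equal(as.numeric(path_length(g1)), as.numeric(path_length(g2)))
  k1 <- kcore_decomposition(g1)$core_number
  k2 <- kcore_decomposition(g2)$core_number
  expect_equal(k1[sort(names(k1))], k2[sort(names(k2))])
  expect_equal(core_periphery_density(g1), core_periphery_density(g2))
})
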