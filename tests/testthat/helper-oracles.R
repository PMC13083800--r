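# Independent oracles used to validate the optimized implementations.
# These deliberately use different algorithms from the package code.

# Brute-force STTC: tiling fraction by an explicit event-sweep interval
# union, and P by an O(n*m) double loop over spike pairs.
sttc_oracle <- function(a, b, dt, window) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  union_len <- function(t) {
    iv <- cbind(pmax(t - dt, window[1]), pmin(t + dt, window[2]))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    total <- 0
    cur_s <- iv[1, 1]
    cur_e <- iv[1, 2]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv[k, 1] > cur_e) {
        total <- total + (cur_e - cur_s)
        cur_s <- iv[k, 1]
        cur_e <- iv[k, 2]
      } else {
        cur_e <- max(cur_e, iv[k, 2])
      }
    }
    total + (cur_e - cur_s)
  }
  Ta <- union_len(a) / diff(window)
  Tb <- union_len(b) / diff(window)
  prop <- function(x, y) {
    hit <- vapply(x, function(t) any(abs(t - y) <= dt), logical(1))
    mean(hit)
  }
  Pa <- prop(a, b)
  Pb <- prop(b, a)
  d1 <- 1 - Pa * Tb
  d2 <- 1 - Pb * Ta
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * ((Pa - Tb) / d1 + (Pb - Ta) / d2)
}

# Brute-force k-core numbers by literal iterative pruning of an adjacency
# matrix at each k.
kcore_oracle <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE]) * alive
      kill <- alive & deg < k
      if (!any(kill)) break
      alive[kill] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

# Direct evaluation of weighted Newman-Girvan modularity for a membership
# vector on an adjacency/weight matrix.
modularity_direct <- function(w, membership, resolution = 1) {
  w[is.na(w)] <- 0
  two_m <- sum(w)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - resolution * outer(k, k) / two_m) * same) / two_m
}

# Adjusted Rand index between two labelings.
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# Build a functional_graph object directly from a binary adjacency matrix
# (weights default to the adjacency itself), for topology unit tests.
fg_from_adj <- function(adj, weights = NULL, ids = NULL) {
  n <- nrow(adj)
  ids <- ids %||% paste0("u", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  w <- weights %||% ifelse(adj > 0, 1, NA_real_)
  dimnames(w) <- dimnames(adj)
  structure(list(adjacency = adj, weights = w, threshold = 0,
                 unit_ids = ids,
                 config = sttcnet::surrogate_config(n_surrogates = 1),
                 n_dropped_units = 0L),
            class = "functional_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ring lattice where each node connects to its k nearest neighbors.
ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# Paired-fixture helper: raise the synchrony of an existing set while
# preserving every unit's spike count exactly, by moving a fraction of
# each unit's spikes onto a shared event train (plus small jitter). The
# synthetic analogue of a drug that changes coupling but not rates.
raise_coupling <- function(s, coupling, jitter_sd = 0.002, seed = 1) {
  set.seed(seed)
  D <- s$t_end - s$t_start
  pr <- max(min(lengths(s$spikes) / D), 0.5)
  parent <- sort(runif(rpois(1, pr * D), s$t_start, s$t_end))
  sp <- lapply(s$spikes, function(t) {
    n_move <- min(rbinom(1, length(t), coupling), length(parent))
    if (n_move == 0) return(t)
    idx <- sample(length(t), n_move)
    tgt <- sample(parent, n_move) + rnorm(n_move, 0, jitter_sd)
    tgt <- s$t_start + (tgt - s$t_start) %% D
    sort(c(t[-idx], tgt))
  })
  out <- s
  out$spikes <- sp
  out
}

two_cliques_adj <- function(k = 5) {
  n <- 2 * k
  adj <- matrix(0L, n, n)
  adj[1:k, 1:k] <- 1L
  adj[(k + 1):n, (k + 1):n] <- 1L
  diag(adj) <- 0L
  adj
}

random_gnp_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}
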