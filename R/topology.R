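# Graph-topology metrics on the binary functional graph. All functions
# accept either a `functional_graph` or a plain undirected igraph object,
# so calibration graphs (Erdos-Renyi, Watts-Strogatz, lattices) can be fed
# straight in.

to_igraph <- function(g, weighted = TRUE) {
  if (inherits(g, "igraph")) return(g)
  if (inherits(g, "functional_graph")) return(as_igraph(g, weighted))
  stop_param("expected a functional_graph or igraph object")
}

#' Mean local clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient (triangles over
#' connected triples); nodes of degree 0 or 1 contribute 0.
#'
#' @param g a `functional_graph` or igraph object with at least 3 nodes.
#' @return C in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  ig <- to_igraph(g, weighted = FALSE)
  if (igraph::vcount(ig) < 3L) stop_param("need at least 3 nodes")
  mean(igraph::transitivity(ig, type = "localundirected", isolates = "zero"))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected ordered pairs within the
#' largest connected component. Functional graphs thresholded at high null
#' percentiles are often disconnected, so the fraction of nodes covered by
#' that component is attached as attribute `"coverage"`.
#'
#' @param g a `functional_graph` or igraph object with at least one edge.
#' @return L (`>= 1`), with attribute `coverage`; `NA` (with a warning) on
#'   edgeless graphs.
#' @export
path_length <- function(g) {
  ig <- to_igraph(g, weighted = FALSE)
  if (igraph::ecount(ig) == 0L) {
    warning("graph has no edges; path length undefined", call. = FALSE)
    return(structure(NA_real_, coverage = 0))
  }
  comp <- igraph::components(ig)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(ig, which(comp$membership == big))
  L <- igraph::mean_distance(sub, directed = FALSE, weights = NA)
  structure(L, coverage = comp$csize[big] / igraph::vcount(ig))
}

#' Degree-preserving random reference values
#'
#' Generates `n_rand` rewired versions of the graph (double-edge swaps,
#' `10 * |E|` swaps each), preserving the degree sequence exactly, and
#' returns the mean clustering coefficient and mean path length across
#' them. These are the denominators of the small-world normalization;
#' degree preservation avoids inflating `C_norm` on heavy-tailed graphs.
#'
#' @param g a `functional_graph` or igraph object.
#' @param n_rand number of random references (default 100).
#' @param seed integer seed.
#' @return list with `C_rand`, `L_rand`.
#' @export
random_reference <- function(g, n_rand = 100L, seed = NULL) {
  ig <- to_igraph(g, weighted = FALSE)
  if (n_rand < 1L) stop_param("n_rand must be >= 1")
  if (igraph::ecount(ig) < 2L) {
    warning("fewer than 2 edges; random reference undefined", call. = FALSE)
    return(list(C_rand = NA_real_, L_rand = NA_real_))
  }
  with_seed(seed, {
    Cs <- numeric(n_rand)
    Ls <- numeric(n_rand)
    niter <- 10L * igraph::ecount(ig)
    for (k in seq_len(n_rand)) {
      r <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
      Cs[k] <- clustering_coefficient(r)
      Ls[k] <- as.numeric(path_length(r))
    }
    list(C_rand = mean(Cs), L_rand = mean(Ls))
  })
}

#' Small-world index
#'
#' `S = (C / C_rand) / (L / L_rand)` with degree-preserving random
#' references. Values well above 1 indicate small-world organization
#' (clustering far above the random expectation at near-random path
#' length); matched random graphs sit near 1 by construction.
#'
#' @inheritParams random_reference
#' @return list with `S`, `C`, `L`, `C_rand`, `L_rand`, `C_norm`, `L_norm`.
#' @export
small_world_index <- function(g, n_rand = 100L, seed = NULL) {
  ig <- to_igraph(g, weighted = FALSE)
  C <- clustering_coefficient(ig)
  L <- as.numeric(path_length(ig))
  ref <- random_reference(ig, n_rand = n_rand, seed = seed)
  if (is.na(ref$C_rand) || is.na(ref$L_rand) ||
      ref$C_rand == 0 || ref$L_rand == 0 || is.na(L)) {
    warning("degenerate random references; S undefined", call. = FALSE)
    return(list(S = NA_real_, C = C, L = L, C_rand = ref$C_rand,
                L_rand = ref$L_rand, C_norm = NA_real_, L_norm = NA_real_))
  }
  C_norm <- C / ref$C_rand
  L_norm <- L / ref$L_rand
  list(S = C_norm / L_norm, C = C, L = L, C_rand = ref$C_rand,
       L_rand = ref$L_rand, C_norm = C_norm, L_norm = L_norm)
}

#' k-core decomposition and core/periphery labels
#'
#' The core number of a node is the largest k such that the node survives
#' iterative pruning of all nodes with degree < k. The "core" is the
#' maximum k-core (nodes whose core number equals the graph maximum);
#' every other node is "periphery". A fixed k can be supplied instead.
#'
#' @param g a `functional_graph` or igraph object.
#' @param k optional fixed k defining the core; default is the maximum
#'   core number.
#' @return list with `core_number` (named integer vector), `core_label`
#'   (named character, `"core"`/`"periphery"`), `k_max`.
#' @export
kcore_decomposition <- function(g, k = NULL) {
  ig <- to_igraph(g, weighted = FALSE)
  cn <- igraph::coreness(ig)
  names(cn) <- igraph::V(ig)$name %||% as.character(seq_along(cn))
  k_max <- if (length(cn)) max(cn) else 0L
  kk <- k %||% k_max
  lab <- ifelse(cn >= kk & kk > 0, "core", "periphery")
  names(lab) <- names(cn)
  list(core_number = cn, core_label = lab, k_max = k_max)
}

#' Core-periphery density
#'
#' Fraction of realized edges among all possible edges between the core
#' and the periphery: `|E(core, periphery)| / (|core| * |periphery|)`.
#'
#' @param g a `functional_graph` or igraph object.
#' @param labels optional named character vector of `"core"`/`"periphery"`
#'   labels; defaults to [kcore_decomposition()] of `g`.
#' @return density in `[0, 1]`; `NA` (with a warning) if either class is
#'   empty.
#' @export
core_periphery_density <- function(g, labels = NULL) {
  ig <- to_igraph(g, weighted = FALSE)
  labels <- labels %||% kcore_decomposition(ig)$core_label
  nm <- igraph::V(ig)$name %||% as.character(seq_len(igraph::vcount(ig)))
  lab <- labels[nm]
  n_core <- sum(lab == "core")
  n_peri <- sum(lab == "periphery")
  if (n_core == 0L || n_peri == 0L) {
    warning("core or periphery empty; density undefined", call. = FALSE)
    return(NA_real_)
  }
  el <- igraph::as_edgelist(ig, names = TRUE)
  cross <- sum(lab[el[, 1]] != lab[el[, 2]])
  cross / (n_core * n_peri)
}

#' Composite hubness scores and hub set
#'
#' Four per-node centralities — binary degree, strength (sum of retained
#' STTC edge weights), normalized shortest-path betweenness, and harmonic
#' closeness (robust to disconnection) — are each z-scored across nodes;
#' the composite is their mean. The hub set is the top `hub_fraction` of
#' nodes by composite score. A metric with zero variance contributes 0
#' with a warning.
#'
#' @param g a `functional_graph` (strength uses its STTC weights) or an
#'   igraph object (strength falls back to degree if unweighted).
#' @param hub_fraction fraction of nodes designated hubs (default 0.1).
#' @return list with `scores` (data frame: unit_id, degree, strength,
#'   betweenness, closeness, hubness), `hubs` (character vector).
#' @export
hubness_scores <- function(g, hub_fraction = 0.1) {
  ig <- to_igraph(g, weighted = TRUE)
  n <- igraph::vcount(ig)
  if (n < 3L || igraph::ecount(ig) < 1L) {
    stop_param("hubness needs >= 3 nodes and >= 1 edge")
  }
  nm <- igraph::V(ig)$name %||% as.character(seq_len(n))
  deg <- igraph::degree(ig)
  str <- if ("weight" %in% igraph::edge_attr_names(ig)) {
    igraph::strength(ig)
  } else deg
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = TRUE,
                             weights = NA)
  clo <- igraph::harmonic_centrality(ig, normalized = TRUE, weights = NA)
  zs <- function(x, what) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning(what, " has zero variance; its z-scores set to 0",
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  comp <- (zs(deg, "degree") + zs(str, "strength") +
             zs(btw, "betweenness") + zs(clo, "closeness")) / 4
  ord <- order(comp, decreasing = TRUE)
  n_hub <- max(1L, ceiling(hub_fraction * n))
  list(
    scores = data.frame(unit_id = nm, degree = deg, strength = str,
                        betweenness = btw, closeness = clo, hubness = comp,
                        row.names = NULL),
    hubs = nm[ord[seq_len(n_hub)]]
  )
}

#' Full topology report for a functional graph
#'
#' Bundles the small-world, core-periphery, hubness and modularity
#' summaries into one flat list (ready for JSON serialization).
#'
#' @param g a `functional_graph`.
#' @param n_rand random references for the small-world normalization.
#' @param seed integer seed (random references and Louvain).
#' @param hub_fraction passed to [hubness_scores()].
#' @return list of class `topology_report`.
#' @export
topology_report <- function(g, n_rand = 100L, seed = 1L, hub_fraction = 0.1) {
  ig <- to_igraph(g, weighted = TRUE)
  n <- igraph::vcount(ig)
  e <- igraph::ecount(ig)
  sw <- if (n >= 3L && e >= 2L) {
    small_world_index(ig, n_rand = n_rand, seed = derive_seed(seed, 1L))
  } else {
    list(S = NA_real_, C = NA_real_, L = NA_real_, C_rand = NA_real_,
         L_rand = NA_real_, C_norm = NA_real_, L_norm = NA_real_)
  }
  kc <- kcore_decomposition(ig)
  cp <- suppressWarnings(core_periphery_density(ig, kc$core_label))
  hub <- if (n >= 3L && e >= 1L) {
    suppressWarnings(hubness_scores(g, hub_fraction))
  } else list(scores = NULL, hubs = character(0))
  part <- if (e >= 1L) {
    louvain_partition(g, seed = derive_seed(seed, 2L))
  } else NULL
  Lval <- sw$L
  structure(
    list(n_nodes = n, n_edges = e,
         C = sw$C, L = Lval, C_rand = sw$C_rand, L_rand = sw$L_rand,
         C_norm = sw$C_norm, L_norm = sw$L_norm, S = sw$S,
         k_max = kc$k_max, core_size = sum(kc$core_label == "core"),
         core_periphery_density = cp,
         modularity_Q = if (is.null(part)) NA_real_ else part$modularity_Q,
         n_modules = if (is.null(part)) NA_integer_ else part$n_modules,
         core_numbers = kc$core_number, core_label = kc$core_label,
         hub_scores = hub$scores, hubs = hub$hubs,
         partition = part),
    class = "topology_report"
  )
}
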