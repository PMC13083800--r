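#' Surrogate / thresholding configuration
#'
#' Settings for building the surrogate null distribution of STTC and for
#' binarizing the functional graph at a percentile of that null.
#'
#' Methods:
#' \describe{
#'   \item{`circular_shift`}{each unit's train is rotated by an independent
#'     uniform offset modulo the recording window. Preserves every unit's
#'     spike count, rate and inter-spike-interval structure while
#'     destroying cross-unit timing; the default and the statistically
#'     meaningful null.}
#'   \item{`isi_shuffle`}{each unit's inter-spike intervals are permuted
#'     (first spike kept). Preserves rate and the ISI marginal.}
#'   \item{`id_shuffle`}{unit labels are permuted across trains. Preserves
#'     all marginals — and, notably, the multiset of pairwise STTC values,
#'     so it cannot produce a null for STTC; provided for completeness and
#'     flagged with a warning when used for a null.}
#' }
#'
#' @param n_surrogates number of surrogate data sets (default 1000).
#' @param method surrogate method, see Details.
#' @param percentile null percentile used as edge threshold, in (0, 100)
#'   (default 90).
#' @param scope `"pooled"` (one recording-wide null, the default) or
#'   `"per_pair"` (one null per unit pair).
#' @param seed integer seed for the surrogate loop.
#' @return list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 1000L,
                             method = c("circular_shift", "isi_shuffle",
                                        "id_shuffle"),
                             percentile = 90, scope = c("pooled", "per_pair"),
                             seed = 1L) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (n_surrogates < 1L) stop_param("n_surrogates must be >= 1")
  if (percentile <= 0 || percentile >= 100) {
    stop_param("percentile must be in (0, 100)")
  }
  structure(list(n_surrogates = as.integer(n_surrogates), method = method,
                 percentile = percentile, scope = scope, seed = seed),
            class = "surrogate_config")
}

#' Generate one surrogate spike-train set
#'
#' All methods preserve every unit's spike count (hence firing rate)
#' exactly; see [surrogate_config()] for what each destroys.
#'
#' @param s a [spike_train_set()].
#' @param method one of `"circular_shift"`, `"isi_shuffle"`, `"id_shuffle"`.
#' @param seed optional integer seed.
#' @return a `spike_train_set` with the same units, window and metadata.
#' @export
make_surrogate <- function(s, method = c("circular_shift", "isi_shuffle",
                                         "id_shuffle"), seed = NULL) {
  method <- match.arg(method)
  with_seed(seed, {
    D <- duration_s(s)
    sp <- switch(method,
      circular_shift = lapply(s$spikes, function(t) {
        if (length(t) == 0L) return(t)
        sort(s$t_start + (t - s$t_start + stats::runif(1, 0, D)) %% D)
      }),
      isi_shuffle = lapply(s$spikes, function(t) {
        if (length(t) < 3L) return(t)
        t[1] + cumsum(c(0, sample(diff(t))))
      }),
      id_shuffle = {
        out <- s$spikes[sample(length(s$spikes))]
        names(out) <- s$unit_ids
        out
      }
    )
    out <- s
    out$spikes <- sp
    out
  })
}

#' Surrogate null distribution of STTC
#'
#' Computes the pairwise STTC of `cfg$n_surrogates` surrogate data sets.
#' With pooled scope all defined pair values are concatenated into one
#' empirical distribution; with per-pair scope a matrix (pairs x
#' surrogates) is kept.
#'
#' @param s a [spike_train_set()] with at least 2 units.
#' @param dt_s STTC coincidence half-window (seconds).
#' @param cfg a [surrogate_config()].
#' @return list of class `sttc_null`: `values` (vector, pooled) or
#'   `per_pair` (matrix), plus `dt_s`, `config`.
#' @export
null_distribution <- function(s, dt_s = 0.010, cfg = surrogate_config()) {
  if (n_units(s) < 2L) stop_param("need at least 2 units")
  if (cfg$method == "id_shuffle") {
    warning("id_shuffle leaves the set of pairwise STTC values unchanged; ",
            "the resulting null cannot separate signal from noise",
            call. = FALSE)
  }
  with_seed(cfg$seed, {
    per <- vector("list", cfg$n_surrogates)
    for (k in seq_len(cfg$n_surrogates)) {
      m <- sttc_matrix(make_surrogate(s, cfg$method), dt_s = dt_s)
      per[[k]] <- m$values[upper.tri(m$values)]
    }
    mat <- do.call(cbind, per)
    if (cfg$scope == "pooled") {
      vals <- as.numeric(mat)
      vals <- vals[!is.na(vals)]
      structure(list(values = vals, per_pair = NULL, dt_s = dt_s,
                     config = cfg), class = "sttc_null")
    } else {
      structure(list(values = NULL, per_pair = mat, dt_s = dt_s,
                     config = cfg), class = "sttc_null")
    }
  })
}

#' Threshold an STTC matrix against a surrogate null
#'
#' The edge threshold is the configured percentile of the null (one scalar
#' for pooled scope; one per pair for per-pair scope). An edge is present
#' iff the observed STTC is defined and strictly exceeds the threshold;
#' undefined pairs never become edges. Units whose train is empty are
#' excluded from the node set (they can carry no defined synchrony);
#' nodes left without edges are retained as isolated nodes.
#'
#' @param m an [sttc_matrix()].
#' @param null an `sttc_null` from [null_distribution()].
#' @param cfg a [surrogate_config()]; defaults to the one stored in `null`.
#' @return object of class `functional_graph`: `adjacency` (0/1 symmetric
#'   matrix), `weights` (STTC on edges, `NA` elsewhere), `threshold`,
#'   `unit_ids`, `config`, `n_dropped_units`.
#' @export
build_graph <- function(m, null, cfg = NULL) {
  cfg <- cfg %||% null$config
  keep <- !apply(m$values, 1L, function(r) all(is.na(r)))
  v <- m$values[keep, keep, drop = FALSE]
  n <- nrow(v)
  if (cfg$scope == "pooled") {
    if (length(null$values) == 0L) stop_param("empty null distribution")
    thr <- stats::quantile(null$values, cfg$percentile / 100, names = FALSE)
    thr_mat <- matrix(thr, n, n)
  } else {
    if (is.null(null$per_pair) || nrow(null$per_pair) == 0L) {
      stop_param("empty null distribution")
    }
    pt <- apply(null$per_pair, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(NA_real_)
      stats::quantile(x, cfg$percentile / 100, names = FALSE)
    })
    full <- matrix(NA_real_, length(m$unit_ids), length(m$unit_ids))
    full[upper.tri(full)] <- pt
    full[lower.tri(full)] <- t(full)[lower.tri(full)]
    thr_mat <- full[keep, keep, drop = FALSE]
    thr <- stats::median(pt, na.rm = TRUE)
  }
  adj <- !is.na(v) & !is.na(thr_mat) & v > thr_mat
  diag(adj) <- FALSE
  w <- ifelse(adj, v, NA_real_)
  structure(
    list(adjacency = adj * 1L, weights = w, threshold = thr,
         unit_ids = m$unit_ids[keep], config = cfg,
         n_dropped_units = sum(!keep)),
    class = "functional_graph"
  )
}

#' @export
print.functional_graph <- function(x, ...) {
  n <- length(x$unit_ids)
  e <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat(sprintf(
    "<functional_graph> %d nodes, %d edges (density %.3f), threshold %.4g\n",
    n, e, if (n > 1) e / (n * (n - 1) / 2) else NA_real_, x$threshold))
  invisible(x)
}

#' Convert a functional graph to an igraph object
#'
#' @param g a `functional_graph`.
#' @param weighted attach retained STTC weights to edges.
#' @return an undirected `igraph` graph with vertex attribute `name`.
#' @export
as_igraph <- function(g, weighted = TRUE) {
  a <- g$adjacency
  dimnames(a) <- list(g$unit_ids, g$unit_ids)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (weighted) {
    el <- igraph::as_edgelist(ig, names = TRUE)
    if (nrow(el) > 0) {
      igraph::E(ig)$weight <- g$weights[cbind(el[, 1], el[, 2])]
    }
  }
  ig
}

#' Write a functional graph as an edge list plus sidecar
#'
#' CSV columns `unit_a,unit_b,sttc_weight`; threshold provenance
#' (percentile, method, n_surrogates, seed) goes in `<path>.json`.
#'
#' @param g a `functional_graph`.
#' @param path output CSV path.
#' @export
write_graph_edges <- function(g, path) {
  ut <- upper.tri(g$adjacency)
  idx <- which(g$adjacency == 1L & ut, arr.ind = TRUE)
  el <- data.frame(unit_a = g$unit_ids[idx[, 1]],
                   unit_b = g$unit_ids[idx[, 2]],
                   sttc_weight = g$weights[idx])
  utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
  cfg <- g$config
  jsonlite::write_json(
    list(schema_version = "1.0", threshold = g$threshold,
         percentile = cfg$percentile, method = cfg$method,
         n_surrogates = cfg$n_surrogates, scope = cfg$scope,
         seed = cfg$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
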