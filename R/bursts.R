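#' Network-burst detector parameters
#'
#' The detector thresholds a smoothed population rate. All parameters are
#' carried in the returned `burst_set` so every detection is auditable.
#'
#' @param bin_s population-rate bin width in seconds (default 0.010).
#' @param smooth_sd_s SD of the Gaussian smoothing kernel in seconds
#'   (default 0.050).
#' @param threshold_k burst threshold is `mean + k * sd` of the smoothed
#'   rate (default 2).
#' @param min_duration_s minimum burst duration in seconds (default 0.050).
#' @param merge_gap_s bursts separated by less than this are merged
#'   (default 0.100).
#' @return list of class `burst_params`.
#' @export
burst_params <- function(bin_s = 0.010, smooth_sd_s = 0.050,
                         threshold_k = 2, min_duration_s = 0.050,
                         merge_gap_s = 0.100) {
  stopifnot(bin_s > 0, smooth_sd_s >= 0, min_duration_s >= 0,
            merge_gap_s >= 0)
  structure(list(bin_s = bin_s, smooth_sd_s = smooth_sd_s,
                 threshold_k = threshold_k, min_duration_s = min_duration_s,
                 merge_gap_s = merge_gap_s), class = "burst_params")
}

# Binned, Gaussian-smoothed population rate (spikes per second, summed over
# units). Returns bin centers and the smoothed rate.
smoothed_population_rate <- function(times, t_start, t_end, bin_s,
                                     smooth_sd_s) {
  n_bins <- floor((t_end - t_start) / bin_s)
  if (n_bins < 1L) stop_param("recording shorter than one bin")
  edges <- t_start + bin_s * (0:n_bins)
  counts <- if (length(times)) {
    times <- times[times < edges[n_bins + 1L]]
    tabulate(findInterval(times, edges, rightmost.closed = FALSE),
             nbins = n_bins)
  } else numeric(n_bins)
  rate <- counts / bin_s
  if (smooth_sd_s > 0) {
    half <- max(1L, ceiling(4 * smooth_sd_s / bin_s))
    kern <- stats::dnorm(seq(-half, half) * bin_s, sd = smooth_sd_s)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), rate, numeric(half))
    sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
    rate <- as.numeric(sm[(half + 1L):(half + n_bins)])
  }
  list(centers = t_start + bin_s * (seq_len(n_bins) - 0.5), rate = rate,
       edges = edges)
}

#' Detect network bursts from the population rate
#'
#' The pooled spike counts in fixed bins are smoothed with a Gaussian
#' kernel; a burst is a maximal interval where the smoothed rate exceeds
#' `mean + k * sd`, extended outward to the surrounding rate minimum on
#' each side. Bursts closer than `merge_gap_s` are merged, and bursts
#' shorter than `min_duration_s` dropped. The burst peak is the time of
#' the maximum smoothed rate within the burst.
#'
#' @param s a [spike_train_set()].
#' @param params a [burst_params()].
#' @return object of class `burst_set`: `bursts` (data frame with
#'   `t_start`, `t_peak`, `t_end`), `participation` (bursts x units spike
#'   counts), `params`, `unit_ids`.
#' @export
detect_network_bursts <- function(s, params = burst_params()) {
  all_times <- sort(unlist(s$spikes, use.names = FALSE))
  pr <- smoothed_population_rate(all_times, s$t_start, s$t_end,
                                 params$bin_s, params$smooth_sd_s)
  rate <- pr$rate
  thr <- mean(rate) + params$threshold_k * stats::sd(rate)
  above <- rate > thr
  bursts <- data.frame(t_start = numeric(0), t_peak = numeric(0),
                       t_end = numeric(0))
  if (any(above) && stats::sd(rate) > 0) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # extend each run outward while the rate keeps decreasing
    for (k in seq_len(nrow(runs))) {
      i <- runs[k, 1]
      while (i > 1L && rate[i - 1L] < rate[i]) i <- i - 1L
      j <- runs[k, 2]
      while (j < length(rate) && rate[j + 1L] < rate[j]) j <- j + 1L
      runs[k, ] <- c(i, j)
    }
    runs <- runs[order(runs[, 1]), , drop = FALSE]
    # merge overlapping or near-adjacent bursts
    merged <- runs[1, , drop = FALSE]
    gap_bins <- params$merge_gap_s / params$bin_s
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        last <- nrow(merged)
        if (runs[k, 1] - merged[last, 2] - 1L < gap_bins) {
          merged[last, 2] <- max(merged[last, 2], runs[k, 2])
        } else {
          merged <- rbind(merged, runs[k, , drop = FALSE])
        }
      }
    }
    t0 <- s$t_start
    b_start <- t0 + (merged[, 1] - 1L) * params$bin_s
    b_end <- pmin(t0 + merged[, 2] * params$bin_s, s$t_end)
    keep <- (b_end - b_start) >= params$min_duration_s
    merged <- merged[keep, , drop = FALSE]
    b_start <- b_start[keep]
    b_end <- b_end[keep]
    t_peak <- vapply(seq_len(nrow(merged)), function(k) {
      idx <- merged[k, 1]:merged[k, 2]
      pr$centers[idx[which.max(rate[idx])]]
    }, numeric(1))
    bursts <- data.frame(t_start = b_start, t_peak = t_peak, t_end = b_end)
  }
  part <- burst_participation(s, bursts)
  structure(list(bursts = bursts, participation = part, params = params,
                 unit_ids = s$unit_ids),
            class = "burst_set")
}

# Per-burst per-unit spike counts within [t_start, t_end) of each burst.
burst_participation <- function(s, bursts) {
  out <- matrix(0L, nrow(bursts), n_units(s),
                dimnames = list(NULL, s$unit_ids))
  for (k in seq_len(nrow(bursts))) {
    out[k, ] <- vapply(s$spikes, function(t) {
      sum(t >= bursts$t_start[k] & t < bursts$t_end[k])
    }, integer(1))
  }
  out
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts over %d units\n",
              nrow(x$bursts), length(x$unit_ids)))
  invisible(x)
}

#' Backbone units
#'
#' A unit is a backbone unit iff it fires at least `min_spikes` spikes in
#' at least a fraction `min_fraction` of the network bursts (defaults: at
#' least twice during 90% of bursts). The proportion of units that are
#' backbone summarizes the network's rigidity.
#'
#' @param b a `burst_set` with at least one burst.
#' @param s optional [spike_train_set()]; only needed if `b` lacks a
#'   participation matrix (e.g. a ground-truth burst set).
#' @param min_spikes minimum spikes per burst (default 2).
#' @param min_fraction minimum fraction of bursts (default 0.9).
#' @return list with `units` (character), `proportion`, and `fraction`
#'   (per-unit fraction of bursts with `>= min_spikes` spikes).
#' @export
backbone_units <- function(b, s = NULL, min_spikes = 2L,
                           min_fraction = 0.9) {
  if (nrow(b$bursts) == 0L) {
    warning("no bursts; backbone undefined", call. = FALSE)
    return(list(units = character(0), proportion = NA_real_,
                fraction = NULL))
  }
  part <- b$participation
  if (is.null(part)) {
    if (is.null(s)) stop_param("burst set has no participation; supply `s`")
    part <- burst_participation(s, b$bursts)
  }
  frac <- colMeans(part >= min_spikes)
  units <- colnames(part)[frac >= min_fraction]
  list(units = units, proportion = length(units) / ncol(part),
       fraction = frac)
}

#' Per-burst participation vectors
#'
#' One vector per burst of per-unit spike counts within the burst window.
#'
#' @param b a `burst_set`.
#' @return numeric matrix, bursts x units.
#' @export
burst_vectors <- function(b) {
  if (nrow(b$bursts) < 2L) stop_param("need at least 2 bursts")
  b$participation
}

#' Burst-to-burst participation correlation
#'
#' Mean Pearson correlation of the per-burst participation vectors over
#' all burst pairs; bursts with constant vectors (zero variance) are
#' excluded and tallied. High values indicate stable ensemble recruitment
#' across bursts.
#'
#' @param b a `burst_set` with at least 2 bursts.
#' @return list with `mean`, `correlations` (upper-triangle values),
#'   `n_constant` (excluded bursts).
#' @export
burst_correlation <- function(b) {
  v <- burst_vectors(b)
  sds <- apply(v, 1L, stats::sd)
  const <- is.na(sds) | sds == 0
  v <- v[!const, , drop = FALSE]
  if (nrow(v) < 2L) {
    warning("fewer than 2 non-constant bursts", call. = FALSE)
    return(list(mean = NA_real_, correlations = numeric(0),
                n_constant = sum(const)))
  }
  cm <- stats::cor(t(v))
  vals <- cm[upper.tri(cm)]
  list(mean = mean(vals), correlations = vals, n_constant = sum(const))
}

#' Write a burst set as CSV plus JSON sidecar
#'
#' `<path>` gets `burst_idx,t_start,t_peak,t_end`; the participation
#' matrix goes to `<path_without_ext>_participation.csv` and the detector
#' parameters to `<path>.json`.
#'
#' @param b a `burst_set`.
#' @param path output CSV path.
#' @export
write_burst_set <- function(b, path) {
  tab <- cbind(burst_idx = seq_len(nrow(b$bursts)), b$bursts)
  utils::write.csv(tab, path, row.names = FALSE)
  ppath <- sub("(\\.[^.]+)?$", "_participation.csv", path)
  utils::write.csv(as.data.frame(b$participation), ppath, row.names = FALSE)
  jsonlite::write_json(c(list(schema_version = "1.0"), unclass(b$params)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
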