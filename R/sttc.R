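#' Spike-time tiling coefficient for a pair of trains
#'
#' The STTC measures pairwise spike-train synchrony on a coincidence
#' half-window `dt_s`, corrected for the fraction of the recording each
#' train "tiles", which makes it largely insensitive to firing rate:
#'
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'       \frac{P_B - T_A}{1 - P_B T_A}\right)}
#'
#' where `T_X` is the fraction of the recording window lying within
#' `dt_s` of any spike of train X (tiles clipped at the window edges and
#' merged where they overlap), and `P_X` is the fraction of X's spikes
#' falling within `dt_s` of any spike of the other train.
#'
#' A tile is the closed interval `[t - dt_s, t + dt_s]`, so `dt_s` is a
#' half-window: the default 0.010 s corresponds to the conventional
#' "10 ms window".
#'
#' @param a,b sorted numeric spike-time vectors (seconds), inside `window`.
#' @param dt_s coincidence half-window in seconds (default 0.010); must be
#'   positive and smaller than the window length.
#' @param window numeric length-2, the recording window `c(t_start, t_end)`.
#' @return a value in `[-1, 1]`, or `NA` when undefined (either train
#'   empty, or a denominator exactly zero).
#' @export
sttc_pair <- function(a, b, dt_s = 0.010, window) {
  if (!is.numeric(window) || length(window) != 2L || window[2] <= window[1]) {
    stop_param("`window` must be c(t_start, t_end) with t_end > t_start")
  }
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0 ||
      dt_s >= (window[2] - window[1])) {
    stop_param("`dt_s` must be in (0, window length)")
  }
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  Ta <- tiled_fraction(a, dt_s, window)
  Tb <- tiled_fraction(b, dt_s, window)
  Pa <- prop_within(a, b, dt_s)
  Pb <- prop_within(b, a, dt_s)
  d1 <- 1 - Pa * Tb
  d2 <- 1 - Pb * Ta
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * ((Pa - Tb) / d1 + (Pb - Ta) / d2)
}

# Fraction of the window covered by the union of tiles [t-dt, t+dt],
# clipped to the window. Tiles share a width, so sorted spike times give
# sorted interval starts; a running maximum of the ends yields the union.
tiled_fraction <- function(t, dt_s, window) {
  s <- pmax(t - dt_s, window[1])
  e <- pmin(t + dt_s, window[2])
  prev <- c(-Inf, cummax(e)[-length(e)])
  sum(pmax(0, e - pmax(s, prev))) / (window[2] - window[1])
}

# Fraction of spikes in `a` lying within dt of some spike of `b`.
prop_within <- function(a, b, dt_s) {
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  near <- pmin(abs(a - b[lo]), abs(b[hi] - a))
  mean(near <= dt_s)
}

#' Pairwise STTC matrix for a spike-train set
#'
#' Computes all unordered unit pairs once and mirrors them. The diagonal is
#' `NA` (self-pairs carry no information and are excluded from every
#' summary), as is any pair involving an empty train.
#'
#' @param s a [spike_train_set()].
#' @param dt_s coincidence half-window in seconds (default 0.010).
#' @return an object of class `sttc_matrix`: a list with `values`
#'   (symmetric numeric matrix with `NA` marking undefined entries),
#'   `dt_s`, `unit_ids`, `window` and `n_undefined_pairs`.
#' @export
sttc_matrix <- function(s, dt_s = 0.010) {
  n <- n_units(s)
  if (n < 2L) stop_param("sttc_matrix needs at least 2 units")
  window <- c(s$t_start, s$t_end)
  v <- matrix(NA_real_, n, n, dimnames = list(s$unit_ids, s$unit_ids))
  # T_X depends only on a unit's own train: compute once per unit
  tiled <- vapply(s$spikes, function(t) {
    if (length(t)) tiled_fraction(t, dt_s, window) else NA_real_
  }, numeric(1))
  for (i in seq_len(n - 1L)) {
    a <- s$spikes[[i]]
    if (length(a) == 0L) next
    for (j in (i + 1L):n) {
      b <- s$spikes[[j]]
      if (length(b) == 0L) next
      Pa <- prop_within(a, b, dt_s)
      Pb <- prop_within(b, a, dt_s)
      d1 <- 1 - Pa * tiled[j]
      d2 <- 1 - Pb * tiled[i]
      if (d1 == 0 || d2 == 0) next
      v[i, j] <- v[j, i] <- 0.5 * ((Pa - tiled[j]) / d1 + (Pb - tiled[i]) / d2)
    }
  }
  n_undef <- sum(is.na(v[upper.tri(v)]))
  structure(
    list(values = v, dt_s = dt_s, unit_ids = s$unit_ids, window = window,
         n_undefined_pairs = n_undef),
    class = "sttc_matrix"
  )
}

#' @export
print.sttc_matrix <- function(x, ...) {
  n <- length(x$unit_ids)
  cat(sprintf("<sttc_matrix> %d units, dt = %g s, %d undefined pairs\n",
              n, x$dt_s, x$n_undefined_pairs))
  invisible(x)
}

#' Summary moments of an STTC matrix
#'
#' Mean and SD over the defined off-diagonal upper-triangle entries, plus
#' the log10 of the mean (via [log_transform()]; the clipping rule applies
#' when the mean is not positive).
#'
#' @param m an `sttc_matrix`.
#' @param floor clipping floor passed to [log_transform()].
#' @return list with `mean`, `sd`, `n_pairs`, `log_mean`, `n_clipped`.
#' @export
sttc_summary <- function(m, floor = 1e-6) {
  vals <- m$values[upper.tri(m$values)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop_param("no defined STTC pairs to summarize")
  lm <- log_transform(mean(vals), floor = floor)
  list(mean = mean(vals), sd = stats::sd(vals), n_pairs = length(vals),
       log_mean = as.numeric(lm), n_clipped = attr(lm, "n_clipped"))
}

#' Write an STTC matrix as CSV plus JSON sidecar
#'
#' Square CSV with unit ids as header row and first column; undefined
#' entries are empty cells. `dt_s` and the window go in `<path>.json`.
#'
#' @param m an `sttc_matrix`.
#' @param path output CSV path.
#' @export
write_sttc_matrix <- function(m, path) {
  utils::write.csv(m$values, path, row.names = TRUE, na = "")
  jsonlite::write_json(
    list(schema_version = "1.0", dt_s = m$dt_s,
         t_start = m$window[1], t_end = m$window[2]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
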