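#' Analysis configuration for the full per-recording pipeline
#'
#' One object governs every stage so that each report is auditable: the
#' STTC window, the surrogate null settings, the burst detector, the
#' small-world randomization, and a single master seed fanned out to
#' per-stage seeds (recorded in the report).
#'
#' @param dt_s STTC coincidence half-window (seconds).
#' @param surrogate a [surrogate_config()].
#' @param burst a [burst_params()].
#' @param n_rand random references for the small-world normalization.
#' @param resolution Louvain resolution.
#' @param hub_fraction hub decile, see [hubness_scores()].
#' @param log_floor clipping floor for [log_transform()].
#' @param seed master seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(dt_s = 0.010, surrogate = surrogate_config(),
                            burst = burst_params(), n_rand = 100L,
                            resolution = 1, hub_fraction = 0.1,
                            log_floor = 1e-6, seed = 1L) {
  surrogate$seed <- derive_seed(seed, 11L)
  structure(list(dt_s = dt_s, surrogate = surrogate, burst = burst,
                 n_rand = n_rand, resolution = resolution,
                 hub_fraction = hub_fraction, log_floor = log_floor,
                 seed = seed), class = "analysis_config")
}

run_stage <- function(stage, rec_id, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed for recording '", rec_id, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline on one recording
#'
#' Executes ingest, firing rates, STTC, surrogate-null thresholding,
#' topology, burst and community analysis with one master seed, and
#' returns (optionally writes) a structured report. Degenerate inputs
#' (too few units, no edges, no bursts) flag the affected fields as `NA`
#' rather than aborting. Any genuine stage failure aborts with the stage
#' name and recording id.
#'
#' @param x a [spike_train_set()] or a path for [read_spike_table()].
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, the report JSON and the
#'   per-stage CSV artifacts are written there.
#' @return list of class `recording_report`.
#' @export
run_recording <- function(x, config = analysis_config(), out_dir = NULL) {
  s <- if (is.character(x)) read_spike_table(x) else x
  rec_id <- paste0(s$metadata$organoid_id, "_d", s$metadata$age_days)
  md <- s$metadata
  stage_label <- if (is.na(md$age_days)) "unbinned" else bin_stage(md$age_days)

  rates <- run_stage("firing_rates", rec_id, firing_rates(s))
  log_rates <- log_transform(rates[rates > 0] , floor = config$log_floor)

  m <- run_stage("sttc", rec_id, {
    if (n_units(s) >= 2L) sttc_matrix(s, dt_s = config$dt_s) else NULL
  })
  sttc_sum <- if (!is.null(m) && any(!is.na(m$values[upper.tri(m$values)]))) {
    sttc_summary(m, floor = config$log_floor)
  } else NULL

  graph <- run_stage("null_threshold", rec_id, {
    if (is.null(m)) NULL else {
      nd <- null_distribution(s, dt_s = config$dt_s, cfg = config$surrogate)
      if (config$surrogate$scope == "pooled" && length(nd$values) == 0L) {
        NULL
      } else build_graph(m, nd)
    }
  })

  topo <- run_stage("topology", rec_id, {
    if (is.null(graph)) NULL else {
      topology_report(graph, n_rand = config$n_rand,
                      seed = derive_seed(config$seed, 21L),
                      hub_fraction = config$hub_fraction)
    }
  })

  b <- run_stage("bursts", rec_id, detect_network_bursts(s, config$burst))
  backbone <- if (nrow(b$bursts) >= 1L) {
    backbone_units(b)
  } else list(units = character(0), proportion = NA_real_)
  bcorr <- if (nrow(b$bursts) >= 2L) burst_correlation(b) else
    list(mean = NA_real_)

  part <- if (!is.null(topo)) topo$partition else NULL
  mbc <- run_stage("communities", rec_id, {
    if (!is.null(part) && part$n_modules >= 2L && nrow(b$bursts) >= 2L) {
      suppressWarnings(module_burst_correlation(part, s, b, config$burst))
    } else list(mean = NA_real_, pairs = NULL)
  })
  spread <- run_stage("communities", rec_id, {
    if (!is.null(part) && nrow(b$bursts) >= 2L) {
      burst_timing_variability(part, s, b, config$burst)
    } else NULL
  })

  report <- structure(list(
    recording_id = rec_id,
    metadata = md,
    stage = stage_label,
    n_units = n_units(s),
    duration_s = duration_s(s),
    rates = list(mean_hz = mean(rates),
                 log_mean = as.numeric(log_transform(mean(rates),
                                                     config$log_floor)),
                 mean_log = if (length(log_rates)) mean(log_rates) else NA_real_),
    sttc = sttc_sum,
    threshold = if (is.null(graph)) NA_real_ else graph$threshold,
    n_edges = if (is.null(graph)) NA_integer_ else
      sum(graph$adjacency[upper.tri(graph$adjacency)]),
    topology = if (is.null(topo)) NULL else topo[
      c("n_nodes", "n_edges", "C", "L", "C_rand", "L_rand", "C_norm",
        "L_norm", "S", "k_max", "core_size", "core_periphery_density",
        "modularity_Q", "n_modules")],
    bursts = list(n_bursts = nrow(b$bursts),
                  backbone_proportion = backbone$proportion,
                  n_backbone = length(backbone$units),
                  burst_correlation = bcorr$mean),
    communities = list(
      n_modules = if (is.null(part)) NA_integer_ else part$n_modules,
      modularity_Q = if (is.null(part)) NA_real_ else part$modularity_Q,
      module_burst_correlation = mbc$mean,
      spread_ms_mean = if (is.null(spread)) NA_real_ else
        mean(spread$spread_ms, na.rm = TRUE)),
    config = list(dt_s = config$dt_s, seed = config$seed,
                  surrogate_seed = config$surrogate$seed,
                  topology_seed = derive_seed(config$seed, 21L),
                  n_surrogates = config$surrogate$n_surrogates,
                  percentile = config$surrogate$percentile,
                  method = config$surrogate$method,
                  n_rand = config$n_rand)
  ), class = "recording_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(out_dir, rec_id)
    write_recording_report(report, paste0(stem, "_report.json"))
    if (!is.null(m)) write_sttc_matrix(m, paste0(stem, "_sttc.csv"))
    if (!is.null(graph)) write_graph_edges(graph, paste0(stem, "_edges.csv"))
    write_burst_set(b, paste0(stem, "_bursts.csv"))
    if (!is.null(part)) write_partition(part, paste0(stem, "_modules.csv"))
  }
  report
}

#' Serialize a recording report to JSON
#'
#' @param report a `recording_report`.
#' @param path output path.
#' @export
write_recording_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.recording_report <- function(x, ...) {
  cat(sprintf("<recording_report> %s (%s, day %s): %d units, %s edges\n",
              x$recording_id, x$metadata$region, x$metadata$age_days,
              x$n_units, x$n_edges))
  invisible(x)
}

report_row <- function(r) {
  data.frame(
    recording_id = r$recording_id,
    organoid_id = r$metadata$organoid_id,
    region = r$metadata$region,
    age_days = r$metadata$age_days,
    stage = r$stage,
    log_mean_rate = r$rates$log_mean,
    log_mean_sttc = if (is.null(r$sttc)) NA_real_ else r$sttc$log_mean,
    mean_sttc = if (is.null(r$sttc)) NA_real_ else r$sttc$mean,
    S = if (is.null(r$topology)) NA_real_ else r$topology$S,
    modularity_Q = if (is.null(r$topology)) NA_real_ else
      r$topology$modularity_Q,
    backbone_proportion = r$bursts$backbone_proportion,
    stringsAsFactors = FALSE
  )
}

#' Tabulate recording reports
#'
#' One row per report with the scalar metrics used by group comparisons.
#'
#' @param reports list of `recording_report`s.
#' @return data frame.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, report_row))
}

ols_slope <- function(y, x) {
  if (length(unique(x)) < 2L) return(NA_real_)
  stats::coef(stats::lm(y ~ x))[[2]]
}

#' Compare developmental trajectories between groups of recordings
#'
#' For each organoid, fits an ordinary least-squares slope of
#' log10-mean STTC (and log10-mean firing rate) against age in days; the
#' group slope is the mean of its organoid slopes, and the between-group
#' slope contrast gets a percentile bootstrap confidence interval over
#' organoids. Stage-level group means (region x stage) are reported
#' alongside; recordings with ages outside the stage bins are kept for
#' slopes but excluded from stage summaries.
#'
#' @param reports list of `recording_report`s.
#' @param group_key metadata field that defines the groups (default
#'   `"region"`).
#' @param metrics report-table columns to contrast.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list of class `group_comparison`: `slopes` (per organoid),
#'   `group_slopes`, `contrasts` (per metric: difference of group mean
#'   slopes, bootstrap CI), `stage_summary`, `table`.
#' @export
compare_groups <- function(reports, group_key = "region",
                           metrics = c("log_mean_sttc", "log_mean_rate"),
                           n_boot = 10000L, seed = 1L, conf = 0.95) {
  tab <- report_table(reports)
  tab$group <- vapply(reports, function(r) as.character(r$metadata[[group_key]]),
                      character(1))
  ok <- stats::aggregate(age_days ~ organoid_id, tab,
                         function(a) length(unique(a)))
  bad <- ok$organoid_id[ok$age_days < 2L]
  if (length(bad)) {
    stop_param("organoid(s) with fewer than 2 recording ages: ",
               paste(bad, collapse = ", "))
  }
  orgs <- unique(tab[, c("organoid_id", "group")])
  if (any(table(orgs$group) < 2L)) {
    stop_param("each group needs at least 2 organoids")
  }
  slopes <- do.call(rbind, lapply(seq_len(nrow(orgs)), function(i) {
    sub <- tab[tab$organoid_id == orgs$organoid_id[i], ]
    row <- data.frame(organoid_id = orgs$organoid_id[i],
                      group = orgs$group[i], stringsAsFactors = FALSE)
    for (mt in metrics) row[[paste0("slope_", mt)]] <-
      ols_slope(sub[[mt]], sub$age_days)
    row
  }))
  groups <- sort(unique(slopes$group))
  if (length(groups) != 2L) stop_param("exactly 2 groups are required")
  group_slopes <- stats::aggregate(
    slopes[paste0("slope_", metrics)], by = list(group = slopes$group), mean)
  alpha <- (1 - conf) / 2
  contrasts <- with_seed(seed, lapply(metrics, function(mt) {
    col <- paste0("slope_", mt)
    s1 <- slopes[[col]][slopes$group == groups[1]]
    s2 <- slopes[[col]][slopes$group == groups[2]]
    obs <- mean(s1) - mean(s2)
    boot <- replicate(n_boot, {
      mean(sample(s1, replace = TRUE)) - mean(sample(s2, replace = TRUE))
    })
    list(metric = mt, groups = groups, contrast = obs,
         ci = stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE))
  }))
  names(contrasts) <- metrics
  staged <- tab[tab$stage != "unbinned", ]
  stage_summary <- if (nrow(staged)) {
    stats::aggregate(staged[, intersect(metrics, names(staged)), drop = FALSE],
                     by = list(group = staged$group, stage = staged$stage),
                     function(x) c(mean = mean(x, na.rm = TRUE),
                                   sd = stats::sd(x), n = sum(!is.na(x))))
  } else NULL
  structure(list(slopes = slopes, group_slopes = group_slopes,
                 contrasts = contrasts, stage_summary = stage_summary,
                 table = tab, n_boot = n_boot, seed = seed, conf = conf),
            class = "group_comparison")
}

#' Paired baseline-versus-treatment comparison
#'
#' Matches units by id between a baseline and a post-treatment recording
#' of the same preparation (e.g. a 10-min recording before and after drug
#' incubation), and reports per-unit firing-rate deltas, per-pair STTC
#' deltas, and burst-duration deltas, each with a paired bootstrap
#' confidence interval. A mean STTC delta whose CI excludes zero at an
#' unchanged firing rate is the signature of a pure synchrony effect
#' (e.g. GABA-A blockade).
#'
#' @param baseline,post [spike_train_set()]s with identical unit ids.
#' @param dt_s STTC half-window.
#' @param burst a [burst_params()] for the burst-duration deltas.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list of class `pharm_comparison` with `rate_delta`,
#'   `sttc_delta`, `burst_duration_delta` (`NULL` when either recording
#'   has no bursts), each `list(mean, ci, n)`.
#' @export
pharm_compare <- function(baseline, post, dt_s = 0.010,
                          burst = burst_params(), n_boot = 10000L,
                          seed = 1L, conf = 0.95) {
  if (!setequal(baseline$unit_ids, post$unit_ids)) {
    miss <- c(setdiff(baseline$unit_ids, post$unit_ids),
              setdiff(post$unit_ids, baseline$unit_ids))
    stop_param("unit sets differ between recordings: ",
               paste(miss, collapse = ", "))
  }
  ids <- baseline$unit_ids
  r0 <- firing_rates(baseline)[ids]
  r1 <- firing_rates(post)[ids]
  d_rate <- r1 - r0
  m0 <- sttc_matrix(baseline, dt_s)$values[ids, ids]
  m1 <- sttc_matrix(post, dt_s)$values[ids, ids]
  d_sttc <- (m1 - m0)[upper.tri(m0)]
  d_sttc <- d_sttc[!is.na(d_sttc)]
  alpha <- (1 - conf) / 2
  boot_ci <- function(d, sub_seed) {
    with_seed(derive_seed(seed, sub_seed), {
      bs <- replicate(n_boot, mean(sample(d, replace = TRUE)))
      list(mean = mean(d),
           ci = stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE),
           n = length(d))
    })
  }
  b0 <- detect_network_bursts(baseline, burst)
  b1 <- detect_network_bursts(post, burst)
  dur_delta <- if (nrow(b0$bursts) >= 2L && nrow(b1$bursts) >= 2L) {
    list(mean = mean(b1$bursts$t_end - b1$bursts$t_start) -
           mean(b0$bursts$t_end - b0$bursts$t_start),
         n = c(baseline = nrow(b0$bursts), post = nrow(b1$bursts)))
  } else NULL
  structure(list(rate_delta = boot_ci(d_rate, 1L),
                 sttc_delta = boot_ci(d_sttc, 2L),
                 burst_duration_delta = dur_delta,
                 n_units = length(ids)),
            class = "pharm_comparison")
}
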