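#' Synthetic spike-train generator configuration
#'
#' The generators emulate the statistical structure the downstream
#' analyses assume: log-normally distributed firing rates, block-modular
#' pairwise correlations produced by common-parent thinning, optional hub
#' units coupled across the whole population, and network bursts with a
#' designated backbone subpopulation. Every generator is reproducible
#' under `seed`.
#'
#' @param n_units number of units.
#' @param duration_s recording duration in seconds.
#' @param rate_mu,rate_sigma mean and SD of the log10 firing rate (Hz);
#'   the per-unit rates are `10^rnorm(n, rate_mu, rate_sigma)`.
#' @param rate_hz optional fixed per-unit rate vector (overrides the
#'   log-normal draw; recycled to `n_units`).
#' @param coupling `NULL` (independent units), a [coupling_blocks()]
#'   specification, or a [coupling_groups()] list.
#' @param hub_spec optional `list(n_hubs, hub_coupling)`: the first
#'   `n_hubs` units copy the global parent train with probability
#'   `hub_coupling`, coupling them to every module.
#' @param burst_spec optional [burst_spec()] for [generate_bursting_set()].
#' @param jitter_sd_s SD of the Gaussian jitter added to each copied
#'   parent spike (default 0.002 s, well inside the 0.010 s STTC window).
#' @param t_start window start (default 0).
#' @param seed integer seed.
#' @param organoid_id,region,age_days,condition metadata passed through to
#'   the generated [spike_train_set()].
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_units = 30L, duration_s = 300, rate_mu = 0,
                         rate_sigma = 0.25, rate_hz = NULL, coupling = NULL,
                         hub_spec = NULL, burst_spec = NULL,
                         jitter_sd_s = 0.002, t_start = 0, seed = 1L,
                         organoid_id = "synth", region = "other",
                         age_days = NA_integer_, condition = NULL) {
  stopifnot(n_units >= 1L, duration_s > 0, jitter_sd_s >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Block-modular coupling specification
#'
#' Units are split into `n_modules` contiguous, equally sized modules;
#' all units copy their module parent with probability `intra_c` and the
#' global parent with probability `inter_c`.
#'
#' @param n_modules number of modules.
#' @param intra_c within-module coupling probability in `[0, 1]`.
#' @param inter_c across-module coupling probability in `[0, 1]`.
#' @export
coupling_blocks <- function(n_modules, intra_c, inter_c = 0) {
  stopifnot(n_modules >= 1, intra_c >= 0, intra_c <= 1,
            inter_c >= 0, inter_c <= 1)
  structure(list(n_modules = as.integer(n_modules), intra_c = intra_c,
                 inter_c = inter_c), class = "coupling_blocks")
}

#' Explicit coupled groups
#'
#' Each group is `list(units = <integer indices>, c = <coupling>)`:
#' members copy a shared parent train with probability `c`. Groups must
#' be disjoint; unlisted units stay independent.
#'
#' @param groups list of groups, see Description.
#' @export
coupling_groups <- function(groups) {
  all_units <- unlist(lapply(groups, `[[`, "units"))
  if (anyDuplicated(all_units)) stop_param("coupling groups must be disjoint")
  structure(list(groups = groups), class = "coupling_groups")
}

#' Burst-generator specification
#'
#' @param n_bursts number of network bursts.
#' @param burst_duration_s duration of each burst (seconds).
#' @param background_rate_hz per-unit Poisson rate between bursts.
#' @param backbone integer indices of the planted backbone units; these
#'   emit at least 2 spikes in every burst by construction.
#' @param participation_p probability that a non-backbone unit
#'   participates in a given burst.
#' @param spikes_per_burst mean of the Poisson spikes-per-burst count for
#'   participating units.
#' @param onsets `"scripted"` (evenly spaced, deterministic; the default)
#'   or `"poisson"` (uniform random non-overlapping onsets).
#' @param scripted_counts optional exact n_bursts x n_units spike-count
#'   matrix, overriding the stochastic participation model (spike times
#'   are still drawn uniformly inside each burst window).
#' @export
burst_spec <- function(n_bursts, burst_duration_s, background_rate_hz = 0.2,
                       backbone = integer(0), participation_p = 0.6,
                       spikes_per_burst = 4,
                       onsets = c("scripted", "poisson"),
                       scripted_counts = NULL) {
  onsets <- match.arg(onsets)
  stopifnot(n_bursts >= 1, burst_duration_s > 0, background_rate_hz >= 0,
            participation_p >= 0, participation_p <= 1)
  structure(list(n_bursts = as.integer(n_bursts),
                 burst_duration_s = burst_duration_s,
                 background_rate_hz = background_rate_hz,
                 backbone = backbone, participation_p = participation_p,
                 spikes_per_burst = spikes_per_burst, onsets = onsets,
                 scripted_counts = scripted_counts), class = "burst_spec")
}

draw_rates <- function(cfg) {
  if (!is.null(cfg$rate_hz)) return(rep_len(cfg$rate_hz, cfg$n_units))
  10^stats::rnorm(cfg$n_units, cfg$rate_mu, cfg$rate_sigma)
}

poisson_train <- function(rate_hz, t_start, duration_s) {
  n <- stats::rpois(1L, rate_hz * duration_s)
  sort(stats::runif(n, t_start, t_start + duration_s))
}

make_set <- function(cfg, spikes) {
  spike_train_set(spikes, t_start = cfg$t_start,
                  t_end = cfg$t_start + cfg$duration_s,
                  organoid_id = cfg$organoid_id, region = cfg$region,
                  age_days = cfg$age_days, condition = cfg$condition)
}

#' Generate independent Poisson spike trains
#'
#' Homogeneous Poisson trains with per-unit rates drawn from the
#' configured log10-normal distribution; the null fixture for the STTC
#' and thresholding stages.
#'
#' @param cfg a [synth_config()] (any coupling specification is ignored).
#' @return a [spike_train_set()] with attribute `"rates_hz"` (the target
#'   rates).
#' @export
generate_poisson_set <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    rates <- draw_rates(cfg)
    spikes <- lapply(rates, poisson_train, t_start = cfg$t_start,
                     duration_s = cfg$duration_s)
    names(spikes) <- paste0("u", seq_along(spikes))
    out <- make_set(cfg, spikes)
    attr(out, "rates_hz") <- stats::setNames(rates, names(spikes))
    out
  })
}

# Resolve a coupling specification into per-unit (group id, coupling) for
# the module parent plus a global coupling vector.
resolve_coupling <- function(cfg) {
  n <- cfg$n_units
  module <- rep(0L, n)     # 0 = no module parent
  c_mod <- rep(0, n)
  c_glob <- rep(0, n)
  if (inherits(cfg$coupling, "coupling_blocks")) {
    cb <- cfg$coupling
    module <- if (cb$n_modules == 1L) rep(1L, n) else {
      as.integer(cut(seq_len(n), breaks = cb$n_modules, labels = FALSE))
    }
    c_mod <- rep(cb$intra_c, n)
    c_glob <- rep(cb$inter_c, n)
  } else if (inherits(cfg$coupling, "coupling_groups")) {
    for (k in seq_along(cfg$coupling$groups)) {
      grp <- cfg$coupling$groups[[k]]
      module[grp$units] <- k
      c_mod[grp$units] <- grp$c
    }
  } else if (!is.null(cfg$coupling)) {
    stop_param("coupling must be coupling_blocks() or coupling_groups()")
  }
  if (!is.null(cfg$hub_spec)) {
    hubs <- seq_len(cfg$hub_spec$n_hubs)
    c_glob[hubs] <- cfg$hub_spec$hub_coupling
  }
  list(module = module, c_mod = c_mod, c_glob = c_glob)
}

# Copy each parent spike with probability p, jitter it, and wrap into the
# window (circular wrap keeps counts and window validity).
thin_and_jitter <- function(parent, p, jitter_sd, t_start, duration) {
  if (p <= 0 || length(parent) == 0L) return(numeric(0))
  kept <- parent[stats::runif(length(parent)) < p]
  if (jitter_sd > 0 && length(kept)) {
    kept <- kept + stats::rnorm(length(kept), 0, jitter_sd)
    kept <- t_start + (kept - t_start) %% duration
  }
  kept
}

#' Generate correlated spike trains by common-parent thinning
#'
#' Each coupled group shares a hidden parent Poisson train; every member
#' copies each parent spike with the group coupling probability and
#' jitters it with centered Gaussian noise. Independent background spikes
#' top each unit up to its target rate, so the coupling shapes pairwise
#' synchrony without changing marginal rates. Parent rates are set to the
#' minimum target rate within the group, which keeps any coupling in
#' `[0, 1]` feasible; a combined coupling demand exceeding a unit's target
#' rate is an error.
#'
#' Pairwise STTC increases monotonically with the coupling probability at
#' fixed jitter; coupling 1 with zero jitter and equal rates yields
#' identical trains (STTC 1).
#'
#' @param cfg a [synth_config()] with a coupling specification.
#' @return a [spike_train_set()] with attribute `"ground_truth"`: a list
#'   with `modules` (per-unit module id, 0 = uncoupled), `hubs`,
#'   `rates_hz`.
#' @export
generate_correlated_set <- function(cfg) {
  rc <- resolve_coupling(cfg)
  with_seed(cfg$seed, {
    rates <- draw_rates(cfg)
    D <- cfg$duration_s
    mods <- sort(unique(rc$module[rc$module > 0L]))
    parent_rate <- vapply(mods, function(m) min(rates[rc$module == m]),
                          numeric(1))
    glob_rate <- if (any(rc$c_glob > 0)) min(rates) else 0
    parents <- lapply(parent_rate, poisson_train, t_start = cfg$t_start,
                      duration_s = D)
    glob_parent <- if (glob_rate > 0) {
      poisson_train(glob_rate, cfg$t_start, D)
    } else numeric(0)
    spikes <- vector("list", cfg$n_units)
    for (i in seq_len(cfg$n_units)) {
      pr_m <- if (rc$module[i] > 0L) parent_rate[match(rc$module[i], mods)] else 0
      bg <- rates[i] - rc$c_mod[i] * pr_m - rc$c_glob[i] * glob_rate
      if (bg < -1e-9) {
        stop_param("unit ", i, ": requested coupling infeasible for its ",
                   "target rate")
      }
      t <- c(
        if (rc$module[i] > 0L) {
          thin_and_jitter(parents[[match(rc$module[i], mods)]], rc$c_mod[i],
                          cfg$jitter_sd_s, cfg$t_start, D)
        } else numeric(0),
        thin_and_jitter(glob_parent, rc$c_glob[i], cfg$jitter_sd_s,
                        cfg$t_start, D),
        poisson_train(max(bg, 0), cfg$t_start, D)
      )
      spikes[[i]] <- sort(t)
    }
    names(spikes) <- paste0("u", seq_len(cfg$n_units))
    out <- make_set(cfg, spikes)
    attr(out, "ground_truth") <- list(
      modules = stats::setNames(rc$module, names(spikes)),
      hubs = if (is.null(cfg$hub_spec)) character(0) else
        names(spikes)[seq_len(cfg$hub_spec$n_hubs)],
      rates_hz = stats::setNames(rates, names(spikes)))
    out
  })
}

#' Generate a bursting spike-train set with ground truth
#'
#' Places non-overlapping burst windows (evenly spaced by default), fills
#' them with per-unit spikes from the participation model — planted
#' backbone units emit at least two spikes in every burst — and adds
#' independent background spikes strictly between bursts. Returns the set
#' together with the ground-truth burst windows and backbone identities,
#' so detector and backbone-rule tests have exact truth.
#'
#' @param cfg a [synth_config()] whose `burst_spec` is set.
#' @return list with `set` (a [spike_train_set()]), `bursts` (a
#'   `burst_set` holding the true windows and participation), `backbone`
#'   (character unit ids).
#' @export
generate_bursting_set <- function(cfg) {
  bs <- cfg$burst_spec
  if (is.null(bs)) stop_param("cfg$burst_spec is required")
  D <- cfg$duration_s
  if (bs$n_bursts * bs$burst_duration_s > D) {
    stop_param("bursts do not fit in the recording duration")
  }
  with_seed(cfg$seed, {
    gap <- D / bs$n_bursts
    onset <- if (bs$onsets == "scripted") {
      cfg$t_start + (seq_len(bs$n_bursts) - 0.5) * gap - bs$burst_duration_s / 2
    } else {
      # rejection-sample until the sorted onsets are non-overlapping
      repeat {
        cand <- sort(stats::runif(bs$n_bursts, cfg$t_start,
                                  cfg$t_start + D - bs$burst_duration_s))
        if (all(diff(cand) > bs$burst_duration_s)) break
      }
      cand
    }
    windows <- data.frame(t_start = onset,
                          t_peak = onset + bs$burst_duration_s / 2,
                          t_end = onset + bs$burst_duration_s)
    n <- cfg$n_units
    counts <- if (!is.null(bs$scripted_counts)) {
      m <- bs$scripted_counts
      stopifnot(nrow(m) == bs$n_bursts, ncol(m) == n)
      m
    } else {
      m <- matrix(0L, bs$n_bursts, n)
      for (k in seq_len(bs$n_bursts)) {
        take <- stats::runif(n) < bs$participation_p
        m[k, take] <- stats::rpois(sum(take), bs$spikes_per_burst)
        if (length(bs$backbone)) {
          m[k, bs$backbone] <- pmax(2L, stats::rpois(length(bs$backbone),
                                                     bs$spikes_per_burst))
        }
      }
      m
    }
    spikes <- lapply(seq_len(n), function(i) {
      t <- unlist(lapply(seq_len(bs$n_bursts), function(k) {
        stats::runif(counts[k, i], windows$t_start[k], windows$t_end[k])
      }))
      if (bs$background_rate_hz > 0) {
        bg <- poisson_train(bs$background_rate_hz, cfg$t_start, D)
        inside <- rep(FALSE, length(bg))
        for (k in seq_len(bs$n_bursts)) {
          inside <- inside | (bg >= windows$t_start[k] & bg < windows$t_end[k])
        }
        t <- c(t, bg[!inside])
      }
      sort(t)
    })
    names(spikes) <- paste0("u", seq_len(n))
    set <- make_set(cfg, spikes)
    part <- burst_participation(set, windows)
    truth <- structure(list(bursts = windows, participation = part,
                            params = NULL, unit_ids = set$unit_ids),
                       class = "burst_set")
    list(set = set, bursts = truth,
         backbone = names(spikes)[bs$backbone])
  })
}

#' Generate a developmental series of spike-train sets
#'
#' One organoid recorded at several ages, following one of two profiles:
#' * `DF_like` — within- and across-module coupling and mean firing rate
#'   all rise steadily with age (progressive synchronization in an
#'   integrated, 2-module network);
#' * `VF_like` — mean rate rises early then plateaus while coupling stays
#'   constant in a segregated 4-module network (flat synchrony, high
#'   modularity).
#'
#' Profile parameters (documented in the returned attribute `"profile"`):
#' DF_like couples 2 modules with intra coupling 0.08 + 0.22 f and inter
#' coupling 0.4 x intra, where f ramps 0 to 1 over days 23-64, and log10
#' rate mean -0.2 + 0.4 f; VF_like couples 4 modules at fixed intra 0.30,
#' inter 0.02, with the rate ramp saturating at f = 0.4 (about day 39).
#'
#' @param profile `"DF_like"` or `"VF_like"`.
#' @param stages integer vector of recording ages (days).
#' @param seed integer master seed (per-stage seeds are derived).
#' @param n_units,duration_s,organoid_id passed to each stage's config.
#' @return list of [spike_train_set()]s, one per stage.
#' @export
generate_development_series <- function(profile = c("DF_like", "VF_like"),
                                        stages = c(25L, 40L, 55L),
                                        seed = 1L, n_units = 30L,
                                        duration_s = 300,
                                        organoid_id = "synth-1") {
  profile <- match.arg(profile)
  if (length(stages) == 0L) stop_param("stages must be non-empty")
  region <- if (profile == "DF_like") "DF" else "VF"
  out <- lapply(seq_along(stages), function(k) {
    a <- stages[k]
    f <- min(max((a - 23) / (64 - 23), 0), 1)
    if (profile == "DF_like") {
      coup <- coupling_blocks(2L, intra_c = 0.08 + 0.22 * f,
                              inter_c = 0.4 * (0.08 + 0.22 * f))
      mu <- -0.2 + 0.4 * f
    } else {
      coup <- coupling_blocks(4L, intra_c = 0.30, inter_c = 0.02)
      mu <- -0.2 + 0.4 * min(f / 0.4, 1)
    }
    cfg <- synth_config(n_units = n_units, duration_s = duration_s,
                        rate_mu = mu, rate_sigma = 0.25, coupling = coup,
                        seed = derive_seed(seed, k),
                        organoid_id = organoid_id, region = region,
                        age_days = as.integer(a))
    generate_correlated_set(cfg)
  })
  attr(out, "profile") <- profile
  out
}
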