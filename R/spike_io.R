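#' Construct a spike-train set
#'
#' The universal input object of the package: per-unit sorted spike times
#' (seconds) over a half-open recording window `[t_start, t_end)`, plus
#' recording metadata. Silent units (zero spikes) are legal and retained;
#' they matter for unit accounting even though they cannot contribute
#' synchrony.
#'
#' Spike times are validated on construction: times outside the window are
#' an error (naming the offending unit), non-monotone times are sorted with
#' a warning, and exact duplicates are dropped with a warning.
#'
#' @param spikes named list of numeric vectors, one per unit, times in
#'   seconds. Names are the unit ids; unnamed lists get ids `u1, u2, ...`.
#' @param t_start,t_end recording window in seconds; `t_end > t_start`.
#'   Spikes at exactly `t_end` are rejected (half-open window).
#' @param organoid_id,region,age_days,line,condition recording metadata.
#'   `region` must be one of `"DF"`, `"VF"`, `"other"`.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, t_start = 0, t_end,
                            organoid_id = NA_character_, region = "other",
                            age_days = NA_integer_, line = NULL,
                            condition = NULL) {
  if (!is.list(spikes)) stop_param("`spikes` must be a list of numeric vectors")
  if (is.null(names(spikes)) || anyNA(names(spikes)) || any(names(spikes) == "")) {
    names(spikes) <- paste0("u", seq_along(spikes))
  }
  if (anyDuplicated(names(spikes))) stop_param("duplicate unit ids")
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start) {
    stop_param("recording window requires t_end > t_start")
  }
  region <- match.arg(region, c("DF", "VF", "other"))
  if (!is.na(age_days) && age_days < 0) stop_param("age_days must be >= 0")

  nm <- names(spikes)
  spikes <- lapply(seq_along(spikes), function(i) {
    t <- as.numeric(spikes[[i]])
    uid <- nm[i]
    if (anyNA(t)) stop_param("unit ", uid, ": NA spike times")
    if (length(t) && (min(t) < t_start || max(t) >= t_end)) {
      stop_param("unit ", uid, ": spike times outside [t_start, t_end)")
    }
    if (is.unsorted(t, strictly = FALSE)) {
      warning("unit ", uid, ": spike times not sorted; sorting", call. = FALSE)
      t <- sort(t)
    }
    if (anyDuplicated(t)) {
      warning("unit ", uid, ": duplicate spike times dropped", call. = FALSE)
      t <- unique(t)
    }
    t
  })
  names(spikes) <- nm
  structure(
    list(
      spikes = spikes, unit_ids = nm,
      t_start = as.numeric(t_start), t_end = as.numeric(t_end),
      metadata = list(organoid_id = organoid_id, region = region,
                      age_days = age_days, line = line,
                      condition = condition)
    ),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d units, %d spikes, window [%g, %g) s\n",
    length(x$unit_ids), sum(lengths(x$spikes)), x$t_start, x$t_end))
  md <- x$metadata
  cat(sprintf("  organoid=%s region=%s age_days=%s condition=%s\n",
              md$organoid_id, md$region, md$age_days,
              md$condition %||% "NA"))
  invisible(x)
}

#' Number of units in a spike-train set
#' @param s a `spike_train_set`.
#' @export
n_units <- function(s) length(s$unit_ids)

#' Recording duration in seconds
#' @param s a `spike_train_set`.
#' @export
duration_s <- function(s) s$t_end - s$t_start

#' Read a delimited spike table
#'
#' Reads a comma- or tab-delimited text file with header columns
#' `unit_id` and `time_s`, together with an optional JSON sidecar
#' `<path>.json` holding the recording window and metadata
#' (`t_start`, `t_end`, `organoid_id`, `region`, `age_days`, and an
#' optional `units` manifest listing unit ids, which lets silent units
#' round-trip). Values in `metadata` override the sidecar.
#'
#' @param path path to the spike table.
#' @param metadata named list of overrides (`t_start`, `t_end`,
#'   `organoid_id`, `region`, `age_days`, `line`, `condition`, `units`).
#' @return a [spike_train_set()].
#' @export
read_spike_table <- function(path, metadata = list()) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(tab))) {
    stop_param("spike table must have columns unit_id, time_s")
  }
  side <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  side[names(metadata)] <- metadata
  if (is.null(side$t_end)) stop_param("t_end must be given in sidecar or metadata")
  units <- side$units %||% unique(tab$unit_id)
  units <- union(units, unique(tab$unit_id))
  spikes <- split(tab$time_s, factor(tab$unit_id, levels = units))
  spikes <- lapply(spikes, function(t) if (is.null(t)) numeric(0) else t)
  spike_train_set(
    spikes,
    t_start = side$t_start %||% 0, t_end = side$t_end,
    organoid_id = side$organoid_id %||% NA_character_,
    region = side$region %||% "other",
    age_days = side$age_days %||% NA_integer_,
    line = side$line, condition = side$condition
  )
}

#' Write a spike table and its JSON sidecar
#'
#' Inverse of [read_spike_table()]: writes `unit_id,time_s` rows (times
#' printed at full double precision) plus a `<path>.json` sidecar with the
#' window, metadata, the full unit manifest and a `schema_version` field.
#'
#' @param s a `spike_train_set`.
#' @param path output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(s, path) {
  tab <- data.frame(
    unit_id = rep(s$unit_ids, lengths(s$spikes)),
    time_s = format(unlist(s$spikes, use.names = FALSE) %||% numeric(0),
                    digits = 17, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  side <- c(list(schema_version = "1.0", t_start = s$t_start,
                 t_end = s$t_end, units = s$unit_ids), s$metadata)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-unit firing rates
#'
#' Rate of each unit in Hz: spike count divided by the recording duration.
#' Silent units return 0.
#'
#' @param s a `spike_train_set`.
#' @return named numeric vector of rates (Hz).
#' @export
firing_rates <- function(s) {
  r <- lengths(s$spikes) / duration_s(s)
  names(r) <- s$unit_ids
  r
}

#' Log10 transform with a positive floor
#'
#' Firing rates and mean STTC values are approximately log-normal, so
#' summaries are reported on a log10 scale. Values at or below zero (and any
#' value below `floor`) are clipped to `floor`; the number of clipped values
#' is attached as attribute `"n_clipped"`.
#'
#' @param values numeric vector.
#' @param floor positive clipping floor (default `1e-6`).
#' @return `log10(pmax(values, floor))`, with attribute `n_clipped`.
#' @export
log_transform <- function(values, floor = 1e-6) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop_param("`floor` must be a positive number")
  }
  out <- log10(pmax(values, floor))
  attr(out, "n_clipped") <- sum(values < floor, na.rm = TRUE)
  out
}

#' Developmental stage bins
#'
#' Returns the stage label for a recording age in days: early (23-33),
#' mid (34-45) or late (46-64); ages outside 23-64 map to `"unbinned"`
#' (such recordings are processed but excluded from stage contrasts).
#'
#' @param age_days integer vector of ages, all `>= 0`.
#' @return character vector of labels.
#' @export
bin_stage <- function(age_days) {
  if (any(age_days < 0, na.rm = TRUE)) stop_param("age_days must be >= 0")
  br <- stage_bins()
  out <- rep("unbinned", length(age_days))
  for (lab in names(br)) {
    out[!is.na(age_days) & age_days >= br[[lab]][1] & age_days <= br[[lab]][2]] <- lab
  }
  out
}

#' @rdname bin_stage
#' @export
stage_bins <- function() {
  list(early = c(23L, 33L), mid = c(34L, 45L), late = c(46L, 64L))
}
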