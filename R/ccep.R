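# Neighbor contacts on the same electrode shaft: label prefix identical,
# numeric index within +/-1.  Labels that do not parse as <prefix><index>
# have no detectable neighbors.
neighbor_labels <- function(labels, of) {
  m <- regmatches(of, regexec("^(.*?)([0-9]+)$", of))[[1]]
  if (length(m) != 3) return(character(0))
  idx <- as.integer(m[3])
  cand <- paste0(m[2], c(idx - 1L, idx + 1L))
  intersect(cand, labels)
}

#' Cut stimulation trials out of a continuous recording
#'
#' Extracts a window around every stimulation onset (default 1 s before to
#' 2 s after), aligned so that time 0 is the onset sample.  The stimulated
#' contact pair and its immediate neighbors on the same electrode are
#' removed from the recorded channels (their signal is stimulation
#' artifact).  Events whose window would cross a recording edge are
#' dropped with a warning.
#'
#' @param rec An [recording()] object.
#' @param events Event tibble with columns `onset_seconds`,
#'   `cathode_label`, `anode_label` (as written by the SPES generator).
#' @param pre,post Window extent in seconds before/after onset; defaults 1
#'   and 2.
#' @param exclude_neighbors Drop contacts adjacent to the stimulated pair;
#'   default `TRUE`.
#' @return A `ccep_trials` object: array `trials` (samples x channels x
#'   trials), `times` in seconds relative to onset, channel metadata and
#'   the stimulated pair.
#' @export
extract_trials <- function(rec, events, pre = 1, post = 2,
                           exclude_neighbors = TRUE) {
  stopifnot(inherits(rec, "mc_recording"))
  if (!nrow(events)) stop("no stimulation events")
  fs <- rec$sampling_rate
  stim <- unique(c(events$cathode_label[1], events$anode_label[1]))
  drop <- stim
  if (exclude_neighbors) {
    drop <- unique(c(drop, unlist(lapply(stim, neighbor_labels,
                                         labels = rec$labels))))
  }
  keep <- setdiff(rec$labels, drop)
  if (!length(keep)) stop("no recording channels left after excluding the stimulated pair")
  ki <- match(keep, rec$labels)
  npre <- round(pre * fs); npost <- round(post * fs)
  nsamp <- npre + npost
  N <- nrow(rec$data)
  onset_idx <- round(events$onset_seconds * fs) + 1
  ok <- (onset_idx - npre) >= 1 & (onset_idx + npost - 1) <= N
  if (!any(ok)) stop("every event window falls outside the recording")
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge dropped")
  }
  onset_idx <- onset_idx[ok]
  trials <- array(0, dim = c(nsamp, length(keep), length(onset_idx)),
                  dimnames = list(NULL, keep, NULL))
  for (tr in seq_along(onset_idx)) {
    rows <- (onset_idx[tr] - npre):(onset_idx[tr] + npost - 1)
    trials[, , tr] <- rec$data[rows, ki, drop = FALSE]
  }
  structure(
    list(trials = trials,
         times = (seq_len(nsamp) - npre - 1) / fs,
         sampling_rate = fs, labels = keep,
         regions = rec$regions[keep],
         stim_pair = stim,
         stim_region = unname(rec$regions[stim[1]]),
         n_dropped = sum(!ok)),
    class = "ccep_trials"
  )
}

#' @export
print.ccep_trials <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<ccep_trials> stim %s-%s: %d trials x %d channels x %d samples\n",
              x$stim_pair[1], x$stim_pair[2], d[3], d[2], d[1]))
  invisible(x)
}

#' Baseline-correct and average stimulation trials
#'
#' Subtracts each trial's per-channel baseline mean, then averages trials
#' aligned on stimulus onset.  The per-channel baseline standard deviation
#' is estimated from the pooled single-trial baseline samples (after mean
#' removal), i.e. it measures the ongoing-activity noise floor against
#' which the evoked response is scored.
#'
#' @param trials A `ccep_trials` object.
#' @param baseline_window Two seconds values `(start, end)` relative to
#'   onset, both pre-stimulus; default `c(-1, -0.01)` (the full
#'   pre-stimulus span minus a 10 ms guard before the trigger).
#' @return A `ccep_avg` object: averaged waveform (samples x channels),
#'   baseline mean/SD per channel, trial count and timing metadata.
#' @export
baseline_average <- function(trials, baseline_window = c(-1, -0.01)) {
  stopifnot(inherits(trials, "ccep_trials"))
  if (baseline_window[1] >= baseline_window[2] || baseline_window[2] > 0) {
    stop("baseline window must be an increasing pre-stimulus interval")
  }
  sel <- which(trials$times >= baseline_window[1] &
                 trials$times < baseline_window[2])
  if (length(sel) < 2) stop("baseline window contains fewer than 2 samples")
  d <- dim(trials$trials)
  corrected <- trials$trials
  for (tr in seq_len(d[3])) {
    bl_mean <- colMeans(trials$trials[sel, , tr, drop = FALSE])
    corrected[, , tr] <- sweep(trials$trials[, , tr], 2, bl_mean)
  }
  avg <- apply(corrected, c(1, 2), mean)
  # pooled single-trial baseline SD per channel
  bl <- corrected[sel, , , drop = FALSE]
  bl_sd <- apply(bl, 2, stats::sd)
  bad <- !is.finite(bl_sd) | bl_sd <= 0
  if (all(bad)) {
    stop("degenerate (zero-variance) baseline on every channel")
  }
  if (any(bad)) {
    warning("zero-variance baseline on channel(s) ",
            paste(trials$labels[bad], collapse = ", "),
            "; their z-scores will be 0 and flagged flat")
    bl_sd[bad] <- NA_real_
  }
  structure(
    list(avg = avg, times = trials$times,
         sampling_rate = trials$sampling_rate,
         labels = trials$labels, regions = trials$regions,
         stim_pair = trials$stim_pair, stim_region = trials$stim_region,
         baseline_mean = colMeans(avg[sel, , drop = FALSE]),
         baseline_sd = bl_sd,
         baseline_sd_avg = apply(avg[sel, , drop = FALSE], 2, stats::sd),
         n_trials = d[3], baseline_window = baseline_window),
    class = "ccep_avg"
  )
}

#' @export
print.ccep_avg <- function(x, ...) {
  cat(sprintf("<ccep_avg> stim %s-%s: average of %d trials, %d channels\n",
              x$stim_pair[1], x$stim_pair[2], x$n_trials, ncol(x$avg)))
  invisible(x)
}

#' Score the N1 component as a baseline z-score
#'
#' For each recording channel, the z-score is the maximum absolute
#' amplitude of the averaged waveform inside the response window (half-open
#' `[0.010, 0.110)` s by default — starting 10 ms after the stimulus so
#' that the stimulation artifact is excluded) divided by the channel's
#' baseline SD.  The latency is the time of that maximum.  Absolute
#' amplitude is used because N1 polarity depends on the referential
#' montage.
#'
#' @param avg A `ccep_avg` from [baseline_average()].
#' @param response_window Half-open window `(start, end)` in seconds;
#'   default `c(0.010, 0.110)`.
#' @return A `ccep_response`: tibble with one row per channel
#'   (`stim_pair`, `channel`, `source_region`, `target_region`, `z`,
#'   `latency_s`, `flat`), carrying the averaged waveforms as attributes.
#' @export
n1_zscore <- function(avg, response_window = c(0.010, 0.110)) {
  stopifnot(inherits(avg, "ccep_avg"))
  if (response_window[1] < min(avg$times) ||
      response_window[2] > max(avg$times)) {
    stop("response window must lie inside the trial window")
  }
  sel <- which(avg$times >= response_window[1] &
                 avg$times < response_window[2])
  seg <- abs(avg$avg[sel, , drop = FALSE])
  peak_idx <- apply(seg, 2, which.max)
  peak <- seg[cbind(peak_idx, seq_len(ncol(seg)))]
  flat <- peak == 0 | is.na(avg$baseline_sd)
  z <- ifelse(flat, 0, peak / avg$baseline_sd)
  out <- tibble::tibble(
    stim_pair = paste(avg$stim_pair, collapse = "-"),
    channel = avg$labels,
    source_region = avg$stim_region %||% NA_character_,
    target_region = unname(avg$regions),
    z = unname(z),
    latency_s = unname(avg$times[sel][peak_idx]),
    flat = unname(flat)
  )
  class(out) <- c("ccep_response", class(out))
  attr(out, "avg") <- avg
  out
}

#' Full SPES quantification for one session
#'
#' Convenience chain: [extract_trials()], [baseline_average()],
#' [n1_zscore()], producing the long-format effective-connectivity table
#' consumed by the directionality statistics.
#'
#' @param rec An [recording()] with the SPES session.
#' @param events Stimulation event table.
#' @param ... Passed to the three stages.
#' @return A `ccep_response` tibble.
#' @export
ccep_table <- function(rec, events, ...) {
  trials <- extract_trials(rec, events, ...)
  n1_zscore(baseline_average(trials))
}

#' Averaged CCEP waveforms with the scoring window marked
#'
#' @param object A `ccep_response`.
#' @param channels Optional subset of channels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccep_response <- function(object, channels = NULL, ...) {
  avg <- attr(object, "avg")
  if (is.null(avg)) stop("waveforms not attached")
  if (is.null(channels)) channels <- avg$labels
  df <- tibble::tibble(
    time = rep(avg$times, times = length(channels)),
    channel = rep(channels, each = length(avg$times)),
    value = as.vector(avg$avg[, channels, drop = FALSE])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::annotate("rect", xmin = 0.010, xmax = 0.110,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time from stimulus (s)", y = "amplitude",
                  title = paste("CCEP, stim", paste(avg$stim_pair, collapse = "-")),
                  subtitle = "shaded: N1 scoring window 10-110 ms") +
    ggplot2::theme_minimal()
}
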