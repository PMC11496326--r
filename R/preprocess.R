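#' Zero-phase high-pass filter a recording
#'
#' Removes DC and slow drift with a zero-phase (forward-backward)
#' Butterworth high-pass applied as second-order sections.  Zero-phase
#' filtering is essential here: phase distortion would masquerade as time
#' lag and bias every directed metric downstream.
#'
#' @param rec An [recording()] object.
#' @param cutoff Cutoff frequency in Hz; default 0.5.
#' @param order Filter order (even); default 4.
#' @return A filtered `mc_recording`.
#' @export
filter_highpass <- function(rec, cutoff = 0.5, order = 4) {
  stopifnot(inherits(rec, "mc_recording"))
  nyq <- rec$sampling_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)")
  }
  sos <- butter_sos(order, cutoff, rec$sampling_rate, type = "high")
  # pad by ~3 time constants of the cutoff so edge transients settle
  padlen <- ceiling(3 * rec$sampling_rate / cutoff)
  rec$data <- filtfilt_sos_matrix(sos, rec$data, padlen)
  rec
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase 8th-order Butterworth low-pass at 0.8 times the new
#' Nyquist frequency, then keeps every `factor`-th sample.  The original
#' rate must be an integer multiple of the target rate.
#'
#' @param rec An [recording()] object.
#' @param target_rate New sampling rate in Hz.
#' @param aa_order Anti-alias filter order; default 8.
#' @param aa_fraction Anti-alias cutoff as a fraction of the new Nyquist;
#'   default 0.8 (preserves the 1-40 Hz analysis band untouched at 250 Hz).
#' @return A downsampled `mc_recording`.
#' @export
downsample <- function(rec, target_rate, aa_order = 8, aa_fraction = 0.8) {
  stopifnot(inherits(rec, "mc_recording"))
  factor <- rec$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("original rate (", rec$sampling_rate,
         " Hz) is not an integer multiple of the target rate (",
         target_rate, " Hz)")
  }
  factor <- as.integer(round(factor))
  if (factor > 1) {
    cutoff <- aa_fraction * target_rate / 2
    sos <- butter_sos(aa_order, cutoff, rec$sampling_rate, type = "low")
    rec$data <- filtfilt_sos_matrix(sos, rec$data,
                                    padlen = ceiling(3 * rec$sampling_rate / cutoff))
    keep <- seq(1L, by = factor, length.out = nrow(rec$data) %/% factor)
    rec$data <- rec$data[keep, , drop = FALSE]
  }
  rec$sampling_rate <- as.numeric(target_rate)
  rec
}

#' Cut a recording into contiguous fixed-length epochs
#'
#' Splits the recording into non-overlapping blocks of `epoch_length`
#' seconds; a trailing partial block is discarded.
#'
#' @param rec An [recording()] object.
#' @param epoch_length Epoch length in seconds; default 10.
#' @return An `epoch_set`.
#' @export
make_epochs <- function(rec, epoch_length = 10) {
  stopifnot(inherits(rec, "mc_recording"))
  nsamp <- round(epoch_length * rec$sampling_rate)
  total <- nrow(rec$data)
  n_ep <- total %/% nsamp
  if (n_ep < 1) {
    stop("recording (", total / rec$sampling_rate,
         " s) is shorter than one epoch (", epoch_length, " s)")
  }
  arr <- array(rec$data[seq_len(n_ep * nsamp), , drop = FALSE],
               dim = c(nsamp, n_ep, ncol(rec$data)))
  arr <- aperm(arr, c(1, 3, 2))  # samples x channels x epochs
  dimnames(arr) <- list(NULL, rec$labels, NULL)
  new_epoch_set(arr, epoch_length, rec$sampling_rate, rec$labels,
                rec$regions, rec$soz,
                start_times = (seq_len(n_ep) - 1) * epoch_length)
}

#' Reject artifact-laden or flat epochs
#'
#' Quantitative surrogate for visual epoch selection: an epoch is removed
#' when, on any channel, the robust z-score of its peak absolute amplitude
#' (relative to the median and MAD of that channel's peaks across epochs)
#' exceeds `amplitude_z_threshold`, or its variance falls below
#' `flat_threshold` (dead channel / flat segment).
#'
#' @param epochs An `epoch_set`.
#' @param amplitude_z_threshold Positive robust-z rejection threshold;
#'   default 6.
#' @param flat_threshold Positive variance floor; default 1e-12.
#' @return The surviving `epoch_set`, with a `selection` attribute — a
#'   tibble logging each epoch's fate and the rejecting criterion.
#' @export
select_epochs <- function(epochs, amplitude_z_threshold = 6,
                          flat_threshold = 1e-12) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (amplitude_z_threshold <= 0 || flat_threshold <= 0) {
    stop("thresholds must be positive")
  }
  d <- dim(epochs$data)
  peaks <- apply(abs(epochs$data), c(2, 3), max)       # channels x epochs
  vars  <- apply(epochs$data, c(2, 3), stats::var)
  med <- apply(peaks, 1, stats::median)
  mad <- apply(peaks, 1, stats::mad)
  mad[mad < .Machine$double.eps] <- .Machine$double.eps
  z <- (peaks - med) / mad
  amp_bad  <- apply(z, 2, function(col) any(col > amplitude_z_threshold))
  flat_bad <- apply(vars, 2, function(col) any(col < flat_threshold))
  keep <- !(amp_bad | flat_bad)
  reason <- rep(NA_character_, d[3])
  reason[amp_bad] <- "amplitude"
  reason[flat_bad & !amp_bad] <- "flat"
  report <- tibble::tibble(
    epoch = seq_len(d[3]), start_time = epochs$start_times,
    kept = keep, reason = reason
  )
  if (!any(keep)) {
    crit <- if (all(amp_bad)) "amplitude artifact criterion" else
      if (all(flat_bad)) "flat-signal criterion" else
        "amplitude/flat criteria"
    stop("no epochs survive selection: all rejected by the ", crit)
  }
  out <- epoch_subset(epochs, which(keep))
  attr(out, "selection") <- report
  out
}

#' Split an epoch set into early and late halves
#'
#' Temporal order is preserved; when the epoch count is odd the early half
#' receives the extra epoch.
#'
#' @param epochs An `epoch_set` with at least two epochs.
#' @return A list with elements `early` and `late`.
#' @export
split_half <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  if (n < 2) stop("need at least 2 epochs to split")
  n_early <- ceiling(n / 2)
  list(early = epoch_subset(epochs, seq_len(n_early)),
       late = epoch_subset(epochs, (n_early + 1):n))
}

#' Remove channels from a recording or epoch set
#'
#' Drops seizure-onset-zone (SOZ) channels and/or explicitly named channels
#' from the data, labels, region map and flags, so that all downstream
#' matrices shrink accordingly.  If the exclusion empties a region, a
#' warning names it: its region pairs will be absent from the statistics.
#'
#' @param x An `mc_recording` or `epoch_set`.
#' @param soz If `TRUE` (default), remove channels flagged as SOZ.
#' @param labels Additional channel labels to remove.
#' @return An object of the same class with the channels removed.
#' @export
exclude_channels <- function(x, soz = TRUE, labels = NULL) {
  stopifnot(inherits(x, "mc_recording") || inherits(x, "epoch_set"))
  drop <- unique(c(if (isTRUE(soz)) x$labels[x$soz], labels))
  drop <- intersect(drop, x$labels)
  if (!length(drop)) return(x)
  keep <- setdiff(x$labels, drop)
  if (!length(keep)) stop("exclusion would remove every channel")
  before <- unique(stats::na.omit(x$regions))
  after <- unique(stats::na.omit(x$regions[keep]))
  lost <- setdiff(before, after)
  if (length(lost)) {
    warning("region(s) left with zero contacts and dropped from pair statistics: ",
            paste(lost, collapse = ", "))
  }
  ki <- match(keep, x$labels)
  if (inherits(x, "mc_recording")) {
    x$data <- x$data[, ki, drop = FALSE]
  } else {
    x$data <- x$data[, ki, , drop = FALSE]
  }
  x$labels <- x$labels[ki]
  x$regions <- x$regions[ki]
  x$soz <- x$soz[ki]
  x
}

#' Run the full conditioning chain on a continuous recording
#'
#' Convenience wrapper chaining [filter_highpass()], [downsample()],
#' optional SOZ-channel exclusion, [make_epochs()] and [select_epochs()] in
#' the standard order.
#'
#' @param rec An [recording()] object.
#' @param highpass High-pass cutoff in Hz (`NULL` to skip); default 0.5.
#' @param target_rate Downsampling target in Hz (`NULL` to skip);
#'   default 250.
#' @param epoch_length Epoch length in seconds; default 10.
#' @param exclude_soz Remove SOZ-flagged channels first; default `FALSE`.
#' @param select Apply [select_epochs()]; default `TRUE`.
#' @param ... Passed on to [select_epochs()].
#' @return An `epoch_set` ready for model fitting.
#' @export
preprocess_recording <- function(rec, highpass = 0.5, target_rate = 250,
                                 epoch_length = 10, exclude_soz = FALSE,
                                 select = TRUE, ...) {
  if (isTRUE(exclude_soz)) rec <- exclude_channels(rec, soz = TRUE)
  if (!is.null(highpass)) rec <- filter_highpass(rec, highpass)
  if (!is.null(target_rate) && target_rate != rec$sampling_rate) {
    rec <- downsample(rec, target_rate)
  }
  epochs <- make_epochs(rec, epoch_length)
  if (isTRUE(select)) epochs <- select_epochs(epochs, ...)
  epochs
}
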