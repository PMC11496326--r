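#' Multichannel continuous recording
#'
#' Container for a continuous multichannel electrophysiological recording in
#' a referential montage: a samples-by-channels numeric matrix together with
#' its sampling rate, channel labels, an optional channel-to-region map, and
#' optional seizure-onset-zone (SOZ) flags.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique channel labels; defaults to the
#'   column names of `data`.
#' @param regions Optional named character vector mapping channel label to
#'   region name.  Channels absent from the map carry `NA` (non-ROI).
#' @param soz Optional named logical vector of SOZ flags per channel label;
#'   unmentioned channels default to `FALSE`.
#'
#' @return An object of class `mc_recording`.
#' @export
#' @examples
#' x <- matrix(rnorm(500 * 2), ncol = 2)
#' rec <- recording(x, sampling_rate = 250, labels = c("HPC1", "HPC2"),
#'                  regions = c(HPC1 = "HPC", HPC2 = "HPC"))
#' rec
recording <- function(data, sampling_rate, labels = colnames(data),
                      regions = NULL, soz = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- ncol(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("label count must equal channel count")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar (Hz)")
  }
  colnames(data) <- labels
  region_of <- rep(NA_character_, n)
  names(region_of) <- labels
  if (!is.null(regions)) {
    known <- intersect(names(regions), labels)
    region_of[known] <- as.character(regions[known])
  }
  soz_flag <- rep(FALSE, n)
  names(soz_flag) <- labels
  if (!is.null(soz)) {
    known <- intersect(names(soz), labels)
    soz_flag[known] <- as.logical(soz[known])
  }
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         labels = labels, regions = region_of, soz = soz_flag),
    class = "mc_recording"
  )
}

#' Flag channels as belonging to the seizure onset zone
#'
#' @param rec An [recording()] object.
#' @param labels Channel labels to flag.
#' @return The recording with updated SOZ flags.
#' @export
set_soz <- function(rec, labels) {
  stopifnot(inherits(rec, "mc_recording"))
  missing <- setdiff(labels, rec$labels)
  if (length(missing)) {
    stop("unknown channel labels: ", paste(missing, collapse = ", "))
  }
  rec$soz[labels] <- TRUE
  rec
}

#' @export
print.mc_recording <- function(x, ...) {
  n <- ncol(x$data)
  dur <- nrow(x$data) / x$sampling_rate
  cat(sprintf("<mc_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              n, nrow(x$data), dur, x$sampling_rate))
  regions <- x$regions[!is.na(x$regions)]
  if (length(regions)) {
    cat("  regions:", paste(sprintf("%s(%d)", names(table(regions)),
                                    table(regions)), collapse = " "), "\n")
  }
  if (any(x$soz)) cat("  SOZ channels:", paste(x$labels[x$soz], collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.mc_recording <- function(x) dim(x$data)

#' Coerce a recording to a long tibble
#'
#' @param x An `mc_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (seconds), `channel`, `region`,
#'   `value`.
#' @export
tidy.mc_recording <- function(x, ...) {
  n <- nrow(x$data)
  tibble::tibble(
    time = rep((seq_len(n) - 1) / x$sampling_rate, times = ncol(x$data)),
    channel = rep(x$labels, each = n),
    region = rep(unname(x$regions), each = n),
    value = as.vector(x$data)
  )
}

#' Set of equal-length epochs cut from a recording
#'
#' Internal constructor for the `epoch_set` container: a
#' samples-by-channels-by-epochs array plus timing and channel metadata.
#'
#' @keywords internal
#' @noRd
new_epoch_set <- function(data, epoch_length, sampling_rate, labels,
                          regions, soz, start_times) {
  stopifnot(length(dim(data)) == 3)
  if (is.unsorted(start_times, strictly = TRUE)) {
    stop("epoch start times must be strictly increasing")
  }
  structure(
    list(data = data, epoch_length = epoch_length,
         sampling_rate = sampling_rate, labels = labels,
         regions = regions, soz = soz, start_times = start_times),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[3], d[2], d[1], x$epoch_length, x$sampling_rate))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  dim(x$data)[3]
}

#' Subset an epoch set by epoch index
#' @param x An `epoch_set`.
#' @param idx Integer indices of the epochs to keep (temporal order kept).
#' @return An `epoch_set` with the selected epochs.
#' @export
epoch_subset <- function(x, idx) {
  stopifnot(inherits(x, "epoch_set"))
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1 | idx > n_epochs(x))) stop("epoch index out of range")
  new_epoch_set(x$data[, , idx, drop = FALSE], x$epoch_length,
                x$sampling_rate, x$labels, x$regions, x$soz,
                x$start_times[idx])
}
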