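#' Read and write recordings as columnar numeric text
#'
#' A plain-text interchange dialect: an optional comment line
#' `# sampling_rate_hz: <rate>`, then a tab-separated header of channel
#' labels, then one row per sample.
#'
#' @param rec An [recording()] object.
#' @param path File path.
#' @return `write_recording_txt` returns `path` invisibly;
#'   `read_recording_txt` returns an `mc_recording`.
#' @export
write_recording_txt <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate), con)
  utils::write.table(rec$data, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @param sampling_rate Required when the file lacks the rate comment.
#' @param regions,soz Optional channel metadata (see [recording()]).
#' @export
read_recording_txt <- function(path, sampling_rate = NULL, regions = NULL,
                               soz = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0
  if (grepl("^#\\s*sampling_rate_hz:", first)) {
    sampling_rate <- as.numeric(sub("^#\\s*sampling_rate_hz:\\s*", "", first))
    skip <- 1
  }
  if (is.null(sampling_rate)) {
    stop("file has no sampling-rate header; supply sampling_rate")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE)
  recording(as.matrix(df), sampling_rate = sampling_rate,
            labels = colnames(df), regions = regions, soz = soz)
}

#' Read and write stimulation event tables as CSV
#'
#' Columns: `onset_seconds`, `cathode_label`, `anode_label`.
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   returns the tibble.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    onset_seconds = readr::col_double(),
                    cathode_label = readr::col_character(),
                    anode_label = readr::col_character()))
}

#' Read a channel-to-region map with SOZ flags from YAML
#'
#' Expected layout:
#' ```yaml
#' regions:
#'   - name: HPC
#'     contacts: [HPC1, HPC2]
#'     soz: false
#'   - name: AMG
#'     contacts: [AMG1]
#'     soz: [true]
#' ```
#' `soz` may be a single logical (applying to all contacts of the region)
#' or one logical per contact.
#'
#' @param path YAML file path.
#' @return A tibble with columns `label`, `region`, `soz`, plus named
#'   vectors as attributes `regions` and `soz` ready for [recording()].
#' @export
read_region_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$regions)) stop("config lacks a 'regions' key")
  rows <- lapply(doc$regions, function(r) {
    contacts <- unlist(r$contacts)
    soz <- r$soz %||% FALSE
    if (length(soz) == 1) soz <- rep(as.logical(soz), length(contacts))
    if (length(soz) != length(contacts)) {
      stop("region '", r$name, "': soz length must be 1 or match contacts")
    }
    tibble::tibble(label = contacts, region = r$name, soz = as.logical(soz))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$label)) stop("duplicate contact labels in config")
  regions <- out$region; names(regions) <- out$label
  soz <- out$soz; names(soz) <- out$label
  attr(out, "regions") <- regions
  attr(out, "soz") <- soz
  out
}

#' Build a ground-truth model from a declarative YAML config
#'
#' Expected layout:
#' ```yaml
#' regions: {AMG: 2, HPC: 2, TP: 2, PHP: 2}
#' edges:
#'   - {source: AMG, target: HPC, strength: 0.4, lag: 8}
#' order: 8
#' seed: 1
#' sampling_rate: 2000
#' ```
#'
#' @param path YAML file path.
#' @return A `ground_truth_model` (see [make_ground_truth_mvar()]).
#' @export
read_generator_config <- function(path) {
  doc <- yaml::read_yaml(path)
  spec <- region_spec(unlist(doc$regions))
  edges <- NULL
  if (length(doc$edges)) {
    edges <- dplyr::bind_rows(lapply(doc$edges, function(e) {
      coupling_edge(e$source, e$target, e$strength, e$lag %||% 1L)
    }))
  }
  args <- list(spec = spec, edges = edges,
               order = doc$order %||% 3L, seed = doc$seed %||% 1L)
  for (nm in c("sampling_rate", "osc_freq_range", "osc_mode",
               "osc_bandwidth_range", "noise_sd")) {
    if (!is.null(doc[[nm]])) args[[nm]] <- unlist(doc[[nm]])
  }
  do.call(make_ground_truth_mvar, args)
}

# ---- EDF (European Data Format) ------------------------------------------
# Minimal EDF support: continuous signals, identical sampling rate on all
# channels, one data record per second, 16-bit samples with per-channel
# physical scaling.  Covers the interchange need of this package; EDF+
# annotations are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits with per-channel physical scaling to
#' the observed amplitude range, one data record per second.  The sampling
#' rate must be a positive integer.
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @param physical_dim Physical dimension string written per channel;
#'   default `"uV"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "mc_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(rec$data)
  n_full <- nrow(rec$data) %/% fs
  if (n_full < 1) stop("recording shorter than one 1-s data record")
  X <- rec$data[seq_len(n_full * fs), , drop = FALSE]
  pmin_ <- apply(X, 2, min); pmax_ <- apply(X, 2, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(n_full, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep(physical_dim, ns), 8)
  field(formatC(pmin_, format = "g", digits = 7), 8)
  field(formatC(pmax_, format = "g", digits = 7), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)                       # reserved
  # re-read the physical extremes exactly as stored, so scaling matches
  pmin_s <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_s <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  gain <- (dmax - dmin) / (pmax_s - pmin_s)
  for (r in seq_len(n_full)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      d <- round((X[rows, j] - pmin_s[j]) * gain[j]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written with a uniform per-channel sampling rate
#'
#' @param path EDF file path.
#' @param regions,soz Optional channel metadata (see [recording()]).
#' @return An `mc_recording`.
#' @export
read_edf <- function(path, regions = NULL, soz = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  fields(8)                              # physical dim
  pmin_ <- as.numeric(fields(8))
  pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)
  nsamp <- as.integer(fields(8))
  fields(32)
  if (length(unique(nsamp)) != 1) {
    stop("reader supports a uniform sampling rate across channels only")
  }
  fs <- nsamp[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  X <- matrix(0, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * nsamp[1] + 1):(r * nsamp[1])
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = nsamp[j], size = 2, signed = TRUE,
                   endian = "little")
      X[rows, j] <- (d - dmin[j]) * gain[j] + pmin_[j]
    }
  }
  recording(X, sampling_rate = fs, labels = labels, regions = regions,
            soz = soz)
}
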