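#' Region layout for a synthetic network
#'
#' Describes the grouping units of a ground-truth network: named regions
#' (e.g. AMG, HPC, TP, PHP for a mesiotemporal montage) each carrying a
#' fixed number of depth-electrode contacts.  Contact labels are formed as
#' `<region><index>` ("AMG1", "AMG2", ...).
#'
#' @param ... Named integers, one per region, giving contacts per region;
#'   alternatively a single named integer vector.
#' @return A `region_spec` tibble with columns `region`, `n_contacts`.
#' @export
#' @examples
#' region_spec(AMG = 2, HPC = 2, TP = 2, PHP = 2)
region_spec <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("every region must be named")
  }
  if (anyDuplicated(names(counts))) stop("region names must be unique")
  if (length(counts) < 2) stop("need at least 2 regions")
  if (any(counts < 1)) stop("each region needs at least 1 contact")
  out <- tibble::tibble(region = names(counts),
                        n_contacts = as.integer(counts))
  class(out) <- c("region_spec", class(out))
  out
}

contact_labels <- function(spec) {
  unlist(mapply(function(r, k) paste0(r, seq_len(k)),
                spec$region, spec$n_contacts, SIMPLIFY = FALSE),
         use.names = FALSE)
}

contact_regions <- function(spec) {
  labs <- contact_labels(spec)
  regs <- rep(spec$region, spec$n_contacts)
  names(regs) <- labs
  regs
}

#' Directed cross-region coupling edge
#'
#' Declares a lagged linear influence from every contact of one region onto
#' every contact of another, the ground truth against which directed
#' metrics are validated.
#'
#' @param source,target Region names (must differ).
#' @param strength Lag-coefficient magnitude (dimensionless, finite).  The
#'   total inflow per target contact equals `strength` (divided evenly over
#'   source contacts).
#' @param lag Positive integer lag in samples.
#' @return A one-row `coupling_edge` tibble.
#' @export
coupling_edge <- function(source, target, strength, lag = 1L) {
  if (identical(source, target)) stop("source and target region must differ")
  if (!is.finite(strength)) stop("strength must be finite")
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be a positive integer")
  out <- tibble::tibble(source = source, target = target,
                        strength = as.numeric(strength), lag = lag)
  class(out) <- c("coupling_edge", class(out))
  out
}

companion_spectral_radius <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- A[, , k]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Build a ground-truth MVAR network model
#'
#' Assembles a stable multivariate autoregressive model with known directed
#' structure: each contact carries a damped AR(2) oscillator whose pole
#' frequency is drawn once per region (giving EEG-like, non-flat spectra),
#' and each declared [coupling_edge()] inserts lag coefficients from the
#' source region's contacts onto the target region's contacts.  Cross-region
#' coefficient blocks with no declared edge are exactly zero.  If the
#' assembled coefficient set is unstable, all lag matrices are repeatedly
#' scaled by 0.95 (at most 50 times) until the companion spectral radius
#' drops below 1.
#'
#' @param spec A [region_spec()].
#' @param edges A tibble of [coupling_edge()] rows (or `NULL` for an
#'   edge-free, block-diagonal network).
#' @param order Model order `p`; must be at least 2 (the oscillator) and at
#'   least the maximum edge lag.
#' @param seed Integer seed; identical seeds give bit-identical models.
#' @param sampling_rate Rate (Hz) at which the model will be simulated;
#'   used only to place oscillator pole frequencies.  Default 2000.
#' @param osc_freq_range Range (Hz) from which oscillator pole frequencies
#'   are drawn uniformly; default `c(4, 8)` — a theta-band background
#'   rhythm, the pervasive rhythm of the mesiotemporal network.  Keeping
#'   the resonance below the beta/gamma analysis bands also keeps the
#'   directed-metric noise floors direction-exchangeable there (see the
#'   vignette).
#' @param osc_mode How oscillator profiles are assigned.  `"common"`
#'   (default): one frequency/bandwidth draw shared by every contact — a
#'   network-wide background rhythm with independent per-contact
#'   innovations, which keeps the spectral noise floors of the directed
#'   metrics exchangeable between directions (the geometry the
#'   directionality statistics assume; see the vignette).  `"per_region"`:
#'   one frequency per region, contacts dispersed around it by
#'   `osc_freq_jitter`.  `"per_contact"`: independent draws per contact.
#' @param osc_bandwidth_range Range (Hz) of oscillator -3 dB-style
#'   bandwidths; the discrete-time pole radius is
#'   `exp(-pi * bandwidth / sampling_rate)`, so the spectral shape is
#'   independent of the simulation rate.  Default `c(20, 30)`, giving
#'   broad, 1/f-like spectra with a theta peak.
#' @param osc_freq_jitter Per-contact relative frequency dispersion in
#'   `"per_region"` mode; default 0.15.
#' @param noise_sd Innovation standard deviation per channel; default 1.
#' @param noise_cov Optional full innovation covariance matrix (overrides
#'   `noise_sd`); off-diagonal terms let instantaneous-correlation
#'   robustness be tested.
#' @return A `ground_truth_model`: list with elements `mvar` (an
#'   `mvar_model`), `region_spec`, and `edges`.
#' @export
make_ground_truth_mvar <- function(spec, edges = NULL, order = 3L,
                                   seed = 1L, sampling_rate = 2000,
                                   osc_freq_range = c(4, 8),
                                   osc_mode = c("common", "per_region",
                                                "per_contact"),
                                   osc_bandwidth_range = c(20, 30),
                                   osc_freq_jitter = 0.15,
                                   noise_sd = 1, noise_cov = NULL) {
  osc_mode <- match.arg(osc_mode)
  stopifnot(inherits(spec, "region_spec"))
  order <- as.integer(order)
  if (order < 2) stop("order must be at least 2 (AR(2) oscillators)")
  if (!is.null(edges) && nrow(edges)) {
    bad <- setdiff(unique(c(edges$source, edges$target)), spec$region)
    if (length(bad)) stop("edge references unknown region(s): ",
                          paste(bad, collapse = ", "))
    if (max(edges$lag) > order) stop("order must be >= the maximum edge lag")
  }
  labs <- contact_labels(spec)
  regs <- contact_regions(spec)
  n <- length(labs)
  set.seed(seed)
  A <- array(0, dim = c(n, n, order), dimnames = list(labs, labs, NULL))
  osc_freq <- stats::runif(nrow(spec), osc_freq_range[1], osc_freq_range[2])
  names(osc_freq) <- spec$region
  common_freq <- stats::runif(1, osc_freq_range[1], osc_freq_range[2])
  common_bw <- stats::runif(1, osc_bandwidth_range[1], osc_bandwidth_range[2])
  contact_freq <- numeric(n)
  names(contact_freq) <- labs
  for (i in seq_len(n)) {
    if (osc_mode == "common") {
      f_i <- common_freq; bw_i <- common_bw
    } else if (osc_mode == "per_region") {
      f_i <- osc_freq[regs[i]] *
        (1 + stats::runif(1, -osc_freq_jitter, osc_freq_jitter))
      bw_i <- stats::runif(1, osc_bandwidth_range[1], osc_bandwidth_range[2])
    } else {
      f_i <- stats::runif(1, osc_freq_range[1], osc_freq_range[2])
      bw_i <- stats::runif(1, osc_bandwidth_range[1], osc_bandwidth_range[2])
    }
    rho_i <- exp(-pi * bw_i / sampling_rate)
    th <- 2 * pi * f_i / sampling_rate
    A[i, i, 1] <- 2 * rho_i * cos(th)
    A[i, i, 2] <- -rho_i^2
    contact_freq[i] <- f_i
  }
  if (!is.null(edges)) {
    for (e in seq_len(nrow(edges))) {
      src <- labs[regs == edges$source[e]]
      tgt <- labs[regs == edges$target[e]]
      A[tgt, src, edges$lag[e]] <- A[tgt, src, edges$lag[e]] +
        edges$strength[e] / length(src)
    }
  }
  # stabilize by monotone shrinkage if needed
  attempts <- 0L
  while (companion_spectral_radius(A) >= 0.999 && attempts < 50L) {
    A <- A * 0.95
    attempts <- attempts + 1L
  }
  if (companion_spectral_radius(A) >= 0.999) {
    stop("could not stabilize the requested network within 50 shrinkage steps")
  }
  C <- if (is.null(noise_cov)) diag(noise_sd^2, n) else as.matrix(noise_cov)
  if (!isSymmetric(unname(C), tol = 1e-10) ||
      any(eigen(C, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("noise_cov must be symmetric positive semi-definite")
  }
  dimnames(C) <- list(labs, labs)
  mvar <- new_mvar_model(order = order, A = A, C = C,
                         sampling_rate = sampling_rate,
                         n_samples_used = NA_integer_,
                         labels = labs, regions = regs, stable = TRUE)
  structure(list(mvar = mvar, region_spec = spec,
                 edges = edges, oscillator_freqs = osc_freq,
                 contact_freqs = contact_freq,
                 shrink_steps = attempts),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("<ground_truth_model> %d channels, order %d, %d edge(s)\n",
              x$mvar$n_channels, x$mvar$order,
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

#' Simulate a continuous recording from a ground-truth MVAR model
#'
#' Draws Gaussian innovations from the model's covariance and runs the
#' autoregression; an initial burn-in (default `10 * order * n_channels`
#' samples) is discarded to wash out the zero initial conditions.
#'
#' @param model A `ground_truth_model` or bare `mvar_model`.
#' @param duration Recording length in seconds (positive).
#' @param sampling_rate Sampling rate in Hz; defaults to the model's.
#' @param seed Integer seed.
#' @param burn_in Burn-in samples; default `10 * order * n_channels`.
#' @return An `mc_recording` with `round(duration * sampling_rate)` samples
#'   per channel.
#' @export
simulate_mvar_recording <- function(model, duration, sampling_rate = NULL,
                                    seed = 1L, burn_in = NULL) {
  mvar <- if (inherits(model, "ground_truth_model")) model$mvar else model
  stopifnot(inherits(mvar, "mvar_model"))
  if (duration <= 0) stop("duration must be positive")
  if (is.null(sampling_rate)) sampling_rate <- mvar$sampling_rate
  rad <- companion_spectral_radius(mvar$A)
  if (rad >= 1) {
    stop(sprintf("model is unstable (companion spectral radius %.4f >= 1)", rad))
  }
  n <- mvar$n_channels
  N <- round(duration * sampling_rate)
  if (N < 10 * mvar$order) stop("duration too short for the model order")
  if (is.null(burn_in)) burn_in <- 10L * mvar$order * n
  set.seed(seed)
  L <- chol(mvar$C + diag(1e-12, n))
  E <- matrix(stats::rnorm((N + burn_in) * n), ncol = n) %*% L
  Y <- var_simulate_cpp(as.numeric(mvar$A), n, mvar$order, E)
  Y <- Y[(burn_in + 1):(burn_in + N), , drop = FALSE]
  recording(Y, sampling_rate = sampling_rate, labels = mvar$labels,
            regions = mvar$regions)
}

#' Specification of a single-pulse electrical stimulation session
#'
#' @param stimulated_pair Character vector of two contact labels (cathode,
#'   anode) through which the biphasic pulses are delivered.
#' @param n1_amplitude_map Named numeric vector: evoked N1 amplitude per
#'   recording channel, in signal units (0 for unconnected channels).
#' @param n_trials Number of stimuli; default 40.
#' @param inter_stimulus_interval Mean spacing in seconds; default 4.
#' @param jitter_fraction Uniform spacing jitter as a fraction of the
#'   interval, in `[0, 1)`; default 0.1.
#' @param n1_latency N1 peak latency in seconds after stimulus onset; must
#'   fall inside the 10-110 ms scoring window.  Default 0.025.
#' @param n1_width Gaussian half-width (SD) of the deflection in seconds;
#'   default 0.005.
#' @param noise_sd White-noise standard deviation, signal units; default 1.
#' @param artifact_amplitude Amplitude of the saturating stimulation
#'   artifact placed in the first 10 ms after each pulse; default
#'   `50 * noise_sd`.
#' @return A `spes_session_spec` list.
#' @export
spes_session_spec <- function(stimulated_pair, n1_amplitude_map,
                              n_trials = 40L, inter_stimulus_interval = 4,
                              jitter_fraction = 0.1, n1_latency = 0.025,
                              n1_width = 0.005, noise_sd = 1,
                              artifact_amplitude = 50 * noise_sd) {
  if (length(stimulated_pair) != 2) stop("stimulated_pair must name two contacts")
  if (!length(n1_amplitude_map) || is.null(names(n1_amplitude_map))) {
    stop("n1_amplitude_map must be a non-empty named numeric vector")
  }
  n_trials <- as.integer(n_trials)
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (jitter_fraction < 0 || jitter_fraction >= 1) {
    stop("jitter_fraction must lie in [0, 1)")
  }
  if (n1_latency < 0.010 || n1_latency >= 0.110) {
    stop("n1_latency must lie inside the post-stimulus response window [0.010, 0.110) s")
  }
  structure(list(stimulated_pair = as.character(stimulated_pair),
                 n1_amplitude_map = n1_amplitude_map,
                 n_trials = n_trials,
                 inter_stimulus_interval = inter_stimulus_interval,
                 jitter_fraction = jitter_fraction,
                 n1_latency = n1_latency, n1_width = n1_width,
                 noise_sd = noise_sd,
                 artifact_amplitude = artifact_amplitude),
            class = "spes_session_spec")
}

#' Simulate a SPES session with known evoked responses
#'
#' Generates a continuous recording containing `n_trials` stimulation
#' events spaced `inter_stimulus_interval * (1 +/- jitter_fraction)` apart.
#' Each event places (i) a saturating biphasic artifact on all channels in
#' the first 10 ms after onset (so artifact-exclusion logic is exercised)
#' and (ii) a negative Gaussian N1-like deflection of the mapped amplitude
#' at `n1_latency` on connected channels, on top of white noise.
#'
#' @param spec A [spes_session_spec()].
#' @param sampling_rate Sampling rate in Hz; default 2000.
#' @param seed Integer seed.
#' @param regions Optional named character vector mapping channel labels to
#'   regions; by default regions are inferred by stripping trailing digits
#'   from the labels.
#' @return A list with elements `recording` (an `mc_recording`) and
#'   `events` (tibble: `onset_seconds`, `cathode_label`, `anode_label`).
#' @export
simulate_spes_session <- function(spec, sampling_rate = 2000, seed = 1L,
                                  regions = NULL) {
  stopifnot(inherits(spec, "spes_session_spec"))
  set.seed(seed)
  labs <- union(spec$stimulated_pair, names(spec$n1_amplitude_map))
  n <- length(labs)
  isi <- spec$inter_stimulus_interval
  gaps <- isi * (1 + stats::runif(spec$n_trials - 1L,
                                  -spec$jitter_fraction, spec$jitter_fraction))
  onsets <- 2 + c(0, cumsum(gaps))
  duration <- onsets[length(onsets)] + 3
  N <- round(duration * sampling_rate)
  X <- matrix(stats::rnorm(N * n, sd = spec$noise_sd), ncol = n)
  colnames(X) <- labs
  t_art <- seq(0, 0.010 - 1 / sampling_rate, by = 1 / sampling_rate)
  art <- spec$artifact_amplitude * ifelse(t_art < 0.005, 1, -1)
  # N1 bump support: +/- 4 SD around the latency
  t_bump <- seq(max(0.010, spec$n1_latency - 4 * spec$n1_width),
                spec$n1_latency + 4 * spec$n1_width, by = 1 / sampling_rate)
  bump_shape <- -exp(-(t_bump - spec$n1_latency)^2 / (2 * spec$n1_width^2))
  for (on in onsets) {
    i0 <- round(on * sampling_rate) + 1
    ia <- i0 + round(t_art * sampling_rate)
    X[ia, ] <- X[ia, ] + art
    ib <- i0 + round(t_bump * sampling_rate)
    for (ch in names(spec$n1_amplitude_map)) {
      a <- spec$n1_amplitude_map[[ch]]
      if (a != 0) X[ib, ch] <- X[ib, ch] + a * bump_shape
    }
  }
  if (is.null(regions)) {
    regions <- sub("[0-9]+$", "", labs)
    names(regions) <- labs
  }
  rec <- recording(X, sampling_rate = sampling_rate, labels = labs,
                   regions = regions)
  events <- tibble::tibble(onset_seconds = onsets,
                           cathode_label = spec$stimulated_pair[1],
                           anode_label = spec$stimulated_pair[2])
  list(recording = rec, events = events)
}
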