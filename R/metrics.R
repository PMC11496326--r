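#' Classical EEG frequency bands
#'
#' The five analysis bands with inclusive integer-Hz edges: delta 1-4,
#' theta 5-8, alpha 9-12, beta 13-24 and low gamma 25-40 Hz.
#'
#' @return A tibble with columns `band`, `lo`, `hi`.
#' @export
default_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "low_gamma"),
    lo = c(1, 5, 9, 13, 25),
    hi = c(4, 8, 12, 24, 40)
  )
}

# Connectivity result container.  values[s, t, f] quantifies the influence
# of source channel s on target channel t at frequency f (rendering
# transposes so targets run along x, sources along y).
new_connectivity_result <- function(metric, values, freqs, labels, regions,
                                    band_values = NULL, bands = NULL,
                                    n_epochs_averaged = 1L) {
  dimnames(values) <- list(labels, labels, NULL)
  structure(
    list(metric = metric, values = values, freqs = freqs,
         band_values = band_values, bands = bands,
         labels = labels, regions = regions,
         n_epochs_averaged = n_epochs_averaged,
         orientation = "values[source, target, ] quantifies source -> target"),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %s: %d x %d channels, %d frequencies%s (avg of %d epoch[s])\n",
              x$metric, dim(x$values)[1], dim(x$values)[2], length(x$freqs),
              if (!is.null(x$band_values))
                paste0(", ", dim(x$band_values)[3], " bands") else "",
              x$n_epochs_averaged))
  cat(" ", x$orientation, "\n")
  invisible(x)
}

#' Frequency-resolved pairwise Granger causality (Geweke)
#'
#' Computes, for every ordered channel pair (s, t), the Geweke spectral
#' Granger causality from the full model's spectral density and residual
#' covariance:
#' `f_{s->t}(w) = ln[ S_tt(w) / (S_tt(w) - (C_ss - C_ts^2 / C_tt) |H_ts(w)|^2) ]`.
#' The second term is the part of the target's spectral power attributable
#' to the source's own innovations after removing instantaneous
#' correlation (the standard normalization leaves the `H_ts` element itself
#' unchanged).  Negative round-off is clipped at zero.  The pairwise
#' measure is evaluated from the single full multivariate model (no
#' per-pair refitting); see the package vignette for the implications.
#'
#' @param decomp A `spectral_decomp` from [evaluate_spectral()].
#' @param model The `mvar_model` the decomposition came from (supplies the
#'   residual covariance).
#' @return A `connectivity_result` with metric `"GC"`; diagonal entries are
#'   reported as 0 and excluded from statistics.
#' @export
granger_spectral <- function(decomp, model) {
  stopifnot(inherits(decomp, "spectral_decomp"),
            inherits(model, "mvar_model"))
  n <- dim(decomp$H)[1]
  if (model$n_channels != n) stop("decomposition and model disagree on channel count")
  nf <- length(decomp$freqs)
  C <- model$C
  vals <- array(0, dim = c(n, n, nf))
  for (fi in seq_len(nf)) {
    Hf <- decomp$H[, , fi]
    Stt <- Re(diag(decomp$S[, , fi]))
    if (any(Stt <= 0)) {
      stop(sprintf("non-positive diagonal spectral power at %g Hz",
                   decomp$freqs[fi]))
    }
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t) next
      gamma <- C[s, s] - C[t, s]^2 / C[t, t]
      denom <- Stt[t] - gamma * Mod(Hf[t, s])^2
      denom <- max(denom, .Machine$double.eps * Stt[t])
      vals[s, t, fi] <- max(0, log(Stt[t] / denom))
    }
  }
  new_connectivity_result("GC", vals, decomp$freqs, decomp$labels,
                          decomp$regions)
}

#' Directed Transfer Function (squared)
#'
#' `DTF2_{s->t}(w) = |H_ts(w)|^2 / sum_m |H_tm(w)|^2`: the inflow from the
#' source into the target relative to all inflows into the target.  Values
#' lie in `[0, 1]` and, for each target channel, sum to 1 over sources at
#' every frequency.  The squared form is the reported quantity.
#'
#' @param decomp A `spectral_decomp`.
#' @return A `connectivity_result` with metric `"DTF"` (squared values).
#' @export
dtf <- function(decomp) {
  stopifnot(inherits(decomp, "spectral_decomp"))
  n <- dim(decomp$H)[1]
  nf <- length(decomp$freqs)
  vals <- array(0, dim = c(n, n, nf))
  for (fi in seq_len(nf)) {
    H2 <- Mod(decomp$H[, , fi])^2      # H2[t, s]
    rs <- rowSums(H2)
    if (any(rs <= 0)) {
      stop(sprintf("zero transfer-matrix row at %g Hz", decomp$freqs[fi]))
    }
    vals[, , fi] <- t(H2 / rs)         # transpose to [source, target]
  }
  new_connectivity_result("DTF", vals, decomp$freqs, decomp$labels,
                          decomp$regions)
}

#' Partial Directed Coherence
#'
#' `PDC_{s->t}(w) = |Abar_ts(w)| / sqrt(a_s*(w) a_s(w))` where `a_s` is the
#' s-th column of the frequency-transformed coefficient matrix
#' `Abar(w) = I - sum_k A(k) e^{-ikw}`.  Each source column's squared
#' magnitudes sum to 1, so the measure normalizes outflows by the source
#' and captures only direct (non-cascaded) influence.  The reported value
#' is the magnitude.
#'
#' @param decomp A `spectral_decomp`.
#' @return A `connectivity_result` with metric `"PDC"`.
#' @export
pdc <- function(decomp) {
  stopifnot(inherits(decomp, "spectral_decomp"))
  n <- dim(decomp$A_bar)[1]
  nf <- length(decomp$freqs)
  vals <- array(0, dim = c(n, n, nf))
  for (fi in seq_len(nf)) {
    Am <- Mod(decomp$A_bar[, , fi])    # Am[t, s]
    cs <- sqrt(colSums(Am^2))
    if (any(cs <= 0)) {
      stop(sprintf("zero coefficient column at %g Hz", decomp$freqs[fi]))
    }
    vals[, , fi] <- t(Am) / cs         # [source, target]; divide rows by cs
  }
  new_connectivity_result("PDC", vals, decomp$freqs, decomp$labels,
                          decomp$regions)
}

#' Aggregate a connectivity cube over frequency bands
#'
#' The band value is the arithmetic mean of the metric over the integer
#' grid frequencies inside the inclusive band edges.
#'
#' @param result A `connectivity_result`.
#' @param bands A band scheme tibble (`band`, `lo`, `hi`); default
#'   [default_bands()].
#' @return The result with a `band_values` array (source x target x band)
#'   attached.
#' @export
band_aggregate <- function(result, bands = default_bands()) {
  stopifnot(inherits(result, "connectivity_result"))
  n <- dim(result$values)[1]
  bv <- array(0, dim = c(n, n, nrow(bands)),
              dimnames = list(result$labels, result$labels, bands$band))
  for (b in seq_len(nrow(bands))) {
    sel <- which(result$freqs >= bands$lo[b] & result$freqs <= bands$hi[b])
    if (!length(sel)) {
      stop("band '", bands$band[b], "' (", bands$lo[b], "-", bands$hi[b],
           " Hz) lies outside the evaluated frequency grid")
    }
    bv[, , b] <- apply(result$values[, , sel, drop = FALSE], c(1, 2), mean)
  }
  result$band_values <- bv
  result$bands <- bands
  result
}

#' Average connectivity results over epochs
#'
#' Element-wise arithmetic mean of per-epoch connectivity cubes (and band
#' matrices, when present on all inputs).
#'
#' @param results A list of `connectivity_result` objects sharing metric,
#'   shape and frequency grid.
#' @return A single averaged `connectivity_result` with
#'   `n_epochs_averaged` recorded.
#' @export
epoch_average <- function(results) {
  if (!length(results)) stop("empty result list")
  stopifnot(all(vapply(results, inherits, TRUE, "connectivity_result")))
  metrics <- unique(vapply(results, function(r) r$metric, ""))
  if (length(metrics) != 1) {
    stop("mixed metrics: ", paste(metrics, collapse = ", "))
  }
  ref <- results[[1]]
  for (r in results[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        !identical(r$freqs, ref$freqs)) {
      stop("results differ in shape or frequency grid")
    }
  }
  m <- length(results)
  vals <- Reduce(`+`, lapply(results, function(r) r$values)) / m
  out <- new_connectivity_result(ref$metric, vals, ref$freqs, ref$labels,
                                 ref$regions,
                                 n_epochs_averaged = sum(vapply(
                                   results, function(r) r$n_epochs_averaged, 1L)))
  if (all(vapply(results, function(r) !is.null(r$band_values), TRUE))) {
    out$band_values <- Reduce(`+`, lapply(results, function(r) r$band_values)) / m
    out$bands <- ref$bands
  }
  out
}

#' Per-epoch connectivity with epoch averaging
#'
#' Fits an independent MVAR model to every epoch, evaluates the requested
#' metric on the frequency grid, averages the metric over epochs, and
#' aggregates into bands — the standard analysis route for ongoing
#' activity, where per-epoch models sidestep slow non-stationarity.
#'
#' @param epochs An `epoch_set`.
#' @param order MVAR model order (integer), or `"auto"` to run
#'   [select_order()] over `order_range` first.
#' @param metric One of `"gc"`, `"dtf"`, `"pdc"`.
#' @param freqs Frequency grid in Hz; default integers 1-40.
#' @param bands Band scheme; default [default_bands()].
#' @param order_range Range for `order = "auto"`; default `c(8, 40)`.
#' @return An epoch-averaged, band-aggregated `connectivity_result`.
#' @export
epoch_connectivity <- function(epochs, order,
                               metric = c("gc", "dtf", "pdc"),
                               freqs = 1:40, bands = default_bands(),
                               order_range = c(8, 40)) {
  stopifnot(inherits(epochs, "epoch_set"))
  metric <- match.arg(metric)
  if (identical(order, "auto")) {
    order <- as.integer(select_order(epochs, order_range[1], order_range[2]))
  }
  per_epoch <- lapply(seq_len(n_epochs(epochs)), function(i) {
    model <- suppressWarnings(fit_mvar(epoch_subset(epochs, i), order))
    dec <- evaluate_spectral(model, freqs)
    switch(metric,
           gc = granger_spectral(dec, model),
           dtf = dtf(dec),
           pdc = pdc(dec))
  })
  band_aggregate(epoch_average(per_epoch), bands)
}

#' Extract one band matrix from a connectivity result
#'
#' @param result A band-aggregated `connectivity_result`.
#' @param band Band name.
#' @return A source-by-target numeric matrix.
#' @export
band_matrix <- function(result, band) {
  stopifnot(inherits(result, "connectivity_result"))
  if (is.null(result$band_values)) stop("result has no band aggregation; run band_aggregate()")
  if (!band %in% dimnames(result$band_values)[[3]]) {
    stop("unknown band '", band, "'")
  }
  result$band_values[, , band]
}

#' @rdname granger_spectral
#' @param x A `connectivity_result`.
#' @param ... Unused.
#' @export
tidy.connectivity_result <- function(x, ...) {
  n <- dim(x$values)[1]
  out <- tibble::tibble(
    metric = x$metric,
    source = rep(x$labels, times = n * length(x$freqs)),
    target = rep(rep(x$labels, each = n), times = length(x$freqs)),
    frequency = rep(x$freqs, each = n * n),
    value = as.vector(x$values)
  )
  if (!is.null(x$band_values)) {
    nb <- dim(x$band_values)[3]
    bandtab <- tibble::tibble(
      metric = x$metric,
      source = rep(x$labels, times = n * nb),
      target = rep(rep(x$labels, each = n), times = nb),
      band = rep(dimnames(x$band_values)[[3]], each = n * n),
      value = as.vector(x$band_values)
    )
    attr(out, "band_values") <- bandtab
  }
  out
}

#' @rdname granger_spectral
#' @export
glance.connectivity_result <- function(x, ...) {
  off <- !diag(dim(x$values)[1])
  tibble::tibble(
    metric = x$metric, n_channels = dim(x$values)[1],
    n_frequencies = length(x$freqs),
    n_epochs_averaged = x$n_epochs_averaged,
    max_offdiag = max(apply(x$values, 3, function(m) max(m[off]))),
    mean_offdiag = mean(apply(x$values, 3, function(m) mean(m[off])))
  )
}

#' Heatmap of band-aggregated connectivity matrices
#'
#' Renders the band matrices with targets along the x-axis and sources
#' along the y-axis, faceted by band.
#'
#' @param object A band-aggregated `connectivity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_result <- function(object, ...) {
  if (is.null(object$band_values)) object <- band_aggregate(object)
  n <- dim(object$band_values)[1]
  nb <- dim(object$band_values)[3]
  df <- tibble::tibble(
    source = factor(rep(object$labels, times = n * nb),
                    levels = rev(object$labels)),
    target = factor(rep(rep(object$labels, each = n), times = nb),
                    levels = object$labels),
    band = factor(rep(dimnames(object$band_values)[[3]], each = n * n),
                  levels = dimnames(object$band_values)[[3]]),
    value = as.vector(object$band_values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band) +
    ggplot2::scale_fill_viridis_c(name = object$metric) +
    ggplot2::labs(x = "target", y = "source",
                  title = paste(object$metric, "band connectivity")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write band matrices to CSV with a JSON sidecar
#'
#' One CSV per band (rows = source contacts, columns = target contacts,
#' labelled header row and column) plus a JSON sidecar recording the
#' metric, band edges, epochs averaged and model order.
#'
#' @param result A band-aggregated `connectivity_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default the metric name.
#' @param order Model order to record in the sidecar (optional).
#' @return Invisibly, the paths written.
#' @export
write_connectivity_csv <- function(result, dir, prefix = tolower(result$metric),
                                   order = NULL) {
  stopifnot(inherits(result, "connectivity_result"))
  if (is.null(result$band_values)) stop("run band_aggregate() first")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (b in dimnames(result$band_values)[[3]]) {
    m <- result$band_values[, , b]
    df <- data.frame(source = rownames(m), m, check.names = FALSE)
    p <- file.path(dir, paste0(prefix, "_", b, ".csv"))
    readr::write_csv(df, p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    list(metric = result$metric,
         bands = result$bands,
         n_epochs_averaged = result$n_epochs_averaged,
         model_order = order,
         orientation = result$orientation),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, side))
}
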