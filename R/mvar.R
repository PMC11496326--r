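#' Multivariate autoregressive model container
#'
#' Holds an MVAR model of order `p`: the representation
#' `x(t) = sum_{k=1}^{p} A(k) x(t-k) + e(t)` with lag-coefficient matrices
#' `A(k)` (rows index the target channel, columns the source) and residual
#' covariance `C` of the zero-mean white innovations `e(t)`.
#'
#' @keywords internal
#' @noRd
new_mvar_model <- function(order, A, C, sampling_rate, n_samples_used,
                           labels, regions = NULL, stable = NA) {
  n <- dim(A)[1]
  stopifnot(dim(A)[2] == n, dim(A)[3] == order,
            nrow(C) == n, ncol(C) == n)
  if (is.null(regions)) {
    regions <- rep(NA_character_, n); names(regions) <- labels
  }
  structure(
    list(order = as.integer(order), A = A, C = C, n_channels = n,
         sampling_rate = sampling_rate, n_samples_used = n_samples_used,
         labels = labels, regions = regions, stable = stable),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels @ %g Hz%s\n",
              x$order, x$n_channels, x$sampling_rate,
              if (isFALSE(x$stable)) " [UNSTABLE FIT]" else ""))
  invisible(x)
}

# Accumulate the lagged-regression cross-products for one epoch matrix
# (samples x channels, already mean-removed): returns list(ZtZ, ZtY, YtY,
# n_obs) for the design Z(t) = [x(t-1), ..., x(t-p)].
epoch_crossprods <- function(X, p) {
  N <- nrow(X); n <- ncol(X)
  if (N <= p) stop("epoch shorter than the model order")
  Z <- matrix(0, N - p, n * p)
  for (k in seq_len(p)) {
    Z[, ((k - 1) * n + 1):(k * n)] <- X[(p + 1 - k):(N - k), , drop = FALSE]
  }
  Y <- X[(p + 1):N, , drop = FALSE]
  list(ZtZ = crossprod(Z), ZtY = crossprod(Z, Y), YtY = crossprod(Y),
       n_obs = N - p)
}

#' Fit an MVAR model by pooled multi-epoch least squares
#'
#' Solves the stacked one-step prediction problem across all epochs: each
#' epoch is mean-removed, lagged regressors never cross epoch boundaries,
#' and the normal equations are accumulated over epochs before a single
#' solve.  The residual covariance is the pooled maximum-likelihood
#' estimate (residual cross-products divided by the pooled residual sample
#' count).
#'
#' @param epochs An `epoch_set`, or a plain samples-by-channels matrix
#'   treated as a single epoch (then `sampling_rate` must be given).
#' @param order Model order `p`.
#' @param sampling_rate Required only for matrix input.
#' @return An `mvar_model`.  If the fitted model is unstable (companion
#'   spectral radius >= 1) it carries `stable = FALSE` and a warning is
#'   raised.
#' @export
fit_mvar <- function(epochs, order, sampling_rate = NULL) {
  order <- as.integer(order)
  if (order < 1) stop("order must be a positive integer")
  if (is.matrix(epochs)) {
    if (is.null(sampling_rate)) stop("sampling_rate required for matrix input")
    labs <- colnames(epochs)
    if (is.null(labs)) labs <- paste0("ch", seq_len(ncol(epochs)))
    eplist <- list(epochs)
    regions <- NULL
    fs <- sampling_rate
  } else {
    stopifnot(inherits(epochs, "epoch_set"))
    eplist <- lapply(seq_len(n_epochs(epochs)),
                     function(i) epochs$data[, , i])
    labs <- epochs$labels
    regions <- epochs$regions
    fs <- epochs$sampling_rate
  }
  n <- ncol(eplist[[1]])
  usable <- sum(vapply(eplist, nrow, 1L)) - order * length(eplist)
  if (usable <= n * order * 10) {
    stop("insufficient data: pooled usable samples (", usable,
         ") must exceed 10 * n_channels * order (", 10 * n * order, ")")
  }
  ZtZ <- matrix(0, n * order, n * order)
  ZtY <- matrix(0, n * order, n)
  YtY <- matrix(0, n, n)
  n_obs <- 0L
  for (X in eplist) {
    X <- sweep(X, 2, colMeans(X))
    cp <- epoch_crossprods(X, order)
    ZtZ <- ZtZ + cp$ZtZ; ZtY <- ZtY + cp$ZtY; YtY <- YtY + cp$YtY
    n_obs <- n_obs + cp$n_obs
  }
  ch <- tryCatch(chol(ZtZ), error = function(e) NULL)
  if (is.null(ch)) stop("rank-deficient regressor matrix")
  B <- backsolve(ch, forwardsolve(t(ch), ZtY))   # (n*p) x n
  C <- (YtY - crossprod(ZtY, B)) / n_obs     # == t(B) %*% ZtY at the optimum
  C <- (C + t(C)) / 2
  A <- array(0, dim = c(n, n, order), dimnames = list(labs, labs, NULL))
  for (k in seq_len(order)) {
    A[, , k] <- t(B[((k - 1) * n + 1):(k * n), , drop = FALSE])
  }
  rad <- companion_spectral_radius(A)
  stable <- rad < 1
  if (!stable) warning(sprintf("fitted model is unstable (spectral radius %.4f)", rad))
  dimnames(C) <- list(labs, labs)
  new_mvar_model(order, A, C, fs, n_obs, labs, regions, stable)
}

#' Select the MVAR model order by Schwarz's Bayesian Criterion
#'
#' Evaluates `SBC(p) = log det C(p) + (log(N)/N) * p * n^2` over an
#' inclusive order range, where `C(p)` is the pooled ML residual covariance
#' and `N` the pooled residual sample count.  All candidate orders are
#' scored on the identical sample (regression starting `max_order` samples
#' into each epoch) so that criterion differences reflect the model, not
#' the sample.  Ties break toward the smaller order.
#'
#' @param epochs An `epoch_set` (or matrix plus `sampling_rate`).
#' @param min_order,max_order Inclusive search range; defaults 8 and 40.
#' @param sampling_rate Required only for matrix input.
#' @return The selected order (integer) with attribute `criterion`, a
#'   tibble of the full SBC trace.
#' @export
select_order <- function(epochs, min_order = 8L, max_order = 40L,
                         sampling_rate = NULL) {
  min_order <- as.integer(min_order); max_order <- as.integer(max_order)
  if (min_order > max_order) stop("min_order must not exceed max_order")
  if (min_order < 1) stop("orders must be positive")
  if (is.matrix(epochs)) {
    eplist <- list(epochs)
  } else {
    stopifnot(inherits(epochs, "epoch_set"))
    eplist <- lapply(seq_len(n_epochs(epochs)),
                     function(i) epochs$data[, , i])
  }
  n <- ncol(eplist[[1]])
  # shrink the range if the data cannot support max_order
  requested_max <- max_order
  repeat {
    usable <- sum(pmax(vapply(eplist, nrow, 1L) - max_order, 0L))
    if (usable > n * max_order * 10 || max_order <= min_order) break
    max_order <- max_order - 1L
  }
  usable <- sum(pmax(vapply(eplist, nrow, 1L) - max_order, 0L))
  if (usable <= n * max_order * 10) {
    stop("insufficient data even for min_order")
  }
  if (max_order < requested_max) {
    warning("insufficient data for max_order ", requested_max,
            "; search range shrunk to ", min_order, "-", max_order)
  }
  ZtZ <- matrix(0, n * max_order, n * max_order)
  ZtY <- matrix(0, n * max_order, n)
  YtY <- matrix(0, n, n)
  n_obs <- 0L
  for (X in eplist) {
    X <- sweep(X, 2, colMeans(X))
    cp <- epoch_crossprods(X, max_order)
    ZtZ <- ZtZ + cp$ZtZ; ZtY <- ZtY + cp$ZtY; YtY <- YtY + cp$YtY
    n_obs <- n_obs + cp$n_obs
  }
  orders <- min_order:max_order
  sbc <- vapply(orders, function(p) {
    idx <- seq_len(n * p)
    ch <- chol(ZtZ[idx, idx, drop = FALSE])
    B <- backsolve(ch, forwardsolve(t(ch), ZtY[idx, , drop = FALSE]))
    C <- (YtY - crossprod(ZtY[idx, , drop = FALSE], B)) / n_obs
    C <- (C + t(C)) / 2
    ld <- determinant(C, logarithm = TRUE)
    as.numeric(ld$modulus) + (log(n_obs) / n_obs) * p * n^2
  }, numeric(1))
  best <- orders[which.min(sbc)]  # which.min returns the first (smallest) tie
  attr(best, "criterion") <- tibble::tibble(order = orders, sbc = sbc)
  best
}

#' Frequency-domain decomposition of an MVAR model
#'
#' Evaluates, on a frequency grid, the coefficient polynomial
#' `Abar(w) = I - sum_k A(k) exp(-i k w)` with `w = 2 pi f / fs`, the
#' transfer matrix `H(w) = Abar(w)^{-1}` (obtained by linear solve), and
#' the spectral density matrix `S(w) = H(w) C H*(w)`.
#'
#' @param model An `mvar_model`.
#' @param freqs Frequency grid in Hz, within `(0, Nyquist]`; default
#'   integers 1-40.
#' @return A `spectral_decomp`: list with `freqs` and complex arrays
#'   `A_bar`, `H`, `S` of dimension channels x channels x frequencies.
#' @export
evaluate_spectral <- function(model, freqs = 1:40) {
  stopifnot(inherits(model, "mvar_model"))
  if (any(freqs <= 0 | freqs > model$sampling_rate / 2)) {
    stop("frequencies must lie in (0, Nyquist]")
  }
  if (!all(is.finite(model$A)) || !all(is.finite(model$C))) {
    stop("model contains non-finite values")
  }
  n <- model$n_channels
  nf <- length(freqs)
  dn <- list(model$labels, model$labels, NULL)
  A_bar <- array(0i, dim = c(n, n, nf), dimnames = dn)
  H <- array(0i, dim = c(n, n, nf), dimnames = dn)
  S <- array(0i, dim = c(n, n, nf), dimnames = dn)
  I <- diag(n)
  for (fi in seq_len(nf)) {
    w <- 2 * pi * freqs[fi] / model$sampling_rate
    Ab <- I + 0i
    for (k in seq_len(model$order)) {
      Ab <- Ab - model$A[, , k] * exp(-1i * k * w)
    }
    Hf <- tryCatch(solve(Ab, I + 0i),
                   error = function(e) NULL)
    if (is.null(Hf) || !all(is.finite(Re(Hf)))) {
      stop(sprintf("Abar(w) is numerically singular at %g Hz", freqs[fi]))
    }
    A_bar[, , fi] <- Ab
    H[, , fi] <- Hf
    S[, , fi] <- Hf %*% model$C %*% Conj(t(Hf))
  }
  structure(list(freqs = freqs, A_bar = A_bar, H = H, S = S,
                 labels = model$labels, regions = model$regions,
                 sampling_rate = model$sampling_rate),
            class = "spectral_decomp")
}

#' @export
print.spectral_decomp <- function(x, ...) {
  cat(sprintf("<spectral_decomp> %d channels, %d frequencies (%g-%g Hz)\n",
              dim(x$H)[1], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @rdname fit_mvar
#' @param x An `mvar_model`.
#' @param ... Unused.
#' @export
tidy.mvar_model <- function(x, ...) {
  n <- x$n_channels
  tibble::tibble(
    target = rep(rep(x$labels, times = n), times = x$order),
    source = rep(rep(x$labels, each = n), times = x$order),
    lag = rep(seq_len(x$order), each = n * n),
    estimate = as.vector(x$A)
  )
}

#' @rdname fit_mvar
#' @export
glance.mvar_model <- function(x, ...) {
  tibble::tibble(
    order = x$order, n_channels = x$n_channels,
    sampling_rate = x$sampling_rate, n_samples_used = x$n_samples_used,
    spectral_radius = companion_spectral_radius(x$A),
    stable = x$stable,
    log_det_C = as.numeric(determinant(x$C, logarithm = TRUE)$modulus)
  )
}

#' Serialize an MVAR model to / from JSON
#'
#' @param model An `mvar_model`.
#' @param path File path.
#' @return `write_mvar_json` returns `path` invisibly; `read_mvar_json`
#'   returns the reconstructed `mvar_model`.
#' @export
write_mvar_json <- function(model, path) {
  stopifnot(inherits(model, "mvar_model"))
  doc <- list(
    order = model$order, n_channels = model$n_channels,
    sampling_rate = model$sampling_rate,
    n_samples_used = model$n_samples_used,
    labels = model$labels,
    regions = as.list(model$regions),
    # row-major per lag matrix
    coefficients = lapply(seq_len(model$order),
                          function(k) as.vector(t(model$A[, , k]))),
    covariance = as.vector(t(model$C)),
    stable = model$stable
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mvar_json
#' @export
read_mvar_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- doc$n_channels
  A <- array(0, dim = c(n, n, doc$order),
             dimnames = list(doc$labels, doc$labels, NULL))
  coefs <- doc$coefficients
  # jsonlite simplifies the per-lag list to a matrix with one ROW per lag
  if (is.matrix(coefs)) coefs <- lapply(seq_len(nrow(coefs)), function(k) coefs[k, ])
  for (k in seq_len(doc$order)) {
    A[, , k] <- matrix(coefs[[k]], n, n, byrow = TRUE)
  }
  C <- matrix(doc$covariance, n, n, byrow = TRUE,
              dimnames = list(doc$labels, doc$labels))
  regions <- unlist(doc$regions)
  new_mvar_model(doc$order, A, C, doc$sampling_rate, doc$n_samples_used,
                 doc$labels, regions,
                 if (is.null(doc$stable)) NA else doc$stable)
}
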