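test_that("least squares recovers known coefficients at large N", {
  fix <- fix2_model()
  model <- as_mvar(fix)
  rec <- simulate_mvar_recording(model, duration = 200, seed = 4)  # 50k samples
  fit <- fit_mvar(rec$data, order = 2, sampling_rate = 250)
  for (k in 1:2) {
    expect_lt(max(abs(fit$A[, , k] - fix$A_list[[k]])), 0.02)
  }
  expect_lt(max(abs(fit$C - fix$C)), 0.05)
  expect_true(fit$stable)
})

test_that("white-noise input yields coefficients within sampling error of zero", {
  set.seed(7)
  N <- 20000
  X <- matrix(rnorm(N * 3), ncol = 3)
  fit <- fit_mvar(X, order = 2, sampling_rate = 250)
  # standard error of each coefficient is ~ 1/sqrt(N)
  expect_lt(max(abs(fit$A)), 4 / sqrt(N))
})

test_that("insufficient data and degenerate regressors are rejected", {
  set.seed(1)
  X <- matrix(rnorm(100 * 8), ncol = 8)
  expect_error(fit_mvar(X, order = 40, sampling_rate = 250), "insufficient")
  # duplicated channel makes the regressor matrix rank-deficient
  Y <- cbind(X[, 1], X[, 1], X[, 2])
  colnames(Y) <- c("a", "b", "c")
  expect_error(fit_mvar(Y, order = 2, sampling_rate = 250), "rank-deficient")
})

test_that("multi-epoch fitting pools information without crossing epoch boundaries", {
  fix <- fix2_model()
  model <- as_mvar(fix)
  rec <- simulate_mvar_recording(model, duration = 120, seed = 8)
  ep <- make_epochs(rec, 10)
  fit <- fit_mvar(ep, order = 2)
  for (k in 1:2) expect_lt(max(abs(fit$A[, , k] - fix$A_list[[k]])), 0.03)
  expect_equal(fit$n_samples_used, 12 * (2500 - 2))
})

test_that("SBC selects the generating order and breaks ties downward", {
  spec <- region_spec(SRC = 2, TGT = 1)
  edges <- coupling_edge("SRC", "TGT", 0.5, lag = 6)
  hits <- 0
  for (s in 1:5) {
    gt <- make_ground_truth_mvar(spec, edges, order = 6, seed = s,
                                 sampling_rate = 250)
    rec <- simulate_mvar_recording(gt, duration = 120, seed = s + 50)
    ep <- make_epochs(rec, 10)
    sel <- select_order(ep, 2, 12)
    hits <- hits + (as.integer(sel) == 6)
    trace <- attr(sel, "criterion")
    expect_equal(nrow(trace), 11)
    expect_equal(trace$order[which.min(trace$sbc)], as.integer(sel))
  }
  expect_gte(hits, 4)
})

test_that("SBC-selected order is non-decreasing in the true generator order", {
  spec <- region_spec(SRC = 1, TGT = 1)
  med_sel <- sapply(c(3, 6, 9), function(p_true) {
    sels <- sapply(1:5, function(s) {
      gt <- make_ground_truth_mvar(spec,
                                   coupling_edge("SRC", "TGT", 0.6, lag = p_true),
                                   order = p_true, seed = s,
                                   sampling_rate = 250)
      rec <- simulate_mvar_recording(gt, duration = 80, seed = s + 70)
      as.integer(select_order(make_epochs(rec, 10), 2, 12))
    })
    median(sels)
  })
  expect_true(all(diff(med_sel) >= 0))
})

test_that("order search range shrinks with a warning when data are scarce", {
  set.seed(2)
  X <- matrix(rnorm(700 * 2), ncol = 2)
  expect_warning(sel <- select_order(X, 2, 40, sampling_rate = 250), "shrunk")
  expect_lte(as.integer(sel), 40)
})

test_that("the spectral decomposition satisfies its defining identities", {
  # zero-coefficient model with unit covariance: H = S = I everywhere
  null_fix <- list(A_list = list(matrix(0, 2, 2)), C = diag(2), fs = 250)
  dec0 <- evaluate_spectral(as_mvar(null_fix), 1:40)
  for (fi in c(1, 20, 40)) {
    expect_equal(dec0$H[, , fi], diag(2) + 0i, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(dec0$S[, , fi], diag(2) + 0i, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # general model: Abar %*% H = I on the whole grid; S Hermitian PSD
  model <- as_mvar(fix2_model())
  dec <- evaluate_spectral(model, 1:40)
  worst <- 0
  for (fi in seq_along(dec$freqs)) {
    worst <- max(worst, max(Mod(dec$A_bar[, , fi] %*% dec$H[, , fi] - diag(2))))
    S <- dec$S[, , fi]
    expect_lt(max(Mod(S - Conj(t(S)))), 1e-10)
    expect_gte(min(Re(eigen(S, only.values = TRUE)$values)), -1e-10)
  }
  expect_lt(worst, 1e-8)
})

test_that("a singular coefficient polynomial is reported with its frequency", {
  fs <- 250
  theta <- 2 * pi * 10 / fs
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  fix <- list(A_list = list(R), C = diag(2), fs = fs)
  expect_error(evaluate_spectral(as_mvar(fix), 1:40), "10")
})

test_that("frequencies outside (0, Nyquist] are rejected", {
  model <- as_mvar(fix2_model())
  expect_error(evaluate_spectral(model, c(0, 10)), "Nyquist")
  expect_error(evaluate_spectral(model, 130), "Nyquist")
})

test_that("the spectral diagonal integrates to the process variance", {
  fix <- fix2_model()
  model <- as_mvar(fix)
  freqs <- seq(0.25, 125, by = 0.25)
  dec <- evaluate_spectral(model, freqs)
  spec_var <- apply(dec$S, c(1, 2), function(v) sum(Re(v)))[cbind(1:2, 1:2)] *
    0.25 * 2 / 250
  rec <- simulate_mvar_recording(model, duration = 800, seed = 12)
  emp_var <- apply(rec$data, 2, var)
  expect_lt(max(abs(spec_var - emp_var) / emp_var), 0.05)
})

test_that("the model spectrum matches the averaged periodogram of a long simulation", {
  fix <- fix2_model()
  model <- as_mvar(fix)
  rec <- simulate_mvar_recording(model, duration = 4000, seed = 3)  # 1e6 samples
  x <- rec$data[, 1]
  fs <- 250
  seg <- 500                                  # 0.5 Hz bins
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))           # Hann
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  P <- matrix(0, seg, length(starts))
  for (i in seq_along(starts)) {
    xi <- x[starts[i]:(starts[i] + seg - 1)]
    P[, i] <- Mod(fft((xi - mean(xi)) * w))^2 / (fs * sum(w^2))
  }
  pgram <- rowMeans(P)                        # two-sided density, 0.5 Hz bins
  dec <- evaluate_spectral(model, 1:40)
  s11 <- Re(dec$S[1, 1, ]) / fs               # model density per Hz
  # smooth over the three 0.5 Hz bins around each integer frequency
  emp <- sapply(1:40, function(f) mean(pgram[2 * f + 0:2]))
  expect_lt(max(abs(emp - s11) / s11), 0.05)
})

test_that("tidy and glance summarize fitted models", {
  model <- as_mvar(fix2_model())
  td <- tidy(model)
  expect_equal(nrow(td), 2 * 2 * 2)
  expect_equal(td$estimate[td$source == "ch1" & td$target == "ch2" & td$lag == 1],
               0.4)
  gl <- glance(model)
  expect_equal(gl$order, 2L)
  expect_lt(gl$spectral_radius, 1)
})

test_that("MVAR JSON serialization round-trips", {
  model <- as_mvar(fix2_model())
  path <- withr::local_tempfile(fileext = ".json")
  write_mvar_json(model, path)
  back <- read_mvar_json(path)
  expect_equal(back$A, model$A)
  expect_equal(back$C, model$C)
  expect_equal(back$order, model$order)
  expect_equal(back$sampling_rate, model$sampling_rate)
})
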