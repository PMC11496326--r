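test_that("GC, DTF and PDC match brute-force oracle evaluations to 1e-10", {
  for (fix in list(fix2_model(), fix3_chain_model())) {
    model <- as_mvar(fix)
    n <- model$n_channels
    dec <- evaluate_spectral(model, 1:40)
    gc <- granger_spectral(dec, model)
    d2 <- dtf(dec)
    pd <- pdc(dec)
    for (f in c(1, 7, 19, 33, 40)) {
      fi <- match(f, dec$freqs)
      for (s in 1:n) for (t in 1:n) {
        if (s == t) next
        expect_equal(gc$values[s, t, fi],
                     oracle_gc_pair(fix$A_list, fix$C, f, fix$fs, s, t),
                     tolerance = 1e-10)
        expect_equal(d2$values[s, t, fi],
                     oracle_dtf2_pair(fix$A_list, f, fix$fs, s, t),
                     tolerance = 1e-10)
        expect_equal(pd$values[s, t, fi],
                     oracle_pdc_pair(fix$A_list, f, fix$fs, s, t),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("independent channels produce vanishing off-diagonal metrics", {
  fix <- list(A_list = list(diag(c(0.5, 0.3, -0.2))), C = diag(3), fs = 250)
  model <- as_mvar(fix)
  dec <- evaluate_spectral(model, 1:40)
  off <- !diag(3)
  expect_lt(max(apply(granger_spectral(dec, model)$values, 3,
                      function(m) max(m[off]))), 1e-10)
  expect_lt(max(apply(dtf(dec)$values, 3, function(m) max(m[off]))), 1e-10)
  expect_lt(max(apply(pdc(dec)$values, 3, function(m) max(m[off]))), 1e-10)
  # identity H: DTF^2 is 1 on the diagonal
  null_fix <- list(A_list = list(matrix(0, 2, 2)), C = diag(2), fs = 250)
  d0 <- dtf(evaluate_spectral(as_mvar(null_fix), 1:10))
  expect_equal(d0$values[cbind(1:2, 1:2, 1)], c(1, 1))
})

test_that("normalizations hold to 1e-10 for models fitted to data", {
  gt <- make_ground_truth_mvar(mtl_region_spec(), mtl_edges(), order = 2,
                               seed = 21, sampling_rate = 250)
  rec <- simulate_mvar_recording(gt, duration = 60, seed = 22)
  fit <- fit_mvar(rec$data, order = 6, sampling_rate = 250)
  dec <- evaluate_spectral(fit, 1:40)
  d2 <- dtf(dec)$values
  pd <- pdc(dec)$values
  for (fi in seq_len(dim(d2)[3])) {
    # DTF^2: sum over sources = 1 for every target
    expect_lt(max(abs(colSums(d2[, , fi]) - 1)), 1e-10)
    # PDC: squared magnitudes sum to 1 over targets for every source
    expect_lt(max(abs(rowSums(pd[, , fi]^2) - 1)), 1e-10)
  }
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_true(all(pd >= 0 & pd <= 1))
  expect_gte(min(granger_spectral(dec, fit)$values), 0)
})

test_that("unidirectional coupling gives a one-sided GC spectrum", {
  fix <- list(A_list = list(matrix(c(0.5, 0.5, 0, 0.3), 2, 2)),
              C = diag(2), fs = 250)
  model <- as_mvar(fix)
  dec <- evaluate_spectral(model, 1:40)
  gc <- granger_spectral(dec, model)
  expect_true(all(gc$values[1, 2, ] > gc$values[2, 1, ]))
  expect_lt(max(gc$values[2, 1, ]), 1e-12)
})

test_that("a chain distinguishes direct (PDC) from cascaded (DTF) influence", {
  fix <- fix3_chain_model()
  model <- as_mvar(fix)
  dec <- evaluate_spectral(model, 1:40)
  pd <- pdc(dec)$values
  d2 <- dtf(dec)$values
  expect_lt(max(pd[1, 3, ]), 1e-12)     # no direct 1 -> 3 coefficient
  expect_gt(min(d2[1, 3, ]), 1e-6)      # but influence flows through 2
})

test_that("band aggregation averages the inclusive integer band", {
  model <- as_mvar(fix2_model())
  dec <- evaluate_spectral(model, 1:40)
  res <- band_aggregate(dtf(dec))
  expect_equal(res$band_values[, , "delta"],
               apply(res$values[, , 1:4], c(1, 2), mean))
  expect_equal(res$band_values[, , "low_gamma"],
               apply(res$values[, , 25:40], c(1, 2), mean))
  # constant metric: every band equals the constant
  cube <- res
  cube$values[] <- 0.25
  agg <- band_aggregate(cube)
  expect_true(all(abs(agg$band_values - 0.25) < 1e-12))
  # toy 3-frequency cube, hand-averaged
  toy <- mvarconn:::new_connectivity_result(
    "DTF", array(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), c(2, 2, 3)),
    freqs = 1:3, labels = c("a", "b"), regions = NULL)
  agg3 <- band_aggregate(toy, tibble::tibble(band = "x", lo = 1, hi = 3))
  expect_equal(agg3$band_values[, , "x"], matrix(c(5, 6, 7, 8), 2, 2),
               ignore_attr = TRUE)
  out_of_grid <- tibble::tibble(band = "hf", lo = 60, hi = 80)
  expect_error(band_aggregate(toy, out_of_grid), "outside")
})

test_that("epoch averaging is an element-wise mean with provenance", {
  model <- as_mvar(fix2_model())
  dec <- evaluate_spectral(model, 1:10)
  a <- dtf(dec)
  b <- a
  b$values <- b$values * 0.5
  avg <- epoch_average(list(a, b))
  expect_equal(avg$values, (a$values + b$values) / 2)
  expect_equal(avg$n_epochs_averaged, 2L)
  expect_equal(epoch_average(list(a, a))$values, a$values)
  expect_error(epoch_average(list()), "empty")
  pd <- pdc(dec)
  expect_error(epoch_average(list(a, pd)), "mixed")
})

test_that("single-edge generators are recovered in the right direction", {
  spec <- region_spec(SRC = 1, TGT = 1)
  edges <- coupling_edge("SRC", "TGT", 0.5, lag = 1)
  wins <- c(gc = 0, dtf = 0, pdc = 0)
  n_runs <- 60
  for (s in seq_len(n_runs)) {
    gt <- make_ground_truth_mvar(spec, edges, order = 2, seed = s,
                                 sampling_rate = 250)
    rec <- simulate_mvar_recording(gt, duration = 30, seed = s + 900)
    fit <- suppressWarnings(fit_mvar(rec$data, 4, sampling_rate = 250))
    dec <- evaluate_spectral(fit, 1:40)
    band <- tibble::tibble(band = "theta", lo = 4, hi = 8)  # rhythm band
    for (m in names(wins)) {
      res <- switch(m, gc = granger_spectral(dec, fit), dtf = dtf(dec),
                    pdc = pdc(dec))
      bv <- band_aggregate(res, band)$band_values[, , 1]
      wins[m] <- wins[m] + (bv["SRC1", "TGT1"] > bv["TGT1", "SRC1"])
    }
  }
  expect_gte(min(wins) / n_runs, 0.95)
})

test_that("direction ordering survives the full 2000 Hz acquisition chain", {
  # record at 2000 Hz, high-pass, decimate to 250, epoch, per-epoch models
  spec <- region_spec(SRC = 1, TGT = 1)
  edges <- coupling_edge("SRC", "TGT", 0.5, lag = 8)
  wins <- 0
  for (s in 1:10) {
    gt <- make_ground_truth_mvar(spec, edges, order = 8, seed = s,
                                 sampling_rate = 2000)
    rec <- simulate_mvar_recording(gt, duration = 60, seed = s + 40)
    ep <- preprocess_recording(rec)
    res <- epoch_connectivity(ep, order = 8, metric = "pdc")
    bv <- band_matrix(res, "theta")
    wins <- wins + (bv["SRC1", "TGT1"] > bv["TGT1", "SRC1"])
  }
  expect_gte(wins, 9)
})

test_that("connectivity results tidy, glance and plot", {
  model <- as_mvar(fix2_model())
  res <- band_aggregate(dtf(evaluate_spectral(model, 1:40)))
  td <- tidy(res)
  expect_equal(nrow(td), 2 * 2 * 40)
  expect_equal(td$value[td$source == "ch1" & td$target == "ch2" &
                          td$frequency == 10],
               res$values[1, 2, 10])
  gl <- glance(res)
  expect_equal(gl$metric, "DTF")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("band matrices export to labelled CSV with a JSON sidecar", {
  model <- as_mvar(fix2_model())
  res <- band_aggregate(dtf(evaluate_spectral(model, 1:40)))
  dir <- withr::local_tempdir()
  paths <- write_connectivity_csv(res, dir, order = 2)
  expect_true(all(file.exists(paths)))
  beta <- readr::read_csv(file.path(dir, "dtf_beta.csv"),
                          show_col_types = FALSE)
  expect_equal(beta$source, c("ch1", "ch2"))
  expect_equal(beta$ch2[1], res$band_values[1, 2, "beta"])
  meta <- jsonlite::read_json(file.path(dir, "dtf_meta.json"))
  expect_equal(meta$metric, "DTF")
  expect_equal(meta$model_order, 2)
})
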