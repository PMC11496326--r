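band_fixture <- function(seed = 31) {
  gt <- make_ground_truth_mvar(mtl_region_spec(), mtl_edges(), order = 2,
                               seed = seed, sampling_rate = 250)
  rec <- simulate_mvar_recording(gt, duration = 60, seed = seed + 1)
  epoch_connectivity(make_epochs(rec, 10), order = 4, metric = "pdc")
}

test_that("region pooling produces one group per unordered region pair", {
  res <- band_fixture()
  pooled <- pool_region_pairs(res, bands = "beta")
  groups <- dplyr::distinct(pooled, region_a, region_b)
  expect_equal(nrow(groups), 6)                     # 4 regions -> 6 pairs
  g <- pooled[pooled$region_a == "AMG" & pooled$region_b == "HPC", ]
  expect_equal(sum(g$direction == "forward"), 4)    # 2x2 contact pairs
  expect_equal(sum(g$direction == "reverse"), 4)
  expect_false(any(pooled$source == pooled$target))
  # two regions -> one group
  res2 <- res
  keep <- c("AMG1", "AMG2", "HPC1", "HPC2")
  res2$band_values <- res2$band_values[keep, keep, , drop = FALSE]
  res2$regions <- res2$regions[keep]
  res2$labels <- keep
  expect_equal(nrow(dplyr::distinct(pool_region_pairs(res2, bands = "beta"),
                                    region_a, region_b)), 1)
})

test_that("CCEP tables pool into region-pair groups with band 'CCEP'", {
  tab <- tibble::tibble(
    stim_pair = "A1-A2", channel = c("B1", "B2", "C1"),
    source_region = "A", target_region = c("B", "B", "C"),
    z = c(5, 6, 1)
  )
  pooled <- pool_region_pairs(tab)
  expect_true(all(pooled$band == "CCEP"))
  expect_equal(nrow(pooled[pooled$region_a == "A" & pooled$region_b == "B", ]), 2)
  expect_true(all(pooled$direction == "forward"))
})

test_that("asymmetry differences are the signed i,j minus j,i elements", {
  m <- matrix(0.1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- 0.4
  m["b", "a"] <- 0.1
  d <- asymmetry_differences(m)
  expect_equal(nrow(d), 3)
  expect_equal(d$difference[d$source == "a" & d$target == "b"], 0.3)
  # symmetric matrix: all zero
  expect_true(all(asymmetry_differences((m + t(m)) / 2)$difference == 0))
  # transpose antisymmetry
  expect_equal(asymmetry_differences(t(m))$difference, -d$difference)
  expect_error(asymmetry_differences(matrix(1, 2, 3)), "square")
})

test_that("the one-sample t-test is calibrated and powered", {
  set.seed(101)
  p_null <- replicate(400, ttest_zero_mean(rnorm(50))$p.value)
  rate <- mean(p_null < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  p_alt <- replicate(200, ttest_zero_mean(rnorm(50, mean = 0.5))$p.value)
  expect_gt(mean(p_alt < 0.05), 0.9)
  expect_error(ttest_zero_mean(rep(1, 10)), "zero variance")
  expect_error(ttest_zero_mean(1), "at least 2")
})

test_that("the direction ANOVA equals the squared pooled t and flags direction", {
  set.seed(55)
  for (i in 1:20) {
    fwd <- rnorm(4 + i %% 3, mean = runif(1, -1, 1))
    rev <- rnorm(4, mean = runif(1, -1, 1))
    out <- anova_direction(fwd, rev)
    tt <- t.test(fwd, rev, var.equal = TRUE)
    expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(out$p.value, tt$p.value, tolerance = 1e-10)
    expect_equal(out$favored,
                 if (mean(fwd) >= mean(rev)) "forward" else "reverse")
  }
  # identical lists: F = 0
  expect_equal(anova_direction(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(anova_direction(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni correction is monotone and capped at one", {
  set.seed(77)
  for (i in 1:20) {
    out <- anova_direction(rnorm(4), rnorm(4), n_comparisons = 12)
    expect_gte(out$p.corrected, out$p.value)
    expect_lte(out$p.corrected, 1)
  }
})

test_that("directionality table favored direction matches the group means", {
  res <- band_fixture()
  da <- directionality_anova(pool_region_pairs(res))
  expect_equal(nrow(da), 30)                        # 6 pairs x 5 bands
  expect_true(all((da$diff_mean >= 0) == (da$favored == "forward")))
  expect_true(all(da$statistic >= 0))
  expect_true(all(da$p.corrected >= da$p.value))
  # t-test direction agrees with the mean difference where defined
  ok <- !is.na(da$t.statistic) & abs(da$diff_mean) > 1e-12
  expect_true(all(sign(da$t.statistic[ok]) == sign(da$diff_mean[ok])))
  expect_output(summarize_directionality(da[1:3, ]), "F\\(1,")
  expect_s3_class(plot_directionality(da), "ggplot")
})

test_that("SOZ contrast flags direction flips and significance changes", {
  res <- band_fixture()
  da <- directionality_anova(pool_region_pairs(res, bands = "beta"))
  expect_equal(sum(soz_contrast(da, da)$direction_flip), 0)
  expect_equal(sum(soz_contrast(da, da)$significance_change), 0)
  flipped <- da
  i <- which(flipped$significant)[1]
  flipped$favored[i] <- setdiff(c("forward", "reverse"), flipped$favored[i])
  ctr <- soz_contrast(da, flipped)
  expect_equal(sum(ctr$direction_flip), 1)
  expect_error(soz_contrast(da, da[-1, ]), "missing in reduced")
})

test_that("an engineered reverse edge among excluded channels flips the call", {
  # full set carries HPC3 (SOZ) with a strong reverse HPC -> AMG influence
  spec <- region_spec(AMG = 2, HPC = 3)
  edges <- dplyr::bind_rows(
    coupling_edge("AMG", "HPC", 0.3, lag = 1),
    coupling_edge("HPC", "AMG", 2.4, lag = 1)   # 0.8 per HPC contact
  )
  gt <- make_ground_truth_mvar(spec, edges, order = 2, seed = 91,
                               sampling_rate = 250)
  # reverse influence flows only out of HPC3
  gt$mvar$A[c("AMG1", "AMG2"), c("HPC1", "HPC2"), 1] <- 0
  rec <- simulate_mvar_recording(gt, duration = 240, seed = 92)
  rec <- set_soz(rec, "HPC3")
  run <- function(r) {
    res <- epoch_connectivity(make_epochs(r, 10), order = 4, metric = "pdc")
    directionality_anova(pool_region_pairs(res, bands = "theta"))
  }
  full <- run(rec)
  reduced <- run(exclude_channels(rec))
  ctr <- soz_contrast(full, reduced)
  expect_equal(full$favored, "reverse")     # HPC -> AMG dominates with HPC3
  expect_equal(reduced$favored, "forward")  # AMG -> HPC without it
  expect_true(ctr$direction_flip[1])
})

test_that("pooling after an emptied region drops its pairs with a warning", {
  gt <- make_ground_truth_mvar(mtl_region_spec(), mtl_edges(), order = 2,
                               seed = 41, sampling_rate = 250)
  rec <- simulate_mvar_recording(gt, duration = 60, seed = 42)
  rec <- set_soz(rec, c("HPC1", "HPC2"))
  expect_warning(red <- exclude_channels(rec), "HPC")
  res <- epoch_connectivity(make_epochs(red, 10), order = 4, metric = "pdc")
  pooled <- pool_region_pairs(res, bands = "beta")
  groups <- dplyr::distinct(pooled, region_a, region_b)
  expect_equal(nrow(groups), 3)                    # pairs among AMG, TP, PHP
  expect_false(any(grepl("HPC", c(groups$region_a, groups$region_b))))
})
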