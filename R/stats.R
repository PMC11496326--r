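#' Pool contact-level metric values into region-pair direction groups
#'
#' Arranges all cross-region ordered contact pairs into one group per
#' unordered region pair, each with a forward (A to B) and a reverse (B to
#' A) direction — for R regions with contacts, `R*(R-1)/2` groups.
#' Within-region elements and the diagonal are excluded.  Regions with
#' zero contacts are omitted with a warning.
#'
#' Two inputs are accepted: a band-aggregated [granger_spectral()] /
#' [dtf()] / [pdc()] `connectivity_result` (one row per contact pair,
#' direction and band), or a `ccep_response`-style data frame with
#' `source_region`, `target_region` and `z` columns (band is then
#' `"CCEP"`).
#'
#' @param x A `connectivity_result` with band values, or a data frame of
#'   CCEP z-scores.
#' @param bands Optional character vector restricting the bands pooled.
#' @return A tibble with columns `region_a`, `region_b` (alphabetical
#'   within pair), `band`, `direction` (`"forward"` = a to b), `source`,
#'   `target`, `value`.
#' @export
pool_region_pairs <- function(x, bands = NULL) {
  if (inherits(x, "connectivity_result")) {
    if (is.null(x$band_values)) stop("run band_aggregate() first")
    regions <- x$regions
    present <- unique(stats::na.omit(unname(regions)))
    if (length(present) < 2) stop("need at least 2 regions with contacts")
    all_bands <- dimnames(x$band_values)[[3]]
    if (is.null(bands)) bands <- all_bands
    rows <- list()
    for (b in bands) {
      m <- x$band_values[, , b]
      long <- tibble::tibble(
        source = rep(rownames(m), times = ncol(m)),
        target = rep(colnames(m), each = nrow(m)),
        value = as.vector(m)
      )
      long$src_region <- unname(regions[long$source])
      long$tgt_region <- unname(regions[long$target])
      long <- long[!is.na(long$src_region) & !is.na(long$tgt_region) &
                     long$src_region != long$tgt_region, ]
      long$band <- b
      rows[[b]] <- long
    }
    long <- dplyr::bind_rows(rows)
  } else {
    df <- tibble::as_tibble(x)
    need <- c("source_region", "target_region", "z")
    if (!all(need %in% names(df))) {
      stop("data frame input needs columns: ", paste(need, collapse = ", "))
    }
    long <- tibble::tibble(
      source = if ("stim_pair" %in% names(df)) df$stim_pair else df$source_region,
      target = if ("channel" %in% names(df)) df$channel else df$target_region,
      value = df$z,
      src_region = df$source_region,
      tgt_region = df$target_region,
      band = "CCEP"
    )
    long <- long[!is.na(long$src_region) & !is.na(long$tgt_region) &
                   long$src_region != long$tgt_region, ]
    present <- unique(c(long$src_region, long$tgt_region))
    if (length(present) < 2) stop("need at least 2 regions with observations")
  }
  if (!nrow(long)) stop("no cross-region observations to pool")
  long$region_a <- pmin(long$src_region, long$tgt_region)
  long$region_b <- pmax(long$src_region, long$tgt_region)
  long$direction <- ifelse(long$src_region == long$region_a,
                           "forward", "reverse")
  out <- dplyr::arrange(
    dplyr::select(long, "region_a", "region_b", "band", "direction",
                  "source", "target", "value"),
    .data$region_a, .data$region_b, .data$band, .data$direction
  )
  out
}

#' Element-wise directional asymmetries of a connectivity matrix
#'
#' For every unordered off-diagonal element pair of a square source-by-
#' target matrix, reports `M[s, t] - M[t, s]` — the raw material of the
#' one-sample t-test for a predominant direction.
#'
#' @param m A square numeric matrix with channel labels, or a
#'   band-aggregated `connectivity_result` plus `band`.
#' @param band Band name when `m` is a `connectivity_result`.
#' @param regions Optional named region map to annotate the pairs.
#' @return A tibble with columns `source`, `target` (source < target by
#'   matrix order), `difference`, and region annotations when available.
#' @export
asymmetry_differences <- function(m, band = NULL, regions = NULL) {
  if (inherits(m, "connectivity_result")) {
    if (is.null(regions)) regions <- m$regions
    m <- band_matrix(m, band)
  }
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  n <- nrow(m)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("ch", seq_len(n))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(
    source = labs[idx[, 1]],
    target = labs[idx[, 2]],
    difference = m[idx] - m[idx[, c(2, 1), drop = FALSE]]
  )
  if (!is.null(regions)) {
    out$source_region <- unname(regions[out$source])
    out$target_region <- unname(regions[out$target])
  }
  out
}

#' One-sample t-test of asymmetries against zero mean
#'
#' Two-sided one-sample t-test of the null hypothesis that the directional
#' differences are drawn from a zero-mean distribution.
#'
#' @param differences Numeric vector of `i,j` minus `j,i` differences.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`, `conf.low`, `conf.high`.
#' @export
ttest_zero_mean <- function(differences) {
  differences <- differences[is.finite(differences)]
  if (length(differences) < 2) stop("need at least 2 finite differences")
  if (stats::var(differences) == 0) {
    stop("zero variance: all differences identical")
  }
  ht <- stats::t.test(differences, mu = 0)
  tibble::tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    conf.low = ht$conf.int[1],
    conf.high = ht$conf.int[2]
  )
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Directionality ANOVA for one region-pair group
#'
#' One-way two-level analysis of variance comparing the forward against
#' the reverse direction values (each ordered contact pair contributes one
#' observation per direction), giving an F statistic with
#' `(1, n_fwd + n_rev - 2)` degrees of freedom — identical to the square
#' of the pooled two-sample t statistic.  The p value is
#' Bonferroni-corrected for the size of the test family.
#'
#' @param forward,reverse Numeric vectors of metric values per direction.
#' @param n_comparisons Bonferroni family size; default 1 (no correction).
#' @param alpha Significance level for the `significant` flag; default
#'   0.05 (applied to the corrected p).
#' @return A one-row tibble: `n_fwd`, `n_rev`, `mean_fwd`, `mean_rev`,
#'   `diff_mean`, `statistic` (F), `df1`, `df2`, `p.value`, `p.corrected`,
#'   `stars`, `favored`, `significant`.
#' @export
anova_direction <- function(forward, reverse, n_comparisons = 1,
                            alpha = 0.05) {
  if (!length(forward) || !length(reverse)) {
    stop("both direction lists must be non-empty")
  }
  df <- data.frame(
    value = c(forward, reverse),
    direction = factor(rep(c("forward", "reverse"),
                           c(length(forward), length(reverse))))
  )
  fit <- stats::aov(value ~ direction, data = df)
  tab <- summary(fit)[[1]]
  Fstat <- tab["direction", "F value"]
  p <- tab["direction", "Pr(>F)"]
  if (is.na(Fstat)) { Fstat <- 0; p <- 1 }  # zero residual df or zero SS
  p_corr <- stats::p.adjust(p, method = "bonferroni", n = n_comparisons)
  dm <- mean(forward) - mean(reverse)
  tibble::tibble(
    n_fwd = length(forward), n_rev = length(reverse),
    mean_fwd = mean(forward), mean_rev = mean(reverse),
    diff_mean = dm,
    statistic = unname(Fstat),
    df1 = 1, df2 = length(forward) + length(reverse) - 2,
    p.value = unname(p), p.corrected = unname(p_corr),
    stars = significance_stars(p_corr),
    favored = if (dm >= 0) "forward" else "reverse",
    significant = p_corr < alpha
  )
}

#' Directionality statistics over all region pairs and bands
#'
#' Runs [anova_direction()] on every (region pair, band) group of a pooled
#' table and attaches the one-sample t-test of the element-wise
#' asymmetries within each group (forward value minus the matching reverse
#' value per contact pair, where identifiable).
#'
#' @param pooled Output of [pool_region_pairs()].
#' @param alpha Significance level; default 0.05.
#' @param n_comparisons Bonferroni family size; default the number of
#'   (pair, band) groups tested.
#' @return A tidy tibble with one row per region pair and band, columns as
#'   in [anova_direction()] plus `region_a`, `region_b`, `band`,
#'   `direction_label`, and t-test columns `t.statistic`, `t.df`,
#'   `t.p.value`.
#' @export
directionality_anova <- function(pooled, alpha = 0.05,
                                 n_comparisons = NULL) {
  groups <- dplyr::distinct(pooled, .data$region_a, .data$region_b,
                            .data$band)
  if (is.null(n_comparisons)) n_comparisons <- nrow(groups)
  res <- purrr::pmap_dfr(groups, function(region_a, region_b, band) {
    g <- pooled[pooled$region_a == region_a & pooled$region_b == region_b &
                  pooled$band == band, ]
    fwd <- g$value[g$direction == "forward"]
    rev <- g$value[g$direction == "reverse"]
    row <- anova_direction(fwd, rev, n_comparisons = n_comparisons,
                           alpha = alpha)
    # paired element-wise asymmetries where contact pairs match up
    diffs <- tryCatch({
      f <- g[g$direction == "forward", ]
      r <- g[g$direction == "reverse", ]
      key_f <- paste(f$source, f$target)
      key_r <- paste(r$target, r$source)
      mi <- match(key_f, key_r)
      f$value[!is.na(mi)] - r$value[mi[!is.na(mi)]]
    }, error = function(e) numeric(0))
    tt <- if (length(diffs) >= 2 && stats::var(diffs) > 0) {
      ttest_zero_mean(diffs)
    } else {
      tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                     df = NA_real_, p.value = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_)
    }
    dplyr::bind_cols(
      tibble::tibble(region_a = region_a, region_b = region_b, band = band),
      row,
      tibble::tibble(t.statistic = tt$statistic, t.df = tt$df,
                     t.p.value = tt$p.value)
    )
  })
  res$direction_label <- ifelse(
    res$favored == "forward",
    paste(res$region_a, "→", res$region_b),
    paste(res$region_b, "→", res$region_a)
  )
  res
}

#' Compare directionality results with and without SOZ channels
#'
#' Side-by-side comparison of two [directionality_anova()] tables produced
#' by identical pipeline configurations differing only in channel
#' exclusion, flagging favored-direction flips and significance changes
#' per region pair and band.
#'
#' @param full Directionality table from the full channel set.
#' @param reduced Directionality table after SOZ exclusion.
#' @return A tibble keyed by (`region_a`, `region_b`, `band`) with both
#'   tables' favored directions and significance, plus logical columns
#'   `direction_flip` and `significance_change`.
#' @export
soz_contrast <- function(full, reduced) {
  key <- c("region_a", "region_b", "band")
  missing_in_reduced <- dplyr::anti_join(full[key], reduced[key], by = key)
  missing_in_full <- dplyr::anti_join(reduced[key], full[key], by = key)
  if (nrow(missing_in_reduced) || nrow(missing_in_full)) {
    desc <- function(d) paste(sprintf("%s-%s/%s", d$region_a, d$region_b,
                                      d$band), collapse = ", ")
    stop("mismatched pair sets; missing in reduced: ",
         if (nrow(missing_in_reduced)) desc(missing_in_reduced) else "none",
         "; missing in full: ",
         if (nrow(missing_in_full)) desc(missing_in_full) else "none")
  }
  f <- dplyr::select(full, dplyr::all_of(key),
                     favored_full = "favored",
                     significant_full = "significant",
                     p_full = "p.corrected")
  r <- dplyr::select(reduced, dplyr::all_of(key),
                     favored_reduced = "favored",
                     significant_reduced = "significant",
                     p_reduced = "p.corrected")
  out <- dplyr::inner_join(f, r, by = key)
  out$direction_flip <- out$favored_full != out$favored_reduced &
    (out$significant_full | out$significant_reduced)
  out$significance_change <- out$significant_full != out$significant_reduced
  out
}

#' Plain-text summary of a directionality table
#'
#' @param x A [directionality_anova()] tibble.
#' @param ... Unused.
#' @return The input, invisibly; prints a compact per-pair summary.
#' @export
summarize_directionality <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %-10s %s  F(%d,%d) = %.2f, p_corr = %.3g %s\n",
                paste0(x$region_a[i], "-", x$region_b[i]), x$band[i],
                x$direction_label[i], x$df1[i], x$df2[i],
                x$statistic[i], x$p.corrected[i], x$stars[i]))
  }
  invisible(x)
}

#' Bar chart of directionality F statistics
#'
#' @param object A [directionality_anova()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_directionality <- function(object, ...) {
  object$pair <- paste0(object$region_a, "-", object$region_b)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pair, y = .data$statistic,
                               fill = .data$favored)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       vjust = -0.3, size = 5) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "region pair", y = "F statistic",
                  fill = "favored direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
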