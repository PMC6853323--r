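#' Assemble per-cell records for cohort statistics
#'
#' Joins the per-track feature table with local pore sizes looked up at
#' each cell's first recorded position.
#'
#' @param features per-track feature table from [track_features()].
#' @param table the underlying [track_table()].
#' @param pore_map optional `pore_map`; when given, a
#'   `local_pore_size_um` column is added via [local_pore_size_at()].
#' @return data.frame of cell records.
#' @export
cell_records <- function(features, table = NULL, pore_map = NULL) {
  out <- features
  if (!is.null(pore_map)) {
    m3d_assert(!is.null(table), "migr3d_validation_error",
               "a track table is required to look up pore sizes")
    tracks <- split_tracks(table)
    out$local_pore_size_um <- vapply(out$track_id, function(id) {
      local_pore_size_at(pore_map, tracks[[id]]$pos[1, ])
    }, numeric(1))
  }
  out
}

#' Pooled percentile threshold
#'
#' The q-quantile of all values pooled across conditions, the
#' convention used to define "fast" and "high-displacement" cells
#' (value higher than 75% of all cells, independent of pore size).
#' Quantiles use linear interpolation between order statistics
#' (`h = (n - 1) q + 1`).
#'
#' @param values numeric vector.
#' @param q percentile in (0, 1), default 0.75.
#' @return scalar threshold.
#' @export
percentile_threshold <- function(values, q = 0.75) {
  values <- values[is.finite(values)]
  m3d_assert(length(values) > 0, "migr3d_degenerate_input",
             "no values to take a percentile of")
  m3d_assert(q > 0 && q < 1, "migr3d_validation_error",
             "percentile must lie in (0, 1)")
  unname(quantile(values, q, type = 7))
}

#' Fractions of cells satisfying a predicate, binned by pore size
#'
#' Bins cells by local pore size into left-closed right-open intervals
#' `[0, w), [w, 2w), ...` anchored at 0 and reports the per-bin
#' fraction of cells satisfying the predicate (e.g. speed above the
#' pooled 75th-percentile threshold, or an amoeboid phenotype label).
#' Empty bins are reported with `n = 0` and fraction `NA`, not 0.
#'
#' @param records cell records with a `local_pore_size_um` column.
#' @param predicate logical vector, one per record (TRUE = "success").
#' @param bin_width_um bin width (default 4).
#' @return data.frame of class `binned_fractions`: `bin_lo_um`,
#'   `bin_hi_um`, `n`, `k`, `fraction`.
#' @export
binned_fractions <- function(records, predicate, bin_width_um = 4) {
  m3d_assert(bin_width_um > 0, "migr3d_validation_error",
             "bin width must be > 0")
  ps <- records$local_pore_size_um
  m3d_assert(!is.null(ps) && any(is.finite(ps)), "migr3d_validation_error",
             "records carry no local pore sizes")
  keep <- is.finite(ps)
  ps <- ps[keep]
  predicate <- predicate[keep]
  n_bins <- floor(max(ps) / bin_width_um) + 1L
  idx <- pmin(floor(ps / bin_width_um) + 1L, n_bins)
  n <- tabulate(idx, n_bins)
  k <- tabulate(idx[predicate], n_bins)
  out <- data.frame(
    bin_lo_um = (seq_len(n_bins) - 1L) * bin_width_um,
    bin_hi_um = seq_len(n_bins) * bin_width_um,
    n = n, k = k,
    fraction = ifelse(n > 0, k / n, NA_real_))
  structure(out, class = c("binned_fractions", "data.frame"))
}

#' Exact test for equality of two binned fractions
#'
#' Compares the success fractions `k1/n1` and `k2/n2` of two pore-size
#' bins.  The default is the exact conditional two-proportion test:
#' conditioning on the total number of successes, the first bin's count
#' follows a hypergeometric law under the null, and the two-sided
#' p-value sums all tables (with the observed margins) whose
#' probability does not exceed that of the observed one
#' (minimum-likelihood method).  A one-sample reading — each bin's
#' count tested against the pooled fraction with an exact binomial test,
#' p-values combined by their minimum — is available via `method`.
#'
#' @param k1,n1 successes and totals in bin 1.
#' @param k2,n2 successes and totals in bin 2.
#' @param method `"exact_conditional"` (default) or
#'   `"binomial_vs_pooled"`.
#' @return list of class `group_test`: `test`, `statistic` (observed
#'   difference of fractions), `p_value`, plus the inputs.
#' @export
binomial_fraction_test <- function(k1, n1, k2, n2,
                                   method = c("exact_conditional",
                                              "binomial_vs_pooled")) {
  method <- match.arg(method)
  m3d_assert(n1 >= 1 && n2 >= 1, "migr3d_degenerate_input",
             "both bins need at least one cell")
  m3d_assert(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
             "migr3d_validation_error", "need 0 <= k <= n in each bin")
  if (method == "exact_conditional") {
    k <- k1 + k2
    x <- max(0, k - n2):min(k, n1)
    pr <- dhyper(x, n1, n2, k)
    p <- sum(pr[pr <= dhyper(k1, n1, n2, k) * (1 + 1e-7)])
    p <- min(p, 1)
  } else {
    pooled <- (k1 + k2) / (n1 + n2)
    p <- min(binom.test(k1, n1, pooled)$p.value,
             binom.test(k2, n2, pooled)$p.value)
  }
  structure(list(test = paste0("two-proportion ", method),
                 statistic = k1 / n1 - k2 / n2, p_value = p,
                 k1 = k1, n1 = n1, k2 = k2, n2 = n2),
            class = "group_test")
}

#' Pairwise fraction tests across pore-size bins
#'
#' @param bf a `binned_fractions` table.
#' @param min_n smallest bin size entering the comparisons.
#' @return data.frame of pairwise bin comparisons with p-values.
#' @export
binned_fraction_tests <- function(bf, min_n = 1L) {
  use <- which(bf$n >= min_n)
  if (length(use) < 2) {
    return(data.frame(bin_a = integer(0), bin_b = integer(0),
                      p_value = numeric(0)))
  }
  pairs <- utils::combn(use, 2)
  data.frame(
    bin_a = pairs[1, ], bin_b = pairs[2, ],
    p_value = apply(pairs, 2, function(ij) {
      binomial_fraction_test(bf$k[ij[1]], bf$n[ij[1]],
                             bf$k[ij[2]], bf$n[ij[2]])$p_value
    }))
}

#' Normality-gated comparison of feature distributions between groups
#'
#' Mirrors the reported test-routing convention: each group is first
#' checked for normality with a Shapiro-Wilk test (gate level 0.05); if
#' every group passes and there are exactly two groups, a two-sample
#' (Welch) t-test is used, otherwise a Mann-Whitney test for two groups
#' or a Kruskal-Wallis test for more than two.  The full routing trail
#' (per-group normality p-values and every gate outcome) is returned.
#'
#' @param groups named list of numeric samples, each with >= 3
#'   observations.
#' @param gate_level Shapiro-Wilk gate level (default 0.05).
#' @return list of class `group_test`: `test`, `statistic`, `p_value`,
#'   `normality_p`, `routing` (character trail).
#' @export
gated_group_test <- function(groups, gate_level = 0.05) {
  m3d_assert(length(groups) >= 2, "migr3d_validation_error",
             "need at least 2 groups")
  for (g in groups) {
    m3d_assert(length(g) >= 3, "migr3d_length_error",
               "every group needs at least 3 observations")
  }
  norm_p <- vapply(groups, function(g) {
    shapiro.test(if (length(g) > 5000) g[seq_len(5000)] else g)$p.value
  }, numeric(1))
  all_normal <- all(norm_p > gate_level)
  routing <- sprintf("shapiro[%s]=%.3g (%s)",
                     names(groups) %||% seq_along(groups), norm_p,
                     ifelse(norm_p > gate_level, "pass", "reject"))
  if (length(groups) == 2 && all_normal) {
    ht <- t.test(groups[[1]], groups[[2]])
    test <- "two-sample t (Welch)"
  } else if (length(groups) == 2) {
    ht <- wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
    test <- "Mann-Whitney"
  } else {
    ht <- kruskal.test(groups)
    test <- "Kruskal-Wallis"
  }
  routing <- c(routing,
               sprintf("all groups normal: %s -> %s", all_normal, test))
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normality_p = norm_p,
                 routing = routing),
            class = "group_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-number boxplot summary
#'
#' The reporting convention for distribution plots: mean, median, box
#' from the 25th and 75th percentiles, whiskers at the 5th and 95th
#' percentiles, and outliers beyond the whiskers.  Quantiles use linear
#' interpolation between order statistics.
#'
#' @param values numeric vector with at least one value.
#' @return list of class `boxplot_summary` with `mean`, `median`,
#'   `q25`, `q75`, `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  m3d_assert(length(values) > 0, "migr3d_degenerate_input", "no values")
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                names = FALSE)
  structure(list(mean = mean(values), median = q[3], q25 = q[2], q75 = q[4],
                 whisker_lo = q[1], whisker_hi = q[5],
                 outliers = values[values < q[1] | values > q[5]]),
            class = "boxplot_summary")
}

#' Normalized turning-angle histogram
#'
#' Fractions of turning angles per bin over `[0, 180]` degrees (last
#' bin right-closed), summing to one — the form in which backtracking
#' excesses of confined cells are compared between conditions.
#'
#' @param angles_deg angles in degrees, each in `[0, 180]`.
#' @param bin_width_deg bin width (default 20).
#' @return data.frame `bin_lo_deg`, `bin_hi_deg`, `count`, `fraction`.
#' @export
angle_histogram <- function(angles_deg, bin_width_deg = 20) {
  m3d_assert(length(angles_deg) > 0, "migr3d_validation_error",
             "no angles to histogram")
  m3d_assert(all(angles_deg >= 0 & angles_deg <= 180),
             "migr3d_validation_error", "angles must lie in [0, 180]")
  n_bins <- ceiling(180 / bin_width_deg)
  idx <- pmin(floor(angles_deg / bin_width_deg) + 1L, n_bins)
  count <- tabulate(idx, n_bins)
  data.frame(bin_lo_deg = (seq_len(n_bins) - 1L) * bin_width_deg,
             bin_hi_deg = pmin(seq_len(n_bins) * bin_width_deg, 180),
             count = count, fraction = count / sum(count))
}
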