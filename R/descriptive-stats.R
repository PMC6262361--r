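# Data-level analyses independent of the ODE model.

#' Monte-Carlo integral expression
#'
#' For each (gene, condition) series, repeatedly samples an expression
#' value at every knot from `N(mean, sd)` (truncated at zero by default:
#' concentrations are non-negative), interpolates the sampled values
#' linearly across time, integrates by the trapezoid rule over the observed
#' span, and reports the mean and s.d. of the replicate integrals.  This is
#' the integral-expression statistic used to compare overall expression
#' between photoperiod conditions.
#'
#' @param data An expression tibble.
#' @param genes,conditions Subsets to analyse (default: everything).
#' @param n_samples Number of Monte-Carlo replicates (default 100).
#' @param seed RNG seed (results are reproducible bit-for-bit).
#' @param allow_negative_draws Keep raw Gaussian draws instead of
#'   truncating at zero.
#' @return Tibble with `gene`, `condition`, `mean_integral`,
#'   `sd_integral`, `n_replicates`.
#' @export
integral_expression <- function(data, genes = NULL, conditions = NULL,
                                n_samples = 100, seed = 1,
                                allow_negative_draws = FALSE) {
  genes <- genes %||% unique(data$gene)
  conditions <- conditions %||% unique(data$condition)
  sub <- data[data$gene %in% genes & data$condition %in% conditions, ]
  set.seed(seed)
  sub |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::group_modify(function(s, key) {
      if (nrow(s) < 2) {
        abort(paste0("integral expression needs >= 2 time points (",
                     key$gene, "/", key$condition, ")"),
              class = "flornet_validation_error")
      }
      s <- s[order(s$time), ]
      ints <- vapply(seq_len(n_samples), function(r) {
        y <- rnorm(nrow(s), s$mean, s$sd)
        if (!allow_negative_draws) y <- pmax(y, 0)
        trapezoid(s$time, y)
      }, numeric(1))
      tibble::tibble(mean_integral = mean(ints), sd_integral = sd(ints),
                     n_replicates = n_samples)
    }) |>
    dplyr::ungroup()
}

trapezoid <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Averaged autocorrelation profile
#'
#' Computes the sample autocorrelation function of each (gene, condition)
#' expression series (biased estimator, lag-0 normalised) and averages the
#' per-lag values over the requested series.  Irregularly spaced series
#' are first interpolated to a regular grid at the median spacing; lags
#' are reported in days.
#'
#' @param data An expression tibble.
#' @param genes Genes to pool (e.g. the FT homologs).
#' @param conditions Conditions to pool.
#' @param max_lag Maximum lag in grid steps.
#' @return Tibble with `lag` (days), `lag_index` and `acf` (averaged).
#' @export
acf_profile <- function(data, genes = ft_genes(),
                        conditions = photoperiod_conditions(),
                        max_lag = NULL) {
  sub <- data[data$gene %in% genes & data$condition %in% conditions, ]
  if (nrow(sub) == 0) {
    abort("no series selected", class = "flornet_lookup_error")
  }
  series <- split(sub, paste(sub$gene, sub$condition))
  lens <- vapply(series, nrow, integer(1))
  max_lag <- max_lag %||% (min(lens) - 1L)
  if (max_lag >= min(lens)) {
    abort(paste0("max_lag (", max_lag, ") must be smaller than the ",
                 "shortest series length (", min(lens), ")"),
          class = "flornet_validation_error")
  }
  per_series <- lapply(series, function(s) {
    s <- s[order(s$time), ]
    dt <- median(diff(s$time))
    tt <- seq(min(s$time), max(s$time), by = dt)
    y <- approx(s$time, s$mean, xout = tt)$y
    a <- acf(y, lag.max = max_lag, plot = FALSE, demean = TRUE)
    list(acf = as.numeric(a$acf), dt = dt)
  })
  dt <- median(vapply(per_series, `[[`, numeric(1), "dt"))
  acfs <- vapply(per_series, function(x) x$acf[seq_len(max_lag + 1)],
                 numeric(max_lag + 1))
  tibble::tibble(lag_index = 0:max_lag, lag = (0:max_lag) * dt,
                 acf = rowMeans(acfs), n_series = length(per_series))
}

#' Cross-gene correlation table
#'
#' Pearson correlation between the mean-expression time courses of gene
#' pairs, per condition, with the test p-value.  Mutually repressing pairs
#' (TFL1 homologs versus the meristem-identity genes) are expected to show
#' negative correlations when the repression is active.
#'
#' @param data An expression tibble.
#' @param pairs A list of 2-vectors, e.g.
#'   `list(c("TFL1a", "LFY"), c("TFL1c", "AP1"))`.
#' @param conditions Conditions to analyse.
#' @param alternative Sidedness passed to [stats::cor.test()].
#' @return Tibble with `gene_a`, `gene_b`, `condition`, `n`, `r`,
#'   `p_value`.
#' @export
correlation_table <- function(data,
                              pairs = list(c("TFL1a", "LFY"), c("TFL1a", "AP1"),
                                           c("TFL1c", "LFY"), c("TFL1c", "AP1")),
                              conditions = photoperiod_conditions(),
                              alternative = "two.sided") {
  purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(conditions, function(cond) {
      a <- data[data$gene == pr[1] & data$condition == cond, ]
      b <- data[data$gene == pr[2] & data$condition == cond, ]
      shared <- intersect(round(a$time, 9), round(b$time, 9))
      if (length(shared) < 3) {
        abort(paste0("fewer than 3 shared time points for ", pr[1], " vs ",
                     pr[2], " (", cond, ")"),
              class = "flornet_validation_error")
      }
      x <- a$mean[match(shared, round(a$time, 9))]
      y <- b$mean[match(shared, round(b$time, 9))]
      if (sd(x) == 0 || sd(y) == 0) {
        abort(paste0("constant series in pair ", pr[1], " vs ", pr[2]),
              class = "flornet_validation_error")
      }
      ht <- cor.test(x, y, method = "pearson", alternative = alternative)
      tibble::tibble(gene_a = pr[1], gene_b = pr[2], condition = cond,
                     n = length(shared), r = unname(ht$estimate),
                     p_value = ht$p.value)
    })
  })
}
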