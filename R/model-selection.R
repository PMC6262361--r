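# Hypothesis comparison: AICc on the ensemble-minimum cost plus rank-based
# comparison of the ensemble cost distributions.

#' Corrected Akaike information criterion from a minimal wRSS
#'
#' `AICc = 2k - 2 log L + 2k(k+1)/(m - k - 1)` with the convention
#' `2 log L = -wRSS_min`, i.e.
#' `AICc = 2k + wRSS_min + (2k^2 + 2k)/(m - k - 1)`.
#' The correction term diverges as k approaches m - 1, which is why
#' single-condition fits (m = 35) cannot be compared for the 37-parameter
#' hypothesis.
#'
#' @param k Number of free parameters.
#' @param m Number of data points used in the fit.
#' @param wrss_min Minimal weighted residual sum of squares over the
#'   ensemble.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(31, 70, 100) # 162 + 1984/38
aicc <- function(k, m, wrss_min) {
  if (m <= k + 1) {
    abort(paste0("AICc undefined: m = ", m, " <= k + 1 = ", k + 1,
                 " (small-sample correction diverges)"),
          class = "flornet_domain_error")
  }
  2 * k + wrss_min + (2 * k^2 + 2 * k) / (m - k - 1)
}

#' AICc with the classical Gaussian least-squares likelihood
#'
#' Uses `-2 log L = m * log(wRSS_min / m)` (up to an additive constant
#' common to all models on the same data), with the same small-sample
#' correction as [aicc()].
#'
#' @inheritParams aicc
#' @return The AICc value (comparable across models fit to the same data).
#' @export
aicc_classical <- function(k, m, wrss_min) {
  if (m <= k + 1) {
    abort(paste0("AICc undefined: m = ", m, " <= k + 1 = ", k + 1,
                 " (small-sample correction diverges)"),
          class = "flornet_domain_error")
  }
  2 * k + m * log(wrss_min / m) + (2 * k^2 + 2 * k) / (m - k - 1)
}

#' Compare two ensembles' cost distributions
#'
#' Two-sample comparison of the fit costs of two ensembles; the default is
#' the two-sided Mann–Whitney (Wilcoxon rank-sum) test, which is invariant
#' under monotone transformations of the cost.
#'
#' @param ensemble_a,ensemble_b `grn_ensemble` objects (or bare numeric
#'   cost vectors).
#' @param test `"mann-whitney"` or `"welch"`.
#' @return A tibble with `p_value`, `direction`
#'   (`"a < b"`, `"b < a"` or `"none"`), and the two median costs.
#' @export
compare_costs <- function(ensemble_a, ensemble_b,
                          test = c("mann-whitney", "welch")) {
  test <- match.arg(test)
  costs_of <- function(x) if (is.numeric(x)) x else ensemble_costs(x)
  a <- costs_of(ensemble_a)
  b <- costs_of(ensemble_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("cost comparison needs at least 2 members per ensemble",
          class = "flornet_insufficient_data_error")
  }
  ht <- if (test == "mann-whitney") {
    suppressWarnings(wilcox.test(a, b, exact = TRUE))
  } else {
    t.test(a, b)
  }
  med_a <- median(a)
  med_b <- median(b)
  direction <- if (isTRUE(all.equal(med_a, med_b))) "none" else
    if (med_a < med_b) "a < b" else "b < a"
  tibble::tibble(test = test, p_value = ht$p.value, direction = direction,
                 median_a = med_a, median_b = med_b)
}

#' Screen the FT-activation hypotheses
#'
#' Fits the baseline cumulative-activation model H0 and the requested
#' single-FT (H1) and singled-out-FT (H2) versions to the same dataset,
#' then tabulates per-hypothesis cost distributions, per-condition cost
#' breakdowns, AICc from the ensemble-minimum cost, AICc relative to H0
#' (ratio, as well as the difference), and rank-test p-values of each
#' alternative against H0.  FTa3 is excluded from the screened candidates
#' by default because of its very low expression.
#'
#' @param data An expression tibble.
#' @param config A [fit_config()]; `n_restarts` controls the per-hypothesis
#'   ensemble size.
#' @param candidates FT genes screened as singled-out/single activators.
#' @param hypotheses Which hypothesis families to include.
#' @param ft_genes FT drivers available to the models.
#' @param aicc_variant `"wrss"` (default) or `"classical"`.
#' @return An object of class `grn_screen`: a tibble with one row per
#'   fitted model and an `ensembles` attribute holding the fit ensembles.
#' @export
run_hypothesis_screen <- function(data, config = fit_config(),
                                  candidates = setdiff(intersect(ft_genes(),
                                                                 unique(data$gene)),
                                                       "FTa3"),
                                  hypotheses = c("H0", "H1", "H2"),
                                  ft_genes = intersect(flornet::ft_genes(),
                                                       unique(data$gene)),
                                  aicc_variant = c("wrss", "classical")) {
  aicc_variant <- match.arg(aicc_variant)
  aicc_fun <- if (aicc_variant == "wrss") aicc else aicc_classical
  specs <- list()
  if ("H0" %in% hypotheses) {
    specs[["H0"]] <- model_spec("H0", ft_genes = ft_genes)
  }
  for (hy in intersect(c("H1", "H2"), hypotheses)) {
    for (g in candidates) {
      specs[[paste(hy, g, sep = "-")]] <- model_spec(hy, singled_ft = g,
                                                     ft_genes = ft_genes)
    }
  }
  m <- n_data_points(data, config$conditions)
  ensembles <- lapply(specs, function(sp) fit_ensemble(data, sp, config))
  h0_costs <- if ("H0" %in% names(ensembles))
    ensemble_costs(ensembles[["H0"]]) else NULL
  rows <- purrr::map_dfr(names(specs), function(nm) {
    sp <- specs[[nm]]
    ens <- ensembles[[nm]]
    costs <- ensemble_costs(ens)
    k <- count_free_parameters(sp)
    by_cond <- purrr::map_dfr(ens$fits, function(f)
      tibble::as_tibble(as.list(f$cost_by_condition)))
    p_vs_h0 <- if (!is.null(h0_costs) && nm != "H0" && length(costs) >= 2 &&
                   length(h0_costs) >= 2) {
      compare_costs(costs, h0_costs)$p_value
    } else NA_real_
    out <- tibble::tibble(
      model = nm, hypothesis = sp$hypothesis,
      singled_ft = sp$singled_ft %||% NA_character_,
      k = k, m = m, n_members = length(costs),
      wrss_min = min(costs), wrss_median = median(costs),
      aicc = aicc_fun(k, m, min(costs)),
      p_vs_H0 = p_vs_h0,
      costs = list(costs))
    for (cond in names(by_cond)) {
      out[[paste0("wrss_min_", cond)]] <- min(by_cond[[cond]])
      out[[paste0("wrss_median_", cond)]] <- median(by_cond[[cond]])
    }
    out
  })
  if ("H0" %in% rows$model) {
    a0 <- rows$aicc[rows$model == "H0"]
    rows$aicc_rel <- rows$aicc / a0
    rows$delta_aicc <- rows$aicc - a0
  }
  structure(rows, class = c("grn_screen", class(rows)),
            ensembles = ensembles, aicc_variant = aicc_variant)
}

#' @export
print.grn_screen <- function(x, ...) {
  cat("<grn_screen>", nrow(x), "models | AICc variant:",
      attr(x, "aicc_variant"), "\n")
  print(tibble::as_tibble(x)[c("model", "k", "m", "wrss_min", "aicc",
                               "aicc_rel", "p_vs_H0")])
  invisible(x)
}

#' Export a screen report
#'
#' Writes the comparison table as JSON plus a small markdown table.
#'
#' @param screen A `grn_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tibble::as_tibble(screen)
  tab$costs <- NULL
  jsonlite::write_json(tab, file.path(dir, "screen.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("| model | k | m | wRSS_min | AICc | AICc/AICc(H0) | p vs H0 |",
          "|---|---|---|---|---|---|---|",
          sprintf("| %s | %d | %d | %.4g | %.4g | %.3g | %.3g |",
                  tab$model, tab$k, tab$m, tab$wrss_min, tab$aicc,
                  if (!is.null(tab$aicc_rel)) tab$aicc_rel else NA,
                  tab$p_vs_H0))
  writeLines(md, file.path(dir, "screen.md"))
  invisible(dir)
}
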