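# Post-fit diagnostics over a fit ensemble: time-averaged regulation
# functions (saturation detection), analytic Jacobian sensitivities, and
# the main/outlying parameter clustering.

# Registry of regulation edges for a hypothesis.  Each edge carries the
# dimensionless Hill factor (activator or repressor), the parameter names
# behind it, the regulator it reads, and the repression gate multiplying
# activating inputs to LFY/AP1 (needed for sensitivities).
grn_edges <- function(spec) {
  h2 <- spec$hypothesis == "H2"
  base <- tibble::tribble(
    ~edge, ~target, ~type, ~K, ~n, ~v, ~regulator, ~gate_K, ~gate_n,
    "AP1 -| TFL1a", "TFL1a", "rep", "K1", "n1", "v1", "AP1", NA, NA,
    "AP1 -| TFL1c", "TFL1c", "rep", "K2", "n2", "v2", "AP1", NA, NA,
    "LFY -> FD", "FD", "act", "K3", "n3", "v3", "LFY", NA, NA,
    "AP1 -> LFY", "LFY", "act", "K4", "n4", "v4", "AP1", "K5", "n5",
    "TFL1-FD -| LFY", "LFY", "rep", "K5", "n5", NA, "cplx", NA, NA,
    "LFY -> AP1", "AP1", "act", "K6", "n6", "v5", "LFY", "K7", "n7",
    "TFL1-FD -| AP1", "AP1", "rep", "K7", "n7", NA, "cplx", NA, NA,
    "FT-FD -> LFY", "LFY", "act", "K8", "n8", "v6", "ftbulk", "K5", "n5")
  if (!h2) {
    rbind(base, tibble::tribble(
      ~edge, ~target, ~type, ~K, ~n, ~v, ~regulator, ~gate_K, ~gate_n,
      "FT-FD -> AP1", "AP1", "act", "K9", "n9", "v7", "ftbulk", "K7", "n7"))
  } else {
    sg <- spec$singled_ft
    rbind(base, tibble::tribble(
      ~edge, ~target, ~type, ~K, ~n, ~v, ~regulator, ~gate_K, ~gate_n,
      paste0(sg, "-FD -> LFY"), "LFY", "act", "K9", "n9", "v7", "ftsingled", "K5", "n5",
      "FT-FD -> AP1", "AP1", "act", "K10", "n10", "v8", "ftbulk", "K7", "n7",
      paste0(sg, "-FD -> AP1"), "AP1", "act", "K11", "n11", "v9", "ftsingled", "K7", "n7"))
  }
}

edge_regulator_value <- function(regulator, spec, params, traces, t) {
  switch(regulator,
         AP1 = trace_eval(traces, "AP1", t),
         LFY = trace_eval(traces, "LFY", t),
         cplx = trace_eval(traces, "FD", t) *
           (trace_eval(traces, "TFL1a", t) + trace_eval(traces, "TFL1c", t)),
         ftbulk = ft_fd_products(spec, traces, t, params[["tau"]])$bulk,
         ftsingled = {
           p <- ft_fd_products(spec, traces, t, params[["tau"]])
           p$singled %||% abort("singled FT product undefined for this spec",
                                class = "flornet_lookup_error")
         },
         abort(paste0("unknown regulator ", regulator),
               class = "flornet_lookup_error"))
}

default_window <- function(traces) {
  starts <- vapply(traces$knots, function(k) {
    tp <- k$time[k$time > 0]
    if (length(tp) == 0) 0 else tp[1]
  }, numeric(1))
  c(min(starts), traces$t_end)
}

#' Time-averaged regulation functions over an ensemble
#'
#' For every regulation edge of the model, computes the time average
#' `(1/T) * integral of h(t) dt` of the dimensionless Hill factor
#' (activator factors are averaged without their v prefactor so all edges
#' share the `[0, 1]` scale), per ensemble member, averaged over the
#' supplied conditions.  An edge whose ensemble-median average falls below
#' `thresholds[1]` or above `thresholds[2]` is flagged as saturated: the
#' target is then insensitive to that regulator and the edge's parameters
#' are not identifiable from the data.
#'
#' @param ensemble A `grn_ensemble` (or single `grn_fit`).
#' @param traces_by_condition Named list of `regulator_traces`, one per
#'   condition.
#' @param t_window Averaging window `c(t0, t1)`; defaults to the observed
#'   data span of each condition.
#' @param n_grid Quadrature grid size (trapezoid rule).
#' @param thresholds Saturation thresholds, default `c(0.05, 0.95)`.
#' @return A tibble of class `regulation_summary` with columns `member`,
#'   `edge`, `value`.
#' @export
average_regulation_functions <- function(ensemble, traces_by_condition,
                                         t_window = NULL, n_grid = 201,
                                         thresholds = c(0.05, 0.95)) {
  if (inherits(ensemble, "grn_fit")) ensemble <- as_param_ensemble(
    list(ensemble$params), ensemble$spec)
  if (length(ensemble$fits) == 0) {
    abort("empty ensemble", class = "flornet_insufficient_data_error")
  }
  spec <- ensemble$spec
  edges <- grn_edges(spec)
  rows <- purrr::map_dfr(seq_along(ensemble$fits), function(i) {
    params <- ensemble$fits[[i]]$params
    per_cond <- purrr::map(traces_by_condition, function(tr) {
      w <- t_window %||% default_window(tr)
      tt <- seq(w[1], w[2], length.out = n_grid)
      vapply(seq_len(nrow(edges)), function(j) {
        e <- edges[j, ]
        x <- edge_regulator_value(e$regulator, spec, params, tr, tt)
        hv <- if (e$type == "act") hill_act(x, params[[e$K]], params[[e$n]])
              else hill_rep(x, params[[e$K]], params[[e$n]])
        mean_trapezoid(tt, hv)
      }, numeric(1))
    })
    tibble::tibble(member = i, edge = edges$edge,
                   value = Reduce(`+`, per_cond) / length(per_cond))
  })
  structure(rows, class = c("regulation_summary", class(rows)),
            thresholds = thresholds, spec = spec)
}

mean_trapezoid <- function(t, y) {
  if (length(t) < 2) return(y[1])
  dt <- diff(t)
  sum(dt * (head(y, -1) + tail(y, -1)) / 2) / (t[length(t)] - t[1])
}

#' Saturation summary of a regulation summary
#'
#' @param rs A `regulation_summary` from
#'   [average_regulation_functions()].
#' @return Tibble with per-edge `median`, `mean`, `sd` and the
#'   `saturated` flag.
#' @export
regulation_saturation <- function(rs) {
  th <- attr(rs, "thresholds") %||% c(0.05, 0.95)
  rs |>
    dplyr::group_by(.data$edge) |>
    dplyr::summarise(median = median(.data$value), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(saturated = .data$median < th[1] | .data$median > th[2])
}

#' Time-averaged Jacobian sensitivity of a regulation edge
#'
#' Time average of `|d(RHS_target)/d(u_regulator)|`, computed analytically
#' from the Hill forms with regulator values taken from the data traces.
#' Complex regulators (FT-FD, TFL1-FD) are differentiated with respect to
#' the complex concentration.  A saturated edge can show a near-zero
#' averaged regulation function while the Jacobian still reports whether
#' the target would respond to perturbations of the regulator.
#'
#' @inheritParams average_regulation_functions
#' @param edge Edge label as in [average_regulation_functions()] output.
#' @return Tibble with `member` and `sensitivity` columns.
#' @export
jacobian_sensitivity <- function(ensemble, traces_by_condition, edge,
                                 t_window = NULL, n_grid = 201) {
  if (inherits(ensemble, "grn_fit")) ensemble <- as_param_ensemble(
    list(ensemble$params), ensemble$spec)
  spec <- ensemble$spec
  edges <- grn_edges(spec)
  if (!edge %in% edges$edge) {
    abort(paste0("unknown edge: ", edge, " (known: ",
                 paste(edges$edge, collapse = "; "), ")"),
          class = "flornet_lookup_error")
  }
  e <- edges[edges$edge == edge, ]
  purrr::map_dfr(seq_along(ensemble$fits), function(i) {
    params <- ensemble$fits[[i]]$params
    vals <- purrr::map_dbl(traces_by_condition, function(tr) {
      w <- t_window %||% default_window(tr)
      tt <- seq(w[1], w[2], length.out = n_grid)
      x <- edge_regulator_value(e$regulator, spec, params, tr, tt)
      jac <- if (e$type == "act") {
        gate <- if (!is.na(e$gate_K)) {
          cplx <- edge_regulator_value("cplx", spec, params, tr, tt)
          hill_rep(cplx, params[[e$gate_K]], params[[e$gate_n]])
        } else 1
        params[[e$v]] * hill_act_deriv(x, params[[e$K]], params[[e$n]]) * gate
      } else if (is.na(e$v)) {
        # repression gate on LFY/AP1: prefactor is the summed activation
        target <- e$target
        act_in <- if (target == "LFY") {
          params[["v4"]] * hill_act(trace_eval(tr, "AP1", tt),
                                    params[["K4"]], params[["n4"]]) +
            ft_input(spec, params, tr, tt, "LFY")
        } else {
          params[["v5"]] * hill_act(trace_eval(tr, "LFY", tt),
                                    params[["K6"]], params[["n6"]]) +
            ft_input(spec, params, tr, tt, "AP1")
        }
        act_in * abs(hill_rep_deriv(x, params[[e$K]], params[[e$n]]))
      } else {
        params[[e$v]] * abs(hill_rep_deriv(x, params[[e$K]], params[[e$n]]))
      }
      mean_trapezoid(tt, abs(jac))
    })
    tibble::tibble(member = i, edge = edge, sensitivity = mean(vals))
  })
}

#' Cluster ensemble members into main and outlying clusters
#'
#' Members are partitioned per parameter by the boxplot convention applied
#' to the time-averaged regulation function of the parameter's edge:
#' members beyond 1.5 IQR of the quartiles on that axis form the
#' "outlying" cluster, the rest the "main" cluster.  When exactly two
#' parameters are requested their main-cluster values are compared
#' (Welch's t-test by default).
#'
#' @inheritParams average_regulation_functions
#' @param parameters Parameter names to report, e.g. `c("K1", "K2")`.
#' @param test `"welch"` or `"mann-whitney"` for the two-parameter
#'   comparison.
#' @return A list of class `parameter_clusters` with elements
#'   `assignments` (member, parameter, cluster, regulation value),
#'   `summary` (per parameter and cluster: n, mean, sd) and `comparison`
#'   (tibble, only for exactly two parameters).
#' @export
cluster_parameters <- function(ensemble, traces_by_condition,
                               parameters = c("K1", "K2"),
                               test = c("welch", "mann-whitney"),
                               t_window = NULL, n_grid = 201) {
  test <- match.arg(test)
  if (length(ensemble$fits) < 5) {
    abort("clustering needs an ensemble of at least 5 members",
          class = "flornet_insufficient_data_error")
  }
  spec <- ensemble$spec
  edges <- grn_edges(spec)
  edge_of <- vapply(parameters, function(p) {
    hit <- edges$edge[edges$K == p | edges$n == p |
                        (!is.na(edges$v) & edges$v == p)]
    if (length(hit) == 0) {
      abort(paste0("parameter ", p, " is not tied to a regulation edge"),
            class = "flornet_lookup_error")
    }
    hit[1]
  }, character(1))
  rs <- average_regulation_functions(ensemble, traces_by_condition,
                                     t_window = t_window, n_grid = n_grid)
  est <- tidy(ensemble)
  assignments <- purrr::map_dfr(parameters, function(p) {
    vals <- rs$value[rs$edge == edge_of[[p]]]
    members <- rs$member[rs$edge == edge_of[[p]]]
    out_vals <- grDevices::boxplot.stats(vals)$out
    cluster <- ifelse(vals %in% out_vals, "outlying", "main")
    tibble::tibble(member = members, parameter = p, cluster = cluster,
                   regulation_value = vals,
                   estimate = est$estimate[match(paste(members, p),
                                                 paste(est$member, est$term))])
  })
  summary <- assignments |>
    dplyr::group_by(.data$parameter, .data$cluster) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$estimate),
                     sd = sd(.data$estimate), .groups = "drop")
  comparison <- NULL
  if (length(parameters) == 2) {
    a <- assignments$estimate[assignments$parameter == parameters[1] &
                                assignments$cluster == "main"]
    b <- assignments$estimate[assignments$parameter == parameters[2] &
                                assignments$cluster == "main"]
    if (length(a) >= 2 && length(b) >= 2) {
      p <- tryCatch({
        ht <- if (test == "welch") t.test(a, b) else
          suppressWarnings(wilcox.test(a, b))
        ht$p.value
      }, error = function(e) NA_real_) # e.g. zero-variance clusters
      comparison <- tibble::tibble(
        parameter_a = parameters[1], parameter_b = parameters[2],
        test = test, p_value = p,
        mean_a = mean(a), mean_b = mean(b))
    }
  }
  structure(list(assignments = assignments, summary = summary,
                 comparison = comparison),
            class = "parameter_clusters")
}

#' @export
print.parameter_clusters <- function(x, ...) {
  cat("<parameter_clusters>\n")
  print(x$summary)
  if (!is.null(x$comparison)) {
    cat("main-cluster comparison:\n")
    print(x$comparison)
  }
  invisible(x)
}
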