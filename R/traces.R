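# Continuous regulator traces.
#
# The model equations are data-driven: every regulator concentration on a
# right-hand side is an interpolant of the observed expression means, not a
# solved state.  Traces are piecewise linear by default (exact at knots,
# non-negative whenever the knots are) with a monotone-cubic option; outside
# the knot span a trace is clamped to its nearest observed value, except for
# genes interpolated back to zero at t = 0 (TFL1a/TFL1c by convention, so
# their zero initial condition is consistent with the trace).

#' Build continuous regulator traces for one condition
#'
#' @param data An expression tibble (see [read_expression_table()]).
#' @param condition Condition label, e.g. `"SD"`.
#' @param genes Genes to build traces for (default: every gene present in
#'   the condition).
#' @param extend_to_zero Genes that get an extra knot (t = 0, value 0)
#'   prepended, so the trace rises from zero concentration at sowing.
#' @param method `"linear"` (default) or `"monotone"`
#'   (Fritsch–Carlson monotone Hermite spline).
#' @return An object of class `regulator_traces`: a list of per-gene
#'   interpolants valid on `[0, t_end]`.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_expression.tsv", package = "flornet")
#' tr <- build_traces(read_expression_table(path), "SD")
#' trace_eval(tr, "AP1", c(8, 10, 12))
build_traces <- function(data, condition,
                         genes = NULL,
                         extend_to_zero = c("TFL1a", "TFL1c"),
                         method = c("linear", "monotone")) {
  method <- match.arg(method)
  sub <- data[data$condition == condition, , drop = FALSE]
  genes <- genes %||% unique(sub$gene)
  missing_genes <- setdiff(genes, unique(sub$gene))
  if (length(missing_genes) > 0) {
    abort(paste0("no series for gene(s) ", paste(missing_genes, collapse = ", "),
                 " in condition ", condition),
          class = "flornet_lookup_error")
  }
  knots <- lapply(stats::setNames(genes, genes), function(g) {
    s <- sub[sub$gene == g, , drop = FALSE]
    s <- s[order(s$time), , drop = FALSE]
    tt <- s$time
    vv <- s$mean
    if (g %in% extend_to_zero && tt[1] > 0) {
      tt <- c(0, tt)
      vv <- c(0, vv)
    }
    list(time = tt, value = vv)
  })
  funs <- lapply(knots, function(k) make_interpolant(k$time, k$value, method))
  structure(
    list(funs = funs, knots = knots,
         condition = condition, method = method,
         t0 = 0, t_end = max(sub$time)),
    class = "regulator_traces"
  )
}

make_interpolant <- function(tt, vv, method) {
  if (length(tt) == 1L) {
    v <- vv[1]
    return(function(t) rep(v, length(t)))
  }
  if (method == "linear") {
    stats::approxfun(tt, vv, rule = 2)
  } else {
    # monoH.FC can still overshoot around sign changes of the slope;
    # concentrations are clamped at zero to keep the trace admissible
    f <- stats::splinefun(tt, vv, method = "monoH.FC")
    t_min <- tt[1]; t_max <- tt[length(tt)]
    function(t) pmax(f(pmin(pmax(t, t_min), t_max)), 0)
  }
}

#' @export
print.regulator_traces <- function(x, ...) {
  cat("<regulator_traces> condition:", x$condition,
      "| genes:", paste(names(x$funs), collapse = ", "),
      "| valid on [0,", x$t_end, "] |", x$method, "interpolation\n")
  invisible(x)
}

#' Evaluate a regulator trace
#'
#' @param traces A `regulator_traces` object.
#' @param gene Gene name.
#' @param t Times (days); values outside the knot span are clamped.
#' @return Numeric vector of concentrations.
#' @export
trace_eval <- function(traces, gene, t) {
  f <- traces$funs[[gene]]
  if (is.null(f)) {
    abort(paste0("no trace for gene ", gene), class = "flornet_lookup_error")
  }
  f(t)
}

#' Evaluate a trace with a transport delay
#'
#' Returns `trace(t - tau)`, with the same clamping convention when the
#' shifted time precedes the first knot.  This implements the delayed FT
#' concentrations entering the meristem-identity activation terms; the delay
#' models transport of FT protein from the leaves to the apical meristem.
#'
#' @inheritParams trace_eval
#' @param tau Non-negative delay in days.
#' @return Numeric vector of concentrations.
#' @export
delayed_value <- function(traces, gene, t, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0) {
    abort("tau must be a single non-negative number",
          class = "flornet_parameter_error")
  }
  trace_eval(traces, gene, t - tau)
}

#' Knots of the pooled (summed) trace of several genes
#'
#' For piecewise-linear traces the sum of several clamped traces is itself
#' piecewise linear on the union of their knot times; this returns those
#' pooled knots, used for the summed-FT driver of the cumulative-activation
#' hypothesis.
#'
#' @inheritParams trace_eval
#' @param genes Genes to sum over.
#' @return A list with `time` and `value` vectors.
#' @export
pooled_trace_knots <- function(traces, genes) {
  stopifnot(length(genes) >= 1)
  tt <- sort(unique(unlist(lapply(traces$knots[genes], `[[`, "time"))))
  vv <- rowSums(vapply(genes, function(g) trace_eval(traces, g, tt),
                       numeric(length(tt))))
  list(time = tt, value = vv)
}
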