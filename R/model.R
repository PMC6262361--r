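# Hypothesis specification, parameter bookkeeping, and the ODE model.
#
# Five target proteins (TFL1a, TFL1c, FD, LFY, AP1) evolve under Hill-type
# synthesis and first-order decay.  Regulator concentrations on the
# right-hand side come from data traces, so each state equation is linear
# in its own state and the system splits into four independent parts:
# TFL1a, TFL1c and FD alone, and LFY+AP1 jointly (they share the FT
# transport delay tau).
#
# Parameter-index map (fixed, so published symbols stay greppable):
#   (v1,K1,n1,lambda1)  AP1 -| TFL1a          (v2,K2,n2,lambda2)  AP1 -| TFL1c
#   (v3,K3,n3,lambda3)  LFY -> FD
#   (v4,K4,n4) AP1 -> LFY   (K5,n5) TFL1-FD -| LFY   lambda4 LFY decay
#   (v5,K6,n6) LFY -> AP1   (K7,n7) TFL1-FD -| AP1   lambda5 AP1 decay
#   (v6,K8,n8) FT-FD -> LFY   (v7,K9,n9) FT-FD -> AP1          [H0/H1]
#   under H2 the LFY activation splits into bulk (v6,K8,n8) + singled
#   (v7,K9,n9), and the AP1 activation into bulk (v8,K10,n10) + singled
#   (v9,K11,n11).

#' Specify an FT-activation hypothesis
#'
#' Three competing schemes for how the five FT homologs activate the
#' meristem-identity genes: `H0` — cumulative activation by the summed FT
#' concentration; `H1` — a single FT homolog carries the whole activation;
#' `H2` — one homolog is singled out with its own regulatory constants
#' while the remaining four act cumulatively.
#'
#' @param hypothesis `"H0"`, `"H1"` or `"H2"`.
#' @param singled_ft The singled-out FT gene (required for H1/H2).
#' @param ft_genes Ordered FT drivers included in the model.
#' @return An object of class `grn_model_spec`.
#' @export
#' @examples
#' model_spec("H0")
#' count_free_parameters(model_spec("H2", "FTb"))
model_spec <- function(hypothesis = c("H0", "H1", "H2"),
                       singled_ft = NULL,
                       ft_genes = flornet::ft_genes()) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis %in% c("H1", "H2")) {
    if (is.null(singled_ft)) {
      abort(paste0(hypothesis, " requires a singled-out FT gene"),
            class = "flornet_spec_error")
    }
    if (!singled_ft %in% ft_genes) {
      abort(paste0("singled_ft ", singled_ft, " not among ft_genes"),
            class = "flornet_spec_error")
    }
  } else {
    singled_ft <- NULL
  }
  structure(list(hypothesis = hypothesis,
                 singled_ft = singled_ft,
                 ft_genes = ft_genes),
            class = "grn_model_spec")
}

#' @export
print.grn_model_spec <- function(x, ...) {
  cat("<grn_model_spec>", x$hypothesis,
      if (!is.null(x$singled_ft)) paste0("(singled-out ", x$singled_ft, ")"),
      "| FT drivers:", paste(x$ft_genes, collapse = ", "),
      "|", count_free_parameters(x), "free parameters\n")
  invisible(x)
}

#' Names of the free parameters of a hypothesis
#'
#' @param spec A `grn_model_spec`.
#' @return Character vector: 31 names for H0/H1 (7 v, 9 K, 9 n, 5 lambda,
#'   tau), 37 for H2 (9 v, 11 K, 11 n, 5 lambda, tau).
#' @export
param_names <- function(spec) {
  h2 <- spec$hypothesis == "H2"
  c(paste0("v", seq_len(if (h2) 9 else 7)),
    paste0("K", seq_len(if (h2) 11 else 9)),
    paste0("n", seq_len(if (h2) 11 else 9)),
    paste0("lambda", 1:5),
    "tau")
}

#' Number of free parameters of a hypothesis
#'
#' @param spec A `grn_model_spec`.
#' @return 31 for H0 and every H1 version; 37 for every H2 version.
#' @export
count_free_parameters <- function(spec) length(param_names(spec))

#' Validate a named parameter vector against a hypothesis
#'
#' Admissibility: all v, K, lambda > 0; all Hill exponents n >= 1;
#' tau >= 0.
#'
#' @param params Named numeric vector.
#' @param spec A `grn_model_spec`.
#' @return `params` (reordered to canonical order), invisibly usable.
#' @export
validate_params <- function(params, spec) {
  wanted <- param_names(spec)
  missing_p <- setdiff(wanted, names(params))
  if (length(missing_p) > 0) {
    abort(paste0("missing parameter(s): ", paste(missing_p, collapse = ", ")),
          class = "flornet_parameter_error")
  }
  params <- params[wanted]
  vk <- grepl("^(v|K|lambda)", wanted)
  if (any(params[vk] <= 0)) {
    abort("all v, K and lambda must be > 0", class = "flornet_parameter_error")
  }
  if (any(params[grepl("^n", wanted)] < 1)) {
    abort("all Hill exponents n must be >= 1", class = "flornet_parameter_error")
  }
  if (params["tau"] < 0) {
    abort("tau must be >= 0", class = "flornet_parameter_error")
  }
  params
}

# Hill regulation functions ---------------------------------------------------

#' Hill regulation functions
#'
#' Dimensionless activator `x^n / (K^n + x^n)` and repressor
#' `K^n / (K^n + x^n)` forms.  Negative regulator values (which can only
#' arise from permissive interpolation settings) are treated as zero.
#'
#' @param x Regulator concentration(s).
#' @param K Half-saturation (Michaelis–Menten) constant, > 0.
#' @param n Hill exponent, >= 1.
#' @return Values in `[0, 1]`.
#' @export
hill_act <- function(x, K, n) {
  x <- pmax(x, 0)
  xn <- x^n
  xn / (K^n + xn)
}

#' @rdname hill_act
#' @export
hill_rep <- function(x, K, n) {
  x <- pmax(x, 0)
  Kn <- K^n
  Kn / (Kn + x^n)
}

# derivative of the activator/repressor form with respect to x
hill_act_deriv <- function(x, K, n) {
  x <- pmax(x, 0)
  Kn <- K^n
  xn <- x^n
  num <- n * Kn * ifelse(x > 0, xn / x, if (n == 1) 1 else 0)
  num / (Kn + xn)^2
}

hill_rep_deriv <- function(x, K, n) -hill_act_deriv(x, K, n)

# FT activation input ----------------------------------------------------------

# pooled delayed FT-FD product(s) feeding LFY/AP1 under a hypothesis;
# returns a list of products (bulk, and singled for H2)
ft_fd_products <- function(spec, traces, t, tau) {
  u_fd <- trace_eval(traces, "FD", t)
  pool_over <- function(genes) {
    Reduce(`+`, lapply(genes, function(g) delayed_value(traces, g, t, tau)))
  }
  if (spec$hypothesis == "H0") {
    list(bulk = u_fd * pool_over(spec$ft_genes))
  } else if (spec$hypothesis == "H1") {
    list(bulk = u_fd * delayed_value(traces, spec$singled_ft, t, tau))
  } else {
    list(bulk = u_fd * pool_over(setdiff(spec$ft_genes, spec$singled_ft)),
         singled = u_fd * delayed_value(traces, spec$singled_ft, t, tau))
  }
}

#' FT-mediated synthesis input to LFY or AP1
#'
#' Evaluates the hypothesis-dependent FT activation term: under H0 a single
#' Hill activator of `u_FD * sum(u_FT(t - tau))`; under H1 the same with a
#' single homolog; under H2 the sum of a bulk (four-homolog) and a
#' singled-out activator with separate constants.
#'
#' @param spec A `grn_model_spec`.
#' @param params Named parameter vector.
#' @param traces `regulator_traces` covering `t - tau` (clamped).
#' @param t Times (days), vectorized.
#' @param target `"LFY"` or `"AP1"`.
#' @return Synthesis-rate contribution (concentration/day).
#' @export
ft_input <- function(spec, params, traces, t, target = c("LFY", "AP1")) {
  target <- match.arg(target)
  p <- ft_fd_products(spec, traces, t, params[["tau"]])
  if (spec$hypothesis != "H2") {
    if (target == "LFY") {
      params[["v6"]] * hill_act(p$bulk, params[["K8"]], params[["n8"]])
    } else {
      params[["v7"]] * hill_act(p$bulk, params[["K9"]], params[["n9"]])
    }
  } else {
    if (target == "LFY") {
      params[["v6"]] * hill_act(p$bulk, params[["K8"]], params[["n8"]]) +
        params[["v7"]] * hill_act(p$singled, params[["K9"]], params[["n9"]])
    } else {
      params[["v8"]] * hill_act(p$bulk, params[["K10"]], params[["n10"]]) +
        params[["v9"]] * hill_act(p$singled, params[["K11"]], params[["n11"]])
    }
  }
}

# Per-gene synthesis forcings s_g(t); everything on the right-hand side
# except each gene's own decay term.  Vectorized over t.
grn_forcing <- function(spec, params, traces, t) {
  u_ap1 <- trace_eval(traces, "AP1", t)
  u_lfy <- trace_eval(traces, "LFY", t)
  u_fd <- trace_eval(traces, "FD", t)
  cplx <- u_fd * (trace_eval(traces, "TFL1a", t) + trace_eval(traces, "TFL1c", t))
  list(
    TFL1a = params[["v1"]] * hill_rep(u_ap1, params[["K1"]], params[["n1"]]),
    TFL1c = params[["v2"]] * hill_rep(u_ap1, params[["K2"]], params[["n2"]]),
    FD = params[["v3"]] * hill_act(u_lfy, params[["K3"]], params[["n3"]]),
    LFY = (params[["v4"]] * hill_act(u_ap1, params[["K4"]], params[["n4"]]) +
             ft_input(spec, params, traces, t, "LFY")) *
      hill_rep(cplx, params[["K5"]], params[["n5"]]),
    AP1 = (params[["v5"]] * hill_act(u_lfy, params[["K6"]], params[["n6"]]) +
             ft_input(spec, params, traces, t, "AP1")) *
      hill_rep(cplx, params[["K7"]], params[["n7"]])
  )
}

#' Right-hand side of the model equations
#'
#' Time derivatives of the five target proteins.  All regulator
#' concentrations are taken from the data traces; only each gene's own
#' decay term uses the solved state.
#'
#' @param spec A `grn_model_spec`.
#' @param params Named parameter vector.
#' @param traces `regulator_traces` for the condition.
#' @param t Time (days), scalar.
#' @param state Named or ordered 5-vector (TFL1a, TFL1c, FD, LFY, AP1).
#' @return Derivative 5-vector (concentration/day).
#' @export
grn_rhs <- function(spec, params, traces, t, state) {
  if (any(!is.finite(state))) {
    abort(paste0("non-finite state at t = ", t, ": ",
                 paste(signif(state, 4), collapse = ", ")),
          class = "flornet_numerical_error")
  }
  s <- grn_forcing(spec, params, traces, t)
  lambda <- unlist(params[paste0("lambda", 1:5)], use.names = FALSE)
  setNames(c(s$TFL1a, s$TFL1c, s$FD, s$LFY, s$AP1) - lambda * as.numeric(state),
           target_genes())
}

#' Default initial state
#'
#' TFL1a and TFL1c start at zero concentration at t = 0 (their traces are
#' interpolated back to zero there); FD, LFY and AP1 start at their first
#' observed value, which the clamped trace returns at t = 0.
#'
#' @param traces `regulator_traces`.
#' @param t0 Integration start time.
#' @return Named 5-vector.
#' @export
initial_state <- function(traces, t0 = 0) {
  vapply(setNames(target_genes(), target_genes()),
         function(g) trace_eval(traces, g, t0), numeric(1))
}

#' Solve the model for one condition
#'
#' Integrates the five target equations against fixed regulator traces.
#' The default integrator is the stiff-capable `lsoda`; `"exp"` uses an
#' exponential (exact linear-decay) integrator on a fine uniform grid,
#' which is valid because each equation is linear in its own state.
#'
#' @param spec A `grn_model_spec`.
#' @param params Named parameter vector.
#' @param traces `regulator_traces` for the condition.
#' @param times Output times; default a fine grid over `[0, t_end]`.
#' @param init Initial 5-vector, default [initial_state()].
#' @param method `"lsoda"`, `"exp"` or `"rk4"`.
#' @param rtol,atol Solver tolerances (lsoda).
#' @param h Internal grid step (days) for the exponential integrator.
#' @return A tibble with columns `time`, `gene`, `value` and a
#'   `condition` attribute.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_expression.tsv", package = "flornet")
#' dat <- read_expression_table(path)
#' tr <- build_traces(dat, "SD")
#' sp <- model_spec("H0")
#' th <- example_truth_params()
#' sol <- solve_grn(sp, th, tr)
#' head(sol)
solve_grn <- function(spec, params, traces,
                      times = NULL, init = NULL,
                      method = c("lsoda", "exp", "rk4"),
                      rtol = 1e-6, atol = 1e-9, h = 0.02) {
  method <- match.arg(method)
  params <- validate_params(unlist(params), spec)
  times <- times %||% sort(unique(c(seq(0, traces$t_end, by = 0.25), traces$t_end)))
  if (times[1] != 0) times <- c(0, times)
  init <- init %||% initial_state(traces)
  lambda <- unlist(params[paste0("lambda", 1:5)], use.names = FALSE)

  if (method == "exp") {
    grid <- seq(0, max(times), by = h)
    if (grid[length(grid)] < max(times)) grid <- c(grid, max(times))
    s <- grn_forcing(spec, params, traces, grid)
    sol <- vapply(seq_along(target_genes()), function(i) {
      u <- lin_ode_forced(s[[i]], h, lambda[i], init[i])
      approx(grid, u, xout = times)$y
    }, numeric(length(times)))
  } else {
    deriv <- function(t, y, parms) {
      sg <- grn_forcing(spec, params, traces, t)
      list(c(sg$TFL1a, sg$TFL1c, sg$FD, sg$LFY, sg$AP1) - lambda * y)
    }
    out <- tryCatch(
      deSolve::ode(y = as.numeric(init), times = times, func = deriv,
                   parms = NULL, method = method, rtol = rtol, atol = atol),
      warning = function(w) {
        abort(paste0("integration problem: ", conditionMessage(w)),
              class = "flornet_integration_error")
      }
    )
    sol <- unname(out[, -1, drop = FALSE])
  }
  colnames(sol) <- target_genes()
  res <- tibble::as_tibble(as.data.frame(sol))
  res$time <- times
  res <- tidyr::pivot_longer(res, -dplyr::all_of("time"),
                             names_to = "gene", values_to = "value")
  attr(res, "condition") <- traces$condition
  res
}

#' Example admissible H0 parameter set
#'
#' A realistic parameter vector on the scale of the shipped synthetic
#' dataset, convenient for examples and smoke tests.  It is the ground
#' truth of the baseline synthetic scenario (see [make_recovery_suite()]).
#'
#' @return Named numeric vector of 31 parameters.
#' @export
example_truth_params <- function() {
  default_scenario_truth()
}
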