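# Ensemble parameter estimation.
#
# The objective is the weighted residual sum of squares over the target
# genes, summed over conditions when both are fit.  Minimization uses
# differential evolution inside box bounds.  Because the regulators are
# data traces, the model splits into four parameter-disjoint subsystems
# (TFL1a, TFL1c, FD alone; LFY+AP1 jointly via the shared delay tau), and
# the default fit runs one DE per subsystem, which is equivalent to the
# joint fit and much faster.

#' Weighted residual sum of squares
#'
#' `sum over conditions, target genes and data times of
#' ((u_model - u_data) / sd)^2`.  Per-condition sums are added when both
#' conditions are fit.  [wrss_with_penalty()] adds `weight` times the sum
#' over target series of the covariance between model and data values at
#' the data times (the variant used for the second cultivar in the source
#' study; see the vignette for the sign caveat).
#'
#' @param solution A solution tibble with columns `condition`, `gene`,
#'   `time`, `value`, or a list of per-condition tibbles from
#'   [solve_grn()].
#' @param data An expression tibble.
#' @param conditions Conditions included in the sum (default: those present
#'   in the solution).
#' @param targets Fit-target genes.
#' @return A single cost value.
#' @export
wrss <- function(solution, data, conditions = NULL, targets = target_genes()) {
  aligned <- align_solution(solution, data, conditions, targets)
  sum(((aligned$value - aligned$mean) / aligned$sd)^2)
}

#' @rdname wrss
#' @param weight Penalty weight (default 1).
#' @export
wrss_with_penalty <- function(solution, data, conditions = NULL,
                              weight = 1, targets = target_genes()) {
  aligned <- align_solution(solution, data, conditions, targets)
  base <- sum(((aligned$value - aligned$mean) / aligned$sd)^2)
  pen <- aligned |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(cv = if (dplyr::n() > 1) cov(.data$value, .data$mean) else 0,
                     .groups = "drop")
  base + weight * sum(pen$cv)
}

combine_solutions <- function(solution) {
  if (is.data.frame(solution)) {
    if (!"condition" %in% names(solution)) {
      cond <- attr(solution, "condition", exact = TRUE)
      if (is.null(cond)) {
        abort("solution lacks a condition column/attribute",
              class = "flornet_alignment_error")
      }
      solution$condition <- cond
    }
    return(solution)
  }
  dplyr::bind_rows(lapply(solution, function(s) {
    s$condition <- s$condition %||% attr(s, "condition", exact = TRUE)
    s
  }))
}

align_solution <- function(solution, data, conditions, targets) {
  sol <- combine_solutions(solution)
  conditions <- conditions %||% unique(sol$condition)
  dat <- data[data$gene %in% targets & data$condition %in% conditions, ]
  sol <- sol[sol$condition %in% conditions, ]
  sol$t_key <- round(sol$time, 9)
  dat$t_key <- round(dat$time, 9)
  aligned <- dplyr::inner_join(
    dat, sol[c("condition", "gene", "t_key", "value")],
    by = c("condition", "gene", "t_key"))
  if (nrow(aligned) < nrow(dat)) {
    miss <- dplyr::anti_join(dat, aligned,
                             by = c("condition", "gene", "t_key"))
    abort(paste0("solution missing at ", nrow(miss), " data time(s), e.g. ",
                 miss$gene[1], "/", miss$condition[1], " t = ", miss$time[1]),
          class = "flornet_alignment_error")
  }
  aligned
}

# Bounds and configuration ----------------------------------------------------

#' Default data-scale-aware optimization bounds
#'
#' K boxes span `[0.01, 100]` times the maximum of the relevant regulator
#' (or regulator-complex) trace; v boxes span `[1e-3, 10 * max target level
#' * lambda_max]`; n in `[1, 8]`; lambda in `[1e-3, 5]` per day; tau in
#' `[0, 5]` days.
#'
#' @param data An expression tibble.
#' @param spec A `grn_model_spec`.
#' @param conditions Conditions used to measure data scales.
#' @return A tibble with columns `term`, `lower`, `upper`.
#' @export
default_parameter_bounds <- function(data, spec,
                                     conditions = photoperiod_conditions()) {
  conditions <- intersect(conditions, unique(data$condition))
  grids <- lapply(conditions, function(cond) {
    tr <- build_traces(data, cond)
    tt <- seq(0, tr$t_end, length.out = 201)
    g <- function(gene) trace_eval(tr, gene, tt)
    ftsum <- function(genes) Reduce(`+`, lapply(genes, g))
    list(AP1 = g("AP1"), LFY = g("LFY"),
         cplx = g("FD") * (g("TFL1a") + g("TFL1c")),
         bulk = g("FD") * ftsum(switch(spec$hypothesis,
                                       H0 = spec$ft_genes,
                                       H1 = spec$singled_ft,
                                       H2 = setdiff(spec$ft_genes, spec$singled_ft))),
         singled = if (spec$hypothesis == "H2")
           g("FD") * g(spec$singled_ft) else NULL,
         targets = vapply(setNames(target_genes(), target_genes()),
                          function(gn) max(g(gn)), numeric(1)))
  })
  scale_of <- function(field) {
    max(vapply(grids, function(x) max(x[[field]]), numeric(1)), 1e-8)
  }
  target_max <- apply(do.call(rbind, lapply(grids, `[[`, "targets")), 2, max)
  lambda_max <- 5
  K_reg <- c(K1 = "AP1", K2 = "AP1", K3 = "LFY", K4 = "AP1", K5 = "cplx",
             K6 = "LFY", K7 = "cplx", K8 = "bulk",
             K9 = if (spec$hypothesis == "H2") "singled" else "bulk",
             K10 = "bulk", K11 = "singled")
  v_target <- c(v1 = "TFL1a", v2 = "TFL1c", v3 = "FD", v4 = "LFY", v5 = "AP1",
                v6 = "LFY",
                v7 = if (spec$hypothesis == "H2") "LFY" else "AP1",
                v8 = "AP1", v9 = "AP1")
  rows <- lapply(param_names(spec), function(term) {
    if (grepl("^v", term)) {
      up <- 10 * max(target_max[[v_target[[term]]]], 1e-8) * lambda_max
      c(1e-3, up)
    } else if (grepl("^K", term)) {
      r <- scale_of(K_reg[[term]])
      c(0.01 * r, 100 * r)
    } else if (grepl("^n", term)) {
      c(1, 8)
    } else if (grepl("^lambda", term)) {
      c(1e-3, 5)
    } else {
      c(0, 5)
    }
  })
  tibble::tibble(term = param_names(spec),
                 lower = vapply(rows, `[[`, numeric(1), 1),
                 upper = vapply(rows, `[[`, numeric(1), 2))
}

#' Fitting configuration
#'
#' @param n_restarts Ensemble size (independent DE runs).
#' @param base_seed Base RNG seed; member i uses `base_seed + i`.
#' @param conditions Conditions entering the objective.
#' @param penalty `"none"` or `"covariance"`.
#' @param penalty_weight Weight of the covariance penalty.
#' @param bounds Optional bounds tibble (`term`, `lower`, `upper`);
#'   default [default_parameter_bounds()].
#' @param h Grid step (days) of the inner integrator.
#' @param split Fit the four parameter-disjoint subsystems separately
#'   (equivalent to the joint fit; much faster).
#' @param polish Run a derivative-free Nelder–Mead refinement (clamped to
#'   the bounds) from the best DE member; `polish_maxit` caps its
#'   iterations.  Improves the returned optimum without changing the
#'   global-search character of the fit.
#' @param polish_maxit Iteration cap for the polish step.
#' @param integer_n Restrict Hill exponents to integers during the search
#'   (candidate exponents are rounded before evaluation).  Continuous
#'   exponents trade off against K along a near-flat ridge on sparse noisy
#'   series; treating cooperativity as a discrete structural choice makes
#'   the half-saturation constants identifiable.
#' @param de Differential-evolution settings: `pop_factor` (population =
#'   `pop_factor * dimension`), `F` (dither range), `CR` (crossover rate),
#'   `max_gen`, `tol` (relative cost-spread stopping tolerance).
#' @return A list of class `grn_fit_config`.
#' @export
fit_config <- function(n_restarts = 100,
                       base_seed = 1,
                       conditions = photoperiod_conditions(),
                       penalty = c("none", "covariance"),
                       penalty_weight = 1,
                       bounds = NULL,
                       h = 0.1,
                       split = TRUE,
                       polish = TRUE,
                       polish_maxit = 2000,
                       integer_n = FALSE,
                       de = list()) {
  penalty <- match.arg(penalty)
  de_defaults <- list(pop_factor = 15, F = c(0.5, 1), CR = 0.7,
                      max_gen = 2000, tol = 1e-6)
  de <- utils::modifyList(de_defaults, de)
  structure(list(n_restarts = n_restarts, base_seed = base_seed,
                 conditions = conditions, penalty = penalty,
                 penalty_weight = penalty_weight, bounds = bounds,
                 h = h, split = split, polish = polish,
                 polish_maxit = polish_maxit, integer_n = integer_n,
                 de = de),
            class = "grn_fit_config")
}

# Differential evolution (best/1/bin with dithered F, reflecting bounds) ------

# fn maps a population matrix (rows = members) to a cost vector
de_optimize <- function(fn, lower, upper, de) {
  d <- length(lower)
  np <- max(15L, as.integer(round(de$pop_factor * d)))
  lo <- matrix(lower, np, d, byrow = TRUE)
  hi <- matrix(upper, np, d, byrow = TRUE)
  pop <- lo + (hi - lo) * matrix(runif(np * d), np, d)
  cost <- fn(pop)
  n_eval <- np
  converged <- FALSE
  gen <- 0L
  while (gen < de$max_gen) {
    gen <- gen + 1L
    spread <- max(cost) - min(cost)
    if (is.finite(spread) && spread <= de$tol * max(1, abs(min(cost)))) {
      converged <- TRUE
      break
    }
    Fg <- runif(1, de$F[1], de$F[2])
    best <- pop[which.min(cost), ]
    r1 <- sample.int(np, np, replace = TRUE)
    r2 <- sample.int(np, np, replace = TRUE)
    mut <- matrix(best, np, d, byrow = TRUE) + Fg * (pop[r1, , drop = FALSE] -
                                                      pop[r2, , drop = FALSE])
    mask <- matrix(runif(np * d) < de$CR, np, d)
    mask[cbind(seq_len(np), sample.int(d, np, replace = TRUE))] <- TRUE
    trial <- ifelse(mask, mut, pop)
    # reflect out-of-box coordinates, then clamp (repeated reflection
    # could still escape for huge mutations)
    below <- trial < lo
    trial[below] <- 2 * lo[below] - trial[below]
    above <- trial > hi
    trial[above] <- 2 * hi[above] - trial[above]
    trial <- pmin(pmax(trial, lo), hi)
    trial_cost <- fn(trial)
    n_eval <- n_eval + np
    improved <- is.finite(trial_cost) & (trial_cost <= cost)
    pop[improved, ] <- trial[improved, , drop = FALSE]
    cost[improved] <- trial_cost[improved]
  }
  if (all(!is.finite(cost))) {
    abort("differential evolution: non-finite cost throughout the population",
          class = "flornet_optimization_error")
  }
  i_best <- which.min(cost)
  list(par = pop[i_best, ], value = cost[i_best],
       converged = converged, generations = gen, n_eval = n_eval)
}

# Nelder-Mead refinement of a DE optimum, clamped to the box.
polish_optimum <- function(res, fn, lower, upper, maxit) {
  fn1 <- function(theta) fn(matrix(pmin(pmax(theta, lower), upper),
                                   nrow = 1))[1]
  pol <- tryCatch(
    stats::optim(res$par, fn1, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < res$value) {
    res$par <- pmin(pmax(pol$par, lower), upper)
    res$value <- pol$value
  }
  res
}

# Subsystem definitions and caches --------------------------------------------

meristem_par_names <- function(spec) {
  if (spec$hypothesis == "H2") {
    c("v4", "K4", "n4", "K5", "n5", "v5", "K6", "n6", "K7", "n7",
      "v6", "K8", "n8", "v7", "K9", "n9", "v8", "K10", "n10",
      "v9", "K11", "n11", "lambda4", "lambda5", "tau")
  } else {
    c("v4", "K4", "n4", "K5", "n5", "v5", "K6", "n6", "K7", "n7",
      "v6", "K8", "n8", "v7", "K9", "n9", "lambda4", "lambda5", "tau")
  }
}

subsystem_defs <- function(spec) {
  list(
    TFL1a = list(pars = c("v1", "K1", "n1", "lambda1"),
                 gene = "TFL1a", reg = "uAP1", activator = FALSE),
    TFL1c = list(pars = c("v2", "K2", "n2", "lambda2"),
                 gene = "TFL1c", reg = "uAP1", activator = FALSE),
    FD = list(pars = c("v3", "K3", "n3", "lambda3"),
              gene = "FD", reg = "uLFY", activator = TRUE),
    meristem = list(pars = meristem_par_names(spec))
  )
}

# Precomputed per-condition grids shared by every objective evaluation.
build_fit_cache <- function(data, spec, conditions, h) {
  caches <- lapply(setNames(conditions, conditions), function(cond) {
    tr <- build_traces(data, cond)
    n_steps <- max(2L, ceiling(tr$t_end / h))
    hh <- tr$t_end / n_steps
    tt <- seq(0, tr$t_end, by = hh)
    g <- function(gene) trace_eval(tr, gene, tt)
    u0 <- initial_state(tr)
    dat_of <- function(gene) {
      s <- data[data$gene == gene & data$condition == cond, ]
      s <- s[order(s$time), ]
      list(t = s$time, y = s$mean, sd = s$sd)
    }
    bulk_genes <- switch(spec$hypothesis,
                         H0 = spec$ft_genes,
                         H1 = spec$singled_ft,
                         H2 = setdiff(spec$ft_genes, spec$singled_ft))
    ftb <- pooled_trace_knots(tr, bulk_genes)
    fts <- if (spec$hypothesis == "H2") tr$knots[[spec$singled_ft]] else
      list(time = 0, value = 0)
    per_gene <- lapply(setNames(target_genes(), target_genes()), dat_of)
    list(traces = tr, t0 = 0, h = hh, grid = tt,
         uAP1 = g("AP1"), uLFY = g("LFY"), uFD = g("FD"),
         cplx = g("FD") * (g("TFL1a") + g("TFL1c")),
         ftb_t = ftb$time, ftb_v = ftb$value,
         fts_t = fts$time, fts_v = fts$value,
         u0 = u0, dat = per_gene)
  })
  caches
}

single_gene_conds <- function(cache, def) {
  lapply(cache, function(cc) {
    d <- cc$dat[[def$gene]]
    list(reg = cc[[def$reg]], t0 = cc$t0, h = cc$h, u0 = cc$u0[[def$gene]],
         tdat = d$t, ydat = d$y, sddat = d$sd)
  })
}

meristem_conds <- function(cache) {
  lapply(cache, function(cc) {
    list(t0 = cc$t0, h = cc$h,
         uAP1 = cc$uAP1, uLFY = cc$uLFY, uFD = cc$uFD, cplx = cc$cplx,
         ftb_t = cc$ftb_t, ftb_v = cc$ftb_v,
         fts_t = cc$fts_t, fts_v = cc$fts_v,
         u0_LFY = cc$u0[["LFY"]], u0_AP1 = cc$u0[["AP1"]],
         LFY_t = cc$dat$LFY$t, LFY_y = cc$dat$LFY$y, LFY_sd = cc$dat$LFY$sd,
         AP1_t = cc$dat$AP1$t, AP1_y = cc$dat$AP1$y, AP1_sd = cc$dat$AP1$sd)
  })
}

# Fitting ----------------------------------------------------------------------

#' Fit the model once by differential evolution
#'
#' One global search inside the configured bounds; deterministic given
#' `seed`.  With `split = TRUE` (default) the four parameter-disjoint
#' subsystems are optimized independently and the costs added, which is
#' equivalent to the joint problem.
#'
#' @param data An expression tibble.
#' @param spec A `grn_model_spec`.
#' @param config A [fit_config()].
#' @param seed RNG seed for this run.
#' @return An object of class `grn_fit` with elements `params`, `cost`,
#'   `cost_by_condition`, `solution`, `converged`, `seed`, `subsystems`.
#' @export
fit_grn <- function(data, spec, config = fit_config(),
                    seed = config$base_seed) {
  assert_fittable(data, config$conditions)
  set.seed(seed)
  cache <- build_fit_cache(data, spec, config$conditions, config$h)
  bounds <- config$bounds %||% default_parameter_bounds(data, spec,
                                                        config$conditions)
  pen_w <- if (config$penalty == "covariance") config$penalty_weight else 0
  defs <- subsystem_defs(spec)
  hyp_code <- match(spec$hypothesis, c("H0", "H1", "H2")) - 1L

  box <- function(pars) {
    i <- match(pars, bounds$term)
    if (anyNA(i)) {
      abort(paste0("bounds missing for: ",
                   paste(pars[is.na(i)], collapse = ", ")),
            class = "flornet_parameter_error")
    }
    list(lower = bounds$lower[i], upper = bounds$upper[i])
  }

  round_wrap <- function(fn, pars) {
    force(fn)
    n_idx <- grep("^n", pars)
    if (!isTRUE(config$integer_n) || length(n_idx) == 0) return(fn)
    function(P) {
      P[, n_idx] <- round(P[, n_idx])
      fn(P)
    }
  }
  snap_n <- function(par, pars) {
    if (isTRUE(config$integer_n)) {
      n_idx <- grep("^n", pars)
      par[n_idx] <- round(par[n_idx])
    }
    par
  }

  params <- numeric(0)
  diag_rows <- list()
  if (config$split) {
    for (nm in names(defs)) {
      def <- defs[[nm]]
      b <- box(def$pars)
      if (nm == "meristem") {
        conds <- meristem_conds(cache)
        fn <- function(P) cost_meristem_pop(P, hyp_code, conds, pen_w)
      } else {
        conds <- single_gene_conds(cache, def)
        fn <- local({
          cs <- conds
          act <- def$activator
          function(P) cost_single_gene_pop(P, cs, act, pen_w)
        })
      }
      fn <- round_wrap(fn, def$pars)
      res <- de_optimize(fn, b$lower, b$upper, config$de)
      if (isTRUE(config$polish)) {
        res <- polish_optimum(res, fn, b$lower, b$upper, config$polish_maxit)
      }
      params[def$pars] <- snap_n(res$par, def$pars)
      diag_rows[[nm]] <- tibble::tibble(subsystem = nm, cost = res$value,
                                        generations = res$generations,
                                        n_eval = res$n_eval,
                                        converged = res$converged)
    }
  } else {
    all_pars <- param_names(spec)
    b <- box(all_pars)
    defs3 <- defs[c("TFL1a", "TFL1c", "FD")]
    conds_sg <- lapply(defs3, function(def) single_gene_conds(cache, def))
    conds_m <- meristem_conds(cache)
    m_idx <- match(meristem_par_names(spec), all_pars)
    sg_idx <- lapply(defs3, function(def) match(def$pars, all_pars))
    fn <- function(P) {
      tot <- cost_meristem_pop(P[, m_idx, drop = FALSE], hyp_code, conds_m,
                               pen_w)
      for (nm in names(defs3)) {
        tot <- tot + cost_single_gene_pop(P[, sg_idx[[nm]], drop = FALSE],
                                          conds_sg[[nm]],
                                          defs3[[nm]]$activator, pen_w)
      }
      tot
    }
    fn <- round_wrap(fn, all_pars)
    res <- de_optimize(fn, b$lower, b$upper, config$de)
    if (isTRUE(config$polish)) {
      res <- polish_optimum(res, fn, b$lower, b$upper, config$polish_maxit)
    }
    params <- setNames(snap_n(res$par, all_pars), all_pars)
    diag_rows$joint <- tibble::tibble(subsystem = "joint", cost = res$value,
                                      generations = res$generations,
                                      n_eval = res$n_eval,
                                      converged = res$converged)
  }
  params <- validate_params(params, spec)

  sols <- lapply(config$conditions, function(cond) {
    tr <- cache[[cond]]$traces
    times <- sort(unique(c(seq(0, tr$t_end, by = 0.25), tr$t_end,
                           unlist(lapply(cache[[cond]]$dat, `[[`, "t")))))
    s <- solve_grn(spec, params, tr, times = times, method = "exp",
                   h = min(0.02, config$h))
    s$condition <- cond
    s
  })
  solution <- dplyr::bind_rows(sols)
  cost_by_condition <- vapply(setNames(config$conditions, config$conditions),
                              function(cond) wrss(solution, data, cond),
                              numeric(1))
  cost <- if (pen_w > 0) {
    wrss_with_penalty(solution, data, config$conditions, weight = pen_w)
  } else {
    sum(cost_by_condition)
  }
  diag <- dplyr::bind_rows(diag_rows)
  structure(list(params = params, cost = cost,
                 cost_by_condition = cost_by_condition,
                 solution = solution,
                 converged = all(diag$converged),
                 seed = seed, spec = spec, config = config,
                 subsystems = diag),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("<grn_fit>", x$spec$hypothesis,
      if (!is.null(x$spec$singled_ft)) paste0("(", x$spec$singled_ft, ")"),
      "| cost =", signif(x$cost, 6),
      "| by condition:",
      paste(names(x$cost_by_condition), signif(x$cost_by_condition, 5),
            sep = "=", collapse = ", "),
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Fit an ensemble of independent optimization runs
#'
#' Repeats [fit_grn()] `n_restarts` times with seeds `base_seed + i`.  All
#' resulting parameter sets are retained; the ensemble philosophy treats
#' every run that converged to a comparable cost as an equally valid
#' description of the data.
#'
#' @inheritParams fit_grn
#' @return An object of class `grn_ensemble`.
#' @export
fit_ensemble <- function(data, spec, config = fit_config()) {
  stopifnot(config$n_restarts >= 1)
  seeds <- config$base_seed + seq_len(config$n_restarts)
  runs <- purrr::map(seeds, function(s) {
    tryCatch(fit_grn(data, spec, config, seed = s),
             error = function(e) e)
  })
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (!any(ok)) {
    abort(paste0("all ensemble members failed; first error: ",
                 conditionMessage(runs[[1]])),
          class = "flornet_optimization_error")
  }
  structure(list(fits = runs[ok], spec = spec, config = config,
                 descriptor = NULL, failures = runs[!ok]),
            class = "grn_ensemble")
}

#' Wrap explicit parameter sets as an ensemble
#'
#' Useful for running the ensemble diagnostics at known parameter values
#' (for example the ground truth of a synthetic scenario).
#'
#' @param params A named parameter vector or a list of them.
#' @param spec The `grn_model_spec` the parameters belong to.
#' @return A `grn_ensemble` whose members carry parameters only.
#' @export
as_param_ensemble <- function(params, spec) {
  if (!is.list(params)) params <- list(params)
  fits <- lapply(seq_along(params), function(i) {
    structure(list(params = validate_params(unlist(params[[i]]), spec),
                   cost = NA_real_, cost_by_condition = NULL,
                   solution = NULL, converged = NA, seed = i,
                   spec = spec, config = NULL, subsystems = NULL),
              class = "grn_fit")
  })
  structure(list(fits = fits, spec = spec, config = NULL,
                 descriptor = NULL, failures = list()),
            class = "grn_ensemble")
}

#' @export
print.grn_ensemble <- function(x, ...) {
  costs <- ensemble_costs(x)
  cat("<grn_ensemble>", length(x$fits), "members |", x$spec$hypothesis,
      if (!is.null(x$spec$singled_ft)) paste0("(", x$spec$singled_ft, ")"),
      "| cost min/median:",
      signif(suppressWarnings(min(costs)), 5), "/",
      signif(median(costs), 5), "\n")
  invisible(x)
}

#' Ensemble cost vector and minimum
#'
#' @param ensemble A `grn_ensemble`.
#' @return `ensemble_costs()`: numeric vector of member costs;
#'   `min_cost()`: the minimum.
#' @export
ensemble_costs <- function(ensemble) {
  vapply(ensemble$fits, function(f) f$cost, numeric(1))
}

#' @rdname ensemble_costs
#' @export
min_cost <- function(ensemble) min(ensemble_costs(ensemble), na.rm = TRUE)

# broom-style methods ----------------------------------------------------------

#' @export
tidy.grn_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.grn_fit <- function(x, ...) {
  out <- tibble::tibble(cost = x$cost, k = count_free_parameters(x$spec),
                        converged = x$converged, seed = x$seed)
  for (cond in names(x$cost_by_condition)) {
    out[[paste0("cost_", cond)]] <- x$cost_by_condition[[cond]]
  }
  out
}

#' @export
tidy.grn_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$fits), function(i) {
    dplyr::mutate(tidy(x$fits[[i]]), member = i, .before = 1)
  })
}

#' @export
glance.grn_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$fits), function(i) {
    dplyr::mutate(glance(x$fits[[i]]), member = i, .before = 1)
  })
}

#' Ensemble-median parameter estimates
#'
#' @param ensemble A `grn_ensemble`.
#' @return A tibble with `term`, `median`, `mean`, `sd` over members.
#' @export
ensemble_param_summary <- function(ensemble) {
  tidy(ensemble) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(median = median(.data$estimate),
                     mean = mean(.data$estimate),
                     sd = sd(.data$estimate), .groups = "drop")
}
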