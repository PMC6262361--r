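# Shared fixtures, simulated once per test session and cached.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_env <- new.env(parent = emptyenv())

fx_suite <- function() {
  if (is.null(.fixture_env$suite)) .fixture_env$suite <- make_recovery_suite()
  .fixture_env$suite
}

fx_sim <- function(name) {
  key <- paste0("sim_", name)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- suppressWarnings(simulate_dataset(fx_suite()[[name]]))
  }
  .fixture_env[[key]]
}

fx_traces <- function(name, which = c("data", "truth")) {
  which <- match.arg(which)
  key <- paste0("tr_", name, "_", which)
  if (is.null(.fixture_env[[key]])) {
    sim <- fx_sim(name)
    .fixture_env[[key]] <- list(SD = build_traces(sim[[which]], "SD"),
                                LD = build_traces(sim[[which]], "LD"))
  }
  .fixture_env[[key]]
}

# reduced-budget optimizer settings for test-scale fits
fast_config <- function(n_restarts = 1, base_seed = 1, max_gen = 350,
                        pop_factor = 12, h = 0.15, ...) {
  fit_config(n_restarts = n_restarts, base_seed = base_seed, h = h,
             de = list(pop_factor = pop_factor, max_gen = max_gen,
                       tol = 1e-8), ...)
}

# a tiny hand-made dataset: two genes, simple numbers
toy_dataset <- function() {
  as_expression_data(tibble::tibble(
    gene = rep(c("AP1", "LFY"), each = 3),
    condition = "SD",
    time = rep(c(8, 10, 12), 2),
    mean = c(1, 2, 4, 3, 3, 3),
    sd = c(1, 1, 1, 0.5, 0.5, 0.5)))
}

# random admissible parameter vector inside data-scale bounds
random_params <- function(spec, bounds) {
  th <- setNames(
    bounds$lower + runif(nrow(bounds)) * (bounds$upper - bounds$lower),
    bounds$term)
  # keep Hill exponents moderate so test problems stay smooth
  th[grepl("^n", names(th))] <- runif(sum(grepl("^n", names(th))), 1, 3)
  th
}
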