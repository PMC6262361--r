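test_that("wRSS matches its definition on hand-checkable cases", {
  dat <- toy_dataset()
  # model equal to data -> zero cost
  sol <- tibble::tibble(condition = "SD",
                        gene = rep(c("AP1", "LFY"), each = 3),
                        time = rep(c(8, 10, 12), 2),
                        value = dat$mean)
  expect_equal(wrss(sol, dat, targets = c("AP1", "LFY")), 0)

  # one point, residual 2, sigma 1 -> 4
  d1 <- dat[dat$gene == "AP1" & dat$time == 8, ]
  s1 <- tibble::tibble(condition = "SD", gene = "AP1", time = 8,
                       value = d1$mean + 2)
  expect_equal(wrss(s1, d1, targets = "AP1"), 4)

  # every residual equal to sigma -> one unit per data point
  sol_sd <- sol
  sol_sd$value <- dat$mean + dat$sd
  expect_equal(wrss(sol_sd, dat, targets = c("AP1", "LFY")), 6)
})

test_that("wRSS is additive over conditions and invariant to row order", {
  sim <- fx_sim("h0_baseline")
  th <- fx_suite()$h0_baseline$true_params
  sp <- model_spec("H0")
  sols <- lapply(c("SD", "LD"), function(cond) {
    tr <- build_traces(sim$data, cond)
    tt <- sort(unique(c(seq(0, 20, 0.5), unique(sim$data$time))))
    s <- solve_grn(sp, th, tr, times = tt, method = "exp", h = 0.02)
    s$condition <- cond
    s
  })
  both <- wrss(sols, sim$data)
  expect_equal(wrss(sols, sim$data, "SD") + wrss(sols, sim$data, "LD"), both)
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  expect_equal(wrss(sols, shuffled), both)
  # missing solution values raise an alignment error
  clipped <- lapply(sols, function(s) s[s$time < 18, ])
  expect_error(wrss(clipped, sim$data), class = "flornet_alignment_error")
})

test_that("covariance penalty behaves as documented", {
  dat <- toy_dataset()
  sol <- tibble::tibble(condition = "SD",
                        gene = rep(c("AP1", "LFY"), each = 3),
                        time = rep(c(8, 10, 12), 2),
                        value = rep(5, 6)) # constant model
  expect_equal(wrss_with_penalty(sol, dat, targets = c("AP1", "LFY")),
               wrss(sol, dat, targets = c("AP1", "LFY")))
  # weight zero reduces to plain wrss for any model
  sol2 <- sol; sol2$value <- c(1, 3, 2, 4, 1, 5)
  expect_equal(wrss_with_penalty(sol2, dat, weight = 0,
                                 targets = c("AP1", "LFY")),
               wrss(sol2, dat, targets = c("AP1", "LFY")))
  # exact model: penalty equals the summed data variances
  sol3 <- sol; sol3$value <- dat$mean
  expect_equal(wrss_with_penalty(sol3, dat, targets = c("AP1", "LFY")),
               var(dat$mean[dat$gene == "AP1"]) +
                 var(dat$mean[dat$gene == "LFY"]))
})

test_that("default bounds contain the generating truth", {
  sim <- fx_sim("h0_baseline")
  th <- fx_suite()$h0_baseline$true_params
  b <- default_parameter_bounds(sim$data, model_spec("H0"))
  expect_setequal(b$term, names(th))
  i <- match(b$term, names(th))
  expect_true(all(th[i] >= b$lower & th[i] <= b$upper))
})

test_that("differential evolution finds the optimum of a known function", {
  # separable quadratic with known minimum as an enumeration-free oracle
  target <- c(0.3, -1.2, 2.5)
  fn <- function(P) colSums((t(P) - target)^2)
  set.seed(1)
  res <- flornet:::de_optimize(fn, lower = rep(-5, 3), upper = rep(5, 3),
                               de = list(pop_factor = 15, F = c(0.5, 1),
                                         CR = 0.7, max_gen = 300,
                                         tol = 1e-12))
  expect_lt(res$value, 1e-6)
  expect_equal(res$par, target, tolerance = 1e-2)
})

test_that("fits are deterministic given a seed", {
  sim <- fx_sim("h0_baseline")
  cfg <- fast_config(max_gen = 30)
  f1 <- fit_grn(sim$data, model_spec("H0"), cfg, seed = 5)
  f2 <- fit_grn(sim$data, model_spec("H0"), cfg, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$cost, f2$cost)
  f3 <- fit_grn(sim$data, model_spec("H0"), cfg, seed = 6)
  expect_false(identical(f1$params, f3$params))
})

test_that("cost bookkeeping: total equals the sum over conditions", {
  sim <- fx_sim("h0_baseline")
  fit <- fit_grn(sim$data, model_spec("H0"), fast_config(max_gen = 40),
                 seed = 2)
  expect_equal(fit$cost, sum(fit$cost_by_condition), tolerance = 1e-8)
  expect_named(fit$cost_by_condition, c("SD", "LD"))
})

test_that("a one-free-parameter fit matches a brute-force grid scan", {
  sim <- fx_sim("h0_baseline")
  truth <- fx_suite()$h0_baseline$true_params
  sp <- model_spec("H0")
  b <- default_parameter_bounds(sim$data, sp)
  # freeze everything at truth except lambda1 by collapsing its box
  i <- match(names(truth), b$term)
  b$lower[i] <- truth
  b$upper[i] <- truth
  j <- b$term == "lambda1"
  b$lower[j] <- 0.05
  b$upper[j] <- 2
  cfg <- fast_config(max_gen = 150)
  cfg$bounds <- b
  fit <- fit_grn(sim$data, sp, cfg, seed = 3)

  # brute-force scan of the same 1-d slice using the public objective
  scan <- vapply(seq(0.05, 2, length.out = 600), function(l1) {
    th <- truth
    th["lambda1"] <- l1
    tr <- build_traces(sim$data, "SD")
    tt <- sort(unique(c(seq(0, 20, 0.5), unique(sim$data$time))))
    s_sd <- solve_grn(sp, th, tr, times = tt, method = "exp", h = 0.02)
    s_sd$condition <- "SD"
    tr2 <- build_traces(sim$data, "LD")
    s_ld <- solve_grn(sp, th, tr2, times = tt, method = "exp", h = 0.02)
    s_ld$condition <- "LD"
    wrss(list(s_sd, s_ld), sim$data)
  }, numeric(1))
  grid_best <- seq(0.05, 2, length.out = 600)[which.min(scan)]
  expect_equal(fit$params[["lambda1"]], grid_best, tolerance = 0.01)
})

test_that("ensembles are deterministic, tidy, and restart-indexed", {
  sim <- fx_sim("h0_baseline")
  cfg <- fast_config(n_restarts = 3, base_seed = 9, max_gen = 25)
  e1 <- fit_ensemble(sim$data, model_spec("H0"), cfg)
  e2 <- fit_ensemble(sim$data, model_spec("H0"), cfg)
  expect_identical(lapply(e1$fits, `[[`, "params"),
                   lapply(e2$fits, `[[`, "params"))
  expect_length(e1$fits, 3)
  expect_identical(vapply(e1$fits, `[[`, numeric(1), "seed"), 9 + 1:3 + 0)
  td <- tidy(e1)
  expect_setequal(unique(td$member), 1:3)
  expect_setequal(unique(td$term), param_names(model_spec("H0")))
  gl <- glance(e1)
  expect_equal(gl$cost, ensemble_costs(e1))
  # single-restart ensemble equals fit_grn with the same seed
  e3 <- fit_ensemble(sim$data, model_spec("H0"),
                     fast_config(n_restarts = 1, base_seed = 9,
                                 max_gen = 25))
  f <- fit_grn(sim$data, model_spec("H0"), cfg, seed = 10)
  expect_identical(e3$fits[[1]]$params, f$params)
})

test_that("ensemble dispersion shrinks relative to uniform draws from the box", {
  sim <- fx_sim("h0_baseline")
  cfg <- fast_config(n_restarts = 8, base_seed = 21, max_gen = 120)
  ens <- fit_ensemble(sim$data, model_spec("H0"), cfg)
  b <- default_parameter_bounds(sim$data, model_spec("H0"))
  est <- tidy(ens)
  # identifiable decay rates: ensemble spread well below the prior spread
  for (p in c("lambda1", "lambda2", "lambda3")) {
    post_sd <- sd(est$estimate[est$term == p])
    prior_sd <- diff(range(b$lower[b$term == p], b$upper[b$term == p])) /
      sqrt(12)
    expect_lt(post_sd, prior_sd)
  }
})
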