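test_that("free-parameter enumeration matches the published composition", {
  h0 <- model_spec("H0")
  expect_identical(count_free_parameters(h0), 31L)
  nm <- param_names(h0)
  expect_identical(sum(grepl("^v", nm)), 7L)
  expect_identical(sum(grepl("^K", nm)), 9L)
  expect_identical(sum(grepl("^n", nm)), 9L)
  expect_identical(sum(grepl("^lambda", nm)), 5L)
  expect_true("tau" %in% nm)
  for (g in setdiff(ft_genes(), "FTa3")) {
    expect_identical(count_free_parameters(model_spec("H1", g)), 31L)
    expect_identical(count_free_parameters(model_spec("H2", g)), 37L)
  }
  nm2 <- param_names(model_spec("H2", "FTb"))
  expect_identical(sum(grepl("^v", nm2)), 9L)
  expect_identical(sum(grepl("^K", nm2)), 11L)
})

test_that("hypothesis specs validate their singled-out gene", {
  expect_error(model_spec("H1"), class = "flornet_spec_error")
  expect_error(model_spec("H2", "NOTAGENE"), class = "flornet_spec_error")
  expect_null(model_spec("H0", singled_ft = "FTb")$singled_ft)
})

test_that("parameter admissibility is enforced", {
  th <- example_truth_params()
  sp <- model_spec("H0")
  expect_silent(validate_params(th, sp))
  bad <- th; bad["K1"] <- -1
  expect_error(validate_params(bad, sp), class = "flornet_parameter_error")
  bad <- th; bad["n3"] <- 0.5
  expect_error(validate_params(bad, sp), class = "flornet_parameter_error")
  bad <- th; bad["tau"] <- -0.1
  expect_error(validate_params(bad, sp), class = "flornet_parameter_error")
  expect_error(validate_params(th[-1], sp), class = "flornet_parameter_error")
})

test_that("Hill factors respect their ranges", {
  x <- c(0, 10^runif(50, -3, 4))
  for (n in c(1, 2, 4.5)) {
    a <- hill_act(x, K = 7, n = n)
    r <- hill_rep(x, K = 7, n = n)
    expect_true(all(a >= 0 & a < 1))
    expect_true(all(r > 0 & r <= 1))
    expect_equal(a + r, rep(1, length(x)))
    expect_equal(hill_act(7, 7, n), 0.5)
  }
})

test_that("FT input reproduces limiting cases per hypothesis", {
  sim <- fx_sim("h0_baseline")
  tr <- build_traces(sim$data, "LD")
  th <- example_truth_params()

  # zero FT traces give zero input under every hypothesis
  zero_ft <- sim$data
  zero_ft$mean[zero_ft$gene %in% ft_genes()] <- 0
  tr0 <- build_traces(as_expression_data(zero_ft), "LD")
  tt <- c(8, 12, 16)
  expect_equal(ft_input(model_spec("H0"), th, tr0, tt, "LFY"), rep(0, 3))
  th2 <- c(th, v8 = 50, v9 = 50, K10 = 1000, K11 = 1000, n10 = 1, n11 = 1)
  expect_equal(ft_input(model_spec("H2", "FTb"), th2, tr0, tt, "AP1"),
               rep(0, 3))

  # half-saturation: constant u_FD * sum(FT) == K8 with n8 = 1 gives v6/2
  dconst <- as_expression_data(tibble::tibble(
    gene = rep(c("TFL1a", "TFL1c", "FD", "LFY", "AP1", "FTb"), each = 2),
    condition = "SD", time = rep(c(8, 20), 6),
    mean = c(0, 0, 0, 0, 2, 2, 0, 0, 0, 0, 3, 3), sd = 0.1))
  trc <- build_traces(dconst, "SD", extend_to_zero = character(0))
  th_h <- th
  th_h[c("K8", "n8")] <- c(6, 1) # product = 2 * 3 = 6 = K8
  expect_equal(ft_input(model_spec("H0", ft_genes = "FTb"), th_h, trc,
                        c(8, 14, 20), "LFY"),
               rep(unname(th_h[["v6"]]) / 2, 3), tolerance = 1e-12)

  # H2 with silent singled-out trace reduces to the four-gene bulk term
  silent_ftb <- sim$data
  silent_ftb$mean[silent_ftb$gene == "FTb"] <- 0
  trs <- build_traces(as_expression_data(silent_ftb), "LD")
  h2 <- model_spec("H2", "FTb")
  h0_rest <- model_spec("H0", ft_genes = setdiff(ft_genes(), "FTb"))
  tt <- seq(8, 20, by = 0.5)
  expect_equal(ft_input(h2, th2, trs, tt, "LFY"),
               ft_input(h0_rest, th, trs, tt, "LFY"), tolerance = 1e-12)
})

test_that("right-hand side matches hand evaluations", {
  # constant traces so the forcings are transparent: u_AP1 = 1, rest 0
  d <- as_expression_data(tibble::tibble(
    gene = rep(c("TFL1a", "TFL1c", "FD", "LFY", "AP1", "FTb"), each = 2),
    condition = "SD", time = rep(c(8, 20), 6),
    mean = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0),
    sd = 0.1))
  tr <- build_traces(d, "SD", extend_to_zero = character(0))
  sp <- model_spec("H0", ft_genes = "FTb")
  th <- example_truth_params()
  th[c("v1", "K1", "n1", "lambda1")] <- c(2, 1, 2, 0.5)
  # u_AP1 = 1, u_TFL1a = 1: dTFL1a/dt = 2 * (1/(1+1)) - 0.5 * 1 = 0.5
  dv <- grn_rhs(sp, th, tr, t = 10, state = c(1, 0, 0, 0, 0))
  expect_equal(unname(dv[["TFL1a"]]), 0.5)

  # zero traces, zero state: only unrepressed TFL1 synthesis survives
  d0 <- as_expression_data(tibble::tibble(
    gene = rep(c("TFL1a", "TFL1c", "FD", "LFY", "AP1", "FTb"), each = 2),
    condition = "SD", time = rep(c(8, 20), 6), mean = 0, sd = 0.1))
  tr0 <- build_traces(d0, "SD", extend_to_zero = character(0))
  dv0 <- grn_rhs(sp, th, tr0, t = 10, state = rep(0, 5))
  expect_equal(unname(dv0), c(th[["v1"]], th[["v2"]], 0, 0, 0))

  # non-finite states are rejected with context
  expect_error(grn_rhs(sp, th, tr, 10, c(NaN, 0, 0, 0, 0)),
               class = "flornet_numerical_error")
})

test_that("solver reproduces closed-form decay and fixed points", {
  d0 <- as_expression_data(tibble::tibble(
    gene = rep(c("TFL1a", "TFL1c", "FD", "LFY", "AP1", "FTb"), each = 2),
    condition = "SD", time = rep(c(8, 20), 6), mean = 0, sd = 0.1))
  tr0 <- build_traces(d0, "SD", extend_to_zero = character(0))
  sp <- model_spec("H0", ft_genes = "FTb")
  th <- example_truth_params()
  th[grepl("^v", names(th))] <- 1e-9          # negligible synthesis
  th[grepl("^lambda", names(th))] <- 1        # unit decay
  tt <- seq(0, 6, by = 0.5)
  sol <- solve_grn(sp, th, tr0, times = tt, init = rep(1, 5))
  for (g in target_genes()) {
    expect_equal(sol$value[sol$gene == g], exp(-tt), tolerance = 1e-5)
  }

  # steady state of the unrepressed TFL1a equation is v1 / lambda1
  th2 <- example_truth_params()
  sol2 <- solve_grn(sp, th2, tr0, times = seq(0, 80, by = 1),
                    init = rep(0, 5))
  final <- sol2$value[sol2$gene == "TFL1a" & sol2$time == 80]
  expect_equal(final, th2[["v1"]] / th2[["lambda1"]], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("solve agrees with an independent RK4 oracle on random models", {
  sim <- fx_sim("h0_baseline")
  tr <- build_traces(sim$data, "SD")
  sp <- model_spec("H0")
  bounds <- default_parameter_bounds(sim$data, sp)
  set.seed(7)
  tt <- seq(0, 20, by = 0.5)
  for (rep in 1:10) {
    th <- random_params(sp, bounds)
    init <- initial_state(tr)
    sol <- solve_grn(sp, th, tr, times = tt, method = "lsoda")
    ora <- oracle_rk4(sp, th, tr, tt, init, h = 0.005)
    for (g in target_genes()) {
      got <- sol$value[sol$gene == g]
      ref <- ora[, g]
      scale <- max(abs(ref), 1e-8)
      expect_lt(max(abs(got - ref)) / scale, 1e-4)
    }
    # the exponential fast path agrees too
    sol_e <- solve_grn(sp, th, tr, times = tt, method = "exp", h = 0.005)
    for (g in target_genes()) {
      scale <- max(abs(ora[, g]), 1e-8)
      expect_lt(max(abs(sol_e$value[sol_e$gene == g] - ora[, g])) / scale,
                1e-4)
    }
  }
})

test_that("joint solve equals the four-subsystem decomposition", {
  sim <- fx_sim("h0_baseline")
  tr <- build_traces(sim$data, "LD")
  sp <- model_spec("H0")
  bounds <- default_parameter_bounds(sim$data, sp)
  set.seed(11)
  tt <- seq(0, 20, by = 0.5)
  for (rep in 1:3) {
    th <- random_params(sp, bounds)
    joint <- solve_grn(sp, th, tr, times = tt, method = "lsoda")
    init <- initial_state(tr)
    # single-gene subsystems integrated alone via deSolve
    lam <- c(TFL1a = th[["lambda1"]], TFL1c = th[["lambda2"]],
             FD = th[["lambda3"]], LFY = th[["lambda4"]],
             AP1 = th[["lambda5"]])
    for (block in list("TFL1a", "TFL1c", "FD", c("LFY", "AP1"))) {
      idx <- match(block, target_genes())
      dfun <- function(t, y, parms) {
        full <- numeric(5)
        full[idx] <- y
        list(oracle_rhs(sp, th, tr, t, full)[idx])
      }
      sub <- deSolve::ode(y = init[idx], times = tt, func = dfun,
                          parms = NULL, rtol = 1e-8, atol = 1e-10)
      for (j in seq_along(block)) {
        g <- block[j]
        ref <- unname(sub[, j + 1])
        got <- joint$value[joint$gene == g]
        expect_lt(max(abs(got - ref)) / max(abs(ref), 1e-8), 1e-4)
      }
    }
  }
})

test_that("increasing an FT trace cannot decrease LFY or AP1", {
  sim <- fx_sim("h0_baseline")
  sp <- model_spec("H0")
  th <- example_truth_params()
  tr <- build_traces(sim$data, "SD")
  boosted <- sim$data
  sel <- boosted$gene == "FTb" & boosted$condition == "SD"
  boosted$mean[sel] <- boosted$mean[sel] * 2
  trb <- build_traces(as_expression_data(boosted), "SD")
  tt <- seq(0, 20, by = 0.25)
  base <- solve_grn(sp, th, tr, times = tt)
  up <- solve_grn(sp, th, trb, times = tt)
  for (g in c("LFY", "AP1")) {
    expect_true(all(up$value[up$gene == g] >=
                      base$value[base$gene == g] - 1e-8))
  }
})
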