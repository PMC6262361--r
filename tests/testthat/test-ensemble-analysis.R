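const_traces <- function(values, condition = "SD") {
  rows <- purrr::imap_dfr(values, function(v, g)
    tibble::tibble(gene = g, condition = condition,
                   time = c(8, 20), mean = v, sd = 0.1))
  build_traces(as_expression_data(rows), condition,
               extend_to_zero = character(0))
}

test_that("averaged regulation functions hit exact limiting values", {
  th <- example_truth_params()
  sp <- model_spec("H0", ft_genes = "FTb")
  ens <- as_param_ensemble(th, sp)

  # repressor with regulator identically zero -> average exactly 1
  tr0 <- const_traces(c(TFL1a = 0, TFL1c = 0, FD = 0, LFY = 0, AP1 = 0,
                        FTb = 0))
  rs0 <- average_regulation_functions(ens, list(SD = tr0))
  expect_equal(rs0$value[rs0$edge == "AP1 -| TFL1a"], 1)
  expect_equal(rs0$value[rs0$edge == "TFL1-FD -| LFY"], 1)
  # activator of a zero regulator -> 0
  expect_equal(rs0$value[rs0$edge == "LFY -> FD"], 0)

  # activator with regulator pinned at K and n = 1 -> exactly 0.5
  th2 <- th
  th2[c("K3", "n3")] <- c(40, 1)
  tr1 <- const_traces(c(TFL1a = 0, TFL1c = 0, FD = 0, LFY = 40, AP1 = 0,
                        FTb = 0))
  rs1 <- average_regulation_functions(as_param_ensemble(th2, sp),
                                      list(SD = tr1))
  expect_equal(rs1$value[rs1$edge == "LFY -> FD"], 0.5)

  # constant regulator: time average equals the pointwise Hill value
  x0 <- 123
  tr2 <- const_traces(c(TFL1a = 0, TFL1c = 0, FD = 0, LFY = 0, AP1 = x0,
                        FTb = 0))
  rs2 <- average_regulation_functions(ens, list(SD = tr2))
  expect_equal(rs2$value[rs2$edge == "AP1 -| TFL1a"],
               hill_rep(x0, th[["K1"]], th[["n1"]]))
  expect_equal(rs2$value[rs2$edge == "AP1 -> LFY"],
               hill_act(x0, th[["K4"]], th[["n4"]]))
})

test_that("averages are bounded by pointwise extremes and need members", {
  sim <- fx_sim("h0_baseline")
  trl <- fx_traces("h0_baseline", "truth")
  th <- fx_suite()$h0_baseline$true_params
  rs <- average_regulation_functions(as_param_ensemble(th, model_spec("H0")),
                                     trl)
  expect_true(all(rs$value >= 0 & rs$value <= 1))
  expect_identical(nrow(rs), 9L)
  empty <- as_param_ensemble(list(), model_spec("H0"))
  expect_error(average_regulation_functions(empty, trl),
               class = "flornet_insufficient_data_error")
})

test_that("H2 specs expose the singled-out edges", {
  sim <- fx_sim("h0_baseline")
  trl <- fx_traces("h0_baseline", "truth")
  th <- example_truth_params()
  th2 <- c(th, v8 = 50, v9 = 50, K10 = 1000, K11 = 1000, n10 = 1, n11 = 1)
  rs <- average_regulation_functions(
    as_param_ensemble(th2, model_spec("H2", "FTb")), trl)
  expect_identical(nrow(rs), 11L)
  expect_true(any(grepl("FTb-FD", rs$edge)))
})

test_that("analytic Hill derivatives match central finite differences", {
  set.seed(5)
  for (rep in 1:20) {
    x <- 10^runif(1, -1, 3)
    K <- 10^runif(1, -1, 3)
    n <- runif(1, 1, 6)
    eps <- x * 1e-6
    fd_act <- (hill_act(x + eps, K, n) - hill_act(x - eps, K, n)) / (2 * eps)
    expect_equal(flornet:::hill_act_deriv(x, K, n), fd_act,
                 tolerance = 1e-6)
    fd_rep <- (hill_rep(x + eps, K, n) - hill_rep(x - eps, K, n)) / (2 * eps)
    expect_equal(flornet:::hill_rep_deriv(x, K, n), fd_rep,
                 tolerance = 1e-6)
  }
  # hand value: activator slope at x = K with n = 1 is 1/(4K)
  expect_equal(flornet:::hill_act_deriv(7, 7, 1), 1 / 28)
})

test_that("Jacobian sensitivities expose saturation and active regulation", {
  th <- example_truth_params()
  sp <- model_spec("H0", ft_genes = "FTb")
  # saturated repressor (u >> K): sensitivity tends to zero
  tr_hi <- const_traces(c(TFL1a = 0, TFL1c = 0, FD = 0, LFY = 0,
                          AP1 = 1e6, FTb = 0))
  js <- jacobian_sensitivity(as_param_ensemble(th, sp), list(SD = tr_hi),
                             "AP1 -| TFL1a")
  expect_lt(js$sensitivity, 1e-6)
  # activator at u = K, n = 1: slope v/(4K), gate at 1 when complex = 0
  th3 <- th
  th3[c("K4", "n4")] <- c(50, 1)
  tr_mid <- const_traces(c(TFL1a = 0, TFL1c = 0, FD = 0, LFY = 0,
                           AP1 = 50, FTb = 0))
  js2 <- jacobian_sensitivity(as_param_ensemble(th3, sp), list(SD = tr_mid),
                              "AP1 -> LFY")
  expect_equal(js2$sensitivity, th3[["v4"]] / (4 * 50), tolerance = 1e-10,
               ignore_attr = TRUE)
  # negligible synthesis rate silences the edge
  th4 <- th3
  th4["v4"] <- 1e-12
  js3 <- jacobian_sensitivity(as_param_ensemble(th4, sp), list(SD = tr_mid),
                              "AP1 -> LFY")
  expect_lt(js3$sensitivity, 1e-10)
  expect_error(jacobian_sensitivity(as_param_ensemble(th, sp),
                                    list(SD = tr_mid), "NOPE -> NOPE"),
               class = "flornet_lookup_error")
})

test_that("clustering separates a constructed bimodal ensemble", {
  trl <- fx_traces("h0_baseline", "truth")
  th <- fx_suite()$h0_baseline$true_params
  sp <- model_spec("H0")
  # 45 members near truth, 5 outliers whose K1 kills the repression edge
  members <- c(
    lapply(1:45, function(i) {
      x <- th
      x["K1"] <- th[["K1"]] * exp(rnorm(1, 0, 0.01))
      x
    }),
    lapply(1:5, function(i) {
      x <- th
      x["K1"] <- th[["K1"]] * 2000 # repression saturated at 1
      x
    }))
  set.seed(8)
  ens <- as_param_ensemble(members, sp)
  cl <- cluster_parameters(ens, trl, parameters = c("K1", "K2"))
  out_k1 <- cl$assignments[cl$assignments$parameter == "K1" &
                             cl$assignments$cluster == "outlying", ]
  expect_identical(sort(out_k1$member), 46:50)
  # permutation invariance of the assignment
  perm <- sample(length(members))
  cl_p <- cluster_parameters(as_param_ensemble(members[perm], sp), trl,
                             parameters = c("K1", "K2"))
  out_p <- cl_p$assignments[cl_p$assignments$parameter == "K1" &
                              cl_p$assignments$cluster == "outlying", ]
  expect_identical(sort(perm[out_p$member]), 46:50)
})

test_that("identical members form a single zero-spread cluster", {
  trl <- fx_traces("h0_baseline", "truth")
  th <- fx_suite()$h0_baseline$true_params
  ens <- as_param_ensemble(lapply(1:6, function(i) th), model_spec("H0"))
  cl <- cluster_parameters(ens, trl, parameters = c("K1", "K2"))
  expect_setequal(unique(cl$assignments$cluster), "main")
  expect_true(all(cl$summary$sd == 0))
  expect_error(cluster_parameters(as_param_ensemble(th, model_spec("H0")),
                                  trl),
               class = "flornet_insufficient_data_error")
})
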