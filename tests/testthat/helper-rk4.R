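# Independent fixed-step RK4 integrator with its own right-hand-side
# implementation, used as the integration oracle.

oracle_rhs <- function(spec, th, traces, t, state) {
  act <- function(x, K, n) { x <- max(x, 0); x^n / (K^n + x^n) }
  rep_ <- function(x, K, n) { x <- max(x, 0); K^n / (K^n + x^n) }
  tr <- function(g, tt) trace_eval(traces, g, tt)
  ap1 <- tr("AP1", t); lfy <- tr("LFY", t); fd <- tr("FD", t)
  cplx <- fd * (tr("TFL1a", t) + tr("TFL1c", t))
  tau <- th[["tau"]]
  ftsum <- function(genes) sum(vapply(genes, function(g) tr(g, t - tau),
                                      numeric(1)))
  if (spec$hypothesis == "H0") {
    pb <- fd * ftsum(spec$ft_genes)
    fL <- th[["v6"]] * act(pb, th[["K8"]], th[["n8"]])
    fA <- th[["v7"]] * act(pb, th[["K9"]], th[["n9"]])
  } else if (spec$hypothesis == "H1") {
    pb <- fd * ftsum(spec$singled_ft)
    fL <- th[["v6"]] * act(pb, th[["K8"]], th[["n8"]])
    fA <- th[["v7"]] * act(pb, th[["K9"]], th[["n9"]])
  } else {
    pb <- fd * ftsum(setdiff(spec$ft_genes, spec$singled_ft))
    ps <- fd * ftsum(spec$singled_ft)
    fL <- th[["v6"]] * act(pb, th[["K8"]], th[["n8"]]) +
      th[["v7"]] * act(ps, th[["K9"]], th[["n9"]])
    fA <- th[["v8"]] * act(pb, th[["K10"]], th[["n10"]]) +
      th[["v9"]] * act(ps, th[["K11"]], th[["n11"]])
  }
  c(th[["v1"]] * rep_(ap1, th[["K1"]], th[["n1"]]) - th[["lambda1"]] * state[1],
    th[["v2"]] * rep_(ap1, th[["K2"]], th[["n2"]]) - th[["lambda2"]] * state[2],
    th[["v3"]] * act(lfy, th[["K3"]], th[["n3"]]) - th[["lambda3"]] * state[3],
    (th[["v4"]] * act(ap1, th[["K4"]], th[["n4"]]) + fL) *
      rep_(cplx, th[["K5"]], th[["n5"]]) - th[["lambda4"]] * state[4],
    (th[["v5"]] * act(lfy, th[["K6"]], th[["n6"]]) + fA) *
      rep_(cplx, th[["K7"]], th[["n7"]]) - th[["lambda5"]] * state[5])
}

oracle_rk4 <- function(spec, th, traces, t_out, init, h = 0.005) {
  t_end <- max(t_out)
  nt <- ceiling(t_end / h)
  h <- t_end / nt
  tt <- seq(0, t_end, by = h)
  u <- matrix(NA_real_, nt + 1, 5)
  u[1, ] <- init
  for (i in seq_len(nt)) {
    t <- tt[i]
    y <- u[i, ]
    k1 <- oracle_rhs(spec, th, traces, t, y)
    k2 <- oracle_rhs(spec, th, traces, t + h / 2, y + h / 2 * k1)
    k3 <- oracle_rhs(spec, th, traces, t + h / 2, y + h / 2 * k2)
    k4 <- oracle_rhs(spec, th, traces, t + h, y + h * k3)
    u[i + 1, ] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- apply(u, 2, function(col) approx(tt, col, xout = t_out)$y)
  colnames(out) <- target_genes()
  out
}
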