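test_that("rhs of the all-free, empty state only transcribes", {
  p <- param_preset("ode_standard", alpha = 0.1)
  y <- ode_state(rep(5, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  dy <- ode_rhs(y, p)
  for (i in 0:2) {
    expect_equal(dy[[paste0("G", i)]], 0)
    expect_equal(dy[[paste0("M", i)]], 0.5)
    expect_equal(dy[[paste0("P", i)]], 0)
    expect_equal(dy[[paste0("Gs", i)]], 0)
  }
})

test_that("rhs respects the cyclic symmetry of the ring", {
  p <- param_preset("ode_standard")
  set.seed(1)
  for (k in 1:5) {
    v <- runif(4, 0, 4)
    y <- ode_state(rep(v[1], 3), rep(v[2], 3), rep(v[3], 3), rep(v[4], 3))
    dy <- ode_rhs(y, p)
    for (comp in c("G", "M", "P", "Gs")) {
      expect_equal(dy[[paste0(comp, 1)]], dy[[paste0(comp, 0)]])
      expect_equal(dy[[paste0(comp, 2)]], dy[[paste0(comp, 0)]])
    }
  }
})

test_that("rhs matches an independent transcription of the equations", {
  p <- param_preset("ode_standard")
  set.seed(2)
  for (k in 1:20) {
    G <- runif(3, 0, 5); Gs <- runif(3, 0, 5 - G)
    y <- ode_state(G, runif(3, 0, 50), runif(3, 0, 2000), Gs)
    expect_equal(ode_rhs(y, p), oracle_rhs(y, p), tolerance = 1e-12)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  p <- param_preset("ode_standard")
  set.seed(3)
  for (k in 1:20) {
    G <- runif(3, 0, 5); Gs <- runif(3, 0, 5 - G)
    y <- ode_state(G, runif(3, 0, 50), runif(3, 0, 2000), Gs)
    J <- ode_jacobian(y, p)
    Jfd <- matrix(0, 12, 12)
    for (c in 1:12) {
      h <- 1e-5 * max(1, abs(y[c]))
      e <- numeric(12); e[c] <- h
      Jfd[, c] <- (ode_rhs(y + e, p) - ode_rhs(y - e, p)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("Jacobian commutes with the cyclic rotation at the symmetric point", {
  p <- param_preset("ode_standard")
  J <- ode_jacobian(steady_state(p), p)
  # rotate gene indices i -> i+1 (blocks of 4 state components)
  perm <- c(5:12, 1:4)
  R <- diag(12)[perm, ]
  expect_equal(unname(R %*% J), unname(J %*% R), tolerance = 1e-12)
})

test_that("decoupled (k_on = 0) Jacobian has the closed-form spectrum", {
  p <- param_preset("ode_standard")
  p$k_on <- 0
  y <- steady_state(p)
  ev <- sort(Re(eigen(ode_jacobian(y, p), only.values = TRUE)$values))
  # per gene: -1/tau_m (mRNA), -1/tau_p (protein), and the two roots of the
  # decoupled (G, Gs) binding block
  # lambda^2 + (k_off + k_off2) lambda + k_off * k_off2 = 0
  s <- p$k_off + p$k_off2
  disc <- sqrt(s^2 - 4 * p$k_off * p$k_off2)
  expected <- sort(rep(c(-1 / p$tau_m, -1 / p$tau_p,
                         (-s + disc) / 2, (-s - disc) / 2), each = 3))
  expect_equal(ev, expected, tolerance = 1e-10)
})

test_that("symmetric steady state solves the system to tight residual", {
  for (tp in c(1e3, 3e5, 1e6)) {
    p <- param_preset("ode_standard", tau_p = tp)
    ss <- steady_state(p)
    expect_equal(ss[["P0"]], ss[["P1"]])
    expect_equal(ss[["P0"]], ss[["P2"]])
    expect_lt(max(abs(ode_rhs(ss, p))), 1e-10 * p$g_t)
  }
})

test_that("k_on -> 0 steady state approaches the uncoupled closed form", {
  p <- param_preset("ode_standard")
  p$k_on <- 0
  ss <- steady_state(p)
  expect_equal(ss[["M0"]], p$alpha * p$g_t * p$tau_m)
  expect_equal(ss[["P0"]], p$alpha * p$beta * p$g_t * p$tau_m * p$tau_p)
  expect_equal(ss[["G0"]], p$g_t)
})

test_that("RK4 integration converges under step halving", {
  p <- param_preset("ode_standard", tau_p = 1e3)
  y0 <- steady_state(p)
  y0["P0"] <- y0["P0"] * 1.2
  t_end <- 2e4
  f1 <- integrate_ode(p, y0, t_end = t_end, dt = 1, record_every = t_end)
  f2 <- integrate_ode(p, y0, t_end = t_end, dt = 0.5, record_every = 2 * t_end)
  a <- as.numeric(f1[nrow(f1), -1]); b <- as.numeric(f2[nrow(f2), -1])
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-4)
})

test_that("symmetric initial conditions stay symmetric under the flow", {
  p <- param_preset("ode_standard", tau_p = 1e3)
  y0 <- ode_state(rep(5, 3), rep(1, 3), rep(10, 3), rep(0, 3))
  tr <- integrate_ode(p, y0, t_end = 5e3, record_every = 100)
  expect_equal(tr$P0, tr$P1, tolerance = 1e-12)
  expect_equal(tr$G0, tr$G2, tolerance = 1e-12)
  expect_equal(tr$Gs1, tr$Gs2, tolerance = 1e-12)
})

test_that("integration preserves positivity and gene conservation", {
  p <- param_preset("ode_standard", tau_p = 1e3)
  y0 <- ode_state(rep(5, 3), rep(0, 3), c(1000, 0, 0), rep(0, 3))
  tr <- integrate_ode(p, y0, t_end = 1e5, record_every = 100)
  tol <- 1e-6 * p$g_t
  for (i in 0:2) {
    expect_gt(min(tr[[paste0("P", i)]]), -tol)
    expect_gt(min(tr[[paste0("G", i)]]), -tol)
    expect_lt(max(tr[[paste0("G", i)]] + tr[[paste0("Gs", i)]]), p$g_t + tol)
  }
})

test_that("classify_point flags the decoupled system as stable", {
  p <- param_preset("ode_standard")
  p$k_on <- 0
  for (a in c(0.01, 0.1, 1)) {
    for (tp in c(1e3, 1e5)) {
      expect_equal(classify_point(a, tp, p)$class, "stable")
    }
  }
})

test_that("limit-cycle envelope collapses on a stable fixed point", {
  # alpha = 0.001, tau_p = 1000 lies outside the oscillatory region
  p <- param_preset("ode_standard", alpha = 0.001, tau_p = 1e3)
  expect_equal(classify_point(0.001, 1e3, p)$class, "stable")
  y0 <- steady_state(p)
  y0["P0"] <- y0["P0"] * 1.2
  tr <- integrate_ode(p, y0, t_end = 2e6, record_every = 1e3)
  env <- limit_cycle_envelope(tr)
  expect_lt((env$max[1] - env$min[1]) / env$max[1], 1e-3)
})

test_that("Hopf boundary points sit on the imaginary axis", {
  p <- param_preset("ode_standard")
  sc <- hopf_scan(c(0.01, 0.1), 10^seq(3, 6, length.out = 7), p)
  expect_gt(nrow(sc$boundary), 0)
  for (k in seq_len(nrow(sc$boundary))) {
    pk <- p
    pk$alpha <- sc$boundary$alpha[k]
    pk$tau_p <- sc$boundary$tau_p[k]
    lam <- eigen(ode_jacobian(steady_state(pk), pk), only.values = TRUE)$values
    lead <- lam[which.max(Re(lam))]
    expect_lt(abs(Re(lead)), 1e-8)
    expect_gt(abs(Im(lead)), 0)
  }
})

test_that("along alpha = 0.1 the oscillatory set is one tau_p interval", {
  p <- param_preset("ode_standard")
  tg <- 10^seq(3, 6, length.out = 13)
  cls <- vapply(tg, function(tp) classify_point(0.1, tp, p)$class,
                character(1))
  osc <- cls == "oscillatory"
  # single contiguous block...
  expect_equal(sum(abs(diff(osc))), 1) # oscillatory from the low end upward
  # ...containing the showcase point tau_p = 3e5
  expect_equal(classify_point(0.1, 3e5, p)$class, "oscillatory")
  expect_true(any(osc))
})

test_that("grid refinement does not move the boundary by more than a cell", {
  p <- param_preset("ode_standard")
  coarse_grid <- 10^seq(3, 6, length.out = 7)
  fine_grid <- 10^seq(3, 6, length.out = 13)
  b1 <- hopf_scan(c(0.1, 0.2), coarse_grid, p)$boundary
  b2 <- hopf_scan(c(0.1, 0.2), fine_grid, p)$boundary
  spacing <- max(diff(log10(coarse_grid)))
  for (a in unique(b1$alpha)) {
    t1 <- sort(b1$tau_p[b1$alpha == a])
    t2 <- sort(b2$tau_p[b2$alpha == a])
    expect_equal(length(t1), length(t2))
    expect_true(all(abs(log10(t1) - log10(t2)) < spacing))
  }
})
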