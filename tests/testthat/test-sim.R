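quiet_params <- function(...) {
  # all-zero-rate parameter set (long lifetimes, no reactions)
  over <- list(...)
  base <- list(alpha = 0, beta = 0, tau_m = 1e12, tau_p = 1e12, k_on = 0,
               k_off = 0, k_off2 = 0, g_t = 2)
  base[names(over)] <- over
  do.call(kinetic_params, base)
}

test_that("initial molecule placement matches the requested totals", {
  lat <- lattice_spec(2, 40)
  lay <- place_uniform(lat, g_t = 5, seed = 1)
  ts <- simulate_circuit(lay, quiet_params(g_t = 5), n_steps = 1,
                         seed = 2, init_mrna = 10, init_protein = 100,
                         record_mrna = TRUE, allow_zero = TRUE)
  expect_equal(as.numeric(ts[1, c("P0", "P1", "P2")]), rep(100, 3))
  expect_equal(as.numeric(ts[1, c("M0", "M1", "M2")]), rep(10, 3))
})

test_that("a zero-rate system stays exactly constant", {
  lat <- lattice_spec(2, 20)
  lay <- place_uniform(lat, g_t = 2, seed = 3)
  ts <- simulate_circuit(lay, quiet_params(), n_steps = 500, seed = 4,
                         init_mrna = 5, init_protein = 50,
                         record_mrna = TRUE, allow_zero = TRUE)
  for (ch in c("P0", "P1", "P2")) expect_true(all(ts[[ch]] == 50))
  for (ch in c("M0", "M1", "M2")) expect_true(all(ts[[ch]] == 5))
})

test_that("identical seeds give bit-identical runs", {
  lat <- lattice_spec(2, 50)
  lay <- place_uniform(lat, g_t = 5, seed = 5)
  p <- param_preset("mc_standard_2d", tau_p = 100)
  a <- simulate_circuit(lay, p, n_steps = 5e3, seed = 77, init_protein = 200,
                        record_mrna = TRUE)
  b <- simulate_circuit(lay, p, n_steps = 5e3, seed = 77, init_protein = 200,
                        record_mrna = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_circuit(lay, p, n_steps = 5e3, seed = 78, init_protein = 200)
  expect_false(identical(a$P0, d$P0))
})

test_that("gene copies are conserved across occupancy states at every step", {
  lat <- lattice_spec(2, 30)
  lay <- place_uniform(lat, g_t = 4, seed = 6)
  # fast binding/unbinding to exercise all occupancy transitions
  p <- kinetic_params(alpha = 0.2, beta = 0.2, tau_m = 20, tau_p = 50,
                      k_on = 1, k_off = 0.05, k_off2 = 0.01, g_t = 4)
  ts <- simulate_circuit(lay, p, n_steps = 2e4, seed = 7, init_protein = 200,
                         record_genes = TRUE)
  for (i in 0:2) {
    tot <- ts[[sprintf("G%d_free", i)]] + ts[[sprintf("G%d_single", i)]] +
      ts[[sprintf("G%d_double", i)]]
    expect_true(all(tot == 4))
  }
  # occupancy actually visits bound states
  expect_gt(sum(ts$G0_single), 0)
  expect_gt(sum(ts$G0_double), 0)
})

test_that("bound proteins are immune to degradation", {
  lat <- lattice_spec(2, 20)
  lay <- place_uniform(lat, g_t = 3, seed = 8)
  # all genes doubly bound, nothing can unbind, very short free lifetime
  p <- quiet_params(g_t = 3, tau_p = 2)
  ts <- simulate_circuit(lay, p, n_steps = 1000, seed = 9, init_mrna = 0,
                         init_protein = 0, init_occupancy = 2,
                         allow_zero = TRUE)
  # each protein type is bound to the 3 copies of its target gene
  for (ch in c("P0", "P1", "P2")) expect_true(all(ts[[ch]] == 6))
})

test_that("only free genes transcribe", {
  lat <- lattice_spec(2, 20)
  lay <- place_uniform(lat, g_t = 3, seed = 10)
  p <- quiet_params(g_t = 3, alpha = 1)
  ts <- simulate_circuit(lay, p, n_steps = 1000, seed = 11, init_mrna = 0,
                         init_protein = 0, init_occupancy = 2,
                         record_mrna = TRUE, allow_zero = TRUE)
  for (ch in c("M0", "M1", "M2")) expect_true(all(ts[[ch]] == 0))
  # control: with free genes the same rates do transcribe
  ts2 <- simulate_circuit(lay, p, n_steps = 100, seed = 11, init_mrna = 0,
                          init_protein = 0, init_occupancy = 0,
                          record_mrna = TRUE, allow_zero = TRUE)
  expect_gt(sum(ts2$M0), 0)
})

test_that("random_walk_step wraps the periodic boundary and can stay put", {
  lat <- lattice_spec(2, 400)
  set.seed(12)
  expect_equal(random_walk_step(c(5, 5), lat, p_move = 0), c(5, 5))
  moves <- t(replicate(200, random_walk_step(c(0, 0), lat, p_move = 1)))
  ok <- matrix(moves %in% c(0, 1, 399), nrow = nrow(moves))
  expect_true(all(rowSums(ok) == 2))
  # all four neighbours reachable, including the wrapped ones
  seen <- unique(apply(moves, 1, paste, collapse = ","))
  expect_setequal(seen, c("1,0", "399,0", "0,1", "0,399"))
})

test_that("free-tracer MSD follows 2 * dim * D * t in 2D and 3D", {
  for (dim in 2:3) {
    m <- tracer_msd(50000, 300, dim = dim, p_move = 1, seed = dim)
    for (tt in c(100, 300)) {
      expect_equal(m$msd[tt], m$expected[tt], tolerance = 0.02)
    }
  }
  # sub-unit movement probability rescales D
  m <- tracer_msd(50000, 200, dim = 2, p_move = 0.4, seed = 9)
  expect_equal(m$msd[200], 2 * 2 * 0.1 * 200, tolerance = 0.03)
})

test_that("recording stride thins the series and keeps step indexing", {
  lat <- lattice_spec(2, 30)
  lay <- place_uniform(lat, g_t = 2, seed = 13)
  p <- param_preset("mc_standard_2d", g_t = 2, tau_p = 50)
  ts <- simulate_circuit(lay, p, n_steps = 1000, burn_in = 100, seed = 14,
                         record_stride = 10, init_protein = 50)
  expect_equal(nrow(ts), 100)
  expect_equal(ts$t[1], 110)
  expect_equal(diff(ts$t), rep(10, 99))
  expect_equal(attr(ts, "stride"), 10)
})

test_that("single-site dynamics match the non-spatial oracle", {
  # on an R = 1 lattice space is irrelevant; an independent count-based
  # Monte-Carlo of the same schedule must give the same stationary means
  p <- kinetic_params(alpha = 0.1, beta = 0.1, tau_m = 10, tau_p = 50,
                      k_on = 0.1, k_off = 0.01, k_off2 = 0.001, g_t = 2)
  lat <- lattice_spec(2, 1)
  lay <- place_uniform(lat, g_t = 2, seed = 15)
  n <- 6e4
  ts <- simulate_circuit(lay, p, n_steps = n, burn_in = 2e3, seed = 16,
                         init_mrna = 0, init_protein = 0, record_mrna = TRUE)
  set.seed(17)
  orc <- oracle_wellmixed(p, n_steps = n + 2e3)
  keep <- (2e3 + 1):(2e3 + n)
  for (i in 1:3) {
    po <- orc$P[keep, i]; ps <- ts[[paste0("P", i - 1)]]
    se <- sqrt(batch_se(po)^2 + batch_se(ps)^2)
    expect_lt(abs(mean(po) - mean(ps)), 3 * se + 1e-9)
    mo <- orc$M[keep, i]; ms <- ts[[paste0("M", i - 1)]]
    se_m <- sqrt(batch_se(mo)^2 + batch_se(ms)^2)
    expect_lt(abs(mean(mo) - mean(ms)), 3 * se_m + 1e-9)
  }
})

test_that("with k_on = 0 the lattice means match the ODE fixed point", {
  p <- kinetic_params(alpha = 0.1, beta = 0.1, tau_m = 20, tau_p = 100,
                      k_on = 0, k_off = 1e-3, k_off2 = 1e-5, g_t = 3)
  lat <- lattice_spec(2, 10)
  lay <- place_uniform(lat, g_t = 3, seed = 18)
  ts <- simulate_circuit(lay, p, n_steps = 1e5, burn_in = 3e3, seed = 19,
                         init_mrna = 0, init_protein = 0,
                         record_mrna = TRUE, allow_zero = TRUE)
  # discrete-time birth-death expectations: M = alpha*g_t*tau_m,
  # P = beta*(1 - 1/tau_m)*M*tau_p
  m_exp <- p$alpha * p$g_t * p$tau_m
  p_exp <- p$beta * (1 - 1 / p$tau_m) * m_exp * p$tau_p
  # pool the three (independent, identically distributed) types
  m <- (ts$M0 + ts$M1 + ts$M2) / 3
  expect_lt(abs(mean(m) - m_exp), 3 * batch_se(m))
  pp <- (ts$P0 + ts$P1 + ts$P2) / 3
  expect_lt(abs(mean(pp) - p_exp), 3 * batch_se(pp))
})
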