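# a tiny run configuration for driver-level tests (dynamics are irrelevant)
tiny_args <- function() {
  list(params = kinetic_params(alpha = 0.2, beta = 0.2, tau_m = 10,
                               tau_p = 30, k_on = 1, k_off = 0.05,
                               k_off2 = 0.01, g_t = 3),
       lattice = lattice_spec(2, 30),
       n_steps = 4000, burn_in = 500, segment_length = 1000,
       n_segments = 4, init_protein = 50)
}

test_that("replicate runs are reproducible and carry distinct seeds", {
  a <- do.call(run_replicates, c(list(scenario = "uniform", n = 3,
                                      master_seed = 5), tiny_args()))
  b <- do.call(run_replicates, c(list(scenario = "uniform", n = 3,
                                      master_seed = 5), tiny_args()))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(length(unique(a$seed)), 3)
  expect_true(all(!is.na(a$fzca_min)))
  d <- do.call(run_replicates, c(list(scenario = "uniform", n = 3,
                                      master_seed = 6), tiny_args()))
  expect_false(identical(a$fzca_min, d$fzca_min))
})

test_that("a missing master seed is an error, not silent nondeterminism", {
  expect_error(do.call(run_replicates,
                       c(list(scenario = "uniform", n = 2), tiny_args())),
               "master_seed")
})

test_that("per-replicate failures are recorded, not fatal", {
  args <- tiny_args()
  res <- do.call(run_replicates, c(list(scenario = "segregated", n = 2,
                                        master_seed = 7, r = 29),
                                   args))
  expect_equal(res$regime, rep("failed", 2))
  expect_true(all(!is.na(res$error)))
})

test_that("aggregation computes mean and n-1 standard deviation", {
  df <- tibble::tibble(scenario = "uniform", param = "g_t", value = 5,
                       fzca_min = c(10, 20, 30))
  agg <- aggregate_sweep(df)
  expect_equal(agg$mean_fzca, 20)
  expect_equal(agg$sd_fzca, 10)
  expect_equal(agg$n_defined, 3)
  # permutation invariance
  agg2 <- aggregate_sweep(df[c(3, 1, 2), ])
  expect_equal(agg, agg2)
  # single defined replicate: sd 0, flagged
  one <- aggregate_sweep(df[1, ])
  expect_equal(one$sd_fzca, 0)
  expect_true(one$sd_flagged)
  # no defined replicates: NA mean, counted
  none <- aggregate_sweep(dplyr::mutate(df, fzca_min = NA_real_))
  expect_true(is.na(none$mean_fzca))
  expect_equal(none$n_undefined, 3)
})

test_that("demixing sweep maps ratios to box sides and adds the reference", {
  args <- tiny_args()
  sw <- sweep_demixing(c(0.1, 0.5), params = args$params,
                       lattice = args$lattice,
                       scenarios = "clustered", replicates = 2,
                       master_seed = 11, n_steps = args$n_steps,
                       burn_in = args$burn_in,
                       segment_length = args$segment_length,
                       n_segments = args$n_segments,
                       init_protein = args$init_protein)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sort(unique(sw$r)), c(3L, 15L))
  expect_true(any(sw$scenario == "uniform"))
  agg <- generics::tidy(sw)
  expect_equal(nrow(agg), 3) # two ratios + uniform reference
  expect_equal(generics::glance(sw)$n_replicates, 6)
})

test_that("scalar sweeps set the swept parameter correctly", {
  args <- tiny_args()
  # inv_tau_m violating the translation constraint is rejected
  expect_error(
    sweep_scalar("inv_tau_m", values = 0.95, params = args$params,
                 lattice = args$lattice, scenarios = "uniform",
                 replicates = 1, master_seed = 3, n_steps = 100),
    "beta")
  # D above the movement-probability ceiling is rejected
  expect_error(
    sweep_scalar("D", values = 0.3, params = args$params,
                 lattice = args$lattice, scenarios = "uniform",
                 replicates = 1, master_seed = 3, n_steps = 100),
    "p_move")
  sw <- sweep_scalar("g_t", values = c(1, 3), params = args$params,
                     lattice = args$lattice, scenarios = "uniform",
                     replicates = 2, master_seed = 13,
                     n_steps = args$n_steps, burn_in = args$burn_in,
                     segment_length = args$segment_length,
                     n_segments = args$n_segments,
                     init_protein = args$init_protein)
  expect_equal(sort(unique(sw$value)), c(1, 3))
  expect_equal(nrow(sw), 4)
})

test_that("sweep seeds are independent of point ordering", {
  args <- tiny_args()
  common <- list(params = args$params, lattice = args$lattice,
                 scenarios = "uniform", replicates = 2,
                 master_seed = 17, n_steps = args$n_steps,
                 burn_in = args$burn_in,
                 segment_length = args$segment_length,
                 n_segments = args$n_segments,
                 init_protein = args$init_protein)
  a <- do.call(sweep_scalar, c(list(param = "g_t", values = c(1, 2)), common))
  b <- do.call(sweep_scalar, c(list(param = "g_t", values = c(2, 1)), common))
  a1 <- dplyr::arrange(dplyr::filter(a, value == 2), replicate)
  b1 <- dplyr::arrange(dplyr::filter(b, value == 2), replicate)
  expect_equal(a1$fzca_min, b1$fzca_min)
  expect_equal(a1$seed, b1$seed)
})

test_that("the reduced fixture pair is labelled and sized as documented", {
  fo <- scaled_down_fixture("oscillatory")
  fs <- scaled_down_fixture("stationary")
  expect_equal(fo$scenario, "clustered")
  expect_equal(fs$scenario, "segregated")
  expect_identical(unclass(fo$params), unclass(fs$params))
  expect_equal(fo$r / fo$lattice$R, 0.01)
  # a single replicate completes quickly and lands in the expected regime
  t0 <- Sys.time()
  r1 <- run_fixture(fo, n = 1, master_seed = 41)
  r2 <- run_fixture(fs, n = 1, master_seed = 41)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_equal(r1$regime, "oscillatory")
  expect_equal(r2$regime, "stationary")
})
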