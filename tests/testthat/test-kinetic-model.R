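test_that("rate constants and states reject invalid inputs", {
  expect_error(rate_constants(k_on_ps = -1), "non-negative")
  expect_error(exchange_state(ps_a = -0.1), "non-negative")
  expect_error(sim_config(t_step = 0), "t_step")
  expect_error(sim_config(rate_window = 0.01, t_step = 0.5), "rate_window")
})

test_that("right-hand side agrees with an independent stoichiometry table", {
  S <- oracle_stoichiometry()
  set.seed(42)
  for (i in 1:20) {
    k <- rate_constants(k_on_mb = runif(1, 0, 20), k_off_mb = runif(1, 0, 2),
                        k_on_ps = runif(1, 0, 20), k_off_ps = runif(1, 0, 2),
                        k_on_pi4p = runif(1, 0, 20), k_off_pi4p = runif(1, 0, 2))
    y <- unclass(do.call(exchange_state,
                         as.list(stats::setNames(runif(11, 0, 5),
                                                 names(unclass(exchange_state()))))))
    d <- build_rhs(k)(0, y)[[1]]
    expected <- drop(S %*% oracle_fluxes(unclass(k), y))
    expect_equal(d[rownames(S)], expected, tolerance = 1e-12)
    # membranes are boundary species
    expect_identical(unname(d[c("m_a", "m_b")]), c(0, 0))
    # protein and each lipid total are in the left null space
    expect_equal(sum(d[c("o_free", "o_ma", "o_mb", "o_ps", "o_pi4p")]), 0,
                 tolerance = 1e-12)
    expect_equal(sum(d[c("ps_a", "ps_b", "o_ps")]), 0, tolerance = 1e-12)
    expect_equal(sum(d[c("pi4p_a", "pi4p_b", "o_pi4p")]), 0, tolerance = 1e-12)
  }
})

test_that("no extraction pathway and no protein give static pools", {
  # k_on_ps = 0 with PS only in A: destination pool has zero derivative
  k <- rate_constants(k_on_ps = 0)
  y <- unclass(exchange_state(o_ma = 0.1, ps_a = 5))
  d <- build_rhs(k)(0, y)[[1]]
  expect_identical(unname(d[["ps_b"]]), 0)
  # no protein anywhere: every protein species and lipid pool is static
  y0 <- unclass(exchange_state(o_free = 0, ps_a = 5, pi4p_b = 5))
  d0 <- build_rhs(rate_constants())(0, y0)[[1]]
  expect_true(all(d0 == 0))
})

test_that("trajectories conserve protein and lipid totals", {
  set.seed(7)
  for (i in 1:5) {
    cfg <- default_transfer_config(k_on_ps = 10^runif(1, -1, 2),
                                   pi4p_b = sample(c(0, 5), 1),
                                   t_end = 60, t_step = 0.5, rate_window = 4)
    drift <- conservation_drift(simulate_exchange(cfg))
    expect_lt(max(drift), 1e-6)
  }
  # the PS total of the standard non-exchange run stays at 5 uM
  tr <- simulate_exchange(default_transfer_config(t_end = 60, t_step = 0.5,
                                                  rate_window = 4))
  tot <- tr$ps_a + tr$ps_b + tr$o_ps
  expect_equal(tot, rep(5, length(tot)), tolerance = 1e-9)
})

test_that("zero-duration and symmetric configurations behave as expected", {
  cfg <- default_transfer_config(t_end = 0)
  tr <- simulate_exchange(cfg)
  expect_equal(nrow(tr), 1L)
  expect_equal(unlist(tr[1, -1]), unclass(cfg$initial_state),
               tolerance = 1e-12, ignore_attr = TRUE)
  # PS split equally between identical membranes stays equal
  sym <- sim_config(initial_state = exchange_state(ps_a = 2.5, ps_b = 2.5),
                    t_end = 30, t_step = 0.5, rate_window = 4)
  tr2 <- simulate_exchange(sym)
  expect_equal(tr2$ps_a, tr2$ps_b, tolerance = 1e-9)
})

test_that("long-time pools match the independent algebraic equilibrium", {
  cfg <- default_transfer_config(t_end = 30000, t_step = 100,
                                 rate_window = 100)
  tr <- simulate_exchange(cfg)
  eq <- oracle_equilibrium_ps(unclass(cfg$rates), m = 100,
                              protein = 0.2, ps_total = 5)
  last <- tr[nrow(tr), ]
  expect_equal(last$ps_a, eq$ps_a, tolerance = 1e-3)
  expect_equal(last$ps_b, eq$ps_b, tolerance = 1e-3)
  expect_equal(last$o_ps, eq$o_ps, tolerance = 1e-3)
})

test_that("the pre-docked limit matches the closed-form linear system", {
  # membrane binding switched off, protein pre-docked in large excess so
  # the docked pools are effectively constant: the lipid subsystem is a
  # linear two-compartment network with an exact eigensolution
  oma <- 1e5; omb <- 1e5; kon <- 2e-4; koff <- 1; ps0 <- 0.01
  cfg <- sim_config(
    rates = rate_constants(k_on_mb = 0, k_off_mb = 0,
                           k_on_ps = kon, k_off_ps = koff),
    initial_state = exchange_state(o_free = 0, o_ma = oma, o_mb = omb,
                                   ps_a = ps0),
    t_end = 2, t_step = 0.1, rate_window = 0.1,
    rel_tol = 1e-10, abs_tol = 1e-14)
  tr <- simulate_exchange(cfg)
  ref <- oracle_linear_transfer(tr$time_s, oma, omb, kon, koff, ps0)
  for (sp in c("ps_a", "ps_b", "o_ps"))
    expect_lt(max(abs(tr[[sp]] - ref[[sp]])) / ps0, 1e-6)
})

test_that("swapping the PS and PI(4)P labels swaps the outputs", {
  mk <- function(kps, kops, kpi, kopi, psa, pib) sim_config(
    rates = rate_constants(k_on_ps = kps, k_off_ps = kops,
                           k_on_pi4p = kpi, k_off_pi4p = kopi),
    initial_state = exchange_state(ps_a = psa, pi4p_b = pib),
    t_end = 10, t_step = 0.5, rate_window = 4)
  a <- simulate_exchange(mk(7, 0.5, 2, 1.2, 5, 3))
  # swapped ligand identities, with the pools mirrored between membranes
  b_cfg <- sim_config(
    rates = rate_constants(k_on_ps = 2, k_off_ps = 1.2,
                           k_on_pi4p = 7, k_off_pi4p = 0.5),
    initial_state = exchange_state(ps_a = 0, pi4p_a = 5, ps_b = 3),
    t_end = 10, t_step = 0.5, rate_window = 4)
  b <- simulate_exchange(b_cfg)
  expect_equal(a$ps_a, b$pi4p_a, tolerance = 1e-6)
  expect_equal(a$ps_b, b$pi4p_b, tolerance = 1e-6)
  expect_equal(a$pi4p_b, b$ps_b, tolerance = 1e-6)
  expect_equal(a$o_ps, b$o_pi4p, tolerance = 1e-6)
  expect_equal(a$o_ma, b$o_ma, tolerance = 1e-6)
})

test_that("configs round-trip through YAML and JSON files", {
  skip_if_not_installed("yaml")
  cfg_list <- list(rates = list(k_on_ps = 3.7, k_off_mb = 0.1),
                   initial = list(ps_a = 5, pi4p_b = 5),
                   membranes = list(m_a_uM = 100, m_b_uM = 100),
                   sim = list(t_end_s = 10, t_step_s = 0.5,
                              rate_window_s = 4))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, yml)
  cfg <- read_sim_config(yml)
  expect_equal(cfg$rates$k_on_ps, 3.7)
  expect_equal(unclass(cfg$initial_state)[["pi4p_b"]], 5)
  expect_equal(cfg$rate_window, 4)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jsn, auto_unbox = TRUE)
  cfg2 <- read_sim_config(jsn)
  expect_equal(unclass(cfg2$rates), unclass(cfg$rates))
})
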