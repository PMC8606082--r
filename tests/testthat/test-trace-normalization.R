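# minimal hand-built two-population assay pair with piecewise-constant
# segments; levels chosen per test
make_pair <- function(f0 = 100, f_eq = 400, f0_eq = 90, f_post = NULL,
                      kinetic_fun = NULL, dt = 0.5) {
  tt <- seq(0, 300, by = dt)
  ev <- data.frame(label = c("liposome_b", "protein"), time_s = c(60, 240))
  f <- rep(f0, length(tt))
  f[tt <= 60] <- f0 * 0.98
  post <- tt >= 240
  if (!is.null(kinetic_fun)) f[post] <- kinetic_fun(tt[post] - 240)
  else if (!is.null(f_post)) f[post] <- f_post
  trace <- fluorescence_trace(tt, f, ev)
  eq_t <- seq(0, 240, by = dt)
  eq <- fluorescence_trace(eq_t, ifelse(eq_t <= 60, f0_eq, f_eq),
                           data.frame(label = "liposome_b", time_s = 60))
  list(trace = trace, eq = eq)
}

test_that("references are segment means between the bounding events", {
  p <- make_pair(f0 = 100, f_eq = 400, f0_eq = 90)
  refs <- compute_refs(p$trace, p$eq, "ps_two_pop")
  expect_equal(refs$f0, 100)
  expect_equal(refs$f_eq, 400)
  expect_equal(refs$f0_eq, 90)
  # PI(4)P assays use the assay baseline in place of the eq-sample baseline
  refs_pi <- compute_refs(p$trace, p$eq, "pi4p_two_pop")
  expect_equal(refs_pi$f0_eq, refs_pi$f0)
  # a trace with no liposome event before the protein is structural error
  bad <- fluorescence_trace(seq(0, 300, 0.5), rep(1, 601),
                            data.frame(label = "protein", time_s = 240))
  expect_error(compute_refs(bad, p$eq, "ps_two_pop"),
               class = "ordflux_missing_event")
})

test_that("noisy references stay within three standard errors of truth", {
  sigma <- 2
  set.seed(101)
  p <- make_pair(f0 = 100, f_eq = 400, f0_eq = 90)
  noisy_trace <- fluorescence_trace(p$trace$time_s,
                                    p$trace$f + rnorm(nrow(p$trace), 0, sigma),
                                    attr(p$trace, "events"))
  noisy_eq <- fluorescence_trace(p$eq$time_s,
                                 p$eq$f + rnorm(nrow(p$eq), 0, sigma),
                                 attr(p$eq, "events"))
  refs <- compute_refs(noisy_trace, noisy_eq, "ps_two_pop")
  n0 <- sum(p$trace$time_s > 60 & p$trace$time_s < 240) - 4
  expect_lt(abs(refs$f0 - 100), 3 * sigma / sqrt(n0))
  n_eq <- sum(p$eq$time_s > 60) - 2
  expect_lt(abs(refs$f_eq - 400), 3 * sigma / sqrt(n_eq))
})

test_that("normalization maps the reference points to 0, the ceiling, and halfway", {
  p0 <- make_pair(f0 = 100, f_eq = 400, f0_eq = 100, f_post = 100)
  refs0 <- compute_refs(p0$trace, p0$eq, "ps_two_pop")
  kin0 <- normalize_trace(p0$trace, refs0)
  expect_true(all(kin0$transferred_uM == 0))
  expect_equal(kin0$time_s[1], 0)

  p1 <- make_pair(f0 = 100, f_eq = 400, f0_eq = 100, f_post = 400)
  kin1 <- normalize_trace(p1$trace, compute_refs(p1$trace, p1$eq, "ps_two_pop"))
  expect_true(all(kin1$transferred_uM == 2.5))

  p2 <- make_pair(f0 = 100, f_eq = 400, f0_eq = 100, f_post = 250)
  kin2 <- normalize_trace(p2$trace, compute_refs(p2$trace, p2$eq, "ps_two_pop"))
  expect_true(all(kin2$transferred_uM == 1.25))
})

test_that("a collapsed calibration is refused", {
  p <- make_pair(f0 = 100, f_eq = 100 + 1e-8, f0_eq = 100)
  refs <- compute_refs(p$trace, p$eq, "ps_two_pop")
  expect_error(normalize_trace(p$trace, refs),
               class = "ordflux_degenerate_calibration")
})

test_that("initial velocity recovers planted slopes", {
  # planted 35.2 lipids/min at 0.2 uM protein, i.e. 35.2*0.2/60 uM/s
  slope <- 35.2 * 0.2 / 60
  kin_fun <- function(tk) 100 + slope * tk / 2.5 * 300  # f0 100, denom 300
  p <- make_pair(f0 = 100, f_eq = 400, f0_eq = 100, kinetic_fun = kin_fun)
  kin <- normalize_trace(p$trace, compute_refs(p$trace, p$eq, "ps_two_pop"))
  expect_equal(initial_velocity(kin, 0.2), 35.2, tolerance = 1e-9)
  # flat kinetics give zero; 0.2 uM/s at 0.2 uM protein gives 60
  pf <- make_pair(f_post = 100, f0_eq = 100)
  kinf <- normalize_trace(pf$trace, compute_refs(pf$trace, pf$eq, "ps_two_pop"))
  expect_equal(initial_velocity(kinf, 0.2), 0)
  kin2 <- data.frame(time_s = seq(0, 3.5, 0.5),
                     transferred_uM = 0.2 * seq(0, 3.5, 0.5))
  class(kin2) <- c("ord_kinetics", "data.frame")
  expect_equal(initial_velocity(kin2, 0.2), 60)
  expect_error(initial_velocity(kin2, 0.2, n_points = 20), "fewer")
})

test_that("three-liposome normalization handles plateaus and missing events", {
  g_full <- gen_transfer_assay(generator_spec(1, 0), assay_kind = "ps_three_pop",
                               equilibration_fraction = 1)
  refs <- compute_refs(g_full$trace, g_full$eq_trace, "ps_three_pop")
  kin <- three_liposome_normalize(g_full$trace, refs)
  expect_equal(tail(kin$transferred_uM, 1), 2.5, tolerance = 1e-3)

  g40 <- gen_transfer_assay(generator_spec(1, 0), assay_kind = "ps_three_pop",
                            equilibration_fraction = 0.4)
  refs40 <- compute_refs(g40$trace, g40$eq_trace, "ps_three_pop")
  kin40 <- three_liposome_normalize(g40$trace, refs40)
  expect_equal(tail(kin40$transferred_uM, 1), 1.0, tolerance = 1e-3)

  # dropping the second acceptor population is a structural error
  ev <- attr(g40$trace, "events")
  stripped <- fluorescence_trace(g40$trace$time_s, g40$trace$f,
                                 ev[ev$label != "liposome_c", ],
                                 direction = "quench")
  expect_error(three_liposome_normalize(stripped, refs40),
               class = "ordflux_missing_event")
})

test_that("normalization is invariant under affine re-scaling of the signal", {
  g <- gen_transfer_assay(generator_spec(9, 0.01))
  refs <- compute_refs(g$trace, g$eq_trace, "ps_two_pop")
  kin <- normalize_trace(g$trace, refs)
  gain <- 3.7; offset <- 12
  rescale <- function(tr) fluorescence_trace(tr$time_s, gain * tr$f + offset,
                                             attr(tr, "events"),
                                             attr(tr, "channel"),
                                             attr(tr, "direction"))
  refs2 <- compute_refs(rescale(g$trace), rescale(g$eq_trace), "ps_two_pop")
  kin2 <- normalize_trace(rescale(g$trace), refs2)
  expect_equal(kin2$transferred_uM, kin$transferred_uM, tolerance = 1e-10)
})

test_that("mirroring a trace about the mid-level flips direction but not kinetics", {
  g <- gen_transfer_assay(generator_spec(13, 0))
  refs <- compute_refs(g$trace, g$eq_trace, "ps_two_pop")
  kin <- normalize_trace(g$trace, refs)
  c0 <- (refs$f0 + refs$f_eq) / 2
  mirror <- function(tr, dir) fluorescence_trace(tr$time_s, 2 * c0 - tr$f,
                                                 attr(tr, "events"),
                                                 direction = dir)
  refs_m <- compute_refs(mirror(g$trace, "quench"), mirror(g$eq_trace, "quench"),
                         "ps_two_pop")
  kin_m <- normalize_trace(mirror(g$trace, "quench"), refs_m)
  expect_equal(kin_m$transferred_uM, kin$transferred_uM, tolerance = 1e-10)
})

test_that("the full pipeline recovers planted rates from noiseless and noisy traces", {
  planted <- 35.2
  recover <- function(seed, noise) {
    g <- gen_transfer_assay(generator_spec(seed, noise), planted_rate = planted)
    refs <- compute_refs(g$trace, g$eq_trace, "ps_two_pop")
    initial_velocity(normalize_trace(g$trace, refs), 0.2)
  }
  expect_equal(recover(1, 0), planted, tolerance = 0.02)
  rates <- vapply(1:50, recover, numeric(1), noise = 0.01)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - planted), 3 * se + 1e-9)
})

test_that("traces survive a CSV round trip with their events", {
  g <- gen_transfer_assay(generator_spec(4, 0.01))
  tf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_trace_csv(g$trace, tf, ef)
  back <- read_trace_csv(tf, ef)
  expect_equal(back$f, g$trace$f)
  expect_equal(attr(back, "events"), attr(g$trace, "events"))
})
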