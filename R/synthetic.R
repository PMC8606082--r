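#' Specification for seeded synthetic data
#'
#' Bundles the seed, the noise level and the sampling interval common to
#' all generators. Identical specs produce bit-identical datasets; every
#' generator returns (and optionally writes) a `truth` record echoing the
#' planted parameters.
#'
#' @param seed integer RNG seed
#' @param noise_sd_fraction Gaussian noise standard deviation as a
#'   fraction of each trace's dynamic range (default 1%)
#' @param sampling_s trace sampling interval (s)
#' @return An object of class `ord_gen_spec`.
#' @export
generator_spec <- function(seed = 1L, noise_sd_fraction = 0.01,
                           sampling_s = 0.5) {
  stopifnot(noise_sd_fraction >= 0, sampling_s > 0)
  structure(list(seed = as.integer(seed),
                 noise_sd_fraction = noise_sd_fraction,
                 sampling_s = sampling_s),
            class = "ord_gen_spec")
}

# two-sample spike right after an injection, exercising the transient
# trimming in compute_refs()
.add_transients <- function(f, time_s, event_times, magnitude) {
  for (te in event_times) {
    i <- which(time_s > te)[1:2]
    i <- i[!is.na(i)]
    f[i] <- f[i] + magnitude
  }
  f
}

#' Generate a synthetic transfer-assay recording
#'
#' Builds a fluorescence trace with the layout of the two- or
#' three-population transfer assays — pre-injection baseline segments,
#' injection events (with two-sample transients), and a post-protein
#' transfer phase — together with its equilibrium-reference companion
#' trace, by mapping a transferred-lipid time course through the inverse
#' of the normalization.
#'
#' The transferred-lipid course is either simulated from the mass-action
#' model (`sim_config`; the destination pool of `track`), or, when
#' `planted_rate` is given, a linear ramp at exactly that initial
#' velocity saturating at 80% of the transfer ceiling, or, for the
#' three-population assay, an exponential approach to
#' `equilibration_fraction` of the ceiling.
#'
#' @param spec an [generator_spec()]
#' @param sim_config an [sim_config()] used when `planted_rate` is `NULL`
#' @param assay_kind `"ps_two_pop"`, `"pi4p_two_pop"` or `"ps_three_pop"`
#' @param planted_rate optional exact initial velocity
#'   (lipids min^-1 per protein) for the ramp mode
#' @param protein_uM protein concentration (uM)
#' @param equilibration_fraction plateau as a fraction of the transfer
#'   ceiling (three-population mode)
#' @param f0 baseline fluorescence level (a.u.)
#' @param dynamic_range `f_eq - f0` (a.u.); sign fixed by the assay
#'   direction
#' @param t_post recording time after the protein injection (s)
#' @param max_transfer_uM transfer ceiling (uM); see [max_transferable()]
#' @param out_dir optional directory: writes `trace.csv`, `events.csv`,
#'   `eq_trace.csv`, `eq_events.csv` and `truth.json`
#' @return List with `trace`, `eq_trace` (both `ord_trace`) and `truth`.
#' @export
gen_transfer_assay <- function(spec = generator_spec(),
                               sim_config = default_transfer_config(),
                               assay_kind = c("ps_two_pop", "pi4p_two_pop",
                                              "ps_three_pop"),
                               planted_rate = NULL,
                               protein_uM = 0.2,
                               equilibration_fraction = 1,
                               f0 = 100, dynamic_range = 300,
                               t_post = 120,
                               max_transfer_uM = max_transferable(),
                               out_dir = NULL) {
  assay_kind <- match.arg(assay_kind)
  set.seed(spec$seed)
  dt <- spec$sampling_s
  dequench <- assay_kind == "ps_two_pop"
  f_eq <- f0 + if (dequench) abs(dynamic_range) else -abs(dynamic_range)
  f0_eq <- if (assay_kind == "ps_two_pop") f0 * 0.9 else f0
  # denominator of the normalization; for the PS assay the eq sample has
  # its own baseline, for the others f0 stands in
  denom <- f_eq - f0_eq

  if (assay_kind == "ps_three_pop") {
    ev <- data.frame(label = c("liposome_b", "liposome_c", "protein"),
                     time_s = c(60, 180, 300))
    t_post <- max(t_post, 600)
  } else {
    ev <- data.frame(label = c("liposome_b", "protein"), time_s = c(60, 240))
  }
  t_prot <- ev$time_s[ev$label == "protein"]
  time_s <- seq(0, t_prot + t_post, by = dt)
  tk <- pmax(time_s - t_prot, 0)  # kinetic time

  if (!is.null(planted_rate)) {
    rate_uMs <- planted_rate * protein_uM / 60
    plateau <- 0.8 * max_transfer_uM
    transferred <- pmin(rate_uMs * tk, plateau)
    truth_rate <- planted_rate
    mode <- "ramp"
  } else if (assay_kind == "ps_three_pop") {
    plateau <- equilibration_fraction * max_transfer_uM
    tau <- 60
    transferred <- plateau * (1 - exp(-tk / tau))
    truth_rate <- plateau / tau / protein_uM * 60  # exact initial slope
    mode <- "exponential"
  } else {
    cfg <- sim_config
    cfg$t_end <- t_post
    cfg$t_step <- dt
    traj <- simulate_exchange(cfg)
    track <- if (assay_kind == "ps_two_pop") "ps_b" else "pi4p_a"
    pool <- traj[[track]][match(round(tk / dt), round(traj$time_s / dt))]
    transferred <- ifelse(time_s < t_prot, 0, pool)
    # truth uses the same eight-sample estimator the analysis applies
    i8 <- seq_len(8L)
    truth_rate <- unname(stats::coef(stats::lm.fit(
      cbind(1, traj$time_s[i8]), traj[[track]][i8]))[2]) / protein_uM * 60
    mode <- "ode"
  }
  transferred[time_s < t_prot] <- 0
  f <- f0 + transferred / max_transfer_uM * denom
  # pre-injection segment sits slightly off the settled baseline
  first_ev <- min(ev$time_s)
  f[time_s <= first_ev] <- f0 * 0.98
  liposome_events <- ev$time_s[ev$label != "protein"]
  f <- .add_transients(f, time_s, liposome_events, 0.05 * abs(denom))

  noise_sd <- spec$noise_sd_fraction * abs(denom)
  direction <- if (dequench) "dequench" else "quench"
  channel <- if (assay_kind == "pi4p_two_pop") "NBD-PHFAPP" else "NBD-C2Lact"
  trace <- fluorescence_trace(time_s, f + stats::rnorm(length(f), 0, noise_sd),
                              ev, channel, direction)

  # equilibrium-reference companion
  if (assay_kind == "ps_three_pop") {
    eq_ev <- data.frame(label = c("liposome_b", "liposome_c"),
                        time_s = c(60, 180))
    eq_t <- seq(0, 180 + 21 * 60, by = dt)
    eq_f <- ifelse(eq_t <= 180, f0_eq, f_eq)
  } else {
    eq_ev <- data.frame(label = "liposome_b", time_s = 60)
    eq_t <- seq(0, 240, by = dt)
    eq_f <- ifelse(eq_t <= 60, f0_eq, f_eq)
  }
  eq_f <- .add_transients(eq_f, eq_t, eq_ev$time_s, 0.05 * abs(denom))
  eq_trace <- fluorescence_trace(eq_t, eq_f + stats::rnorm(length(eq_f), 0, noise_sd),
                                 eq_ev, channel, direction)

  truth <- list(assay_kind = assay_kind, mode = mode,
                initial_rate = truth_rate, protein_uM = protein_uM,
                f0 = f0, f_eq = f_eq, f0_eq = f0_eq,
                max_transfer_uM = max_transfer_uM,
                noise_sd = noise_sd, seed = spec$seed)
  if (assay_kind == "ps_three_pop") truth$plateau_uM <- plateau
  out <- list(trace = trace, eq_trace = eq_trace, truth = truth)
  if (!is.null(out_dir)) .write_synth(out_dir, trace = trace,
                                      eq_trace = eq_trace, truth = truth)
  out
}

#' Generate a synthetic competitive-displacement curve
#'
#' Hyperbolic displacement of the fluorescent reporter by unlabelled
#' competitor over the standard injection series (accessible competitor
#' from 0 to 1.25 uM).
#'
#' @param spec an [generator_spec()]
#' @param l50 planted half-displacement concentration (uM)
#' @param f_min,f_max planted plateaus (normalized fluorescence); equal
#'   values plant a no-displacement curve
#' @param n_points points in the injection series
#' @param x_max largest accessible competitor concentration (uM)
#' @param replicates independent replicates (jointly fitted downstream)
#' @param out_dir optional output directory (`curve.csv`, `truth.json`)
#' @return List with `curve` (an `ord_titration`) and `truth`.
#' @export
gen_competition <- function(spec = generator_spec(), l50 = 0.2,
                            f_min = 0.75, f_max = 1, n_points = 11,
                            x_max = 1.25, replicates = 1, out_dir = NULL) {
  set.seed(spec$seed)
  x <- seq(0, x_max, length.out = n_points)
  noise_sd <- spec$noise_sd_fraction * abs(f_max - f_min)
  xx <- rep(x, replicates)
  rid <- rep(paste0("r", seq_len(replicates)), each = n_points)
  y <- f_min + (f_max - f_min) * xx / (l50 + xx) +
    stats::rnorm(length(xx), 0, noise_sd)
  curve <- titration_curve(xx, y, "competition", rid)
  truth <- list(l50 = l50, inv_l50 = 1 / l50, f_min = f_min, f_max = f_max,
                noise_sd = noise_sd, seed = spec$seed)
  if (!is.null(out_dir)) .write_synth(out_dir, curve = curve, truth = truth)
  list(curve = curve, truth = truth)
}

#' Generate a synthetic thermal-shift melt curve
#'
#' Boltzmann unfolding sigmoid on the standard scan (25 to 95 degC in
#' 1 degC steps).
#'
#' @param spec an [generator_spec()]
#' @param t_m planted melting temperature (degC)
#' @param slope planted transition width (degC)
#' @param f_native,f_denatured planted plateaus
#' @param t_range scanned temperature range (degC)
#' @param step scan step (degC)
#' @param replicates independent replicates
#' @param out_dir optional output directory
#' @return List with `curve` and `truth`.
#' @export
gen_melt <- function(spec = generator_spec(), t_m = 52, slope = 2.5,
                     f_native = 0.05, f_denatured = 1,
                     t_range = c(25, 95), step = 1, replicates = 1,
                     out_dir = NULL) {
  set.seed(spec$seed)
  x <- seq(t_range[1], t_range[2], by = step)
  noise_sd <- spec$noise_sd_fraction * abs(f_denatured - f_native)
  xx <- rep(x, replicates)
  rid <- rep(paste0("r", seq_len(replicates)), each = length(x))
  y <- f_native + (f_denatured - f_native) / (1 + exp((t_m - xx) / slope)) +
    stats::rnorm(length(xx), 0, noise_sd)
  curve <- titration_curve(xx, y, "melt", rid)
  truth <- list(t_m = t_m, slope = slope, f_native = f_native,
                f_denatured = f_denatured, noise_sd = noise_sd,
                seed = spec$seed)
  if (!is.null(out_dir)) .write_synth(out_dir, curve = curve, truth = truth)
  list(curve = curve, truth = truth)
}

#' Generate a synthetic saturation membrane-binding curve
#'
#' Probe intensity versus titrated total lipid (0 to 300 uM), a
#' hyperbolic rise to `fold_change` times the lipid-free intensity.
#' `fold_change = 1` plants a no-binding curve.
#'
#' @param spec an [generator_spec()]
#' @param k planted half-saturation lipid concentration (uM)
#' @param fold_change planted intensity fold-change at saturation
#' @param y0 planted lipid-free intensity (a.u.)
#' @param x titration grid (uM), must include 0
#' @param replicates independent replicates
#' @param out_dir optional output directory
#' @return List with `curve` and `truth`.
#' @export
gen_saturation <- function(spec = generator_spec(), k = 40,
                           fold_change = 2.2, y0 = 100,
                           x = c(0, 10, 20, 40, 60, 90, 120, 160, 200, 250, 300),
                           replicates = 1, out_dir = NULL) {
  set.seed(spec$seed)
  noise_sd <- spec$noise_sd_fraction * y0 * max(abs(fold_change - 1), 0.1)
  xx <- rep(x, replicates)
  rid <- rep(paste0("r", seq_len(replicates)), each = length(x))
  y <- y0 * (1 + (fold_change - 1) * xx / (k + xx)) +
    stats::rnorm(length(xx), 0, noise_sd)
  curve <- titration_curve(xx, y, "saturation", rid)
  truth <- list(k = k, fold_change = fold_change, y0 = y0,
                noise_sd = noise_sd, seed = spec$seed)
  if (!is.null(out_dir)) .write_synth(out_dir, curve = curve, truth = truth)
  list(curve = curve, truth = truth)
}

.write_synth <- function(dir, trace = NULL, eq_trace = NULL, curve = NULL,
                         truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(trace))
    write_trace_csv(trace, file.path(dir, "trace.csv"),
                    file.path(dir, "events.csv"))
  if (!is.null(eq_trace))
    write_trace_csv(eq_trace, file.path(dir, "eq_trace.csv"),
                    file.path(dir, "eq_events.csv"))
  if (!is.null(curve))
    utils::write.csv(as.data.frame(curve), file.path(dir, "curve.csv"),
                     row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
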