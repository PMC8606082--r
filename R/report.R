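#' Reproduce the capture-rate sweep analysis end to end
#'
#' Runs the full simulation study behind the rate-versus-affinity
#' analysis: the log-spaced k_ON-PS sweep of initial PS and PI(4)P
#' transfer rates in non-exchange and exchange conditions, the refined
#' location of the interior non-exchange PS rate maximum and the PS
#' acceleration factor evaluated there, the paired acceleration-factor
#' curves at fixed k_ON-PI(4)P of 75 and 40 uM^-1 s^-1 (the values that
#' track the Osh6p and ORD8 experimental scatter), and optionally the
#' variant regimes: k_ON-PI(4)P in {10, 40, 75, 100} uM^-1 s^-1 and the
#' high-affinity-by-slow-release regime k_OFF-PI(4)P = 0.1 s^-1.
#'
#' @param base_config an [sim_config()]
#' @param per_decade sweep resolution (points per decade)
#' @param curve_kon_pi4p k_ON-PI(4)P values for the paired
#'   acceleration-factor curves
#' @param include_variants also run the variant k_ON-PI(4)P and
#'   k_OFF-PI(4)P sweeps
#' @param out_dir optional directory; writes `sweep.csv`, `curves.csv`,
#'   variant CSVs, `summary.json` and `manifest.json`
#' @return List with `sweep` (`ord_sweep`), `curves` (data.frame),
#'   `variants` (list or `NULL`), and `summary` (list with
#'   `argmax_kon_ps`, `rate_at_max`, `accel_ps_at_argmax`).
#' @export
run_sweep_study <- function(base_config = default_transfer_config(),
                           per_decade = 25,
                           curve_kon_pi4p = c(75, 40),
                           include_variants = FALSE,
                           out_dir = NULL) {
  grid <- default_sweep_grid(per_decade = per_decade)
  sw <- sweep_rates(base_config, "k_on_ps", grid)
  mx <- find_rate_maximum(sw, "nonexchange", "ps")
  cfg_max <- .set_rate(base_config, "k_on_ps", mx$parameter)
  tracked <- unclass(base_config$initial_state)[["ps_a"]]
  rate_ex <- .rate_at(.set_pools(cfg_max, tracked, 5), "ps_b")
  summary <- list(argmax_kon_ps = mx$parameter,
                  rate_at_max = mx$rate,
                  accel_ps_at_argmax = acceleration_factor(rate_ex, mx$rate))
  curves <- do.call(rbind, lapply(curve_kon_pi4p, function(kp)
    parametric_acceleration_curve(base_config, grid, kp)))
  variants <- NULL
  if (include_variants) {
    variants <- list(
      kon_pi4p = do.call(rbind, lapply(c(10, 40, 75, 100), function(kp)
        parametric_acceleration_curve(base_config, grid, kp))),
      slow_pi4p_release = {
        cfg <- base_config
        cfg$rates <- do.call(rate_constants,
                             utils::modifyList(unclass(base_config$rates),
                                               list(k_off_pi4p = 0.1)))
        sw2 <- sweep_rates(cfg, "k_on_ps", grid)
        as.data.frame(sw2)
      })
  }
  out <- list(sweep = sw, curves = curves, variants = variants,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(sweep = file.path(out_dir, "sweep.csv"),
               curves = file.path(out_dir, "curves.csv"),
               summary = file.path(out_dir, "summary.json"))
    write_sweep_csv(sw, files["sweep"])
    utils::write.csv(curves, files["curves"], row.names = FALSE)
    jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (include_variants) {
      files["variants_kon"] <- file.path(out_dir, "curves_kon_pi4p.csv")
      files["variants_koff"] <- file.path(out_dir, "sweep_koff_pi4p_0p1.csv")
      utils::write.csv(variants$kon_pi4p, files["variants_kon"], row.names = FALSE)
      utils::write.csv(variants$slow_pi4p_release, files["variants_koff"],
                       row.names = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("ordflux")),
      per_decade = per_decade,
      rates = unclass(base_config$rates),
      rate_window_s = base_config$rate_window,
      membranes_uM = unname(unclass(base_config$initial_state)[c("m_a", "m_b")]),
      output_md5 = as.list(tools::md5sum(unname(files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Merge experimental acceleration factors with a theoretical curve
#'
#' Produces the long-format table behind the acceleration-factor overlay:
#' experimentally determined (PI(4)P, PS) acceleration pairs next to the
#' simulated parametric curve. No statistics are computed.
#'
#' @param experimental data.frame with columns `accel_pi4p`, `accel_ps`
#'   (optionally `species`); may have zero rows
#' @param theoretical data.frame from [parametric_acceleration_curve()]
#' @return Data.frame with columns `source` (`"experiment"`/`"theory"`),
#'   `accel_pi4p`, `accel_ps`, `species`, `k_on_ps`.
#' @export
overlay_factors <- function(experimental, theoretical) {
  need <- c("accel_pi4p", "accel_ps")
  if (!all(need %in% names(theoretical)))
    stop("theoretical table lacks columns: ",
         paste(setdiff(need, names(theoretical)), collapse = ", "),
         call. = FALSE)
  if (nrow(experimental) > 0 && !all(need %in% names(experimental)))
    stop("experimental table lacks columns: ",
         paste(setdiff(need, names(experimental)), collapse = ", "),
         call. = FALSE)
  th <- data.frame(source = "theory",
                   accel_pi4p = theoretical$accel_pi4p,
                   accel_ps = theoretical$accel_ps,
                   species = NA_character_,
                   k_on_ps = theoretical$k_on_ps %||% NA_real_)
  if (nrow(experimental) == 0L) return(th)
  ex <- data.frame(source = "experiment",
                   accel_pi4p = experimental$accel_pi4p,
                   accel_ps = experimental$accel_ps,
                   species = if ("species" %in% names(experimental))
                     experimental$species else NA_character_,
                   k_on_ps = NA_real_)
  rbind(ex, th)
}

#' Plot a sweep result
#'
#' Quick base-graphics view of the bell-shaped rate curves on a log
#' parameter axis.
#'
#' @param x an `ord_sweep`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.ord_sweep <- function(x, ...) {
  cols <- c("rate_ps_nonexchange", "rate_ps_exchange",
            "rate_pi4p_nonexchange", "rate_pi4p_exchange")
  graphics::matplot(x$parameter_value, as.matrix(x[, cols]),
                    type = "l", log = "x", lty = 1:4, col = 1:4,
                    xlab = attr(x, "swept_parameter"),
                    ylab = "initial rate (lipids / min / protein)", ...)
  graphics::legend("topright", legend = cols, lty = 1:4, col = 1:4,
                   cex = 0.7, bty = "n")
  invisible(x)
}
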