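#' Initial transfer rate from a simulated trajectory
#'
#' Least-squares slope (uM/s) of the destination lipid pool over the first
#' `window` seconds of the trajectory, divided by the total protein
#' concentration and expressed in lipids min^-1 per protein — the unit in
#' which all transfer rates are reported. `species = "ps_b"` tracks A-to-B
#' PS transfer, `species = "pi4p_a"` the opposite PI(4)P transfer.
#'
#' @param trajectory an `ord_trajectory` from [simulate_exchange()]
#' @param species destination pool: `"ps_b"` or `"pi4p_a"`
#' @param protein_total total protein (uM); defaults to the conserved total
#'   of the trajectory's initial state
#' @param window fitting window (s); defaults to the trajectory config's
#'   `rate_window`
#' @return Initial transfer rate (lipids min^-1 per protein).
#' @export
initial_transfer_rate <- function(trajectory,
                                  species = c("ps_b", "pi4p_a"),
                                  protein_total = NULL, window = NULL) {
  species <- match.arg(species)
  cfg <- attr(trajectory, "config")
  if (is.null(window)) window <- cfg$rate_window
  if (is.null(protein_total))
    protein_total <- sum(unclass(cfg$initial_state)[.PROTEIN_SPECIES])
  if (!(protein_total > 0)) stop("protein_total must be > 0", call. = FALSE)
  tt <- trajectory$time_s
  if (max(tt) < window - 1e-9)
    stop("rate window (", window, " s) exceeds the trajectory span (",
         max(tt), " s)", call. = FALSE)
  sel <- tt <= window + 1e-9
  if (sum(sel) < 2L)
    stop("fewer than two samples inside the rate window", call. = FALSE)
  slope <- stats::coef(stats::lm.fit(cbind(1, tt[sel]),
                                     trajectory[[species]][sel]))[2]
  unname(slope) / protein_total * 60
}

#' Acceleration factor of transfer under exchange conditions
#'
#' log10 of the ratio of a lipid's initial transfer rate with the
#' counterligand present in the opposite membrane (exchange) to its rate
#' without it (non-exchange). Zero means no coupling; 1 means a ten-fold
#' acceleration.
#'
#' @param rate_exchange,rate_nonexchange initial transfer rates
#'   (lipids min^-1 per protein), both > 0
#' @return log10 rate ratio, or `NA` (with a warning of class
#'   `ordflux_undefined_factor`) if either rate is non-positive or missing.
#' @export
acceleration_factor <- function(rate_exchange, rate_nonexchange) {
  bad <- !is.finite(rate_exchange) | !is.finite(rate_nonexchange) |
    rate_exchange <= 0 | rate_nonexchange <= 0
  out <- ifelse(bad, NA_real_, log10(rate_exchange / rate_nonexchange))
  if (any(bad))
    warning(warningCondition(
      "acceleration factor undefined for non-positive rate; reported as NA",
      class = "ordflux_undefined_factor"))
  out
}
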