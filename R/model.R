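#' Mass-action right-hand side of the exchange cycle
#'
#' Builds the derivative function for the nine dynamic species from a set of
#' rate constants. The six reversible reactions are
#'
#' 1. `O + M_A  ⇌ O−M_A`  (k_on_mb / k_off_mb)
#' 2. `O + M_B  ⇌ O−M_B`  (k_on_mb / k_off_mb)
#' 3. `O−M_A + PS_A ⇌ O(PS)`  (k_on_ps / k_off_ps)
#' 4. `O−M_B + PS_B ⇌ O(PS)`  (k_on_ps / k_off_ps)
#' 5. `O−M_A + PI4P_A ⇌ O(PI4P)`  (k_on_pi4p / k_off_pi4p)
#' 6. `O−M_B + PI4P_B ⇌ O(PI4P)`  (k_on_pi4p / k_off_pi4p)
#'
#' `M_A` and `M_B` are boundary species: docking does not consume them and
#' the reverse of reactions 3–6 regenerates docked protein without
#' consuming membrane, so their concentrations enter the fluxes but never
#' change. Because the two soluble complexes each sit at the apex of two
#' reactions (one per membrane), a loaded domain releases its lipid toward
#' either membrane at the full release rate.
#'
#' @param rates an [rate_constants()] object
#' @return A function `(t, y, parms)` in the form expected by
#'   [deSolve::ode()], where `y` is the full 11-species state vector
#'   (dynamic species plus `m_a`, `m_b`); it returns the derivatives of the
#'   nine dynamic species (with zeros for `m_a`, `m_b`).
#' @export
build_rhs <- function(rates) {
  stopifnot(inherits(rates, "ord_rates"))
  k <- unclass(rates)
  function(t, y, parms = NULL) {
    v1f <- k$k_on_mb * y[["o_free"]] * y[["m_a"]]
    v1r <- k$k_off_mb * y[["o_ma"]]
    v2f <- k$k_on_mb * y[["o_free"]] * y[["m_b"]]
    v2r <- k$k_off_mb * y[["o_mb"]]
    v3f <- k$k_on_ps * y[["o_ma"]] * y[["ps_a"]]
    v3r <- k$k_off_ps * y[["o_ps"]]
    v4f <- k$k_on_ps * y[["o_mb"]] * y[["ps_b"]]
    v4r <- k$k_off_ps * y[["o_ps"]]
    v5f <- k$k_on_pi4p * y[["o_ma"]] * y[["pi4p_a"]]
    v5r <- k$k_off_pi4p * y[["o_pi4p"]]
    v6f <- k$k_on_pi4p * y[["o_mb"]] * y[["pi4p_b"]]
    v6r <- k$k_off_pi4p * y[["o_pi4p"]]
    list(c(
      o_free = -v1f + v1r - v2f + v2r,
      o_ma   =  v1f - v1r - v3f + v3r - v5f + v5r,
      o_mb   =  v2f - v2r - v4f + v4r - v6f + v6r,
      o_ps   =  v3f - v3r + v4f - v4r,
      o_pi4p =  v5f - v5r + v6f - v6r,
      ps_a   = -v3f + v3r,
      ps_b   = -v4f + v4r,
      pi4p_a = -v5f + v5r,
      pi4p_b = -v6f + v6r,
      m_a = 0, m_b = 0
    ))
  }
}

#' Integrate the exchange model
#'
#' Runs the stiff integrator (lsoda) on the mass-action system defined by
#' `config` and returns the trajectory on the fixed output grid
#' `seq(0, t_end, by = t_step)`. Concentrations are clipped to zero on
#' output (they may undershoot by at most the absolute solver tolerance).
#'
#' @param config an [sim_config()] object
#' @return An object of class `ord_trajectory`: a data.frame with column
#'   `time_s` followed by one column per species (uM), carrying the config
#'   as attribute `config`.
#' @export
simulate_exchange <- function(config) {
  stopifnot(inherits(config, "ord_sim_config"))
  y0 <- unclass(config$initial_state)
  times <- seq(0, config$t_end, by = config$t_step)
  if (config$t_end == 0) times <- 0
  if (length(times) == 1L) {
    out <- matrix(y0, nrow = 1, dimnames = list(NULL, names(y0)))
    traj <- data.frame(time_s = 0, out, check.names = FALSE)
  } else {
    rhs <- build_rhs(config$rates)
    sol <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                            method = "lsoda",
                            rtol = config$rel_tol, atol = config$abs_tol),
               silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times))
      stop(integration_error(config))
    traj <- as.data.frame(sol)
    names(traj)[1] <- "time_s"
  }
  for (nm in names(y0)) traj[[nm]] <- pmax(traj[[nm]], 0)
  structure(traj, class = c("ord_trajectory", "data.frame"), config = config)
}

integration_error <- function(config) {
  structure(
    class = c("ordflux_integration_error", "error", "condition"),
    list(message = paste0(
      "ODE integration failed (k_on_ps = ", config$rates$k_on_ps,
      ", k_on_pi4p = ", config$rates$k_on_pi4p, ")"),
      call = NULL, config = config))
}

#' Conserved totals along a trajectory
#'
#' Total protein (all five protein-containing species), total PS and total
#' PI(4)P are invariants of the reaction scheme; this helper reports their
#' maximum absolute drift from the initial value, used to audit solver
#' accuracy.
#'
#' @param trajectory an `ord_trajectory`
#' @return Named numeric vector with elements `protein`, `ps`, `pi4p`
#'   (maximum drift, uM).
#' @export
conservation_drift <- function(trajectory) {
  tot <- function(cols) rowSums(trajectory[, cols, drop = FALSE])
  p <- tot(.PROTEIN_SPECIES)
  s <- tot(c("ps_a", "ps_b", "o_ps"))
  q <- tot(c("pi4p_a", "pi4p_b", "o_pi4p"))
  c(protein = max(abs(p - p[1])),
    ps = max(abs(s - s[1])),
    pi4p = max(abs(q - q[1])))
}

#' Write a trajectory to CSV
#'
#' @param trajectory an `ord_trajectory`
#' @param path output file
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
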