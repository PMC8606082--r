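#' Rate constants of the six-reaction exchange cycle
#'
#' The exchange cycle couples membrane docking of the soluble lipid-transfer
#' domain (O + M ⇌ O−M, identical for both membranes) to lipid capture and
#' release at either membrane (O−M + L ⇌ O(L), one pair of reactions per
#' lipid per membrane). Bimolecular constants are in uM^-1 s^-1, unimolecular
#' constants in s^-1; the two kinds are kept in named fields and are never
#' interchangeable.
#'
#' Defaults follow the convention that all lipid capture rates are
#' 10 uM^-1 s^-1 and all lipid release rates 1 s^-1; membrane docking is
#' 10 uM^-1 s^-1 with undocking at 0.1 s^-1 (see the methods vignette for
#' how the undocking rate and the membrane boundary concentration were
#' fixed).
#'
#' @param k_on_mb membrane docking rate (uM^-1 s^-1)
#' @param k_off_mb membrane undocking rate (s^-1)
#' @param k_on_ps PS capture rate (uM^-1 s^-1)
#' @param k_off_ps PS release rate (s^-1)
#' @param k_on_pi4p PI(4)P capture rate (uM^-1 s^-1)
#' @param k_off_pi4p PI(4)P release rate (s^-1)
#' @return An object of class `ord_rates`.
#' @export
rate_constants <- function(k_on_mb = 10, k_off_mb = 0.1,
                           k_on_ps = 10, k_off_ps = 1,
                           k_on_pi4p = 10, k_off_pi4p = 1) {
  r <- list(k_on_mb = k_on_mb, k_off_mb = k_off_mb,
            k_on_ps = k_on_ps, k_off_ps = k_off_ps,
            k_on_pi4p = k_on_pi4p, k_off_pi4p = k_off_pi4p)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate constant '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  structure(r, class = "ord_rates")
}

#' Concentration state of the exchange system
#'
#' Nine dynamic species plus the two membrane boundary species. `o_free` is
#' the empty soluble domain, `o_ma`/`o_mb` its membrane-docked empty forms,
#' `o_ps`/`o_pi4p` the soluble 1:1 lipid complexes; `ps_a`, `ps_b`,
#' `pi4p_a`, `pi4p_b` are the accessible lipid pools of membranes A and B.
#' `m_a` and `m_b` are held constant during integration (boundary species):
#' docking does not deplete them and lipid release regenerates the docked
#' protein without consuming membrane.
#'
#' @param o_free,o_ma,o_mb,o_ps,o_pi4p protein species (uM)
#' @param ps_a,ps_b,pi4p_a,pi4p_b membrane lipid pools (uM)
#' @param m_a,m_b membrane boundary concentrations (uM)
#' @return An object of class `ord_state` (named numeric vector).
#' @export
exchange_state <- function(o_free = 0.2, o_ma = 0, o_mb = 0,
                           o_ps = 0, o_pi4p = 0,
                           ps_a = 5, ps_b = 0,
                           pi4p_a = 0, pi4p_b = 0,
                           m_a = 100, m_b = 100) {
  s <- c(o_free = o_free, o_ma = o_ma, o_mb = o_mb,
         o_ps = o_ps, o_pi4p = o_pi4p,
         ps_a = ps_a, ps_b = ps_b, pi4p_a = pi4p_a, pi4p_b = pi4p_b,
         m_a = m_a, m_b = m_b)
  if (anyNA(s) || any(s < 0))
    stop("all concentrations must be non-negative", call. = FALSE)
  structure(s, class = "ord_state")
}

.DYNAMIC_SPECIES <- c("o_free", "o_ma", "o_mb", "o_ps", "o_pi4p",
                      "ps_a", "ps_b", "pi4p_a", "pi4p_b")
.PROTEIN_SPECIES <- c("o_free", "o_ma", "o_mb", "o_ps", "o_pi4p")

#' Simulation configuration
#'
#' @param rates an [rate_constants()] object
#' @param initial_state an [exchange_state()] object
#' @param t_end simulated duration (s)
#' @param t_step output grid spacing (s)
#' @param rate_window duration (s) over which the initial transfer rate is
#'   measured by a least-squares slope. The default (0.55 s) is the value
#'   calibrated for simulated sweeps; trace analysis of assay recordings
#'   uses the experimental 4 s / 8 point convention instead (see
#'   [initial_velocity()]).
#' @param rel_tol,abs_tol solver tolerances (abs_tol in uM)
#' @return An object of class `ord_sim_config`.
#' @export
sim_config <- function(rates = rate_constants(),
                       initial_state = exchange_state(),
                       t_end = 60, t_step = 0.05,
                       rate_window = 0.55,
                       rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(rates, "ord_rates"), inherits(initial_state, "ord_state"))
  if (!(t_step > 0)) stop("t_step must be > 0", call. = FALSE)
  if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (t_end > 0 && rate_window < t_step)
    stop("rate_window must be >= t_step", call. = FALSE)
  if (!(rel_tol > 0) || !(abs_tol > 0))
    stop("solver tolerances must be > 0", call. = FALSE)
  structure(list(rates = rates, initial_state = initial_state,
                 t_end = t_end, t_step = t_step, rate_window = rate_window,
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "ord_sim_config")
}

#' Paper-default configuration for transfer simulations
#'
#' Convenience constructor for the standard simulated assay: 0.2 uM protein
#' injected as free soluble domain, 5 uM accessible PS in membrane A, B
#' membrane empty (non-exchange) or carrying 5 uM accessible PI(4)P
#' (exchange), both membranes at 100 uM boundary concentration.
#'
#' @param k_on_ps PS capture rate (uM^-1 s^-1)
#' @param k_on_pi4p PI(4)P capture rate (uM^-1 s^-1)
#' @param k_off_pi4p PI(4)P release rate (s^-1)
#' @param pi4p_b initial accessible PI(4)P in membrane B (uM); 0 for the
#'   non-exchange condition, 5 for exchange
#' @param ps_a initial accessible PS in membrane A (uM)
#' @param k_off_mb membrane undocking rate (s^-1)
#' @param ... further arguments passed to [sim_config()]
#' @return An `ord_sim_config`.
#' @export
default_transfer_config <- function(k_on_ps = 10, k_on_pi4p = 10,
                                    k_off_pi4p = 1,
                                    pi4p_b = 0, ps_a = 5,
                                    k_off_mb = 0.1, ...) {
  sim_config(
    rates = rate_constants(k_on_ps = k_on_ps, k_on_pi4p = k_on_pi4p,
                           k_off_pi4p = k_off_pi4p, k_off_mb = k_off_mb),
    initial_state = exchange_state(ps_a = ps_a, pi4p_b = pi4p_b),
    ...
  )
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Expected keys: `rates` (any of the six constants), `initial` (any
#' dynamic species), `membranes` (`m_a_uM`, `m_b_uM`) and `sim`
#' (`t_end_s`, `t_step_s`, `rate_window_s`, `rel_tol`, `abs_tol`). Missing
#' keys fall back to the package defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return An `ord_sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  rates <- do.call(rate_constants, as.list(cfg$rates %||% list()))
  init <- as.list(cfg$initial %||% list())
  if (!is.null(cfg$membranes$m_a_uM)) init$m_a <- cfg$membranes$m_a_uM
  if (!is.null(cfg$membranes$m_b_uM)) init$m_b <- cfg$membranes$m_b_uM
  state <- do.call(exchange_state, init)
  sim <- as.list(cfg$sim %||% list())
  args <- list(rates = rates, initial_state = state)
  map <- c(t_end = "t_end_s", t_step = "t_step_s",
           rate_window = "rate_window_s",
           rel_tol = "rel_tol", abs_tol = "abs_tol")
  for (nm in names(map)) if (!is.null(sim[[map[[nm]]]])) args[[nm]] <- sim[[map[[nm]]]]
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
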