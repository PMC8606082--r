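# Independent oracles used across the model tests. None of these call the
# package's right-hand side or solver internals.

# Hand-written stoichiometry table of the twelve irreversible fluxes
# (forward/reverse of the six reactions) over the nine dynamic species.
# Columns: v1f v1r v2f v2r v3f v3r v4f v4r v5f v5r v6f v6r
oracle_stoichiometry <- function() {
  S <- matrix(0, nrow = 9, ncol = 12,
              dimnames = list(
                c("o_free", "o_ma", "o_mb", "o_ps", "o_pi4p",
                  "ps_a", "ps_b", "pi4p_a", "pi4p_b"),
                c("v1f", "v1r", "v2f", "v2r", "v3f", "v3r",
                  "v4f", "v4r", "v5f", "v5r", "v6f", "v6r")))
  S["o_free", c("v1f", "v1r", "v2f", "v2r")] <- c(-1, 1, -1, 1)
  S["o_ma", c("v1f", "v1r", "v3f", "v3r", "v5f", "v5r")] <- c(1, -1, -1, 1, -1, 1)
  S["o_mb", c("v2f", "v2r", "v4f", "v4r", "v6f", "v6r")] <- c(1, -1, -1, 1, -1, 1)
  S["o_ps", c("v3f", "v3r", "v4f", "v4r")] <- c(1, -1, 1, -1)
  S["o_pi4p", c("v5f", "v5r", "v6f", "v6r")] <- c(1, -1, 1, -1)
  S["ps_a", c("v3f", "v3r")] <- c(-1, 1)
  S["ps_b", c("v4f", "v4r")] <- c(-1, 1)
  S["pi4p_a", c("v5f", "v5r")] <- c(-1, 1)
  S["pi4p_b", c("v6f", "v6r")] <- c(-1, 1)
  S
}

oracle_fluxes <- function(k, y) {
  c(v1f = k$k_on_mb * y[["o_free"]] * y[["m_a"]],
    v1r = k$k_off_mb * y[["o_ma"]],
    v2f = k$k_on_mb * y[["o_free"]] * y[["m_b"]],
    v2r = k$k_off_mb * y[["o_mb"]],
    v3f = k$k_on_ps * y[["o_ma"]] * y[["ps_a"]],
    v3r = k$k_off_ps * y[["o_ps"]],
    v4f = k$k_on_ps * y[["o_mb"]] * y[["ps_b"]],
    v4r = k$k_off_ps * y[["o_ps"]],
    v5f = k$k_on_pi4p * y[["o_ma"]] * y[["pi4p_a"]],
    v5r = k$k_off_pi4p * y[["o_pi4p"]],
    v6f = k$k_on_pi4p * y[["o_mb"]] * y[["pi4p_b"]],
    v6r = k$k_off_pi4p * y[["o_pi4p"]])
}

# Algebraic equilibrium of the single-ligand system with identical
# membranes, from detailed balance plus the two conservation laws.
oracle_equilibrium_ps <- function(k, m, protein, ps_total) {
  r <- k$k_on_mb * m / k$k_off_mb
  resid <- function(x) {
    ops <- ps_total - 2 * x
    o <- (protein - ops) / (1 + 2 * r)
    k$k_on_ps * r * o * x / k$k_off_ps - ops
  }
  x <- stats::uniroot(resid, c(1e-12, ps_total / 2), tol = 1e-14)$root
  list(ps_a = x, ps_b = x, o_ps = ps_total - 2 * x)
}

# Closed-form solution (eigendecomposition) of the linear two-compartment
# limit: docked protein pools held constant, species (ps_a, ps_b, o_ps).
oracle_linear_transfer <- function(times, oma, omb, k_on_ps, k_off_ps, ps_a0) {
  A <- rbind(c(-k_on_ps * oma, 0, k_off_ps),
             c(0, -k_on_ps * omb, k_off_ps),
             c(k_on_ps * oma, k_on_ps * omb, -2 * k_off_ps))
  e <- eigen(A)
  c0 <- solve(e$vectors, c(ps_a0, 0, 0))
  sol <- sapply(times, function(t) Re(e$vectors %*% (c0 * exp(e$values * t))))
  out <- as.data.frame(t(sol))
  names(out) <- c("ps_a", "ps_b", "o_ps")
  out$time_s <- times
  out
}
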