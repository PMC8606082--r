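#' Maximum transferable lipid for a two-population assay geometry
#'
#' At full equilibration between two identical liposome populations, half
#' of the accessible (outer-leaflet) ligand of the donor population has
#' moved to the acceptor. With the standard geometry — 5% ligand, half of
#' 200 uM total lipid accessible — this is 2.5 uM.
#'
#' @param total_uM total lipid per population (uM)
#' @param fraction ligand mole fraction
#' @param leaflet_share accessible (outer leaflet) share of total lipid
#' @return Maximum transferable lipid (uM).
#' @export
max_transferable <- function(total_uM = 200, fraction = 0.05,
                             leaflet_share = 0.5) {
  accessible_lipid(total_uM, fraction, leaflet_share) / 2
}

# mean of the samples strictly inside (t_lo, t_hi), dropping `trim`
# samples next to each bound to avoid injection transients
segment_mean <- function(trace, t_lo = -Inf, t_hi = Inf, trim = 2L) {
  idx <- which(trace$time_s > t_lo & trace$time_s < t_hi)
  if (trim > 0L && is.finite(t_lo) && length(idx) > trim)
    idx <- idx[-seq_len(trim)]
  if (trim > 0L && is.finite(t_hi) && length(idx) > trim)
    idx <- idx[-(length(idx) - seq_len(trim) + 1L)]
  if (length(idx) == 0L)
    stop("no usable samples in the averaging window", call. = FALSE)
  mean(trace$f[idx])
}

#' Normalization references for a transfer trace
#'
#' Computes the baseline `f0`, equilibrium reference `f_eq` and pre-mix
#' reference `f0_eq` used to map fluorescence to transferred lipid:
#'
#' * `f0` — mean of the assay trace between the last liposome injection
#'   and the protein injection.
#' * `f_eq` — mean plateau of the equilibrium calibration trace: for
#'   two-population assays, after its last liposome addition; for the
#'   three-population assay, the 5-minute window starting 15 minutes after
#'   its final liposome addition.
#' * `f0_eq` — for the PS two-population assay, the baseline of the
#'   equilibrium sample before its second liposome addition; for PI(4)P
#'   and three-population assays the normalization uses `f0` in its
#'   place.
#'
#' Averaging windows take all samples strictly between the bounding
#' events, trimming two samples adjacent to each event to avoid injection
#' transients.
#'
#' @param trace assay `ord_trace`; must carry a `protein` event preceded
#'   by at least one liposome event
#' @param eq_trace equilibrium-reference `ord_trace`
#' @param assay_kind `"ps_two_pop"`, `"pi4p_two_pop"` or `"ps_three_pop"`
#' @param max_transfer_uM maximum transferable lipid (uM); see
#'   [max_transferable()]
#' @return An object of class `ord_norm_refs`: list with `f0`, `f_eq`,
#'   `f0_eq`, `max_transfer_uM`, `assay_kind`.
#' @export
compute_refs <- function(trace, eq_trace,
                         assay_kind = c("ps_two_pop", "pi4p_two_pop",
                                        "ps_three_pop"),
                         max_transfer_uM = max_transferable()) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(inherits(trace, "ord_trace"), inherits(eq_trace, "ord_trace"),
            max_transfer_uM > 0)
  t_prot <- event_time(trace, "protein")
  ev <- attr(trace, "events")
  pre <- ev$time_s[ev$time_s < t_prot & ev$label != "protein"]
  if (assay_kind == "ps_three_pop" && !has_event(trace, "liposome_c"))
    stop(structural_error("liposome_c"))
  if (length(pre) == 0L) stop(structural_error("liposome_b"))
  f0 <- segment_mean(trace, max(pre), t_prot)

  eq_ev <- attr(eq_trace, "events")
  if (assay_kind == "ps_three_pop") {
    t_c <- event_time(eq_trace, "liposome_c")
    f_eq <- segment_mean(eq_trace, t_c + 15 * 60, t_c + 20 * 60, trim = 0L)
    f0_eq <- f0
  } else {
    t_last <- if (nrow(eq_ev)) max(eq_ev$time_s) else -Inf
    f_eq <- segment_mean(eq_trace, t_last, Inf)
    f0_eq <- if (assay_kind == "ps_two_pop") {
      if (nrow(eq_ev) == 0L) stop(structural_error("liposome_b"))
      segment_mean(eq_trace, -Inf, min(eq_ev$time_s))
    } else {
      f0
    }
  }
  structure(list(f0 = f0, f_eq = f_eq, f0_eq = f0_eq,
                 max_transfer_uM = max_transfer_uM, assay_kind = assay_kind),
            class = "ord_norm_refs")
}

#' Normalize a transfer trace to absolute transferred lipid
#'
#' Truncates the trace at the protein injection (that sample becomes time
#' zero) and maps fluorescence to transferred lipid:
#' `transferred_uM(t) = max_transfer_uM * (f(t) - f0) / (f_eq - f0_eq)`.
#' The same formula serves quench-direction traces, where `f_eq < f0`
#' makes the numerator and denominator both negative. Noise-driven
#' negative values are retained for unbiased rate fitting.
#'
#' @param trace assay `ord_trace` with a `protein` event
#' @param refs an [compute_refs()] result
#' @return An object of class `ord_kinetics`: data.frame with `time_s`
#'   (re-zeroed at the protein injection) and `transferred_uM`.
#' @export
normalize_trace <- function(trace, refs) {
  stopifnot(inherits(trace, "ord_trace"), inherits(refs, "ord_norm_refs"))
  denom <- refs$f_eq - refs$f0_eq
  if (abs(denom) < 1e-6 * abs(refs$f0))
    stop(structure(
      class = c("ordflux_degenerate_calibration", "error", "condition"),
      list(message = paste0(
        "degenerate calibration: |f_eq - f0_eq| = ", format(abs(denom)),
        " is below the relative floor"), call = NULL)))
  t_prot <- event_time(trace, "protein")
  keep <- trace$time_s >= t_prot - 1e-9
  structure(
    data.frame(time_s = trace$time_s[keep] - t_prot,
               transferred_uM = refs$max_transfer_uM *
                 (trace$f[keep] - refs$f0) / denom),
    class = c("ord_kinetics", "data.frame"),
    refs = refs, channel = attr(trace, "channel"))
}

#' Normalize a three-liposome routing trace
#'
#' The three-population PS routing assay adds a second acceptor population
#' before the protein; its baseline is the average after the last
#' (`liposome_c`) injection and the normalization denominator uses the
#' plain baseline (`f_eq - f0`). Requires `liposome_b`, `liposome_c` and
#' `protein` events.
#'
#' @param trace assay `ord_trace` (quench direction)
#' @param refs refs computed with `assay_kind = "ps_three_pop"`
#' @return An `ord_kinetics`.
#' @export
three_liposome_normalize <- function(trace, refs) {
  for (lab in c("liposome_b", "liposome_c", "protein"))
    if (!has_event(trace, lab)) stop(structural_error(lab))
  stopifnot(identical(refs$assay_kind, "ps_three_pop"))
  normalize_trace(trace, refs)
}

#' Initial transfer velocity of normalized kinetics
#'
#' Least-squares slope (uM/s) through the first `n_points` samples of the
#' transferred-lipid time course — by default the first eight points,
#' i.e. 4 s at the nominal 0.5 s sampling — divided by the protein
#' concentration and expressed in lipids min^-1 per protein.
#'
#' @param kinetics an `ord_kinetics` from [normalize_trace()]
#' @param protein_uM protein concentration (uM), > 0
#' @param n_points number of leading samples fitted
#' @return Initial velocity (lipids min^-1 per protein).
#' @export
initial_velocity <- function(kinetics, protein_uM, n_points = 8L) {
  stopifnot(inherits(kinetics, "ord_kinetics"))
  if (!(protein_uM > 0)) stop("protein_uM must be > 0", call. = FALSE)
  if (nrow(kinetics) < n_points)
    stop("kinetics has fewer than ", n_points, " samples", call. = FALSE)
  i <- seq_len(n_points)
  slope <- stats::coef(stats::lm.fit(cbind(1, kinetics$time_s[i]),
                                     kinetics$transferred_uM[i]))[2]
  unname(slope) / protein_uM * 60
}
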