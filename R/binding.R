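#' Accessible lipid concentration
#'
#' The pool of a lipid available to a soluble protein: total lipid times
#' the ligand mole fraction times the outer-leaflet share (one half for a
#' symmetric bilayer). E.g. 100 uM total lipid doped with 2% labelled
#' lipid exposes 1 uM of it.
#'
#' @param total_uM total lipid (uM), >= 0
#' @param fraction ligand mole fraction, in `[0, 1]`
#' @param leaflet_share outer-leaflet share of total lipid
#' @return Accessible lipid (uM).
#' @export
accessible_lipid <- function(total_uM, fraction, leaflet_share = 0.5) {
  if (total_uM < 0) stop("total_uM must be >= 0", call. = FALSE)
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (leaflet_share < 0 || leaflet_share > 1)
    stop("leaflet_share must lie in [0, 1]", call. = FALSE)
  total_uM * fraction * leaflet_share
}

#' Construct a titration curve
#'
#' Concentration-response (or temperature-response) table feeding the
#' competition, melt and saturation fitters. `x` is accessible competitor
#' lipid (uM) for competition, temperature (degC) for melts, total lipid
#' (uM) for saturation binding; `y` is the (normalized) fluorescence.
#'
#' @param x predictor, strictly increasing within each replicate
#' @param y response
#' @param kind `"competition"`, `"melt"` or `"saturation"`
#' @param replicate_id optional replicate labels (same length as `x`)
#' @return An object of class `ord_titration`.
#' @export
titration_curve <- function(x, y, kind = c("competition", "melt", "saturation"),
                            replicate_id = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  rid <- if (is.null(replicate_id)) rep("r1", length(x)) else as.character(replicate_id)
  for (r in unique(rid)) {
    xs <- x[rid == r]
    if (is.unsorted(xs, strictly = TRUE))
      stop("x must be strictly increasing within each replicate", call. = FALSE)
    if (kind == "competition" && xs[1] != 0)
      stop("competition curves must start at x = 0", call. = FALSE)
    if (kind == "melt" && diff(range(xs)) < 20)
      stop("melt curves must span at least 20 degC", call. = FALSE)
  }
  structure(data.frame(x = x, y = y, replicate_id = rid),
            class = c("ord_titration", "data.frame"), kind = kind)
}

# joint Levenberg-Marquardt fit with shared shape parameters and a
# per-replicate gain (first replicate's gain fixed to 1)
.fit_joint <- function(curve, shape_fun, start, lower, upper,
                       par_names = names(start)) {
  rid <- factor(curve$replicate_id)
  R <- nlevels(rid)
  ri <- as.integer(rid)
  np <- length(start)
  resid_fun <- function(par) {
    p <- par[seq_len(np)]
    gains <- c(1, par[-seq_len(np)])[ri]
    gains * shape_fun(curve$x, p) - curve$y
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = c(start, rep(1, R - 1L)), fn = resid_fun,
    lower = c(lower, rep(0, R - 1L)), upper = c(upper, rep(Inf, R - 1L)),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4))
    return(structure(list(), class = "ordflux_failed_fit"))
  p <- fit$par[seq_len(np)]
  names(p) <- par_names
  se <- try({
    s <- summary(fit)$coefficients[seq_len(np), "Std. Error"]
    names(s) <- par_names
    s
  }, silent = TRUE)
  if (inherits(se, "try-error")) se <- NULL
  list(p = p, se = se, residuals = fit$fvec)
}

#' Fit a competitive-displacement curve
#'
#' Models the recovery of the protein's tryptophan fluorescence as
#' unlabelled competitor lipid displaces the bound fluorescent reporter:
#' a single-site hyperbola in accessible competitor concentration,
#' `y(x) = f_min + (f_max - f_min) * x / (l50 + x)`. `l50` is the
#' concentration displacing half the reporter; `1/l50` serves as the
#' relative-affinity proxy. This is an operational half-displacement
#' concentration, not an equilibrium inhibition constant.
#'
#' When several replicates are present they are fitted jointly with
#' shared `l50` and plateaus and a per-replicate gain.
#'
#' @param curve an [titration_curve()] of kind `"competition"` with at
#'   least 5 points
#' @return An object of class `ord_competition_fit`: list with `l50`,
#'   `f_min`, `f_max`, `inv_l50`, `se` (asymptotic standard errors) and
#'   `flag` (`NA` or `"no_displacement"` when the fitted dynamic range is
#'   within 3x the residual noise, in which case `l50` is `NA`).
#' @export
fit_competition <- function(curve) {
  stopifnot(inherits(curve, "ord_titration"),
            identical(attr(curve, "kind"), "competition"))
  if (nrow(curve) < 5L) stop("need at least 5 points", call. = FALSE)
  r1 <- curve[curve$replicate_id == curve$replicate_id[1], ]
  n <- nrow(r1)
  head_n <- max(1L, ceiling(n * 0.1))
  f_min0 <- mean(utils::head(r1$y, head_n))
  f_max0 <- mean(utils::tail(r1$y, head_n))
  half <- (f_min0 + f_max0) / 2
  l50_0 <- max(r1$x[which.min(abs(r1$y - half))], min(r1$x[r1$x > 0]))
  shape <- function(x, p) p[1] + (p[2] - p[1]) * x / (p[3] + x)
  fit <- .fit_joint(curve, shape, start = c(f_min0, f_max0, l50_0),
                    lower = c(-Inf, -Inf, 1e-9), upper = c(Inf, Inf, Inf),
                    par_names = c("f_min", "f_max", "l50"))
  out <- list(l50 = NA_real_, f_min = NA_real_, f_max = NA_real_,
              inv_l50 = NA_real_, se = NULL, flag = "no_displacement")
  if (inherits(fit, "ordflux_failed_fit"))
    return(structure(out, class = "ord_competition_fit"))
  p <- fit$p
  noise <- stats::sd(fit$residuals)
  if (abs(p[2] - p[1]) <= 3 * noise + 1e-9 * max(abs(curve$y)))
    return(structure(out, class = "ord_competition_fit"))
  structure(list(l50 = unname(p[3]), f_min = unname(p[1]), f_max = unname(p[2]),
                 inv_l50 = 1 / unname(p[3]), se = fit$se, flag = NA_character_),
            class = "ord_competition_fit")
}

#' Fit a thermal-shift melt curve
#'
#' Boltzmann sigmoid of the dye fluorescence during protein unfolding:
#' `y(T) = f_native + (f_denatured - f_native) / (1 + exp((t_m - T)/slope))`.
#' `t_m` is the melting midpoint, `slope` the transition width (degC).
#' Replicates, when present, share `t_m`, `slope` and plateau shape with a
#' per-replicate gain.
#'
#' @param curve an [titration_curve()] of kind `"melt"` with at least
#'   15 points
#' @return An object of class `ord_melt_fit`: list with `t_m`, `slope`,
#'   `f_native`, `f_denatured`, `se` and `flag` (`NA` or `"melt_failure"`
#'   when the fit does not converge, the midpoint sits at the scanned
#'   edge, or no sigmoidal transition is resolved).
#' @export
fit_melt <- function(curve) {
  stopifnot(inherits(curve, "ord_titration"),
            identical(attr(curve, "kind"), "melt"))
  if (nrow(curve) < 15L) stop("need at least 15 points", call. = FALSE)
  r1 <- curve[curve$replicate_id == curve$replicate_id[1], ]
  n <- nrow(r1)
  head_n <- max(1L, ceiling(n * 0.1))
  fn0 <- mean(utils::head(r1$y, head_n))
  fd0 <- mean(utils::tail(r1$y, head_n))
  tm0 <- r1$x[which.max(abs(diff(r1$y)))]  # steepest-slope temperature
  shape <- function(x, p) p[1] + (p[2] - p[1]) / (1 + exp((p[3] - x) / p[4]))
  fit <- .fit_joint(curve, shape, start = c(fn0, fd0, tm0, 2),
                    lower = c(-Inf, -Inf, -Inf, 1e-6),
                    upper = c(Inf, Inf, Inf, Inf),
                    par_names = c("f_native", "f_denatured", "t_m", "slope"))
  fail <- structure(list(t_m = NA_real_, slope = NA_real_,
                         f_native = NA_real_, f_denatured = NA_real_,
                         se = NULL, flag = "melt_failure"),
                    class = "ord_melt_fit")
  if (inherits(fit, "ordflux_failed_fit")) return(fail)
  p <- fit$p
  rng <- range(curve$x)
  span <- diff(rng)
  noise <- stats::sd(fit$residuals)
  edge <- p[3] < rng[1] + 1 || p[3] > rng[2] - 1
  if (edge || p[4] > span / 4 ||
      abs(p[2] - p[1]) <= 3 * noise + 1e-9 * max(abs(curve$y))) return(fail)
  structure(list(t_m = unname(p[3]), slope = unname(p[4]),
                 f_native = unname(p[1]), f_denatured = unname(p[2]),
                 se = fit$se, flag = NA_character_),
            class = "ord_melt_fit")
}

#' Fit a saturation membrane-binding curve
#'
#' Fluorescence intensity of a membrane-binding probe as a function of
#' titrated lipid: `y(x) = y0 * (1 + (a - 1) * x / (k + x))`, where `a`
#' is the intensity fold-change at saturation and `k` the half-saturation
#' lipid concentration (uM).
#'
#' @param curve an [titration_curve()] of kind `"saturation"` with at
#'   least 5 points including `x = 0`
#' @return An object of class `ord_saturation_fit`: list with `k`,
#'   `fold_change`, `y0`, `se` and `flag` (`NA` or `"no_binding"` when
#'   the fold-change is indistinguishable from 1).
#' @export
fit_saturation <- function(curve) {
  stopifnot(inherits(curve, "ord_titration"),
            identical(attr(curve, "kind"), "saturation"))
  if (nrow(curve) < 5L) stop("need at least 5 points", call. = FALSE)
  if (!any(curve$x == 0)) stop("curve must include x = 0", call. = FALSE)
  r1 <- curve[curve$replicate_id == curve$replicate_id[1], ]
  y0_0 <- r1$y[r1$x == 0][1]
  a0 <- max(utils::tail(r1$y, 2)) / y0_0
  half <- y0_0 * (1 + a0) / 2
  k0 <- max(r1$x[which.min(abs(r1$y - half))], min(r1$x[r1$x > 0]))
  shape <- function(x, p) p[1] * (1 + (p[2] - 1) * x / (p[3] + x))
  fit <- .fit_joint(curve, shape, start = c(y0_0, max(a0, 1.01), k0),
                    lower = c(1e-12, 1e-6, 1e-9), upper = c(Inf, Inf, Inf),
                    par_names = c("y0", "fold_change", "k"))
  fail <- structure(list(k = NA_real_, fold_change = NA_real_, y0 = NA_real_,
                         se = NULL, flag = "no_binding"),
                    class = "ord_saturation_fit")
  if (inherits(fit, "ordflux_failed_fit")) return(fail)
  p <- fit$p
  noise <- stats::sd(fit$residuals)
  se_a <- if (!is.null(fit$se)) fit$se[["fold_change"]] else NA_real_
  if (abs(p[2] - 1) * p[1] <= 3 * noise + 1e-9 * max(abs(curve$y)) ||
      (is.finite(se_a) && abs(p[2] - 1) <= 3 * se_a)) return(fail)
  structure(list(k = unname(p[3]), fold_change = unname(p[2]), y0 = unname(p[1]),
                 se = fit$se, flag = NA_character_),
            class = "ord_saturation_fit")
}

#' Pair transfer rates with competition-derived affinities
#'
#' Inner-joins per-species non-exchange transfer rates with per-species
#' `1/l50` affinity proxies and reports the Spearman rank correlation —
#' the quantity behind the observation that high-affinity ligands are
#' transferred more slowly.
#'
#' @param rates named numeric vector of transfer rates
#'   (lipids min^-1 per protein), names are species
#' @param fits named list of [fit_competition()] results (or named
#'   numeric vector of `inv_l50` values)
#' @return List with `table` (data.frame `species`, `rate`, `inv_l50`,
#'   sorted by `inv_l50`), `spearman_rho`, and `flag`
#'   (`"correlation_undefined"` when fewer than 3 shared species).
#' @export
rate_affinity_table <- function(rates, fits) {
  inv <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$inv_l50, numeric(1))
  shared <- intersect(names(rates), names(inv))
  if (length(shared) == 0L)
    stop("no species shared between rates and fits", call. = FALSE)
  tab <- data.frame(species = shared,
                    rate = unname(rates[shared]),
                    inv_l50 = unname(inv[shared]))
  tab <- tab[order(tab$inv_l50), ]
  rownames(tab) <- NULL
  if (nrow(tab) < 3L) {
    list(table = tab, spearman_rho = NA_real_, flag = "correlation_undefined")
  } else {
    rho <- stats::cor(tab$rate, tab$inv_l50, method = "spearman")
    list(table = tab, spearman_rho = rho, flag = NA_character_)
  }
}

#' Serialize a fit object to a JSON report
#'
#' @param fit a competition, melt or saturation fit
#' @param path output JSON path
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$se <- as.list(x$se)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
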