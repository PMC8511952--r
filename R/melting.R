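#' Hill melting model for CD thermal denaturation
#'
#' Empirical sigmoid describing a protein thermal melt monitored by CD at
#' 222 nm:
#' \deqn{CD(T) = CD_{min} + (CD_{max} - CD_{min})
#'   \frac{T^n}{T_m^n + T^n}}
#' where `CDmin` and `CDmax` are the signals of the folded and melted states,
#' `Tm` the apparent melting temperature and `n` the Hill coefficient
#' (cooperativity).  The equation is applied to the temperature in degrees
#' Celsius, as is conventional for apparent melting parameters reported on
#' this form; it is an empirical, not a thermodynamic, description.
#'
#' @param temperature temperature(s), degrees C, > 0.
#' @param Tm apparent melting temperature, degrees C.
#' @param n Hill coefficient, > 0.
#' @param CDmin,CDmax CD signal of the folded / melted state.
#' @return Model CD signal (vectorized over `temperature`).
#' @export
hill_melting_value <- function(temperature, Tm, n, CDmin, CDmax) {
  if (any(temperature <= 0)) stop("temperature must be > 0 (degrees C)")
  if (Tm <= 0 || n <= 0) stop("Tm and n must be > 0")
  # (T/Tm)^n form avoids overflow of T^n at large n
  z <- (temperature / Tm)^n
  CDmin + (CDmax - CDmin) * z / (1 + z)
}

#' Construct a CD melting curve
#'
#' @param temp_C temperatures, degrees C, strictly increasing, >= 10 points.
#' @param cd_signal ellipticity at 222 nm (machine units or MRE).
#' @param replicate,label annotations.
#' @return A `melting_curve` data frame.
#' @export
melting_curve <- function(temp_C, cd_signal, replicate = 1L,
                          label = "scenario") {
  if (length(temp_C) < 10L) stop("at least 10 temperature points required")
  if (any(diff(temp_C) <= 0)) stop("temp_C must be strictly increasing")
  if (length(cd_signal) != length(temp_C))
    stop("temp_C and cd_signal lengths differ")
  out <- data.frame(temp_C = temp_C, cd_signal = cd_signal,
                    replicate = replicate, label = label)
  class(out) <- c("melting_curve", "data.frame")
  out
}

#' Fit the Hill melting model to a CD melt
#'
#' Nonlinear least squares over (CDmin, CDmax, Tm, n).  Initialization:
#' CDmin / CDmax from the means of the first and last three points, Tm from
#' the half-range crossing, n = 10.  The curve must span both baselines: a
#' signal range below five times the point-to-point noise estimate is
#' rejected as having no detectable transition.
#'
#' @param curve a [melting_curve()].
#' @return An object of class `melt_fit` with elements `Tm`, `n`, `CDmin`,
#'   `CDmax`, `se_Tm`, `se_n`, `converged`, `reliable`, `label`.  A Tm at a
#'   grid boundary is flagged unreliable.
#' @export
fit_melting_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  d <- data.frame(T = curve$temp_C, cd = curve$cd_signal)
  rng <- diff(range(d$cd))
  # robust point-to-point noise estimate from successive differences
  noise <- stats::mad(diff(d$cd)) / sqrt(2)
  if (rng < 5 * max(noise, .Machine$double.eps))
    stop("no transition detectable: signal range (", format(rng),
         ") below 5 x point-to-point noise (", format(noise), ")")
  cd_lo <- mean(utils::head(d$cd, 3))
  cd_hi <- mean(utils::tail(d$cd, 3))
  half <- (cd_lo + cd_hi) / 2
  tm0 <- d$T[which.min(abs(d$cd - half))]
  start <- list(CDmin = cd_lo, CDmax = cd_hi, Tm = tm0, n = 10)
  fit <- minpack.lm::nlsLM(
    cd ~ hill_melting_value(T, Tm, n, CDmin, CDmax), data = d,
    start = start,
    lower = c(CDmin = -Inf, CDmax = -Inf, Tm = 1e-3, n = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 4), names(est)))
  reliable <- est[["Tm"]] > min(d$T) && est[["Tm"]] < max(d$T)
  if (!reliable)
    warning("fitted Tm (", format(est[["Tm"]]),
            " C) lies at or beyond the scanned range: fit unreliable")
  structure(
    list(Tm = est[["Tm"]], n = est[["n"]], CDmin = est[["CDmin"]],
         CDmax = est[["CDmax"]], se_Tm = unname(se["Tm"]),
         se_n = unname(se["n"]), converged = fit$convInfo$isConv,
         reliable = reliable, label = curve$label[1], data = d),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit> %s: Tm = %.4g +/- %.2g C, n = %.3g +/- %.2g%s\n",
    x$label, x$Tm, x$se_Tm, x$n, x$se_n,
    if (!x$reliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Mean residue molar ellipticity
#'
#' Converts a raw ellipticity reading to mean residue molar ellipticity:
#' `MRE = theta_mdeg / (10 * pathlength_cm * conc_molar * n_residues)` in
#' deg cm^2 dmol^-1.
#'
#' @param theta_mdeg observed ellipticity, millidegrees (sign preserved).
#' @param n_residues number of residues in the protein, > 0.
#' @param conc_molar protein concentration, mol/L, > 0.
#' @param pathlength_cm cuvette pathlength, cm, > 0.
#' @return MRE in deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(theta_mdeg, n_residues, conc_molar,
                                     pathlength_cm) {
  if (n_residues <= 0 || conc_molar <= 0 || pathlength_cm <= 0)
    stop("n_residues, conc_molar and pathlength_cm must all be > 0")
  theta_mdeg / (10 * pathlength_cm * conc_molar * n_residues)
}
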