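#' Construct a progress curve
#'
#' @param time_s seconds, strictly increasing.
#' @param product_uM charged tRNA, uM; must lie in
#'   `[0, substrate_uM + tolerance]`.
#' @param substrate_uM,enzyme_uM total tRNA / enzyme, uM (scalars).
#' @param replicate,label optional annotations.
#' @return A `progress_curve` data frame.
#' @export
progress_curve <- function(time_s, product_uM, substrate_uM, enzyme_uM,
                           replicate = 1L, label = "scenario") {
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (length(product_uM) != length(time_s))
    stop("time_s and product_uM lengths differ")
  tol <- 1e-6 * max(substrate_uM, 1)
  if (any(product_uM < -tol) || any(product_uM > substrate_uM + tol))
    stop("product_uM must lie within [0, substrate_uM]")
  out <- data.frame(time_s = time_s, product_uM = product_uM,
                    substrate_uM = substrate_uM, enzyme_uM = enzyme_uM,
                    replicate = replicate, label = label)
  class(out) <- c("progress_curve", "data.frame")
  out
}

#' Initial rate from the low-conversion window of a progress curve
#'
#' Fits an ordinary least-squares line (free intercept) through the early
#' points of a progress curve, restricted to product below
#' `max_conversion_fraction` of the total substrate — the standard linear
#' initial-rate window.  At least four qualifying points are required.
#'
#' @param curve a [progress_curve()] (any data frame with `time_s`,
#'   `product_uM`, `substrate_uM`).
#' @param max_conversion_fraction conversion cap defining the window
#'   (default 0.10).
#' @return The initial rate in uM/s (non-negative).  A negative fitted slope
#'   is truncated to 0 with a warning, as is an all-zero signal.
#' @export
extract_initial_rate <- function(curve, max_conversion_fraction = 0.10) {
  stopifnot(all(c("time_s", "product_uM", "substrate_uM") %in% names(curve)))
  cap <- max_conversion_fraction * curve$substrate_uM[1]
  keep <- curve$product_uM <= cap
  if (sum(keep) < 4L)
    stop("fewer than 4 points below the conversion cap (",
         sum(keep), " qualify)")
  d <- curve[keep, ]
  if (all(d$product_uM == 0)) {
    warning("all-zero product signal: degenerate fit, rate = 0")
    return(0)
  }
  slope <- unname(stats::coef(stats::lm(product_uM ~ time_s, data = d))[2])
  if (is.na(slope)) stop("degenerate initial-rate fit")
  if (slope < 0) {
    warning("negative fitted initial slope (", format(slope),
            "); truncated to 0")
    slope <- 0
  }
  slope
}

#' Michaelis-Menten velocity
#'
#' `v = kcat * E0 * S / (KM + S)`, the steady-state initial velocity.
#'
#' @param S substrate concentration(s), uM.
#' @param kcat turnover number, s^-1.
#' @param KM Michaelis constant, uM.
#' @param E0 total enzyme, uM.
#' @return Velocity in uM/s.
#' @export
mm_velocity <- function(S, kcat, KM, E0) kcat * E0 * S / (KM + S)

#' Fit the Michaelis-Menten equation to initial rates
#'
#' Nonlinear least squares of `v = kcat * E0 * S / (KM + S)` over (kcat, KM),
#' initialized at `KM0 = median(S)` and `kcat0 = max(v) / E0`.  Fits whose KM
#' falls outside `[min(S)/100, max(S)*100]` are flagged unreliable (the data
#' do not constrain saturation).
#'
#' @param substrate substrate concentrations, uM (>= 5 values).
#' @param rates initial rates, uM/s, same length.
#' @param enzyme_total total enzyme, uM (> 0).
#' @param label scenario annotation carried into summaries.
#' @return An object of class `mm_fit` with elements `kcat`, `KM`,
#'   `kcat_over_KM`, `se_kcat`, `se_KM`, `n_points`, `converged`,
#'   `reliable`, `label` and the fitted `data`.
#' @export
fit_michaelis_menten <- function(substrate, rates, enzyme_total,
                                 label = "scenario") {
  if (length(substrate) != length(rates))
    stop("substrate and rates lengths differ")
  if (length(substrate) < 5L)
    stop("at least 5 (S, v) pairs are required")
  if (enzyme_total <= 0) stop("enzyme_total must be > 0")
  d <- data.frame(S = substrate, v = rates)
  kcat0 <- max(max(d$v) / enzyme_total, .Machine$double.eps)
  # retry ladder: unidentifiable (e.g. purely linear) data can make the
  # gradient singular at the default start; larger KM starts move off the
  # singularity so the fit can run to its flagged-unreliable outcome
  fit <- NULL
  for (km0 in c(stats::median(d$S), 10 * max(d$S), 100 * max(d$S))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ kcat * enzyme_total * S / (KM + S), data = d,
        start = list(kcat = kcat0 * max(1, km0 / max(d$S)), KM = km0),
        lower = c(kcat = 0, KM = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(kcat = NA_real_, KM = NA_real_))
    converged <- fit$convInfo$isConv
  } else {
    # unidentifiable saturation (KM runs beyond the data) makes the model
    # gradient singular at the optimum; fall back to the raw
    # Levenberg-Marquardt optimizer to still report flagged estimates
    res_fn <- function(p) d$v - p[1] * enzyme_total * d$S / (p[2] + d$S)
    lm_fit <- minpack.lm::nls.lm(
      par = c(kcat = kcat0 * 100, KM = 100 * max(d$S)), fn = res_fn,
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- lm_fit$par
    se <- c(kcat = NA_real_, KM = NA_real_)
    converged <- lm_fit$info %in% 1:4
  }
  reliable <- est[["KM"]] >= min(d$S) / 100 && est[["KM"]] <= max(d$S) * 100
  if (!reliable)
    warning("fitted KM (", format(est[["KM"]]),
            " uM) is far outside the substrate range: fit unreliable ",
            "(saturation not constrained by the data)")
  structure(
    list(kcat = est[["kcat"]], KM = est[["KM"]],
         kcat_over_KM = est[["kcat"]] / est[["KM"]],
         se_kcat = unname(se["kcat"]), se_KM = unname(se["KM"]),
         n_points = nrow(d), converged = converged,
         reliable = reliable, enzyme_total = enzyme_total,
         label = label, data = d),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> %s: kcat = %.4g +/- %.2g s^-1, KM = %.4g +/- %.2g uM, kcat/KM = %.4g uM^-1 s^-1%s\n",
    x$label, x$kcat, x$se_kcat, x$KM, x$se_KM, x$kcat_over_KM,
    if (!x$reliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Replicate summary of Michaelis-Menten fits with fold changes
#'
#' Aggregates a list of [fit_michaelis_menten()] results by scenario label:
#' per-scenario mean and SD of kcat, KM and kcat/KM (catalytic efficiency is
#' averaged per replicate, i.e. mean of ratios), plus fold decreases of each
#' parameter relative to a named reference scenario
#' (`fold = reference mean / scenario mean`).  A single replicate reports SD
#' as `NA`, not 0.
#'
#' @param fits list of `mm_fit` objects (each carries its scenario `label`).
#' @param reference_label scenario used as the fold-change reference.
#' @return A `kinetic_summary` data frame with one row per scenario.
#' @export
summarize_replicates <- function(fits, reference_label) {
  if (length(fits) == 0L) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, TRUE, "mm_fit")))
  labs <- vapply(fits, `[[`, "", "label")
  if (!reference_label %in% labs)
    stop("unknown reference label: ", reference_label)
  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  agg <- function(lab) {
    f <- fits[labs == lab]
    kcat <- vapply(f, `[[`, 0, "kcat")
    km <- vapply(f, `[[`, 0, "KM")
    eff <- vapply(f, `[[`, 0, "kcat_over_KM")
    data.frame(label = lab, n = length(f),
               kcat_mean = mean(kcat), kcat_sd = sd_or_na(kcat),
               KM_mean = mean(km), KM_sd = sd_or_na(km),
               eff_mean = mean(eff), eff_sd = sd_or_na(eff))
  }
  out <- do.call(rbind, lapply(unique(labs), agg))
  ref <- out[out$label == reference_label, ]
  out$fold_decrease_kcat <- ref$kcat_mean / out$kcat_mean
  out$fold_decrease_KM <- ref$KM_mean / out$KM_mean
  out$fold_decrease_eff <- ref$eff_mean / out$eff_mean
  attr(out, "reference") <- reference_label
  class(out) <- c("kinetic_summary", "data.frame")
  out
}
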