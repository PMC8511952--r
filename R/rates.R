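#' Rate-constant set for the eight-step aminoacylation mechanism
#'
#' Bundles the forward and reverse rate constants of the eight elementary
#' steps of the tRNA-dependent aminoacylation mechanism (see
#' [build_eight_step_scheme()] for the step ordering).  Second-order
#' constants are in uM^-1 s^-1, first-order constants in s^-1.  Steps 6
#' (aminoacyl transfer) and 8 (charged-tRNA release) are treated as
#' committed, irreversible steps: their reverse constants must be exactly 0.
#'
#' @param k_fwd numeric(8), forward rate constants, all >= 0.
#' @param k_rev numeric(8), reverse rate constants, all >= 0; entries 6 and 8
#'   must be 0.
#' @param label scenario name, e.g. `"WT"` or `"P14R"`.
#' @return An object of class `rate_set`.
#' @seealso [default_rates()], [perturb_rate()]
#' @export
rate_set <- function(k_fwd, k_rev, label = "scenario") {
  if (length(k_fwd) != 8L || length(k_rev) != 8L)
    stop("k_fwd and k_rev must each have length 8")
  if (!is.numeric(k_fwd) || !is.numeric(k_rev) ||
      anyNA(k_fwd) || anyNA(k_rev))
    stop("rate constants must be numeric and non-missing")
  if (any(k_fwd < 0) || any(k_rev < 0))
    stop("rate constants must be >= 0")
  irrev <- c(6L, 8L)
  if (any(k_rev[irrev] != 0))
    stop("steps 6 and 8 are irreversible: k_rev[6] and k_rev[8] must be 0")
  structure(
    list(k_fwd = as.numeric(k_fwd), k_rev = as.numeric(k_rev),
         label = as.character(label)[1]),
    class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>", x$label, "\n")
  steps <- c("tRNA binding", "Glu binding", "ATP binding", "activation",
             "PPi release", "transfer", "AMP release", "product release")
  for (i in 1:8)
    cat(sprintf("  step %d %-15s k_fwd = %-10.4g k_rev = %.4g\n",
                i, steps[i], x$k_fwd[i], x$k_rev[i]))
  invisible(x)
}

#' Shipped default rate constants
#'
#' Returns the calibrated default `rate_set` for the wild-type enzyme, or the
#' variant obtained by slowing the glutamate-activation step (step 4) 10-fold,
#' the perturbation that reproduces the altered steady-state kinetics of the
#' P14R variant.
#'
#' The wild-type constants were derived analytically from the steady-state
#' algebra of the scheme (see the package vignette) so that an apparent
#' Michaelis-Menten scan of the mechanism under the standard assay condition
#' (20 uM Glu, 4 mM ATP, 100 nM enzyme, 0.5-16 uM tRNA) yields
#' kcat ~ 0.167 s^-1 and KM ~ 1.62 uM.  They are a calibrated, internally
#' consistent parameterization, not measured microscopic constants.
#'
#' @param scenario `"WT"` or `"P14R"` (step-4 forward rate divided by 10).
#' @return A `rate_set`.
#' @export
default_rates <- function(scenario = c("WT", "P14R")) {
  scenario <- match.arg(scenario)
  wt <- rate_set(
    k_fwd = c(0.119, 10, 1, 0.2, 100, 1.45, 100, 8.7),
    k_rev = c(2.4,   10, 100, 1, 0.1, 0,  0.001, 0),
    label = "WT")
  if (scenario == "WT") return(wt)
  perturb_rate(wt, step = 4L, factor = 0.1, label = "P14R")
}

#' Scale one forward rate constant
#'
#' @param rates a `rate_set`.
#' @param step integer in 1..8, the step whose forward constant is scaled.
#' @param factor multiplicative factor > 0 (or 0 to switch the step off).
#' @param label optional new scenario label.
#' @return A new `rate_set` differing from `rates` in exactly one entry.
#' @export
perturb_rate <- function(rates, step, factor, label = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  step <- as.integer(step)
  if (length(step) != 1L || is.na(step) || step < 1L || step > 8L)
    stop("step must be a single integer in 1..8")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0)
    stop("factor must be a single number >= 0")
  kf <- rates$k_fwd
  kf[step] <- kf[step] * factor
  if (is.null(label))
    label <- sprintf("%s[step%d x %g]", rates$label, step, factor)
  rate_set(kf, rates$k_rev, label = label)
}
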