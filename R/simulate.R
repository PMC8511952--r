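#' Assay condition (initial concentrations)
#'
#' All concentrations in uM.  `labeled_ppi_fraction` is the mole fraction of
#' the pyrophosphate pool carrying the radiolabel at t = 0 (isotope-exchange
#' assays only).
#'
#' @param enzyme_total,tRNA_total,glu_total,atp_total,ppi_total initial
#'   totals, uM, all >= 0.
#' @param labeled_ppi_fraction fraction in `[0, 1]`.
#' @param temperature_label free-text annotation (not used numerically).
#' @return An object of class `assay_condition`.
#' @export
assay_condition <- function(enzyme_total, tRNA_total, glu_total = 20,
                            atp_total = 4000, ppi_total = 0,
                            labeled_ppi_fraction = 0,
                            temperature_label = "37C") {
  conc <- c(enzyme_total = enzyme_total, tRNA_total = tRNA_total,
            glu_total = glu_total, atp_total = atp_total,
            ppi_total = ppi_total)
  if (anyNA(conc) || any(conc < 0))
    stop("all concentrations must be non-negative")
  if (labeled_ppi_fraction < 0 || labeled_ppi_fraction > 1)
    stop("labeled_ppi_fraction must be in [0, 1]")
  structure(c(as.list(conc),
              list(labeled_ppi_fraction = labeled_ppi_fraction,
                   temperature_label = temperature_label)),
            class = "assay_condition")
}

#' Solver control for mechanism simulations
#'
#' @param rtol,atol relative / absolute integration tolerances (atol in uM).
#' @param conservation_rtol maximum tolerated relative drift of any conserved
#'   total along a trajectory.
#' @param method a [deSolve::ode()] method; `"lsoda"` switches automatically
#'   between stiff and non-stiff regimes.
#' @return A list of class `ode_control`.
#' @export
ode_control <- function(rtol = 1e-8, atol = 1e-10,
                        conservation_rtol = 1e-6, method = "lsoda") {
  structure(list(rtol = rtol, atol = atol,
                 conservation_rtol = conservation_rtol, method = method),
            class = "ode_control")
}

# Initial state vector for a scheme under a condition.  Exchange-style
# preincubation equilibrates the enzyme-tRNA binding step (step 1 alone)
# before t = 0; otherwise all species start free.
.initial_state <- function(scheme, cond, preincubate = FALSE) {
  y <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  y["E"] <- cond$enzyme_total
  y["tRNA"] <- cond$tRNA_total
  y["Glu"] <- cond$glu_total
  lam <- cond$labeled_ppi_fraction
  if (scheme$labeled) {
    y["ATP"] <- cond$atp_total
    y["ATP_star"] <- 0
    y["PPi"] <- cond$ppi_total * (1 - lam)
    y["PPi_star"] <- cond$ppi_total * lam
  } else {
    y["ATP"] <- cond$atp_total
    y["PPi"] <- cond$ppi_total
  }
  if (preincubate) {
    k1 <- scheme$rates$k_fwd[1]
    km1 <- scheme$rates$k_rev[1]
    if (k1 > 0) {
      Kd <- km1 / k1
      b <- .bound_depletion(y[["E"]], y[["tRNA"]], Kd)
      y["E"] <- y[["E"]] - b
      y["tRNA"] <- y[["tRNA"]] - b
      y["E.tRNA"] <- b
    }
  }
  y
}

# Exact bound concentration for E + T <-> ET with dissociation constant Kd
# (numerically stable quadratic root; Kd = 0 gives the stoichiometric limit).
.bound_depletion <- function(E0, T0, Kd) {
  if (E0 == 0 || T0 == 0) return(0)
  s <- E0 + T0 + Kd
  disc <- s^2 - 4 * E0 * T0
  2 * E0 * T0 / (s + sqrt(max(disc, 0)))
}

# Mass-action derivative closure for deSolve.
.derivative_fn <- function(scheme) {
  N <- stoichiometry_matrix(scheme)
  nr <- length(scheme$reactions)
  ridx <- lapply(scheme$reactions, function(r)
    match(names(r$reactants), scheme$species))
  pidx <- lapply(scheme$reactions, function(r)
    match(names(r$products), scheme$species))
  kf <- vapply(scheme$reactions, `[[`, 0, "kf")
  kr <- vapply(scheme$reactions, `[[`, 0, "kr")
  function(t, y, parms) {
    v <- numeric(nr)
    for (j in seq_len(nr)) {
      fwd <- kf[j] * prod(y[ridx[[j]]])
      rev <- if (kr[j] > 0) kr[j] * prod(y[pidx[[j]]]) else 0
      v[j] <- fwd - rev
    }
    list(drop(N %*% v))
  }
}

#' Integrate a mechanism time course
#'
#' Numerically integrates the mass-action ODE system of a
#' [build_eight_step_scheme()] scheme from the initial concentrations in
#' `cond`, using a stiff-safe solver.  Conservation of every conserved total
#' is verified at every output time; drift beyond
#' `control$conservation_rtol`, or negative-concentration excursions beyond
#' tolerance, are errors.
#'
#' @param scheme a `kinetic_scheme`.
#' @param cond an [assay_condition()].
#' @param time_grid strictly increasing times in seconds, starting at 0.
#' @param preincubate if `TRUE`, the enzyme-tRNA binding step is brought to
#'   equilibrium before t = 0 (exchange-assay protocol); otherwise all
#'   species start free (aminoacylation protocol, reaction initiated by
#'   enzyme addition).
#' @param control an [ode_control()].
#' @return A `trajectory`: data frame with column `time_s` followed by one
#'   column per species (uM), with the scheme attached as attribute
#'   `"scheme"`.
#' @export
simulate_time_course <- function(scheme, cond, time_grid,
                                 preincubate = FALSE,
                                 control = ode_control()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(cond, "assay_condition"))
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L || time_grid[1] != 0 ||
      any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing and start at 0")

  y0 <- .initial_state(scheme, cond, preincubate = preincubate)
  sol <- deSolve::ode(y = y0, times = time_grid, func = .derivative_fn(scheme),
                      parms = NULL, method = control$method,
                      rtol = control$rtol, atol = control$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1],
         ", rtol = ", control$rtol, ", atol = ", control$atol, ")")
  conc <- as.matrix(sol[, -1, drop = FALSE])

  neg_tol <- 1e3 * control$atol
  if (min(conc) < -neg_tol)
    stop("negative concentration excursion beyond tolerance: min = ",
         format(min(conc)))
  conc[conc < 0] <- 0

  for (nm in names(scheme$conserved)) {
    tot <- drop(conc %*% scheme$conserved[[nm]])
    scale <- max(abs(tot[1]), control$atol)
    if (max(abs(tot - tot[1])) > control$conservation_rtol * scale)
      stop("conserved total '", nm, "' drifts beyond tolerance (",
           format(max(abs(tot - tot[1])) / scale), " relative)")
  }

  out <- data.frame(time_s = time_grid, conc, check.names = FALSE)
  attr(out, "scheme") <- scheme
  attr(out, "condition") <- cond
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Total charged tRNA along a trajectory
#'
#' Sums free charged tRNA and the enzyme-bound charged-tRNA complexes, the
#' quantity reported by a filter-binding aminoacylation assay.
#'
#' @param traj a `trajectory` from [simulate_time_course()].
#' @return A `progress_curve` data frame with columns `time_s` and
#'   `product_uM`, plus `substrate_uM` and `enzyme_uM` copied from the
#'   simulated condition.
#' @export
charged_tRNA_observable <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  need <- c("GlutRNA", "E.GlutRNA", "E.GlutRNA.AMP")
  if (!all(need %in% names(traj)))
    stop("trajectory lacks charged-tRNA species: ",
         paste(setdiff(need, names(traj)), collapse = ", "))
  cond <- attr(traj, "condition")
  out <- data.frame(
    time_s = traj$time_s,
    product_uM = traj[["GlutRNA"]] + traj[["E.GlutRNA"]] +
      traj[["E.GlutRNA.AMP"]],
    substrate_uM = cond$tRNA_total,
    enzyme_uM = cond$enzyme_total)
  class(out) <- c("progress_curve", "data.frame")
  out
}

#' Simulate an ATP-PPi isotope-exchange time course
#'
#' Runs the mechanism in its exchange configuration (nonchargeable tRNA,
#' transfer step disabled) with a radiolabeled pyrophosphate pool and tracks
#' the labeled and unlabeled ATP/PPi pools explicitly.  Label enters ATP
#' only through reversal of the activation step followed by reversal of ATP
#' binding, so exchange reports on the amino-acid activation step in
#' isolation.  The enzyme is preincubated with tRNA (binding step at
#' equilibrium) before the reaction starts, matching the assay protocol.
#'
#' @param scheme a `kinetic_scheme` built with `chargeable_tRNA = FALSE`.
#' @param cond an [assay_condition()] with `ppi_total > 0` and
#'   `labeled_ppi_fraction > 0`.
#' @param time_grid seconds, starting at 0.
#' @param control an [ode_control()].
#' @return An `exchange_curve` data frame with columns `time_s` and
#'   `frac_atp` (fraction of total label residing in the ATP pool, counting
#'   enzyme-bound ATP isotopologues).
#' @export
simulate_ppi_exchange <- function(scheme, cond, time_grid,
                                  control = ode_control()) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (scheme$chargeable || vapply(scheme$reactions, `[[`, 0, "kf")[6] != 0)
    stop("exchange mode requires a nonchargeable-tRNA scheme ",
         "(build_eight_step_scheme(..., chargeable_tRNA = FALSE))")
  if (cond$labeled_ppi_fraction <= 0 || cond$ppi_total <= 0)
    stop("exchange simulation needs a labeled pyrophosphate pool")

  lab <- .expand_labeled_scheme(scheme)
  traj <- simulate_time_course(lab, cond, time_grid, preincubate = TRUE,
                               control = control)
  label_total <- traj[["ATP_star"]] + traj[["E.tRNA.Glu.ATP_star"]] +
    traj[["E.tRNA.GluAMP.PPi_star"]] + traj[["PPi_star"]]
  atp_label <- traj[["ATP_star"]] + traj[["E.tRNA.Glu.ATP_star"]]
  out <- data.frame(time_s = traj$time_s,
                    frac_atp = atp_label / label_total)
  attr(out, "condition") <- cond
  class(out) <- c("exchange_curve", "data.frame")
  out
}
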