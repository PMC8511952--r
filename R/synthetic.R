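#' Noise model for synthetic assay data
#'
#' @param kind `"gaussian_absolute"` (sigma in signal units) or
#'   `"gaussian_relative"` (sigma as a fraction of each true value).
#' @param sigma noise magnitude, >= 0.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_absolute", "gaussian_relative"),
                        sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# Evaluate `expr` under a private RNG stream seeded from the noise model,
# restoring the caller's RNG state afterwards, so generation is
# deterministic under a fixed seed and does not disturb the session.
.with_noise_rng <- function(noise, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  force(expr)
}

# Additive draw under the model; values outside [lo, hi] are redrawn
# point-wise (seed-stable: redraws consume the same stream).
.noisy <- function(truth, noise, lo = -Inf, hi = Inf) {
  if (noise$sigma == 0) return(pmin(pmax(truth, lo), hi))
  sd <- switch(noise$kind,
               gaussian_absolute = rep(noise$sigma, length(truth)),
               gaussian_relative = noise$sigma * abs(truth))
  out <- truth + stats::rnorm(length(truth), 0, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    out[bad] <- truth[bad] + stats::rnorm(length(bad), 0, sd[bad])
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(truth[bad], lo), hi)
  out
}

#' Integrated Michaelis-Menten progress curve
#'
#' Product at time t solves the implicit integrated rate law
#' `KM * log(S0 / (S0 - P)) + P = kcat * E0 * t`; each time point is
#' resolved by bisection (stats::uniroot), which is exact to tolerance and
#' robust for all parameter values.
#'
#' @param time_s seconds.
#' @param kcat,KM,E0 Michaelis-Menten parameters (s^-1, uM, uM).
#' @param S0 initial substrate, uM.
#' @return Product concentrations, uM.
#' @export
integrated_mm_product <- function(time_s, kcat, KM, E0, S0) {
  vapply(time_s, function(t) {
    if (t <= 0 || kcat * E0 == 0) return(0)
    g <- function(P) KM * log(S0 / (S0 - P)) + P - kcat * E0 * t
    upper <- S0 * (1 - 1e-12)
    if (g(upper) < 0) return(S0)
    stats::uniroot(g, c(0, upper), tol = 1e-12 * max(S0, 1))$root
  }, numeric(1))
}

#' Scenario specification for the synthetic generators
#'
#' A light container naming the scenario, the generating truth and the assay
#' design.  The design defaults of each generator correspond to the standard
#' designs of the four assays (see the individual generators).
#'
#' @param label scenario name.
#' @param truth named list of generating parameters (e.g. `kcat`, `KM`, or
#'   `Kd`, `r_free`, `r_bound`, or `Tm`, `n`, `CDmin`, `CDmax`, or a
#'   `rate_set`).
#' @param design named list of design overrides (grids, concentrations,
#'   `replicates`).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(label, truth, design = list()) {
  stopifnot(is.list(truth), is.list(design))
  if (!is.null(design$replicates) && design$replicates < 1)
    stop("replicate count must be >= 1")
  structure(list(label = label, truth = truth, design = design),
            class = "scenario_spec")
}

.design <- function(spec, name, default) {
  if (!is.null(spec$design[[name]])) spec$design[[name]] else default
}

#' Generate synthetic aminoacylation progress curves
#'
#' One progress curve per (substrate, replicate) on the steady-state assay
#' design: by default the WT design of 0.5-16 uM tRNA with 100 nM enzyme.
#' Truth may be Michaelis-Menten parameters (`kcat`, `KM`; curves from the
#' integrated rate law) or a `rate_set` (`rates`; curves simulated from the
#' full mechanism).  Each curve's time grid runs to ~15% conversion in 10
#' points, so the 10% initial-rate window retains at least 4 points.
#' Gaussian noise (default relative) is applied to the product readings,
#' clipped draws re-sampled within `[0, S0]`.
#'
#' @param spec a [scenario_spec()]; design fields `substrate_uM`,
#'   `enzyme_uM`, `replicates`, `n_time` override the defaults.
#' @param noise a [noise_model()].
#' @return A list of [progress_curve()]s with the generating truth attached
#'   as attribute `"truth"`.
#' @export
generate_aminoacylation_dataset <- function(spec, noise = noise_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  S_grid <- .design(spec, "substrate_uM", c(0.5, 1, 2, 4, 8, 16))
  E0 <- .design(spec, "enzyme_uM", 0.1)
  reps <- .design(spec, "replicates", 1L)
  n_time <- .design(spec, "n_time", 10L)

  mech <- !is.null(spec$truth$rates)
  if (mech) {
    scheme <- build_eight_step_scheme(spec$truth$rates)
  } else if (is.null(spec$truth$kcat) || is.null(spec$truth$KM)) {
    stop("truth must supply either `rates` or both `kcat` and `KM`")
  }

  curves <- list()
  .with_noise_rng(noise, {
    for (S0 in S_grid) {
      if (mech) {
        cond <- assay_condition(enzyme_total = E0, tRNA_total = S0)
        t15 <- .time_to_conversion(scheme, cond, frac = 0.15)
        grid <- seq(0, t15, length.out = n_time)
        truth_curve <- charged_tRNA_observable(
          simulate_time_course(scheme, cond, grid))$product_uM
      } else {
        v0 <- mm_velocity(S0, spec$truth$kcat, spec$truth$KM, E0)
        t15 <- if (v0 > 0) 0.15 * S0 / v0 else 1
        grid <- seq(0, t15, length.out = n_time)
        truth_curve <- integrated_mm_product(grid, spec$truth$kcat,
                                             spec$truth$KM, E0, S0)
      }
      for (rep in seq_len(reps)) {
        obs <- .noisy(truth_curve, noise, lo = 0, hi = S0)
        obs[1] <- 0  # t = 0 blank
        curves[[length(curves) + 1L]] <-
          progress_curve(grid, obs, S0, E0, replicate = rep,
                         label = spec$label)
      }
    }
  })
  attr(curves, "truth") <- spec$truth
  attr(curves, "design") <- list(substrate_uM = S_grid, enzyme_uM = E0,
                                 replicates = reps)
  curves
}

#' Generate synthetic fluorescence-anisotropy titrations
#'
#' Default design: 5 nM labeled tRNA, protein on a 2-fold serial dilution
#' from Kd/10 up past 30 x Kd (10 points), the standard titration layout.
#' Truth: `Kd` (nM), optional `r_free` (default 0.05), `r_bound` (default
#' 0.18), `q` (default 1).  Absolute Gaussian noise on anisotropy, clipped
#' draws re-sampled within (0, 0.4].
#'
#' @param spec a [scenario_spec()]; design fields `protein_nM`, `ligand_nM`,
#'   `replicates` override the defaults.
#' @param noise a [noise_model()].
#' @return A list of [titration_curve()]s with attribute `"truth"`.
#' @export
generate_titration <- function(spec, noise = noise_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  Kd <- spec$truth$Kd
  if (is.null(Kd)) stop("truth must supply Kd")
  r_free <- if (is.null(spec$truth$r_free)) 0.05 else spec$truth$r_free
  r_bound <- if (is.null(spec$truth$r_bound)) 0.18 else spec$truth$r_bound
  q <- if (is.null(spec$truth$q)) 1 else spec$truth$q
  P <- .design(spec, "protein_nM", Kd / 10 * 2^(0:9))
  L <- .design(spec, "ligand_nM", 5)
  reps <- .design(spec, "replicates", 1L)

  f <- fraction_bound_depletion(P, L, Kd)
  r_true <- anisotropy_signal(f, r_free, r_bound, q)
  curves <- list()
  .with_noise_rng(noise, {
    for (rep in seq_len(reps)) {
      r_obs <- .noisy(r_true, noise, lo = 1e-6, hi = 0.4)
      curves[[length(curves) + 1L]] <-
        titration_curve(P, r_obs, ligand_nM = L, replicate = rep,
                        label = spec$label)
    }
  })
  attr(curves, "truth") <- list(Kd = Kd, r_free = r_free,
                                r_bound = r_bound, q = q)
  attr(curves, "design") <- list(protein_nM = P, ligand_nM = L,
                                 replicates = reps)
  curves
}

#' Generate synthetic CD melting curves
#'
#' Default design: 20-90 degrees C in 2 degree increments (36 points), the
#' standard melt protocol.  Truth: `Tm`, `n`, and signal endpoints `CDmin`
#' (folded), `CDmax` (melted; defaults -10 and -2).  Absolute Gaussian noise
#' on the CD signal.
#'
#' @param spec a [scenario_spec()]; design fields `temp_C`, `replicates`
#'   override the defaults.
#' @param noise a [noise_model()].
#' @return A list of [melting_curve()]s with attribute `"truth"`.
#' @export
generate_melting <- function(spec, noise = noise_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$truth$Tm) || is.null(spec$truth$n))
    stop("truth must supply Tm and n")
  CDmin <- if (is.null(spec$truth$CDmin)) -10 else spec$truth$CDmin
  CDmax <- if (is.null(spec$truth$CDmax)) -2 else spec$truth$CDmax
  temp <- .design(spec, "temp_C", seq(20, 90, by = 2))
  reps <- .design(spec, "replicates", 1L)

  cd_true <- hill_melting_value(temp, spec$truth$Tm, spec$truth$n,
                                CDmin, CDmax)
  curves <- list()
  .with_noise_rng(noise, {
    for (rep in seq_len(reps)) {
      cd_obs <- .noisy(cd_true, noise)
      curves[[length(curves) + 1L]] <-
        melting_curve(temp, cd_obs, replicate = rep, label = spec$label)
    }
  })
  attr(curves, "truth") <- list(Tm = spec$truth$Tm, n = spec$truth$n,
                                CDmin = CDmin, CDmax = CDmax)
  attr(curves, "design") <- list(temp_C = temp, replicates = reps)
  curves
}

#' Generate synthetic ATP-PPi exchange time courses
#'
#' Default design: the standard exchange assay (3 uM enzyme, 10 uM
#' nonchargeable tRNA, 1.6 mM Glu, 4 mM ATP, 2 mM PPi with tracer label),
#' sampled every 6 min over 30 min.  Truth: a `rate_set` under `rates`; the
#' transfer step is disabled automatically.  Absolute Gaussian noise on the
#' label fraction, clipped draws re-sampled within [0, 1].
#'
#' @param spec a [scenario_spec()]; design fields `time_s`, `enzyme_uM`,
#'   `tRNA_uM`, `glu_uM`, `atp_uM`, `ppi_uM`, `replicates` override the
#'   defaults.
#' @param noise a [noise_model()].
#' @return A list of `exchange_curve` data frames (columns `time_s`,
#'   `frac_atp`, `replicate`, `label`) with attribute `"truth"`.
#' @export
generate_exchange <- function(spec, noise = noise_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$truth$rates)) stop("truth must supply `rates`")
  time_s <- .design(spec, "time_s", seq(0, 30, by = 6) * 60)
  cond <- assay_condition(
    enzyme_total = .design(spec, "enzyme_uM", 3),
    tRNA_total = .design(spec, "tRNA_uM", 10),
    glu_total = .design(spec, "glu_uM", 1600),
    atp_total = .design(spec, "atp_uM", 4000),
    ppi_total = .design(spec, "ppi_uM", 2000),
    labeled_ppi_fraction = 0.01)
  reps <- .design(spec, "replicates", 1L)

  scheme <- build_eight_step_scheme(spec$truth$rates, chargeable_tRNA = FALSE)
  truth_curve <- simulate_ppi_exchange(scheme, cond, time_s)
  curves <- list()
  .with_noise_rng(noise, {
    for (rep in seq_len(reps)) {
      obs <- .noisy(truth_curve$frac_atp, noise, lo = 0, hi = 1)
      out <- data.frame(time_s = time_s, frac_atp = obs,
                        replicate = rep, label = spec$label)
      class(out) <- c("exchange_curve", "data.frame")
      curves[[length(curves) + 1L]] <- out
    }
  })
  attr(curves, "truth") <- spec$truth
  attr(curves, "noise_free") <- truth_curve
  curves
}
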