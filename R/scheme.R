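#' @keywords internal
#' Species names of the core scheme, in a fixed order.
.core_species <- c(
  "E", "tRNA", "Glu", "ATP",
  "E.tRNA", "E.tRNA.Glu", "E.tRNA.Glu.ATP",
  "E.tRNA.GluAMP.PPi", "E.tRNA.GluAMP", "PPi",
  "E.GlutRNA.AMP", "AMP", "E.GlutRNA", "GlutRNA")

.reaction <- function(reactants, products, kf, kr, name) {
  list(reactants = reactants, products = products,
       kf = kf, kr = kr, name = name)
}

#' Build the eight-step tRNA-dependent aminoacylation scheme
#'
#' Constructs the elementary mass-action scheme for glutamylation of tRNA by
#' a glutamyl-tRNA synthetase, in which amino-acid activation requires prior
#' tRNA binding (as for GluRS, GlnRS, ArgRS and class I LysRS).  The eight
#' ordered steps are:
#'
#' 1. `E + tRNA <-> E.tRNA`
#' 2. `E.tRNA + Glu <-> E.tRNA.Glu`
#' 3. `E.tRNA.Glu + ATP <-> E.tRNA.Glu.ATP`
#' 4. activation: `E.tRNA.Glu.ATP <-> E.tRNA.GluAMP.PPi`
#' 5. PPi release: `E.tRNA.GluAMP.PPi <-> E.tRNA.GluAMP + PPi`
#' 6. transfer: `E.tRNA.GluAMP -> E.GlutRNA.AMP` (irreversible)
#' 7. AMP release: `E.GlutRNA.AMP <-> E.GlutRNA + AMP`
#' 8. product release: `E.GlutRNA -> E + GlutRNA` (irreversible)
#'
#' There is no pathway from free enzyme plus Glu and ATP to the adenylate
#' without tRNA bound, which encodes the tRNA requirement for activation.
#' With `chargeable_tRNA = FALSE` (a 3'-oxidized, nonchargeable tRNA, the
#' configuration of an ATP-PPi isotope-exchange assay) the transfer step 6 is
#' forced to rate 0, so flux stops at the enzyme-bound adenylate.
#'
#' Four conserved totals (enzyme, tRNA, adenine nucleotide, pyrophosphate
#' moiety) are attached to the scheme and verified against the stoichiometry
#' of every reaction at construction time.
#'
#' @param rates a [rate_set()].
#' @param chargeable_tRNA logical; if `FALSE` the transfer step is disabled.
#' @return An object of class `kinetic_scheme` with elements `species`,
#'   `reactions`, `conserved` (named list of coefficient vectors),
#'   `rates`, and `chargeable`.
#' @export
build_eight_step_scheme <- function(rates, chargeable_tRNA = TRUE) {
  stopifnot(inherits(rates, "rate_set"))
  kf <- rates$k_fwd
  kr <- rates$k_rev
  if (!chargeable_tRNA) kf[6] <- 0

  rx <- list(
    .reaction(c(E = 1, tRNA = 1),        c(E.tRNA = 1),                kf[1], kr[1], "tRNA binding"),
    .reaction(c(E.tRNA = 1, Glu = 1),    c(E.tRNA.Glu = 1),            kf[2], kr[2], "Glu binding"),
    .reaction(c(E.tRNA.Glu = 1, ATP = 1), c(E.tRNA.Glu.ATP = 1),       kf[3], kr[3], "ATP binding"),
    .reaction(c(E.tRNA.Glu.ATP = 1),     c(E.tRNA.GluAMP.PPi = 1),     kf[4], kr[4], "activation"),
    .reaction(c(E.tRNA.GluAMP.PPi = 1),  c(E.tRNA.GluAMP = 1, PPi = 1), kf[5], kr[5], "PPi release"),
    .reaction(c(E.tRNA.GluAMP = 1),      c(E.GlutRNA.AMP = 1),         kf[6], kr[6], "transfer"),
    .reaction(c(E.GlutRNA.AMP = 1),      c(E.GlutRNA = 1, AMP = 1),    kf[7], kr[7], "AMP release"),
    .reaction(c(E.GlutRNA = 1),          c(E = 1, GlutRNA = 1),        kf[8], kr[8], "product release"))

  species <- .core_species
  conserved <- list(
    enzyme = .coef(species, c("E", "E.tRNA", "E.tRNA.Glu", "E.tRNA.Glu.ATP",
                              "E.tRNA.GluAMP.PPi", "E.tRNA.GluAMP",
                              "E.GlutRNA.AMP", "E.GlutRNA")),
    tRNA = .coef(species, c("tRNA", "E.tRNA", "E.tRNA.Glu", "E.tRNA.Glu.ATP",
                            "E.tRNA.GluAMP.PPi", "E.tRNA.GluAMP",
                            "E.GlutRNA.AMP", "E.GlutRNA", "GlutRNA")),
    adenine = .coef(species, c("ATP", "E.tRNA.Glu.ATP", "E.tRNA.GluAMP.PPi",
                               "E.tRNA.GluAMP", "E.GlutRNA.AMP", "AMP")),
    pyrophosphate = .coef(species, c("ATP", "E.tRNA.Glu.ATP",
                                     "E.tRNA.GluAMP.PPi", "PPi")))

  scheme <- structure(
    list(species = species, reactions = rx, conserved = conserved,
         rates = rates, chargeable = chargeable_tRNA, labeled = FALSE),
    class = "kinetic_scheme")
  .check_conservation_stoichiometry(scheme)
  scheme
}

.coef <- function(species, members, weight = 1) {
  v <- stats::setNames(numeric(length(species)), species)
  v[members] <- weight
  v
}

# Every conserved total must be invariant under every reaction's net
# stoichiometry; a defect here is a programming error, so stop hard.
.check_conservation_stoichiometry <- function(scheme) {
  N <- stoichiometry_matrix(scheme)
  for (nm in names(scheme$conserved)) {
    dev <- drop(scheme$conserved[[nm]] %*% N)
    if (any(abs(dev) > 1e-12))
      stop("conserved total '", nm, "' is not stoichiometrically invariant")
  }
  invisible(TRUE)
}

#' Net stoichiometric matrix of a scheme
#'
#' @param scheme a `kinetic_scheme`.
#' @return A species-by-reaction matrix of net stoichiometric coefficients.
#' @export
stoichiometry_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  N <- matrix(0, length(scheme$species), length(scheme$reactions),
              dimnames = list(scheme$species, vapply(scheme$reactions,
                                                     `[[`, "", "name")))
  for (j in seq_along(scheme$reactions)) {
    r <- scheme$reactions[[j]]
    N[names(r$reactants), j] <- N[names(r$reactants), j] - r$reactants
    N[names(r$products), j]  <- N[names(r$products), j] + r$products
  }
  N
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme>", x$rates$label,
      if (!x$chargeable) "(nonchargeable tRNA: transfer disabled)", "\n")
  cat(" ", length(x$species), "species,", length(x$reactions), "reactions,",
      length(x$conserved), "conserved totals\n")
  for (j in seq_along(x$reactions)) {
    r <- x$reactions[[j]]
    arrow <- if (r$kr > 0) "<->" else "-->"
    cat(sprintf("  %2d. %s %s %s   kf=%.4g kr=%.4g\n", j,
                paste(names(r$reactants), collapse = " + "), arrow,
                paste(names(r$products), collapse = " + "), r$kf, r$kr))
  }
  invisible(x)
}

# Expand a nonchargeable scheme with isotopically labeled ATP/PPi pools.
# Labeled and unlabeled isotopologues are kinetically equivalent; steps 3-5
# are duplicated for the labeled species and the label travels with the
# beta/gamma-phosphates (PPi moiety): it can enter ATP only via reversal of
# activation (step 4) followed by reversal of ATP binding (step 3).
.expand_labeled_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"), !scheme$labeled)
  kf <- vapply(scheme$reactions, `[[`, 0, "kf")
  kr <- vapply(scheme$reactions, `[[`, 0, "kr")
  species <- c(scheme$species,
               "ATP_star", "E.tRNA.Glu.ATP_star", "E.tRNA.GluAMP.PPi_star",
               "PPi_star")
  rx <- c(scheme$reactions, list(
    .reaction(c(E.tRNA.Glu = 1, ATP_star = 1), c(E.tRNA.Glu.ATP_star = 1),
              kf[3], kr[3], "ATP binding (labeled)"),
    .reaction(c(E.tRNA.Glu.ATP_star = 1), c(E.tRNA.GluAMP.PPi_star = 1),
              kf[4], kr[4], "activation (labeled)"),
    .reaction(c(E.tRNA.GluAMP.PPi_star = 1), c(E.tRNA.GluAMP = 1, PPi_star = 1),
              kf[5], kr[5], "PPi release (labeled)")))

  star <- c("ATP_star", "E.tRNA.Glu.ATP_star", "E.tRNA.GluAMP.PPi_star",
            "PPi_star")
  conserved <- lapply(scheme$conserved, function(v) {
    w <- .coef(species, character(0))
    w[names(v)] <- v
    w
  })
  conserved$enzyme[c("E.tRNA.Glu.ATP_star", "E.tRNA.GluAMP.PPi_star")] <- 1
  conserved$tRNA[c("E.tRNA.Glu.ATP_star", "E.tRNA.GluAMP.PPi_star")] <- 1
  conserved$adenine[c("ATP_star", "E.tRNA.Glu.ATP_star",
                      "E.tRNA.GluAMP.PPi_star")] <- 1
  conserved$pyrophosphate[star] <- 1
  conserved$label <- .coef(species, star)

  out <- structure(
    list(species = species, reactions = rx, conserved = conserved,
         rates = scheme$rates, chargeable = scheme$chargeable,
         labeled = TRUE),
    class = "kinetic_scheme")
  .check_conservation_stoichiometry(out)
  out
}
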