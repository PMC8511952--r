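# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the binding oracle solves the equilibrium by
# root-bracketing on the mass-action equation, and the rapid-equilibrium
# Michaelis-Menten oracle is the closed-form steady-state algebra of the
# scheme, not an ODE integration.

# Fraction of ligand bound for E + L <-> EL at totals (P, L), by uniroot on
# (P - B)(L - B) = Kd * B.
oracle_fraction_bound <- function(P, L, Kd) {
  vapply(P, function(p) {
    if (p == 0 || L == 0) return(0)
    g <- function(B) (p - B) * (L - B) - Kd * B
    stats::uniroot(g, c(0, min(p, L)), tol = 1e-14)$root / L
  }, numeric(1))
}

# Closed-form apparent Michaelis-Menten parameters of the eight-step scheme
# in the rapid-equilibrium limit: binding steps 1-3 equilibrate fast
# relative to activation (step 4), and every step after activation is fast
# and irreversible.  With dissociation constants K1..K3 and co-substrate
# concentrations G (Glu) and A (ATP):
#   weights per tRNA-bound enzyme: w = 1 + G/K2 + (G/K2)(A/K3)
#   kcat = k4 * (G/K2)(A/K3) / w,   KM = K1 / w
oracle_rapid_eq_mm <- function(k4, K1, K2, K3, G = 20, A = 4000) {
  wGA <- (G / K2) * (A / K3)
  w <- 1 + G / K2 + wGA
  list(kcat = k4 * wGA / w, KM = K1 / w)
}

# A rapid-equilibrium rate set realizing the oracle's assumptions: binding
# >= 2000x faster than chemistry, post-activation steps fast/irreversible.
rapid_eq_rates <- function(k4 = 0.05, K1 = 1, K2 = 10, K3 = 1000) {
  rate_set(
    k_fwd = c(100, 100, 100, k4, 1000, 1000, 1000, 1000),
    k_rev = c(100 * K1, 100 * K2, 100 * K3, 0, 0, 0, 0, 0),
    label = "rapid-eq")
}

# Reference designs used throughout (steady-state assay layouts).
wt_design <- list(substrate_uM = c(0.5, 1, 2, 4, 8, 16), enzyme_uM = 0.1)
p14r_design <- list(substrate_uM = c(0.063, 0.125, 0.25, 0.5, 1, 2),
                    enzyme_uM = 0.01)

# Exchange assay condition (uM): 3 uM enzyme, 10 uM nonchargeable tRNA,
# 1.6 mM Glu, 4 mM ATP, 2 mM PPi with tracer label.
exchange_condition <- function(labeled = 0.01) {
  assay_condition(enzyme_total = 3, tRNA_total = 10, glu_total = 1600,
                  atp_total = 4000, ppi_total = 2000,
                  labeled_ppi_fraction = labeled)
}
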