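# Independent numeric oracles for the closed-form rule predictions.

# strict restraint: root of min(P_T - a*p, L_T - a*l), a piecewise-linear
# decreasing function of the amount walked along the rail
oracle_strict <- function(diet, target) {
  f <- function(a) min(target$point$protein_mg - a * diet$protein_frac,
                       target$point$lipid_mg - a * diet$lipid_frac)
  upper <- 2 * max(target$point$protein_mg / diet$protein_frac,
                   target$point$lipid_mg / diet$lipid_frac)
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

# closest distance: numeric minimisation of squared distance to the target
oracle_closest <- function(diet, target) {
  f <- function(a) (a * diet$protein_frac - target$point$protein_mg)^2 +
    (a * diet$lipid_frac - target$point$lipid_mg)^2
  upper <- 4 * max(target$point$protein_mg / diet$protein_frac,
                   target$point$lipid_mg / diet$lipid_frac)
  stats::optimize(f, c(0, upper), tol = 1e-10)$minimum
}

# equal distance: root of |dP| - |dL| along the rail, bracketed between the
# two threshold amounts so the root found is the complementary-error one
# (over-eat one nutrient, under-eat the other)
oracle_equal <- function(diet, target) {
  f <- function(a) abs(a * diet$protein_frac - target$point$protein_mg) -
    abs(a * diet$lipid_frac - target$point$lipid_mg)
  a1 <- target$point$protein_mg / diet$protein_frac
  a2 <- target$point$lipid_mg / diet$lipid_frac
  stats::uniroot(f, sort(c(a1, a2)), tol = 1e-12)$root
}
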