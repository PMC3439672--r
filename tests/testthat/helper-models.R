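# Shared fixtures, built in code.

# Minimal reversible binding system A + B <-> C with Kd = kr/kf.
binding_model <- function(kf = 1, kr = 1, a0 = 1, b0 = 1) {
  network_model(
    "binding",
    list(species("A", c(A = 1)),
         species("B", c(B = 1)),
         species("C", c(A = 1, B = 1), "complex")),
    list(reaction("R1", c(A = 1, B = 1), c(C = 1), kf = kf, kr = kr)),
    initial = c(A = a0, B = b0),
    readout_moiety = "A")
}

# Analytic equilibrium of the binding quadratic for equal totals T and
# dissociation constant Kd: positive root of C^2 - (2T + Kd) C + T^2 = 0.
binding_equilibrium <- function(total = 1, kd = 1) {
  b <- 2 * total + kd
  (b - sqrt(b^2 - 4 * total^2)) / 2
}

# SM monomer name of a catalog model (ySM / nSM).
catalog_sm <- function(model) {
  mono <- names(model$species)[vapply(model$species,
                                      function(s) s$role == "monomer",
                                      logical(1))]
  grep("SM$", mono, value = TRUE)
}

# The four catalog motifs, freshly constructed.
catalog_models <- function() {
  list(yeast = yeast_ssnm(), neuronal = neuronal_ssnm(),
       mutant_neuronal = mutant_neuronal_ssnm(),
       extended_neuronal = extended_neuronal_ssnm())
}

# Left-null-space dimension of the net stoichiometric matrix, computed
# independently of conservation_laws() via QR rank.
left_nullspace_dim <- function(model) {
  S <- ssnm:::stoich_matrices(model)$S
  nrow(S) - qr(S)$rank
}
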