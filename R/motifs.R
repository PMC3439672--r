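# Catalog of SM-SNARE network motifs (SSNMs).
#
# The four motifs encode the assembly cascade of exocytic membrane fusion:
# syntaxin and SNAP25 preassemble into the t-SNARE complex, the v-SNARE
# (synaptobrevin/VAMP) joins to form the SNAREpin, the SM protein
# (Sec1p/Munc18-1) binds the assembled SNAREpin (pattern-2 binding) and
# stimulates fusion. The wildtype neuronal motif additionally carries the
# pattern-1 closed binding mode, Munc18-1 clamping monomeric syntaxin-1 in a
# closed conformation that cannot enter SNAREpin assembly; its deletion gives
# the mutant motif, and adding an abstract displacement factor (DF,
# Munc13/Tomosyn-like) that strips SM off the closed complex gives the
# extended motif.
#
# The exact supplementary reaction list and rate constants of the source
# model are not reproduced here; the reaction sets below are the package's
# documented reconstruction from the published network diagrams and text,
# and the default rate set is the package's own calibration (see the methods
# vignette). Rates are configuration: every simulation entry point accepts a
# rate-set argument.

# Shared default rate table; labels are common across motifs so that rate
# sets are comparable by construction. Units: associations uM^-1 s^-1,
# dissociations and fusion s^-1.
.default_rate_table <- list(
  R1 = c(kf = 1,     kr = 0.1),    # Syx + S25 <-> t-SNARE complex
  R2 = c(kf = 1,     kr = 0.01),   # T + Syb <-> SNAREpin
  R3 = c(kf = 5,     kr = 0.05),   # Pin + SM <-> Pin.SM (pattern 2)
  R4 = c(kf = 2e-5,  kr = 0),      # Pin -> Fused            (basal, kf0)
  R5 = c(kf = 1e-3,  kr = 0),      # Pin.SM -> Fused.SM      (stimulated, kf1)
  R6 = c(kf = 30,    kr = 0.003),  # Syx + SM <-> closed complex (pattern 1)
  R7 = c(kf = 1,     kr = 0.1)     # DF + closed <-> DF.SM + Syx (displacement)
)

# Build the five-reaction assembly/fusion cascade with a species-name prefix
# ("y" or "n"). Proteins are named after the prefixed monomers.
.cascade_model <- function(prefix, name, sm0 = 0, snare0 = 4.5) {
  p <- function(x) paste0(prefix, x)
  syx <- p("Syx"); s25 <- p("S25"); syb <- p("Syb"); sm <- p("SM")
  tc <- p("T"); pin <- p("Pin"); pinsm <- p("PinSM")
  fus <- p("Fused"); fussm <- p("FusedSM")
  one <- function(...) {
    prot <- c(...)
    stats::setNames(rep(1L, length(prot)), prot)
  }
  sp <- list(
    species(syx, one(syx), "monomer"),
    species(s25, one(s25), "monomer"),
    species(syb, one(syb), "monomer"),
    species(sm,  one(sm),  "monomer"),
    species(tc,    one(syx, s25), "complex"),
    species(pin,   one(syx, s25, syb), "complex"),
    species(pinsm, one(syx, s25, syb, sm), "complex"),
    species(fus,   one(syx, s25, syb), "fused"),
    species(fussm, one(syx, s25, syb, sm), "fused")
  )
  k <- .default_rate_table
  rx <- list(
    reaction("R1", one(syx, s25), one(tc), kf = k$R1[["kf"]], kr = k$R1[["kr"]]),
    reaction("R2", one(tc, syb), one(pin), kf = k$R2[["kf"]], kr = k$R2[["kr"]]),
    reaction("R3", one(pin, sm), one(pinsm), kf = k$R3[["kf"]], kr = k$R3[["kr"]]),
    reaction("R4", one(pin), one(fus), kf = k$R4[["kf"]], kr = 0),
    reaction("R5", one(pinsm), one(fussm), kf = k$R5[["kf"]], kr = 0)
  )
  init <- stats::setNames(c(snare0, snare0, snare0, sm0), c(syx, s25, syb, sm))
  network_model(name, sp, rx, initial = init, readout_moiety = syb)
}

#' The cascade-like yeast SM-SNARE network motif
#'
#' Yeast exocytic SNAREs Sso1p (ySyx), Sec9p (yS25) and Snc1/2p (ySyb)
#' assemble sequentially (t-SNARE complex, then SNAREpin) and the yeast SM
#' protein Sec1p (ySM) binds only the assembled SNAREpin (pattern 2),
#' stimulating fusion. Nine species, five reactions (R1-R5); fusion is an
#' irreversible state change to a fused species carrying the same moieties.
#'
#' @param sm0 Initial ySM concentration (uM); default 0 (scanned 0-6 uM).
#' @param snare0 Initial concentration of each SNARE (uM); default 4.5.
#' @return A validated \code{ssnm_model} with readout moiety \code{ySyb}.
#' @examples
#' yeast_ssnm()
#' @export
yeast_ssnm <- function(sm0 = 0, snare0 = 4.5) {
  .cascade_model("y", "yeast", sm0 = sm0, snare0 = snare0)
}

#' The feedback-loop-like wildtype neuronal SM-SNARE network motif
#'
#' Same assembly cascade as the yeast motif (syntaxin-1 = nSyx, SNAP25 =
#' nS25, VAMP2 = nSyb, Munc18-1 = nSM) plus the neuron-specific pattern-1
#' reaction R6: nSM binds monomeric nSyx in the closed conformation,
#' producing a complex (\code{nSyxSM_closed}) that cannot enter SNAREpin
#' assembly. Pattern-2 binding of nSM to the SNAREpin sequesters nSM away
#' from nSyx, closing a feedback loop; the interplay of the two binding
#' modes produces the biphasic ("bifurcation") fusion dose-response in nSM.
#' Ten species, six reactions.
#'
#' @inheritParams yeast_ssnm
#' @return A validated \code{ssnm_model} with readout moiety \code{nSyb}.
#' @examples
#' neuronal_ssnm(sm0 = 4.5)
#' @export
neuronal_ssnm <- function(sm0 = 0, snare0 = 4.5) {
  m <- .cascade_model("n", "neuronal", sm0 = sm0, snare0 = snare0)
  closed <- species("nSyxSM_closed", c(nSyx = 1L, nSM = 1L), "complex")
  m$species[[closed$name]] <- closed
  m$initial[closed$name] <- 0
  k <- .default_rate_table$R6
  m$reactions$R6 <- reaction("R6", c(nSyx = 1, nSM = 1),
                             c(nSyxSM_closed = 1),
                             kf = k[["kf"]], kr = k[["kr"]])
  # re-run constructor checks on the augmented model
  network_model("neuronal", m$species, m$reactions, initial = m$initial,
                readout_moiety = m$readout_moiety)
}

#' The mutant neuronal SM-SNARE network motif (open syntaxin)
#'
#' The wildtype neuronal motif with the closed-binding reaction R6 removed
#' (and the then-orphaned closed complex dropped), emulating the
#' constitutively open syntaxin-1 mutant (L165A/E166A) that abolishes
#' pattern-1 binding. Structurally isomorphic to the yeast motif under the
#' y/n species renaming; its fusion dose-response is monotone like yeast's.
#'
#' @inheritParams yeast_ssnm
#' @return A validated \code{ssnm_model} with 9 species and 5 reactions.
#' @export
mutant_neuronal_ssnm <- function(sm0 = 0, snare0 = 4.5) {
  .cascade_model("n", "mutant_neuronal", sm0 = sm0, snare0 = snare0)
}

#' The displacement-factor-extended neuronal motif
#'
#' Wildtype neuronal motif plus an abstract displacement factor DF
#' (Munc13/Tomosyn-like) that strips nSM off the closed nSyx complex by a
#' single reversible exchange, R7: DF + closed <-> DF.nSM + nSyx. The
#' extension does not change the feedback-loop topology, and the motif
#' retains the biphasic dose-response of the wildtype neuronal model.
#'
#' @inheritParams yeast_ssnm
#' @param df0 Initial DF concentration (uM); default 1.0.
#' @return A validated \code{ssnm_model} with 12 species and 7 reactions.
#' @export
extended_neuronal_ssnm <- function(sm0 = 0, snare0 = 4.5, df0 = 1.0) {
  m <- neuronal_ssnm(sm0 = sm0, snare0 = snare0)
  m$species$DF <- species("DF", c(DF = 1L), "monomer")
  m$species$DFnSM <- species("DFnSM", c(DF = 1L, nSM = 1L), "complex")
  m$initial["DF"] <- df0
  m$initial["DFnSM"] <- 0
  k <- .default_rate_table$R7
  m$reactions$R7 <- reaction("R7", c(DF = 1, nSyxSM_closed = 1),
                             c(DFnSM = 1, nSyx = 1),
                             kf = k[["kf"]], kr = k[["kr"]])
  network_model("extended_neuronal", m$species, m$reactions,
                initial = m$initial, readout_moiety = m$readout_moiety)
}

#' Catalog motif constructor lookup
#'
#' @param motif One of \code{"yeast"}, \code{"neuronal"},
#'   \code{"mutant_neuronal"} (alias \code{"mutant"}),
#'   \code{"extended_neuronal"} (alias \code{"extended"}).
#' @param ... Passed to the motif constructor.
#' @return An \code{ssnm_model}.
#' @export
ssnm_motif <- function(motif, ...) {
  switch(match.arg(motif, c("yeast", "neuronal", "mutant_neuronal", "mutant",
                            "extended_neuronal", "extended")),
         yeast = yeast_ssnm(...),
         neuronal = neuronal_ssnm(...),
         mutant_neuronal = ,
         mutant = mutant_neuronal_ssnm(...),
         extended_neuronal = ,
         extended = extended_neuronal_ssnm(...))
}

#' Default rate set of a catalog motif
#'
#' Returns the package's documented default rate constants for a motif.
#' Labels are shared across motifs (R1-R5 cascade, R6 closed binding, R7
#' displacement), so the neuronal defaults restricted to cascade labels
#' equal the yeast defaults. Associations are order 1-30 uM^-1 s^-1
#' (sub-diffusion-limited) and dissociations order 0.003-0.1 s^-1
#' (strong-binding regime; the closed Munc18-syntaxin complex, a
#' nanomolar-affinity interaction, dissociates more slowly than
#' SNAREpin.SM); basal fusion kf0 = 2e-5 s^-1 and SM-stimulated fusion
#' kf1 = 1e-3 s^-1 (a 50-fold stimulation). See the methods vignette for
#' the calibration rationale.
#'
#' @inheritParams ssnm_motif
#' @return Named list: reaction label -> \code{c(kf = , kr = )}.
#' @examples
#' default_rates("yeast")
#' @export
default_rates <- function(motif) {
  rate_set(ssnm_motif(motif))
}
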