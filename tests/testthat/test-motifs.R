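test_that("catalog motifs have the documented species and reaction counts", {
  counts <- list(yeast = c(9, 5), neuronal = c(10, 6),
                 mutant_neuronal = c(9, 5), extended_neuronal = c(12, 7))
  for (nm in names(counts)) {
    m <- ssnm_motif(nm)
    expect_length(m$species, counts[[nm]][1])
    expect_length(m$reactions, counts[[nm]][2])
    expect_length(validate_model(m), 0)
  }
})

test_that("default initial conditions follow the study design", {
  m <- neuronal_ssnm()
  expect_equal(unname(m$initial[c("nSyx", "nS25", "nSyb")]), rep(4.5, 3))
  expect_equal(unname(m$initial[["nSM"]]), 0)
  expect_identical(m$readout_moiety, "nSyb")
  expect_equal(unname(extended_neuronal_ssnm()$initial[["DF"]]), 1.0)
  expect_equal(unname(neuronal_ssnm(sm0 = 3)$initial[["nSM"]]), 3)
})

test_that("conservation-law counts: 4 per SNARE/SM system, 5 with the displacement factor", {
  expect_length(conservation_laws(yeast_ssnm()), 4)
  expect_length(conservation_laws(neuronal_ssnm()), 4)
  expect_length(conservation_laws(extended_neuronal_ssnm()), 5)
})

test_that("mutant motif is the wildtype minus the closed-binding reaction", {
  wt <- neuronal_ssnm()
  mu <- mutant_neuronal_ssnm()
  expect_setequal(names(mu$reactions), setdiff(names(wt$reactions), "R6"))
  # reaction set is a strict subset, species minus the orphaned closed complex
  expect_setequal(names(mu$species),
                  setdiff(names(wt$species), "nSyxSM_closed"))
  for (lb in names(mu$reactions)) {
    expect_identical(mu$reactions[[lb]]$reactants, wt$reactions[[lb]]$reactants)
    expect_identical(mu$reactions[[lb]]$products, wt$reactions[[lb]]$products)
  }
})

test_that("yeast and mutant-neuronal motifs are isomorphic under the y/n renaming", {
  y <- yeast_ssnm()
  mu <- mutant_neuronal_ssnm()
  rename <- function(x) gsub("^y", "n", x)
  expect_setequal(rename(names(y$species)), names(mu$species))
  for (s in y$species) {
    s2 <- mu$species[[rename(s$name)]]
    expect_identical(s2$role, s$role)
    expect_setequal(rename(names(s$moieties)), names(s2$moieties))
  }
  for (r in y$reactions) {
    r2 <- mu$reactions[[r$label]]
    expect_setequal(rename(names(r$reactants)), names(r2$reactants))
    expect_setequal(rename(names(r$products)), names(r2$products))
  }
})

test_that("default rates are shared across motifs and respect the fusion hierarchy", {
  ry <- default_rates("yeast")
  rn <- default_rates("neuronal")
  # cascade labels identical across motifs
  expect_identical(rn[names(ry)], ry)
  for (k in rn) expect_true(all(k >= 0))
  # fusion irreversible; SM-stimulated faster than basal
  expect_equal(unname(rn$R4[["kr"]]), 0)
  expect_equal(unname(rn$R5[["kr"]]), 0)
  expect_gt(rn$R5[["kf"]], rn$R4[["kf"]])
  # closed complex dissociates more slowly than SNAREpin.SM
  expect_lt(rn$R6[["kr"]], rn$R3[["kr"]])
  expect_error(default_rates("marsupial"))
})
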