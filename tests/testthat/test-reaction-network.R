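test_that("validator accepts the catalog motifs and reports degenerate inputs", {
  expect_length(validate_model(yeast_ssnm()), 0)

  # reaction consuming an undeclared species
  m <- network_model(
    "bad1",
    list(species("A", c(A = 1)), species("C", c(A = 1, B = 1), "complex")),
    list(reaction("R1", c(A = 1, B = 1), c(C = 1), kf = 1)),
    initial = c(A = 1), readout_moiety = "A", validate = FALSE)
  v <- validate_model(m)
  expect_length(v, 1)
  expect_identical(v[[1]]$type, "undeclared_species")

  # A + B -> A loses B's moiety
  m2 <- network_model(
    "bad2",
    list(species("A", c(A = 1)), species("B", c(B = 1))),
    list(reaction("R1", c(A = 1, B = 1), c(A = 1), kf = 1)),
    initial = c(A = 1, B = 1), readout_moiety = "A", validate = FALSE)
  v2 <- validate_model(m2)
  expect_length(v2, 1)
  expect_identical(v2[[1]]$type, "moiety_imbalance")

  # negative concentration
  m3 <- binding_model()
  m3$initial[["A"]] <- -1
  expect_identical(validate_model(m3)[[1]]$type, "negative_concentration")
})

test_that("mass-action RHS matches the hand-expanded law and has no sources", {
  m <- binding_model(kf = 1, kr = 1)
  f <- build_mass_action_rhs(m)
  d <- f(c(A = 1, B = 1, C = 0))
  expect_equal(unname(d[c("A", "B", "C")]), c(-1, -1, 1))

  # all-zero state has an all-zero derivative in every catalog motif
  for (cm in catalog_models()) {
    rhs <- build_mass_action_rhs(cm)
    z <- rhs(stats::setNames(numeric(length(cm$initial)), names(cm$initial)))
    expect_true(all(z == 0))
  }
})

test_that("RHS is zero exactly at the binding-quadratic equilibrium", {
  m <- binding_model(kf = 1, kr = 1)
  f <- build_mass_action_rhs(m)
  ceq <- binding_equilibrium(total = 1, kd = 1)  # (3 - sqrt(5)) / 2
  expect_equal(ceq, (3 - sqrt(5)) / 2)
  d <- f(c(A = 1 - ceq, B = 1 - ceq, C = ceq))
  expect_true(all(abs(d) < 1e-12))
})

test_that("RHS is linear in the rate constants", {
  m <- neuronal_ssnm(sm0 = 2)
  r1 <- rate_set(m)
  r2 <- lapply(r1, function(k) 2 * k)
  f1 <- build_mass_action_rhs(m, r1)
  f2 <- build_mass_action_rhs(m, r2)
  set.seed(11)
  for (i in 1:5) {
    y <- stats::setNames(runif(length(m$initial), 0, 3), names(m$initial))
    expect_equal(f2(y), 2 * f1(y), tolerance = 1e-12)
  }
})

test_that("missing rate labels are reported by name", {
  m <- yeast_ssnm()
  r <- rate_set(m)
  r$R3 <- NULL
  expect_error(build_mass_action_rhs(m, r), "R3")
})

test_that("conservation laws are the moiety totals and span the left null space", {
  for (cm in catalog_models()) {
    laws <- conservation_laws(cm)
    # one law per protein, and the count matches the QR null-space oracle
    expect_length(laws, length(model_proteins(cm)))
    expect_gte(left_nullspace_dim(cm), length(laws))
    S <- ssnm:::stoich_matrices(cm)$S
    for (law in laws) {
      expect_true(all(abs(law$coefficients %*% S) < 1e-12))
      expect_equal(law$total, sum(law$coefficients * cm$initial))
    }
  }
  # no reactions: the species itself is conserved
  m1 <- network_model("lone", list(species("A", c(A = 1))), list(),
                      initial = c(A = 2), readout_moiety = "A",
                      validate = FALSE)
  laws <- conservation_laws(m1)
  expect_length(laws, 1)
  expect_equal(laws[[1]]$total, 2)
})

test_that("the SM conservation law tracks the closed complex", {
  laws <- conservation_laws(neuronal_ssnm())
  sm_law <- laws[[which(vapply(laws, `[[`, character(1), "protein") == "nSM")]]
  expect_equal(unname(sm_law$coefficients[["nSyxSM_closed"]]), 1)
  expect_equal(unname(sm_law$coefficients[["nPinSM"]]), 1)
  expect_equal(unname(sm_law$coefficients[["nFusedSM"]]), 1)
  expect_equal(unname(sm_law$coefficients[["nPin"]]), 0)
})

test_that("remove_reaction deletes one reaction, preserves the rest, errors on unknown labels", {
  m <- neuronal_ssnm()
  m2 <- remove_reaction(m, "R6")
  expect_length(m2$reactions, 5)
  expect_false("R6" %in% names(m2$reactions))
  expect_identical(names(m2$species), names(m$species))
  expect_identical(m2$initial, m$initial)
  expect_length(m$reactions, 6)  # input unmodified
  expect_error(remove_reaction(yeast_ssnm(), "nonexistent"), "R1")
  # moiety laws survive reaction deletion
  expect_length(conservation_laws(m2), length(conservation_laws(m)))
})
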