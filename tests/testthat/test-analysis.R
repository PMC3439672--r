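test_that("classification labels constructed dose-response shapes", {
  mk <- function(f) list(doses = seq_along(f), fusion = f)
  expect_identical(classify_response(mk(c(.1, .3, .5, .6, .65)))$shape,
                   "monotonic_increasing")
  expect_identical(classify_response(mk(c(.65, .6, .5, .3, .1)))$shape,
                   "monotonic_decreasing")
  expect_identical(classify_response(mk(c(.1, .5, .9, .5, .1)))$shape,
                   "biphasic")
  expect_identical(classify_response(mk(rep(0.4, 6)))$shape, "flat")
  # sub-tolerance wiggle is flat
  expect_identical(classify_response(mk(0.4 + c(0, 1e-4, -1e-4, 5e-5, 0)))$shape,
                   "flat")
  expect_error(classify_response(mk(c(.1, .2, .3, .4))), "at least 5")
  # at equal maxima the smallest dose wins
  cls <- classify_response(mk(c(.1, .5, .9, .9, .1)))
  expect_equal(cls$argmax_dose, 3)
})

test_that("LHS sampling honors bounds, stratification, degeneracy and seeding", {
  nominal <- default_rates("neuronal")
  k <- unlist(lapply(nominal, function(x) c(x[["kf"]], x[["kr"]])))
  n <- 20
  v <- 0.30
  s <- lhs_sample(nominal, n, v, seed = 3)
  expect_length(s, n)
  mat <- do.call(rbind, lapply(s, function(r)
    unlist(lapply(r, function(x) c(x[["kf"]], x[["kr"]])))))
  for (j in seq_along(k)) {
    if (k[j] == 0) {
      expect_true(all(mat[, j] == 0))  # irreversible stays irreversible
      next
    }
    expect_true(all(mat[, j] >= (1 - v) * k[j] & mat[, j] <= (1 + v) * k[j]))
    # exactly one sample per equal-width stratum
    u <- (mat[, j] - (1 - v) * k[j]) / (2 * v * k[j])
    bins <- floor(pmin(u, 1 - 1e-12) * n)
    expect_setequal(bins, 0:(n - 1))
  }
  # v = 0 reproduces the nominal set n times
  s0 <- lhs_sample(nominal, 4, 0, seed = 1)
  for (r in s0) expect_equal(r, nominal)
  # seeded reproducibility
  expect_identical(lhs_sample(nominal, 5, v, seed = 9),
                   lhs_sample(nominal, 5, v, seed = 9))
  expect_false(identical(lhs_sample(nominal, 5, v, seed = 9),
                         lhs_sample(nominal, 5, v, seed = 10)))
})

test_that("robustness analysis bookkeeping: degenerate variance, counts, reproducibility", {
  m <- neuronal_ssnm()
  grid <- seq(0, 6, by = 1)
  r0 <- robustness_analysis(m, n = 3, variance_fraction = 0, seed = 5,
                            values = grid, t_max = 800)
  expect_equal(r0$preservation_fraction, 1.0)
  expect_length(r0$shapes, 3)
  r1 <- robustness_analysis(m, n = 8, variance_fraction = 0.3, seed = 6,
                            values = grid, t_max = 800)
  r2 <- robustness_analysis(m, n = 8, variance_fraction = 0.3, seed = 6,
                            values = grid, t_max = 800)
  expect_identical(r1$shapes, r2$shapes)
  expect_equal(r1$n, 8)
  # the biphasic label survives +/-30% rate perturbation in the majority
  # of samples
  expect_identical(r1$nominal_shape, "biphasic")
  expect_gte(r1$preservation_fraction, 0.5)
})

test_that("optimum search agrees with a finer grid argmax within resolution", {
  m <- neuronal_ssnm()
  res <- 0.25
  opt <- find_optimum_sm(m, lo = 3.5, hi = 5.5, resolution = res,
                         t_max = 800)
  fine <- dose_response(m, scan_species = "nSM",
                        values = seq(3.5, 5.5, by = res / 10), t_max = 800)
  fine_arg <- fine$doses[which.max(fine$fusion)]
  expect_lt(abs(opt$optimum - fine_arg), res)
  expect_lt(abs(opt$grid_argmax - fine_arg), res + 1e-9)
})

test_that("overexpression with fold 1 is unchanged", {
  o <- overexpression_outcome(neuronal_ssnm(), baseline_sm = 2,
                              fold_increase = 1, t_max = 500)
  expect_identical(o$outcome, "unchanged")
  expect_equal(o$fusion_baseline, o$fusion_overexpressed)
})

test_that("motif comparison requires at least two motifs and aligns tables", {
  expect_error(compare_motifs(list(a = yeast_ssnm())), "at least 2")
  grid <- seq(0, 6, by = 1)
  cmp <- compare_motifs(list(yeast = yeast_ssnm(),
                             mutant = mutant_neuronal_ssnm()),
                        values = grid, t_max = 800)
  expect_identical(names(cmp$table), c("dose", "yeast", "mutant"))
  expect_equal(cmp$table$dose, grid)
  # isomorphic motifs under identical rates give identical fusion columns
  expect_equal(cmp$table$yeast, cmp$table$mutant, tolerance = 1e-10)
})
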