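test_that("scenario presets encode the expected ground-truth structure", {
  expect_error(make_scenario("bogus"), "paper_like")

  null_sc <- make_scenario("null", seed = 7)
  expect_true(all(null_sc$true_psas == 0))

  sc <- make_scenario("paper_like", seed = 1)
  expect_true(all(sc$true_psas[, "Glu"] < 0))
  expect_true(all(sc$true_psas[, "Asp"] < 0))
  # anionic solvents are the strongest insolubilizers
  others <- setdiff(sc$solvents, c("Glu", "Asp"))
  expect_true(min(sc$true_psas[, c("Glu", "Asp")]) <
                min(sc$true_psas[, others]))
  # Tyr/Trp solvents carry the largest positive slopes
  expect_true(min(sc$true_psas[, c("Tyr", "Trp")]) >
                max(sc$true_psas[, setdiff(others, c("Tyr", "Trp"))]))
  # same preset + seed twice -> identical scenario
  expect_identical(sc, make_scenario("paper_like", seed = 1))
})

test_that("noiseless simulation follows the linear solubility model exactly", {
  tp <- matrix(0.5, 1, 1, dimnames = list("Trp", "Gly"))
  sc <- make_scenario("custom", true_psas = tp, s0 = c(Trp = 2),
                      cmax = c(Gly = 1), noise_sd = 0)
  rec <- simulate_assay(sc, assay_design(n_conc = 2, n_reps = 1))
  expect_equal(sort(rec$solubility), c(2.0, 3.0))
  expect_false(any(rec$truncated))

  # explicit grid beyond the solvent ceiling is rejected by name
  expect_error(simulate_assay(sc, assay_design(conc = c(0, 2))), "Gly")
})

test_that("replicate noise matches the stated model", {
  sc <- make_scenario("paper_like", seed = 3, noise_sd = 0.05)
  rec <- simulate_assay(sc, assay_design(n_conc = 5, n_reps = 8), seed = 11)
  noiseless <- simulate_assay(make_scenario("paper_like", noise_sd = 0),
                              assay_design(n_conc = 5, n_reps = 1))
  means <- dplyr::summarise(
    dplyr::group_by(rec, solute, solvent, conc),
    m = mean(solubility), .groups = "drop")
  joined <- dplyr::inner_join(
    means, noiseless, by = c("solute", "solvent", "conc"))
  sem <- 0.05 * sc$s0[joined$solute] / sqrt(8)
  frac_in <- mean(abs(joined$m - joined$solubility) <= 3 * sem)
  # 3-SEM band should hold for ~99.7% of the 300 grid points
  expect_gt(frac_in, 0.97)

  # empirical replicate SD converges to noise_sd * s0 at large n_reps
  tp <- matrix(0.2, 1, 1, dimnames = list("Trp", "Gly"))
  big <- make_scenario("custom", true_psas = tp, s0 = c(Trp = 1.32),
                       cmax = c(Gly = 1), noise_sd = 0.05)
  rec2 <- simulate_assay(big, assay_design(n_conc = 2, n_reps = 1e4), seed = 5)
  sds <- tapply(rec2$solubility, rec2$conc, sd)
  expect_equal(as.numeric(sds), rep(0.05 * 1.32, 2), tolerance = 0.05)
})

test_that("seeded runs are reproducible down to the written CSV bytes", {
  sc <- make_scenario("paper_like", seed = 42)
  r1 <- simulate_assay(sc)
  r2 <- simulate_assay(sc)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(r1, f1)
  write_assay_csv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed -> different draws
  expect_false(identical(r1$solubility,
                         simulate_assay(sc, seed = 43)$solubility))
})

test_that("assay CSV and scenario YAML round-trips preserve content", {
  sc <- make_scenario("paper_like", seed = 9, noise_sd = 0.02)
  rec <- simulate_assay(sc, assay_design(n_conc = 3, n_reps = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(rec, f)
  back <- read_assay_csv(f)
  expect_equal(back$solubility, rec$solubility)
  expect_identical(back$solute, rec$solute)
  expect_equal(back$conc, rec$conc)

  y <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, y)
  sc2 <- read_scenario_yaml(y)
  expect_equal(sc2$true_psas, sc$true_psas)
  expect_equal(sc2$cmax, sc$cmax)
  expect_equal(sc2$s0, sc$s0)
  expect_equal(sc2$noise_sd, sc$noise_sd)
})

test_that("negative noise draws are truncated at zero and flagged", {
  tp <- matrix(0, 1, 1, dimnames = list("Tyr", "Gly"))
  sc <- make_scenario("custom", true_psas = tp, s0 = c(Tyr = 0.054),
                      cmax = c(Gly = 1), noise_sd = 3)
  rec <- simulate_assay(sc, assay_design(n_conc = 3, n_reps = 50), seed = 2)
  expect_true(all(rec$solubility >= 0))
  expect_true(any(rec$truncated))
  expect_true(all(rec$solubility[rec$truncated] == 0))
})

test_that("absorbance observation respects the standard-curve valid range", {
  expect_error(standard_curve("Trp", slope = -1), "positive")
  expect_error(standard_curve("Trp", slope = 1, wavelength = 300), "260")

  cv <- standard_curve("Trp", slope = 1, intercept = 0,
                       valid_range = c(0.05, 1))
  rec <- tibble::tibble(solute = "Trp", solvent = "Gly", conc = 0,
                        replicate = 1L, solubility = 5,
                        truncated = FALSE, absorbance = NA_real_,
                        dilution = NA_real_)
  out <- observe_absorbance(rec, list(Trp = cv))
  expect_equal(out$absorbance, cv$slope * 5 / out$dilution + cv$intercept)
  expect_true(out$absorbance >= 0.05 && out$absorbance <= 1)
  # smallest feasible dilution from the 1-2-5 series: 5/5 = 1.0 in range
  expect_equal(out$dilution, 5)

  # zero solubility with a blank outside the trusted range is infeasible
  cv2 <- standard_curve("Trp", slope = 1, intercept = 0.01,
                        valid_range = c(0.1, 1))
  rec$solubility <- 0
  expect_warning(out2 <- observe_absorbance(rec, list(Trp = cv2)),
                 "no feasible dilution")
  expect_true(is.na(out2$absorbance))
  expect_identical(out2$flag, "no_feasible_dilution")
})
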