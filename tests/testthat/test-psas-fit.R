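test_that("calibration inverts the standard curve", {
  cv <- standard_curve("Trp", slope = 1, intercept = 0)
  expect_equal(calibrate(0.5, cv, dilution = 10), 5.0)
  expect_equal(calibrate(cv$intercept, cv, dilution = 3), 0)
  expect_warning(out <- calibrate(-0.2, cv), "calibration error")
  expect_true(is.na(out))
  expect_error(calibrate(0.5, cv, dilution = 0.5), "dilution")
})

test_that("observe/calibrate compose to the identity on random records", {
  set.seed(101)
  rec <- tibble::tibble(
    solute = sample(c("Tyr", "Trp", "Phe"), 100, replace = TRUE),
    solvent = "Gly", conc = runif(100, 0, 2), replicate = 1L,
    solubility = runif(100, 0.01, 50), truncated = FALSE,
    absorbance = NA_real_, dilution = NA_real_)
  curves <- default_standard_curves()
  obs <- observe_absorbance(rec, curves)
  back <- recover_solubility(obs, curves)
  expect_lt(max(abs(back$solubility - rec$solubility)), 1e-9)
})

test_that("ratio normalization pins the water baseline at exactly 1", {
  rec <- tibble::tibble(
    solute = "Trp", solvent = "Arg",
    conc = c(0, 0, 1, 1), replicate = c(1L, 2L, 1L, 2L),
    solubility = c(2, 2, 3, 3), truncated = FALSE,
    absorbance = NA_real_, dilution = NA_real_)
  cv <- to_ratio(rec)
  expect_identical(cv$ratio[cv$conc == 0], 1)
  expect_equal(cv$ratio[cv$conc == 1], 1.5)
  expect_equal(attr(cv, "s0"), 2)
  expect_false(attr(cv, "unfittable"))

  # only-baseline records are a degenerate, unfittable curve
  base_only <- rec[rec$conc == 0, ]
  cv0 <- to_ratio(base_only)
  expect_true(attr(cv0, "unfittable"))
  expect_error(fit_psas(cv0), "distinct")

  # zero baseline is an error
  rec0 <- rec
  rec0$solubility[rec0$conc == 0] <- 0
  expect_error(to_ratio(rec0), "positive")

  # without baseline rows, s0 must be supplied explicitly
  no_base <- rec[rec$conc > 0, ]
  expect_error(to_ratio(no_base), "s0")
  cv2 <- to_ratio(no_base, s0 = 2)
  expect_equal(cv2$ratio, 1.5)
})

test_that("fixed-intercept slope matches the closed form and a grid-search oracle", {
  # two-point case has an exact answer
  pts <- structure(tibble::tibble(conc = c(0, 1), ratio = c(1, 1.5),
                                  n_rep = c(3L, 3L)),
                   class = c("solubility_curve", "tbl_df", "tbl",
                             "data.frame"),
                   solute = "Trp", solvent = "Arg", s0 = 1,
                   unfittable = FALSE)
  expect_equal(fit_psas(pts, mode = "fixed")$psas, 0.5)

  for (seed in 1:20) {
    cv <- random_curve(seed)
    fit <- fit_psas(cv, mode = "fixed")
    closed <- sum(cv$conc * (cv$ratio - 1)) / sum(cv$conc^2)
    expect_equal(fit$psas, closed, tolerance = 1e-12)
    expect_equal(fit$psas, oracle_slope_grid(cv$conc, cv$ratio),
                 tolerance = 1e-6)
    expect_gte(fit$stderr, 0)
    expect_lte(fit$r2, 1)
  }
})

test_that("free-intercept mode reduces to ordinary least squares", {
  cv <- random_curve(33)
  fit <- fit_psas(cv, mode = "free")
  ols <- stats::lm(cv$ratio ~ cv$conc)
  expect_equal(fit$psas, unname(coef(ols)[2]))
  expect_equal(fit$r2, summary(ols)$r.squared)
})

test_that("degenerate concentration designs are rejected", {
  flat <- structure(tibble::tibble(conc = c(1, 1), ratio = c(1.2, 1.3),
                                   n_rep = c(1L, 1L)),
                    class = c("solubility_curve", "tbl_df", "tbl",
                              "data.frame"),
                    solute = "Trp", solvent = "Arg", s0 = 1,
                    unfittable = TRUE)
  expect_error(fit_psas(flat), "distinct")
})

test_that("PSAS is equivariant under rescaling of solubility and concentration", {
  sc <- make_scenario("paper_like", seed = 6, noise_sd = 0.05)
  rec <- simulate_assay(sc, seed = 17)
  one <- function(r) fit_psas(to_ratio(r, "Trp", "Arg"))$psas
  base <- one(rec)
  # multiplying all solubilities by k > 0 changes nothing
  rec_k <- rec
  rec_k$solubility <- rec_k$solubility * 7.3
  expect_equal(one(rec_k), base, tolerance = 1e-12)
  # multiplying all concentrations by k divides the slope by k
  rec_c <- rec
  rec_c$conc <- rec_c$conc * 4
  expect_equal(one(rec_c), base / 4, tolerance = 1e-12)
})

test_that("matrix assembly enforces a complete, unique grid in fixed order", {
  rec <- simulate_assay(make_scenario("paper_like", seed = 2, noise_sd = 0))
  m <- fit_psas_matrix(rec)
  expect_s3_class(m, "psas_matrix")
  expect_equal(nrow(m), 60)
  mm <- as.matrix(m)
  expect_identical(rownames(mm), c("Tyr", "Trp", "Phe"))
  expect_identical(colnames(mm), aa_residues())

  entries <- tibble::as_tibble(m)
  expect_error(build_psas_matrix(entries[-1, ]), "missing")
  expect_error(build_psas_matrix(rbind(entries, entries[1, ])), "duplicate")
})

test_that("interaction classification follows the signed threshold rule", {
  expect_identical(as.character(classify_interaction(c(0.5, 0, -0.3))),
                   c("soluble", "neutral", "insoluble"))
  expect_identical(as.character(classify_interaction(0, tau = 0.2)),
                   "neutral")
  expect_identical(as.character(classify_interaction(c(0.051, -0.051))),
                   c("soluble", "insoluble"))
  expect_error(classify_interaction(0.1, tau = -1), "tau")
})

test_that("matrix TSV export has solvent rows in canonical order", {
  rec <- simulate_assay(make_scenario("paper_like", seed = 2, noise_sd = 0))
  m <- fit_psas_matrix(rec)
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- withr::local_tempfile(fileext = ".csv")
  write_psas_tsv(m, f, diagnostics = d)
  tab <- utils::read.delim(f)
  expect_identical(tab$solvent, aa_residues())
  expect_identical(names(tab), c("solvent", "Tyr", "Trp", "Phe"))
  diag <- utils::read.csv(d)
  expect_equal(nrow(diag), 60)
  expect_true(all(c("psas", "stderr", "r2", "n_points", "class") %in%
                    names(diag)))
})
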