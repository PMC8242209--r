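#' Invert a standard curve to recover solubility
#'
#' Back-calculates the saturation solubility of a diluted supernatant from
#' its absorbance reading: `solubility = dilution * (A - intercept) / slope`.
#' Readings below the blank (negative implied concentration) are flagged
#' with a warning and returned as `NA`.
#'
#' @param absorbance Numeric vector of readings.
#' @param curve A [standard_curve()].
#' @param dilution Dilution factor(s), >= 1.
#' @return Numeric vector of solubilities.
#' @export
#' @examples
#' calibrate(0.5, standard_curve("Trp", slope = 1), dilution = 10)
calibrate <- function(absorbance, curve, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(dilution < 1, na.rm = TRUE)) {
    stop("dilution must be >= 1", call. = FALSE)
  }
  out <- dilution * (absorbance - curve$intercept) / curve$slope
  neg <- which(out < 0)
  if (length(neg) > 0) {
    warning(length(neg), " absorbance reading(s) below the blank; ",
            "negative implied solubility flagged as NA (calibration error)",
            call. = FALSE)
    out[neg] <- NA_real_
  }
  out
}

#' Recover solubilities for a whole record set from absorbance
#'
#' Applies [calibrate()] per solute, replacing the `solubility` column with
#' values back-calculated from `absorbance` and `dilution`.
#'
#' @param records An `assay_records` tibble with absorbance filled (see
#'   [observe_absorbance()]).
#' @param curves Named list of standard curves per solute.
#' @return `records` with recalculated `solubility`.
#' @export
recover_solubility <- function(records, curves = default_standard_curves()) {
  for (s in unique(records$solute)) {
    rows <- which(records$solute == s)
    records$solubility[rows] <- calibrate(records$absorbance[rows],
                                          curves[[s]],
                                          records$dilution[rows])
  }
  records
}

#' Normalize one (solute, solvent) pair to a solubility-ratio curve
#'
#' Computes the water baseline `s0` as the mean of the 0 M replicate
#' solubilities (or takes it from the `s0` argument when no baseline rows
#' exist), averages replicates at each concentration, and divides by `s0`.
#' By construction the 0 M point has ratio exactly 1.
#'
#' @param records Assay records for a single (solute, solvent) pair, or a
#'   larger set together with `solute` and `solvent` selectors.
#' @param solute,solvent Optional selectors when `records` holds several
#'   pairs.
#' @param s0 Optional externally measured water solubility, used only when
#'   the records contain no 0 M rows.
#' @return A `solubility_curve`: tibble with columns `conc`, `ratio`,
#'   `n_rep`, and attributes `solute`, `solvent`, `s0`, `unfittable`.
#' @export
to_ratio <- function(records, solute = NULL, solvent = NULL, s0 = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(solute)) records <- records[records$solute == normalize_residue(solute), ]
  if (!is.null(solvent)) records <- records[records$solvent == normalize_residue(solvent), ]
  if (nrow(records) == 0) stop("no records for the requested pair", call. = FALSE)
  pair <- unique(records[, c("solute", "solvent")])
  if (nrow(pair) > 1) {
    stop("records contain more than one (solute, solvent) pair; ",
         "use the solute/solvent arguments or fit_psas_matrix()", call. = FALSE)
  }
  base <- records$solubility[records$conc == 0]
  if (length(base) == 0) {
    if (is.null(s0)) {
      stop("no 0 M baseline records for ", pair$solute, " in ", pair$solvent,
           "; supply the water solubility via the s0 argument", call. = FALSE)
    }
    s0_use <- s0
  } else {
    s0_use <- mean(base)
  }
  if (!is.finite(s0_use) || s0_use <= 0) {
    stop("water-baseline solubility must be positive (got ", s0_use, ")",
         call. = FALSE)
  }
  agg <- records |>
    dplyr::group_by(conc = .data$conc) |>
    dplyr::summarise(ratio = mean(.data$solubility) / s0_use,
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$conc)
  structure(agg,
            class = c("solubility_curve", class(agg)),
            solute = pair$solute, solvent = pair$solvent, s0 = s0_use,
            unfittable = length(unique(agg$conc)) < 2)
}

#' Fit the solubility-ratio slope (PSAS) of one curve
#'
#' The PSAS of a (solute, solvent) pair is the slope of the solubility
#' ratio (water = 1) against solvent concentration, in ratio units per M.
#' Two fitting modes:
#'
#' * `"fixed"` (default) — the intercept is pinned at the definitional
#'   value 1, and the slope is the least-squares slope of `(ratio - 1)` on
#'   `conc` through the origin, in closed form
#'   `sum(c * (r - 1)) / sum(c^2)`. This honours the normalization: the
#'   ratio in plain water is 1 by definition.
#' * `"free"` — ordinary least squares of `ratio` on `conc`; a robustness
#'   check when the baseline itself is suspect.
#'
#' The standard error and R^2 use the standard linear-regression formulas
#' (uncentered R^2 in fixed mode, as usual for through-origin fits).
#'
#' @param curve A [to_ratio()] curve with at least two distinct
#'   concentrations.
#' @param mode `"fixed"` or `"free"`.
#' @return A one-row `psas_entry` tibble: `solute`, `solvent`, `psas`,
#'   `stderr`, `r2`, `n_points`, `fit_mode`.
#' @export
#' @examples
#' rec <- simulate_assay(make_scenario("null", seed = 1, noise_sd = 0))
#' fit_psas(to_ratio(rec, "Trp", "Arg"))
fit_psas <- function(curve, mode = c("fixed", "free")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "solubility_curve"))
  cc <- curve$conc
  rr <- curve$ratio
  n <- length(cc)
  if (length(unique(cc)) < 2) {
    stop("cannot fit a slope: need at least two distinct solvent ",
         "concentrations (got ", length(unique(cc)), ")", call. = FALSE)
  }
  if (mode == "fixed") {
    x <- cc
    y <- rr - 1
    slope <- sum(x * y) / sum(x^2)
    res <- y - slope * x
    df <- n - 1
    s2 <- if (df > 0) sum(res^2) / df else NA_real_
    se <- if (df > 0) sqrt(s2 / sum(x^2)) else NA_real_
    tss <- sum(y^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  } else {
    fit <- stats::lm(rr ~ cc)
    slope <- unname(stats::coef(fit)[2])
    sm <- summary(fit)
    se <- if (n > 2) sm$coefficients[2, 2] else NA_real_
    r2 <- sm$r.squared
  }
  out <- tibble::tibble(
    solute = attr(curve, "solute"), solvent = attr(curve, "solvent"),
    psas = slope, stderr = se, r2 = r2, n_points = n, fit_mode = mode)
  class(out) <- c("psas_entry", class(out))
  out
}

#' Assemble fitted slopes into a complete solute-x-solvent matrix
#'
#' Checks the entries form exactly one fit per (solute, solvent) pair over
#' the requested grid and orders them deterministically: solvents in the
#' canonical table row order, solutes Tyr, Trp, Phe.
#'
#' @param entries A tibble of [fit_psas()] rows (e.g. via
#'   `dplyr::bind_rows()`).
#' @param solutes,solvents Expected grid; defaults to the three aromatics
#'   across all 20 solvents.
#' @return A `psas_matrix` tibble; use [as.matrix()] for the numeric
#'   solute-x-solvent slope matrix.
#' @export
build_psas_matrix <- function(entries, solutes = c("Tyr", "Trp", "Phe"),
                              solvents = aa_residues()) {
  stopifnot(is.data.frame(entries))
  key <- paste(entries$solute, entries$solvent, sep = ":")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicate entries for pair(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  want <- as.vector(outer(solutes, solvents, paste, sep = ":"))
  gaps <- setdiff(want, key)
  if (length(gaps) > 0) {
    stop("missing entries for pair(s): ",
         paste(utils::head(gaps, 10), collapse = ", "),
         if (length(gaps) > 10) sprintf(" ... and %d more", length(gaps) - 10),
         call. = FALSE)
  }
  extra <- setdiff(key, want)
  if (length(extra) > 0) {
    stop("unexpected entries outside the grid: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  entries$solute <- factor(entries$solute, levels = solutes)
  entries$solvent <- factor(entries$solvent, levels = solvents)
  out <- dplyr::arrange(entries, .data$solvent, .data$solute)
  out$solute <- as.character(out$solute)
  out$solvent <- as.character(out$solvent)
  structure(out, class = c("psas_matrix", class(tibble::as_tibble(out))),
            solutes = solutes, solvents = solvents)
}

#' @export
as.matrix.psas_matrix <- function(x, ...) {
  solutes <- attr(x, "solutes")
  solvents <- attr(x, "solvents")
  m <- matrix(NA_real_, length(solutes), length(solvents),
              dimnames = list(solutes, solvents))
  m[cbind(match(x$solute, solutes), match(x$solvent, solvents))] <- x$psas
  m
}

#' @export
print.psas_matrix <- function(x, ...) {
  cat("<psas_matrix>", length(attr(x, "solutes")), "solutes x",
      length(attr(x, "solvents")), "solvents\n")
  print(round(as.matrix(x), 3))
  invisible(x)
}

#' Fit the full PSAS matrix from assay records
#'
#' Convenience pipeline: split the records by (solute, solvent), normalize
#' each pair with [to_ratio()], fit with [fit_psas()], and assemble with
#' [build_psas_matrix()].
#'
#' @param records An `assay_records` tibble covering a full grid.
#' @param mode Fit mode passed to [fit_psas()].
#' @param solutes,solvents Expected grid (defaults inferred from the
#'   records, in canonical order).
#' @return A `psas_matrix`.
#' @export
#' @examples
#' rec <- simulate_assay(make_scenario("paper_like", seed = 1, noise_sd = 0))
#' m <- fit_psas_matrix(rec)
#' as.matrix(m)[, 1:4]
fit_psas_matrix <- function(records, mode = "fixed",
                            solutes = NULL, solvents = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(solutes)) {
    solutes <- intersect(c("Tyr", "Trp", "Phe"), unique(records$solute))
    if (length(solutes) == 0) solutes <- unique(records$solute)
  }
  if (is.null(solvents)) {
    solvents <- intersect(aa_residues(), unique(records$solvent))
  }
  pairs <- tidyr::expand_grid(solute = solutes, solvent = solvents)
  entries <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    fit_psas(to_ratio(records, pairs$solute[k], pairs$solvent[k]), mode = mode)
  }))
  build_psas_matrix(entries, solutes = solutes, solvents = solvents)
}

#' Classify interactions as soluble, neutral or insoluble
#'
#' A solvent amino acid that raises the solute's solubility ratio
#' (`psas > tau`) makes a soluble, droplet-like interaction; one that
#' lowers it (`psas < -tau`) an insoluble, aggregate-like interaction;
#' slopes within `tau` of zero are neutral — interactions about as weak as
#' those with water.
#'
#' @param psas Numeric vector of slopes (per M).
#' @param tau Non-negative neutral half-width (per M). Default 0.05.
#' @return Factor with levels `soluble`, `neutral`, `insoluble`.
#' @export
#' @examples
#' classify_interaction(c(0.5, 0, -0.3))
classify_interaction <- function(psas, tau = 0.05) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  lab <- ifelse(psas > tau, "soluble",
                ifelse(psas < -tau, "insoluble", "neutral"))
  factor(lab, levels = c("soluble", "neutral", "insoluble"))
}

#' Per-cell and per-solvent classification of a PSAS matrix
#'
#' `classify_matrix()` appends a `class` column (one label per fitted
#' pair). `solvent_classes()` labels each solvent by the class of its mean
#' slope across the solutes, which is the grouping used in the comparison
#' report.
#'
#' @param matrix A `psas_matrix`.
#' @param tau Neutral half-width, as in [classify_interaction()].
#' @return `classify_matrix()`: the matrix tibble with `class` added;
#'   `solvent_classes()`: named factor over solvents.
#' @export
classify_matrix <- function(matrix, tau = 0.05) {
  stopifnot(inherits(matrix, "psas_matrix"))
  matrix$class <- classify_interaction(matrix$psas, tau)
  matrix
}

#' @rdname classify_matrix
#' @export
solvent_classes <- function(matrix, tau = 0.05) {
  stopifnot(inherits(matrix, "psas_matrix"))
  m <- as.matrix(matrix)
  classify_interaction(colMeans(m), tau)
}

#' Write a PSAS matrix as TSV
#'
#' Solvent rows (canonical order) by solute columns, plus an optional
#' per-pair diagnostics CSV (`psas,stderr,r2,n_points,class`).
#'
#' @param matrix A `psas_matrix`.
#' @param path Output TSV path.
#' @param diagnostics Optional path for the per-pair diagnostics CSV.
#' @param tau Threshold used for the diagnostics `class` column.
#' @return `path`, invisibly.
#' @export
write_psas_tsv <- function(matrix, path, diagnostics = NULL, tau = 0.05) {
  stopifnot(inherits(matrix, "psas_matrix"))
  m <- t(as.matrix(matrix))
  out <- data.frame(solvent = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(diagnostics)) {
    d <- classify_matrix(matrix, tau)
    utils::write.csv(
      d[, c("solute", "solvent", "psas", "stderr", "r2", "n_points", "class")],
      diagnostics, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Heatmap of a PSAS matrix
#'
#' Red tiles mark solubilizing (positive) and green insolubilizing
#' (negative) interactions, matching the field's usual color convention.
#'
#' @param x A `psas_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.psas_matrix <- function(x, ...) {
  df <- tibble::as_tibble(x[, c("solute", "solvent", "psas")])
  df$solvent <- factor(df$solvent, levels = attr(x, "solvents"))
  df$solute <- factor(df$solute, levels = rev(attr(x, "solutes")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$solvent, y = .data$solute,
                                   fill = .data$psas)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red3", midpoint = 0,
                                  name = "PSAS (per M)") +
    ggplot2::labs(x = "solvent amino acid", y = "aromatic solute") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
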