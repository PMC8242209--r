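#' Solvent concentration ceilings derived from water solubility
#'
#' The usable concentration range of each amino-acid solvent is bounded by
#' that amino acid's own solubility. The bundled water-solubility scale is
#' converted to an approximate molar ceiling by a single documented
#' constant: printed values are interpreted as g per 100 mL, scaled to g/L
#' (x10) and divided by a nominal molar mass of 125 g/mol, i.e.
#' `cmax = 0.08 * solubility_water` (M). The constant is deliberately crude
#' (the source units are unstated); override `cmax` in [make_scenario()]
#' when real ceilings are known.
#'
#' @param set An `aa_index_set` containing a `solubility_water` scale.
#' @return Named numeric vector of ceilings (M) over the 20 residues.
#' @export
solvent_cmax <- function(set = load_index_set()) {
  v <- 0.08 * get_index_value(set, "solubility_water", aa_residues())
  stats::setNames(v, aa_residues())
}

.aaa_solutes <- function() c("Tyr", "Trp", "Phe")

# paper-like ground truth: per-solvent base slope (per M) times a per-solute
# multiplier chosen so that solubilizing solvents order the aromatics
# Trp > Tyr > Phe, anionic/amide insolubilizers order them Phe > Trp > Tyr
# and hydrophobic insolubilizers Trp > Phe > Tyr.
.paper_like_true_psas <- function() {
  base <- c(Tyr = 2.0, Trp = 1.8, Phe = 0.9, Arg = 0.8, Lys = 0, His = 0.4,
            Pro = 0.3, Gly = 0, Ala = -0.30, Ser = 0, Cys = -0.35,
            Met = -0.40, Val = -0.45, Leu = -0.50, Ile = -0.50, Thr = 0,
            Gln = -0.50, Asn = -0.50, Glu = -1.6, Asp = -1.8)
  base <- base[aa_residues()]
  mult_pos <- c(Tyr = 1.0, Trp = 1.2, Phe = 0.8)
  mult_anionic <- c(Tyr = 1.2, Trp = 1.0, Phe = 0.8)
  mult_hydrophobic <- c(Tyr = 1.25, Phe = 1.0, Trp = 0.8)
  hydrophobic <- c("Ala", "Val", "Leu", "Ile", "Met", "Cys")
  solutes <- .aaa_solutes()
  m <- matrix(0, nrow = 3, ncol = 20,
              dimnames = list(solutes, aa_residues()))
  for (sv in aa_residues()) {
    b <- base[[sv]]
    mult <- if (b > 0) mult_pos
            else if (sv %in% hydrophobic) mult_hydrophobic
            else mult_anionic
    m[solutes, sv] <- b * mult[solutes]
  }
  m
}

#' Build a simulation scenario
#'
#' A scenario fixes the ground truth of the synthetic assay: the true
#' solute-x-solvent slope matrix (solubility-ratio units per M), the water
#' solubility `s0` of each aromatic solute, per-solvent concentration
#' ceilings `cmax`, the relative replicate noise, and optional quadratic
#' curvature. Presets:
#'
#' * `"paper_like"` — encodes the qualitative structure reported for the
#'   real assay: solvents Tyr, Trp, Phe, Arg, His and Pro solubilize the
#'   aromatics (Tyr/Trp solvents strongest), the anionic solvents Glu and
#'   Asp insolubilize most strongly, the amide (Gln, Asn) and hydrophobic
#'   (Ala, Val, Leu, Ile, Met, Cys) solvents insolubilize moderately, and
#'   Gly, Ser, Thr and Lys are neutral (slope 0). Magnitudes are package
#'   defaults; only signs and within-solvent solute orderings mirror the
#'   reported pattern.
#' * `"null"` — all true slopes 0 (no interaction).
#' * `"custom"` — all fields supplied via overrides.
#'
#' Any field can be overridden by name for any preset.
#'
#' @param preset One of `"paper_like"`, `"null"`, `"custom"`.
#' @param seed Integer seed stored with the scenario and used as the
#'   default seed of [simulate_assay()].
#' @param true_psas,s0,cmax,noise_sd,nonlinearity Optional overrides.
#'   `true_psas` and `nonlinearity` are solute-x-solvent matrices with
#'   dimnames; `s0` and `cmax` named vectors; `noise_sd` a scalar fraction
#'   of `s0`.
#' @return A `psas_scenario`.
#' @export
#' @examples
#' sc <- make_scenario("paper_like", seed = 1)
#' sc$true_psas[, "Glu"]
make_scenario <- function(preset = c("paper_like", "null", "custom"),
                          seed = 1L, true_psas = NULL, s0 = NULL,
                          cmax = NULL, noise_sd = NULL, nonlinearity = NULL) {
  presets <- c("paper_like", "null", "custom")
  if (!is.character(preset) || !preset[1] %in% presets) {
    stop("unknown preset '", preset[1], "'; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  preset <- preset[1]
  idx <- load_index_set()
  solutes <- .aaa_solutes()
  solvents <- aa_residues()
  def_psas <- switch(preset,
    paper_like = .paper_like_true_psas(),
    matrix(0, 3, 20, dimnames = list(solutes, solvents)))
  tp <- if (is.null(true_psas)) def_psas else true_psas
  if (is.null(dimnames(tp)) || !all(rownames(tp) %in% solutes)) {
    stop("true_psas must be a solute-x-solvent matrix with dimnames",
         call. = FALSE)
  }
  s0v <- if (is.null(s0)) {
    stats::setNames(get_index_value(idx, "solubility_water", solutes), solutes)
  } else s0
  cmx <- if (is.null(cmax)) solvent_cmax(idx)[colnames(tp)] else cmax
  nl <- if (is.null(nonlinearity)) {
    matrix(0, nrow(tp), ncol(tp), dimnames = dimnames(tp))
  } else nonlinearity
  nsd <- if (is.null(noise_sd)) 0.05 else noise_sd
  if (any(cmx <= 0)) stop("cmax must be positive for every solvent", call. = FALSE)
  if (any(s0v <= 0)) stop("s0 must be positive for every solute", call. = FALSE)
  if (nsd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(preset = preset, seed = as.integer(seed),
         solutes = rownames(tp), solvents = colnames(tp),
         true_psas = tp, s0 = s0v, cmax = cmx,
         noise_sd = nsd, nonlinearity = nl),
    class = "psas_scenario")
}

#' @export
print.psas_scenario <- function(x, ...) {
  cat("<psas_scenario> preset:", x$preset, " seed:", x$seed, "\n")
  cat(length(x$solutes), "solutes x", length(x$solvents),
      "solvents; noise_sd =", x$noise_sd, "\n")
  invisible(x)
}

#' Assay design: concentration grid and replication
#'
#' @param n_conc Number of concentration levels per solvent (including the
#'   0 M water baseline when `include_zero = TRUE`). Default 5.
#' @param n_reps Replicates per level. Default 3.
#' @param include_zero Include the 0 M baseline level. Default `TRUE`.
#' @param conc Optional explicit concentration grid (M) applied to every
#'   solvent in place of the evenly spaced one; must not exceed any
#'   solvent's `cmax`.
#' @return An `assay_design` list.
#' @export
assay_design <- function(n_conc = 5, n_reps = 3, include_zero = TRUE,
                         conc = NULL) {
  stopifnot(n_conc >= 2, n_reps >= 1)
  structure(list(n_conc = n_conc, n_reps = n_reps,
                 include_zero = include_zero, conc = conc),
            class = "assay_design")
}

#' Simulate saturation-solubility assay records
#'
#' Generates one record per (solute, solvent, concentration, replicate).
#' The measured solubility is
#' `s0 * (1 + slope * c + curvature * c^2) + e`, with
#' `e ~ Normal(0, (noise_sd * s0)^2)`; negative draws are truncated at 0
#' and flagged in the `truncated` column. Each solvent's grid spans
#' `[0, cmax]` evenly (the 0 M rows are the water baseline used later for
#' normalization).
#'
#' @param scenario A `psas_scenario`.
#' @param design An [assay_design()].
#' @param seed Integer seed; defaults to the scenario's stored seed. The
#'   same scenario, design and seed give byte-identical output.
#' @return A tibble of class `assay_records` with columns `solute`,
#'   `solvent`, `conc`, `replicate`, `solubility`, `truncated`,
#'   `absorbance`, `dilution`.
#' @export
#' @examples
#' rec <- simulate_assay(make_scenario("null", seed = 1),
#'                       assay_design(n_conc = 3, n_reps = 2))
#' head(rec)
simulate_assay <- function(scenario, design = assay_design(),
                           seed = scenario$seed) {
  stopifnot(inherits(scenario, "psas_scenario"),
            inherits(design, "assay_design"))
  solvents <- scenario$solvents
  solutes <- scenario$solutes
  grids <- lapply(solvents, function(sv) {
    cm <- scenario$cmax[[sv]]
    if (!is.null(design$conc)) {
      g <- sort(unique(design$conc))
      if (max(g) > cm) {
        stop("concentration grid exceeds cmax (", signif(cm, 4),
             " M) for solvent ", sv, call. = FALSE)
      }
      g
    } else if (design$include_zero) {
      seq(0, cm, length.out = design$n_conc)
    } else {
      seq(cm / design$n_conc, cm, length.out = design$n_conc)
    }
  })
  names(grids) <- solvents
  grid_tbl <- dplyr::bind_rows(lapply(solvents, function(sv) {
    tibble::tibble(solvent = sv, conc = grids[[sv]])
  }))
  rec <- tidyr::expand_grid(solute = solutes, grid_tbl,
                            replicate = seq_len(design$n_reps))
  i <- match(rec$solute, rownames(scenario$true_psas))
  j <- match(rec$solvent, colnames(scenario$true_psas))
  slope <- scenario$true_psas[cbind(i, j)]
  curv <- scenario$nonlinearity[cbind(i, j)]
  s0 <- scenario$s0[rec$solute]
  mu <- s0 * (1 + slope * rec$conc + curv * rec$conc^2)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(nrow(rec), 0, scenario$noise_sd * s0)
  sol <- unname(mu + eps)
  truncated <- sol < 0
  sol[truncated] <- 0
  out <- tibble::tibble(
    solute = rec$solute, solvent = rec$solvent, conc = rec$conc,
    replicate = rec$replicate, solubility = sol, truncated = truncated,
    absorbance = NA_real_, dilution = NA_real_)
  class(out) <- c("assay_records", class(out))
  out
}

#' Absorbance standard curve for one solute
#'
#' Linear absorbance-vs-concentration calibration used to quantify an
#' aromatic amino acid spectrophotometrically in the near-UV (260-280 nm).
#'
#' @param solute Residue identifier of the aromatic solute.
#' @param slope Absorbance per concentration unit; must be positive.
#' @param intercept Blank absorbance. Default 0.
#' @param wavelength Reading wavelength in nm, within \[260, 280\].
#' @param valid_range Absorbance interval in which readings are trusted.
#' @return A `standard_curve`.
#' @export
standard_curve <- function(solute, slope, intercept = 0, wavelength = 280,
                           valid_range = c(0.05, 1.0)) {
  if (slope <= 0) stop("standard-curve slope must be positive", call. = FALSE)
  if (wavelength < 260 || wavelength > 280) {
    stop("wavelength must lie in [260, 280] nm", call. = FALSE)
  }
  if (length(valid_range) != 2 || valid_range[1] >= valid_range[2]) {
    stop("valid_range must be a non-empty interval (lo, hi)", call. = FALSE)
  }
  structure(list(solute = normalize_residue(solute), slope = slope,
                 intercept = intercept, wavelength = wavelength,
                 valid_range = valid_range),
            class = "standard_curve")
}

#' Default standard curves for the three aromatic solutes
#'
#' Plausible near-UV responses: Trp absorbs most strongly, Phe weakly.
#'
#' @param solutes Residues to build curves for.
#' @return Named list of [standard_curve()] objects.
#' @export
default_standard_curves <- function(solutes = .aaa_solutes()) {
  pars <- list(Tyr = list(slope = 0.9, wl = 275),
               Trp = list(slope = 1.2, wl = 280),
               Phe = list(slope = 0.3, wl = 260))
  out <- lapply(normalize_residue(solutes), function(s) {
    p <- pars[[s]]
    if (is.null(p)) p <- list(slope = 0.5, wl = 270)
    standard_curve(s, slope = p$slope, intercept = 0.01, wavelength = p$wl)
  })
  stats::setNames(out, normalize_residue(solutes))
}

#' Fill in absorbance readings for simulated records
#'
#' Emulates the bench step of diluting each saturated supernatant until its
#' absorbance falls inside the standard curve's trusted range, then reading
#' `A = slope * solubility / dilution + intercept`. The dilution is chosen
#' per record as the smallest factor from `dilutions` whose reading lands
#' in range. Records with no feasible dilution keep `absorbance = NA` and
#' are flagged (with a warning) in the `flag` column.
#'
#' @param records An `assay_records` tibble.
#' @param curves Named list of [standard_curve()]s, one per solute.
#' @param dilutions Candidate dilution factors (>= 1), a 1-2-5 series by
#'   default.
#' @return `records` with `absorbance`, `dilution` and `flag` filled.
#' @export
observe_absorbance <- function(records, curves = default_standard_curves(),
                               dilutions = as.vector(outer(c(1, 2, 5), 10^(0:5)))) {
  stopifnot(is.data.frame(records))
  if (any(dilutions < 1)) stop("dilution factors must be >= 1", call. = FALSE)
  dilutions <- sort(dilutions)
  missing_curve <- setdiff(unique(records$solute), names(curves))
  if (length(missing_curve) > 0) {
    stop("no standard curve for solute(s): ",
         paste(missing_curve, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  abs_out <- rep(NA_real_, n)
  dil_out <- rep(NA_real_, n)
  flag <- rep(NA_character_, n)
  for (s in unique(records$solute)) {
    cv <- curves[[s]]
    rows <- which(records$solute == s)
    sol <- records$solubility[rows]
    # absorbance is decreasing in dilution; take the smallest in-range factor
    for (d in dilutions) {
      a <- cv$slope * sol / d + cv$intercept
      ok <- is.na(abs_out[rows]) & a >= cv$valid_range[1] & a <= cv$valid_range[2]
      abs_out[rows][ok] <- a[ok]
      dil_out[rows][ok] <- d
    }
    bad <- rows[is.na(abs_out[rows])]
    flag[bad] <- "no_feasible_dilution"
  }
  if (any(!is.na(flag))) {
    warning(sum(!is.na(flag)),
            " record(s) had no feasible dilution and were flagged",
            call. = FALSE)
  }
  records$absorbance <- abs_out
  records$dilution <- dil_out
  records$flag <- flag
  records
}

#' Read and write assay records as CSV
#'
#' Schema: `solute,solvent,conc_M,replicate,solubility,absorbance,dilution`.
#' Writing then reading is the identity on these columns; identical seeds
#' give byte-identical files.
#'
#' @param records An `assay_records` tibble.
#' @param path File path.
#' @return `read_assay_csv()` returns an `assay_records` tibble.
#' @export
write_assay_csv <- function(records, path) {
  out <- data.frame(solute = records$solute, solvent = records$solvent,
                    conc_M = records$conc, replicate = records$replicate,
                    solubility = records$solubility,
                    absorbance = records$absorbance,
                    dilution = records$dilution)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("assay file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("solute", "solvent", "conc_M", "replicate", "solubility")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("assay CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    solute = normalize_residue(tab$solute),
    solvent = normalize_residue(tab$solvent),
    conc = as.numeric(tab$conc_M),
    replicate = as.integer(tab$replicate),
    solubility = as.numeric(tab$solubility),
    truncated = NA,
    absorbance = if ("absorbance" %in% names(tab)) as.numeric(tab$absorbance) else NA_real_,
    dilution = if ("dilution" %in% names(tab)) as.numeric(tab$dilution) else NA_real_)
  class(out) <- c("assay_records", class(out))
  out
}

#' Read and write scenarios as YAML
#'
#' Serializes every scenario field (including the full ground-truth
#' matrices), so reading a written file reconstructs the scenario exactly.
#'
#' @param scenario A `psas_scenario`.
#' @param path File path.
#' @return `read_scenario_yaml()` returns a `psas_scenario`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "psas_scenario"))
  obj <- list(
    preset = scenario$preset, seed = scenario$seed,
    solutes = scenario$solutes, solvents = scenario$solvents,
    noise_sd = scenario$noise_sd,
    s0 = as.list(scenario$s0), cmax = as.list(scenario$cmax),
    true_psas = apply(scenario$true_psas, 1, as.list, simplify = FALSE),
    nonlinearity = apply(scenario$nonlinearity, 1, as.list, simplify = FALSE))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  solutes <- unlist(obj$solutes)
  solvents <- unlist(obj$solvents)
  unmat <- function(x) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[solvents]))
    rownames(m) <- names(x)
    m[solutes, , drop = FALSE]
  }
  sc <- make_scenario("custom", seed = obj$seed,
                      true_psas = unmat(obj$true_psas),
                      s0 = unlist(obj$s0)[solutes],
                      cmax = unlist(obj$cmax)[solvents],
                      noise_sd = obj$noise_sd,
                      nonlinearity = unmat(obj$nonlinearity))
  sc$preset <- obj$preset
  sc
}
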