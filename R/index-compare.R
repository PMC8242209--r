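#' Rank correlation with explicit tie handling
#'
#' Spearman's coefficient (Pearson correlation of mid-ranks) or Kendall's
#' tau-b (concordant minus discordant pairs with tie correction in the
#' denominator). Constant vectors have no defined rank correlation and
#' raise an error rather than silently returning 0 or NA.
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return A single coefficient in \[-1, 1\].
#' @export
#' @examples
#' rank_correlation(1:5, c(2, 1, 4, 3, 5))
rank_correlation <- function(a, b, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(a) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(a, b, method = method)
}

#' Compare one solute's slope profile against every classical scale
#'
#' "By-row" comparison: for a given aromatic solute, the fitted slope
#' across the 20 solvents is rank-correlated with each scale in the index
#' set, each evaluated over the same 20 solvent residues. The coefficient
#' quantifies how far the solvent ordering induced by the slopes matches
#' the ordering induced by each classical property.
#'
#' @param matrix A `psas_matrix`.
#' @param solute One of the matrix's solutes.
#' @param set An `aa_index_set`.
#' @param method Rank statistic, as in [rank_correlation()].
#' @param on_undefined What to do when a coefficient is undefined (either
#'   vector constant): `"error"` (default) or `"na"`, which records
#'   `NA` with an explanatory `note` instead of failing — used by
#'   [consistency_report()] so one degenerate profile cannot sink the
#'   whole report.
#' @return Tibble with columns `scale`, `coefficient`, `n`, `n_ties`
#'   (tied value pairs in the scale over the solvent set), `note`.
#' @export
row_compare <- function(matrix, solute, set = load_index_set(),
                        method = "spearman",
                        on_undefined = c("error", "na")) {
  on_undefined <- match.arg(on_undefined)
  stopifnot(inherits(matrix, "psas_matrix"))
  solute <- normalize_residue(solute)
  if (!solute %in% attr(matrix, "solutes")) {
    stop("solute '", solute, "' not in matrix (solutes: ",
         paste(attr(matrix, "solutes"), collapse = ", "), ")", call. = FALSE)
  }
  solvents <- attr(matrix, "solvents")
  prof <- as.matrix(matrix)[solute, solvents]
  dplyr::bind_rows(lapply(index_scales(set), function(sc) {
    vals <- get_index_value(set, sc, solvents)
    tie_pairs <- sum(table(vals) * (table(vals) - 1) / 2)
    note <- NA_character_
    coef <- if (on_undefined == "error") {
      rank_correlation(prof, vals, method = method)
    } else {
      tryCatch(rank_correlation(prof, vals, method = method),
               error = function(e) {
                 note <<- conditionMessage(e)
                 NA_real_
               })
    }
    tibble::tibble(scale = sc, coefficient = coef,
                   n = length(solvents), n_ties = tie_pairs, note = note)
  }))
}

.order_string <- function(values, names) {
  # descending by value; tied names grouped with "=", alphabetical within a
  # tie group so tie rendering does not depend on input order
  ord <- order(-values, names)
  v <- values[ord]
  nm <- names[ord]
  grp <- cumsum(c(TRUE, diff(v) != 0))
  parts <- vapply(split(nm, grp),
                  function(g) paste(sort(g), collapse = "="), "")
  paste(parts, collapse = ">")
}

#' Solute ordering within one solvent column
#'
#' "By-column" comparison: renders the aromatic solutes sorted by
#' descending fitted slope in the given solvent, e.g. `"Trp>Tyr>Phe"`.
#' Ties are grouped with `"="` and listed alphabetically.
#'
#' @param matrix A `psas_matrix`.
#' @param solvent Solvent residue.
#' @return Ordering string over the solutes.
#' @export
#' @examples
#' rec <- simulate_assay(make_scenario("paper_like", seed = 1, noise_sd = 0))
#' column_order(fit_psas_matrix(rec), "Arg")
column_order <- function(matrix, solvent) {
  stopifnot(inherits(matrix, "psas_matrix"))
  solvent <- normalize_residue(solvent)
  if (!solvent %in% attr(matrix, "solvents")) {
    stop("solvent '", solvent, "' not in matrix", call. = FALSE)
  }
  m <- as.matrix(matrix)
  .order_string(m[, solvent], rownames(m))
}

#' Ordering of selected residues under a classical scale
#'
#' Same rendering as [column_order()], but for an index-set scale over an
#' arbitrary residue subset (typically the three aromatic solutes).
#'
#' @param set An `aa_index_set`.
#' @param index_name Scale name.
#' @param residues Residues to order (default the three aromatics).
#' @return Ordering string.
#' @export
#' @examples
#' index_order(load_index_set(), "aromaphilicity")
index_order <- function(set, index_name,
                        residues = c("Tyr", "Trp", "Phe")) {
  residues <- normalize_residue(residues)
  vals <- get_index_value(set, index_name, residues)
  .order_string(vals, residues)
}

#' Full consistency report between fitted slopes and classical scales
#'
#' Reproduces the two complementary reads of the slope matrix:
#'
#' * by row — for each solute, rank correlations of its solvent profile
#'   against every scale ([row_compare()]);
#' * by column — for each solvent, the solute ordering string and whether
#'   it matches the ordering implied by aromaphilicity, water solubility,
#'   or side-chain hydrophobicity over the same solutes.
#'
#' Solvents are grouped soluble / neutral / insoluble by the class of
#' their mean slope ([solvent_classes()]). The scientific expectation is
#' that soluble-solvent columns follow the aromaphilicity ordering (ring
#' affinity drives solubilization) while insoluble-solvent columns follow
#' water solubility or side-chain hydrophobicity (water affinity drives
#' insolubilization).
#'
#' @param matrix A `psas_matrix`.
#' @param set An `aa_index_set`.
#' @param tau Neutral half-width for solvent grouping.
#' @param method Rank statistic for the by-row part.
#' @return A `psas_report`: list with `by_row`, `by_column`,
#'   `solvent_groups`.
#' @export
consistency_report <- function(matrix, set = load_index_set(), tau = 0.05,
                               method = "spearman") {
  stopifnot(inherits(matrix, "psas_matrix"))
  solutes <- attr(matrix, "solutes")
  solvents <- attr(matrix, "solvents")
  cls <- solvent_classes(matrix, tau)
  ref_scales <- c("aromaphilicity", "solubility_water",
                  "side_chain_hydrophobicity")
  ref_orders <- vapply(ref_scales, function(sc)
    index_order(set, sc, solutes), "")
  by_column <- dplyr::bind_rows(lapply(solvents, function(sv) {
    o <- column_order(matrix, sv)
    tibble::tibble(
      solvent = sv, class = as.character(cls[[sv]]), ordering = o,
      matches_aromaphilicity = o == ref_orders[["aromaphilicity"]],
      matches_solubility_water = o == ref_orders[["solubility_water"]],
      matches_hydrophobicity = o == ref_orders[["side_chain_hydrophobicity"]])
  }))
  by_row <- dplyr::bind_rows(lapply(solutes, function(s) {
    out <- row_compare(matrix, s, set, method = method, on_undefined = "na")
    out$solute <- s
    out[, c("solute", "scale", "coefficient", "n", "n_ties", "note")]
  }))
  groups <- split(solvents, cls[solvents])
  structure(list(by_row = by_row, by_column = by_column,
                 solvent_groups = groups,
                 reference_orders = ref_orders, tau = tau, method = method),
            class = "psas_report")
}

#' @export
print.psas_report <- function(x, ...) {
  cat("PSAS consistency report (tau =", x$tau, ", method:", x$method, ")\n\n")
  cat("Solvent groups:\n")
  for (g in names(x$solvent_groups)) {
    cat(sprintf("  %-9s %s\n", g,
                paste(x$solvent_groups[[g]], collapse = ", ")))
  }
  cat("\nReference solute orderings:\n")
  for (nm in names(x$reference_orders)) {
    cat(sprintf("  %-26s %s\n", nm, x$reference_orders[[nm]]))
  }
  cat("\nBy column (solute ordering per solvent):\n")
  print(as.data.frame(x$by_column), row.names = FALSE)
  cat("\nBy row (rank correlation of solvent profiles):\n")
  print(as.data.frame(
    tidyr::pivot_wider(x$by_row[, c("solute", "scale", "coefficient")],
                       names_from = "solute", values_from = "coefficient")),
    row.names = FALSE)
  invisible(x)
}

#' Write a consistency report as TSV
#'
#' Writes the by-column table to `path` and, optionally, the by-row
#' coefficients to `by_row_path`.
#'
#' @param report A `psas_report`.
#' @param path Output TSV for the by-column section.
#' @param by_row_path Optional TSV for the by-row section.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, by_row_path = NULL) {
  stopifnot(inherits(report, "psas_report"))
  utils::write.table(report$by_column, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(by_row_path)) {
    utils::write.table(report$by_row, by_row_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
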