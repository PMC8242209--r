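#' Amino-acid index sets
#'
#' An `aa_index_set` stores named amino-acid scales (one value per canonical
#' residue per scale) together with provenance metadata: a citation string
#' and a direction note saying what larger values mean. The bundled default
#' carries eight classical scales:
#'
#' * `solubility_water` — saturation solubility of the free amino acid in
#'   water, stored as printed (the source units are not stated; treat the
#'   numbers as an opaque ordering).
#' * `side_chain_hydrophobicity` — octanol/water transfer free energy of the
#'   side chain relative to Gly (Fauchere–Pliska style).
#' * `in_out_propensity` — buried-vs-surface propensity from protein crystal
#'   structures (Miller style).
#' * `hydropathy` — Kyte–Doolittle hydropathy.
#' * `alpha_helix`, `beta_sheet`, `coil` — Chou–Fasman secondary-structure
#'   propensities.
#' * `aromaphilicity` — binding affinity of the free amino acid for aromatic
#'   carbon surfaces.
#'
#' @name aa_index_set
NULL

.index_meta_default <- function() {
  tibble::tibble(
    scale = c("solubility_water", "side_chain_hydrophobicity",
              "in_out_propensity", "hydropathy", "alpha_helix",
              "beta_sheet", "coil", "aromaphilicity"),
    source = c(
      "Dalton & McMeekin-style water solubility of free amino acids (units as printed; not stated in source table)",
      "Fauchere-Pliska octanol/water side-chain transfer free energy relative to Gly",
      "Miller interior/exterior propensity from protein crystal structures",
      "Kyte-Doolittle hydropathy",
      "Chou-Fasman alpha-helix propensity",
      "Chou-Fasman beta-sheet propensity",
      "Chou-Fasman coil propensity",
      "Aromaphilicity: affinity of free amino acids for aromatic carbon surfaces"
    ),
    direction = c(
      "larger = more soluble in water",
      "larger = more hydrophobic side chain",
      "larger = more buried (interior)",
      "larger = more hydrophobic",
      "larger = stronger helix former",
      "larger = stronger sheet former",
      "larger = stronger coil former",
      "larger = stronger aromatic-ring affinity"
    )
  )
}

new_aa_index_set <- function(values, meta) {
  structure(list(values = values, meta = meta), class = "aa_index_set")
}

.validate_index_table <- function(tab, where = "index table") {
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop(where, ": expected a 'residue' column plus at least one scale column",
         call. = FALSE)
  }
  if (names(tab)[1] != "residue") {
    stop(where, ": first column must be named 'residue'", call. = FALSE)
  }
  res <- as.character(tab$residue)
  res_canon <- tryCatch(normalize_residue(res), error = function(e) {
    stop(where, ": ", conditionMessage(e), call. = FALSE)
  })
  dup <- res_canon[duplicated(res_canon)]
  if (length(dup) > 0) {
    stop(where, ": duplicate residue row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(aa_residues(), res_canon)
  if (length(missing) > 0) {
    stop(where, ": missing residue row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(tab)[-1]) {
    col <- tab[[nm]]
    if (is.character(col)) {
      # normalize unicode minus before numeric conversion
      col <- gsub("−", "-", col)
      num <- suppressWarnings(as.numeric(col))
    } else {
      num <- suppressWarnings(as.numeric(col))
    }
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0) {
      stop(where, ": non-numeric value in scale '", nm, "', row ", bad[1],
           " (residue ", res_canon[bad[1]], "): '", col[bad[1]], "'",
           call. = FALSE)
    }
    if (anyNA(num)) {
      stop(where, ": missing value in scale '", nm, "' for residue ",
           res_canon[which(is.na(num))[1]], call. = FALSE)
    }
    tab[[nm]] <- num
  }
  tab$residue <- res_canon
  tab
}

#' Load an amino-acid index set
#'
#' With `source = NULL` (the default) returns the bundled set of eight
#' classical scales. Otherwise reads a CSV with header
#' `residue,<scale1>,<scale2>,...`, one row per canonical residue
#' (three-letter codes; one-letter accepted), "." decimal separator; a
#' unicode minus sign is normalized on read. Every scale must cover all 20
#' residues; missing, duplicate, or non-numeric rows are schema errors that
#' name the offending residue or cell.
#'
#' @param source Path to an index CSV, or `NULL` for the bundled default.
#' @param meta Optional tibble with columns `scale`, `source`, `direction`
#'   describing user-supplied scales.
#' @return An `aa_index_set`.
#' @export
#' @examples
#' idx <- load_index_set()
#' index_scales(idx)
load_index_set <- function(source = NULL, meta = NULL) {
  if (is.null(source)) {
    path <- system.file("extdata", "aa_indices.csv", package = "psas",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    tab <- .validate_index_table(tab, where = "bundled index table")
    return(new_aa_index_set(tibble::as_tibble(tab), .index_meta_default()))
  }
  if (!file.exists(source)) stop("index file not found: ", source, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(source, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("failed to parse index CSV '", source, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  tab <- .validate_index_table(tab, where = paste0("index file '", source, "'"))
  if (is.null(meta)) {
    meta <- tibble::tibble(scale = names(tab)[-1],
                           source = NA_character_,
                           direction = NA_character_)
  }
  new_aa_index_set(tibble::as_tibble(tab), meta)
}

#' Write an index set to CSV
#'
#' Writes the schema read by [load_index_set()]; a write-then-read
#' round-trip is the identity on scale names and values.
#'
#' @param set An `aa_index_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_set <- function(set, path) {
  stopifnot(inherits(set, "aa_index_set"))
  utils::write.csv(set$values, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' List the scales in an index set
#'
#' @param set An `aa_index_set`.
#' @return Character vector of scale names.
#' @export
index_scales <- function(set) {
  stopifnot(inherits(set, "aa_index_set"))
  setdiff(names(set$values), "residue")
}

.check_scale <- function(set, index_name) {
  scales <- index_scales(set)
  if (!index_name %in% scales) {
    stop("unknown scale '", index_name, "'; available: ",
         paste(scales, collapse = ", "), call. = FALSE)
  }
}

#' Look up an index value
#'
#' @param set An `aa_index_set`.
#' @param index_name Scale name (see [index_scales()]).
#' @param residue Residue identifier(s), any accepted form.
#' @return Numeric vector of stored values.
#' @export
#' @examples
#' get_index_value(load_index_set(), "hydropathy", "Ile")
get_index_value <- function(set, index_name, residue) {
  stopifnot(inherits(set, "aa_index_set"))
  .check_scale(set, index_name)
  res <- normalize_residue(residue)
  set$values[[index_name]][match(res, set$values$residue)]
}

#' Rank residues by an index
#'
#' Sorts the 20 residues by scale value. Ties are broken by the canonical
#' row order of the bundled table (see [aa_residues()]), so output is
#' deterministic even for constant scales.
#'
#' @param set An `aa_index_set`.
#' @param index_name Scale name.
#' @param descending Sort largest-first? Default `FALSE`.
#' @param n Optionally return only the first `n` residues.
#' @return Character vector of residue codes in rank order.
#' @export
#' @examples
#' rank_residues(load_index_set(), "aromaphilicity", descending = TRUE, n = 3)
rank_residues <- function(set, index_name, descending = FALSE, n = NULL) {
  stopifnot(inherits(set, "aa_index_set"))
  .check_scale(set, index_name)
  vals <- set$values[[index_name]]
  # stable order(): ties stay in table row order
  ord <- if (descending) order(-vals) else order(vals)
  out <- set$values$residue[ord]
  if (!is.null(n)) out <- utils::head(out, n)
  out
}

#' Add a scale to an index set
#'
#' Used to file a fitted slope profile (one value per solvent residue)
#' alongside the classical scales so it can be ranked and compared with the
#' same tools.
#'
#' @param set An `aa_index_set`.
#' @param name New scale name (must not already exist).
#' @param values Named numeric vector covering all 20 canonical residues.
#' @param source,direction Metadata strings.
#' @return The extended `aa_index_set`.
#' @export
add_scale <- function(set, name, values, source = NA_character_,
                      direction = NA_character_) {
  stopifnot(inherits(set, "aa_index_set"))
  if (name %in% index_scales(set)) {
    stop("scale '", name, "' already exists", call. = FALSE)
  }
  res <- normalize_residue(names(values))
  missing <- setdiff(aa_residues(), res)
  if (length(missing) > 0) {
    stop("values missing for residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set$values[[name]] <- as.numeric(values[match(set$values$residue, res)])
  set$meta <- dplyr::bind_rows(
    set$meta,
    tibble::tibble(scale = name, source = source, direction = direction)
  )
  set
}

#' @export
print.aa_index_set <- function(x, ...) {
  cat("<aa_index_set>", length(index_scales(x)), "scales x",
      nrow(x$values), "residues\n")
  cat("scales:", paste(index_scales(x), collapse = ", "), "\n")
  invisible(x)
}
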