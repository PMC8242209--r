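#' Canonical amino-acid residues
#'
#' The 20 canonical residues in the fixed row order used throughout the
#' package: the three aromatic amino acids first (Tyr, Trp, Phe), then the
#' remaining residues in the order of the bundled index table. This order is
#' the deterministic tie-break for rankings and the row/column order of
#' fitted slope matrices.
#'
#' @return Character vector of 20 three-letter codes.
#' @export
#' @examples
#' aa_residues()
aa_residues <- function() {
  c("Tyr", "Trp", "Phe", "Arg", "Lys", "His", "Pro", "Gly", "Ala", "Ser",
    "Cys", "Met", "Val", "Leu", "Ile", "Thr", "Gln", "Asn", "Glu", "Asp")
}

# one-letter codes, aligned with aa_residues()
.aa_one <- c(Tyr = "Y", Trp = "W", Phe = "F", Arg = "R", Lys = "K",
             His = "H", Pro = "P", Gly = "G", Ala = "A", Ser = "S",
             Cys = "C", Met = "M", Val = "V", Leu = "L", Ile = "I",
             Thr = "T", Gln = "Q", Asn = "N", Glu = "E", Asp = "D")

#' Normalize residue identifiers to canonical three-letter codes
#'
#' Accepts one-letter or three-letter codes in any letter case ("W", "trp",
#' "TRP" all map to "Trp"). Only the 20 canonical residues are recognized;
#' anything else is an error naming the offending value.
#'
#' @param x Character vector of residue identifiers.
#' @return Character vector of canonical three-letter codes.
#' @export
#' @examples
#' normalize_residue(c("w", "TYR", "Phe"))
normalize_residue <- function(x) {
  if (!is.character(x)) stop("residue identifiers must be character", call. = FALSE)
  canon <- aa_residues()
  out <- character(length(x))
  three <- match(toupper(x), toupper(canon))
  one <- match(toupper(x), .aa_one)
  idx <- ifelse(!is.na(three), three, one)
  bad <- is.na(idx)
  if (any(bad)) {
    stop("unknown residue identifier(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one- or three-letter codes for the 20 canonical residues)",
         call. = FALSE)
  }
  out[] <- canon[idx]
  out
}

#' Convert between one-letter and three-letter residue codes
#'
#' @param x Character vector of residue identifiers (any accepted form).
#' @return `to_one_letter()` returns one-letter codes; `to_three_letter()`
#'   canonical three-letter codes.
#' @export
#' @examples
#' to_one_letter("Trp")
#' to_three_letter("W")
to_one_letter <- function(x) {
  unname(.aa_one[normalize_residue(x)])
}

#' @rdname to_one_letter
#' @export
to_three_letter <- function(x) {
  normalize_residue(x)
}
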