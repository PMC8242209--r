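#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector. Empty files and duplicate record ids are errors;
#' characters outside the 20 canonical residues are tolerated but reported
#' in the `nonstandard` attribute (a tibble of id, position, character) and
#' via a warning, and their windows are skipped during profiling.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences, with attribute
#'   `nonstandard`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta() requires the Biostrings package", call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(toupper(as.character(seqs)), ids)
  canon1 <- unname(to_one_letter(aa_residues()))
  flagged <- dplyr::bind_rows(lapply(ids, function(id) {
    ch <- strsplit(out[[id]], "")[[1]]
    bad <- which(!ch %in% canon1)
    if (length(bad) == 0) return(NULL)
    tibble::tibble(id = id, position = bad, char = ch[bad])
  }))
  if (nrow(flagged) > 0) {
    warning(nrow(flagged), " position(s) with non-canonical residues; ",
            "their windows will be skipped in profiles", call. = FALSE)
  }
  attr(out, "nonstandard") <- flagged
  out
}

#' Sliding-window index profile of a protein sequence
#'
#' Classic hydropathy-plot-style profiling: the score at each window
#' center is the mean index value of the `w` residues in the window, for
#' any scale in the index set (including a fitted slope profile filed with
#' [add_scale()]). Positions are 1-based window centers, so a sequence of
#' length `L` yields `L - w + 1` scores at centers `(w+1)/2 ... L-(w-1)/2`;
#' with `w = 1` the profile is just the per-residue values. Windows
#' containing a non-canonical residue are skipped (score `NA`) rather than
#' imputed.
#'
#' @param sequence One-letter amino-acid string (or a single element of
#'   [read_fasta()] output).
#' @param set An `aa_index_set`.
#' @param index_name Scale to profile with.
#' @param w Odd window width, `1 <= w <= nchar(sequence)`.
#' @param id Optional sequence id stored with the profile.
#' @return A `seq_profile` tibble with columns `position`, `score` and
#'   attributes `id`, `index`, `window`, `n_skipped`.
#' @export
#' @examples
#' profile_index("GGGGG", index_name = "hydropathy", w = 3)
profile_index <- function(sequence, set = load_index_set(), index_name,
                          w = 9, id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  .check_scale(set, index_name)
  L <- nchar(sequence)
  if (w %% 2 != 1) stop("window width w must be odd", call. = FALSE)
  if (w < 1 || w > L) {
    stop("window width w must satisfy 1 <= w <= sequence length (L = ",
         L, ")", call. = FALSE)
  }
  ch <- strsplit(toupper(sequence), "")[[1]]
  canon1 <- unname(to_one_letter(aa_residues()))
  vals <- rep(NA_real_, L)
  known <- ch %in% canon1
  if (any(known)) {
    vals[known] <- get_index_value(set, index_name, ch[known])
  }
  # moving average; any NA in a window propagates -> window skipped
  scores <- as.numeric(stats::filter(vals, rep(1 / w, w), sides = 2))
  half <- (w - 1) / 2
  centers <- seq(half + 1, L - half)
  scores <- scores[centers]
  out <- tibble::tibble(position = centers, score = scores)
  structure(out, class = c("seq_profile", class(out)),
            id = id, index = index_name, window = w,
            n_skipped = sum(is.na(scores)))
}

#' Profile every sequence of a FASTA file
#'
#' @param path FASTA file path.
#' @param set An `aa_index_set`.
#' @param index_name Scale to profile with.
#' @param w Odd window width.
#' @return Tibble with columns `seq_id`, `position`, `score`.
#' @export
profile_fasta <- function(path, set = load_index_set(), index_name, w = 9) {
  seqs <- read_fasta(path)
  dplyr::bind_rows(lapply(names(seqs), function(id) {
    p <- profile_index(seqs[[id]], set, index_name, w = w, id = id)
    tibble::tibble(seq_id = id, position = p$position, score = p$score)
  }))
}
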