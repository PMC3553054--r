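# Restriction enzyme definitions and IUPAC pattern handling.
#
# Recognition patterns use the IUPAC nucleotide alphabet; scanning is
# forward-strand only, which is lossless because every bundled enzyme site is
# a degenerate palindrome (its IUPAC reverse complement equals itself).

IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  W = "AT", S = "CG", M = "AC", K = "GT", R = "AG", Y = "CT",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Convert an IUPAC pattern to a regular expression
#'
#' Each degenerate code expands to a character class over `ACGT`. An `N` in
#' the scanned sequence therefore never matches (the classes contain only
#' unambiguous bases), so sites spanning an `N` are skipped.
#'
#' @param pattern IUPAC nucleotide pattern (uppercase).
#' @return A regular expression string.
#' @keywords internal
iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(paste0("Invalid IUPAC character(s) in pattern '", pattern, "': ",
                 paste(unique(bad), collapse = ", ")))
  }
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC pattern
#' @keywords internal
iupac_revcomp <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

#' Expand an IUPAC pattern into its explicit sequence set
#'
#' Used by the brute-force digestion oracle in the test suite; exported so the
#' expansion logic is inspectable.
#'
#' @inheritParams iupac_to_regex
#' @return Character vector of all unambiguous sequences matching the pattern.
#' @export
iupac_expand <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- lapply(chars, function(ch) strsplit(IUPAC_SETS[[ch]], "")[[1]])
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1L,
        paste, collapse = "")
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition pattern (uppercase).
#' @param cut_offset Bases from the pattern start to the top-strand cut
#'   (`0 <= cut_offset <= nchar(recognition)`).
#' @return An object of class `restriction_enzyme` with fields `name`,
#'   `recognition`, `cut_offset` and the derived `remnant` (the genomic bases
#'   a read begins with after the cut, `recognition[cut_offset + 1 ..]` as an
#'   IUPAC pattern).
#' @examples
#' restriction_enzyme("ApeKI", "GCWGC", 1)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(recognition), length(recognition) == 1L)
  recognition <- toupper(recognition)
  if (nchar(recognition) == 0L) abort("recognition pattern must be non-empty")
  iupac_to_regex(recognition)  # validates characters
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L ||
      cut_offset > nchar(recognition)) {
    abort("cut_offset must lie in [0, nchar(recognition)]")
  }
  if (iupac_revcomp(recognition) != recognition) {
    abort(paste0("Recognition pattern '", recognition, "' is not a ",
                 "degenerate palindrome; forward-strand-only scanning would ",
                 "miss bottom-strand sites. Non-palindromic enzymes are not ",
                 "supported."))
  }
  structure(
    list(name = name,
         recognition = recognition,
         cut_offset = cut_offset,
         remnant = substr(recognition, cut_offset + 1L, nchar(recognition))),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut after %d, remnant %s)\n",
              x$name, x$recognition, x$cut_offset, x$remnant))
  invisible(x)
}

#' Bundled GBS enzymes
#'
#' Recognition sites and top-strand cut offsets for the enzymes commonly
#' evaluated for GBS library construction, following REBASE conventions:
#' ApeKI `G^CWGC`, PstI `CTGCA^G`, MseI `T^TAA`.
#'
#' @return A tibble with columns `name`, `recognition`, `cut_offset`.
#' @export
gbs_enzymes <- function() {
  tibble(
    name = c("ApeKI", "PstI", "MseI"),
    recognition = c("GCWGC", "CTGCAG", "TTAA"),
    cut_offset = c(1L, 5L, 1L)
  )
}

#' Look up an enzyme by name or pass one through
#'
#' @param enzyme A `restriction_enzyme`, or the name of a bundled enzyme
#'   (see [gbs_enzymes()]).
#' @param enzyme_table Optional tibble with columns `name`, `recognition`,
#'   `cut_offset` overriding the bundled table (e.g. read from a TSV).
#' @return A `restriction_enzyme`.
#' @export
get_enzyme <- function(enzyme, enzyme_table = gbs_enzymes()) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  stopifnot(is.character(enzyme), length(enzyme) == 1L)
  hit <- enzyme_table[enzyme_table$name == enzyme, , drop = FALSE]
  if (nrow(hit) != 1L) {
    abort(paste0("Unknown enzyme '", enzyme, "'; known: ",
                 paste(enzyme_table$name, collapse = ", ")))
  }
  restriction_enzyme(hit$name, hit$recognition, hit$cut_offset)
}

#' Read an enzyme definition table from TSV
#'
#' Expected columns: `name`, `recognition`, `cut_offset`.
#' @param path Path to a tab-separated file.
#' @return A tibble usable as `enzyme_table` in [get_enzyme()].
#' @export
read_enzyme_file <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    recognition = readr::col_character(),
    cut_offset = readr::col_integer()
  ))
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(tab)))
  tab
}
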