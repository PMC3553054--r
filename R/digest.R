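# In silico restriction digestion and enzyme-suitability profiling.
#
# Coordinates are 0-based half-open throughout; cut positions are 0-based
# between-base coordinates. 1-based coordinates appear only at VCF/GFF
# boundaries.

#' Read a reference FASTA into a DNAStringSet
#'
#' Accepts a path or an existing `DNAStringSet` (returned unchanged).
#' @param reference FASTA path or `Biostrings::DNAStringSet`.
#' @return A `DNAStringSet`.
#' @export
read_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    ref <- reference
  } else {
    if (!file.exists(reference)) {
      abort(paste0("Reference FASTA not found: ", reference))
    }
    ref <- tryCatch(Biostrings::readDNAStringSet(reference),
                    error = function(e) abort(paste0(
                      "Could not read FASTA '", reference, "': ",
                      conditionMessage(e))))
  }
  if (length(ref) == 0L) abort("Reference contains no sequences")
  # FASTA headers may carry descriptions; keep the first token as the name
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

check_sequence <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    abort("Sequence contains characters outside ACGTN")
  }
  seq
}

#' Find restriction cut positions in a sequence
#'
#' Scans the forward strand for every (possibly overlapping) match of the
#' enzyme's IUPAC recognition pattern and reports the 0-based between-base
#' cut coordinate of each (match start + cut offset). Matches that would span
#' an `N` do not fire. Duplicate cut positions are collapsed.
#'
#' @param seq A nucleotide string (ACGTN; case-insensitive).
#' @param enzyme A `restriction_enzyme` or bundled enzyme name.
#' @return Strictly increasing integer vector of cut positions.
#' @examples
#' find_cut_sites("TTGCAGCTT", "ApeKI")   # 3
#' find_cut_sites("GCAGCAGC", "ApeKI")    # overlapping sites: 1, 4
#' @export
find_cut_sites <- function(seq, enzyme) {
  enzyme <- get_enzyme(enzyme)
  seq <- check_sequence(seq)
  if (nchar(seq) == 0L) return(integer(0))
  rx <- paste0("(?=", iupac_to_regex(enzyme$recognition), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  sort(unique(as.integer(m) - 1L + enzyme$cut_offset))
}

#' Digest one sequence into fragments
#'
#' Fragments are the half-open intervals between successive cut positions
#' (plus the two terminal pieces). A fragment is `internal` iff both of its
#' ends are cut sites; only internal fragments can acquire adapters at both
#' ends and be sequenced in GBS. `left_internal` / `right_internal` record
#' the 1-2 insert bases a read from that end would show immediately after the
#' restriction remnant (for the right end: on the bottom strand, i.e. the
#' reverse complement of the corresponding top-strand bases). They are `NA`
#' at chromosome termini or when the fragment is too short to expose them.
#'
#' @inheritParams find_cut_sites
#' @param chrom Name recorded in the `chrom` column.
#' @return Tibble with columns `chrom`, `start`, `end`, `length`, `internal`,
#'   `left_internal`, `right_internal`.
#' @export
digest_sequence <- function(seq, enzyme, chrom = "seq1") {
  enzyme <- get_enzyme(enzyme)
  seq <- check_sequence(seq)
  len <- nchar(seq)
  if (len == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), internal = logical(),
                  left_internal = character(), right_internal = character()))
  }
  cuts <- find_cut_sites(seq, enzyme)
  cuts <- cuts[cuts > 0L & cuts < len]
  bounds <- c(0L, cuts, len)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  left_cut <- starts %in% cuts
  right_cut <- ends %in% cuts
  P <- nchar(enzyme$recognition)
  o <- enzyme$cut_offset
  rem_len <- P - o
  flen <- ends - starts

  # left: insert bases just after the remnant at the 5' cut
  li_from <- starts + rem_len + 1L        # 1-based
  li_to <- pmin(starts + rem_len + 2L, ends)
  left_internal <- ifelse(left_cut & li_from <= ends,
                          substring(seq, li_from, li_to), NA_character_)
  # right: the bottom-strand read consumes the last `cut_offset` fragment
  # bases as part of its remnant, then shows revcomp of the two preceding
  ri_to <- ends - o                        # 1-based index of first shown base
  ri_from <- pmax(ri_to - 1L, starts + 1L)
  right_raw <- ifelse(right_cut & ri_from >= starts + 1L & ri_to >= ri_from &
                        ri_to <= ends,
                      substring(seq, ri_from, ri_to), NA_character_)
  right_internal <- rep(NA_character_, length(right_raw))
  ok <- !is.na(right_raw) & nchar(right_raw) > 0L
  if (any(ok)) right_internal[ok] <- revcomp(right_raw[ok])

  tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
         length = as.integer(flen),
         internal = left_cut & right_cut,
         left_internal = as.character(left_internal),
         right_internal = as.character(right_internal))
}

#' Reverse complement of an unambiguous/N nucleotide string (vectorised)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fast scalar reverse complement (hot loops; ACGTN only)
revcomp1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

#' Digest every sequence of a reference
#'
#' @inheritParams profile_digest
#' @return Tibble of fragments (see [digest_sequence()]) over all contigs.
#' @export
digest_reference <- function(reference, enzyme) {
  ref <- read_reference(reference)
  enzyme <- get_enzyme(enzyme)
  purrr::map2_dfr(as.character(ref), names(ref),
                  function(s, nm) digest_sequence(s, enzyme, chrom = nm))
}

#' Profile an in silico digest
#'
#' Aggregates [digest_sequence()] over all reference contigs and reports the
#' fragment-size distribution and the fraction of fragments inside a size
#' window suitable for short-read sequencing. The fraction is computed over
#' internal fragments only (terminal fragments are never sequenced in GBS);
#' terminal fragments are still counted in `n_total` and the histogram.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param enzyme A `restriction_enzyme` or bundled enzyme name.
#' @param size_range Numeric length-2: inclusive fragment-size window in bp.
#' @param binwidth Histogram bin width in bp.
#' @return A `digest_profile` object: list with `enzyme`, `fragments`,
#'   `per_chrom_counts`, `size_histogram`, `n_total`, `n_internal`,
#'   `n_in_range`, `fraction_in_range`, `size_range`.
#' @export
profile_digest <- function(reference, enzyme, size_range = c(100, 400),
                           binwidth = 50) {
  enzyme <- get_enzyme(enzyme)
  frags <- digest_reference(reference, enzyme)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  n_total <- nrow(frags)
  n_internal <- sum(frags$internal)
  in_range <- frags$internal & frags$length >= size_range[1] &
    frags$length <= size_range[2]
  n_in_range <- sum(in_range)
  if (n_internal == 0L) {
    warn("No internal fragments; fraction_in_range reported as 0")
    fraction <- 0
  } else {
    fraction <- n_in_range / n_internal
  }
  brks <- seq(0, max(frags$length, binwidth) + binwidth, by = binwidth)
  bin <- cut(frags$length, breaks = brks, right = FALSE)
  hist_tab <- tibble(
    bin_lo = brks[-length(brks)], bin_hi = brks[-1],
    count = as.integer(table(factor(bin, levels = levels(bin))))
  )
  structure(
    list(enzyme = enzyme,
         fragments = frags,
         per_chrom_counts = dplyr::count(frags, .data$chrom,
                                         name = "n_fragments"),
         size_histogram = hist_tab,
         n_total = n_total,
         n_internal = n_internal,
         n_in_range = n_in_range,
         fraction_in_range = fraction,
         size_range = size_range),
    class = "digest_profile"
  )
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf(
    "<digest_profile> %s: %d fragments (%d internal) on %d contig(s)\n",
    x$enzyme$name, x$n_total, x$n_internal, nrow(x$per_chrom_counts)))
  cat(sprintf("  %.1f%% of internal fragments in [%d, %d] bp\n",
              100 * x$fraction_in_range, x$size_range[1], x$size_range[2]))
  invisible(x)
}

#' @rdname profile_digest
#' @param x A `digest_profile`.
#' @param ... Unused.
#' @export
tidy.digest_profile <- function(x, ...) x$size_histogram

#' @rdname profile_digest
#' @export
glance.digest_profile <- function(x, ...) {
  tibble(enzyme = x$enzyme$name, n_total = x$n_total,
         n_internal = x$n_internal, n_in_range = x$n_in_range,
         fraction_in_range = x$fraction_in_range)
}

#' @rdname profile_digest
#' @param object A `digest_profile`.
#' @export
autoplot.digest_profile <- function(object, ...) {
  ggplot2::ggplot(object$size_histogram,
                  ggplot2::aes(x = .data$bin_lo + diff(c(
                    object$size_histogram$bin_lo[1:2]))[1] / 2,
                    y = .data$count)) +
    ggplot2::geom_col(width = diff(object$size_histogram$bin_lo[1:2])) +
    ggplot2::annotate("rect", xmin = object$size_range[1],
                      xmax = object$size_range[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::labs(x = "Fragment size (bp)", y = "Fragments",
                  title = paste0(object$enzyme$name,
                                 " in silico fragment-size distribution")) +
    ggplot2::theme_minimal()
}

#' Write a digest profile to TSV
#'
#' Emits per-chromosome counts, the size histogram, and the in-range summary
#' as a single keyed TSV suitable for downstream inspection.
#' @param profile A `digest_profile`.
#' @param path Output path.
#' @export
write_digest_profile <- function(profile, path) {
  tsv <- function(x) sub("\n$", "", readr::format_tsv(x))
  writeLines(c("# section: summary", tsv(glance(profile)),
               "# section: per_chrom_counts", tsv(profile$per_chrom_counts),
               "# section: size_histogram", tsv(profile$size_histogram)),
             path)
  invisible(path)
}

#' Subset internal fragments by selective amplification bases
#'
#' Models PCR with a common primer that extends 1-2 bases past the
#' restriction remnant into the insert: only internal fragments whose insert
#' begins with `selective` at at least one end are retained (adapter ligation
#' is orientation-agnostic, so either fragment end may carry the common
#' adapter). An empty `selective` string returns all internal fragments
#' (the standard protocol).
#'
#' @param fragments Fragment tibble from [digest_sequence()] or
#'   [digest_reference()].
#' @param selective 0-2 bases over ACGT.
#' @return The retained internal fragments.
#' @export
selective_subset <- function(fragments, selective = "") {
  stopifnot(is.character(selective), length(selective) == 1L)
  selective <- toupper(selective)
  if (grepl("[^ACGT]", selective)) {
    abort("selective bases must be over ACGT")
  }
  if (nchar(selective) > 2L) abort("at most 2 selective bases are supported")
  internal <- dplyr::filter(fragments, .data$internal)
  if (nchar(selective) == 0L) return(internal)
  hit_l <- !is.na(internal$left_internal) &
    startsWith(internal$left_internal, selective)
  hit_r <- !is.na(internal$right_internal) &
    startsWith(internal$right_internal, selective)
  internal[hit_l | hit_r, , drop = FALSE]
}
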