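# Desk-scale read placement: a built-in substitution-only unique mapper
# (k-mer seed + extension) and import of externally produced SAM alignments.
#
# Alignment tibble convention (shared with the pileup builder): `seq` is the
# forward-reference-strand sequence (reverse-strand reads stored reverse
# complemented), `pos` is the 0-based leftmost reference position, `cigar`
# uses M/I/D runs.

#' Build a k-mer seed index over a reference
#'
#' Indexes every canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement) to its forward-strand positions. Contigs shorter than
#' `k` are skipped with a warning.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param k Seed length (odd values avoid self-reverse-complement ties).
#' @return A `kmer_index` object.
#' @export
build_index <- function(reference, k = 31L) {
  ref <- read_reference(reference)
  if (anyDuplicated(names(ref))) abort("Duplicate contig names in reference")
  k <- as.integer(k)
  seqs <- setNames(as.character(ref), names(ref))
  lens <- nchar(seqs)
  usable <- lens >= k
  if (any(!usable)) {
    warn(paste0("Skipping contig(s) shorter than k=", k, ": ",
                paste(names(seqs)[!usable], collapse = ", ")))
  }
  if (!any(usable)) abort("No contig is at least k bases long")
  km_chrom <- character(0); km_pos <- integer(0); km <- character(0)
  for (nm in names(seqs)[usable]) {
    starts <- seq_len(lens[[nm]] - k + 1L)
    kmers <- substring(seqs[[nm]], starts, starts + k - 1L)
    km <- c(km, kmers)
    km_chrom <- c(km_chrom, rep(nm, length(starts)))
    km_pos <- c(km_pos, starts - 1L)      # 0-based
  }
  valid <- !grepl("N", km, fixed = TRUE)
  km <- km[valid]; km_chrom <- km_chrom[valid]; km_pos <- km_pos[valid]
  rc <- revcomp(km)
  canon <- ifelse(km <= rc, km, rc)
  tab <- data.frame(chrom = km_chrom, pos = km_pos, stringsAsFactors = FALSE)
  idx <- list2env(split(tab, canon), envir = new.env(hash = TRUE))
  structure(list(env = idx, k = k, seqs = seqs, lens = lens),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d contig(s), %d distinct seeds\n",
              x$k, length(x$seqs), length(ls(x$env))))
  invisible(x)
}

count_mismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Map processed reads with the built-in unique mapper
#'
#' Seeds each read with k-mers at a few fixed offsets (read start, k, 2k and
#' read end, both strands via canonical lookup) so that a read carrying a
#' variant inside one seed window is still recoverable from another, and
#' extends every candidate placement by direct comparison over the full
#' read, allowing up to `max_mismatch` substitutions (the built-in mapper is
#' ungapped; indel discovery requires SAM import). A read is emitted only
#' when exactly one location passes: reads matching several locations are
#' `ambiguous`, reads matching none `unmapped`, mirroring the
#' retain-unique-mappings policy.
#'
#' @param reads Processed-read tibble (`sample_id`, `id`, `seq`, ...).
#' @param index A `kmer_index` from [build_index()].
#' @param max_mismatch Maximum substitutions allowed.
#' @return List: `alignments` tibble (`read_id`, `sample_id`, `chrom`, `pos`,
#'   `strand`, `cigar`, `seq`, `nm`) and `status` tibble tallying
#'   unique / ambiguous / unmapped per sample.
#' @export
map_reads <- function(reads, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  n <- nrow(reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- NA_character_
  seqs <- index$seqs
  lens <- index$lens
  status <- character(n)
  out_chrom <- character(n); out_pos <- integer(n)
  out_strand <- character(n); out_seq <- character(n); out_nm <- integer(n)
  rlens <- nchar(reads$seq)
  clean <- !grepl("[^ACGT]", reads$seq)
  mappable <- clean & rlens >= k
  # precompute seed k-mers (offsets 0, k, 2k, read end), their canonical
  # forms, and full-read reverse complements in vectorised passes
  off_mat <- matrix(NA_integer_, n, 4L)
  if (any(mappable)) {
    off_mat[mappable, 1] <- 0L
    off_mat[mappable, 2] <- ifelse(2L * k <= rlens[mappable], k, NA)
    off_mat[mappable, 3] <- ifelse(3L * k <= rlens[mappable], 2L * k, NA)
    last <- rlens[mappable] - k
    last[last %in% c(0L, k, 2L * k)] <- NA
    off_mat[mappable, 4] <- last
  }
  km_mat <- matrix(NA_character_, n, 4L)
  for (j in 1:4) {
    has <- !is.na(off_mat[, j])
    km_mat[has, j] <- substring(reads$seq[has], off_mat[has, j] + 1L,
                                off_mat[has, j] + k)
  }
  canon_mat <- km_mat
  has_km <- !is.na(km_mat)
  if (any(has_km)) {
    rc_all <- revcomp(km_mat[has_km])
    canon_mat[has_km] <- ifelse(km_mat[has_km] <= rc_all,
                                km_mat[has_km], rc_all)
  }
  read_rc <- rep(NA_character_, n)
  read_rc[mappable] <- revcomp(reads$seq[mappable])
  for (i in seq_len(n)) {
    rlen <- rlens[i]
    if (!mappable[i]) { status[i] <- "unmapped"; next }
    rseq <- reads$seq[i]
    passes <- list()
    seen <- character(0)
    for (j in which(!is.na(off_mat[i, ]))) {
      q_off <- off_mat[i, j]
      km <- km_mat[i, j]
      hits <- index$env[[canon_mat[i, j]]]
      if (is.null(hits)) next
      for (h in seq_len(nrow(hits))) {
        chrom <- hits$chrom[h]; p <- hits$pos[h]     # 0-based seed pos
        W <- substr(seqs[[chrom]], p + 1L, p + k)
        if (km == W) {                                # forward candidate
          start0 <- p - q_off
          strand <- "+"
          query <- rseq
        } else {                                      # reverse candidate
          start0 <- p - (rlen - q_off - k)
          strand <- "-"
          query <- read_rc[i]
        }
        key <- paste(chrom, start0, strand)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (start0 < 0L || start0 + rlen > lens[[chrom]]) next
        refseq <- substr(seqs[[chrom]], start0 + 1L, start0 + rlen)
        nm <- count_mismatch(query, refseq)
        if (nm <= max_mismatch) {
          passes[[length(passes) + 1L]] <-
            list(chrom = chrom, pos = start0, strand = strand,
                 seq = query, nm = nm)
        }
      }
    }
    if (length(passes) == 0L) {
      status[i] <- "unmapped"
    } else if (length(passes) > 1L) {
      status[i] <- "ambiguous"
    } else {
      status[i] <- "unique"
      a <- passes[[1]]
      out_chrom[i] <- a$chrom; out_pos[i] <- a$pos
      out_strand[i] <- a$strand; out_seq[i] <- a$seq; out_nm[i] <- a$nm
    }
  }
  uq <- status == "unique"
  alignments <- tibble(read_id = reads$id[uq],
                       sample_id = reads$sample_id[uq],
                       chrom = out_chrom[uq], pos = out_pos[uq],
                       strand = out_strand[uq],
                       cigar = paste0(rlens[uq], "M"),
                       seq = out_seq[uq], nm = out_nm[uq])
  status_tab <- tibble(sample_id = reads$sample_id, status = status) %>%
    dplyr::count(.data$sample_id, .data$status)
  list(alignments = alignments, status = status_tab)
}

#' Import alignments from SAM
#'
#' Keeps primary, mapped records with MAPQ at or above `min_mapq` and without
#' secondary/supplementary flags, operationalising "reads mapping to a unique
#' location". CIGAR I/D runs are preserved for indel calling. The SAM header
#' must agree with the reference contigs.
#'
#' @param path SAM file path.
#' @param reference FASTA path or `DNAStringSet` the SAM was produced
#'   against.
#' @param min_mapq Minimum mapping quality retained.
#' @param sample_id Sample label attached to the alignments, or a function
#'   applied to each QNAME returning the label.
#' @return Alignment tibble as in [map_reads()].
#' @export
import_sam <- function(path, reference, min_mapq = 20L, sample_id = NA) {
  ref <- read_reference(reference)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!all(names(hdr) %in% names(ref)) ||
      !all(hdr == Biostrings::width(ref)[match(names(hdr), names(ref))])) {
    abort("SAM @SQ header does not match the reference contigs")
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "seq", "mapq", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)))
  mc <- S4Vectors::mcols(ga)
  keep <- !is.na(mc$mapq) & mc$mapq >= min_mapq
  ga <- ga[keep]; mc <- mc[keep, , drop = FALSE]
  sid <- if (is.function(sample_id)) {
    vapply(mc$qname, sample_id, character(1), USE.NAMES = FALSE)
  } else rep(as.character(sample_id), length(ga))
  tibble(read_id = mc$qname,
         sample_id = sid,
         chrom = as.character(GenomicAlignments::seqnames(ga)),
         pos = GenomicAlignments::start(ga) - 1L,
         strand = as.character(GenomicAlignments::strand(ga)),
         cigar = GenomicAlignments::cigar(ga),
         seq = as.character(mc$seq),
         nm = NA_integer_)
}

#' Write alignments as SAM
#'
#' Minimal SAM 1.6 emission used to hand alignments to external tools and to
#' serialise simulator truth alignments as text fixtures. Reverse-strand
#' alignments are stored per SAM convention (sequence already on the forward
#' reference strand here, so no flipping is needed beyond FLAG 16).
#'
#' @param alignments Alignment tibble (see [map_reads()]).
#' @param reference FASTA path or `DNAStringSet`.
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, reference, path) {
  ref <- read_reference(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(ref)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref)[i],
                       Biostrings::width(ref)[i]), con)
  }
  if (nrow(alignments) > 0) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       alignments$read_id, flag, alignments$chrom,
                       alignments$pos + 1L, alignments$cigar,
                       alignments$seq,
                       strrep("I", nchar(alignments$seq))), con)
  }
  invisible(path)
}
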