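# Raw-read grooming: barcode demultiplexing with restriction-remnant
# validation, common-adapter clipping of read-through, and quality filters.

#' Default common-adapter prefix seen on read-through
#'
#' The first bases of the common adapter as they appear 3' of the distal
#' restriction remnant when a read runs off the end of a short fragment.
#' @export
GBS_ADAPTER_PREFIX <- "AGATCGGAAGAGC"

# full read-through continuation used by the simulator (reverse complement of
# the common amplification primer, minus the remnant/selective bases)
GBS_ADAPTER_READTHROUGH <- paste0(
  "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGATCTCGTATGCCGTCTTCTGCTTG")

#' Demultiplex reads by barcode with remnant validation
#'
#' A read is assigned to a sample iff its sequence starts with exactly one
#' sheet barcode AND the bases immediately following the barcode match the
#' enzyme's restriction remnant pattern (e.g. `C[AT]GC` for ApeKI): a proper
#' GBS read layout is barcode + remnant + insert. The barcode is removed; the
#' remnant is genomic sequence and is retained. Barcode matching is exact;
#' the prefix-free sheet guarantees at most one match.
#'
#' @param reads Tibble with `id`, `seq`, `qual` (see [read_fastq()]).
#' @param sheet Sample sheet (path or tibble; see [read_sample_sheet()]).
#' @param enzyme `restriction_enzyme` or bundled enzyme name.
#' @return The input tibble with added columns `sample_id` (`NA` when
#'   unassigned), `reason` (`NA` | `"no_barcode"` | `"bad_remnant"`), and
#'   `seq`/`qual` stripped of the barcode for assigned reads;
#'   `source_read_id` preserves the original id.
#' @export
demultiplex <- function(reads, sheet, enzyme) {
  sheet <- read_sample_sheet(sheet)
  enzyme <- get_enzyme(enzyme)
  if (nchar(enzyme$remnant) == 0L) {
    abort("Enzyme has an empty remnant; cannot validate read layout")
  }
  rem_rx <- paste0("^", iupac_to_regex(enzyme$remnant))
  n <- nrow(reads)
  bc_idx <- rep(NA_integer_, n)
  for (i in seq_len(nrow(sheet))) {
    hit <- startsWith(reads$seq, sheet$barcode[i])
    bc_idx[hit] <- i
  }
  bl <- ifelse(is.na(bc_idx), 0L, nchar(sheet$barcode)[bc_idx])
  after <- substr(reads$seq, bl + 1L, nchar(reads$seq))
  rem_ok <- grepl(rem_rx, after)
  assigned <- !is.na(bc_idx) & rem_ok
  out <- reads
  out$source_read_id <- reads$id
  out$sample_id <- ifelse(assigned, sheet$sample_id[bc_idx], NA_character_)
  out$reason <- dplyr::case_when(
    assigned ~ NA_character_,
    is.na(bc_idx) ~ "no_barcode",
    TRUE ~ "bad_remnant")
  out$seq <- ifelse(assigned, after, reads$seq)
  out$qual <- ifelse(assigned,
                     substr(reads$qual, bl + 1L, nchar(reads$qual)),
                     reads$qual)
  out
}

#' Clip read-through adapter sequence
#'
#' Scans each read for a restriction-remnant match followed by at least
#' `min_adapter` exact bases of the common-adapter prefix (or a remnant flush
#' at the read end, which marks a fragment boundary with nothing to remove)
#' and truncates immediately AFTER the distal remnant, discarding the adapter
#' bases. Reads without such evidence are returned unchanged. The operation
#' is idempotent.
#'
#' @param seq,qual Character vectors of equal lengths per element.
#' @param enzyme `restriction_enzyme` or bundled enzyme name.
#' @param adapter Common-adapter prefix expected after the distal remnant.
#' @param min_adapter Minimum number of exact adapter bases required as
#'   clipping evidence.
#' @return List with clipped `seq` and `qual`.
#' @export
clip_adapter <- function(seq, qual, enzyme,
                         adapter = GBS_ADAPTER_PREFIX, min_adapter = 5L) {
  enzyme <- get_enzyme(enzyme)
  rem_rx <- paste0("(?=", iupac_to_regex(enzyme$remnant), ")")
  rl <- nchar(enzyme$remnant)
  ad_len <- nchar(adapter)
  clip_one <- function(s) {
    n <- nchar(s)
    m <- gregexpr(rem_rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(n)
    for (st in as.integer(m)) {
      e <- st + rl - 1L
      if (e > n) next
      if (e == n) return(n)               # remnant flush at read end
      avail <- n - e
      k <- min(avail, ad_len)
      if (avail >= min_adapter &&
          substr(s, e + 1L, e + k) == substr(adapter, 1L, k)) {
        return(e)
      }
    }
    n
  }
  keep <- vapply(seq, clip_one, integer(1), USE.NAMES = FALSE)
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

#' Length / N quality filter
#'
#' Drops reads shorter than `min_length` bases or containing any `N`.
#'
#' @param reads Tibble with at least `seq`.
#' @param min_length Minimum retained read length (bases).
#' @return Input tibble with added `keep` (logical) and `drop_reason`
#'   (`NA` | `"too_short"` | `"contains_N"`).
#' @export
quality_filter <- function(reads, min_length = 25L) {
  too_short <- nchar(reads$seq) < min_length
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  reads$keep <- !too_short & !has_n
  reads$drop_reason <- dplyr::case_when(
    too_short ~ "too_short",
    has_n ~ "contains_N",
    TRUE ~ NA_character_)
  reads
}

#' Process a raw GBS FASTQ end to end
#'
#' Streams reads through [demultiplex()] -> [clip_adapter()] ->
#' [quality_filter()] and tallies a per-sample run summary. Deterministic
#' given its inputs.
#'
#' @param fastq FASTQ path(s) or a read tibble.
#' @param sheet Sample sheet (path or tibble).
#' @param enzyme `restriction_enzyme` or bundled enzyme name.
#' @param min_length Minimum processed-read length.
#' @param adapter Common-adapter prefix for clipping.
#' @param out_dir Optional directory; when given, per-sample FASTQs
#'   (`<sample_id>.fq`) and `run_summary.tsv` are written there.
#' @return List with `reads` (processed reads: `sample_id`, `id`, `seq`,
#'   `qual`, `source_read_id`), `unassigned` (with `reason`), `dropped`
#'   (assigned but filtered, with `drop_reason`) and `summary`
#'   (see [run_summary()]).
#' @export
process_fastq <- function(fastq, sheet, enzyme, min_length = 25L,
                          adapter = GBS_ADAPTER_PREFIX, out_dir = NULL) {
  reads <- if (is.data.frame(fastq)) as_tibble(fastq) else read_fastq(fastq)
  sheet <- read_sample_sheet(sheet)
  enzyme <- get_enzyme(enzyme)
  dm <- demultiplex(reads, sheet, enzyme)
  unassigned <- dm[is.na(dm$sample_id),
                   c("id", "seq", "qual", "reason")]
  asg <- dm[!is.na(dm$sample_id), , drop = FALSE]
  if (nrow(asg) > 0) {
    cl <- clip_adapter(asg$seq, asg$qual, enzyme, adapter = adapter)
    asg$seq <- cl$seq
    asg$qual <- cl$qual
  }
  asg <- quality_filter(asg, min_length = min_length)
  kept <- asg[asg$keep,
              c("sample_id", "id", "seq", "qual", "source_read_id")]
  dropped <- asg[!asg$keep,
                 c("sample_id", "id", "seq", "qual", "drop_reason")]
  summ <- run_summary(raw = dplyr::count(asg, .data$sample_id, name = "raw"),
                      processed = dplyr::count(kept, .data$sample_id,
                                               name = "processed"),
                      samples = sheet$sample_id,
                      n_unassigned = nrow(unassigned))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in sheet$sample_id) {
      write_fastq(kept[kept$sample_id == sid, c("id", "seq", "qual")],
                  file.path(out_dir, paste0(sid, ".fq")))
    }
    readr::write_tsv(summ, file.path(out_dir, "run_summary.tsv"))
  }
  list(reads = kept, unassigned = unassigned, dropped = dropped,
       summary = summ)
}

#' Per-sample read accounting
#'
#' Mirrors the raw -> processed -> mapped bookkeeping of a GBS run summary
#' table: absolute counts plus derived percentages (2 decimals), with a
#' `Total` row. `processed <= raw` and `mapped <= processed` by construction.
#'
#' @param raw Tibble `sample_id`, `raw` (reads sorted to that sample).
#' @param processed Tibble `sample_id`, `processed`.
#' @param mapped Optional tibble `sample_id`, `mapped`.
#' @param samples Character vector fixing row order.
#' @param n_unassigned Reads assigned to no sample (recorded as an attribute).
#' @return Tibble with columns `sample_id`, `raw_reads`, `processed_reads`,
#'   `pct_processed`, and (when available) `mapped_reads`, `pct_mapped`.
#' @export
run_summary <- function(raw, processed, mapped = NULL, samples = NULL,
                        n_unassigned = 0L) {
  if (is.null(samples)) samples <- raw$sample_id
  raw$sample_id <- as.character(raw$sample_id)
  processed$sample_id <- as.character(processed$sample_id)
  if (!is.null(mapped)) mapped$sample_id <- as.character(mapped$sample_id)
  tab <- tibble(sample_id = as.character(samples)) %>%
    left_join(raw, by = "sample_id") %>%
    left_join(processed, by = "sample_id")
  tab$raw[is.na(tab$raw)] <- 0L
  tab$processed[is.na(tab$processed)] <- 0L
  if (!is.null(mapped)) {
    tab <- left_join(tab, mapped, by = "sample_id")
    tab$mapped[is.na(tab$mapped)] <- 0L
  }
  tot <- tibble(sample_id = "Total",
                raw = sum(tab$raw), processed = sum(tab$processed))
  if (!is.null(mapped)) tot$mapped <- sum(tab$mapped)
  tab <- bind_rows(tab, tot)
  out <- tibble(
    sample_id = tab$sample_id,
    raw_reads = tab$raw,
    processed_reads = tab$processed,
    pct_processed = round(ifelse(tab$raw > 0,
                                 100 * tab$processed / tab$raw, 0), 2))
  if (!is.null(mapped)) {
    out$mapped_reads <- tab$mapped
    out$pct_mapped <- round(ifelse(tab$processed > 0,
                                   100 * tab$mapped / tab$processed, 0), 2)
  }
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Downsample a read set
#'
#' Uniform random subsample without replacement, reproducible by seed. Used
#' to emulate higher multiplex levels (fewer reads per sample).
#'
#' @param reads Read tibble.
#' @param n Number of reads to keep (exclusive with `fraction`).
#' @param fraction Fraction in (0, 1] to keep.
#' @param seed Integer RNG seed.
#' @return Subsampled tibble (original row order preserved).
#' @export
downsample_reads <- function(reads, n = NULL, fraction = NULL, seed) {
  stopifnot(xor(is.null(n), is.null(fraction)))
  total <- nrow(reads)
  if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    if (fraction == 1) return(reads)
    n <- round(total * fraction)
  }
  if (n > total) abort("Requested more reads than available")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(sample.int(total, n))
  reads[keep, , drop = FALSE]
}

# save/restore global RNG state so seeded helpers do not perturb the session
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
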