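# FASTQ and sample-sheet I/O. Reads travel as tibbles with columns
# id / seq / qual (phred+33); Biostrings does the file-format work
# (gzip transparently supported).

#' Read FASTQ into a tibble
#'
#' @param path One or more FASTQ paths (optionally gzipped).
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(all(file.exists(path)))
  out <- lapply(path, function(p) {
    dss <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e) abort(paste0("Malformed FASTQ '", p, "': ",
                                       conditionMessage(e))))
    tibble(id = unname(names(dss)),
           seq = unname(as.character(dss)),
           qual = unname(as.character(S4Vectors::mcols(dss)$qualities)))
  })
  bind_rows(out)
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual`.
#' @param path Output path (`.gz` suffix triggers compression).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  Biostrings::writeXStringSet(
    dss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' A sample sheet maps barcodes to sample identifiers
#' (TSV: `sample_id<TAB>barcode`). Validation enforces: unique sample ids,
#' unique barcodes of 4-8 ACGT bases, and the prefix-free property (no
#' barcode is a prefix of another), which guarantees unambiguous matching.
#'
#' @param sheet TSV path or a tibble with columns `sample_id`, `barcode`.
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(sheet) {
  if (is.character(sheet) && length(sheet) == 1L) {
    sheet <- readr::read_tsv(sheet, col_types = readr::cols(
      sample_id = readr::col_character(),
      barcode = readr::col_character()))
  }
  sheet <- as_tibble(sheet)
  stopifnot(all(c("sample_id", "barcode") %in% names(sheet)))
  sheet$barcode <- toupper(sheet$barcode)
  if (anyDuplicated(sheet$sample_id)) abort("Duplicate sample_id in sheet")
  if (anyDuplicated(sheet$barcode)) abort("Duplicate barcode in sheet")
  if (any(!grepl("^[ACGT]{4,8}$", sheet$barcode))) {
    abort("Barcodes must be 4-8 bases over ACGT")
  }
  bcs <- sheet$barcode
  for (i in seq_along(bcs)) {
    pref <- bcs[-i][startsWith(bcs[-i], bcs[i])]
    if (length(pref) > 0) {
      abort(paste0("Barcode '", bcs[i], "' is a prefix of '", pref[1],
                   "'; sheet is not prefix-free"))
    }
  }
  sheet
}
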