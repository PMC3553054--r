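# VCF 4.2 emission and import for gbs_variants objects. Writing is simple
# line emission (GT:DP per sample, './.' for missing); reading goes through
# vcfR so externally produced VCFs are equally importable.

#' Write variants to VCF 4.2
#'
#' Emits contig header lines, GT:DP per-sample fields (MISSING as `./.`),
#' and an `ANN=category|gene|effect` INFO key when annotations have been
#' attached (see [classify_snps()]). Input must be coordinate-sorted.
#'
#' @param x A `gbs_variants` object.
#' @param reference FASTA path or `DNAStringSet` (for contig headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, reference, path) {
  stopifnot(inherits(x, "gbs_variants"))
  ref <- read_reference(reference)
  sites <- x$sites
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos, sites$ref)
    if (!identical(o, seq_len(nrow(sites)))) {
      abort("Sites are not coordinate-sorted")
    }
  }
  samples <- x$samples
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbskit",
    sprintf("##contig=<ID=%s,length=%d>", names(ref),
            Biostrings::width(ref)),
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation: category|gene|effect\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- character(nrow(sites))
  geno <- x$geno
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    alleles <- c(s$ref, strsplit(s$alt, ",", fixed = TRUE)[[1]])
    g <- geno[geno$site == s$site, , drop = FALSE]
    g <- g[match(samples, g$sample_id), , drop = FALSE]
    gt <- ifelse(
      is.na(g$a1), "./.",
      {
        i1 <- match(g$a1, alleles) - 1L
        i2 <- match(g$a2, alleles) - 1L
        paste(pmin(i1, i2), pmax(i1, i2), sep = "/")
      })
    info <- if ("annotation" %in% names(sites) && !is.na(s$annotation)) {
      paste0("ANN=", s$annotation)
    } else "."
    body[i] <- paste(c(
      s$chrom, s$pos + 1L, ".", s$ref, s$alt, ".", "PASS", info, "GT:DP",
      paste0(gt, ":", g$depth)), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a gbs_variants object
#'
#' Parses chrom/pos/ref/alt and per-sample GT:DP fields.
#' Fields the model does not carry (QUAL, FILTER, other FORMAT keys) are
#' ignored, so `read_vcf(write_vcf(x))` recovers `x` on all modelled fields.
#'
#' @param path VCF path.
#' @return A `gbs_variants` object.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    return(new_gbs_variants(
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), type = character(), site = character()),
      tibble(site = character(), chrom = character(), pos = integer(),
             ref = character(), sample_id = character(), a1 = character(),
             a2 = character(), code = character(), depth = integer()),
      samples))
  }
  samples <- colnames(v@gt)[-1]
  pos <- as.integer(fix$POS) - 1L
  is_indel <- nchar(fix$REF) > 1L |
    vapply(strsplit(fix$ALT, ","), function(a) any(nchar(a) > 1L),
           logical(1))
  sites <- tibble(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                  alt = fix$ALT,
                  type = ifelse(is_indel, "INDEL", "SNP"),
                  site = site_key(fix$CHROM, pos, fix$REF))
  ann <- sub("^ANN=", "", fix$INFO)
  ann[!grepl("^ANN=", fix$INFO)] <- NA_character_
  if (any(!is.na(ann))) sites$annotation <- ann
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    apply(vcfR::extract.gt(v, element = "DP"), 2, as.integer))
  if (is.null(dim(dp))) dp <- matrix(dp, nrow = nrow(sites))
  geno_rows <- vector("list", length(samples))
  allele_list <- Map(function(r, a) c(r, strsplit(a, ",")[[1]]),
                     fix$REF, fix$ALT)
  for (j in seq_along(samples)) {
    gts <- gt[, j]
    parts <- strsplit(ifelse(is.na(gts), "./.", gts), "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    i2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    a1 <- mapply(function(al, k) if (is.na(k)) NA_character_ else al[k + 1L],
                 allele_list, i1)
    a2 <- mapply(function(al, k) if (is.na(k)) NA_character_ else al[k + 1L],
                 allele_list, i2)
    code <- dplyr::case_when(
      is.na(a1) | is.na(a2) ~ "MISSING",
      a1 != a2 ~ "HET",
      a1 == sites$ref ~ "HOM_REF",
      TRUE ~ "HOM_ALT")
    geno_rows[[j]] <- tibble(site = sites$site, chrom = sites$chrom,
                             pos = sites$pos, ref = sites$ref,
                             sample_id = samples[j],
                             a1 = unname(a1), a2 = unname(a2), code = code,
                             depth = dplyr::coalesce(dp[, j], 0L))
  }
  geno <- bind_rows(geno_rows) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$sample_id)
  new_gbs_variants(sites, geno, samples)
}
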