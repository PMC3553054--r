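# Pileup construction, per-sample genotype calling, variant filters and
# heterozygote correction.
#
# A `gbs_variants` object holds two tibbles: `sites` (one row per variant
# site: chrom, pos [0-based], ref, alt [comma-joined], type SNP|INDEL, site
# key) and `geno` (one row per site x sample: alleles a1/a2, code in
# HOM_REF|HET|HOM_ALT|MISSING, depth).

GT_CODES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

site_key <- function(chrom, pos, ref) sprintf("%s:%d:%s", chrom, pos, ref)

new_gbs_variants <- function(sites, geno, samples) {
  sites <- arrange(sites, .data$chrom, .data$pos, .data$ref)
  geno$code <- factor(geno$code, levels = GT_CODES)
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "gbs_variants")
}

#' @export
print.gbs_variants <- function(x, ...) {
  cat(sprintf("<gbs_variants> %d site(s) (%d SNP, %d indel) x %d sample(s)\n",
              nrow(x$sites), sum(x$sites$type == "SNP"),
              sum(x$sites$type == "INDEL"), length(x$samples)))
  invisible(x)
}

#' Tidy a variant set into one row per site x sample
#' @param x A `gbs_variants` object.
#' @param ... Unused.
#' @export
tidy.gbs_variants <- function(x, ...) {
  left_join(x$geno,
            select(x$sites, "site", "alt", "type"), by = "site") %>%
    select("chrom", "pos", "ref", "alt", "type", "sample_id",
           "a1", "a2", "code", "depth")
}

#' Genotype-category accounting for a variant set
#'
#' Fractions of HOM_REF / HOM_ALT / HET / MISSING genotype calls over all
#' site x sample cells; they always sum to 1.
#' @inheritParams tidy.gbs_variants
#' @export
glance.gbs_variants <- function(x, ...) {
  n <- nrow(x$geno)
  tab <- table(factor(x$geno$code, levels = GT_CODES))
  tibble(n_sites = nrow(x$sites), n_samples = length(x$samples),
         n_genotypes = n,
         frac_hom_ref = as.numeric(tab["HOM_REF"]) / n,
         frac_het = as.numeric(tab["HET"]) / n,
         frac_hom_alt = as.numeric(tab["HOM_ALT"]) / n,
         frac_missing = as.numeric(tab["MISSING"]) / n,
         mean_depth = mean(x$geno$depth[x$geno$code != "MISSING"]))
}

cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", m)),
       op = sub("^\\d+", "", m))
}

cigar_ref_span <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_span <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a pileup from alignments
#'
#' Tallies per-sample base counts at every covered reference position, and
#' converts CIGAR I/D runs into indel events anchored (VCF-style) at the
#' preceding matched reference base: deletions as (anchor + deleted bases ->
#' anchor), insertions as (anchor -> anchor + inserted bases).
#'
#' @param alignments Alignment tibble ([map_reads()] / [import_sam()]).
#' @param reference FASTA path or `DNAStringSet`.
#' @return A `gbs_pileup`: list of tibbles `bases` (`chrom`, `pos`,
#'   `sample_id`, `base`, `n`) and `indels` (`chrom`, `pos`, `sample_id`,
#'   `ref`, `alt`, `n`).
#' @export
build_pileup <- function(alignments, reference) {
  ref <- read_reference(reference)
  lens <- setNames(Biostrings::width(ref), names(ref))
  seqs <- setNames(as.character(ref), names(ref))
  if (nrow(alignments) > 0) {
    spans <- cigar_ref_span(alignments$cigar)
    bad <- alignments$pos < 0L |
      alignments$pos + spans > lens[alignments$chrom]
    if (any(bad)) {
      abort(paste0("Alignment beyond contig bounds (e.g. read ",
                   alignments$read_id[which(bad)[1]], ")"))
    }
  }
  pure <- grepl("^[0-9]+M$", alignments$cigar)
  base_parts <- list()
  indel_parts <- list()
  a <- alignments[pure, , drop = FALSE]
  if (nrow(a) > 0) {
    l <- nchar(a$seq)
    base_parts[[1]] <- tibble(
      chrom = rep(a$chrom, l),
      pos = rep(a$pos, l) + sequence(l) - 1L,
      sample_id = rep(a$sample_id, l),
      base = unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE))
  }
  g <- alignments[!pure, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    ops <- cigar_ops(g$cigar[i])
    rp <- g$pos[i]          # 0-based ref cursor
    qp <- 1L                # 1-based query cursor
    chrom <- g$chrom[i]
    for (j in seq_along(ops$op)) {
      len <- ops$len[j]
      op <- ops$op[j]
      if (op %in% c("M", "=", "X")) {
        base_parts[[length(base_parts) + 1L]] <- tibble(
          chrom = chrom, pos = rp + seq_len(len) - 1L,
          sample_id = g$sample_id[i],
          base = strsplit(substr(g$seq[i], qp, qp + len - 1L), "")[[1]])
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") {
        if (rp > g$pos[i]) {
          anchor <- substr(seqs[[chrom]], rp, rp)   # base at 0-based rp-1
          indel_parts[[length(indel_parts) + 1L]] <- tibble(
            chrom = chrom, pos = rp - 1L, sample_id = g$sample_id[i],
            ref = anchor,
            alt = paste0(anchor, substr(g$seq[i], qp, qp + len - 1L)))
        }
        qp <- qp + len
      } else if (op %in% c("D", "N")) {
        if (rp > g$pos[i]) {
          anchor <- substr(seqs[[chrom]], rp, rp)
          indel_parts[[length(indel_parts) + 1L]] <- tibble(
            chrom = chrom, pos = rp - 1L, sample_id = g$sample_id[i],
            ref = paste0(anchor, substr(seqs[[chrom]], rp + 1L, rp + len)),
            alt = anchor)
        }
        rp <- rp + len
      } else if (op == "S") {
        qp <- qp + len
      }
    }
  }
  bases <- if (length(base_parts) > 0) {
    bind_rows(base_parts) %>%
      dplyr::count(.data$chrom, .data$pos, .data$sample_id, .data$base,
                   name = "n")
  } else {
    tibble(chrom = character(), pos = integer(), sample_id = character(),
           base = character(), n = integer())
  }
  indels <- if (length(indel_parts) > 0) {
    bind_rows(indel_parts) %>%
      dplyr::count(.data$chrom, .data$pos, .data$sample_id, .data$ref,
                   .data$alt, name = "n")
  } else {
    tibble(chrom = character(), pos = integer(), sample_id = character(),
           ref = character(), alt = character(), n = integer())
  }
  structure(list(bases = bases, indels = indels), class = "gbs_pileup")
}

#' @export
print.gbs_pileup <- function(x, ...) {
  cat(sprintf("<gbs_pileup> %d covered position-sample cells, %d indel events\n",
              nrow(dplyr::distinct(x$bases, .data$chrom, .data$pos,
                                   .data$sample_id)),
              nrow(x$indels)))
  invisible(x)
}

#' Call one sample's genotype from allele counts
#'
#' The calling rule applied at every site: depth below `min_depth` gives
#' MISSING; a single observed allele gives a homozygous call; two alleles
#' give a heterozygous call only when each has at least `het_min_reads`
#' reads and the minor fraction is at least `het_min_frac`; otherwise the
#' majority allele is called homozygous (a lone stray read of a second
#' allele, typical of sequencing error at GBS depths, is ignored). Count
#' ties are broken toward the reference allele.
#'
#' @param counts Named integer vector of read counts per allele.
#' @param ref_base Reference allele at the site.
#' @param min_depth Minimum total depth for a call.
#' @param het_min_reads,het_min_frac Heterozygote evidence thresholds.
#' @return List with `code`, `a1`, `a2`, `depth`.
#' @export
call_genotype <- function(counts, ref_base, min_depth = 2L,
                          het_min_reads = 2L, het_min_frac = 0.2) {
  depth <- sum(counts)
  if (depth < min_depth || length(counts) == 0L) {
    return(list(code = "MISSING", a1 = NA_character_, a2 = NA_character_,
                depth = depth))
  }
  ord <- order(-counts, names(counts) != ref_base, names(counts))
  alleles <- names(counts)[ord]
  cnts <- as.integer(counts[ord])
  a1 <- alleles[1]
  if (length(alleles) >= 2L && cnts[2] >= het_min_reads &&
      cnts[2] / depth >= het_min_frac) {
    return(list(code = "HET", a1 = a1, a2 = alleles[2], depth = depth))
  }
  code <- if (a1 == ref_base) "HOM_REF" else "HOM_ALT"
  list(code = code, a1 = a1, a2 = a1, depth = depth)
}

# vectorised genotype calling over a long allele-count table
# counts: chrom,pos,sample_id,allele,n ; sites_ref: chrom,pos,ref
call_counts_table <- function(counts, sites_ref, samples, min_depth,
                              het_min_reads, het_min_frac) {
  full <- tidyr::expand_grid(
    dplyr::distinct(sites_ref, .data$chrom, .data$pos, .data$ref),
    sample_id = samples)
  if (nrow(counts) == 0L) {
    calls <- full
    calls$depth <- 0L
    calls$a1 <- NA_character_; calls$a2 <- NA_character_
    calls$code <- "MISSING"
    return(calls)
  }
  smry <- counts %>%
    inner_join(sites_ref, by = c("chrom", "pos")) %>%
    mutate(is_ref = .data$allele == .data$ref) %>%
    arrange(.data$chrom, .data$pos, .data$sample_id,
            dplyr::desc(.data$n), dplyr::desc(.data$is_ref),
            .data$allele) %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$sample_id) %>%
    summarise(depth = sum(.data$n),
              a1 = first(.data$allele),
              c1 = first(.data$n),
              a2 = dplyr::nth(.data$allele, 2L),
              c2 = dplyr::coalesce(dplyr::nth(.data$n, 2L), 0L),
              .groups = "drop")
  calls <- left_join(full, smry,
                     by = c("chrom", "pos", "ref", "sample_id"))
  calls$depth[is.na(calls$depth)] <- 0L
  het <- !is.na(calls$a2) & calls$c2 >= het_min_reads &
    calls$c2 / calls$depth >= het_min_frac
  missing <- calls$depth < min_depth
  calls$code <- dplyr::case_when(
    missing ~ "MISSING",
    het ~ "HET",
    calls$a1 == calls$ref ~ "HOM_REF",
    TRUE ~ "HOM_ALT")
  calls$a2 <- ifelse(het, calls$a2, calls$a1)
  calls$a1[missing] <- NA_character_
  calls$a2[missing] <- NA_character_
  select(calls, "chrom", "pos", "ref", "sample_id", "a1", "a2", "code",
         "depth")
}

#' Discover variants from a pileup
#'
#' Calls per-sample genotypes at every candidate site (a position where some
#' sample shows a non-reference allele with enough reads to possibly yield a
#' call) and emits a record for each site where at least one called genotype
#' includes a non-reference allele. Multi-allelic sites carry all observed
#' alternate alleles; SNPs and indels are typed separately.
#'
#' @param pileup A `gbs_pileup` from [build_pileup()].
#' @param reference FASTA path or `DNAStringSet`.
#' @param samples Character vector of all samples (defaults to those seen in
#'   the pileup; pass explicitly so uncovered samples appear as MISSING).
#' @param min_depth Minimum reads for any per-sample call.
#' @param het_min_reads,het_min_frac Heterozygote evidence thresholds
#'   (see [call_genotype()]).
#' @return A `gbs_variants` object.
#' @export
discover_variants <- function(pileup, reference, samples = NULL,
                              min_depth = 2L, het_min_reads = 2L,
                              het_min_frac = 0.2) {
  stopifnot(inherits(pileup, "gbs_pileup"))
  ref <- read_reference(reference)
  seqs <- setNames(as.character(ref), names(ref))
  if (is.null(samples)) {
    samples <- sort(unique(c(pileup$bases$sample_id,
                             pileup$indels$sample_id)))
  }
  cand_min <- if (min_depth >= 2L) 2L else 1L

  ## --- SNPs ---
  bases <- pileup$bases
  pos_tab <- dplyr::distinct(bases, .data$chrom, .data$pos)
  pos_tab$ref <- ref_base_at(seqs, pos_tab$chrom, pos_tab$pos)
  with_ref <- left_join(bases, pos_tab, by = c("chrom", "pos"))
  cand <- with_ref %>%
    filter(.data$base != .data$ref, .data$base %in% c("A", "C", "G", "T"),
           .data$n >= cand_min) %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$ref)
  snp_counts <- bases %>%
    inner_join(select(cand, "chrom", "pos"), by = c("chrom", "pos")) %>%
    rename(allele = "base")
  snp_calls <- call_counts_table(snp_counts, cand, samples, min_depth,
                                 het_min_reads, het_min_frac)

  ## --- indels ---
  ind <- pileup$indels
  indel_calls <- NULL
  if (nrow(ind) > 0) {
    ind_cand <- ind %>% filter(.data$n >= cand_min) %>%
      dplyr::distinct(.data$chrom, .data$pos, .data$ref)
    if (nrow(ind_cand) > 0) {
      ev <- ind %>%
        inner_join(ind_cand, by = c("chrom", "pos", "ref")) %>%
        rename(allele = "alt")
      # reference support at the anchor = spanning reads minus indel reads
      anchor_depth <- bases %>%
        inner_join(dplyr::distinct(ind_cand, .data$chrom, .data$pos),
                   by = c("chrom", "pos")) %>%
        group_by(.data$chrom, .data$pos, .data$sample_id) %>%
        summarise(dp = sum(.data$n), .groups = "drop")
      ev_tot <- ev %>%
        group_by(.data$chrom, .data$pos, .data$ref, .data$sample_id) %>%
        summarise(n_ind = sum(.data$n), .groups = "drop")
      ref_support <- ev_tot %>%
        left_join(anchor_depth, by = c("chrom", "pos", "sample_id")) %>%
        mutate(n = pmax(dplyr::coalesce(.data$dp, 0L) - .data$n_ind, 0L),
               allele = .data$ref) %>%
        select("chrom", "pos", "ref", "sample_id", "allele", "n") %>%
        filter(.data$n > 0L)
      # samples without the indel still support the reference run
      others <- anchor_depth %>%
        anti_join(ev_tot, by = c("chrom", "pos", "sample_id")) %>%
        inner_join(ind_cand, by = c("chrom", "pos")) %>%
        mutate(allele = .data$ref, n = .data$dp) %>%
        select("chrom", "pos", "ref", "sample_id", "allele", "n")
      ind_counts <- bind_rows(
        select(ev, "chrom", "pos", "ref", "sample_id", "allele", "n"),
        ref_support, others)
      indel_calls <- call_counts_table(
        select(ind_counts, -"ref") %>% dplyr::distinct(),
        ind_cand, samples, min_depth, het_min_reads, het_min_frac)
    }
  }

  assemble_variants(snp_calls, indel_calls, samples)
}

ref_base_at <- function(seqs, chrom, pos) {
  out <- character(length(chrom))
  for (nm in unique(chrom)) {
    i <- chrom == nm
    out[i] <- substring(seqs[[nm]], pos[i] + 1L, pos[i] + 1L)
  }
  out
}

# build the gbs_variants object from call tables, keeping only polymorphic
# sites (>= 1 non-reference allele among the calls)
assemble_variants <- function(snp_calls, indel_calls, samples) {
  snp_calls$type <- if (nrow(snp_calls) > 0) "SNP" else character(0)
  calls <- snp_calls
  if (!is.null(indel_calls) && nrow(indel_calls) > 0) {
    indel_calls$type <- "INDEL"
    calls <- bind_rows(calls, indel_calls)
  }
  if (nrow(calls) == 0L) {
    return(new_gbs_variants(
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), type = character(), site = character()),
      tibble(site = character(), chrom = character(), pos = integer(),
             ref = character(), sample_id = character(),
             a1 = character(), a2 = character(), code = character(),
             depth = integer()),
      samples))
  }
  calls$site <- site_key(calls$chrom, calls$pos, calls$ref)
  alts <- calls %>%
    filter(.data$code != "MISSING") %>%
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") %>%
    filter(.data$allele != .data$ref) %>%
    group_by(.data$site) %>%
    summarise(alt = paste(sort(unique(.data$allele)), collapse = ","))
  sites <- calls %>%
    dplyr::distinct(.data$site, .data$chrom, .data$pos, .data$ref,
                    .data$type) %>%
    inner_join(alts, by = "site") %>%
    select("chrom", "pos", "ref", "alt", "type", "site")
  geno <- calls %>%
    inner_join(select(sites, "site"), by = "site") %>%
    select("site", "chrom", "pos", "ref", "sample_id", "a1", "a2",
           "code", "depth") %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$sample_id)
  new_gbs_variants(sites, geno, samples)
}

#' Site and genotype filters
#'
#' Applies, in order: (1) sample-level depth masking - genotypes with depth
#' below `min_depth` are set MISSING; (2) site-level filters - sites whose
#' missing fraction exceeds `max_missing` or whose minor allele frequency
#' (over non-missing allele calls; for multi-allelic sites 1 minus the major
#' allele frequency) falls below `min_maf` are dropped. Applying the same
#' filter twice is a no-op.
#'
#' @param x A `gbs_variants` object.
#' @param min_depth Minimum per-genotype depth.
#' @param max_missing Maximum tolerated per-site missing fraction.
#' @param min_maf Minimum minor allele frequency.
#' @return Filtered `gbs_variants`; per-rule tallies in
#'   `attr(, "filter_tally")`.
#' @export
filter_variants <- function(x, min_depth = 2L, max_missing = 0.5,
                            min_maf = 0) {
  stopifnot(inherits(x, "gbs_variants"),
            min_depth >= 1L, max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5)
  geno <- x$geno
  geno$code <- as.character(geno$code)
  mask <- geno$depth < min_depth & geno$code != "MISSING"
  geno$code[mask] <- "MISSING"
  geno$a1[mask] <- NA_character_
  geno$a2[mask] <- NA_character_
  stats <- site_stats(geno)
  drop_missing <- stats$site[stats$missing_frac > max_missing]
  drop_maf <- setdiff(stats$site[stats$maf < min_maf], drop_missing)
  keep <- setdiff(x$sites$site, c(drop_missing, drop_maf))
  out <- new_gbs_variants(x$sites[x$sites$site %in% keep, , drop = FALSE],
                          geno[geno$site %in% keep, , drop = FALSE],
                          x$samples)
  attr(out, "filter_tally") <- tibble(
    rule = c("depth_masked_genotypes", "dropped_missing_fraction",
             "dropped_maf"),
    n = c(sum(mask), length(drop_missing), length(drop_maf)))
  out
}

# per-site missing fraction and minor allele frequency over non-missing calls
site_stats <- function(geno) {
  geno %>%
    group_by(.data$site) %>%
    summarise(
      n = dplyr::n(),
      n_missing = sum(.data$code == "MISSING"),
      missing_frac = .data$n_missing / .data$n,
      maf = {
        al <- c(.data$a1[.data$code != "MISSING"],
                .data$a2[.data$code != "MISSING"])
        if (length(al) == 0L) 0 else 1 - max(table(al)) / length(al)
      },
      .groups = "drop")
}

#' Heterozygote correction
#'
#' Replaces every heterozygous call with MISSING and drops sites that become
#' monomorphic (fewer than two distinct alleles among the remaining
#' non-missing calls). Never creates new non-missing calls.
#'
#' @param x A `gbs_variants` object.
#' @return Corrected `gbs_variants`.
#' @export
het_correction <- function(x) {
  stopifnot(inherits(x, "gbs_variants"))
  geno <- x$geno
  geno$code <- as.character(geno$code)
  het <- geno$code == "HET"
  geno$code[het] <- "MISSING"
  geno$a1[het] <- NA_character_
  geno$a2[het] <- NA_character_
  poly <- geno %>%
    filter(.data$code != "MISSING") %>%
    group_by(.data$site) %>%
    summarise(n_alleles = dplyr::n_distinct(c(.data$a1, .data$a2)),
              .groups = "drop")
  keep <- poly$site[poly$n_alleles >= 2L]
  new_gbs_variants(x$sites[x$sites$site %in% keep, , drop = FALSE],
                   geno[geno$site %in% keep, , drop = FALSE],
                   x$samples)
}

#' Extract a genotype matrix
#'
#' @param x A `gbs_variants` object.
#' @return Character matrix samples x sites of sorted allele pairs
#'   (`"A/G"`), `NA` for missing; column names are site keys, with site
#'   metadata in `attr(, "sites")`.
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "gbs_variants"))
  geno <- x$geno
  gt <- ifelse(is.na(geno$a1), NA_character_,
               paste(pmin(geno$a1, geno$a2), pmax(geno$a1, geno$a2),
                     sep = "/"))
  wide <- tibble(site = geno$site, sample_id = geno$sample_id, gt = gt) %>%
    tidyr::pivot_wider(names_from = "site", values_from = "gt")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m <- m[, x$sites$site, drop = FALSE]
  attr(m, "sites") <- x$sites
  m
}

#' Export genotypes in a fastPHASE-compatible layout
#'
#' Writes the simple haplotype-pair layout consumed by the external
#' fastPHASE imputation program (number of individuals, number of sites,
#' then per individual an id line and two allele lines; missing alleles as
#' `?`). Imputation itself is performed by fastPHASE outside this package.
#'
#' @param x A `gbs_variants` object (biallelic SNP sites are exported).
#' @param path Output path.
#' @export
export_fastphase <- function(x, path) {
  stopifnot(inherits(x, "gbs_variants"))
  snp <- x$sites[x$sites$type == "SNP" & !grepl(",", x$sites$alt), ,
                 drop = FALSE]
  geno <- x$geno[x$geno$site %in% snp$site, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(x$samples)), con)
  writeLines(as.character(nrow(snp)), con)
  writeLines(paste0("P ", paste(snp$pos + 1L, collapse = " ")), con)
  for (sid in x$samples) {
    g <- geno[geno$sample_id == sid, , drop = FALSE]
    g <- g[match(snp$site, g$site), , drop = FALSE]
    writeLines(paste0("# ", sid), con)
    writeLines(paste(ifelse(is.na(g$a1), "?", g$a1), collapse = ""), con)
    writeLines(paste(ifelse(is.na(g$a2), "?", g$a2), collapse = ""), con)
  }
  invisible(path)
}
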