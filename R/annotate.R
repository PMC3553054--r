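# SNP effect classification against GFF3 gene models: structural categories
# (exon/intron/UTR/splice-site/flank/intergenic) and coding effects
# (synonymous / nonsynonymous / stop gained).

SNP_CATEGORIES <- c("SPLICE_SITE", "UTR5", "UTR3", "EXON", "INTRON",
                    "UPSTREAM_5KB", "DOWNSTREAM_5KB", "INTERGENIC")
# in-gene priority when a position is claimed by several features/genes
CATEGORY_PRIORITY <- c(SPLICE_SITE = 1, UTR5 = 2, UTR3 = 2, EXON = 3,
                       INTRON = 4)

#' Parse gene models from GFF3
#'
#' Builds one gene model per gene from `gene`/`mRNA`/`exon`/`CDS` features
#' linked by `Parent` attributes. When a gene has several isoforms the one
#' with the longest total CDS is kept (ties to the lexicographically
#' smallest mRNA id). UTRs are derived as exon minus CDS, orientation-aware;
#' introns as the gaps between exons. Models whose CDS length is not a
#' multiple of 3 (or whose first CDS phase is nonzero) are flagged partial
#' and excluded from codon-effect calls. Coordinates are converted to
#' 0-based half-open.
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object: list of tibbles `genes` (`gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `mrna_id`, `cds_len`, `partial`) and
#'   `segments` (`gene_id`, `type` in exon/cds/utr5/utr3/intron, `start`,
#'   `end`, `phase`).
#' @export
parse_gff3 <- function(path) {
  if (file.size(path) == 0L ||
      !any(!startsWith(readLines(path, warn = FALSE), "#"))) {
    return(structure(list(
      genes = tibble(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer(), mrna_id = character(),
                     cds_len = integer(), partial = logical()),
      segments = tibble(gene_id = character(), type = character(),
                        start = integer(), end = integer(),
                        phase = integer())),
      class = "gene_models"))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) abort(paste0(
                   "Malformed GFF3 '", path, "': ", conditionMessage(e))))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))
  df$ID <- as.character(df$ID)
  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  feat_df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- !is.na(feat_df$Parent) & !(feat_df$Parent %in% mrna_df$ID)
  if (any(orphan)) {
    warn(paste0(sum(orphan), " exon/CDS feature(s) with unknown Parent ",
                "skipped"))
    feat_df <- feat_df[!orphan, , drop = FALSE]
  }
  gene_rows <- list(); seg_rows <- list()
  for (gi in seq_len(nrow(genes_df))) {
    g <- genes_df[gi, ]
    gene_id <- g$ID
    iso <- mrna_df[!is.na(mrna_df$Parent) & mrna_df$Parent == gene_id, ,
                   drop = FALSE]
    if (nrow(iso) == 0L) next
    cds_len_of <- vapply(iso$ID, function(mid) {
      sum(feat_df$width[feat_df$type == "CDS" & feat_df$Parent == mid])
    }, numeric(1))
    pick <- iso$ID[order(-cds_len_of, iso$ID)][1]
    ex <- feat_df[feat_df$type == "exon" & feat_df$Parent == pick, ,
                  drop = FALSE]
    cds <- feat_df[feat_df$type == "CDS" & feat_df$Parent == pick, ,
                   drop = FALSE]
    if (nrow(ex) == 0L && nrow(cds) > 0L) ex <- cds   # CDS-only annotations
    if (nrow(ex) == 0L) next
    strand <- as.character(g$strand)
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    cds_len <- sum(cds$width)
    # phase of the transcription-order first CDS segment
    first_phase <- if (nrow(cds) == 0L) NA_integer_ else {
      ph <- if (strand == "-") cds$phase[nrow(cds)] else cds$phase[1]
      if (is.na(ph)) 0L else as.integer(ph)
    }
    partial <- nrow(cds) > 0L &&
      (cds_len %% 3L != 0L || isTRUE(first_phase != 0L))
    segs <- list(tibble(gene_id = gene_id, type = "exon",
                        start = ex$start - 1L, end = ex$end,
                        phase = NA_integer_))
    if (nrow(cds) > 0L) {
      segs <- c(segs, list(tibble(
        gene_id = gene_id, type = "cds", start = cds$start - 1L,
        end = cds$end,
        phase = ifelse(is.na(cds$phase), 0L, as.integer(cds$phase)))))
      # UTRs = exon minus CDS span, split by orientation
      cds_lo <- min(cds$start) - 1L
      cds_hi <- max(cds$end)
      utr <- interval_diff(ex$start - 1L, ex$end, cds_lo, cds_hi)
      if (nrow(utr) > 0) {
        before <- utr$end <= cds_lo
        utr$type <- ifelse(
          before,
          if (strand == "-") "utr3" else "utr5",
          if (strand == "-") "utr5" else "utr3")
        segs <- c(segs, list(tibble(gene_id = gene_id, type = utr$type,
                                    start = utr$start, end = utr$end,
                                    phase = NA_integer_)))
      }
    }
    if (nrow(ex) > 1L) {
      segs <- c(segs, list(tibble(
        gene_id = gene_id, type = "intron",
        start = ex$end[-nrow(ex)], end = ex$start[-1] - 1L,
        phase = NA_integer_)))
    }
    gene_rows[[length(gene_rows) + 1L]] <- tibble(
      gene_id = gene_id, chrom = as.character(g$seqnames), strand = strand,
      start = g$start - 1L, end = g$end, mrna_id = pick,
      cds_len = as.integer(cds_len), partial = partial)
    seg_rows[[length(seg_rows) + 1L]] <- bind_rows(segs)
  }
  structure(list(genes = bind_rows(gene_rows),
                 segments = bind_rows(seg_rows)),
            class = "gene_models")
}

# parts of [starts,ends) intervals outside [lo,hi) ; all 0-based half-open
interval_diff <- function(starts, ends, lo, hi) {
  out <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (s < lo) out[[length(out) + 1L]] <- c(s, min(e, lo))
    if (e > hi) out[[length(out) + 1L]] <- c(max(s, hi), e)
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2])
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d segment(s)\n",
              nrow(x$genes), nrow(x$segments)))
  invisible(x)
}

# category of one 0-based position inside one gene model, or NA
categorise_in_gene <- function(pos, gene, segments, splice_window = 2L) {
  if (pos < gene$start || pos >= gene$end) return(NA_character_)
  seg <- segments[segments$gene_id == gene$gene_id, , drop = FALSE]
  within <- function(tp) {
    s <- seg[seg$type == tp, , drop = FALSE]
    any(pos >= s$start & pos < s$end)
  }
  introns <- seg[seg$type == "intron", , drop = FALSE]
  if (nrow(introns) > 0) {
    in_intron <- pos >= introns$start & pos < introns$end
    if (any(in_intron)) {
      d5 <- pos - introns$start[in_intron]
      d3 <- introns$end[in_intron] - 1L - pos
      if (any(d5 < splice_window | d3 < splice_window)) return("SPLICE_SITE")
      return("INTRON")
    }
  }
  if (within("utr5")) return("UTR5")
  if (within("utr3")) return("UTR3")
  if (within("exon")) return("EXON")
  # inside the gene span but in no segment (e.g. gene span wider than mRNA)
  "INTRON"
}

#' Classify variants against gene models
#'
#' Assigns each variant exactly one structural category. Inside a gene:
#' `SPLICE_SITE` within the first/last 2 intron bases, otherwise
#' `UTR5`/`UTR3`/`EXON`/`INTRON` by segment membership, with ties across
#' overlapping genes resolved by the priority SPLICE > UTR > EXON > INTRON
#' and then the lexicographically smallest gene id. Outside all genes:
#' `UPSTREAM_5KB`/`DOWNSTREAM_5KB` relative to the nearest gene's strand
#' when within `flank` bp (inclusive) of its span, else `INTERGENIC`.
#' Coding effects are computed for EXON variants overlapping the CDS of a
#' complete model (see [coding_effect()]).
#'
#' @param x A `gbs_variants` object, or a tibble with `chrom`, `pos`
#'   (0-based), `ref`, `alt`.
#' @param models A `gene_models` object from [parse_gff3()].
#' @param reference FASTA path or `DNAStringSet` (needed for coding
#'   effects; optional otherwise).
#' @param flank Flank width in bp (inclusive boundary).
#' @param splice_window Intron bases at each junction called SPLICE_SITE.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `category`, `gene_id`,
#'   `coding_effect` (NA outside CDS).
#' @export
classify_snps <- function(x, models, reference = NULL, flank = 5000L,
                          splice_window = 2L) {
  sites <- if (inherits(x, "gbs_variants")) x$sites else as_tibble(x)
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  segments <- models$segments
  seqs <- if (!is.null(reference)) {
    r <- read_reference(reference); setNames(as.character(r), names(r))
  } else NULL
  n <- nrow(sites)
  category <- character(n); gene_id <- rep(NA_character_, n)
  effect <- rep(NA_character_, n)
  warned_chroms <- character(0)
  for (i in seq_len(n)) {
    pos <- sites$pos[i]; chrom <- sites$chrom[i]
    gch <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(gch) == 0L) {
      if (!(chrom %in% warned_chroms)) {
        warn(paste0("Chromosome '", chrom, "' absent from annotation; ",
                    "variants there reported INTERGENIC"))
        warned_chroms <- c(warned_chroms, chrom)
      }
      category[i] <- "INTERGENIC"
      next
    }
    containing <- gch[pos >= gch$start & pos < gch$end, , drop = FALSE]
    if (nrow(containing) > 0L) {
      cats <- vapply(seq_len(nrow(containing)), function(k)
        categorise_in_gene(pos, containing[k, ], segments, splice_window),
        character(1))
      prio <- CATEGORY_PRIORITY[cats]
      best <- order(prio, containing$gene_id)[1]
      category[i] <- cats[best]
      gene_id[i] <- containing$gene_id[best]
      if (category[i] == "EXON" && !is.null(seqs)) {
        gmodel <- containing[best, ]
        cds <- segments[segments$gene_id == gmodel$gene_id &
                          segments$type == "cds", , drop = FALSE]
        if (nrow(cds) > 0L && any(pos >= cds$start & pos < cds$end)) {
          if (gmodel$partial) {
            warn(paste0("Variant in partial CDS of ", gmodel$gene_id,
                        "; effect NA"))
          } else {
            effect[i] <- coding_effect(
              chrom, pos, sites$ref[i], sites$alt[i], gmodel, cds, seqs)
          }
        }
      }
    } else {
      # strand-aware flank relative to the nearest gene
      dist_up <- ifelse(pos < gch$start, gch$start - pos, Inf)
      dist_dn <- ifelse(pos >= gch$end, pos - gch$end + 1L, Inf)
      d <- pmin(dist_up, dist_dn)
      nearest <- order(d, gch$gene_id)[1]
      if (d[nearest] <= flank) {
        g <- gch[nearest, ]
        before <- pos < g$start
        upstream <- (before & g$strand == "+") | (!before & g$strand == "-")
        category[i] <- if (upstream) "UPSTREAM_5KB" else "DOWNSTREAM_5KB"
        gene_id[i] <- g$gene_id
      } else {
        category[i] <- "INTERGENIC"
      }
    }
  }
  tibble(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
         alt = sites$alt, category = category, gene_id = gene_id,
         coding_effect = effect)
}

#' Coding effect of a SNP within a CDS
#'
#' Splices the CDS segments in transcription order (reverse complemented for
#' minus-strand genes), locates the affected codon, substitutes each
#' alternate allele on the coding strand and translates with the standard
#' genetic code. For multi-allelic SNPs the worst effect is reported
#' (STOP_GAINED > NONSYNONYMOUS > SYNONYMOUS).
#'
#' @param chrom,pos Variant position (0-based) on the genome.
#' @param ref_allele,alt Reference and alternate allele(s)
#'   (comma-separated string or vector).
#' @param gene One row of `gene_models$genes`.
#' @param cds CDS segment rows for that gene (0-based half-open, with
#'   `phase`).
#' @param seqs Named character vector of contig sequences.
#' @return `"SYNONYMOUS"`, `"NONSYNONYMOUS"`, `"STOP_GAINED"`, or NA for
#'   non-SNP alleles.
#' @export
coding_effect <- function(chrom, pos, ref_allele, alt, gene, cds, seqs) {
  alts <- unlist(strsplit(alt, ",", fixed = TRUE))
  alts <- alts[nchar(alts) == 1L & nchar(ref_allele) == 1L]
  if (length(alts) == 0L) return(NA_character_)
  cds <- cds[order(cds$start), , drop = FALSE]
  pieces <- substring(seqs[[chrom]], cds$start + 1L, cds$end)
  # offset of pos within the spliced, genome-ordered CDS
  cum <- c(0L, cumsum(cds$end - cds$start))
  seg_i <- which(pos >= cds$start & pos < cds$end)
  if (length(seg_i) == 0L) return(NA_character_)
  off_fwd <- cum[seg_i] + (pos - cds$start[seg_i])   # 0-based
  cds_seq <- paste(pieces, collapse = "")
  L <- nchar(cds_seq)
  minus <- gene$strand == "-"
  coding <- if (minus) revcomp(cds_seq) else cds_seq
  off <- if (minus) L - 1L - off_fwd else off_fwd
  codon_i <- off %/% 3L
  within <- off %% 3L
  ref_codon <- substr(coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(ref_codon) < 3L) return(NA_character_)
  worst <- NA_character_
  rank <- c(SYNONYMOUS = 1, NONSYNONYMOUS = 2, STOP_GAINED = 3)
  for (a in alts) {
    a_cod <- if (minus) revcomp(a) else a
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- a_cod
    ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    eff <- if (alt_aa == "*" && ref_aa != "*") "STOP_GAINED"
    else if (alt_aa == ref_aa) "SYNONYMOUS"
    else "NONSYNONYMOUS"
    if (is.na(worst) || rank[eff] > rank[worst]) worst <- eff
  }
  worst
}

#' Summarise an annotation table
#'
#' Percentages over all variants for the eight structural categories, the
#' genic/intergenic split (flank categories count as intergenic), and the
#' synonymous/nonsynonymous/stop split among CDS variants. Percentages sum
#' to 100 within each partition.
#'
#' @param ann Tibble from [classify_snps()].
#' @return Tibble `partition`, `class`, `n`, `pct`.
#' @export
annotation_summary <- function(ann) {
  if (nrow(ann) == 0L) {
    return(tibble(partition = character(), class = character(),
                  n = integer(), pct = numeric()))
  }
  n_tot <- nrow(ann)
  cat_tab <- tibble(partition = "category",
                    class = SNP_CATEGORIES) %>%
    left_join(dplyr::count(ann, class = .data$category), by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L), pct = 100 * .data$n / n_tot)
  genic_classes <- c("EXON", "INTRON", "UTR5", "UTR3", "SPLICE_SITE")
  genic_n <- sum(ann$category %in% genic_classes)
  split_tab <- tibble(partition = "genic_split",
                      class = c("GENIC", "INTERGENIC"),
                      n = c(genic_n, n_tot - genic_n)) %>%
    mutate(pct = 100 * .data$n / n_tot)
  cds <- ann[!is.na(ann$coding_effect), , drop = FALSE]
  coding_tab <- if (nrow(cds) > 0) {
    tibble(partition = "coding_split",
           class = c("SYNONYMOUS", "NONSYNONYMOUS", "STOP_GAINED")) %>%
      left_join(dplyr::count(cds, class = .data$coding_effect),
                by = "class") %>%
      mutate(n = dplyr::coalesce(.data$n, 0L),
             pct = 100 * .data$n / nrow(cds))
  } else NULL
  bind_rows(cat_tab, split_tab, coding_tab)
}

#' Attach annotations to a variant set
#'
#' Adds an `annotation` column (`category|gene|effect`) to `x$sites`, which
#' [write_vcf()] serialises as the `ANN` INFO key.
#'
#' @param x A `gbs_variants` object.
#' @param ann Tibble from [classify_snps()] for the same sites.
#' @return The annotated `gbs_variants`.
#' @export
add_annotation <- function(x, ann) {
  stopifnot(inherits(x, "gbs_variants"))
  key <- site_key(ann$chrom, ann$pos, ann$ref)
  lab <- paste(ann$category,
               ifelse(is.na(ann$gene_id), "", ann$gene_id),
               ifelse(is.na(ann$coding_effect), "", ann$coding_effect),
               sep = "|")
  x$sites$annotation <- lab[match(x$sites$site, key)]
  x
}
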