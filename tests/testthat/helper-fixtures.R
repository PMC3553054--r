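# Shared fixtures and independent oracles, built in code at test time.

# brute-force cut-site oracle: expand the IUPAC pattern into its explicit
# sequence set and scan every substring
oracle_cut_sites <- function(seq, enzyme) {
  enzyme <- get_enzyme(enzyme)
  pats <- iupac_expand(enzyme$recognition)
  P <- nchar(enzyme$recognition)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < P) return(integer(0))
  starts <- which(vapply(seq_len(n - P + 1L), function(i)
    substr(seq, i, i + P - 1L) %in% pats, logical(1)))
  sort(unique(starts - 1L + enzyme$cut_offset))
}

# random sequence helper
rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

dna_ref <- function(seqs) {
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- names(seqs)
  ref
}

# a two-gene GFF3 fixture on a 20 kb chromosome:
#   geneP (+): exons 1001-1120 / 1301-1420 / 1601-1720, CDS 1051-1120 /
#              1301-1420 / 1601-1660 (230 bases... adjusted to 240 for
#              complete codons: CDS 1051-1120 (70) + 1301-1420 (120) +
#              1601-1650 (50) = 240)
#   geneM (-): mirrored structure on the minus strand at 9001-9720
write_gff_fixture <- function(path) {
  lines <- c(
    "##gff-version 3",
    "chr1\tfix\tgene\t1001\t1720\t.\t+\t.\tID=geneP",
    "chr1\tfix\tmRNA\t1001\t1720\t.\t+\t.\tID=geneP.1;Parent=geneP",
    "chr1\tfix\texon\t1001\t1120\t.\t+\t.\tID=geneP.e1;Parent=geneP.1",
    "chr1\tfix\texon\t1301\t1420\t.\t+\t.\tID=geneP.e2;Parent=geneP.1",
    "chr1\tfix\texon\t1601\t1720\t.\t+\t.\tID=geneP.e3;Parent=geneP.1",
    "chr1\tfix\tCDS\t1051\t1120\t.\t+\t0\tID=geneP.c1;Parent=geneP.1",
    "chr1\tfix\tCDS\t1301\t1420\t.\t+\t2\tID=geneP.c2;Parent=geneP.1",
    "chr1\tfix\tCDS\t1601\t1650\t.\t+\t2\tID=geneP.c3;Parent=geneP.1",
    "chr1\tfix\tgene\t9001\t9720\t.\t-\t.\tID=geneM",
    "chr1\tfix\tmRNA\t9001\t9720\t.\t-\t.\tID=geneM.1;Parent=geneM",
    "chr1\tfix\texon\t9001\t9120\t.\t-\t.\tID=geneM.e1;Parent=geneM.1",
    "chr1\tfix\texon\t9301\t9420\t.\t-\t.\tID=geneM.e2;Parent=geneM.1",
    "chr1\tfix\texon\t9601\t9720\t.\t-\t.\tID=geneM.e3;Parent=geneM.1",
    "chr1\tfix\tCDS\t9073\t9120\t.\t-\t0\tID=geneM.c1;Parent=geneM.1",
    "chr1\tfix\tCDS\t9301\t9420\t.\t-\t0\tID=geneM.c2;Parent=geneM.1",
    "chr1\tfix\tCDS\t9601\t9672\t.\t-\t0\tID=geneM.c3;Parent=geneM.1")
  writeLines(lines, path)
  path
}

fixture_reference <- function(seed = 424L) {
  dna_ref(list(chr1 = rand_seq(20000L, seed = seed)))
}

# naive classification oracle: scan every segment of every gene directly
oracle_classify <- function(pos, chrom, models, flank = 5000L,
                            splice_window = 2L) {
  genes <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  seg <- models$segments
  best_cat <- NA_character_; best_gene <- NA_character_; best_p <- Inf
  prio <- c(SPLICE_SITE = 1, UTR5 = 2, UTR3 = 2, EXON = 3, INTRON = 4)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (pos < g$start || pos >= g$end) next
    s <- seg[seg$gene_id == g$gene_id, , drop = FALSE]
    memb <- function(tp) {
      rows <- s[s$type == tp, , drop = FALSE]
      any(pos >= rows$start & pos < rows$end)
    }
    cat <- NULL
    introns <- s[s$type == "intron", , drop = FALSE]
    for (ii in seq_len(nrow(introns))) {
      if (pos >= introns$start[ii] && pos < introns$end[ii]) {
        near5 <- pos - introns$start[ii] < splice_window
        near3 <- introns$end[ii] - 1L - pos < splice_window
        cat <- if (near5 || near3) "SPLICE_SITE" else "INTRON"
      }
    }
    if (is.null(cat)) {
      cat <- if (memb("utr5")) "UTR5" else if (memb("utr3")) "UTR3"
      else if (memb("exon")) "EXON" else "INTRON"
    }
    p <- prio[[cat]]
    if (p < best_p || (p == best_p && g$gene_id < best_gene)) {
      best_cat <- cat; best_gene <- g$gene_id; best_p <- p
    }
  }
  if (!is.na(best_cat)) return(list(category = best_cat, gene = best_gene))
  if (nrow(genes) == 0L) return(list(category = "INTERGENIC", gene = NA))
  d_up <- ifelse(pos < genes$start, genes$start - pos, Inf)
  d_dn <- ifelse(pos >= genes$end, pos - genes$end + 1L, Inf)
  d <- pmin(d_up, d_dn)
  k <- order(d, genes$gene_id)[1]
  if (d[k] > flank) return(list(category = "INTERGENIC", gene = NA))
  g <- genes[k, ]
  before <- pos < g$start
  up <- (before && g$strand == "+") || (!before && g$strand == "-")
  list(category = if (up) "UPSTREAM_5KB" else "DOWNSTREAM_5KB",
       gene = g$gene_id)
}

# full-translation oracle for coding effects: rebuild the whole CDS with and
# without the variant and diff the protein sequences
oracle_coding_effect <- function(chrom, pos, ref_allele, alt, gene, cds,
                                 seqs) {
  build_cds <- function(genome) {
    cds <- cds[order(cds$start), , drop = FALSE]
    s <- paste(substring(genome, cds$start + 1L, cds$end), collapse = "")
    if (gene$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  genome <- seqs[[chrom]]
  mut <- genome
  substr(mut, pos + 1L, pos + 1L) <- alt
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }
  p_ref <- tr(build_cds(genome))
  p_alt <- tr(build_cds(mut))
  if (p_ref == p_alt) return("SYNONYMOUS")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  if (substr(p_alt, d, d) == "*") "STOP_GAINED" else "NONSYNONYMOUS"
}
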