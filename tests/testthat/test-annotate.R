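test_that("GFF3 parsing builds gene models with introns, UTRs and phases", {
  gff <- write_gff_fixture(tempfile(fileext = ".gff3"))
  gm <- parse_gff3(gff)
  expect_equal(nrow(gm$genes), 2L)
  expect_false(any(gm$genes$partial))
  segP <- gm$segments[gm$segments$gene_id == "geneP", ]
  expect_equal(sum(segP$type == "intron"), 2L)
  expect_equal(sum(segP$type == "exon"), 3L)
  expect_equal(gm$genes$cds_len, c(240L, 240L))
  # UTRs derived orientation-aware: minus-strand gene has its 5' UTR at the
  # high-coordinate end
  segM <- gm$segments[gm$segments$gene_id == "geneM", ]
  u5 <- segM[segM$type == "utr5", ]
  u3 <- segM[segM$type == "utr3", ]
  expect_true(min(u5$start) > max(u3$end))
  # gene with no CDS: exonic variants get no coding effect
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t200\t.\t+\t.\tID=nc1",
               "chr1\tx\tmRNA\t100\t200\t.\t+\t.\tID=nc1.1;Parent=nc1",
               "chr1\tx\texon\t100\t200\t.\t+\t.\tID=nc1.e;Parent=nc1.1"),
             gff2)
  gm2 <- parse_gff3(gff2)
  ann <- classify_snps(tibble::tibble(chrom = "chr1", pos = 150L,
                                      ref = "A", alt = "G"),
                       gm2, reference = fixture_reference())
  expect_equal(ann$category, "EXON")
  expect_true(is.na(ann$coding_effect))
  # empty file -> empty model set
  gff3 <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff3)
  expect_equal(nrow(parse_gff3(gff3)$genes), 0L)
})

test_that("structural categories follow the splice window and flank rules", {
  gm <- parse_gff3(write_gff_fixture(tempfile(fileext = ".gff3")))
  ref <- fixture_reference()
  # geneP: intron1 is [1120, 1300) 0-based
  probes <- c(1120L, 1121L, 1122L,        # 1st/2nd/3rd intron base
              1299L, 1297L,               # last, third-to-last intron base
              1030L, 1080L, 1690L,        # utr5 / cds exon / utr3 (geneP)
              999L)                       # 1 bp upstream of geneP
  ann <- classify_snps(
    tibble::tibble(chrom = "chr1", pos = probes,
                   ref = "A", alt = "G"), gm, reference = ref)
  expect_equal(ann$category[1:2], c("SPLICE_SITE", "SPLICE_SITE"))
  expect_equal(ann$category[3], "INTRON")
  expect_equal(ann$category[4:5], c("SPLICE_SITE", "INTRON"))
  expect_equal(ann$category[6:9],
               c("UTR5", "EXON", "UTR3", "UPSTREAM_5KB"))
  # flank boundary: inclusive at exactly 5000
  up <- classify_snps(tibble::tibble(
    chrom = "chr1", pos = c(1000L - 4999L, 9720L + 4999L),
    ref = "A", alt = "G"), gm)
  expect_equal(up$category[1], "UPSTREAM_5KB")   # 5' of + strand geneP
  # 3' of minus-strand geneM's high-coordinate end = its 5' side
  expect_equal(up$category[2], "UPSTREAM_5KB")
  # far from any gene -> intergenic (no other gene within 5 kb)
  deep <- classify_snps(tibble::tibble(chrom = "chr1", pos = 19900L,
                                       ref = "A", alt = "G"), gm)
  expect_equal(deep$category, "INTERGENIC")
  # unknown chromosome -> intergenic with warning
  expect_warning(
    offc <- classify_snps(tibble::tibble(chrom = "chrZ", pos = 5L,
                                         ref = "A", alt = "G"), gm),
    "absent")
  expect_equal(offc$category, "INTERGENIC")
})

test_that("categories agree with the naive full-scan oracle", {
  gm <- parse_gff3(write_gff_fixture(tempfile(fileext = ".gff3")))
  set.seed(7)
  pos <- sort(unique(c(sample(0:19999, 400),
                       1115:1130, 9110:9130, 995:1005, 5995:6010)))
  ann <- classify_snps(tibble::tibble(chrom = "chr1", pos = pos,
                                      ref = "A", alt = "G"), gm)
  oracle <- vapply(pos, function(p)
    oracle_classify(p, "chr1", gm)$category, character(1))
  expect_equal(ann$category, oracle)
})

test_that("coding effects match hand-worked codons and the translation oracle", {
  gm <- parse_gff3(write_gff_fixture(tempfile(fileext = ".gff3")))
  ref <- fixture_reference()
  seqs <- stats::setNames(as.character(ref), names(ref))
  # third-position GCT -> GCC is synonymous (Ala -> Ala): build by editing
  # the reference so the first geneP codon is GCT, then substitute T -> C
  s <- seqs[["chr1"]]
  substr(s, 1051, 1053) <- "GCT"
  ref2 <- dna_ref(list(chr1 = s))
  ann <- classify_snps(tibble::tibble(chrom = "chr1", pos = 1052L,
                                      ref = "T", alt = "C"),
                       gm, reference = ref2)
  expect_equal(ann$coding_effect, "SYNONYMOUS")
  # TGC -> TGA gains a stop
  substr(s, 1051, 1053) <- "TGC"
  ref3 <- dna_ref(list(chr1 = s))
  ann2 <- classify_snps(tibble::tibble(chrom = "chr1", pos = 1052L,
                                       ref = "C", alt = "A"),
                        gm, reference = ref3)
  expect_equal(ann2$coding_effect, "STOP_GAINED")
  # every CDS position in both genes agrees with the full-translation oracle
  cds_pos <- integer(0)
  for (g in c("geneP", "geneM")) {
    seg <- gm$segments[gm$segments$gene_id == g &
                         gm$segments$type == "cds", ]
    cds_pos <- c(cds_pos, unlist(Map(function(s0, e0) s0:(e0 - 1L),
                                     seg$start, seg$end)))
  }
  set.seed(12)
  cds_pos <- sample(cds_pos, 60)
  for (p in cds_pos) {
    rb <- substr(seqs[["chr1"]], p + 1, p + 1)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    ann_p <- classify_snps(tibble::tibble(chrom = "chr1", pos = p,
                                          ref = rb, alt = ab),
                           gm, reference = ref)
    gid <- ann_p$gene_id
    gene <- gm$genes[gm$genes$gene_id == gid, ]
    cds <- gm$segments[gm$segments$gene_id == gid &
                         gm$segments$type == "cds", ]
    expect_equal(ann_p$coding_effect,
                 oracle_coding_effect("chr1", p, rb, ab, gene, cds, seqs),
                 label = paste("pos", p))
  }
})

test_that("annotation is invariant under reverse-complementing the genome", {
  gm <- parse_gff3(write_gff_fixture(tempfile(fileext = ".gff3")))
  ref <- fixture_reference()
  L <- Biostrings::width(ref)[1]
  # flip: position p -> L-1-p, strands swap, exon/CDS coords mirror
  flip_gff <- tempfile(fileext = ".gff3")
  src <- readLines(write_gff_fixture(tempfile(fileext = ".gff3")))
  flipped <- vapply(src, function(ln) {
    if (startsWith(ln, "#")) return(ln)
    f <- strsplit(ln, "\t")[[1]]
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(L - e + 1L); f[5] <- as.character(L - s + 1L)
    f[7] <- if (f[7] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(flipped, flip_gff)
  gm_flip <- parse_gff3(flip_gff)
  ref_flip <- dna_ref(list(chr1 = as.character(
    Biostrings::reverseComplement(ref[[1]]))))
  seqs <- as.character(ref[[1]])
  set.seed(3)
  pos <- sample(0:(L - 1L), 250)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rb <- vapply(pos, function(p) substr(seqs, p + 1, p + 1), character(1))
  ab <- vapply(rb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  ann <- classify_snps(tibble::tibble(chrom = "chr1", pos = pos, ref = rb,
                                      alt = unname(ab)),
                       gm, reference = ref)
  ann_f <- classify_snps(tibble::tibble(chrom = "chr1", pos = L - 1L - pos,
                                        ref = unname(comp[rb]),
                                        alt = unname(comp[ab])),
                         gm_flip, reference = ref_flip)
  expect_equal(ann_f$category, ann$category)
  expect_equal(ann_f$coding_effect, ann$coding_effect)
})

test_that("annotation summary partitions sum to 100", {
  ann_all_inter <- tibble::tibble(chrom = "c", pos = 1:10, ref = "A",
                                  alt = "G", category = "INTERGENIC",
                                  gene_id = NA, coding_effect = NA)
  s <- annotation_summary(ann_all_inter)
  expect_equal(s$pct[s$partition == "category" &
                       s$class == "INTERGENIC"], 100)
  ann_mix <- tibble::tibble(
    chrom = "c", pos = 1:4, ref = "A", alt = "G", category = "EXON",
    gene_id = "g",
    coding_effect = c("SYNONYMOUS", "SYNONYMOUS",
                      "NONSYNONYMOUS", "NONSYNONYMOUS"))
  s2 <- annotation_summary(ann_mix)
  cs <- s2[s2$partition == "coding_split", ]
  expect_equal(cs$pct[cs$class == "SYNONYMOUS"], 50)
  expect_equal(cs$pct[cs$class == "NONSYNONYMOUS"], 50)
  gs <- s2[s2$partition == "genic_split", ]
  expect_equal(sum(gs$pct), 100)
  expect_equal(nrow(annotation_summary(ann_mix[0, ])), 0L)
})
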