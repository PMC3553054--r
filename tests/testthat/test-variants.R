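toy_ref <- function() dna_ref(list(c1 = rand_seq(200L, seed = 500)))

test_that("pileup counts bases per sample and walks cigars", {
  ref <- toy_ref()
  aln <- tibble::tibble(
    read_id = c("r1", "r2"), sample_id = c("sA", "sB"),
    chrom = "c1", pos = c(10L, 10L), strand = "+",
    cigar = "20M",
    seq = substr(as.character(ref[[1]]), 11, 30), nm = 0L)
  pl <- build_pileup(aln, ref)
  at10 <- pl$bases[pl$bases$pos == 10, ]
  expect_equal(nrow(at10), 2L)          # two independent per-sample maps
  expect_equal(sort(unique(at10$sample_id)), c("sA", "sB"))
  expect_true(all(at10$n == 1L))
  # 5M2D5M: deletion anchored at the 5th matched position
  refseq <- as.character(ref[[1]])
  aln2 <- tibble::tibble(
    read_id = "d1", sample_id = "sA", chrom = "c1", pos = 50L,
    strand = "+", cigar = "5M2D5M",
    seq = paste0(substr(refseq, 51, 55), substr(refseq, 58, 62)), nm = 0L)
  pl2 <- build_pileup(aln2, ref)
  expect_equal(nrow(pl2$indels), 1L)
  expect_equal(pl2$indels$pos, 54L)     # 0-based anchor = 5th matched base
  expect_equal(pl2$indels$ref, substr(refseq, 55, 57))
  expect_equal(pl2$indels$alt, substr(refseq, 55, 55))
  # alignment beyond contig bounds is a hard error
  aln3 <- aln
  aln3$pos <- 190L
  expect_error(build_pileup(aln3, ref), "bounds")
})

test_that("genotype calling applies depth, stray-read and het rules", {
  call <- function(counts, ref = "A")
    call_genotype(counts, ref_base = ref)
  expect_equal(call(c(A = 5))$code, "HOM_REF")
  expect_equal(call(c(A = 5))$depth, 5)
  # a single read never yields a call
  expect_equal(call(c(A = 1))$code, "MISSING")
  # balanced support -> heterozygote
  het <- call(c(A = 3, G = 3))
  expect_equal(het$code, "HET")
  expect_setequal(c(het$a1, het$a2), c("A", "G"))
  # one stray read of a second allele is ignored
  expect_equal(call(c(G = 7, A = 1))$code, "HOM_ALT")
  # minor fraction below 0.2 is not a het
  expect_equal(call(c(A = 20, G = 2))$code, "HOM_REF")
  # count tie broken toward the reference
  expect_equal(call(c(G = 1, A = 1), ref = "A")$code, "HOM_REF")
})

test_that("variant discovery emits only polymorphic sites", {
  ref <- toy_ref()
  refseq <- as.character(ref[[1]])
  mk_aln <- function(id, sample, pos, seq) tibble::tibble(
    read_id = id, sample_id = sample, chrom = "c1", pos = pos,
    strand = "+", cigar = paste0(nchar(seq), "M"), seq = seq, nm = 0L)
  # all-reference coverage -> no record
  aln <- dplyr::bind_rows(
    mk_aln("a1", "s1", 10L, substr(refseq, 11, 40)),
    mk_aln("a2", "s1", 10L, substr(refseq, 11, 40)),
    mk_aln("b1", "s2", 10L, substr(refseq, 11, 40)),
    mk_aln("b2", "s2", 10L, substr(refseq, 11, 40)))
  v0 <- discover_variants(build_pileup(aln, ref), ref,
                          samples = c("s1", "s2"))
  expect_equal(nrow(v0$sites), 0L)
  # one sample homozygous alternate at position 20 -> biallelic SNP record
  mut <- substr(refseq, 11, 40)
  old <- substr(mut, 10, 10)
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(mut, 10, 10) <- alt
  aln2 <- dplyr::bind_rows(
    mk_aln("a1", "s1", 10L, mut), mk_aln("a2", "s1", 10L, mut),
    mk_aln("b1", "s2", 10L, substr(refseq, 11, 40)),
    mk_aln("b2", "s2", 10L, substr(refseq, 11, 40)))
  v1 <- discover_variants(build_pileup(aln2, ref), ref,
                          samples = c("s1", "s2"))
  expect_equal(nrow(v1$sites), 1L)
  expect_equal(v1$sites$pos, 19L)
  expect_equal(v1$sites$ref, old)
  expect_equal(v1$sites$alt, alt)
  expect_equal(v1$sites$type, "SNP")
  g <- v1$geno
  expect_equal(as.character(g$code[g$sample_id == "s1"]), "HOM_ALT")
  expect_equal(as.character(g$code[g$sample_id == "s2"]), "HOM_REF")
})

test_that("filters mask low depth, drop missing-heavy and low-MAF sites", {
  mk <- function(codes, a_ref = "A", a_alt = "G", depths = NULL) {
    n <- length(codes)
    if (is.null(depths)) depths <- rep(5L, n)
    a1 <- ifelse(codes == "HOM_ALT" | codes == "HET", a_alt, a_ref)
    a2 <- ifelse(codes == "HOM_ALT", a_alt, a_ref)
    a1[codes == "MISSING"] <- NA; a2[codes == "MISSING"] <- NA
    sites <- tibble::tibble(chrom = "c1", pos = 5L, ref = a_ref,
                            alt = a_alt, type = "SNP",
                            site = paste0("c1:5:", a_ref))
    geno <- tibble::tibble(site = sites$site, chrom = "c1", pos = 5L,
                           ref = a_ref,
                           sample_id = sprintf("s%02d", seq_len(n)),
                           a1 = a1, a2 = a2, code = codes, depth = depths)
    gbskit:::new_gbs_variants(sites, geno, geno$sample_id)
  }
  # 8/8 missing -> dropped under any max_missing < 1
  v_all_missing <- mk(rep("MISSING", 8))
  expect_equal(nrow(filter_variants(v_all_missing,
                                    max_missing = 0.99)$sites), 0L)
  # MAF arithmetic: alleles 15 A vs 1 G over 8 diploid samples
  v_maf <- mk(c("HET", rep("HOM_REF", 7)))
  expect_equal(nrow(filter_variants(v_maf, min_maf = 0.1)$sites), 0L)
  expect_equal(nrow(filter_variants(v_maf, min_maf = 0)$sites), 1L)
  # permissive parameters are the identity; filtering is idempotent
  v <- mk(c("HOM_ALT", "HET", "HOM_REF", "MISSING"),
          depths = c(5L, 5L, 1L, 0L))
  f1 <- filter_variants(v, min_depth = 2, max_missing = 0.9, min_maf = 0)
  f2 <- filter_variants(f1, min_depth = 2, max_missing = 0.9, min_maf = 0)
  expect_equal(f1$geno, f2$geno)
  # depth masking precedes site filters
  expect_equal(as.character(
    f1$geno$code[f1$geno$sample_id == "s03"]), "MISSING")
  tal <- attr(f1, "filter_tally")
  expect_equal(tal$n[tal$rule == "depth_masked_genotypes"], 1L)
})

test_that("heterozygote correction removes het calls and monomorphic sites", {
  mk3 <- function(codes) {
    sites <- tibble::tibble(chrom = "c1", pos = 5L, ref = "A", alt = "G",
                            type = "SNP", site = "c1:5:A")
    a1 <- c(HOM_REF = "A", HET = "G", HOM_ALT = "G")[codes]
    a2 <- c(HOM_REF = "A", HET = "A", HOM_ALT = "G")[codes]
    geno <- tibble::tibble(site = "c1:5:A", chrom = "c1", pos = 5L,
                           ref = "A",
                           sample_id = sprintf("s%d", seq_along(codes)),
                           a1 = unname(a1), a2 = unname(a2), code = codes,
                           depth = 5L)
    gbskit:::new_gbs_variants(sites, geno, geno$sample_id)
  }
  v <- mk3(c("HOM_REF", "HET", "HOM_ALT"))
  hc <- het_correction(v)
  expect_equal(as.character(hc$geno$code),
               c("HOM_REF", "MISSING", "HOM_ALT"))
  # no hets -> unchanged
  v2 <- mk3(c("HOM_REF", "HOM_ALT", "HOM_ALT"))
  expect_equal(het_correction(v2)$geno$code, v2$geno$code)
  # monomorphic after correction -> dropped
  v3 <- mk3(c("HOM_REF", "HET", "HOM_REF"))
  expect_equal(nrow(het_correction(v3)$sites), 0L)
  # never creates non-missing calls
  expect_true(all(as.character(hc$geno$code) %in%
                    c(as.character(v$geno$code), "MISSING")))
})

test_that("genotype-category fractions sum to one", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 8000L, n_samples = 4L,
                    n_snps = 20L, n_indels = 0L, het_fraction = 0.3,
                    mean_depth = 6, seed = 202L)
  sim <- simulate_gbs(cfg)
  g <- glance(sim$truth)
  expect_equal(g$frac_hom_ref + g$frac_het + g$frac_hom_alt +
                 g$frac_missing, 1)
  expect_gt(g$frac_het, 0)
})

test_that("VCF writing and reading round-trip all modelled fields", {
  cfg <- sim_config(n_contigs = 2L, contig_length = 8000L, n_samples = 4L,
                    n_snps = 30L, n_indels = 3L, mean_depth = 6,
                    seed = 91L)
  sim <- simulate_gbs(cfg)
  proc <- process_fastq(sim$reads, sim$sheet, "ApeKI")
  sam <- tempfile(fileext = ".sam")
  write_truth_sam(sim, sam)
  aln <- import_sam(sam, sim$reference)
  aln$sample_id <- proc$reads$sample_id[match(aln$read_id, proc$reads$id)]
  v <- discover_variants(build_pileup(aln, sim$reference), sim$reference,
                         samples = sim$sheet$sample_id)
  p <- tempfile(fileext = ".vcf")
  write_vcf(v, sim$reference, p)
  rt <- read_vcf(p)
  expect_equal(rt$sites[, c("chrom", "pos", "ref", "alt", "type", "site")],
               v$sites[, c("chrom", "pos", "ref", "alt", "type", "site")])
  expect_equal(unname(genotype_matrix(rt)), unname(genotype_matrix(v)))
  expect_equal(rt$geno$depth, v$geno$depth)
  expect_equal(as.character(rt$geno$code), as.character(v$geno$code))
  # empty set -> header-only VCF
  p2 <- tempfile(fileext = ".vcf")
  empty <- gbskit:::assemble_variants(
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   sample_id = character(), a1 = character(),
                   a2 = character(), code = character(), depth = integer()),
    NULL, sim$sheet$sample_id)
  write_vcf(empty, sim$reference, p2)
  expect_true(all(startsWith(readLines(p2), "#")))
  # het serialised as 0/1
  het_line <- grep("0/1", readLines(p), value = TRUE)
  if (any(as.character(v$geno$code) == "HET")) {
    expect_gt(length(het_line), 0L)
  }
})

test_that("fastPHASE export writes the expected layout", {
  sites <- tibble::tibble(chrom = "c1", pos = c(5L, 9L), ref = c("A", "C"),
                          alt = c("G", "T"), type = "SNP",
                          site = c("c1:5:A", "c1:9:C"))
  geno <- tidyr::expand_grid(site = sites$site,
                             sample_id = c("s1", "s2")) |>
    dplyr::left_join(sites, by = "site") |>
    dplyr::mutate(a1 = ref, a2 = ref, code = "HOM_REF", depth = 4L) |>
    dplyr::select(site, chrom, pos, ref, sample_id, a1, a2, code, depth)
  geno$a1[1] <- NA; geno$a2[1] <- NA; geno$code[1] <- "MISSING"
  v <- gbskit:::new_gbs_variants(sites, geno, c("s1", "s2"))
  p <- tempfile()
  export_fastphase(v, p)
  lines <- readLines(p)
  expect_equal(lines[1], "2")
  expect_equal(lines[2], "2")
  expect_true(startsWith(lines[3], "P "))
  expect_equal(substr(lines[5], 1, 1), "?")
})
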