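test_that("simulation is fully reproducible from its seed", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 6000L, n_samples = 3L,
                    n_snps = 12L, n_indels = 2L, mean_depth = 4,
                    seed = 61L)
  s1 <- simulate_gbs(cfg)
  s2 <- simulate_gbs(cfg)
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$geno, s2$truth$geno)
  # different seed -> different data
  s3 <- simulate_gbs(sim_config(n_contigs = 1L, contig_length = 6000L,
                                n_samples = 3L, n_snps = 12L,
                                n_indels = 2L, mean_depth = 4, seed = 62L))
  expect_false(identical(as.character(s1$reference),
                         as.character(s3$reference)))
})

test_that("planted sites are recovered exactly by digestion", {
  for (seed in c(5L, 6L)) {
    cfg <- sim_config(n_contigs = 2L, contig_length = 7000L,
                      n_samples = 2L, n_snps = 5L, n_indels = 0L,
                      seed = seed)
    ref <- simulate_reference(cfg)
    planted <- attr(ref, "planted_sites")
    for (nm in names(ref)) {
      cuts <- find_cut_sites(as.character(ref[[nm]]), cfg$enzyme)
      expect_identical(cuts,
                       sort(planted$pos[planted$chrom == nm] +
                              cfg$enzyme$cut_offset))
    }
  }
  # infeasible density is a configuration error
  expect_error(sim_config(spacing = c(6L, 10L), seed = 1L), "Infeasible")
})

test_that("truth variants respect placement and class constraints", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 10000L, n_samples = 4L,
                    n_snps = 30L, n_indels = 2L, het_fraction = 0,
                    seed = 71L)
  ref <- simulate_reference(cfg)
  truth <- simulate_genotypes(cfg, ref)
  sites <- truth$variants$sites
  expect_equal(sum(sites$type == "SNP"), 30L)
  expect_equal(sum(sites$type == "INDEL"), 2L)
  # no heterozygous truth genotypes when het_fraction = 0
  expect_false(any(truth$variants$geno$code == "HET"))
  # every site polymorphic
  poly <- truth$variants$geno |>
    dplyr::group_by(site) |>
    dplyr::summarise(n_alt = sum(a1 != ref | a2 != ref))
  expect_true(all(poly$n_alt >= 1))
  # variant positions stay clear of planted recognition sites
  planted <- attr(ref, "planted_sites")
  P <- nchar(cfg$enzyme$recognition)
  for (i in seq_len(nrow(sites))) {
    near <- planted$pos[planted$chrom == sites$chrom[i]]
    expect_false(any(sites$pos[i] >= near & sites$pos[i] < near + P))
  }
  # het_fraction > 0 produces hets
  cfg_h <- sim_config(n_contigs = 1L, contig_length = 10000L,
                      n_samples = 4L, n_snps = 30L, n_indels = 0L,
                      het_fraction = 0.5, seed = 72L)
  truth_h <- simulate_genotypes(cfg_h, simulate_reference(cfg_h))
  expect_gt(sum(truth_h$variants$geno$code == "HET"), 0L)
})

test_that("reads follow the barcode + remnant layout and read-through rule", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 8000L, n_samples = 3L,
                    n_snps = 10L, n_indels = 0L, mean_depth = 3,
                    spacing = c(40L, 90L),   # short fragments: read-through
                    seed = 81L)
  sim <- simulate_gbs(cfg)
  bc <- stats::setNames(sim$sheet$barcode, sim$sheet$sample_id)
  pv <- sim$provenance
  reads <- sim$reads$seq[match(pv$read_id, sim$reads$id)]
  expect_true(all(startsWith(reads, bc[pv$sample_id])))
  after <- substr(reads, nchar(bc[pv$sample_id]) + 1L, nchar(reads))
  expect_true(all(grepl("^C[AT]GC", after)))
  expect_true(all(nchar(reads) == cfg$read_length))
  # fragments shorter than the read leave distal remnant + adapter in reads
  # (pick reads with enough adapter fill for the motif to be visible)
  glen <- cfg$read_length - nchar(bc[pv$sample_id])
  short <- pv[pv$genomic_len <= glen - 9L, ]
  expect_gt(nrow(short), 0L)
  short_reads <- sim$reads$seq[match(short$read_id, sim$reads$id)]
  expect_true(all(grepl("C[AT]GCAGATCGG", short_reads)))
  # error rate 0: every read's genomic part matches its template exactly
  proc <- process_fastq(sim$reads, sim$sheet, "ApeKI")
  expect_equal(nrow(proc$unassigned), 0L)
})

test_that("read counts scale with depth and selective bases boost depth", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 20000L, n_samples = 4L,
                    n_snps = 40L, n_indels = 0L, mean_depth = 4,
                    seed = 5L)
  ref <- simulate_reference(cfg)
  truth <- simulate_genotypes(cfg, ref)
  std <- simulate_reads(cfg, truth)
  exp_reads <- nrow(truth$internal) * cfg$n_samples * cfg$mean_depth
  expect_gt(nrow(std$reads), exp_reads * 0.85)
  expect_lt(nrow(std$reads), exp_reads * 1.15)
  # selective = "" is the identity protocol
  expect_identical(simulate_reads(cfg, truth)$reads, std$reads)
  # selective subsetting holds the budget while multiplying per-fragment
  # depth by about n_total / n_retained
  sel <- simulate_reads(cfg, truth, selective = "AC")
  n_ret <- nrow(selective_subset(truth$internal, "AC"))
  expect_equal(sel$mean_depth_used,
               cfg$mean_depth * nrow(truth$internal) / n_ret)
  expect_gt(sel$mean_depth_used, std$mean_depth_used)
  # empirical per-fragment depth matches the rescaled mean within noise
  per_frag <- sel$provenance |>
    dplyr::count(frag_start, sample_id)
  expect_gt(mean(per_frag$n), sel$mean_depth_used * 0.75)
  expect_lt(mean(per_frag$n), sel$mean_depth_used * 1.25)
  # SNPs on unselected fragments receive zero reads
  sel_frags <- selective_subset(truth$internal, "AC")
  covered <- unique(sel$provenance$frag_start)
  expect_true(all(covered %in% sel_frags$start))
})

test_that("substitution errors appear at the configured rate", {
  set.seed(99)
  seqs <- rep(strrep("A", 100L), 300L)
  mut <- gbskit:::add_substitution_errors(seqs, 0.02)
  frac <- sum(vapply(mut, function(s)
    sum(charToRaw(s) != charToRaw("A")[1]), numeric(1))) / (300 * 100)
  expect_gt(frac, 0.014)
  expect_lt(frac, 0.026)
  # errors never touch read length and rate 0 is the identity
  expect_true(all(nchar(mut) == 100L))
  expect_identical(gbskit:::add_substitution_errors(seqs, 0), seqs)
})
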