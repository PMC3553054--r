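gm_fixture <- function() {
  m <- rbind(
    a = c("A/A", "C/C", "G/G", "T/T", "A/A", NA),
    b = c("A/A", "C/C", "G/G", "A/T", "A/G", "C/C"),
    c = c("A/A", "C/T", "A/G", "T/T", NA, "C/C"))
  colnames(m) <- paste0("s", 1:6)
  m
}

test_that("pairwise informative counts ignore missing pairs", {
  gm <- gm_fixture()
  pw <- pairwise_informative(gm)
  # a vs b: shared sites 1-5; differ at 4 (T/T vs A/T) and 5 (A/A vs A/G)
  expect_equal(pw$n_informative[pw$sample_a == "a" & pw$sample_b == "b"],
               2L)
  # identical rows -> 0
  dup <- rbind(x = gm["a", ], y = gm["a", ])
  expect_equal(pairwise_informative(dup)$n_informative, 0L)
})

test_that("p-distance applies the allele-sharing weights", {
  gm <- rbind(a = c("A/A", "A/A", "A/A", "A/A", "A/A",
                    "A/A", "A/A", "A/A", "A/A", "A/A"),
              b = c("G/G", "G/G", "G/G", "G/G", "A/A",
                    "A/A", "A/A", "A/A", "A/A", "A/A"))
  colnames(gm) <- paste0("s", 1:10)
  D <- p_distance(gm)
  expect_equal(D["a", "b"], 0.4)     # 4 of 10 differ
  expect_equal(diag(D), c(a = 0, b = 0))
  # het against hom sharing one allele counts 0.5
  gm2 <- rbind(a = c("A/A", "A/A"), b = c("A/G", "A/A"))
  colnames(gm2) <- c("s1", "s2")
  expect_equal(p_distance(gm2)["a", "b"], 0.25)
  # informative count equals shared x distance when all diffs are 0/1
  gm3 <- gm_fixture()
  gm3[gm3 == "A/T"] <- "T/T"; gm3[gm3 == "A/G"] <- "G/G"
  gm3[gm3 == "C/T"] <- "T/T"
  pw <- pairwise_informative(gm3)
  D3 <- p_distance(gm3)
  for (r in seq_len(nrow(pw))) {
    shared <- sum(!is.na(gm3[pw$sample_a[r], ]) &
                    !is.na(gm3[pw$sample_b[r], ]))
    expect_equal(pw$n_informative[r],
                 shared * D3[pw$sample_a[r], pw$sample_b[r]])
  }
  # no shared sites is an error naming the pair
  gm4 <- rbind(a = c("A/A", NA), b = c(NA, "C/C"))
  colnames(gm4) <- c("s1", "s2")
  expect_error(p_distance(gm4), "share no genotyped site")
})

test_that("neighbor joining solves n=3 exactly and recovers additive trees", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D3)
  # three-point closed form: lx = (dxy+dxz-dyz)/2 = 1, ly = 2, lz = 4
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens, c(x = 1, y = 2, z = 4))
  # additive 4-taxon matrix -> exact recovery of topology and path lengths
  D4 <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t4 <- neighbor_joining(D4)
  cd <- stats::cophenetic(t4)[letters[1:4], letters[1:4]]
  expect_equal(unname(cd), unname(D4))
  # 6-taxon additive matrix generated from a known tree
  nwk <- "((a:2,b:3):2,(c:1,d:2):3,(e:4,f:1):1);"
  t_true <- ape::read.tree(text = nwk)
  D6 <- stats::cophenetic(t_true)
  t6 <- neighbor_joining(D6)
  expect_equal(unname(stats::cophenetic(t6)[rownames(D6), colnames(D6)]),
               unname(D6))
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(t6, t_true), 0)
  # cross-check against the reference NJ implementation
  expect_equal(phangorn::RF.dist(t6, ape::nj(as.dist(D6))), 0)
})

test_that("neighbor joining is invariant to label order and validates input", {
  D4 <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  perm <- c("c", "a", "d", "b")
  t_perm <- neighbor_joining(D4[perm, perm])
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(t_perm, neighbor_joining(D4)), 0)
  Dbad <- D4; Dbad[1, 2] <- 7
  expect_error(neighbor_joining(Dbad), "symmetric")
  Dneg <- D4; Dneg[1, 2] <- Dneg[2, 1] <- -1
  expect_error(neighbor_joining(Dneg), "negative")
})

test_that("bootstrap consensus supports duplicate samples at 100%", {
  set.seed(42)
  base <- matrix(sample(c("A/A", "G/G"), 5 * 40, replace = TRUE), 5, 40,
                 dimnames = list(paste0("t", 1:5), paste0("s", 1:40)))
  gm <- rbind(base, DUP = base["t1", ])
  bt <- bootstrap_consensus(gm, B = 40, seed = 7)
  mrca <- ape::getMRCA(bt, c("t1", "DUP"))
  lab <- bt$node.label[mrca - length(bt$tip.label)]
  expect_equal(lab, "100")
  # determinism: same seed, same supports
  bt2 <- bootstrap_consensus(gm, B = 40, seed = 7)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  # B = 1: consensus is that single replicate's topology
  bt1 <- bootstrap_consensus(gm, B = 1, seed = 3)
  rep1 <- attr(bt1, "replicates")[[1]]
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(bt1, rep1), 0)
})

test_that("concordance tables reproduce validation arithmetic", {
  # identical call sets validate at 100%
  calls <- tibble::tibble(sample_id = rep(c("x", "y"), each = 3),
                          site = rep(c("s1", "s2", "s3"), 2),
                          code = c("HOM_REF", "HET", "HOM_ALT",
                                   "HOM_REF", "HOM_REF", "HOM_ALT"))
  ct <- genotype_concordance(calls, calls)
  expect_equal(ct$pct_validated[ct$class == "overall"], 100)
  # missing pairs are excluded
  calls_b <- calls
  calls_b$code[1] <- "MISSING"
  ct2 <- genotype_concordance(calls, calls_b)
  expect_equal(sum(ct2$concordant[ct2$class != "overall"]), 5L)
  # key mismatch errors listing offenders
  calls_c <- calls[-1, ]
  expect_error(genotype_concordance(calls, calls_c), "offenders")
  # symmetric in total percent when strata are ignored
  calls_d <- calls
  calls_d$code[2] <- "HOM_REF"
  f <- genotype_concordance(calls, calls_d)
  r <- genotype_concordance(calls_d, calls)
  expect_equal(f$pct_validated[f$class == "overall"],
               r$pct_validated[r$class == "overall"])
})

test_that("run comparisons reproduce percent-change arithmetic", {
  cr <- compare_runs(list(snp_count = 6252, mean_depth = 11.7),
                     list(snp_count = 8652, mean_depth = 25.2))
  expect_equal(cr$pct_change[cr$metric == "snp_count"], 38.4)
  expect_gt(cr$ratio[cr$metric == "mean_depth"], 2)
  cr2 <- compare_runs(list(snp_count = 6252), list(snp_count = 6846))
  expect_equal(cr2$pct_change, 9.5)
  cr3 <- compare_runs(list(snp_count = 100, mean_depth = 5),
                      list(snp_count = 100, mean_depth = 5))
  expect_equal(cr3$pct_change, c(0, 0))
  expect_error(compare_runs(list(snp_count = 0), list(snp_count = 5)),
               "zero snp_count")
})
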