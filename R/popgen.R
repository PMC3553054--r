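# Pairwise diversity, p-distances, neighbor-joining with bootstrap
# consensus, genotype concordance and protocol comparison statistics.

# numeric difference between two genotype strings ("A/G" sorted pairs):
# 0 identical, 0.5 sharing one allele (het vs hom), 1 no shared allele
genotype_diff <- function(g1, g2) {
  if (g1 == g2) return(0)
  a <- strsplit(g1, "/", fixed = TRUE)[[1]]
  b <- strsplit(g2, "/", fixed = TRUE)[[1]]
  shared <- 0L
  for (x in a) {
    hit <- match(x, b)
    if (!is.na(hit)) { shared <- shared + 1L; b <- b[-hit] }
  }
  (2 - shared) / 2
}

pair_table <- function(gm, fun) {
  samples <- rownames(gm)
  n <- length(samples)
  stopifnot(n >= 2L)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      rows[[length(rows) + 1L]] <-
        tibble(sample_a = samples[i], sample_b = samples[j],
               value = fun(gm[i, ], gm[j, ], samples[i], samples[j]))
    }
  }
  bind_rows(rows)
}

#' Pairwise informative-site counts
#'
#' For every pair of samples, the number of sites where both calls are
#' non-missing and the genotypes differ (sites polymorphic between the
#' pair).
#'
#' @param gm Genotype matrix from [genotype_matrix()] (samples x sites,
#'   `NA` for missing).
#' @return Tibble `sample_a`, `sample_b`, `n_informative`.
#' @export
pairwise_informative <- function(gm) {
  out <- pair_table(gm, function(x, y, ...) {
    ok <- !is.na(x) & !is.na(y)
    sum(x[ok] != y[ok])
  })
  rename(out, n_informative = "value")
}

#' Pairwise p-distance matrix
#'
#' d(i,j) = (sum of genotype differences) / (number of sites non-missing in
#' both samples). Identical genotypes contribute 0, a heterozygote against a
#' homozygote sharing one allele contributes 0.5, genotypes sharing no
#' allele contribute 1 (after heterozygote correction all differences are
#' 0/1 and d is the simple mismatch proportion).
#'
#' @inheritParams pairwise_informative
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(gm) {
  samples <- rownames(gm)
  D <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  tab <- pair_table(gm, function(x, y, na_, nb) {
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) {
      abort(paste0("Samples ", na_, " and ", nb,
                   " share no genotyped site; p-distance undefined"))
    }
    diffs <- mapply(genotype_diff, x[ok], y[ok])
    sum(diffs) / sum(ok)
  })
  for (r in seq_len(nrow(tab))) {
    D[tab$sample_a[r], tab$sample_b[r]] <- tab$value[r]
    D[tab$sample_b[r], tab$sample_a[r]] <- tab$value[r]
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising
#' Q(i,j) = (n-2) d(i,j) - r(i) - r(j) is joined, with the standard
#' branch-length formulas. Ties are broken deterministically by the smallest
#' label pair. Negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling branch (Kuhner-Felsenstein convention).
#'
#' @param D Symmetric distance matrix with labels (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D))) abort("Distance matrix must be symmetric")
  if (any(D < 0)) abort("Distance matrix has negative entries")
  labels <- rownames(D)
  stopifnot(!is.null(labels), length(labels) >= 3L)
  fmt <- function(x) format(max(x, 0), digits = 15, scientific = FALSE,
                            trim = TRUE)
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- max(li - lj, 0); lj <- 0 }
    c(li, lj)
  }
  nwk <- labels                # Newick fragment per active node
  act <- labels                # tie-break label per active node
  while (length(act) > 3L) {
    n <- length(act)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(c(act[ij[1]], act[ij[2]])), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    ll <- clamp_pair(li, lj)
    new_nwk <- paste0("(", nwk[i], ":", fmt(ll[1]), ",",
                      nwk[j], ":", fmt(ll[2]), ")")
    new_lab <- min(act[i], act[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    act <- c(act[keep], new_lab)
  }
  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  lx <- (dxy + dxz - dyz) / 2
  ly <- (dxy + dyz - dxz) / 2
  lz <- (dxz + dyz - dxy) / 2
  tree_str <- paste0("(", nwk[1], ":", fmt(lx), ",", nwk[2], ":", fmt(ly),
                     ",", nwk[3], ":", fmt(lz), ");")
  ape::read.tree(text = tree_str)
}

#' Bootstrap majority-rule consensus NJ tree
#'
#' Resamples sites with replacement `B` times, reconstructs a
#' neighbor-joining tree per replicate, and returns the majority-rule
#' consensus with internal-node support values (percent of replicates
#' containing each retained bipartition). Reproducible by seed.
#'
#' @param gm Genotype matrix ([genotype_matrix()]) with >= 4 samples.
#' @param B Number of bootstrap replicates.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return An `ape::phylo` consensus tree; `node.label` holds percent
#'   support, and the replicate trees are attached as
#'   `attr(, "replicates")` (class `multiPhylo`).
#' @export
bootstrap_consensus <- function(gm, B = 1000L, seed) {
  stopifnot(nrow(gm) >= 4L, B >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_sites <- ncol(gm)
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    trees[[b]] <- neighbor_joining(p_distance(gm[, idx, drop = FALSE]))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  support <- round(100 * counts / B, 1)
  cons$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(cons, "replicates") <- trees
  cons
}

#' Genotype concordance between two call sets
#'
#' Compares two genotype call sets over identical (sample, site) keys,
#' stratified by the first set's genotype class: AA (homozygous reference),
#' AB (heterozygous), BB (homozygous alternate). Pairs where either call is
#' missing are excluded. Typical use: GBS calls against Sanger-validated
#' genotypes.
#'
#' @param calls_a,calls_b Tibbles with columns `sample_id`, `site`, `code`
#'   (HOM_REF/HET/HOM_ALT/MISSING or AA/AB/BB).
#' @return A `concordance_table` (see [concordance_table()]).
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  norm <- function(d) {
    d <- as_tibble(d)
    stopifnot(all(c("sample_id", "site", "code") %in% names(d)))
    map <- c(HOM_REF = "AA", HET = "AB", HOM_ALT = "BB", MISSING = NA,
             AA = "AA", AB = "AB", BB = "BB")
    d$class <- unname(map[as.character(d$code)])
    d
  }
  a <- norm(calls_a); b <- norm(calls_b)
  ka <- paste(a$sample_id, a$site); kb <- paste(b$sample_id, b$site)
  if (!setequal(ka, kb)) {
    off <- c(setdiff(ka, kb), setdiff(kb, ka))
    abort(paste0("Call sets do not share identical (sample, site) keys; ",
                 "offenders: ", paste(head(off, 5), collapse = "; ")))
  }
  m <- left_join(select(a, "sample_id", "site", class_a = "class"),
                 select(b, "sample_id", "site", class_b = "class"),
                 by = c("sample_id", "site")) %>%
    filter(!is.na(.data$class_a), !is.na(.data$class_b))
  conc <- vapply(c("AA", "AB", "BB"), function(cl)
    sum(m$class_a == cl & m$class_b == cl), integer(1))
  disc <- vapply(c("AA", "AB", "BB"), function(cl)
    sum(m$class_a == cl & m$class_b != cl), integer(1))
  concordance_table(conc, disc)
}

#' Build a concordance table from stratified counts
#'
#' @param concordant,discordant Integer vectors named or ordered AA, AB, BB.
#' @return A `concordance_table`: tibble with per-class and overall
#'   concordant/discordant counts and percent validated
#'   (100 x concordant / (concordant + discordant)).
#' @export
concordance_table <- function(concordant, discordant) {
  stopifnot(length(concordant) == 3L, length(discordant) == 3L)
  concordant <- as.integer(unname(concordant))
  discordant <- as.integer(unname(discordant))
  tab <- tibble(
    class = c("AA", "AB", "BB", "overall"),
    concordant = c(concordant, sum(concordant)),
    discordant = c(discordant, sum(discordant))) %>%
    mutate(pct_validated = 100 * .data$concordant /
             (.data$concordant + .data$discordant))
  class(tab) <- c("concordance_table", class(tab))
  tab
}

#' @export
tidy.concordance_table <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.concordance_table <- function(x, ...) {
  ov <- x[x$class == "overall", ]
  tibble(n = ov$concordant + ov$discordant,
         concordant = ov$concordant,
         pct_validated = ov$pct_validated)
}

#' Compare two runs' SNP yield and depth
#'
#' Percent change and ratio of SNP count and mean depth between a baseline
#' run `a` and a comparison run `b` (e.g. standard vs selective-primer
#' protocol, or different multiplex levels). Percent changes are rounded to
#' one decimal for reporting.
#'
#' @param a,b Lists or one-row data frames with `snp_count` and optionally
#'   `mean_depth`.
#' @return Tibble `metric`, `a`, `b`, `pct_change`, `ratio`.
#' @export
compare_runs <- function(a, b) {
  get <- function(x, f) if (is.null(x[[f]]) || is.na(x[[f]])) NA_real_
  else as.numeric(x[[f]])
  sa <- get(a, "snp_count"); sb <- get(b, "snp_count")
  da <- get(a, "mean_depth"); db <- get(b, "mean_depth")
  if (is.na(sa) || sa == 0) abort("Baseline run has zero snp_count")
  rows <- tibble(metric = "snp_count", a = sa, b = sb,
                 pct_change = round(100 * (sb - sa) / sa, 1),
                 ratio = sb / sa)
  if (!is.na(da) && !is.na(db)) {
    rows <- bind_rows(rows, tibble(
      metric = "mean_depth", a = da, b = db,
      pct_change = round(100 * (db - da) / da, 1),
      ratio = db / da))
  }
  rows
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param D Symmetric labelled matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(as.data.frame(D), rownames = "sample"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste0(formatC(rownames(D)[i], width = -10),
                        paste(sprintf("%.6f", D[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
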