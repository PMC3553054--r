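# Seeded GBS read simulator: reference with planted restriction sites,
# truth SNP/indel genotypes, and barcoded single-end reads with
# fragment-depth variation, adapter read-through on short fragments and
# optional substitution error. Every stage of the pipeline is testable
# against the recorded truth.
#
# All randomness flows from config$seed: each stage derives its stream from
# the seed plus a small fixed offset, so stages are individually
# reproducible and the whole simulation is byte-identical given the config.

#' Simulation configuration
#'
#' Defaults emulate a small selfing-crop GBS experiment: an ApeKI-style
#' digest with fragments mostly inside the sequencing-friendly 100-400 bp
#' window, 8 barcoded samples, ~200 truth SNPs plus ~5% indels, fully
#' homozygous lines (selfing species; heterozygosity configurable), 100 b
#' single-end reads at Poisson mean depth 5 per fragment and sample.
#'
#' @param n_contigs,contig_length Reference shape.
#' @param enzyme Bundled enzyme name or `restriction_enzyme`.
#' @param spacing Length-2: uniform range of planted cut-site spacing (bp);
#'   controls the fragment-size distribution.
#' @param n_samples Number of barcoded samples.
#' @param barcodes Optional character vector (defaults to generated distinct
#'   6-mers, which are prefix-free by construction).
#' @param n_snps,n_indels Truth variant counts (indels 1-5 bp).
#' @param het_fraction Probability a sample's genotype at a variant is
#'   heterozygous.
#' @param alt_freq_range Per-site alternate-allele frequency range.
#' @param read_length Read length (bases, barcode included).
#' @param mean_depth Poisson mean reads per (sample, internal fragment).
#' @param error_rate Per-base substitution error probability.
#' @param adapter_readthrough Fill short-fragment reads with common-adapter
#'   sequence after the distal remnant.
#' @param seed Integer seed (mandatory).
#' @param gc Genome GC content (soybean-like default 0.35).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_contigs = 2L, contig_length = 30000L,
                       enzyme = "ApeKI", spacing = c(130L, 240L),
                       n_samples = 8L, barcodes = NULL,
                       n_snps = 200L, n_indels = 10L,
                       het_fraction = 0, alt_freq_range = c(0.2, 0.8),
                       read_length = 100L, mean_depth = 5,
                       error_rate = 0, adapter_readthrough = TRUE,
                       seed, gc = 0.35) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  enz <- get_enzyme(enzyme)
  P <- nchar(enz$recognition)
  if (spacing[1] < P + 4L) {
    abort(paste0("Infeasible site density: minimum spacing must be at ",
                 "least recognition length + 4 (", P + 4L, ")"))
  }
  stopifnot(error_rate >= 0, error_rate < 1, n_snps >= 0, n_indels >= 0,
            het_fraction >= 0, het_fraction <= 1, mean_depth > 0)
  if (!is.null(barcodes)) stopifnot(length(barcodes) == n_samples)
  structure(list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    enzyme = enz, spacing = as.integer(spacing),
    n_samples = as.integer(n_samples), barcodes = barcodes,
    n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
    het_fraction = het_fraction, alt_freq_range = alt_freq_range,
    read_length = as.integer(read_length), mean_depth = mean_depth,
    error_rate = error_rate, adapter_readthrough = adapter_readthrough,
    seed = as.integer(seed), gc = gc), class = "sim_config")
}

rand_bases <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# resolve a degenerate IUPAC pattern into one concrete instance
concrete_site <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_SETS[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a reference with planted restriction sites
#'
#' Generates random contigs, scrubs all chance occurrences of the enzyme's
#' recognition pattern, then plants concrete site instances at spacings
#' drawn from `config$spacing` and removes any spurious sites created at
#' planting junctions, so the digest of the output recovers exactly the
#' planted sites. Deterministic by seed.
#'
#' @param config A `sim_config`.
#' @return A `DNAStringSet`; planted match positions (0-based) per contig in
#'   `attr(, "planted_sites")`.
#' @export
simulate_reference <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  enz <- config$enzyme
  P <- nchar(enz$recognition)
  rx <- paste0("(?=", iupac_to_regex(enz$recognition), ")")
  contigs <- character(config$n_contigs)
  planted <- list()
  for (ci in seq_len(config$n_contigs)) {
    s <- rand_bases(config$contig_length, config$gc)
    # plant sites at the target spacing
    pos <- integer(0)
    p <- sample(config$spacing[1]:config$spacing[2], 1L)
    while (p + P + 50L <= config$contig_length) {
      pos <- c(pos, p)
      p <- p + sample(config$spacing[1]:config$spacing[2], 1L)
    }
    for (m in pos) {
      substr(s, m + 1L, m + P) <- concrete_site(enz$recognition)
    }
    footprint <- unlist(lapply(pos, function(m) (m + 1L):(m + P)))
    for (iter in 1:100) {
      starts <- as.integer(gregexpr(rx, s, perl = TRUE)[[1]]) - 1L
      starts <- starts[starts >= 0L]
      extra <- setdiff(starts, pos)
      if (length(extra) == 0L) break
      for (m in extra) {
        cand <- setdiff((m + 1L):(m + P), footprint)
        if (length(cand) == 0L) next  # cannot happen at enforced spacing
        b1 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        cur <- substr(s, b1, b1)
        substr(s, b1, b1) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    starts <- as.integer(gregexpr(rx, s, perl = TRUE)[[1]]) - 1L
    starts <- starts[starts >= 0L]
    if (length(setdiff(starts, pos)) > 0L) {
      abort("Failed to scrub spurious recognition sites")
    }
    contigs[ci] <- s
    planted[[ci]] <- tibble(chrom = paste0("contig", ci), pos = pos)
  }
  ref <- Biostrings::DNAStringSet(contigs)
  names(ref) <- paste0("contig", seq_len(config$n_contigs))
  attr(ref, "planted_sites") <- bind_rows(planted)
  ref
}

generate_barcodes <- function(n, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    b <- paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE),
               collapse = "")
    if (!(b %in% out)) out <- c(out, b)
  }
  out
}

#' Simulate truth genotypes over a reference
#'
#' Places `n_snps` biallelic SNPs and `n_indels` short (1-5 bp) indels
#' uniformly over positions inside internal fragments that (a) avoid the
#' restriction remnants and selective bases at both fragment ends and (b)
#' are reachable by a read from at least one fragment end. Per-site
#' alternate-allele frequency is drawn from `alt_freq_range`; per-sample
#' genotypes are heterozygous with probability `het_fraction`, otherwise
#' homozygous alt/ref by the site frequency. Sites drawn with no alternate
#' carrier are redrawn (the generator emits a fixed number of polymorphic
#' sites).
#'
#' @param config A `sim_config`.
#' @param reference From [simulate_reference()].
#' @return A truth set list: `reference`, `fragments`, `sheet`, `variants`
#'   (a `gbs_variants` with truth genotypes; depth is NA).
#' @export
simulate_genotypes <- function(config, reference) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  enz <- config$enzyme
  P <- nchar(enz$recognition)
  o <- enz$cut_offset
  rem_len <- P - o
  frags <- digest_reference(reference, enz)
  internal <- frags[frags$internal, , drop = FALSE]
  if (nrow(internal) == 0L) abort("Simulated digest has no internal fragment")
  barcodes <- config$barcodes
  if (is.null(barcodes)) {
    barcodes <- generate_barcodes(config$n_samples, config$seed + 7L)
  }
  sheet <- tibble(sample_id = sprintf("S%02d", seq_len(config$n_samples)),
                  barcode = barcodes)
  glen <- config$read_length - max(nchar(barcodes))
  # eligible variant positions (0-based genome coords)
  margin <- rem_len + 3L
  elig <- list()
  for (i in seq_len(nrow(internal))) {
    L <- internal$length[i]
    if (L - margin - 6L < margin) next
    offs <- seq.int(margin, L - margin - 6L)
    offs <- offs[offs <= glen - 6L | offs >= L - glen + P]
    if (length(offs) > 0) {
      elig[[length(elig) + 1L]] <- tibble(
        chrom = internal$chrom[i], pos = internal$start[i] + offs,
        frag = i)
    }
  }
  elig <- bind_rows(elig)
  n_var <- config$n_snps + config$n_indels
  if (nrow(elig) < n_var * 2L) {
    abort("Not enough eligible positions for the requested variants")
  }
  seqs <- setNames(as.character(reference), names(reference))
  take <- sample.int(nrow(elig), n_var)
  snp_rows <- elig[take[seq_len(config$n_snps)], , drop = FALSE]
  ind_rows <- elig[take[seq_len(config$n_indels) + config$n_snps], ,
                   drop = FALSE]
  vars <- list()
  if (nrow(snp_rows) > 0) {
    refb <- ref_base_at(seqs, snp_rows$chrom, snp_rows$pos)
    altb <- vapply(refb, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    vars[[1]] <- tibble(chrom = snp_rows$chrom, pos = snp_rows$pos,
                        ref = refb, alt = unname(altb), type = "SNP",
                        frag = snp_rows$frag)
  }
  if (nrow(ind_rows) > 0) {
    ilen <- sample(1:5, nrow(ind_rows), replace = TRUE)
    is_del <- runif(nrow(ind_rows)) < 0.5
    iref <- character(nrow(ind_rows)); ialt <- character(nrow(ind_rows))
    for (i in seq_len(nrow(ind_rows))) {
      anchor <- substring(seqs[[ind_rows$chrom[i]]], ind_rows$pos[i] + 1L,
                          ind_rows$pos[i] + 1L)
      if (is_del[i]) {
        iref[i] <- substring(seqs[[ind_rows$chrom[i]]], ind_rows$pos[i] + 1L,
                             ind_rows$pos[i] + 1L + ilen[i])
        ialt[i] <- anchor
      } else {
        iref[i] <- anchor
        ialt[i] <- paste0(anchor, rand_bases(ilen[i], 0.5))
      }
    }
    vars[[length(vars) + 1L]] <- tibble(
      chrom = ind_rows$chrom, pos = ind_rows$pos, ref = iref, alt = ialt,
      type = "INDEL", frag = ind_rows$frag)
  }
  sites <- bind_rows(vars)
  sites$site <- site_key(sites$chrom, sites$pos, sites$ref)
  # per-sample genotypes; redraw until each site is polymorphic
  geno_rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p_alt <- runif(1, config$alt_freq_range[1], config$alt_freq_range[2])
    for (try in 1:50) {
      het <- runif(config$n_samples) < config$het_fraction
      alt_hom <- runif(config$n_samples) < p_alt
      a1 <- ifelse(het | !alt_hom, sites$ref[i], sites$alt[i])
      a2 <- ifelse(het | alt_hom, sites$alt[i], sites$ref[i])
      if (any(a1 != sites$ref[i] | a2 != sites$ref[i])) break
    }
    code <- dplyr::case_when(a1 != a2 ~ "HET",
                             a1 == sites$ref[i] ~ "HOM_REF",
                             TRUE ~ "HOM_ALT")
    geno_rows[[i]] <- tibble(site = sites$site[i], chrom = sites$chrom[i],
                             pos = sites$pos[i], ref = sites$ref[i],
                             sample_id = sheet$sample_id,
                             a1 = a1, a2 = a2, code = code,
                             depth = NA_integer_)
  }
  variants <- new_gbs_variants(
    select(sites, "chrom", "pos", "ref", "alt", "type", "site"),
    bind_rows(geno_rows), sheet$sample_id)
  frag_of_variant <- setNames(sites$frag, sites$site)
  list(reference = reference, fragments = frags, internal = internal,
       sheet = sheet, variants = variants,
       frag_of_variant = frag_of_variant, config = config)
}

# apply variants (VCF-style, 0-based rel_pos within the window) to a window
# sequence; returns mutated sequence and the M/I/D cigar runs of the FULL
# window template (window orientation)
mutate_window <- function(window, rel) {
  if (nrow(rel) == 0L) {
    return(list(seq = window,
                runs = tibble(len = nchar(window), op = "M")))
  }
  rel <- rel[order(rel$pos), , drop = FALSE]
  n <- nchar(window)
  pieces <- character(0)
  lens <- integer(0); ops <- character(0)
  push <- function(l, op) {
    if (l <= 0L) return()
    k <- length(lens)
    if (k > 0L && ops[k] == op) {
      lens[k] <<- lens[k] + l
    } else {
      lens[k + 1L] <<- l; ops[k + 1L] <<- op
    }
  }
  cur <- 0L   # 0-based cursor in window
  for (i in seq_len(nrow(rel))) {
    p <- rel$pos[i]; rf <- rel$ref[i]; al <- rel$alt[i]
    if (p < cur) next   # overlapping variant; skip
    gap <- p - cur
    pieces <- c(pieces, substr(window, cur + 1L, p))
    push(gap, "M")
    if (nchar(rf) == 1L && nchar(al) == 1L) {          # SNP
      pieces <- c(pieces, al)
      push(1L, "M")
      cur <- p + 1L
    } else if (nchar(rf) > nchar(al)) {                 # deletion
      pieces <- c(pieces, al)
      push(1L, "M")
      push(nchar(rf) - 1L, "D")
      cur <- p + nchar(rf)
    } else {                                            # insertion
      pieces <- c(pieces, al)
      push(1L, "M")
      push(nchar(al) - 1L, "I")
      cur <- p + 1L
    }
  }
  pieces <- c(pieces, substr(window, cur + 1L, n))
  push(n - cur, "M")
  list(seq = paste(pieces, collapse = ""),
       runs = tibble(len = lens, op = ops))
}

runs_to_cigar <- function(runs) paste0(runs$len, runs$op, collapse = "")

cigar_to_runs <- function(cg) {
  ops <- cigar_ops(cg)
  tibble(len = ops$len, op = ops$op)
}

# truncate template-orientation runs to q query bases (M/I consume query)
truncate_runs <- function(runs, q) {
  out_len <- integer(0); out_op <- character(0)
  left <- q
  for (i in seq_len(nrow(runs))) {
    if (left <= 0L) break
    l <- runs$len[i]; op <- runs$op[i]
    if (op %in% c("M", "I")) {
      take <- min(l, left)
      out_len <- c(out_len, take); out_op <- c(out_op, op)
      left <- left - take
    } else {
      out_len <- c(out_len, l); out_op <- c(out_op, op)
    }
  }
  # drop trailing deletions
  while (length(out_op) > 0 && tail(out_op, 1) %in% c("D", "N")) {
    out_len <- head(out_len, -1); out_op <- head(out_op, -1)
  }
  tibble(len = out_len, op = out_op)
}

#' Simulate barcoded GBS reads from a truth set
#'
#' For every sample x internal fragment, draws a Poisson number of reads;
#' each read starts at a randomly chosen fragment end (which fixes its
#' strand), carries the sample barcode followed by the restriction remnant
#' and insert, and - when the fragment is shorter than the read - runs
#' through the distal remnant into common-adapter sequence. Substitution
#' errors are applied at `config$error_rate`. Reads are shuffled into a
#' single multiplexed set. Deterministic by seed.
#'
#' @param config A `sim_config`.
#' @param truth Truth set from [simulate_genotypes()].
#' @param selective Optional 1-2 selective bases: restricts fragments via
#'   [selective_subset()] while holding the total read budget constant, so
#'   retained fragments receive proportionally higher depth.
#' @return List: `reads` (tibble `id`, `seq`, `qual`), `provenance` (per
#'   read: sample, fragment, end, strand, truth window and cigar),
#'   `mean_depth_used` (per-fragment Poisson mean after any selective
#'   rescaling).
#' @export
simulate_reads <- function(config, truth, selective = "") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  enz <- config$enzyme
  P <- nchar(enz$recognition)
  o <- enz$cut_offset
  seqs <- setNames(as.character(truth$reference), names(truth$reference))
  internal <- truth$internal
  frag_set <- if (nchar(selective) > 0) {
    selective_subset(internal, selective)
  } else internal
  if (nrow(frag_set) == 0L) abort("No fragment retained by selective bases")
  mean_depth <- config$mean_depth * nrow(internal) / nrow(frag_set)
  sheet <- truth$sheet
  geno <- truth$variants$geno
  sites <- truth$variants$sites
  frag_of <- truth$frag_of_variant
  # map retained fragments back to their index in `internal`
  frag_idx <- match(paste(frag_set$chrom, frag_set$start),
                    paste(internal$chrom, internal$start))
  adapter <- strrep(GBS_ADAPTER_READTHROUGH, 4L)
  # reads within one (fragment, sample, end, haplotype) combination are
  # identical before sequencing error, so accumulate per-combination vectors
  acc <- list()
  add <- function(cnt, sid, bc, f, end, win_start, win_ref_len, cigar,
                  genomic_len, hap, seqv) {
    acc[[length(acc) + 1L]] <<- list(
      n = cnt, sample_id = sid, barcode = bc, chrom = f$chrom,
      frag_start = f$start, frag_end = f$end, end = end,
      strand = if (end == "L") "+" else "-", win_start = win_start,
      win_ref_len = win_ref_len, tmpl_cigar = cigar,
      genomic_len = genomic_len, hap = hap, seq = seqv)
  }
  for (fi in seq_along(frag_idx)) {
    f <- internal[frag_idx[fi], ]
    winL_start <- f$start
    winL <- substr(seqs[[f$chrom]], f$start + 1L, f$end + P - o)
    winR_start <- f$start - o
    winR <- substr(seqs[[f$chrom]], f$start - o + 1L, f$end + P - 2L * o)
    fsites <- names(frag_of)[frag_of == frag_idx[fi]]
    fgeno <- geno[geno$site %in% fsites, , drop = FALSE]
    for (si in seq_len(nrow(sheet))) {
      sid <- sheet$sample_id[si]
      bc <- sheet$barcode[si]
      glen <- config$read_length - nchar(bc)
      n_reads <- rpois(1L, mean_depth)
      if (n_reads == 0L) next
      g <- fgeno[fgeno$sample_id == sid, , drop = FALSE]
      is_het <- nrow(g) > 0 && any(g$a1 != g$a2, na.rm = TRUE)
      ends <- sample(c("L", "R"), n_reads, replace = TRUE)
      haps <- if (is_het) sample(1:2, n_reads, replace = TRUE)
      else rep(1L, n_reads)
      hap_alleles <- list(g$a1, g$a2)
      for (h in unique(haps)) {
        al <- hap_alleles[[h]]
        mut <- g[al != g$ref, , drop = FALSE]
        alm <- al[al != g$ref]
        for (e in c("L", "R")) {
          cnt <- sum(ends == e & haps == h)
          if (cnt == 0L) next
          if (e == "L") {
            m <- mutate_window(
              winL, tibble(pos = mut$pos - winL_start, ref = mut$ref,
                           alt = alm))
            tseq <- m$seq; runs <- m$runs
            ws <- winL_start; wl <- nchar(winL)
          } else {
            m <- mutate_window(
              winR, tibble(pos = mut$pos - winR_start, ref = mut$ref,
                           alt = alm))
            tseq <- revcomp1(m$seq)
            runs <- m$runs    # stored in window orientation
            ws <- winR_start; wl <- nchar(winR)
          }
          gseq <- substr(tseq, 1L, glen)
          if (nchar(gseq) < glen && config$adapter_readthrough) {
            gseq <- paste0(gseq, substr(adapter, 1L, glen - nchar(gseq)))
          }
          add(cnt, sid, bc, f, e, ws, wl, runs_to_cigar(runs),
              nchar(tseq), h, paste0(bc, gseq))
        }
      }
    }
  }
  if (length(acc) == 0L) abort("Simulation produced no reads")
  n_of <- vapply(acc, `[[`, integer(1), "n")
  pull_rep <- function(field, template) {
    v <- vapply(acc, `[[`, template, field)
    rep(v, n_of)
  }
  prov <- tibble(
    sample_id = pull_rep("sample_id", character(1)),
    barcode = pull_rep("barcode", character(1)),
    chrom = pull_rep("chrom", character(1)),
    frag_start = pull_rep("frag_start", integer(1)),
    frag_end = pull_rep("frag_end", integer(1)),
    end = pull_rep("end", character(1)),
    strand = pull_rep("strand", character(1)),
    win_start = pull_rep("win_start", integer(1)),
    win_ref_len = pull_rep("win_ref_len", integer(1)),
    tmpl_cigar = pull_rep("tmpl_cigar", character(1)),
    genomic_len = pull_rep("genomic_len", integer(1)),
    hap = pull_rep("hap", integer(1)),
    seq = pull_rep("seq", character(1)))
  if (config$adapter_readthrough) {
    # pad any residual shortfall to the full read length with adapter
    short <- nchar(prov$seq) < config$read_length
    if (any(short)) {
      prov$seq[short] <- substr(
        paste0(prov$seq[short], substr(adapter, 1L, config$read_length)),
        1L, config$read_length)
    }
  }
  # substitution errors
  if (config$error_rate > 0) {
    prov$seq <- add_substitution_errors(prov$seq, config$error_rate)
  }
  shuffle <- sample.int(nrow(prov))
  prov <- prov[shuffle, , drop = FALSE]
  prov$read_id <- sprintf("r%07d", seq_len(nrow(prov)))
  reads <- tibble(id = prov$read_id, seq = prov$seq,
                  qual = strrep("I", nchar(prov$seq)))
  prov$seq <- NULL
  list(reads = reads, provenance = prov, mean_depth_used = mean_depth)
}

# NOTE: tmpl_cigar is stored in WINDOW (forward-reference) orientation for
# both strands; for "-" reads the template walk is its reversal.

add_substitution_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  tot <- sum(lens)
  hit <- which(runif(tot) < rate)
  if (length(hit) == 0L) return(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  read_of <- findInterval(hit, starts)
  pos_in <- hit - starts[read_of] + 1L
  for (i in seq_along(hit)) {
    r <- read_of[i]; p <- pos_in[i]
    cur <- substr(seqs[r], p, p)
    if (!cur %in% c("A", "C", "G", "T")) next
    substr(seqs[r], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  seqs
}

#' Run a full GBS simulation
#'
#' Orchestrates [simulate_reference()], [simulate_genotypes()] and
#' [simulate_reads()]; optionally writes all artifacts (reference FASTA,
#' truth VCF, multiplexed FASTQ, sample sheet, provenance table) to a
#' directory.
#'
#' @param config A `sim_config`.
#' @param selective Optional selective bases (see [simulate_reads()]).
#' @param out_dir Optional output directory.
#' @return A `gbs_sim` list: `config`, `reference`, `fragments`,
#'   `internal`, `sheet`, `truth` (`gbs_variants`), `reads`, `provenance`,
#'   `mean_depth_used`.
#' @export
simulate_gbs <- function(config, selective = "", out_dir = NULL) {
  ref <- simulate_reference(config)
  truth <- simulate_genotypes(config, ref)
  rd <- simulate_reads(config, truth, selective = selective)
  sim <- structure(
    list(config = config, reference = ref, fragments = truth$fragments,
         internal = truth$internal, sheet = truth$sheet,
         truth = truth$variants, frag_of_variant = truth$frag_of_variant,
         reads = rd$reads, provenance = rd$provenance,
         mean_depth_used = rd$mean_depth_used),
    class = "gbs_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(ref, file.path(out_dir, "ref.fa"))
    write_fastq(sim$reads, file.path(out_dir, "reads.fq"))
    readr::write_tsv(sim$sheet, file.path(out_dir, "sheet.tsv"))
    readr::write_tsv(sim$provenance, file.path(out_dir, "provenance.tsv"))
    write_vcf(sim$truth, ref, file.path(out_dir, "truth.vcf"))
  }
  sim
}

#' @export
print.gbs_sim <- function(x, ...) {
  cat(sprintf(paste0("<gbs_sim> %d sample(s), %d internal fragment(s), ",
                     "%d truth site(s), %d read(s)\n"),
              nrow(x$sheet), nrow(x$internal), nrow(x$truth$sites),
              nrow(x$reads)))
  invisible(x)
}

#' Write simulator truth alignments as SAM
#'
#' Demultiplexes and adapter-clips the simulated reads with the package's
#' own deterministic read processing, then serialises each processed read at
#' its TRUE location with the truth CIGAR (including I/D runs for
#' indel-carrying haplotypes). This provides an aligner-independent SAM for
#' exercising the import path and indel calling.
#'
#' @param sim A `gbs_sim`.
#' @param path Output SAM path.
#' @param min_length Minimum processed-read length retained.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, path, min_length = 25L) {
  proc <- process_fastq(sim$reads, sim$sheet, sim$config$enzyme,
                        min_length = min_length)
  kept <- proc$reads
  prov <- sim$provenance
  m <- match(kept$source_read_id, prov$read_id)
  stopifnot(!anyNA(m))
  pv <- prov[m, , drop = FALSE]
  n <- nrow(kept)
  aln <- vector("list", n)
  for (i in seq_len(n)) {
    q <- nchar(kept$seq[i])
    q <- min(q, pv$genomic_len[i])   # ignore any unclipped adapter tail
    runs_win <- cigar_to_runs(pv$tmpl_cigar[i])
    if (pv$strand[i] == "+") {
      tr <- truncate_runs(runs_win, q)
      cigar <- runs_to_cigar(tr)
      pos <- pv$win_start[i]
      seq_fwd <- substr(kept$seq[i], 1L, q)
    } else {
      # template walk is the reversal of the stored window-orientation runs
      tr <- truncate_runs(runs_win[rev(seq_len(nrow(runs_win))), ,
                                   drop = FALSE], q)
      ref_span <- sum(tr$len[tr$op %in% c("M", "D", "N")])
      cigar <- runs_to_cigar(tr[rev(seq_len(nrow(tr))), , drop = FALSE])
      pos <- pv$win_start[i] + pv$win_ref_len[i] - ref_span
      seq_fwd <- revcomp(substr(kept$seq[i], 1L, q))
    }
    aln[[i]] <- tibble(read_id = kept$id[i], sample_id = kept$sample_id[i],
                       chrom = pv$chrom[i], pos = pos,
                       strand = pv$strand[i], cigar = cigar, seq = seq_fwd,
                       nm = NA_integer_)
  }
  write_sam(bind_rows(aln), sim$reference, path)
}
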