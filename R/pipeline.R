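# One-shot pipeline runner chaining demultiplexing, mapping, SNP calling,
# filtering, heterozygote correction, annotation and diversity analysis.
# Every stage's inputs and outputs are plain files, so stages remain
# independently re-runnable.

#' Validate a pipeline configuration
#'
#' @param fastq Raw multiplexed FASTQ path(s) (or a read tibble).
#' @param sheet Sample sheet path or tibble.
#' @param reference Reference FASTA path or `DNAStringSet`.
#' @param enzyme Bundled enzyme name or `restriction_enzyme`.
#' @param sam Optional SAM path: when given, alignments are imported from
#'   it (MAPQ-filtered) instead of the built-in mapper.
#' @param gff Optional GFF3 path enabling annotation.
#' @param out_dir Output directory for stage artifacts.
#' @param min_length Minimum processed-read length.
#' @param k,max_mismatch Built-in mapper parameters.
#' @param min_mapq SAM-import uniqueness threshold.
#' @param min_depth,max_missing,min_maf Variant filter parameters.
#' @param het_min_reads,het_min_frac Heterozygote call thresholds.
#' @param drop_het Apply heterozygote correction.
#' @param flank Annotation flank width (bp).
#' @param bootstrap Bootstrap replicates for the consensus tree (0 = plain
#'   NJ tree).
#' @param seed RNG seed for the bootstrap.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(fastq, sheet, reference, enzyme = "ApeKI",
                            sam = NULL, gff = NULL, out_dir = tempfile(),
                            min_length = 25L, k = 31L, max_mismatch = 2L,
                            min_mapq = 20L, min_depth = 2L,
                            max_missing = 0.5, min_maf = 0,
                            het_min_reads = 2L, het_min_frac = 0.2,
                            drop_het = TRUE, flank = 5000L,
                            bootstrap = 0L, seed = 1L) {
  for (p in list(fastq, sheet, reference, sam, gff)) {
    if (is.character(p) && length(p) >= 1L && !all(file.exists(p))) {
      abort(paste0("Input path does not exist: ",
                   paste(p[!file.exists(p)], collapse = ", ")))
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the GBS pipeline end to end
#'
#' demultiplex -> clip/filter -> map (built-in or SAM import) -> pileup ->
#' genotype calling -> depth/missing/MAF filters -> optional heterozygote
#' correction -> VCF -> optional annotation -> p-distance matrix and
#' (bootstrap) neighbor-joining tree. Per-stage read accounting is written
#' alongside the artifacts; the run is deterministic given its inputs and
#' seed.
#'
#' @param config A `pipeline_config`.
#' @return List with `summary` (run accounting), `variants`
#'   (`gbs_variants` after all filters), `annotation` (or NULL), `distance`
#'   matrix, `tree` (`phylo` or NULL), and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  ref <- stage("reference", read_reference(config$reference))
  proc <- stage("readproc", process_fastq(
    config$fastq, config$sheet, config$enzyme,
    min_length = config$min_length, out_dir = config$out_dir))
  if (!is.null(config$sam)) {
    aln <- stage("import_sam", import_sam(
      config$sam, ref, min_mapq = config$min_mapq,
      sample_id = function(q) NA_character_))
    # recover sample labels from the processed reads
    m <- match(aln$read_id, proc$reads$id)
    aln$sample_id <- proc$reads$sample_id[m]
    aln <- aln[!is.na(aln$sample_id), , drop = FALSE]
  } else {
    idx <- stage("index", build_index(ref, k = config$k))
    mp <- stage("map", map_reads(proc$reads, idx,
                                 max_mismatch = config$max_mismatch))
    aln <- mp$alignments
  }
  mapped_counts <- dplyr::count(aln, .data$sample_id, name = "mapped")
  sheet <- read_sample_sheet(config$sheet)
  summary <- run_summary(
    raw = dplyr::count(
      bind_rows(proc$reads, proc$dropped), .data$sample_id, name = "raw"),
    processed = dplyr::count(proc$reads, .data$sample_id,
                             name = "processed"),
    mapped = mapped_counts, samples = sheet$sample_id,
    n_unassigned = nrow(proc$unassigned))
  pl <- stage("pileup", build_pileup(aln, ref))
  vars <- stage("call", discover_variants(
    pl, ref, samples = sheet$sample_id, min_depth = config$min_depth,
    het_min_reads = config$het_min_reads,
    het_min_frac = config$het_min_frac))
  vars <- stage("filter", filter_variants(
    vars, min_depth = config$min_depth, max_missing = config$max_missing,
    min_maf = config$min_maf))
  if (config$drop_het) vars <- stage("het_correction", het_correction(vars))
  ann <- NULL
  if (!is.null(config$gff)) {
    models <- stage("gff", parse_gff3(config$gff))
    ann <- stage("annotate", classify_snps(vars, models, reference = ref,
                                           flank = config$flank))
    vars <- add_annotation(vars, ann)
  }
  paths <- list(vcf = file.path(config$out_dir, "variants.vcf"),
                summary = file.path(config$out_dir, "run_summary.tsv"),
                dist = file.path(config$out_dir, "distance.tsv"),
                tree = file.path(config$out_dir, "tree.nwk"))
  stage("vcf", write_vcf(vars, ref, paths$vcf))
  readr::write_tsv(summary, paths$summary)
  D <- NULL; tree <- NULL
  if (nrow(vars$sites) > 0 && length(vars$samples) >= 3) {
    gm <- genotype_matrix(vars)
    D <- tryCatch(p_distance(gm), error = function(e) NULL)
    if (!is.null(D)) {
      write_distance_matrix(D, paths$dist)
      tree <- if (config$bootstrap > 0 && nrow(gm) >= 4) {
        bootstrap_consensus(gm, B = config$bootstrap, seed = config$seed)
      } else {
        neighbor_joining(D)
      }
      ape::write.tree(tree, paths$tree)
    }
  }
  list(summary = summary, variants = vars, annotation = ann,
       distance = D, tree = tree, paths = paths)
}
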