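# Bundled summary tables from a published eight-cultivar soybean GBS
# experiment (raw-read accounting, Sanger validation counts, and
# selective-primer protocol comparisons). They serve as worked-example
# inputs for run_summary()/concordance_table()/compare_runs().

#' Bundled soybean GBS example tables
#'
#' Small summary tables from a published eight-cultivar soybean GBS
#' experiment:
#' \describe{
#'   \item{`"run_reads"`}{per-cultivar raw read counts with the percentage
#'     retained after processing and the percentage of processed reads
#'     mapping uniquely;}
#'   \item{`"sanger_validation"`}{Sanger-validation counts of GBS genotype
#'     calls, stratified by genotype class (AA/AB/BB) for two 8-cultivar
#'     panels;}
#'   \item{`"selective_runs"`}{SNP counts and mean depth of coverage for the
#'     standard protocol and selective-base protocols at several simulated
#'     multiplex levels.}
#' }
#'
#' @param which One of `"run_reads"`, `"sanger_validation"`,
#'   `"selective_runs"`.
#' @return A tibble.
#' @examples
#' soy_gbs_example("run_reads")
#' @export
soy_gbs_example <- function(which = c("run_reads", "sanger_validation",
                                      "selective_runs")) {
  which <- match.arg(which)
  file <- c(run_reads = "soy_run_reads.tsv",
            sanger_validation = "soy_sanger_validation.tsv",
            selective_runs = "soy_selective_runs.tsv")[[which]]
  path <- system.file("extdata", file, package = "gbskit", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
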