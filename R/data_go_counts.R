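#' Reported GO-term differential-expression counts by culture age
#'
#' The published per-term counts for the *Euglena gracilis* culture-age
#' gravitaxis experiment: for each culture age contrasted against the
#' day-6 reference, the number of differentially expressed transcripts
#' annotated to a GO term (`n_de`) and the term's total annotated size
#' (`n_term`). These pairs are the inputs from which the reported coverage
#' percentages (100 * n_de / n_term) are computed, e.g. 33/93 = 35.48%
#' for cyclic nucleotide biosynthetic process at day 9.
#'
#' @return data.frame with columns `age`, `term_id`, `term_name`, `n_de`,
#'   `n_term`.
#' @examples
#' go <- culture_age_go_counts()
#' coverage_percent(go$n_de, go$n_term)
#' @export
culture_age_go_counts <- function() {
  path <- system.file("extdata", "culture_age_go_counts.tsv",
                      package = "euglenaGravitax", mustWork = TRUE)
  read_tsv_table(path)
}
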