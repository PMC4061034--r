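#' Bundled 22-candidate example table
#'
#' A worked example set of 22 familial Crohn's disease candidate SNVs
#' (one per gene) with their coordinates, codon change, SIFT and
#' MutationTaster calls, GERP conservation score, and whether carriers
#' of the variant were observed among the 401 screened healthy controls
#' (`hc_positive`).  Predictor calls are missing (`-`) for three
#' non-missense candidates.  The set illustrates the co-segregation and
#' prioritization stages at the scale a real family-exome study produces
#' after dominant-model filtering.
#'
#' @return data.frame with columns `no`, `chrom`, `pos`, `ref`, `gene`,
#'   `codons`, `sift`, `mutation_taster`, `gerp`, `hc_positive` and a
#'   derived `id` (`chrom_pos` — the alternate allele is not part of the
#'   published identifier)
#' @export
example_candidates <- function() {
  path <- system.file("extdata", "candidate_snvs.tsv", package = "famvar")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$sift <- normalize_predictor_call(tab$sift, "sift")
  tab$mutation_taster <- normalize_predictor_call(tab$mutation_taster,
                                                  "mutation_taster")
  tab$id <- paste(tab$chrom, tab$pos, sep = "_")
  tab
}
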