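#' Minimal transcript model for SNV consequence calling
#'
#' Holds one gene's coding structure: ordered CDS intervals on the
#' genome (1-based inclusive, stored in ascending genomic order) and the
#' spliced CDS nucleotide sequence on the sense (mRNA) strand.  The CDS
#' length must be a multiple of 3 and match the summed interval widths.
#'
#' @param gene gene symbol
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param cds_start,cds_end integer vectors of CDS interval bounds
#'   (1-based inclusive)
#' @param cds_seq spliced CDS sequence, sense strand, 5'->3'
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(gene, chrom, strand, cds_start, cds_end, cds_seq) {
  stopifnot(strand %in% c("+", "-"), length(cds_start) == length(cds_end),
            all(cds_end >= cds_start))
  ord <- order(cds_start)
  cds_start <- cds_start[ord]; cds_end <- cds_end[ord]
  if (length(cds_start) > 1 &&
      any(cds_start[-1] <= cds_end[-length(cds_end)]))
    stop("CDS intervals overlap")
  cds_seq <- toupper(cds_seq)
  total <- sum(cds_end - cds_start + 1)
  if (nchar(cds_seq) != total)
    stop("CDS sequence length (", nchar(cds_seq),
         ") does not match summed interval length (", total, ")")
  if (total %% 3 != 0) stop("CDS length must be divisible by 3")
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 cds_start = cds_start, cds_end = cds_end,
                 cds_seq = cds_seq), class = "transcript_model")
}

#' Read transcript models from a 6-column TSV
#'
#' Columns: `gene`, `chrom`, `strand`, `cds_starts`, `cds_ends`
#' (comma-separated integers) and `cds_sequence` (spliced, sense strand).
#' @param path TSV path
#' @return named list of [transcript_model()] objects
#' @export
read_transcripts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    transcript_model(tab$gene[i], tab$chrom[i], tab$strand[i],
                     as.integer(strsplit(tab$cds_starts[i], ",")[[1]]),
                     as.integer(strsplit(tab$cds_ends[i], ",")[[1]]),
                     tab$cds_sequence[i])
  })
  setNames(models, tab$gene)
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# genomic position -> 1-based index into the spliced sense-strand CDS,
# or NA when the position is not coding
cds_index_of <- function(model, pos) {
  widths <- model$cds_end - model$cds_start + 1
  hit <- which(pos >= model$cds_start & pos <= model$cds_end)
  if (!length(hit)) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
    before + (pos - model$cds_start[hit]) + 1L
  } else {
    # sense strand runs right-to-left along the genome
    after <- if (hit < length(widths)) sum(widths[seq(hit + 1, length(widths))]) else 0L
    after + (model$cds_end[hit] - pos) + 1L
  }
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon: ", codon)
  aa
}

#' Classify the consequence of a single-nucleotide variant
#'
#' Positions outside the gene span are intergenic.  Inside the span but
#' outside the CDS, positions within `splice_window` bp of an internal
#' CDS edge are splice-site; the rest are in-gene noncoding (the minimal
#' model cannot distinguish UTR from intron, and both are excluded
#' classes downstream, so they share the label `noncoding_in_gene`).
#' Coding positions are classified by translating the affected codon
#' with the standard genetic code (alleles are reverse-complemented for
#' minus-strand models): synonymous, missense, nonsense (gain of stop)
#' or stoploss.  The codon change is rendered as
#' `<refCodon><CDS position><altCodon>` (e.g. `ATC374ACC`) and the
#' protein change as `p.<ref><codon number><alt>` (e.g. `p.I125T`).
#'
#' @param chrom,pos,ref,alt the SNV (genome plus-strand alleles)
#' @param model a [transcript_model()]
#' @param splice_window bp around internal CDS edges called splice-site
#'   (default 2, the canonical donor/acceptor dinucleotides)
#' @return list with `gene`, `consequence`, `codon_change`, `aa_change`
#' @export
classify_snv <- function(chrom, pos, ref, alt, model, splice_window = 2) {
  stopifnot(inherits(model, "transcript_model"),
            nchar(ref) == 1, nchar(alt) == 1, ref != alt)
  res <- list(gene = model$gene, consequence = NULL,
              codon_change = NA_character_, aa_change = NA_character_)
  span <- range(c(model$cds_start, model$cds_end))
  if (chrom != model$chrom || pos < span[1] || pos > span[2]) {
    res$consequence <- "intergenic"
    return(res)
  }
  ci <- cds_index_of(model, pos)
  if (is.na(ci)) {
    edges <- c(model$cds_start, model$cds_end)
    internal <- setdiff(edges, span)          # outermost CDS bounds excluded
    if (length(internal) && min(abs(pos - internal)) <= splice_window) {
      res$consequence <- "splice_site"
    } else {
      res$consequence <- "noncoding_in_gene"
    }
    return(res)
  }
  sense_ref <- if (model$strand == "+") toupper(ref) else comp_base(toupper(ref))
  sense_alt <- if (model$strand == "+") toupper(alt) else comp_base(toupper(alt))
  model_base <- substr(model$cds_seq, ci, ci)
  if (model_base != sense_ref)
    stop("reference allele mismatch at ", chrom, ":", pos, " (model has ",
         model_base, ", variant says ", sense_ref, " on the sense strand)")
  codon_i <- (ci - 1) %/% 3 + 1
  codon <- substr(model$cds_seq, 3 * codon_i - 2, 3 * codon_i)
  offset <- (ci - 1) %% 3 + 1
  alt_codon <- codon
  substr(alt_codon, offset, offset) <- sense_alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  res$codon_change <- paste0(codon, ci, alt_codon)
  res$aa_change <- paste0("p.", aa_ref, codon_i, aa_alt)
  res$consequence <-
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stoploss"
    else "missense"
  res
}

#' The consequence vocabulary
#'
#' @return list with elements `retained` (protein-disrupting classes)
#'   and `excluded` (classes removed by the consequence filter)
#' @export
consequence_classes <- function() {
  list(retained = c("missense", "nonsense", "stoploss", "splice_site",
                    "frameshift", "inframe_indel"),
       excluded = c("intergenic", "intronic", "utr", "synonymous",
                    "noncoding_in_gene"))
}

#' Keep only protein-disrupting variants
#'
#' Retains missense, nonsense, stoploss, splice-site, frameshift and
#' in-frame indels; drops intergenic, intronic, UTR and synonymous
#' variants.  Unknown consequence labels are an error.
#'
#' @param x a [variant_cohort()]
#' @param consequence character vector of consequence labels aligned
#'   with the cohort's sites (e.g. an annotation-table column)
#' @return the filtered cohort, with attribute `n_dropped`
#' @export
filter_protein_disrupting <- function(x, consequence) {
  stopifnot(inherits(x, "variant_cohort"), length(consequence) == n_sites(x))
  cls <- consequence_classes()
  unknown <- setdiff(unique(consequence), c(cls$retained, cls$excluded))
  if (length(unknown))
    stop("unknown consequence label(s): ", paste(unknown, collapse = ", "))
  keep <- consequence %in% cls$retained
  out <- subset_sites(x, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
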