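#' Dominant-model shared-variant filter
#'
#' Retains exactly the variants carried (het or hom_alt) by every
#' affected exome case and absent (hom_ref — the strictest reading of
#' "absent") in every sequenced unaffected control.  With an empty
#' control set this reduces to the intersection over cases; with an
#' empty case set nothing can be "shared by all cases" and the result is
#' empty.  A missing genotype in any listed sample drops the variant
#' under `strict` mode (the default; validation re-genotyping resolves
#' such sites upstream) or retains it flagged under `permissive` mode.
#'
#' @param geno character genotype matrix (sites x samples) with column
#'   names, entries in hom_ref/het/hom_alt/missing
#' @param cases,controls character vectors of sample ids
#' @param mode `"strict"` or `"permissive"` missing-genotype handling
#' @return logical keep vector over sites; attribute `flagged` marks
#'   variants retained despite missing genotypes (permissive mode only)
#' @export
dominant_shared_filter <- function(geno, cases, controls,
                                   mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(c(cases, controls), colnames(geno))
  if (length(missing_ids))
    stop("config error: case/control id(s) absent from cohort: ",
         paste(missing_ids, collapse = ", "))
  n <- nrow(geno)
  if (length(cases) == 0L) {
    out <- rep(FALSE, n)
    attr(out, "flagged") <- rep(FALSE, n)
    return(out)
  }
  gcase <- geno[, cases, drop = FALSE]
  gctrl <- geno[, controls, drop = FALSE]
  any_missing <- rowSums(gcase == "missing") > 0 |
    (length(controls) > 0 & rowSums(gctrl == "missing") > 0)
  shared <- rowSums(gcase == "het" | gcase == "hom_alt" |
                    gcase == "missing") == length(cases)
  absent <- if (length(controls) == 0L) rep(TRUE, n) else
    rowSums(gctrl == "hom_ref" | gctrl == "missing") == length(controls)
  keep <- shared & absent
  if (mode == "strict") {
    keep <- keep & !any_missing
    flagged <- rep(FALSE, n)
  } else {
    flagged <- keep & any_missing
  }
  attr(keep, "flagged") <- flagged
  keep
}

#' Co-segregation check against unaffected relatives
#'
#' A candidate passes iff no unaffected relative carries the alternate
#' allele; failures report which relatives carry it.  Relatives with
#' unknown affection status are excluded from the check (logged); with
#' no usable relatives every candidate passes vacuously with a warning.
#'
#' @param geno character genotype matrix (candidates x relatives) with
#'   row names = candidate ids and column names = relative ids
#' @param ped optional [pedigree()] used to verify affection status of
#'   the relatives; relatives not `unaffected` are dropped
#' @return list with `passing` (candidate ids), `failing` (data.frame
#'   `id`, `carriers` with comma-separated carrier ids) and `excluded`
#'   (relatives excluded for unknown affection)
#' @export
cosegregation_check <- function(geno, ped = NULL) {
  geno <- as.matrix(geno)
  relatives <- colnames(geno)
  excluded <- character(0)
  if (!is.null(ped)) {
    status <- setNames(ped$affected, ped$id)[relatives]
    excluded <- relatives[is.na(status) | status != "unaffected"]
    if (length(excluded))
      message("excluding relative(s) with non-unaffected or unknown status: ",
              paste(excluded, collapse = ", "))
    geno <- geno[, setdiff(relatives, excluded), drop = FALSE]
  }
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  if (ncol(geno) == 0L) {
    warning("no unaffected relatives genotyped; all candidates pass vacuously")
    return(list(passing = ids,
                failing = data.frame(id = character(0), carriers = character(0)),
                excluded = excluded))
  }
  carrier <- geno == "het" | geno == "hom_alt"
  fails <- rowSums(carrier) > 0
  carriers <- vapply(seq_len(nrow(geno)), function(i)
    paste(colnames(geno)[carrier[i, ]], collapse = ","), character(1))
  list(passing = ids[!fails],
       failing = data.frame(id = ids[fails], carriers = carriers[fails],
                            stringsAsFactors = FALSE),
       excluded = excluded)
}

# can this single genotype transmit allele a (0 or 1)?
can_transmit <- function(geno, allele) {
  switch(geno,
         hom_ref = allele == 0,
         het = TRUE,
         hom_alt = allele == 1,
         missing = TRUE)
}

#' Mendelian consistency of a child genotype given both parents
#'
#' A trio genotype combination is consistent iff the child's two alleles
#' can be drawn one from each parent.  Missing genotypes cannot witness
#' a violation and return `NA`.
#'
#' @param child,father,mother character vectors of zygosity labels
#' @return logical vector: `TRUE` consistent, `FALSE` violation,
#'   `NA` when any member is missing
#' @export
mendelian_consistent <- function(child, father, mother) {
  n <- max(length(child), length(father), length(mother))
  child <- rep_len(child, n); father <- rep_len(father, n)
  mother <- rep_len(mother, n)
  vapply(seq_len(n), function(i) {
    if (any(c(child[i], father[i], mother[i]) == "missing")) return(NA)
    child_pairs <- switch(child[i],
                          hom_ref = list(c(0, 0)),
                          het = list(c(0, 1), c(1, 0)),
                          hom_alt = list(c(1, 1)))
    any(vapply(child_pairs, function(p)
      can_transmit(father[i], p[1]) && can_transmit(mother[i], p[2]),
      logical(1)))
  }, logical(1))
}

#' Mendelian screen of a cohort over all resolvable trios
#'
#' @param x a [variant_cohort()]
#' @param ped a [pedigree()]; trios are the members with both parents
#'   present in the pedigree and the cohort
#' @return logical matrix (sites x trios, named by child id):
#'   consistency of each trio at each site
#' @export
mendelian_consistency <- function(x, ped) {
  trios <- pedigree_trios(ped)
  trios <- trios[trios$child %in% x$samples &
                 trios$father %in% x$samples &
                 trios$mother %in% x$samples, , drop = FALSE]
  out <- matrix(NA, n_sites(x), nrow(trios),
                dimnames = list(NULL, trios$child))
  for (k in seq_len(nrow(trios))) {
    out[, k] <- mendelian_consistent(x$geno[, trios$child[k]],
                                     x$geno[, trios$father[k]],
                                     x$geno[, trios$mother[k]])
  }
  out
}
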