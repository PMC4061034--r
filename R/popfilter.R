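#' Single-database rejection rule
#'
#' For the allele-frequency databases (dbSNP, 1000 Genomes, HapMap) a
#' variant is rejected iff it is present with a known allele frequency
#' strictly above `threshold` (default 0.5%).  The YH single personal
#' genome carries no population frequency, so presence alone rejects
#' ("except for YH" exempts YH from the frequency condition, not from
#' the rejection).  Absent records retain; a presence record with
#' unknown AF in a frequency database retains and is flagged
#' indeterminate.
#'
#' @param db database name: `dbSNP`, `KG1000`, `HapMap`, `YH`, `EVS`
#'   or `inhouse` (vectors recycled against `present`/`af`)
#' @param present logical membership flag
#' @param af allele frequency in `[0, 1]`, `NA` = unknown
#' @param threshold rejection threshold on AF (strict inequality)
#' @return logical vector, `TRUE` = reject; attribute `indeterminate`
#'   flags present-with-unknown-AF records in frequency databases
#' @export
reject_by_database <- function(db, present, af = NA_real_, threshold = 0.005) {
  stopifnot(threshold >= 0, threshold <= 1)
  n <- max(length(db), length(present), length(af))
  db <- rep_len(db, n); present <- rep_len(present, n); af <- rep_len(af, n)
  known <- c("dbSNP", "KG1000", "HapMap", "YH", "EVS", "inhouse")
  if (!all(db %in% known))
    stop("unknown database name(s): ", paste(setdiff(db, known), collapse = ", "))
  presence_only <- db == "YH"
  reject <- ifelse(presence_only, present,
                   present & !is.na(af) & af > threshold)
  reject[is.na(reject)] <- FALSE
  attr(reject, "indeterminate") <- !presence_only & present & is.na(af)
  reject
}

#' Run the ordered population-database exclusion cascade
#'
#' Applies [reject_by_database()] sequentially over the configured
#' database order, recording per-sample survivor counts after each
#' stage.  A variant with no record for a database is treated as absent
#' (retained).  The final survivor set is order-invariant (each
#' rejection is a per-variant predicate); only the intermediate stage
#' counts depend on the order.
#'
#' @param x a [variant_cohort()]
#' @param popdb population table from [read_popdb()]
#' @param order database order (default `dbSNP`, `KG1000`, `HapMap`,
#'   `YH`; append `"inhouse"` to add the optional in-house stage)
#' @param threshold AF rejection threshold
#' @param active optional logical site x sample matrix of live calls
#'   used for the per-stage counts (default: any non-reference genotype)
#' @return list with `cohort` (survivors), `active` (subset of input
#'   `active`), and `stages` (data.frame: one row per stage with
#'   per-sample survivor counts)
#' @export
run_cascade <- function(x, popdb, order = c("dbSNP", "KG1000", "HapMap", "YH"),
                        threshold = 0.005, active = NULL) {
  stopifnot(inherits(x, "variant_cohort"))
  if (anyDuplicated(order)) stop("database order contains duplicates")
  if (is.null(active)) active <- x$geno == "het" | x$geno == "hom_alt"
  keep <- rep(TRUE, n_sites(x))
  stages <- list()
  label <- character(0)
  for (db_name in order) {
    recs <- popdb[popdb$db == db_name, , drop = FALSE]
    m <- match(x$sites$id, recs$id)
    present <- !is.na(m) & recs$present[m]
    af <- recs$af[m]
    rej <- reject_by_database(db_name, present, af, threshold)
    keep <- keep & !rej
    label <- c(label, db_name)
    counts <- colSums(active & keep)
    stages[[length(stages) + 1L]] <- data.frame(
      stage = paste(label, collapse = "+"), t(counts), check.names = FALSE)
  }
  out <- subset_sites(x, keep)
  list(cohort = out, active = active[keep, , drop = FALSE],
       stages = do.call(rbind, stages))
}
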