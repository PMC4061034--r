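#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run uses, so a run is fully
#' reproducible from its logged configuration.
#'
#' @param thresholds a [qc_thresholds()]
#' @param db_order population-database cascade order; append
#'   `"inhouse"` to enable the optional fifth stage
#' @param af_threshold allele-frequency rejection threshold
#' @param gerp_conserved_threshold,conservation_weight consensus-score
#'   parameters, see [consensus_score()]
#' @param missing_mode missing-genotype policy of the dominant filter
#' @param include_familial_cases add the exome-sequenced familial cases
#'   to the sporadic case panel for the association test (the only
#'   documented reading under which the nominated variant can reach
#'   significance; see the methods vignette)
#' @param splice_window bp window for splice-site calls when a
#'   transcript model is used
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(thresholds = qc_thresholds(),
                            db_order = c("dbSNP", "KG1000", "HapMap", "YH"),
                            af_threshold = thresholds$af_reject_threshold,
                            gerp_conserved_threshold = 4.0,
                            conservation_weight = 0.25,
                            missing_mode = c("strict", "permissive"),
                            include_familial_cases = TRUE,
                            splice_window = 2) {
  missing_mode <- match.arg(missing_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

relatives_matrix <- function(relatives, ids) {
  rel_ids <- sort(unique(relatives$sample))
  m <- matrix("missing", length(ids), length(rel_ids),
              dimnames = list(ids, rel_ids))
  hit <- relatives[relatives$id %in% ids, , drop = FALSE]
  m[cbind(match(hit$id, ids), match(hit$sample, rel_ids))] <- hit$geno
  m
}

#' Run the full family-exome filtering pipeline
#'
#' Executes the stages in cascade order — capture-region restriction,
#' quality control and indel re-calling, protein-disrupting consequence
#' filter, the population-database exclusion cascade, the dominant-model
#' shared-variant filter, co-segregation against unaffected relatives,
#' predictor-consensus ranking, and case-control association on the
#' surviving candidates — recording per-sample survivor counts at every
#' stage.
#'
#' @param bundle a `famvar_bundle` from [simulate_family_bundle()] /
#'   [read_bundle()], or a bundle directory path
#' @param config a [pipeline_config()]
#' @return object of class `famvar_run`: `stages` (cascade report),
#'   `candidates`, `cosegregation`, `ranked`, `assoc`, `config`, `log`
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "famvar_bundle"),
            inherits(config, "pipeline_config"))
  x <- bundle$cohort
  ped <- bundle$pedigree
  cases <- role_ids(ped, "exome_case")
  controls <- role_ids(ped, "exome_control")
  if (length(cases) == 0) stop("pedigree defines no exome_case samples")
  thr <- config$thresholds
  log <- c(sprintf("samples: cases=%s controls=%s",
                   paste(cases, collapse = ","),
                   paste(controls, collapse = ",")),
           sprintf("thresholds: GQ>=%g DP>=%g CN<=%g NSD>=%g flank=%g AF<=%g",
                   thr$min_genotype_quality, thr$min_depth,
                   thr$max_copy_number, thr$min_snp_distance_bp,
                   thr$target_flank_bp, config$af_threshold),
           sprintf("het band: [%g, %g]; db order: %s; missing mode: %s",
                   thr$het_fraction_lo, thr$het_fraction_hi,
                   paste(config$db_order, collapse = "+"),
                   config$missing_mode))
  samples <- x$samples
  stages <- list()
  add_stage <- function(label, counts, shared = NA_real_) {
    row <- as.data.frame(as.list(c(counts, shared = shared)))
    stages[[length(stages) + 1L]] <<- cbind(stage = label, row)
  }
  called <- x$geno == "het" | x$geno == "hom_alt"
  add_stage("total_calls", colSums(called))

  x <- restrict_to_targets(x, bundle$targets, flank = thr$target_flank_bp)
  called <- x$geno == "het" | x$geno == "hom_alt"
  add_stage("on_target", colSums(called))

  qc <- qc_cohort(x, thr, missing_policy = "fail")
  x$geno <- qc$geno
  active <- qc$active
  add_stage("quality_passing", colSums(active))

  ann <- bundle$annotations
  m <- match(x$sites$id, ann$id)
  if (anyNA(m))
    stop("annotation table lacks ", sum(is.na(m)), " site(s), e.g. ",
         x$sites$id[which(is.na(m))[1]])
  ann <- ann[m, , drop = FALSE]
  x <- filter_protein_disrupting(x, ann$consequence)
  keep <- !is.na(match(ann$id, x$sites$id))
  active <- active[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  add_stage("protein_disrupting", colSums(active))

  casc <- run_cascade(x, bundle$popdb, order = config$db_order,
                      threshold = config$af_threshold, active = active)
  x <- casc$cohort
  active <- casc$active
  ann <- ann[match(x$sites$id, ann$id), , drop = FALSE]
  for (i in seq_len(nrow(casc$stages)))
    add_stage(casc$stages$stage[i],
              unlist(casc$stages[i, samples, drop = TRUE]))

  dom <- dominant_shared_filter(x$geno, cases, controls,
                                mode = config$missing_mode)
  dom <- dom & rowSums(active[, cases, drop = FALSE]) == length(cases)
  x <- subset_sites(x, dom)
  ann <- ann[dom, , drop = FALSE]
  add_stage("dominant_shared", setNames(rep(NA_real_, length(samples)), samples),
            shared = sum(dom))

  candidates <- cbind(x$sites, ann[, setdiff(names(ann), "id"), drop = FALSE])
  rel_geno <- relatives_matrix(bundle$relatives, x$sites$id)
  coseg <- cosegregation_check(rel_geno, ped)
  add_stage("cosegregation", setNames(rep(NA_real_, length(samples)), samples),
            shared = length(coseg$passing))
  final <- candidates[candidates$id %in% coseg$passing, , drop = FALSE]

  panel <- bundle$panel
  ctrl_carriers <- vapply(final$id, function(v) {
    g <- panel$geno[panel$id == v & panel$group == "control"]
    sum(g %in% c("het", "hom_alt"))
  }, numeric(1))
  sc <- consensus_score(final$sift, final$mutation_taster, final$polyphen2,
                        final$pmut, final$gerp,
                        gerp_conserved_threshold = config$gerp_conserved_threshold,
                        conservation_weight = config$conservation_weight)
  ranked <- if (nrow(final)) rank_candidates(final, sc, ctrl_carriers) else
    cbind(final, sc[0, ], control_carriers = numeric(0), rank = integer(0))

  assoc <- do.call(rbind, lapply(seq_len(nrow(ranked)), function(i) {
    v <- ranked$id[i]
    sub <- panel[panel$id == v, , drop = FALSE]
    cg <- sub$geno[sub$group == "case"]
    if (config$include_familial_cases && v %in% x$sites$id)
      cg <- c(cg, x$geno[x$sites$id == v, cases])
    sp <- screen_panel(cg, sub$geno[sub$group == "control"])
    if (sp$degenerate || nrow(sub) == 0)
      return(data.frame(id = v, gene = ranked$gene[i], a = NA, b = NA,
                        c = NA, d = NA, chi2 = NA, p_chisq = NA,
                        odds_ratio = NA, p_fisher = NA,
                        note = "no panel data"))
    tab <- contingency_2x2(sp$case_alt, sp$case_alleles - sp$case_alt,
                           sp$control_alt, sp$control_alleles - sp$control_alt)
    ch <- allelic_chisq(tab)
    data.frame(id = v, gene = ranked$gene[i], a = tab$a, b = tab$b,
               c = tab$c, d = tab$d, chi2 = ch$chi2, p_chisq = ch$p,
               odds_ratio = ch$odds_ratio,
               p_fisher = fisher_exact(tab, "two"),
               note = ifelse(is.na(ch$p), ch$reason, ""))
  }))
  if (is.null(assoc))
    assoc <- data.frame(id = character(0), gene = character(0))

  stages <- do.call(rbind, stages)
  structure(list(stages = stages, candidates = candidates,
                 cosegregation = coseg, ranked = ranked, assoc = assoc,
                 config = config, log = log),
            class = "famvar_run")
}

#' @export
print.famvar_run <- function(x, ...) {
  cat("famvar pipeline run\n")
  cat("-------------------\n")
  print(x$stages, row.names = FALSE)
  cat("\nfinal candidates:", nrow(x$ranked), "\n")
  if (nrow(x$ranked)) {
    show <- head(x$ranked[, c("rank", "gene", "id", "score",
                              "control_carriers")], 6)
    print(show, row.names = FALSE)
  }
  if (nrow(x$assoc)) {
    cat("\nassociation (top candidate):\n")
    print(head(x$assoc, 1), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.famvar_run <- function(object, ...) {
  cat("stages:", nrow(object$stages),
      "| dominant-model candidates:", nrow(object$candidates),
      "| co-segregating:", length(object$cosegregation$passing),
      "| ranked:", nrow(object$ranked), "\n")
  invisible(object$stages)
}

#' Serialize a pipeline run to TSV and JSON
#'
#' Writes `report.tsv`/`report.json` (the cascade report),
#' `candidates.tsv`, `ranked.tsv`, `assoc.tsv`,
#' `cosegregation_passing.tsv`, `cosegregation_failing.tsv` and
#' `log.txt` into `dir`.
#' @param run a `famvar_run`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "famvar_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(run$stages, "report.tsv")
  jsonlite::write_json(run$stages, file.path(dir, "report.json"),
                       dataframe = "rows", na = "null", digits = NA)
  tsv(run$candidates, "candidates.tsv")
  tsv(run$ranked, "ranked.tsv")
  tsv(run$assoc, "assoc.tsv")
  tsv(data.frame(id = run$cosegregation$passing), "cosegregation_passing.tsv")
  tsv(run$cosegregation$failing, "cosegregation_failing.tsv")
  writeLines(run$log, file.path(dir, "log.txt"))
  invisible(dir)
}
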