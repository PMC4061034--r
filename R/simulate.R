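#' Built-in pedigree shape: affected father-daughter pair with sequenced
#' unaffected mother and grandmother, plus unaffected validation relatives
#'
#' The quartet mirrors the study design the pipeline targets: the
#' proband (father) and his affected daughter are the exome cases; the
#' proband's unaffected mother (the grandmother) and wife (the mother)
#' are the exome controls; `n_relatives` additional unaffected family
#' members are genotyped only in the validation (co-segregation) phase.
#'
#' @param n_relatives number of unaffected validation relatives
#' @return a [pedigree()]
#' @export
family_a_pedigree <- function(n_relatives = 10) {
  rel_ids <- sprintf("REL%02d", seq_len(n_relatives))
  ped <- data.frame(
    family = "FAMA",
    id = c("GRANDMOTHER", "MOTHER", "FATHER", "DAUGHTER", rel_ids),
    father = c(NA, NA, NA, "FATHER", rep(NA, n_relatives)),
    mother = c(NA, NA, "GRANDMOTHER", "MOTHER", rep(NA, n_relatives)),
    sex = c("female", "female", "male", "female",
            rep(c("male", "female"), length.out = n_relatives)),
    affected = c("unaffected", "unaffected", "affected", "affected",
                 rep("unaffected", n_relatives)),
    stringsAsFactors = FALSE)
  pedigree(ped, roles = list(
    exome_case = c("FATHER", "DAUGHTER"),
    exome_control = c("MOTHER", "GRANDMOTHER"),
    relative = rel_ids))
}

#' Simulation configuration
#'
#' Defines the generative world for the synthetic pedigree-exome bundle:
#' site count, allele-frequency spectrum (a rare component below the
#' database rejection threshold and a common Beta component skewed
#' high), variant-class and consequence-class fractions, database
#' membership probabilities (calibrated so the cascade removes mass in
#' the proportions seen in real family-exome filtering), per-field
#' quality-noise fractions, the planted causal variant, and the
#' case-control panel composition.  `n_variants = 2000` is the desk
#' scale; ~115,000 emulates a full quality-passing exome.
#'
#' @param seed integer seed; fixes every downstream draw
#' @param n_variants number of segregating sites in the bundle
#' @param pedigree pedigree shape, default [family_a_pedigree()]
#' @param frac_rare fraction of sites whose AF is drawn from the rare
#'   component
#' @param rare_af_range uniform support of the rare AF component (kept
#'   below the 0.5% rejection threshold)
#' @param common_af_shape Beta shape parameters of the common component
#' @param frac_indel fraction of sites that are indels
#' @param frac_disrupting fraction of sites with a protein-disrupting
#'   consequence
#' @param db_membership per-class database membership probabilities:
#'   list with numeric vectors `common` and `rare` named by database
#' @param qc_fail per-criterion marginal failure fractions for the
#'   quality-noise model (`gq`, `dp`, `cn`, `nsd`)
#' @param depth_mean mean sequencing depth for passing calls
#' @param frac_flank,frac_offtarget fractions of sites placed in the
#'   200-bp flank and beyond it (the latter are dropped by the region
#'   restriction)
#' @param n_targets,target_width capture-target count and width (bp)
#' @param p_predictor_missing probability each predictor call is missing
#'   for a passenger missense site
#' @param causal list: `gene`, `af`, predictor `profile` (sift,
#'   mutation_taster, polyphen2, pmut, gerp), and planted panel carrier
#'   counts `panel_case_carriers`, `panel_uc_carriers`,
#'   `panel_control_carriers`
#' @param panel_n named vector: panel cohort sizes (`cases` sporadic
#'   affected, `uc` a second affected cohort, `controls` healthy)
#' @param thresholds [qc_thresholds()] assumed by the noise model
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 2000L,
                       pedigree = family_a_pedigree(10),
                       frac_rare = 0.15,
                       rare_af_range = c(1e-4, 0.005),
                       common_af_shape = c(5, 2),
                       frac_indel = 0.06,
                       frac_disrupting = 0.125,
                       db_membership = list(
                         common = c(dbSNP = 0.85, KG1000 = 0.32,
                                    HapMap = 0.0015, YH = 0.025),
                         rare = c(dbSNP = 0.10, KG1000 = 0.02,
                                  HapMap = 0.001, YH = 0.005)),
                       qc_fail = c(gq = 0.15, dp = 0.08, cn = 0.06, nsd = 0.04),
                       depth_mean = 150,
                       frac_flank = 0.02,
                       frac_offtarget = 0.01,
                       n_targets = 250L,
                       target_width = 2000L,
                       p_predictor_missing = 0.10,
                       causal = list(
                         gene = "GCAUSAL",
                         af = 5e-4,
                         profile = list(sift = "DAMAGING",
                                        mutation_taster = "disease_causing",
                                        polyphen2 = "damaging",
                                        pmut = "pathological",
                                        gerp = 5.2),
                         panel_case_carriers = 1L,
                         panel_uc_carriers = 0L,
                         panel_control_carriers = 0L),
                       panel_n = c(cases = 278L, uc = 123L, controls = 401L),
                       thresholds = qc_thresholds()) {
  cfg <- as.list(environment())
  probs <- c(frac_rare, frac_indel, frac_disrupting, qc_fail,
             frac_flank, frac_offtarget, p_predictor_missing,
             unlist(db_membership))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (frac_flank + frac_offtarget > 1)
    stop("frac_flank + frac_offtarget exceeds 1")
  if (rare_af_range[2] > thresholds$af_reject_threshold)
    warning("rare AF component extends above the rejection threshold")
  stopifnot(n_variants >= 1, n_targets >= 1, target_width >= 10,
            causal$af > 0, causal$af < 1)
  class(cfg) <- "sim_config"
  cfg
}

# one allele transmitted by a genotype coded 0/1/2
transmit_allele <- function(gt) rbinom(length(gt), 1L, gt / 2)

# genotypes (0/1/2) for every pedigree member at n sites with per-site AF
simulate_pedigree_genotypes <- function(ped, af) {
  n <- length(af)
  gt <- matrix(0L, n, nrow(ped), dimnames = list(NULL, ped$id))
  for (i in seq_len(nrow(ped))) {         # pedigree() orders parents first
    pat <- if (is.na(ped$father[i])) rbinom(n, 1L, af) else
      transmit_allele(gt[, ped$father[i]])
    mat <- if (is.na(ped$mother[i])) rbinom(n, 1L, af) else
      transmit_allele(gt[, ped$mother[i]])
    gt[, i] <- pat + mat
  }
  gt
}

zyg_label <- function(gt) c("hom_ref", "het", "hom_alt")[gt + 1L]

sample_positions <- function(cfg) {
  # non-overlapping targets laid out on chr1..chr22; each site lands in a
  # random target's core, its flank, or beyond the flank
  chroms <- paste0("chr", rep(1:22, length.out = cfg$n_targets))
  slot <- ave(seq_len(cfg$n_targets), chroms, FUN = seq_along)
  start <- 1e6 + (slot - 1) * 1e5
  end <- start + cfg$target_width - 1
  targets <- data.frame(chrom = chroms, start = start, end = end)

  n <- cfg$n_variants
  region <- sample(c("target", "flank", "off"), n, replace = TRUE,
                   prob = c(1 - cfg$frac_flank - cfg$frac_offtarget,
                            cfg$frac_flank, cfg$frac_offtarget))
  tid <- sample.int(cfg$n_targets, n, replace = TRUE)
  flank <- cfg$thresholds$target_flank_bp
  pos <- integer(n)
  for (t in unique(tid)) {
    for (rg in c("target", "flank", "off")) {
      idx <- which(tid == t & region == rg)
      if (!length(idx)) next
      pool <- switch(rg,
        target = seq(targets$start[t], targets$end[t]),
        flank = c(seq(targets$start[t] - flank, targets$start[t] - 1),
                  seq(targets$end[t] + 1, targets$end[t] + flank)),
        off = seq(targets$end[t] + flank + 100, targets$end[t] + flank + 5000))
      pos[idx] <- sample(pool, length(idx))
    }
  }
  list(targets = targets, chrom = chroms[tid], pos = pos, region = region)
}

random_alleles <- function(n, vclass) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- ref
  snv <- vclass == "SNV"
  alt[snv] <- vapply(ref[snv], function(r)
    sample(setdiff(bases, r), 1), character(1))
  ins <- vclass == "insertion"
  alt[ins] <- paste0(ref[ins], vapply(seq_len(sum(ins)), function(i)
    paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = ""),
    character(1)))
  del <- vclass == "deletion"
  ref[del] <- paste0(alt[del] <- ref[del],
                     vapply(seq_len(sum(del)), function(i)
                       paste(sample(bases, sample(1:3, 1), replace = TRUE),
                             collapse = ""), character(1)))
  list(ref = ref, alt = alt)
}

#' Generate a complete synthetic family-exome input bundle
#'
#' Draws per-site allele frequencies from the configured mixture,
#' genotypes every pedigree member by Mendelian transmission (founders
#' from Hardy-Weinberg at the site AF, unobserved parents integrated
#' out), attaches quality noise, consequences, predictor profiles and
#' database records, plants one fully-penetrant heterozygous causal
#' missense variant (het in every affected member, hom_ref in every
#' unaffected member, absent from all databases, clean quality — so its
#' retention probability is 1 by construction), and assembles the
#' case-control panel.  The truth table records every site's expected
#' fate at each filter stage.
#'
#' @param config a [sim_config()]
#' @param dir optional directory: when given, the bundle files
#'   (`quartet.vcf`, `family.ped`, `targets.bed`, `annotations.tsv`,
#'   `popdb.tsv`, `panel.tsv`, `relatives.tsv`, `truth.tsv`) are written
#'   there via [write_bundle()]
#' @return a list of class `famvar_bundle` with elements `cohort`,
#'   `pedigree`, `targets`, `annotations`, `popdb`, `panel`,
#'   `relatives`, `truth`, `config`
#' @export
simulate_family_bundle <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  phase_seed <- sample.int(.Machine$integer.max, 8)  # per-phase substreams

  ped <- cfg$pedigree
  exome_ids <- c(role_ids(ped, "exome_case"), role_ids(ped, "exome_control"))
  rel_ids <- role_ids(ped, "relative")
  n <- cfg$n_variants

  ## -- sites ---------------------------------------------------------------
  set.seed(phase_seed[1])
  loc <- sample_positions(cfg)
  rare <- runif(n) < cfg$frac_rare
  af <- ifelse(rare,
               runif(n, cfg$rare_af_range[1], cfg$rare_af_range[2]),
               rbeta(n, cfg$common_af_shape[1], cfg$common_af_shape[2]))
  vclass <- ifelse(runif(n) < cfg$frac_indel,
                   sample(c("insertion", "deletion"), n, replace = TRUE), "SNV")
  al <- random_alleles(n, vclass)

  ## -- consequences & genes ------------------------------------------------
  set.seed(phase_seed[2])
  disrupting <- runif(n) < cfg$frac_disrupting
  consequence <- character(n)
  snv <- vclass == "SNV"
  consequence[disrupting & snv] <- sample(
    c("missense", "nonsense", "splice_site"), sum(disrupting & snv),
    replace = TRUE, prob = c(0.90, 0.06, 0.04))
  consequence[disrupting & !snv] <- sample(
    c("frameshift", "inframe_indel"), sum(disrupting & !snv),
    replace = TRUE, prob = c(0.7, 0.3))
  consequence[!disrupting] <- sample(
    c("synonymous", "intronic", "utr", "intergenic"), sum(!disrupting),
    replace = TRUE, prob = c(0.30, 0.40, 0.15, 0.15))
  gene <- sprintf("G%05d", sample.int(max(2L, n %/% 4L), n, replace = TRUE))

  ## -- database membership -------------------------------------------------
  set.seed(phase_seed[3])
  dbs <- names(cfg$db_membership$common)
  member <- sapply(dbs, function(d)
    runif(n) < ifelse(rare, cfg$db_membership$rare[[d]],
                      cfg$db_membership$common[[d]]))
  in_dbsnp <- member[, "dbSNP"]

  ## -- genotypes (Mendelian transmission) ----------------------------------
  set.seed(phase_seed[4])
  gt <- simulate_pedigree_genotypes(ped, af)

  ## -- causal plant ---------------------------------------------------------
  causal_idx <- which(loc$region == "target" & snv)[1]
  if (is.na(causal_idx)) stop("no in-target SNV available for the causal plant")
  rare[causal_idx] <- TRUE
  af[causal_idx] <- cfg$causal$af
  disrupting[causal_idx] <- TRUE
  consequence[causal_idx] <- "missense"
  gene[causal_idx] <- cfg$causal$gene
  member[causal_idx, ] <- FALSE
  in_dbsnp[causal_idx] <- FALSE
  gt[causal_idx, ] <- ifelse(ped$affected == "affected", 1L, 0L)

  ## -- quality noise over the exome samples --------------------------------
  set.seed(phase_seed[5])
  s <- length(exome_ids)
  draw <- function(fail_frac, fail_pool, pass_fun) {
    fail <- matrix(runif(n * s) < fail_frac, n, s)
    val <- matrix(pass_fun(n * s), n, s)
    val[fail] <- sample(fail_pool, sum(fail), replace = TRUE)
    val
  }
  gq <- draw(cfg$qc_fail[["gq"]], 0:19, function(m) 20 + rpois(m, 45))
  dp <- draw(cfg$qc_fail[["dp"]], 0:3,
             function(m) 4 + rpois(m, cfg$depth_mean - 4))
  cn <- draw(cfg$qc_fail[["cn"]], seq(2.05, 4, by = 0.05),
             function(m) round(runif(m, 0.5, 2), 2))
  nsd <- draw(cfg$qc_fail[["nsd"]], 0:4, function(m) sample(5:2000, m, TRUE))
  # the planted variant carries clean quality in every sample
  gq[causal_idx, ] <- 60; dp[causal_idx, ] <- 120
  cn[causal_idx, ] <- 1.0; nsd[causal_idx, ] <- 500

  geno_exome <- matrix(zyg_label(gt[, exome_ids]), n, s,
                       dimnames = list(NULL, exome_ids))
  indel_support <- indel_total <- matrix(NA_real_, n, s)
  ind <- which(!snv)
  for (j in seq_len(s)) {
    called <- ind[geno_exome[ind, j] != "hom_ref"]
    het <- called[geno_exome[called, j] == "het"]
    hom <- called[geno_exome[called, j] == "hom_alt"]
    indel_total[called, j] <- dp[called, j]
    indel_support[het, j] <- rbinom(length(het), dp[het, j], 0.5)
    indel_support[hom, j] <- rbinom(length(hom), dp[hom, j], 0.95)
  }

  sites <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = al$ref,
                      alt = al$alt, vclass = vclass, in_dbsnp = in_dbsnp,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  reord <- function(m) m[ord, , drop = FALSE]
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  for (v in c("af", "rare", "disrupting", "consequence", "gene"))
    assign(v, get(v)[ord])
  region <- loc$region[ord]
  gt <- reord(gt); geno_exome <- reord(geno_exome); member <- reord(member)
  gq <- reord(gq); dp <- reord(dp); cn <- reord(cn); nsd <- reord(nsd)
  indel_support <- reord(indel_support); indel_total <- reord(indel_total)
  causal_idx <- which(ord == causal_idx)
  id <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(id)) stop("internal error: duplicate simulated site ids")

  cohort <- variant_cohort(sites, exome_ids, geno_exome,
                           gq = gq, dp = dp, cn = cn, nsd = nsd,
                           indel_support = indel_support,
                           indel_total = indel_total)

  ## -- annotation & population tables --------------------------------------
  set.seed(phase_seed[6])
  ann <- data.frame(id = id, gene = gene, consequence = consequence,
                    codons = NA_character_, sift = NA_character_,
                    mutation_taster = NA_character_,
                    polyphen2 = NA_character_, pmut = NA_character_,
                    gerp = NA_real_, stringsAsFactors = FALSE)
  mis <- which(consequence == "missense")
  pick <- function(opts) {
    out <- sample(opts, length(mis), replace = TRUE)
    out[runif(length(mis)) < cfg$p_predictor_missing] <- NA
    out
  }
  ann$sift[mis] <- pick(c("DAMAGING", "TOLERATED"))
  ann$mutation_taster[mis] <- pick(c("disease_causing", "polymorphism"))
  ann$polyphen2[mis] <- pick(c("damaging", "benign"))
  ann$pmut[mis] <- pick(c("pathological", "neutral"))
  ann$gerp[disrupting] <- round(runif(sum(disrupting), -2, 6), 2)
  pr <- cfg$causal$profile
  ann$sift[causal_idx] <- pr$sift
  ann$mutation_taster[causal_idx] <- pr$mutation_taster
  ann$polyphen2[causal_idx] <- pr$polyphen2
  ann$pmut[causal_idx] <- pr$pmut
  ann$gerp[causal_idx] <- pr$gerp

  af_rec <- round(af, 6)   # frequency as recorded in the database tables
  pop_rows <- which(member, arr.ind = TRUE)
  popdb <- data.frame(
    chrom = sites$chrom[pop_rows[, 1]], pos = sites$pos[pop_rows[, 1]],
    ref = sites$ref[pop_rows[, 1]], alt = sites$alt[pop_rows[, 1]],
    db = dbs[pop_rows[, 2]], present = TRUE,
    af = ifelse(dbs[pop_rows[, 2]] == "YH", NA_real_, af_rec[pop_rows[, 1]]),
    stringsAsFactors = FALSE)
  popdb <- popdb[order(popdb$chrom, popdb$pos, popdb$db), , drop = FALSE]
  rownames(popdb) <- NULL
  popdb$id <- variant_id(popdb$chrom, popdb$pos, popdb$ref, popdb$alt)

  ## -- truth table ----------------------------------------------------------
  thr <- cfg$thresholds$af_reject_threshold
  db_reject <- member[, "dbSNP"] & af_rec > thr
  db_reject <- db_reject | (member[, "KG1000"] & af_rec > thr)
  db_reject <- db_reject | (member[, "HapMap"] & af_rec > thr)
  db_reject <- db_reject | member[, "YH"]
  truth <- data.frame(
    id = id, chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
    alt = sites$alt, vclass = sites$vclass, gene = gene,
    af = af_rec, rare = rare, region = region,
    consequence = consequence, disrupting = disrupting,
    in_dbsnp = sites$in_dbsnp, db_reject = db_reject,
    causal = seq_len(n) == causal_idx, stringsAsFactors = FALSE)

  ## -- validation relatives & case-control panel ---------------------------
  set.seed(phase_seed[7])
  candidate_pool <- which(disrupting & !db_reject & region != "off")
  relatives <- data.frame(
    id = rep(id[candidate_pool], each = length(rel_ids)),
    sample = rep(rel_ids, length(candidate_pool)),
    geno = zyg_label(as.integer(t(gt[candidate_pool, rel_ids, drop = FALSE]))),
    stringsAsFactors = FALSE)

  set.seed(phase_seed[8])
  groups <- rep(c("case", "uc", "control"), cfg$panel_n)
  panel_samples <- sprintf("%s%03d", toupper(groups),
                           unlist(lapply(cfg$panel_n, seq_len)))
  panel <- do.call(rbind, lapply(candidate_pool, function(i) {
    g <- zyg_label(rbinom(length(panel_samples), 2L, af[i]))
    if (i == causal_idx) {
      g[] <- "hom_ref"
      for (grp in c("case", "uc", "control")) {
        k <- cfg$causal[[paste0("panel_", grp, "_carriers")]]
        if (k > 0) g[which(groups == grp)[seq_len(k)]] <- "het"
      }
    }
    data.frame(id = id[i], sample = panel_samples, group = groups, geno = g,
               stringsAsFactors = FALSE)
  }))

  bundle <- structure(list(
    cohort = cohort, pedigree = ped, targets = loc$targets,
    annotations = ann, popdb = popdb, panel = panel,
    relatives = relatives, truth = truth, config = cfg),
    class = "famvar_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.famvar_bundle <- function(x, ...) {
  cat("famvar_bundle:", n_sites(x$cohort), "sites,",
      nrow(x$pedigree), "pedigree members,",
      length(unique(x$panel$sample)), "panel subjects\n")
  cat("  causal:", x$truth$id[x$truth$causal], "\n")
  invisible(x)
}

#' Write a simulated bundle to disk as plain-text standard formats
#' @param bundle a `famvar_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_variants(bundle$cohort, file.path(dir, "quartet.vcf"))
  write_pedigree(bundle$pedigree, file.path(dir, "family.ped"))
  write_targets(bundle$targets, file.path(dir, "targets.bed"))
  tsv(bundle$annotations, "annotations.tsv")
  tsv(bundle$popdb, "popdb.tsv")
  tsv(bundle$panel, "panel.tsv")
  tsv(bundle$relatives, "relatives.tsv")
  tsv(bundle$truth, "truth.tsv")
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir bundle directory
#' @param roles role assignment for the pedigree; default matches
#'   [family_a_pedigree()]
#' @return a `famvar_bundle` (without a config; `truth` only if present)
#' @export
read_bundle <- function(dir, roles = NULL) {
  ped_raw <- read.table(file.path(dir, "family.ped"), stringsAsFactors = FALSE)
  if (is.null(roles)) {
    ids <- as.character(ped_raw[[2]])
    roles <- list(
      exome_case = intersect(c("FATHER", "DAUGHTER"), ids),
      exome_control = intersect(c("MOTHER", "GRANDMOTHER"), ids),
      relative = grep("^REL", ids, value = TRUE))
  }
  truth_path <- file.path(dir, "truth.tsv")
  structure(list(
    cohort = read_variants(file.path(dir, "quartet.vcf")),
    pedigree = read_pedigree(file.path(dir, "family.ped"), roles),
    targets = as.data.frame(read_targets(file.path(dir, "targets.bed")))[
      , c("seqnames", "start", "end")] |>
      stats::setNames(c("chrom", "start", "end")),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    popdb = read_popdb(file.path(dir, "popdb.tsv")),
    panel = read_panel(file.path(dir, "panel.tsv")),
    relatives = read.delim(file.path(dir, "relatives.tsv"),
                           stringsAsFactors = FALSE),
    truth = if (file.exists(truth_path))
      read.delim(truth_path, stringsAsFactors = FALSE),
    config = NULL), class = "famvar_bundle")
}
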