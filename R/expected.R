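#' Closed-form expected survivor counts under the generative model
#'
#' Analytic companion to [simulate_family_bundle()]: for each pipeline
#' stage, the expected number of surviving variants and its binomial
#' standard error.  Because sites are drawn i.i.d. from the configured
#' mixture, each stage count of passenger sites is Binomial(n-1, r) with
#' r the per-site marginal retention probability; the planted causal
#' variant adds a deterministic +1 to case-sample and shared streams
#' (its retention probability is 1 by construction).  Marginal genotype
#' distributions are Hardy-Weinberg at the site AF for every pedigree
#' member, and the probability that a passenger is carried by both
#' cases and homozygous-reference in both sequenced controls is
#' p(1-p)^4/2 for the built-in quartet (father's father unobserved).
#' The AF mixture is integrated on a fine grid; indel no-call
#' probabilities are enumerated exactly over the low-depth branch of
#' the quality model (the high-depth branch contributes negligibly and
#' is taken as zero).
#'
#' Only the [family_a_pedigree()] shape (2 exome cases = father +
#' daughter, 2 exome controls = mother + grandmother) is supported.
#'
#' @param config a [sim_config()]
#' @param n_grid grid size per mixture component for the AF integral
#' @return data.frame: `stage`, `stream` (`per_sample` or `shared`),
#'   `expected_case`, `expected_control` (NA for shared stages),
#'   `se` (binomial SE of the passenger count)
#' @export
expected_survivors <- function(config, n_grid = 500) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ped <- cfg$pedigree
  if (!setequal(role_ids(ped, "exome_case"), c("FATHER", "DAUGHTER")) ||
      !setequal(role_ids(ped, "exome_control"), c("MOTHER", "GRANDMOTHER")))
    stop("expected_survivors supports only the family_a_pedigree shape")
  n_rel <- length(role_ids(ped, "relative"))
  thr <- cfg$thresholds$af_reject_threshold
  f <- cfg$qc_fail
  r_region <- 1 - cfg$frac_offtarget
  f_dis <- cfg$frac_disrupting
  f_ind <- cfg$frac_indel

  # indel no-call probability, enumerated over the low-depth failure branch
  lo <- cfg$thresholds$het_fraction_lo
  nocall <- function(pr) {
    per_d <- vapply(0:3, function(d) {
      if (d == 0) return(1)
      x <- 0:d
      sum(stats::dbinom(x, d, pr)[x / d < lo])
    }, numeric(1))
    f[["dp"]] * mean(per_d)
  }
  a_het_ind <- 1 - nocall(0.5)
  a_hom_ind <- 1 - nocall(0.95)

  # mixture grid: list of (p, w, membership) blocks
  grid_block <- function(p, w, memb) list(p = p, w = w, m = memb)
  mids <- function(a, b) a + (seq_len(n_grid) - 0.5) * (b - a) / n_grid
  p_r <- mids(cfg$rare_af_range[1], cfg$rare_af_range[2])
  p_c <- mids(0, 1)
  dens <- dbeta(p_c, cfg$common_af_shape[1], cfg$common_af_shape[2])
  blocks <- list(
    grid_block(p_r, rep(cfg$frac_rare / n_grid, n_grid),
               cfg$db_membership$rare),
    grid_block(p_c, (1 - cfg$frac_rare) * dens / sum(dens),
               cfg$db_membership$common))

  stage_names <- c("total_calls", "on_target", "quality_passing",
                   "protein_disrupting", "dbSNP", "dbSNP+KG1000",
                   "dbSNP+KG1000+HapMap", "dbSNP+KG1000+HapMap+YH")
  r_per <- setNames(numeric(10), c(stage_names, "dominant_shared",
                                   "cosegregation"))
  for (bl in blocks) {
    p <- bl$p; w <- bl$w; m <- bl$m
    common_reject <- as.numeric(p > thr)      # recorded AF = true AF
    p_het <- 2 * p * (1 - p); p_hom <- p^2
    p_call <- p_het + p_hom
    qc_pass_iv0 <- (1 - f[["gq"]]) * (1 - f[["dp"]]) * (1 - f[["cn"]])
    qc_snv_in <- qc_pass_iv0                       # in dbSNP: iv waived
    qc_snv_out <- qc_pass_iv0 * (1 - f[["nsd"]])
    act_ind <- p_het * a_het_ind + p_hom * a_hom_ind
    db_tail <- (1 - m[["KG1000"]] * common_reject) *
      (1 - m[["HapMap"]] * common_reject) * (1 - m[["YH"]])

    # per-sample stream: dbSNP-membership branches for SNVs
    acc <- function(stage_probs) sum(w * stage_probs)
    snv_branch <- function(qc, dbsnp_keep) {
      c3 <- p_call * r_region * qc
      c4 <- c3 * f_dis
      c5 <- c4 * dbsnp_keep
      list(c3 = c3, c4 = c4, c5 = c5,
           c6 = c5 * (1 - m[["KG1000"]] * common_reject),
           c7 = c5 * (1 - m[["KG1000"]] * common_reject) *
                (1 - m[["HapMap"]] * common_reject),
           c8 = c5 * (1 - m[["KG1000"]] * common_reject) *
                (1 - m[["HapMap"]] * common_reject) * (1 - m[["YH"]]))
    }
    b_in <- snv_branch(qc_snv_in, 1 - common_reject)
    b_out <- snv_branch(qc_snv_out, 1)
    mix_snv <- function(k) m[["dbSNP"]] * b_in[[k]] + (1 - m[["dbSNP"]]) * b_out[[k]]
    ind_c3 <- act_ind * r_region
    ind_c4 <- ind_c3 * f_dis
    ind_c5 <- ind_c4 * (1 - m[["dbSNP"]] * common_reject)
    ind_stream <- list(c3 = ind_c3, c4 = ind_c4, c5 = ind_c5,
                       c6 = ind_c5 * (1 - m[["KG1000"]] * common_reject),
                       c7 = ind_c5 * (1 - m[["KG1000"]] * common_reject) *
                            (1 - m[["HapMap"]] * common_reject),
                       c8 = ind_c5 * db_tail)
    r_per["total_calls"] <- r_per["total_calls"] + acc(p_call)
    r_per["on_target"] <- r_per["on_target"] + acc(p_call * r_region)
    for (k in 3:8) {
      nm <- stage_names[k]
      r_per[nm] <- r_per[nm] +
        acc((1 - f_ind) * mix_snv(paste0("c", k)) +
            f_ind * ind_stream[[paste0("c", k)]])
    }

    # shared stream: both cases het carriers, both controls hom_ref
    p_quartet <- p * (1 - p)^4 / 2
    dom_snv <- m[["dbSNP"]] * qc_snv_in^2 * (1 - common_reject) +
      (1 - m[["dbSNP"]]) * qc_snv_out^2
    dom_ind <- a_het_ind^2 * (1 - m[["dbSNP"]] * common_reject)
    dom <- p_quartet * r_region * f_dis * db_tail *
      ((1 - f_ind) * dom_snv + f_ind * dom_ind)
    r_per["dominant_shared"] <- r_per["dominant_shared"] + acc(dom)
    r_per["cosegregation"] <- r_per["cosegregation"] +
      acc(dom * (1 - p)^(2 * n_rel))
  }

  n_pass <- cfg$n_variants - 1          # one site is replaced by the plant
  shared <- names(r_per) %in% c("dominant_shared", "cosegregation")
  data.frame(
    stage = names(r_per),
    stream = ifelse(shared, "shared", "per_sample"),
    expected_case = n_pass * r_per + 1,             # + planted causal
    expected_control = ifelse(shared, NA, n_pass * r_per),
    se = sqrt(n_pass * r_per * (1 - r_per)),
    row.names = NULL)
}
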