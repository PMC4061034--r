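#' Screen a genotype panel for carriers and allele counts
#'
#' A carrier holds at least one alternate allele; a het contributes one
#' alternate allele and a hom_alt two.  Missing genotypes are excluded
#' from all denominators and reported.
#'
#' @param case_geno,control_geno character vectors of panel genotypes
#'   (hom_ref/het/hom_alt/missing)
#' @return list: `case_carriers`, `control_carriers`, `case_alt`,
#'   `case_alleles`, `control_alt`, `control_alleles`, `n_missing`,
#'   `degenerate` (TRUE when a denominator is zero)
#' @export
screen_panel <- function(case_geno, control_geno) {
  count <- function(g) {
    g <- g[!is.na(g)]
    miss <- sum(g == "missing")
    g <- g[g != "missing"]
    list(carriers = sum(g %in% c("het", "hom_alt")),
         alt = sum(g == "het") + 2L * sum(g == "hom_alt"),
         alleles = 2L * length(g), missing = miss)
  }
  ca <- count(case_geno); co <- count(control_geno)
  list(case_carriers = ca$carriers, control_carriers = co$carriers,
       case_alt = ca$alt, case_alleles = ca$alleles,
       control_alt = co$alt, control_alleles = co$alleles,
       n_missing = ca$missing + co$missing,
       degenerate = ca$alleles == 0 || co$alleles == 0)
}

#' Basic allelic chi-square association test
#'
#' The 1-df allelic test on the case/control x alt/ref allele-count
#' table, without continuity correction (the convention of PLINK's basic
#' `--assoc`): `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.  The
#' odds ratio is `ad / bc`; with a zero cell the Haldane-Anscombe +0.5
#' correction is applied to all cells and reported as corrected.  A
#' table with any zero margin (e.g. a monomorphic variant) is not
#' testable and returns a missing p with a reason.
#'
#' @param t a [contingency_2x2()] (a = case alt, b = case ref,
#'   c = control alt, d = control ref)
#' @return list: `chi2`, `df`, `p`, `odds_ratio`, `or_corrected`,
#'   `reason` (NA unless not applicable)
#' @export
allelic_chisq <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                odds_ratio = NA_real_, or_corrected = FALSE,
                reason = "zero margin: test not applicable"))
  }
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  if (a * d == 0 || b * c == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    corrected <- TRUE
  } else {
    or <- (a * d) / (b * c)
    corrected <- FALSE
  }
  list(chi2 = chi2, df = 1L, p = p, odds_ratio = or,
       or_corrected = corrected, reason = NA_character_)
}

#' Fisher exact test by hypergeometric enumeration
#'
#' Enumerates every 2x2 table with the observed margins.  The two-sided
#' p sums the probabilities of all tables no more probable than the
#' observed one; the one-sided p is the smaller of the two exact tail
#' probabilities `P(A <= a)` and `P(A >= a)` of the upper-left cell.
#'
#' @param t a [contingency_2x2()]
#' @param sided `"two"` (default) or `"one"`
#' @return exact p-value
#' @export
fisher_exact <- function(t, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; r2 <- c + d; k <- a + c
  support <- max(0, k - r2):min(k, r1)
  probs <- dhyper(support, r1, r2, k)
  p_obs <- probs[match(a, support)]
  if (sided == "two") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(lower, upper)
  }
  min(p, 1)
}
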