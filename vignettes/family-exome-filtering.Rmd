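---
title: "Family-based exome variant filtering: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome variant filtering: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem

When a rare, strongly penetrant variant segregates with disease in a small
family, exome sequencing of a handful of members can localize it without the
large pedigrees classical linkage needs. The design famvar implements is the
two-affected / two-unaffected quartet: a proband and a second affected
relative are sequenced as *cases*, two unaffected members as *controls*, and
a cascade of filters whittles ~10^5 called variants per exome down to a
handful of candidates, which are then validated by re-genotyping additional
relatives (co-segregation) and screened in a sporadic case-control panel.

famvar re-implements that cascade as composable, tested stages with an audit
trail (per-stage survivor counts per sample), plus a seeded generator that
produces complete synthetic input bundles so the whole pipeline can be
exercised end to end with no external data.

## The filtering model

A variant site enters as a biallelic (chrom, pos, ref, alt) record with
per-sample zygosity and quality fields. The stages, in order:

1. **Capture-target restriction.** Variant detection is only reliable inside
   the enriched regions; sites outside any target interval expanded by
   `target_flank_bp` (default 200 bp, both endpoints inclusive) are dropped.
2. **SNV quality control.** A SNV call is discarded if *any* of four
   criteria holds: (i) genotype quality < 20; (ii) covering reads < 4;
   (iii) estimated copy number > 2; (iv) distance to the nearest SNP < 5 bp
   — with (iv) waived for sites already catalogued in dbSNP. The criteria
   are evaluated in order (i)→(iv) and the first failure is recorded; since
   one failing criterion suffices to discard, the order affects only the
   audit label, never the outcome (tested).
3. **Indel zygosity from read support.** With supporting-read fraction
   f = supporting/total: f ∈ [0.30, 0.70] is heterozygous, f > 0.70
   homozygous, f < 0.30 a no-call (dropped, counted). The het band is
   closed on both ends: "30–70%" is read inclusively, and "> 70%" fixes the
   hom side as exclusive of 0.70 — the only reading consistent with both
   phrases. No third genotype class exists for indels, so sub-band
   fractions are no-calls rather than reference calls.
4. **Consequence exclusion.** Intergenic, intronic, UTR and synonymous
   variants are excluded; missense, nonsense, stoploss, splice-site
   (± 2 bp of an internal CDS edge, the canonical donor/acceptor
   dinucleotides), frameshift and in-frame indels are retained as
   "protein-disrupting". Consequences normally arrive as an annotation
   column; for SNVs a built-in minimal classifier over a transcript model
   (ordered CDS intervals + spliced sense-strand sequence, standard genetic
   code, reverse-complemented for minus-strand genes) can compute them, and
   is verified against whole-protein translation in the tests.
5. **Population-database cascade.** In order dbSNP → 1000 Genomes → HapMap
   → YH, a variant is rejected if it is present with allele frequency
   *strictly above* 0.5%. YH is a single personal genome and carries no
   population frequency, so presence alone rejects there — we read the
   frequency exception as exempting YH from the frequency *condition*, not
   from the rejection. A presence record with unknown AF in a frequency
   database retains the variant and is flagged indeterminate. Each
   rejection is a per-variant predicate, so the final survivor set is
   order-invariant; only the intermediate counts depend on the order
   (tested by permutation). An optional fifth "inhouse" stage exists but is
   off by default, since in-house/EVS occurrence is a prioritization input,
   not a rejection rule.
6. **Dominant-model shared filter.** Retain exactly the variants carried
   (het or hom-alt) by *every* case and homozygous-reference in *every*
   control — "absent" is read strictly: a het or hom-alt control excludes
   the variant. A missing genotype in any listed member drops the variant
   under the default `strict` policy (validation re-genotyping resolves
   such sites anyway); `permissive` retains it flagged.
7. **Co-segregation.** A candidate passes iff no unaffected relative
   carries the alternate allele; failures name the carriers. Relatives with
   unknown affection are excluded (logged); zero usable relatives passes
   vacuously with a warning.
8. **Prioritization.** The original study ranked genes with four web
   services trained on known susceptibility genes — irreproducible offline.
   famvar replaces this with a transparent consensus: damaging votes among
   SIFT / MutationTaster / PolyPhen-2 / PMut over the non-missing calls,
   plus a conservation bonus when GERP ≥ 4.0, ordered by
   (absent-from-control-panel, score, GERP, gene symbol). The GERP cutoff
   and the 0.25 bonus weight are artifact choices, configurable, and the
   ordering is a deterministic total order (tested by permutation).
9. **Association.** For each final candidate, the 2×2 allele-count table
   (case alt/ref vs control alt/ref) is tested with the basic allelic
   chi-square without continuity correction,
   χ² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)) on 1 df — the convention of
   PLINK's plain `--assoc`, which the study names without options — plus an
   exact companion test by full hypergeometric enumeration. Odds ratios
   with a zero cell use the Haldane–Anscombe +0.5 correction, reported as
   corrected. Tables with a zero margin are declared not testable rather
   than given a p of 1.

### The association cohort reconstruction

The published claim is that the nominated variant reached P < 0.05 in a
PLINK analysis, with one carrier among 278 sporadic CD cases and none among
401 healthy controls. A 1-vs-0 carrier table cannot reach 0.05 by any 2×2
test, so the tested cohort must have included the two exome-sequenced
familial carriers: 280 cases contributing 3 alternate alleles among 560
versus 0 among 802 control alleles gives χ² = 4.306, p = 0.038 < 0.05.
`run_pipeline()` therefore appends the familial cases' alleles to the case
panel by default (`include_familial_cases = TRUE`); the reconstruction is a
documented reading, not a published table.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_genotype_quality` | 20 | phred | QC criterion (i) |
| `min_depth` | 4 | reads | QC criterion (ii) |
| `max_copy_number` | 2 | copies | QC criterion (iii) |
| `min_snp_distance_bp` | 5 | bp | QC criterion (iv), waived in dbSNP |
| `af_reject_threshold` | 0.005 | fraction | database rejection, strict `>` |
| `het_fraction_lo/hi` | 0.30 / 0.70 | fraction | closed indel het band |
| `target_flank_bp` | 200 | bp | detection extends this far off-target |
| `gerp_conserved_threshold` | 4.0 | GERP RS | conservation flag (artifact choice) |
| `conservation_weight` | 0.25 | score | consensus bonus (artifact choice) |
| `splice_window` | 2 | bp | canonical splice dinucleotides |

All are carried in `qc_thresholds()` / `pipeline_config()` and recorded in
the run log, so a run is reproducible from its log.

## What the simulator emulates — and what it does not

`simulate_family_bundle()` draws a stated world chosen once and documented
here; none of its defaults were tuned against test outcomes.

* **Scale.** 2,000 segregating sites at desk scale (the full-exome analogue
  is ~115,000 quality-passing SNVs; tests scale down for runtime, and the
  per-site model is scale-free).
* **AF spectrum.** A site is "rare" with probability 0.15 (AF uniform on
  [10⁻⁴, 0.005], below the rejection threshold) and otherwise common with
  AF ~ Beta(5, 2), skewed high. 12.5% of sites are protein-disrupting
  (~14.5k of ~116k in the emulated design) and 6% are indels (~7.5k vs
  ~117k).
* **Database membership**, per class: common sites are in dbSNP with
  probability 0.85, 1000 Genomes 0.32, HapMap 0.0015, YH 0.025; rare sites
  0.10 / 0.02 / 0.001 / 0.005. These are calibrated so the cascade removes
  mass in the proportions the emulated study reports per stage (dbSNP
  removes ~85% of protein-disrupting variants, +1000G ~32% of the
  remainder, +HapMap ~0.1%, +YH ~2.5%). Recorded database AFs equal the
  true simulation AFs.
* **Quality noise.** Marginal failure fractions gq 0.15, dp 0.08, cn 0.06,
  nsd 0.04 — jointly ~70% of calls pass, matching the reported
  quality-passing/total ratio; passing depth is 4 + Poisson(146) around the
  reported ~130–200× means. Indel read support is Binomial(depth, 0.5) for
  het and Binomial(depth, 0.95) for hom calls — standard sampling models,
  stated here because the source design reports none.
* **Genotypes.** Founders are Hardy–Weinberg at the site AF; children
  receive one allele from each parent; unobserved parents (the proband's
  father) are integrated out by drawing their transmitted allele from the
  AF. Every non-causal trio genotype passes the Mendelian screen
  (generator-correctness test).
* **The plant.** One in-target missense SNV, absent from all databases,
  heterozygous in every affected member, hom-ref in every unaffected member
  (relatives included), with clean quality fields — so its retention
  probability is 1 by construction, and its predictor profile (default:
  all four damaging, GERP 5.2) and panel carriers (default: one sporadic
  case, no controls) are configuration, not information leaked to the
  filters. Passenger predictor profiles are drawn independently of
  causality; only the truth table distinguishes the plant.
* **Not emulated:** reads (no FASTQ, no error model), linkage
  disequilibrium between sites, population stratification, penetrance
  below 1, relatedness among panel subjects, and real chromosome geometry
  (targets are synthetic, evenly spaced). A green parameter-recovery test
  therefore establishes that the pipeline recovers a fully penetrant
  dominant variant under clean Mendelian transmission — not that it would
  under incomplete penetrance or cryptic relatedness.

`expected_survivors()` is the analytic companion: per-stage retention
probabilities integrated over the AF mixture on a fine grid (the only
approximations are the neglected O(10⁻⁷) high-depth indel no-call term and
grid quadrature), with the quartet-sharing probability p(1−p)⁴/2 in closed
form. Because sites are i.i.d. draws from the mixture, each passenger stage
count is exactly Binomial(n−1, r), which supplies the standard errors the
tests use. It supports only the built-in quartet shape and says so.

## Numerical and policy choices

* Coordinates are 1-based inclusive throughout (VCF convention); BED input
  is converted at the reader boundary.
* Multi-allelic VCF records are decomposed into one biallelic site per
  alternate allele before any filtering; every rule is stated per variant.
* Quality FORMAT keys are mapped via configuration (`default_format_map()`),
  since caller-specific fields (copy number, nearest-SNP distance) have no
  reserved VCF tags. A remapped key absent from the header is a
  configuration error; an absent *default* optional key is a warning and
  the field is missing. Missing values needed by a QC criterion fail that
  criterion by default (conservative), switchable to pass.
* UTR vs intronic cannot be distinguished by the minimal transcript model;
  both are excluded classes, so in-gene noncoding positions collapse to one
  label when no annotation column supplies the distinction. When both a
  provided consequence column and a transcript model exist, the provided
  column wins (the original annotations came from gene-model databases this
  package does not reimplement).
* The exact test's "one-sided" p is the smaller of the two exact tail
  probabilities, which guarantees one-sided ≤ two-sided under the
  probability-mass two-sided definition.
* Ranking tie-breaks end at the gene symbol, making the order total and
  run-to-run stable; undefined consensus scores (all predictors missing)
  rank last and are flagged rather than imputed.
* One seed governs all simulator randomness; per-phase substreams are
  derived from it so the bundle is byte-identical across runs and file
  ordering is canonical (chrom, pos, ref, alt).

## Known limitations

* Only the autosomal dominant, fully penetrant model is implemented — no
  recessive, compound-het or X-linked filters, and no penetrance parameter:
  the emulated design never states one, and its validation family with
  unaffected carriers shows the question is real but unanswerable here.
* Indel consequences are consumed from annotation, never computed.
* The consequence classifier handles one transcript per gene; no
  multi-transcript arbitration.
* No liftover, no reference-genome validation of ref alleles, no phasing,
  no genome-wide association machinery or multiple-testing correction (one
  candidate variant is tested, as in the emulated design).
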