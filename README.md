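# famvar — family-based exome variant filtering and prioritization

famvar is for statistical geneticists and bioinformaticians who need a
tested, reproducible implementation of the classic small-pedigree exome
filtering strategy: sequence two affected and two unaffected members of a
disease family, and reduce ~10⁵ called variants per exome to a short list
of rare, dominant candidate variants, validated by co-segregation in
additional relatives and screened in a sporadic case-control panel.

## The model

Each stage is a retention predicate applied in cascade, with per-sample
survivor counts recorded at every step:

1. **Target restriction** — keep sites within a capture interval ± 200 bp.
2. **Quality control** — discard SNV calls with genotype quality < 20,
   depth < 4, estimated copy number > 2, or a SNP within 5 bp (waived for
   dbSNP sites). Indels are genotyped from the supporting-read fraction f:
   het for f ∈ [0.30, 0.70], hom for f > 0.70, otherwise no call.
3. **Consequence** — keep protein-disrupting classes (missense, nonsense,
   stoploss, splice-site, frameshift, in-frame indel); drop intergenic,
   intronic, UTR and synonymous.
4. **Population databases** — reject variants present in dbSNP, 1000
   Genomes or HapMap with allele frequency > 0.5%, or present at all in the
   YH personal genome.
5. **Dominant family filter** — keep variants with zygosity ∈ {het,
   hom-alt} in *all* affected exomes and hom-ref in *all* unaffected
   exomes.
6. **Co-segregation** — a candidate fails if any unaffected relative
   carries the alternate allele.
7. **Consensus ranking** — damaging-vote fraction over
   SIFT/MutationTaster/PolyPhen-2/PMut plus a GERP ≥ 4 conservation bonus,
   ordered by absence from the healthy-control panel, then score, GERP and
   gene symbol.
8. **Association** — basic allelic chi-square on the case/control allele
   table, χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), df = 1, without
   continuity correction, plus an exact test by hypergeometric enumeration
   and a Haldane–Anscombe-corrected odds ratio.

A seeded simulator generates complete synthetic input bundles (multi-sample
VCF, PED pedigree, BED targets, annotation / population / panel TSVs) with
Mendelian transmission and one planted causal variant, so every stage and
the end-to-end run are testable offline. `expected_survivors()` provides
closed-form expected counts per stage for calibration checks.

## Worked example

```r
library(famvar)
bundle <- simulate_family_bundle(sim_config(seed = 42))
run <- run_pipeline(bundle)
print(run)
```

```
famvar pipeline run
-------------------
                  stage FATHER DAUGHTER GRANDMOTHER MOTHER shared
            total_calls   1545     1535        1546   1533     NA
              on_target   1527     1518        1532   1515     NA
        quality_passing   1121     1133        1127   1114     NA
     protein_disrupting    139      135         149    135     NA
                  dbSNP     26       22          26     19     NA
           dbSNP+KG1000     20       15          17     14     NA
    dbSNP+KG1000+HapMap     20       15          17     14     NA
 dbSNP+KG1000+HapMap+YH     20       15          17     14     NA
        dominant_shared     NA       NA          NA     NA      1
          cosegregation     NA       NA          NA     NA      1

final candidates: 1
 rank    gene                id score control_carriers
    1 GCAUSAL chr13_1201448_G_A  1.25                0

association (top candidate):
                id    gene a   b c   d     chi2   p_chisq odds_ratio  p_fisher
 chr13_1201448_G_A GCAUSAL 3 557 0 802 4.305913 0.0379801   10.07623 0.0692883
```

Reading the output: each exome starts with ~1,540 called variants; target
restriction, quality control, the protein-disrupting filter and the
four-database cascade reduce each sample's stream to ~15–20; the dominant
family filter leaves exactly the planted causal variant, which co-segregates
(no unaffected relative carries it), ranks first (all-damaging predictor
profile, conserved, absent from the control panel), and reaches allelic
significance: 3 alternate alleles among 560 case alleles vs 0 among 802
control alleles gives χ² = 4.31, p = 0.038, with an exact-test p of 0.069.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/famvar simulate --seed 1 --n-variants 2000 --out bundle/
Rscript inst/cli/famvar run --bundle bundle/ --out results/
Rscript inst/cli/famvar assoc --a 3 --b 557 --c 0 --d 802
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantity from
scratch with the installed package: it assembles the bundled 22-candidate
example table, builds the validation genotype matrix in which one of ten
unaffected relatives carries the KLF4 variant, runs the co-segregation
check, and writes the count of passing candidates as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/family-exome-filtering.Rmd`) documents the
filtering rules and their edge conventions, the simulator's generative
model and what it does and does not emulate, the association-cohort
reconstruction, and known limitations.
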