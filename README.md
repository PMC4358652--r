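# varprior

Ranking the handful of plausibly causal variants out of the thousands of
SNVs and small indels called in a sequencing study is the daily bottleneck
of molecular diagnostics and disease-gene discovery. `varprior` is an R
package for exactly that step: it reads cohort VCF files, consumes
per-transcript annotations (a generic tab-separated annotation table or
SnpEff `ANN` strings), assigns every variant an integer pathogenicity
score, summarizes carrier status across the cohort in a zygosity
*barcode*, applies a quality/frequency filter cascade, and writes ranked
per-variant and per-gene reports for each sample.

## The scoring scheme

Each variant is annotated on **all** transcripts; per transcript both the
coding effect and the splice effect are scored and the more pathogenic
pathway wins, then the most pathogenic transcript is retained (the
reported transcript is the gene's longest unless another one scores
strictly higher). Base scores by category:

| Category                 | Score | Adjusted |
|--------------------------|-------|----------|
| known mutation           | 110   | —        |
| nonsense                 | 100   | 105      |
| frameshift               | 100   | —        |
| essential splice site    | 90    | 95       |
| start loss / stop loss   | 80    | 85       |
| intron–exon boundary     | 70    | 75       |
| missense                 | 50    | 55/60/65 |
| in-frame indel           | 40    | —        |
| deep intronic (splicing) | 25    | 30       |
| synonymous               | 10    | 15       |

"Adjusted" adds +5 when phastCons > 0.95; missense additionally gains +5
per deleterious protein prediction (SIFT and/or PolyPhen-2). A variant
whose dbSNP clinical significance is pathogenic/probable-pathogenic (or
whose id is in a user-supplied known-mutation list) scores 110 outright.

Splice effects use three programs (MaxEntScan, NNSplice,
SpliceSiteFinder): a variant affects splicing when at least two of the
three report a score drop of at least 10%, 5% and 15% respectively.
Positionally, the two first intronic bases are *essential* (90, no
consensus required); the donor −3..+6 / acceptor −12..+2 windows are
*intron–exon boundary* (70); intronic positions beyond them are *deep*
(25).

The cohort **barcode** is one digit per sample — `0` hom-ref, `1` het,
`2` hom-alt — in a fixed (lexicographic) sample order, with derived
`Hom_Count`/`Het_Count`/`Allele_Count` columns; a *family barcode*
restricts it to a user-ordered subset (`"121"`: homozygous proband with
heterozygous parents; `"010"`: candidate de novo). Default filters remove
calls with total depth ≤ 10, supporting reads ≤ 10, supporting-read ratio
≤ 15%, dbSNP-validated benign variants (≥ 2 evidences), and variants with
any population allele frequency > 1%; known-pathogenic variants are
exempt from the two annotation-based rules.

## Worked example

The built-in simulator generates a cohort with a known causal spike —
here 4 samples, 50 common background polymorphisms, and one private
homozygous nonsense mutation (at a conserved position) in sample `S02`:

```r
library(varprior)

sim <- simulate_cohort(
  simulation_config(n_samples = 4, n_background_variants = 50,
                    spikes = tibble::tibble(sample = "S02",
                                            category = "nonsense",
                                            zygosity = 2L, conserved = TRUE),
                    seed = 2024),
  dir = "demo")

cohort <- read_cohort(sim$vcf_path)
#> cohort: 51 variant(s), 4 sample(s), 102 carrier call(s)
ann <- read_annotation_table(sim$annotation_path)
fit <- prioritize(cohort, ann)
fit
#> Variant prioritization: 51 variant(s) x 4 sample(s)
#> Top variants:
#> # A tibble: 5 x 5
#>   variant_id      gene    category final_score barcode
#>   <chr>           <chr>   <chr>          <int> <chr>
#> 1 5_44159123_C_G  SPIKE01 nonsense         105 0200
#> 2 14_47455070_A_T GENE270 missense          50 0000
#> 3 1_47153030_A_C  GENE147 missense          50 1011
#> 4 7_46002630_C_T  GENE115 missense          50 1010
#> 5 20_40500357_T_C GENE127 missense          50 1001
```

The spiked nonsense scores 105 (base 100 + conservation adjustment) and
its barcode `0200` shows a single homozygous carrier — `S02`. After the
default filter cascade (which removes the common, dbSNP-validated
background), it is the only variant left in `S02`'s filtered ranking:

```r
rank_by_variant(cohort, fit$scored, "S02", filtered = TRUE)[
  , c("variant_id", "gene", "category", "final_score", "rank")]
#> # A tibble: 1 x 5
#>   variant_id     gene    category final_score  rank
#>   <chr>          <chr>   <chr>          <int> <int>
#> 1 5_44159123_C_G SPIKE01 nonsense         105     1
```

`glance(fit)` summarizes the run (51 variants, 102 carrier calls, 1
passing the cascade, top score 105); `tidy(fit)` returns the full ranked
table; `autoplot(fit)` plots the score spectrum by category.
`write_reports(cohort, fit$scored, "reports/")` writes the four
tab-separated files per sample
(`<sample>.{AllVariants,filteredVariants}.rankingBy{Var,Gene}.tsv`) plus
a per-category count summary. A command-line front end with the same
options (`-vcf`, `-ann`, `-fam`, `-extann`, filter and score overrides)
is installed as `exec/varprior`.

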