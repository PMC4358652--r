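---
title: "Scoring, filtering and ranking variants with varprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, filtering and ranking variants with varprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprior)
```

## The problem and the model

Targeted, exome or genome sequencing of a patient yields hundreds to
thousands of SNVs and small indels, of which at most one or two are the
causal mutation. `varprior` ranks them with a *category* score: rather
than estimating a pathogenicity probability, it encodes the triage rules
a molecular geneticist applies by hand — a truncating variant outranks a
missense, a canonical splice-site change outranks a boundary change, a
variant already reported pathogenic outranks everything — as a fixed
integer scale that makes reports sortable and reproducible.

Every variant is annotated on **all** transcripts. Per transcript, two
pathways are scored independently and the larger wins:

* **coding pathway** — the annotated coding effect, mapped to base
  scores: nonsense and frameshift 100, start/stop loss 80, missense 50,
  in-frame indel 40, synonymous 10. This captures e.g. the SNV at an
  exon's last base that is simultaneously a missense and a splice-site
  disruption: the splice pathway (90) then overrides the missense (50).
* **splice pathway** — positional category relative to the nearest splice
  site, gated by a program consensus (below): essential 90, intron–exon
  boundary 70, deep intronic 25.

Across transcripts the most pathogenic effect is retained; the reported
transcript is the gene's longest unless another transcript scores
strictly higher (ties on score go to the longer transcript, then to the
lexicographically smaller accession, making the choice order-invariant).
Known-mutation evidence — a dbSNP clinical significance token of
`pathogenic`/`probable-pathogenic`, or membership in a user-supplied id
list — overrides everything with the top score 110, never adjusted. The
token match is deliberate: substring matching would let `non-pathogenic`
trigger the override.

### Adjustments

A +5 adjustment rewards nucleotide-level conservation: phastCons
**strictly above 0.95** adds one step to nonsense, start/stop loss,
missense, synonymous and all three splice categories. Frameshift,
in-frame and known mutation never adjust — the frameshift/in-frame calls
are length-based and a conservation bump adds no information, and the
known-mutation score is already maximal. Missense variants additionally
gain +5 per deleterious protein prediction (SIFT and/or PolyPhen-2), so
the missense ladder is 50/55/60/65. Under the default configuration the
reachable score set is exactly
{0, 10, 15, 25, 30, 40, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100,
105, 110}, which the test suite asserts by enumeration.

### The splice consensus and its windows

Three splice-site assessment programs are consumed as annotations
(MaxEntScan, NNSplice, SpliceSiteFinder); their wild-type and variant
scores give a percent change each. A variant is considered to affect
splicing when **at least two of the three** programs report a drop at or
beyond −10% (MES), −5% (NNS) and −15% (SSF) respectively. Numerical
choices worth stating:

* a delta **exactly at** the threshold counts as significant (the
  thresholds are read as "a change of 10% or more");
* when both wild-type and variant scores are present (and wt > 0) the
  delta is recomputed as `100*(var−wt)/wt`; a supplied delta column is
  used only when the raw scores are absent;
* absent programs abstain — they neither vote for nor against; with all
  three absent the consensus fails.

Distances use signed offsets from the nearest splice site: positive =
intronic side, zero/negative = exonic side, the standard c.-nomenclature
orientation. The essential category is the two first intronic bases
(+1/+2) of either site and applies **without** requiring the consensus —
disruption of the canonical GT/AG dinucleotides is taken as significant
per se. The boundary (close) windows are donor −3..+6 and acceptor −12
(intronic) .. +2 (exonic); in the signed convention the acceptor window
is therefore −2..+12. Intronic positions beyond the windows are deep. An
intronic variant whose nearest-site *type* is unknown cannot be placed in
a window and is scored `none` with a warning rather than guessed.

## Cohort structure: barcode and counts

The cohort barcode is one digit per sample — 0 hom-ref, 1 het, 2 hom-alt
— in a fixed sample order. The order is lexicographic by sample id and is
printed in the `## Barcode:` header line of every report, so barcodes are
comparable across runs regardless of input file order. Missing genotypes
(`./.`) have no digit of their own (the alphabet is only {0,1,2}); they
render as 0 but are tallied separately in QC output, an ambiguity we log
rather than resolve with a fourth symbol. The derived counts obey
`Allele_Count = 2*Hom_Count + Het_Count`, a property tested over random
cohorts. `cohort_frequency_filter()` turns the counts into an internal
frequency database: keep a variant only if it is seen fewer than
`max_het` times heterozygous **and** fewer than `max_hom` times
homozygous. Both bounds are strict, matching the "present less than n
times" reading.

The family barcode is the restriction of the cohort barcode to a
user-ordered sample subset, with `match_pattern()` for inheritance
queries (`"121"`, `"010"`); the `?` wildcard is a convenience extension —
the canonical patterns are exact strings.

## The filter cascade

Five removal rules build the `filteredVariants` reports (defaults in
`filter_config()`): total depth ≤ 10; supporting reads ≤ 10; supporting
read ratio ≤ 15%; dbSNP-validated (≥ 2 evidences) and not flagged
pathogenic; any available population allele frequency > 1%. Frequencies
are compared as the **maximum over all available population columns** —
with several dbSNP/EVS/1000g columns available, the conservative choice
for a removal filter. The quality boundaries are inclusive and the
frequency boundary strict, exactly as stated; note the read-count rules
overlap by construction (a call with total depth ≤ 10 necessarily has
≤ 10 supporting reads), so both ids appear in such a call's reasons. Rules
whose inputs are missing do not fire — a call without depth information
must not be silently discarded. Known-pathogenic variants are exempt from
the two annotation-based rules (iv, v): a reported mutation that is
common in the cohort is a thing the analyst should *see* and then remove
via the barcode counts, not lose to an automatic filter.

## Rankings

`byVar` sorts a sample's carried variants by final score descending; ties
break by lowest maximum population frequency (absent frequency sorts
first — no frequency record is the strongest rarity evidence available),
then genomic coordinates, making output byte-deterministic.

`byGene` serves the recessive/compound-heterozygote hypothesis. A gene is
scored along two criteria — its best homozygous variant and its two best
heterozygous variants — and the published description leaves their
combination open; we use `max(best homozygous, second-best heterozygous)`
as the gene key. Rationale: under a recessive model both alleles must be
hit, so a compound heterozygote is only as damaging as its *weaker*
allele, and a single heterozygous variant (no second allele) contributes
nothing however high it scores. The best heterozygous score breaks ties,
then the gene symbol. Every variant of a reported gene appears in its
block so nothing is overlooked.

## Input handling

VCF parsing is delegated to vcfR (plain or gzip). Multi-allelic records
are split per ALT, with zygosity recomputed against each alternate alone
(`1/2` is heterozygous for both); symbolic alleles (`<DEL>`, breakends,
`*`) are skipped with a warning — structural variation is out of scope.
Alleles are normalized to the minimal anchored representation
(suffix-trim, then prefix-trim keeping one anchor base, shifting the
position), so differently padded indel spellings from different callers
merge into one key, `<chrom>_<pos>_<ref>_<alt>`. Depths are read from
`DP`/`AD` with an `RO`/`AO` fallback; haploid genotypes code as
homozygous. Duplicate sample ids across files keep their first occurrence
with a warning. Coordinates are 1-based VCF convention throughout.

## The simulator

`simulate_cohort()` generates the data structure the pipeline is built
for: a pool of common polymorphisms shared across samples, plus private
spiked mutations with known expected scores. Background variants draw
their population frequency uniformly from 1%–50% — all above the
frequency-removal threshold, as common polymorphisms are — and genotypes
follow Hardy–Weinberg at that frequency, which reproduces the saturating
growth of the non-redundant variant count as samples accumulate.
Read depths are negative-binomial (mean 50, dispersion 10), emulating
~50× targeted coverage with realistic overdispersion; alternate-read
counts are binomial at 50%/100% for het/hom carriers, with at least one
supporting read per called carrier. Background annotations are benign:
synonymous/missense/intronic types, dbSNP-validated with two evidences,
phastCons below the cutoff, benign predictions. Spikes are private to
their sample, frequency-less, and annotated so the scorer assigns their
category; the truth table records the expected default-config score. A
seed fully determines every output byte.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: linkage between variants, realistic site-level
annotation error, caller-specific artifacts, population structure,
sequence context, or structural variation. It validates the engine's
bookkeeping and ranking logic, not annotation quality.

## Validation problem sizes

The test suite validates the scoring table and adjustment arithmetic by
direct construction, the splice consensus by enumerating all 2³ vote
patterns at and inside the thresholds, the scorer against an independent
brute-force oracle on random annotation sets, and barcode arithmetic over
random cohorts. The end-to-end recovery experiment runs 100 simulated
cohorts of 30 samples × 1,000 common background variants with one private
causal spike per cohort, alternating a nonsense and a known mutation,
and requires the spike to top the filtered `byVar` ranking in ≥ 95 runs.
The spike is **homozygous**: the experiment mirrors the
recessive-disease setting (consanguineous pedigrees) where causal
mutations are predominantly homozygous, and it keeps the experiment a
test of the ranking engine rather than of depth-sampling noise — a
heterozygous carrier loses ~3–4% of runs to the (correctly) inclusive
supporting-read filters before ranking is even involved. Non-redundancy
is checked on a 20-sample fixture by comparing union annotation against
per-sample annotation row for row.

## Known limitations

* The splice windows assume the annotation source reports a signed
  distance and a site type; sources that only report unsigned distances
  need preprocessing.
* PolyPhen-2/SIFT vocabularies vary between annotation engines; the
  deleterious test is a case-insensitive match on
  "deleterious"/"damaging", which covers the HumVar and HumDiv label
  sets but should be checked against new engines.
* Gene-level ranking assumes compound heterozygotes are in trans; without
  phasing two cis variants can inflate a gene's key.
* CNVs and other structural variants are excluded by design (symbolic
  alleles are skipped), so a causal CNV is invisible to the ranking.
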