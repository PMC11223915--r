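---
title: "Methods: QC, normalization, frequencies and discrepancy resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC, normalization, frequencies and discrepancy resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`varconcord` is the computational backend of a multi-laboratory variant
sharing platform for hereditary cancer diagnostics. This vignette
documents the models and procedures it implements, the tunable
parameters, the numerical choices made where the design was open, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## The setting

Laboratories submit two kinds of datasets: *variant classifications*
(tabular: variant, five-tier ACMG/AMP label, date, reasoning) and
*variants of individuals* (one single-sample VCF per patient plus a
clinical-metadata table and rich dataset metadata: platform, panel
version and region file, genome build, aligner, caller, depth
threshold). Each laboratory keeps its own table layout; a per-lab
format spec (JSON) maps source columns and vocabularies onto the
canonical schema, so onboarding a new lab requires configuration, not
code. Acceptance is all-or-nothing: any invalid row rejects the dataset
with row-level diagnostics, because partial ingestion would corrupt the
incremental dataset versioning.

Identifiers are pseudo-anonymized at submission: codes are drawn
uniformly from the 36 uppercase alphanumerics, 6 characters for
individuals and 5 for families, regenerating on collision; the
source-to-code map is kept in a restricted table. One global namespace
per kind is used across datasets, so resubmissions of the same
individual map to the same code.

## Record-level VCF QC

A call record is excluded iff any of:

* `FILTER` differs from `PASS` (an unset `.` is treated as non-PASS —
  the conservative reading);
* genotype is homozygous reference; missing (`./.`) genotypes are also
  dropped, as they carry no allele evidence;
* allele balance `alt/(ref+alt)` is **below 0.2** (strict: exactly 0.2
  passes); undefined balance (no usable allelic depths) drops the
  record;
* depth is **below the submitter threshold** (minimum 10; depth exactly
  at the threshold passes). Depth comes from `FORMAT/DP` with an AD-sum
  fallback, recorded per record;
* the position lies outside the panel BED.

Multi-allelic records are decomposed into biallelic records before
anything else; allele balance for a decomposed alternate uses
ref + that-alternate reads. A per-caller adapter absorbs dialect
differences (e.g. VarScan-style `RD`/`AD` scalars).

## Cohort-level sample tests

All pairwise tests run on the *intersection* of the two samples' panel
regions, since submitted VCFs come from different targeted panels.

* **Noisy / empty**: Tukey's fences on the cohort's per-sample variant
  counts, upper `Q3 + 5·IQR`, lower `Q1 − 4·IQR`. Quartiles use linear
  interpolation between order statistics (R's default type 7); the
  choice matters when cohorts are small, so it is fixed and recorded.
  Flagging is strict (`count > upper`, `count < lower`). At least four
  samples are required, otherwise the test is skipped with a warning.
* **Duplicates**: `p1` = fraction of sample-1 calls also called in
  sample 2 (presence-based, genotype-agnostic), `p2` the converse; a
  pair is duplicated iff `(p1+p2)/2 > 0.9` (strict). The later-submitted
  member of a duplicate pair is the one rejected (deterministic). If
  either sample has no calls in the shared regions the score is
  undefined and the pair is skipped: a vacuous 1.0 would mark unrelated
  sparse samples as duplicates, and true empties are already caught by
  the fences.
* **Kinship**: the robust pairwise estimator
  `φ = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa(1) + N_Aa(2))` over the union of
  called sites in the shared regions, treating uncalled positions as
  homozygous reference (single-sample VCFs carry no reference blocks).
  `φ = 0.5` for a sample against itself, ≈0.25 for parent–offspring,
  ≈0 for unrelated pairs; the relatedness cutoff is 0.25. Because the
  parent–offspring expectation sits exactly at the cutoff, individual
  pairs fall on either side of it; the tests therefore assert recovery
  of φ (±0.03 at 2000 sites), not the binary flag.

Noisy, empty and duplicated samples are not inserted. Kin-related
samples are inserted but de-duplicated for frequencies: relatedness
clusters are the connected components of kinship edges ∪ shared-family
edges.

## Variant normalization

Indels inside repeat tracts admit many equivalent VCF representations.
After trimming shared allele context (always retaining one anchor
base), `shift_left()` rolls the variant to its most-5′ placement — the
canonical identity key `chrom:pos:ref:alt` used throughout the database
— and `shift_right()` to its most-3′ placement, which backs
coding-DNA-style naming. Both operations are idempotent and preserve
the edited sequence exactly; the test suite checks them against a
brute-force enumeration of equivalent placements on repeat-rich
synthetic references. Full HGVS string grammar (dup/ins naming,
protein-level names) is deliberately out of scope: the package exposes
right-shifted alleles plus cDNA coordinates, which determine the HGVS
name.

cDNA mapping counts coding bases from the translation start (negative
in the 5′ UTR); intronic positions are nearest-exon-boundary plus a
signed offset, ties going to the donor side. Reverse-strand transcripts
count along the antisense direction. The main transcript of a gene is
the one matching the gene's first LRG transcript, else the annotator's
canonical flag; across genes the candidates compete on a configurable
consequence-severity ranking (the default follows the ordering
published by common effect annotators), with ties broken
deterministically by transcript id — the tie rule is this package's own
choice, flagged here because no published rule exists.

## Allele frequencies

`AF = AC/AN` per variant and stratum. `AN` counts two alleles for every
AF-eligible individual whose panel covers the position — coverage is
panel membership, not per-site depth, because non-carrier depth is not
available from single-sample VCFs. Exactly one representative per
relatedness cluster is eligible: the member with the widest merged
panel (it can contribute to the most sites), ties broken by earliest
submission. `AC` adds 1 per heterozygous and 2 per homozygous-alternate
eligible carrier. Strata can be formed from any combination of metadata
fields; an `"all"` stratum is always emitted, and per-stratum AC/AN sum
exactly to the overall values for any partition of the eligible
individuals. Diploid AN is used everywhere, including sex chromosomes;
chrX/Y rows carry a limitation flag rather than a haploid correction.

## Ledger, concordance models and printed percentages

The ledger keeps the most recent classification per (variant, lab) by
classification date; same-date resubmissions resolve to the last row in
file order and are flagged. Concordance is assessed for variants
classified by ≥2 laboratories under three nested partitions of the
five labels: five-tier (all distinct), three-tier {LP/P}, {VUS},
{LB/B}, and two-tier actionable {LP/P} vs non-actionable {VUS/LB/B}.
Discordance across the two-tier boundary is *clinically significant*.
Nesting (two-tier discordance ⇒ three-tier ⇒ five-tier) is a theorem
of the partition refinement and is property-tested.

Printed percentages round **half-up to one decimal**. One published
value cannot be reproduced under any standard rounding: 15 of 33 cases
resolved in Phase 2 is 45.45%, printed as 45.4 in the source
publication, while 14/18 = 77.78% is printed as 77.8. The package
computes 45.5 and the acceptance test asserting the printed value is
intentionally left failing to document the discrepancy.

## Discrepancy resolution

Only two-tier-discordant variants enter the three-phase procedure; all
assigned laboratories resubmit after each phase and discordance is
re-assessed.

* **Phase 1** (minimize workload): two labs → the *oldest*
  classification reviews; >2 labs → a lone lab opposing ≥2 (*outlier*)
  reviews; else a group of exactly two facing ≥2 → one of the two at
  random (*random-of-two*; when both groups have exactly two labs, the
  "first" group is the one holding the older classification — the
  package's deterministic reading of an ambiguous rule); else *all*
  labs review.
* **Phase 2**: after oldest/outlier/random-of-two, the *remaining* labs
  review; after an "all" Phase 1, the single dissenting lab carries out
  a *further review*. More than one dissenter after an "all" Phase 1 is
  undefined in the source procedure and is flagged for manual handling
  with no assignment planned.
* **Phase 3**: an email discussion group for variants classified by up
  to three labs, a joint meeting for four or more. Discussions are not
  revisions.

Revisions are counted over Phases 1–2 (every assigned lab counts,
whether or not it changes its label). The brute-force comparator is the
sum of classifying-lab counts over the initially discordant cases. Note
that a case handled by "all"-then-further-review costs `n + 1` reviews:
the once-per-lab property holds for the oldest/outlier/random-of-two
paths only, while the planner-versus-brute-force economy holds globally
on every tested fixture.

The planner *plans*; laboratory behaviour is supplied to
`execute_resolution()` as scripted post-review labels (a lab without a
script entry reaffirms). This separation keeps the algorithm testable
without modelling reviewer decision-making.

## The synthetic-data generator

`simulate_cohort()` emulates targeted-panel germline calling: biallelic
SNV sites on a synthetic reference, genotypes drawn binomially from a
per-site allele frequency, one GT:AD:DP VCF per individual, a shared
panel BED, metadata tables, all byte-reproducible under the recipe
seed. Default stated-world parameters: 20 unrelated individuals, one
parent–offspring pair (one transmitted allele per site, kinship
expectation 0.25), one shared-family pair, one duplicate (2% of calls
perturbed; sharing > 90%), one noisy sample (calls at 95% of sites plus
off-site noise, above the upper fence by construction), one empty
sample (10 calls), 2000 sites at allele frequency 0.5 — the regime in
which the kinship expectations φ = 0 / 0.25 hold and the published QC
thresholds separate cleanly. Real panel data differ in ways the
generator does not model: skewed rare-variant frequency spectra,
linkage disequilibrium, indels and error modes correlated with depth;
a green sample-QC test therefore establishes correct implementation of
the statistics, not field performance of the thresholds.

`make_classification_fixture()` realizes an exact concordance profile.
The default reproduces the published cohort counts — 10 035 classified
variants, 2469 multi-classified, 1697 consensus, 367 five-tier-only,
321 three-tier-not-two, 84 two-tier discordant — and a per-case design
for the 84 whose scripted outcomes yield the published resolution
worked examples (93 + 52 revisions; 51, 15 and 14 variants resolved in
Phases 1–3; 285 brute-force). Only the aggregate counts are published;
the per-case composition (how many cases had 2, 3, 4, 5 or 10
classifying labs) is this package's own synthetic realization,
constructed to satisfy every printed total simultaneously.

## Numerical and design notes

* Coordinates are 1-based inclusive in memory and in VCF; 0-based
  half-open only on BED disk files, converted at the I/O layer.
* Tabular submissions are ingested as TSV/CSV; the spreadsheet layer of
  the original platform is not reproduced (no xlsx reader in the
  supported stack), and the format-spec mechanism is format-agnostic.
* Excel-era caller dialects are handled by adapters at the VCF reader;
  the fixture generator emits a single clean dialect, and dialect
  variation is tested with small hand-written files.
* The allele-frequency VCF output is sites-only with gnomAD-style
  per-stratum INFO tags.
* Expert-group and ClinVar classifications can be stored alongside but
  are excluded from the discrepancy analysis, which is among submitting
  laboratories.

## Limitations

* Kinship treats uncalled positions as homozygous reference; cohorts
  with very heterogeneous panels lose power, and φ is biased for pairs
  with grossly different call counts (the noisy/empty tests run first
  for this reason).
* AN does not require the record-QC depth threshold in non-carriers —
  panel membership is the only coverage criterion available from
  single-sample VCFs.
* Liftover between genome builds, annotation by external predictors,
  HGVS string generation, and the web/authorization tier are out of
  scope.
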