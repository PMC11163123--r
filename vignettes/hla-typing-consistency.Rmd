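---
title: "Scoring HLA typing consistency in trios and duplicate samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring HLA typing consistency in trios and duplicate samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaconcord)
```

## The problem

Calling HLA alleles from short-read sequencing (whole exome, whole genome,
or a targeted amplicon panel) is error-prone: the loci are extremely
polymorphic, the DRB paralogs share long stretches of sequence, and capture
designs differ in how well they cover the region. When no gold-standard
typing exists, two internal-consistency checks remain available:

* **Mendelian consistency in family trios** — a child's two alleles should
  be explainable as one transmitted allele from each parent;
* **duplicate-sample concordance** — the same DNA typed twice (two assays,
  or two callers) should yield the same alleles.

`hlaconcord` implements both checks at one-, two- and three-field allele
resolution, together with the aggregation that turns per-family and
per-pair scores into the per-locus percentage tables these evaluations
report, and a seeded simulator that generates pedigrees with the full
statistical structure the scorers assume.

## Allele names and resolution

An allele name such as `HLA-DRB3*02:02:01` is a locus plus a colon-separated
hierarchy of numeric fields: field 1 is the allele (serological) group,
field 2 the specific protein, field 3 synonymous coding differences. Two
alleles *match at resolution k* iff both are typed, both carry at least
`k` fields, and their first `k` field tokens are equal as zero-padded
strings. Three consequences worth spelling out:

* a call typed to two fields matches **nothing** at field 3, not even an
  identical two-field call. Shallow calls are a coverage symptom, and both
  the trio and the duplicate analyses count them as third-field
  inconsistencies rather than excluding them;
* two *not typed* calls match each other in duplicate comparisons:
  concordant absence is informative agreement for copy-number-variable
  loci (a typed call never matches a not-typed one);
* expression suffixes (`N`, `L`, `S`, `C`, `A`, `Q`) are parsed and
  preserved but ignored during matching. No suffix-aware comparison rule is
  defined for these evaluations, so matching stays field-token-based;
  suffixes survive round-trips through the readers and writers so no
  information is lost.

## The trio point system

At one locus, with child genotype $\{c_1, c_2\}$ and parental genotypes
$F$ and $M$, the score at resolution $k$ is

$$
s_k = \begin{cases}
1 & \exists\ \text{assignment } c_i \to F,\ c_j \to M\ (i \ne j)
    \text{ with both matches at } k\\
0.5 & \text{no such assignment, but some } c_i \text{ matches some
    parental allele}\\
0 & \text{otherwise.}
\end{cases}
$$

Each parent contributes exactly one transmitted haplotype, so one parent
can never cover both child alleles: a homozygous child whose allele occurs
in only one parent scores 0.5, which is precisely the "matched only one
parent" pattern that homozygote-prone loci produce. The per-locus
consistency percentage is $100 \sum s_k / n$ over the $n$ included
families, so a locus with 3 zero-score, 6 half-score and 5 full-score
trios out of 14 reports $100 \cdot 8/14 = 57.14\%$.

Scores are monotone non-increasing in resolution (matching only gets
harder), which the test suite asserts for every score it produces, and the
implementation is checked against an exhaustive enumeration over all
child-to-parent assignments on randomly generated trios.

### Exclusions

Exclusion is per family *and* per locus: a family whose father is not typed
at DRB6 still counts at every other locus. The two reasons are recorded
separately in the audit trail:

* `not_typed_member` — some member's genotype at the locus has a not-typed
  slot (typing failure or dropout);
* `locus_not_assayed` — some member has no entry for the locus at all
  (assay design; a targeted panel simply does not cover most loci).

Shallow (two-field) calls are **not** an exclusion reason at field 3; they
are included and fail to match there.

### The DRB3/4/5 unit

A haplotype carries at most one of DRB3/DRB4/DRB5 — or none — and which one
is linked to the DRB1 allele group. An individual therefore carries 0, 1 or
2 secondary-DRB alleles, and per-locus genotype slots cannot distinguish
hemizygosity from homozygosity. [pool_drb345()] collapses the three loci
into one variation unit per sample: the multiset of all typed alleles
across them (a homozygote contributes its allele twice). Unit scoring
follows the same point system with one extension: a child unit holding a
single allele scores 1 if that allele matches either parent's unit, because
the second haplotype may legitimately carry no secondary DRB gene. Families
in which any member's unit is empty are excluded from the unit row — with
two-slot calls, an empty unit (all three loci not typed) cannot be told
apart from true absence of all secondary DRB genes, so the unit analysis is
restricted to trios with complete typing across the region.

In the generic TSV dialect `-` means *not typed*, so a one-copy carrier is
written `allele<TAB>-` and pools to a single-allele unit. The HLA-HD
final-result dialect instead uses `-` in the second slot as the tool's
homozygote shorthand, and the reader expands it to two copies — faithfully
reproducing the hemizygote/homozygote ambiguity real output carries. The
two dialects are deliberately kept behind separate readers.

## Duplicate concordance

Two genotypes of the same sample are compared by a maximum matching between
their two slot sets (slot order in files is arbitrary), scored as matched
slots over two. A homozygote against a heterozygote sharing one allele
scores 0.5. Not-typed slots participate and match only not-typed slots;
this is the *affected-slot* rule — a pair with one not-typed slot on one
side loses at most that slot, it is not zeroed wholesale. Duplicate pairs
are never excluded for not-typed results, so the comparison measures the
technology end to end. Loci absent from one dataset's assay design are
skipped entirely rather than scored 0: a panel is compared only on the loci
it targets. Concordance for the secondary DRB loci is reported per locus;
no pooled-unit concordance row is defined, since a denominator over
variable-size multisets would be arbitrary.

## Aggregation and rounding

Per-resolution averages are **unweighted across loci** (a 2-family DRB5 row
counts as much as a 25-family HLA-A row), and NA rows (zero evaluable
families) are excluded from the mean rather than zero-filled; both
conventions are required to reproduce the column averages of the packaged
reference tables. The overall average is the arithmetic mean of the three
per-resolution means. Presentation rounding is half-up to two decimals
(`round_half_up()`); base R's half-even rounding disagrees on exact
`.005` boundaries. Comparisons against the packaged tables use a ±0.01
band because a few published cells appear truncated rather than rounded
(e.g. 90.21 where the column mean is 90.2189). Raw unrounded values are
kept in the objects and in the pipeline's JSON sidecar; rounding happens
only when tables are written.

One packaged table lists a DRB3 row of 94.45% over 24 families, which is
not a multiple of $0.5/24$ — the source's denominator for secondary-DRB
rows may have been haplotype- rather than family-based. The implementation
reports family-denominator percentages only, and keeps per-trio raw scores
in the audit trail so alternative denominators can be computed downstream.

## The simulator

`sim_config()` fixes the study conditions; the defaults are:

* **loci**: the full 29-locus registry, with DRB3/4/5 driven by linkage
  rather than sampled independently;
* **allele pools**: 8 alleles per locus, three fields each, frequencies
  proportional to $1/\mathrm{rank}$ (a skewed, realistic-shaped spectrum);
  pool-mates share field-1 groups pairwise so every resolution level is
  informative;
* **DRB1 pool**: eight alleles spanning groups linked to DRB3 (total
  haplotype frequency 0.35), DRB4 (0.25), DRB5 (0.25) and no secondary gene
  (0.15). These weights keep all three secondary loci populated — including
  the rare all-members-two-copy families the per-locus rows need — at
  moderate trio counts, while leaving the no-gene haplotype common enough
  to exercise single-allele and empty units;
* **n_families = 14, n_duplicates = 100**, matching the smallest trio
  dataset and the duplicate-sample count of the evaluation design the
  package addresses;
* **noise rates = 0**: the baseline is clean Mendelian transmission, and
  noise (dropout, two-field truncation, mistyping) is switched on
  explicitly per experiment.

Founders draw two independent haplotypes per locus; children receive one
whole haplotype per parent, co-transmitting the DRB region. Noise applies
per allele call, independently, in a fixed conditional order: dropout,
else truncation, else mistyping. Every modification is logged and the log
replays truth into the observed table exactly, which makes rate-recovery
tests sharp: marginal event probabilities are $d$, $(1-d)t$ and
$(1-d)(1-t)m$.

Allele names are synthetic numeric tokens on the real locus registry, so
the simulator exercises the same parser and registry validation as real
data. What the simulator does **not** emulate: realistic population allele
spectra, linkage disequilibrium beyond the DRB1-DRB3/4/5 block, correlated
noise between datasets or within samples, and read-level error processes.
Green simulation-based tests therefore demonstrate that the scoring and
aggregation machinery is correct under the stated model — not that any
particular sequencing technology achieves a given consistency on real
data; conclusions about technologies come from the packaged reference
tables and from user-supplied typings.

### Determinism and problem sizes

Every simulation entry point takes a seed (default: the config's) and is
reproducible to the byte; the pipeline manifest records config and input
digests so a run can be re-verified. The test suite uses 2,000 noise-free
trios for the end-to-end perfection check (large enough that even the
rarest per-locus rows — all-members-two-copy DRB5 families, expected
frequency $\approx 0.004$ per family — are populated), $10^4$ random toy
trios for oracle equivalence, and 1,000 duplicate pairs for the
closed-form truncation check with a $3\,\mathrm{SE}$ binomial band.

## Known limitations

* Duo (single-parent) scoring, phasing beyond the one-generation
  assignment, and imputation of missing members are out of scope.
* G-group/P-group collapsing and fourth-field comparison are not
  implemented; resolution is capped at three fields.
* Suffix-aware matching is not offered; suffixes are metadata only.
* No significance testing on concordance differences — the outputs are
  descriptive percentages with their denominators.
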