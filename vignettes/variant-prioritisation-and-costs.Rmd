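---
title: "Methods: variant prioritisation cascades and the cost-consequence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritisation cascades and the cost-consequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

`varcascade` models the computational core of a germline WGS testing
programme for suspected hereditary cancer: reducing variant calls to a
reviewable short-list, book-keeping the reportability decisions around a
multidisciplinary team (MDT), summarising diagnostic yield over a cohort,
and weighing three national testing strategies against each other in
dollars. This vignette records the models, their assumptions, and the design
decisions taken where a published description leaves the implementation
genuinely open.

## The small-variant cascade

A small-variant record carries per-subpopulation gnomAD exome and genome
allele frequencies (AF), a within-cohort and an in-house AF, ClinVar status,
molecular consequence, in-silico scores and the variant allele fraction
(VAF, the fraction of reads supporting the alternate allele). Three gates
apply in order:

1. **Panel restriction** — only variants in virtual-panel genes proceed.
   Because the later gates are per-variant, applying the restriction first
   is output-equivalent to applying it last; doing it first keeps audit
   tables small.
2. **Frequency gate** — drop when AF > 1% (strict: exactly 1% passes) in
   *any* eligible gnomAD subpopulation, exome- and genome-derived
   frequencies considered separately, or in the cohort or in-house
   resource. Subpopulation eligibility (the n ≥ 2000 condition) is a flag
   in the subpopulation resource, not recomputed from sample sizes. A
   variant absent from a resource is treated as AF = 0: absence from gnomAD
   implies rarity, and penalising missingness would discard exactly the
   novel variants the workflow exists to find. A ClinVar LP/P
   classification rescues the variant past this gate.
3. **VAF gate** — substitutions (SNVs, and dinucleotide substitutions,
   which are substitution-type calls) are dropped below 30%, indels below
   20%; boundary values are retained. The ClinVar rescue deliberately does
   **not** waive this gate: low VAF indicates an unreliable call or
   mosaicism, a property of the sequencing evidence rather than of the
   variant's clinical record, so a quality filter must apply
   unconditionally.

Multi-allelic sites must be pre-decomposed to one record per alternate
allele. The within-cohort frequency is interpreted as an allele frequency
(per-allele rather than per-carrier); with the 1% threshold and diploid
samples the two interpretations differ only for recurrent variants, and the
choice is confined to whatever table the caller supplies in `cohort_af`.

## The SV/CNV cascade

Structural and copy-number calls come from two callers: caller A
(split-read/paired-end; deletions, duplications, inversions, insertions,
translocations) and caller B (read-depth; deletions and duplications, with
a `q0` zero-mapping-quality fraction and a genotype score).

* **q0 rule.** B-calls with q0 < 0 or q0 > 0.5 are flagged for removal
  unless the genotype score is below 0.25. Flagged calls are removed
  *before* concordance matching — "flagged for removal" is read as removal,
  so a q0-failed call cannot lend dual-caller support to its partner.
* **Concordance.** Two calls describe the same CNV when they have the same
  type and reciprocal overlap `min(|a∩b|/|a|, |a∩b|/|b|)` ≥ 0.80
  (inclusive). Matching is greedy by descending overlap with ties broken by
  the smaller id pair, each call matched at most once; no matching
  discipline is canonical here, and greedy best-first is deterministic,
  order-invariant and easy to audit. Unmatched CNVs are retained but
  flagged `SINGLE_CALLER` + `MANUAL_REVIEW`; only CNVs face the dual-caller
  requirement, since the SV types are called by one tool by design.
* **Blacklist regions.** Deletions, duplications and inversions are
  excluded when ≥ 80% of their span is covered by the *union* of
  exclusionary regions — merged-region coverage, matching BEDTools
  `-f 0.80` semantics against a merged blacklist — rather than by any
  single region. Translocations and insertions are excluded on any
  breakpoint hit.
* **Population frequency.** A call is assigned, per resource (gnomAD-SV,
  in-house, cohort), the maximum AF over same-type records at ≥ 80%
  reciprocal overlap (spans) or with both corresponding breakpoints within
  100 bp (translocations/insertions; requiring both breakpoints is the
  stricter reading of "within a 100-bp window" and avoids matching a local
  breakpoint cluster to an unrelated distant event). The call is excluded
  when any assigned AF exceeds 5% (strict).
* **Gene association.** Gene footprints run from 2,000 bp upstream of the
  transcription start to the transcription end. Upstream is strand-aware
  (`[start−2000, end)` on +, `[start, end+2000)` on −), clipped at
  chromosome bounds; a `stranded = FALSE` mode extends the left end always,
  for reproducing strandless annotation conventions. CNVs associate with
  any footprint they overlap by one base; other SV types only through their
  breakpoints. Retained calls must touch at least one panel-gene footprint.

Internally all SV/CNV and region coordinates are 0-based half-open (the BED
convention), converted to 1-based at VCF boundaries and when handed to
IRanges; half-open arithmetic makes interval lengths and adjacency
unambiguous.

## Reportability and MDT book-keeping

ACMG/AMP classification is expert judgement and therefore an *input*.
Variants that are not benign/likely-benign are suppressed from the
preliminary MDT report only when an exclusionary category applies —
missense with REVEL < 0.5, synonymous without predicted splice impact,
in-frame indel with PROVEAN > −2.5 — and no rescue holds: a gene–phenotype
association (an input flag; no operational definition is attempted), an
alternative predictor calling the variant deleterious (operationalised as
CADD > 20, the threshold being a `cadd_rescue` argument so further
predictors can be added), or any ClinVar LP/P submitter. LP/P variants
always report. Frameshift, nonsense and splice variants match no
exclusionary category and always pass. The gate is monotone in rescues by
construction, and a safety invariant refuses to build a report containing a
B/LB variant. Direct-return variants (returned without formal MDT review)
are ordinary `return` verdicts carrying a `direct_return` provenance flag —
the downstream effect is identical. VUS tiers (A/B/C) are post-MDT
annotations applied through the verdict table, never computed.

## The synthetic data and what passing tests mean

The generators exist so that every pipeline stage can be exercised, with
ground-truth labels, without any sequencing data. They emulate the *shape*
of annotated call tables — frequencies above/below the filtering
thresholds in randomly chosen resources, low-VAF artefacts, paired-caller
CNVs with controllable reciprocal overlap, blacklisted placements,
q0 mixtures — over a synthetic genome: a single linear coordinate space
(default 8 Mb) partitioned into eight pseudo-chromosomes, with a
deterministic panel (`G008`…, plus seven familiar cancer-gene names so the
fixture can tally by symbol). They do **not** simulate reads, caller error
processes, linkage, or realistic allele-frequency spectra; a passing oracle
test demonstrates that the cascades implement the stated rules exactly, not
that the rules have any particular sensitivity on real genomes. Ground
truth is computed at generation time by plain per-record arithmetic scans,
deliberately sharing no interval machinery with the cascades (which use
IRanges/GenomicRanges), so the comparison is a genuine dual-route check.
Generator defaults (1,000 variants, 200 SVs per caller, 30% common
fraction, 5% ClinVar LP/P, VAF noise SD 0.05) are one-time choices of a
plausible post-calling workload; the caller-concordance mix (60%
concordant / 15% poor / 25% absent) is a free parameter with no published
counterpart. Oracle tests run at 1,000 variants and 1,000 SVs per caller,
and kernel-vs-brute-force checks at 100 random instances of ≤ 200
intervals — sizes at which the O(n·m) oracles remain exact and fast.

The cohort fixture is *code-generated, not random*, so that the study-level
tallies it encodes (195 cases; 119 returned variants = 31 LP/P + 88 VUS
tiered 7/54/27; 92 reported cases with multiplicities 67/23/2; 10 causal,
19 secondary, 20 risk-management-changed, 9 uninformative LP/P cases;
eligibility counts 28/83/52/29/42) are exact. Attribute combinations not
pinned by those tallies (which sex goes with which age band, and so on) are
assigned by deterministic index arithmetic and carry no meaning. One
invariant is deliberately relaxed: a VUS receives its tier only once a
return verdict exists, because tiering is a post-MDT act — excluded VUS
keep an `NA` tier.

## The cost-consequence model

Three scenarios are evaluated as expected-value decision trees over one
year, in 2020 Australian dollars, no discounting (all costs and benefits
accrue within twelve months), from a national public-health-system
perspective:

* **S1** — 13,230 referred individuals (a state count of 2,666 scaled by
  the 2020 population ratio 25,687,041 / 5,176,186); 35.04% offered
  targeted testing; uptake 90%; per-tested yield 11%.
* **S2** — S1, then WGS + virtual MDT offered to (a) the targeted-tested
  negatives and (b) those never offered targeted testing; offer 100% to
  both subgroups, uptake 79.6%, subgroup yields 13.3% and 17.97%.
* **S3** — upfront WGS offered to all referred; uptake 96.8%; per-tested
  yield 38.4%; MDT (and complex-case administration) costs applied to a
  55% complex fraction, or to all cases under the `mdt_all_cases_s3`
  sensitivity switch.

Counts flow through the tree as real numbers and are rounded only for
display — an expected-value cohort model must not round internally, and
13,230 × 0.968 × 0.384 then rounds to the integer case count the model is
meant to report. Costs accrue per tested case (pre-test counselling, test
price, programme overhead, MDT/administration) and per result
(post-test counselling higher for positives). Unit costs: counselling
150 / 300 / 75 (pre / post-positive / post-negative), targeted test average
925, WGS 1,750 (sensitivity alternative 1,366), MDT 1,400, overhead 310,
administration 400 (complex) / 150 (non-complex), all AUD per case.

The referral volume, offer proportion, both WGS uptakes and the S3 yield
are externally given quantities; the remaining unit costs and the S2
subgroup yields are **calibrated placeholders**, chosen once so the model
reproduces the three published programme totals, and they function as
regression pins — agreement on totals is a consistency check of the tree
arithmetic, not independent validation of the costing. Quantities derived
*across* scenarios (costs per actionable case, marginal costs, the
expenditure ratio) then follow from the model rather than being pinned.

`one_way_sensitivity()` clones the configuration, perturbs exactly one
parameter (top-level or cost component) and re-evaluates all three
scenarios; referral-volume sensitivity (50%/150% of base) is expressed by
varying `referred_national`. Flow conservation at every tree node, the
identity `cost_per_actionable × actionable_cases = total_cost`, and
monotonicity in unit costs and uptakes are enforced by tests. With zero
uptake everywhere a scenario degenerates to zero cost and zero cases,
since every cost in the model is conditioned on testing.

## Numerical conventions and degenerate inputs

* All printed thresholds are strict or inclusive exactly as stated:
  AF 1% and 5% strict (boundary retained), VAF 30%/20% retained at the
  boundary, reciprocal overlap and region coverage ≥ 0.80 inclusive,
  CADD rescue strict at 20.
* Percentages round half-up to one decimal (`pct()`), and integer displays
  round half-up — base R's banker's rounding would mis-render tallies.
* Zero-length intervals are data errors for the overlap kernel; empty call
  tables, empty region sets and empty verdict tables are valid inputs and
  produce empty (not missing) outputs.
* Generator RNG: random data avoid landing exactly on filter boundaries
  (common AFs start at 1.05%, rare ones stop at 0.99%), so boundary
  behaviour is pinned by dedicated unit tests rather than left to chance.

## Interfaces and limitations

The package's interface is its exported functions plus
`scripts/acceptance.R`; the per-module file formats (TSV dialects, VCF,
BED, YAML config, JSON summaries) are covered by reader/writer pairs, and
no shell CLI is shipped — an R analysis package is driven from R. Known
limitations: the cascades operate on annotated call tables and perform no
calling, normalisation or annotation themselves; ACMG/AMP classification,
MDT verdicts and gene–phenotype matches are inputs; the economic model is
cost-consequence only (no QALYs, no probabilistic sensitivity analysis, no
inflation adjustment), and its placeholder unit costs should be replaced
with jurisdiction-specific values before any real-world use.
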