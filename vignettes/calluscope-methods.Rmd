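---
title: "Methods: callus-specific promoter discovery and base-editing genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: callus-specific promoter discovery and base-editing genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calluscope)
```

# The problem

Plant transformation begins at the callus stage, so a promoter that is active
in callus but quiet in regenerated tissues can confine the expression of a
genome editor (here, a cytosine base editor: a cytidine deaminase fused to
nCas9(D10A) plus a uracil-glycosylase inhibitor) to the window where editing
is wanted. Prolonged editor expression in regenerated plants risks additional
somatic mutations and off-target edits. `calluscope` implements the
computational side of such a program end to end:

1. **Expression screen** — find candidate callus-specific genes from bulk
   RNA-seq of callus at two subculture generations plus a multi-tissue
   expression atlas.
2. **RT-qPCR** — relative expression of candidates across tissues by the
   2^−ΔCt^ method.
3. **Promoter motif scan** — cis-regulatory element content of candidate
   promoters against an IUPAC consensus catalog.
4. **Amplicon genotyping** — classify base-editing outcomes per regenerated
   line from amplicon read-count tables and compute cohort editing
   statistics.
5. **Off-target scan** — enumerate and rank candidate off-target sites of
   the sgRNA.

A sixth module generates seeded synthetic inputs with ground-truth manifests
so that every stage can be exercised and validated without external data.

# Expression screen

Input is a gene × sample matrix in FPKM, or raw fragment counts plus gene
lengths (then FPKM = fragments · 10⁹ / (library size · length), with library
size the column sum). The screen proceeds in four steps:

* **Per-replicate top-N.** The `top_n` (default 400) most expressed genes of
  each callus replicate. Ties at the cutoff are all included, so selection is
  independent of input order; the set can therefore slightly exceed N.
* **Within-stage consensus = union.** A gene counts as highly expressed at a
  stage if it reaches the top N in *any* replicate of that stage. The union
  (rather than an intersection) is what makes per-stage consensus sets larger
  than N — with three replicates of top-400 per stage, consensus sets of
  ~450–490 genes arise naturally.
* **Cross-stage intersection.** Genes highly expressed at *every* stage.
* **Atlas specificity filter.** Against per-tissue mean expression, a gene is
  kept when callus ≥ `min_callus_expr` (default 10 FPKM), the maximum over
  all other tissues ≤ `max_other_expr` (default 1 FPKM), and the
  pseudocounted ratio (callus + ε)/(max other + ε) ≥ `min_ratio` (default
  10, ε = 0.01 so a gene silent everywhere else does not divide by zero).

The three filter thresholds are explicit parameters, not a claim about how
any particular published shortlist was drawn: "high in callus, undetectable
or much lower elsewhere" is a judgement that different analysts will encode
with different numbers, so the defaults are deliberately conservative
(10-fold separation with an absolute floor and ceiling) and everything is
configurable. A precomputed differential-expression table (gene, log2FC,
FDR) can be attached to the candidate report as annotation; the package does
not re-implement differential expression testing, for which DESeq2/edgeR are
the standard tools.

# RT-qPCR relative expression

`relative_expression(ct_target, ct_reference)` is 2^−(Ct_target −
Ct_reference)^. The pipeline averages *technical* replicate Ct values within
each biological replicate first (separately for target and reference gene),
computes one 2^−ΔCt^ per biological replicate, and reports mean ± sample SD
(n − 1) across biological replicates. Averaging raw Ct before exponentiation
matches how plate replicates are usually collapsed; the alternative order is
available by setting `average_technical = FALSE` and pre-collapsing
externally. A single replicate reports SD 0 with a warning rather than NA,
so downstream tables stay numeric.

# Promoter motif scanning

The scanner matches IUPAC consensus strings (e.g. ABRE `ACGTG`, W = A/T,
S = C/G) on both strands, reporting 1-based inclusive forward-strand
coordinates; minus-strand hits carry the forward-strand bases in
`matched_seq`. Matching rules:

* all overlapping and nested occurrences are reported — no greedy masking;
* `N` in the *pattern* matches any base, but `N` in the *sequence* matches
  nothing (a conservative rule: ambiguous sequence never creates a hit);
* output is sorted by (start, motif name) and is independent of catalog
  order.

The shipped catalog (`inst/extdata/plantcare_catalog.tsv`) holds published
PLACE/PlantCARE consensus strings for the element classes that matter for
promoter characterisation in this setting: core transcription elements
(TATA-box, CAAT-box), light-responsive elements (Box 4, GATA-motif,
AT1-motif), hormone-responsive elements (ABRE, TGACG-motif, TCA-element,
P-box) and stress-responsive elements (as-1, ARE, WUN-motif, TC-rich
repeats, STRE). Web services that curate many more matrices will report
additional (and sometimes different) hits; the catalog here is configuration,
not code, and makes the scan reproducible offline. Consequently,
per-promoter element counts from such services are not a comparison surface;
the invariants that are tested are strand symmetry, determinism, and
round-trip validity of every hit.

`extract_promoters()` implements the usual promoter proxy: the ~2000 bp
(configurable) immediately 5′ of the start codon on the gene's strand,
clipped at contig boundaries.

# Amplicon genotyping

Input is the per-target output shape of high-throughput amplicon genotyping
(one row per observed read variant: line, locus, variant sequence, read
count). Per line and locus:

1. **Read filter.** Variants with raw frequency (count / pre-filter total)
   strictly below 1% are excluded; a variant at exactly 1% is kept.
   Frequencies are then *renormalised over the retained reads* — excluded
   reads are excluded from analysis, not merely hidden (the pre-filter
   denominator is available via `renormalize = FALSE`). Renormalisation can
   only increase a survivor's frequency, which makes the filter idempotent.
2. **Variant classification.** Each variant is globally aligned to the
   reference amplicon (Needleman–Wunsch via `Biostrings::pairwiseAlignment`,
   match +2, mismatch −1, affine gap penalties chosen to favour one
   contiguous gap for short indels). No gaps and no mismatches → wildtype;
   mismatches only → substitution; gaps only → indel; both → complex
   (complex counts as indel-containing downstream). Substitutions are
   reported in protospacer coordinates with position 1 at the PAM-distal
   end — the convention of base-editing window reports; mismatches outside
   the protospacer keep amplicon coordinates and are flagged. Exact gap
   *placement* within a homopolymer follows the aligner; only the class and
   the length change feed the downstream calls, so placement conventions do
   not affect results.
3. **Locus call.** Mutation frequency is the cumulative frequency of all
   non-wildtype variants — when several mutation types co-occur at a locus
   they are summed, not taken separately. Zygosity: > 0.90 homozygous
   (strictly "exceeds"), 0.20–0.90 heterozygous (inclusive), below 0.20
   chimeric, exactly 0 wildtype. These bands partition [0, 1] with no gaps
   or overlaps.
4. **Line call.** A line is *edited* if at least one locus is heterozygous
   or homozygous (chimeric-only lines are not edited), *homozygous* if some
   locus is homozygous. A line *carries indels* when the cumulative
   indel-class frequency at some locus reaches the heterozygous threshold
   (0.20) on its own — i.e. the same classification approach applied to the
   indel class; `indel_rule = "any"` instead flags any surviving
   indel-class variant.
5. **Cohort summary.** Editing efficiency, homozygous rate and indel rate
   are percentages of genotyped lines, rounded to one decimal with halves
   away from zero.

Open reading of the source material: the phrase "homologous mutation" in the
genotyping rules is read as "homozygous" (consistent with a homozygous-rate
column); whether the 1% filter denominator is per locus or per sample is not
stated — per locus is used, matching the per-target structure of the input
tables; and whether chimeric calls contributed to any published tally cannot
be determined — they are excluded from "edited" here, per the stated rule.

# Off-target enumeration and scoring

`enumerate_sites()` reports every 20-mer that sits immediately 5′ of a PAM
match (default NGG and NAG) on either strand with Hamming distance ≤
`max_mismatches` (default 4) to the spacer, each site exactly once, the
on-target site included at 0 mismatches. The implementation prefilters PAM
positions with a regular expression and computes mismatch counts
vectorised; it is validated against a position-by-position brute-force
oracle in the tests.

Scores are multiplicative per-position penalties: score = Π over mismatched
positions of (1 − w_p), with the default weight profile PAM-proximal-heavy
(positions 13–20 at 0.3, positions 1–12 at 0.1; position 1 = PAM-distal), and
a 0.5 multiplier for NAG PAMs. This scheme is deliberately simple and
explicit — published web tools each use their own proprietary/unpublished
scoring, so no attempt is made to reproduce any particular tool's numbers.
What the scheme guarantees, and what is tested: a perfect match scores 1,
every added mismatch strictly decreases the score, and a 1-mismatch site
(such as a homoeologous near-target in an allotetraploid genome) always
outranks any 4-mismatch site under positive weights. `rank_sites()` returns
the top k (default 3) by score with deterministic tie-breaks (fewer
mismatches, then sequence id, then coordinate), excluding the on-target by
default.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their arguments including the seed, and
each returns a manifest that is sufficient ground truth on its own —
recovery tests consult the manifest, never a re-simulation. Generators save
and restore the caller's RNG state.

**Expression atlas** (`simulate_expression_atlas`). Two callus stages × 3
replicates plus one sample per non-callus tissue. Per-gene baseline is
log-normal (meanlog 1, sdlog 1.5 — a right-skewed expression distribution
spanning ~4 orders of magnitude), replicate noise multiplicative log-normal
(sdlog 0.2). Planted callus-specific genes get their callus expression
multiplied by `effect_fold` (default 100) and other-tissue expression drawn
from U(0, 0.5) — half the default `max_other_expr`. Planted baselines are
resampled until `effect_fold` × baseline ≥ 50 FPKM so that the planted
signal exceeds the default thresholds several-fold; with that margin, the
screen's expected recovery is 20/20 with zero false positives, which is what
the tests assert. What this generator does *not* emulate: count overdispersion,
correlated tissues, batch effects, or genes specific to a non-callus tissue;
recovery at 100% on this synthetic structure demonstrates the *logic* of the
filter, not its sensitivity/specificity trade-off on real atlases, where the
thresholds would need tuning.

**Designed two-stage screen input** (`simulate_staged_atlas`). For checks of
the set algebra at realistic sizes, this generator plants per-replicate
top-400 sets as sliding windows over designed stage sets (e.g. sizes 487 and
453 with overlap 419 — union sizes above 400 are exactly what a union of
staggered top-400 replicates produces), with in-window values strictly above
the background so the top-N cutoff is unambiguous. The pipeline then
*re-derives* those sizes from the values alone.

**Amplicon cohort** (`simulate_amplicon_cohort`). Per line/locus the designed
zygosity class draws an edited fraction from its band (homozygous
U(0.91, 1.0), heterozygous U(0.20, 0.90), chimeric U(0.01, 0.19)); reads are
multinomial at the chosen depth over wildtype/edited/noise variants. Because
a multinomial draw near a class boundary can cross it, draws are
rejection-sampled (bounded retries) until the realised post-filter read
population reproduces the designed class — the manifest is thereby exact
ground truth at any depth and seed. Edited variants are C→T substitutions at
a protospacer cytosine (the canonical base-editing outcome) or 1-bp
deletions for indel-flagged lines; noise variants are single substitutions
outside the protospacer, each held below the 1% filter, so default-filter
behaviour is exactly recoverable. Not emulated: sequencing error profiles,
PCR chimeras, multi-allelic outcomes beyond one edited haplotype per locus,
or editing-window position effects.

**Promoters and genomes.** Promoter backgrounds are uniform A/C/G/T with
planted motif realisations at stated coordinates/strands (overlaps are an
error); chance background hits are expected and are verified against the
matcher's oracle rather than forbidden. Off-target genomes plant sites at
exact designed Hamming distances with concrete NGG PAMs, alternating
strands, and the genome is rejection-sampled until a full scan finds
*exactly* the planted set — so "100% recovery" statements are meaningful.

# Numerical and degenerate-input choices

* Rates are rounded half away from zero (`round_half_up`), not banker's
  rounding, to one decimal.
* The zygosity boundaries are strict/inclusive exactly as stated above;
  0.90 is heterozygous, 0.20 is heterozygous.
* A locus whose variants are all filtered away is a *no-call* (classed error
  from `filter_low_frequency`, recorded as `NA` zygosity by
  `genotype_cohort` with a warning) rather than silently wildtype.
* Empty candidate sets, all-zero count columns, sequences shorter than
  protospacer + PAM, and empty hit tables all return well-formed empty
  results rather than errors, except where the input is structurally invalid
  (missing tissue labels, missing gene lengths for expressed genes, invalid
  IUPAC codes, non-DNA characters), which error early and name the offender.
* Problem sizes in the test suite — 2000-gene atlases, 24–28-line cohorts at
  depth 5000, 100 kb off-target genomes — mirror the study-scale inputs the
  pipeline is designed around while keeping the whole suite fast.

# Known limitations

* The genotyper classifies variants against a single reference amplicon per
  locus; it does not phase multiple edited haplotypes within a line.
* The motif catalog is a small curated consensus list; it is not a
  re-implementation of any web service's matrix library.
* The off-target score is an explicit, simple model for ranking; it is not
  calibrated to cleavage or deamination efficiencies.
* The screen's atlas filter assumes per-tissue means are comparable across
  tissues (same normalisation); it applies no cross-sample renormalisation
  of its own.
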