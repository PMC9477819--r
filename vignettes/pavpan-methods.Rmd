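---
title: "Pan-genome PAV analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome PAV analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavpan)
```

## The problem

A single reference genome does not contain every sequence present in a
population: individual genomes carry kilobase-scale insertions of
non-reference sequence, and many annotated genes are wholly deleted in some
individuals. A *pan-genome* augments the reference with the non-reference
sequences discovered in per-sample de novo assemblies, and *gene
presence–absence variation* (PAV) describes which genes each individual
actually carries. Cohort comparisons of per-gene absence frequencies (for
example tumour cohorts against population controls) can then point at genes
whose loss is associated with disease.

pavpan implements this pipeline end to end: contig classification against a
reference, extraction and de-duplication of non-reference sequence,
pan-genome assembly, depth-based PAV calling, cohort statistics,
anchor-based chromosomal placement of non-reference genes using long-read
contigs, and cross-validation of PAV calls against merged multi-caller
structural variants (SVs). Because the real studies this mirrors rest on
controlled-access data, the package ships a deterministic simulator that
generates a complete toy study with machine-readable truth; every pipeline
property is tested against that truth.

## Numeric rules

All thresholds live in one validated object, `pav_thresholds()`, threaded
explicitly through every function. The defaults encode the pipeline's
standard operating point:

* contigs are kept when **longer than 500 bp** (strictly);
* a contig is *reference* when it aligns with **identity ≥ 0.95 over
  ≥ 0.95 of its length** (both inclusive, matching the "95% or more …
  covering 95%" phrasing);
* a gene is *present* when **more than 80%** of its representative CDS is
  covered by reads (strictly more; exactly 80% is an absence);
* the top-ranked distributed genes split into highly vs lowly absent at
  **50% CDS coverage** among their absence-called samples;
* anchors are the **3000 bp** flanking a gene hit on a long-read contig, a
  placement is accepted when the anchor's best reference alignment is
  **longer than 1500 bp at identity above 80%**, and the inter-anchor gap
  becomes the locus when **shorter than twice the gene length**;
* SV merging uses max breakpoint distance **1000 bp**, support **≥ 2**
  callers, type and strand agreement, minimum size **30 bp**; insertions
  that are **more than half** tandem-repetitive are dropped (exactly half is
  kept);
* comparisons flag genes at **FDR < 0.05** and odds ratios **> 1.5**.

Comparison semantics follow each rule's wording literally; the boundary
behaviour (inclusive 95/95, strict >80%) is asserted in the test suite.

## Alignment model

The internal aligner is an exact-seed chaining aligner: k-mer seeds
(k = 15, both strands) are grouped by (target, strand, diagonal), chained
when consecutive seed starts are within a gap budget (100 bp), extended
ungapped under an X-drop rule, and scored by exact column comparison.
Because it never opens gaps it is only suitable for substitution-level
divergence; that is exactly what the simulator produces, and real-data
users are expected to import PAF from a production aligner via
`read_paf()` instead. On random sequences with up to 5% substitutions the
chained blocks agree with `Biostrings::pairwiseAlignment()`'s local optimum
to within one seed length at each end (a property test).

Two numerical details matter downstream:

* **Extensions keep ≥ 90% identity.** A pure X-drop extension can drift a
  handful of bases past the junction between reference flank and novel
  sequence on chance matches (about one base in four matches at random).
  The drift is bounded by the X-drop but still trimmed short cassettes by
  up to ~13 bp per side, which matters for sub-kilobase insertions.
  Requiring the accepted extension to keep score ≥ 0.8 × length (identity
  ≥ 0.9) pins block ends to within a base or two of true junctions while
  leaving extensions through ≤5% substitution noise unaffected.
* **Overlapping blocks are all reported.** Selection pressure is applied
  only in `summarize_query()`, which takes the maximal-total-length
  non-overlapping subset (ties toward higher identity) by weighted interval
  scheduling. Classification rules consume coverage, not a unique
  alignment.

The gene-to-contig matcher used in placement raises the same-diagonal gap
budget to 250 bp: its acceptance rule is a *global* identity over the
coding region ("matching columns / coding length > 0.8"), so seedless
stretches caused by error clusters at 10–20% divergence must be bridged
within one block rather than split into fragments that individually fail a
length floor.

## Contig classification and the pan-genome

Each contig with any alignment is summarized by covered fraction and
length-weighted identity; the 95/95 rule decides REFERENCE, no alignment at
all decides FULLY_UNALIGNED, and everything else is partially unaligned.
The rule has a consequence worth knowing: a long contig carrying a small
insertion (under 5% of the contig's length) still passes 95/95 and is
absorbed as reference, so its novel segment is not extracted from *that*
contig. Discovery of such cassettes relies on shorter carrier contigs,
which assembly fragmentation supplies in practice; the acceptance test
verifies ≥ 99% cassette recovery at the default break rate.

Flank placement of an unaligned segment is not defined numerically in the
literature this follows; the rule adopted is: a flanking aligned segment
qualifies when it is at least `min_contig_len` long, two qualifying flanks
on the same chromosome and strand with a reference gap below 10× the
segment length give a two-end placement, exactly one qualifying flank a
one-end placement. The 10× bound rejects chimeric joins.

Redundancy removal is greedy longest-first with the 95/95 pair reused
(absorption needs identity ≥ 0.95 over ≥ 0.95 of the candidate's own
length); the operation is idempotent and records which sequences each kept
sequence absorbed. The weighted (rather than best-single-alignment) form of
identity is used throughout; with substitution-only divergence the two
coincide except on fragmented alignments, where the weighted form is the
more faithful reading of "95% identity covering 95%".

`mapping_rate()` counts a read as mapped when one block covers ≥ 90% of it;
the 0.9 was chosen so substitution noise of a few percent never unmaps a
read — the scientific contract is the reference-vs-pan-genome *comparison*,
which is monotone by construction (the pan-genome's targets are a superset).

## PAV calling

Only the transcript with the longest total CDS represents a gene (ties: the
first listed). Coverage is |covered ∩ CDS| / |CDS| on that transcript, with
a base "covered" at depth ≥ 1 by default (`depth_presence_min`; the choice
of 1 follows the plain reading of "covered by mapped reads" and is
configurable). Genes present in all evaluable samples are CORE; chrY genes
are evaluated over males only, since females carry no chrY; a chrY gene in
an all-female cohort is UNEVALUABLE — a label introduced here because the
motivating cohorts always contained males, so the case is otherwise
undefined.

## Cohort statistics

Per gene, a 2×2 table of absent/present counts in two cohorts (chrY genes
counted over males only) is tested with the two-sided Fisher's exact test
under the probability-ordering convention — the sum of hypergeometric
probabilities of tables at most as probable as the observed one, with the
customary 1 + 1e-7 relative tolerance on ties. The implementation
enumerates `dhyper` terms directly; tests compare it against an independent
binomial-coefficient oracle over every table with row sums ≤ 30 and against
`stats::fisher.test`. q-values are Benjamini–Hochberg over exactly the
genes in the comparison (never pooled across comparisons), via
`stats::p.adjust`, cross-checked against a hand-written step-up. Odds
ratios use the Haldane–Anscombe +0.5 correction when any cell is zero, and
are reported on the absence scale (case-absence odds over control-absence
odds).

Two conventions are deliberate decisions where the source material is
silent: "top 20" ranking for the HAG/LAG split uses case absence frequency
(descending), isolated behind `top_n`; and HAG membership summarizes a
gene's coverage by the *median* over its absence-called samples, compared
against the 50% threshold.

A note on null behaviour: Fisher p-values on small 2×2 tables are discrete
and conservative, so their null distribution is super-uniform — a
Kolmogorov–Smirnov test against U(0,1) would reject by construction. The
test suite therefore checks the meaningful property directly:
P(p ≤ α) ≤ α (within Monte-Carlo error) across a grid of levels, plus
empirical FDR control of the flags and power on planted 0.6-vs-0.05
absence differences at n = 50 per cohort.

## Anchor placement

A gene is matched to a long-read contig when matching columns exceed 80% of
its coding length; the 3000 bp flanking the hit become anchors (a side with
a shorter flank is disqualified rather than shortened, keeping the 1500 bp
acceptance rule meaningful); each anchor's best reference block (by length,
then identity) must exceed 1500 bp and 80% identity; and the reference gap
between the inner anchor boundaries is the locus if it is shorter than
twice the gene length — abutting or overlapping anchors yield the
zero-length insertion point, which is accepted. Loci accepted across
contigs are clustered by interval overlap (single linkage) and the cluster
with most supporting contigs wins (ties: leftmost), with median consensus
boundaries. Reverse-complementing a contig leaves the locus unchanged, and
genes never planted in a genome are essentially never placed (both tested).

## SV merging

The merge follows the decoded parameter string "1000 2 1 1 0 30": max
breakpoint distance 1000 bp, at least 2 supporting callers, type and strand
agreement, no distance scaling, minimum size 30 bp. Clustering is *seeded*:
the leftmost unassigned call opens a cluster and recruits, from each other
caller, the closest unassigned call whose start and end breakpoints are
both within the cap; at most one call per caller. Pure single linkage was
tried first and rejected on the simulator's evidence: deletions of
neighbouring genes can lie closer than 1000 bp, single linkage chains them
into one cluster, and the one-call-per-caller rule then discards genuine
calls — truth recovery fell measurably below the binomial expectation for
"2 of 3 callers" at the simulated false-negative rate. Seeded clustering
keeps neighbouring events separate, the way pairwise merging tools behave.

DEL-derived PAV subtracts merged deletion intervals from an
everywhere-covered track and reuses `cds_coverage()` and `call_presence()`
verbatim (optionally restricted to homozygous DELs, trusting the caller
genotypes). The tandem-repeat fraction used by the insertion filter is an
explicit simplification — perfect tandem tracts of period ≤ 6 and length
≥ 20 — not a re-implementation of full repeat masking; real-data users can
supply a precomputed `repeat_frac` column from an external masker instead.

## The simulator: what it emulates, and what it does not

`sim_params()` defaults define the package's reference study: 3 chromosomes
of 100 kb (the last named chrY), 120 reference genes (10% on chrY,
1–3 CDS exons, spans 600–2000 bp), 6 novel genes inserted as contiguous
cassettes (gene ± 50 bp pad) at fixed intergenic autosomal loci carried by
half the population, two cohorts of 25 samples with genes g001–g005 planted
at 0.6 and g006–g010 at 0.3 case absence (controls at 0.05), sex ratio 0.5,
150 bp reads at mean depth 30, one assembly break per 10 kb, error-free
bases, and three SV callers with 50 bp Gaussian breakpoint jitter, 10%
false negatives and 5% false positives. These sizes keep the full
end-to-end analysis and its tests in the low minutes on one CPU while
leaving every rule's operating range exercised (multi-exon genes, chrY
males-only evaluation, sub-kilobase and multi-kilobase cassettes, adjacent
deletions closer than the SV merge cap).

Deletions excise the gene span ± 50 bp exactly, so PAV truth and SV truth
coincide by construction — that is what makes the depth-PAV vs DEL-SV-PAV
concordance property exact rather than approximate. Insertion loci are
planted at least a long-read flank (+1 kb) from chromosome ends; otherwise
the generator could not honour its own contract that spanning long-read
contigs carry a full anchor flank on each side. Randomness uses one seed
plus per-sample sub-seeds derived by stable hashing of the sample id, so
outputs are byte-identical across runs and adding a sample never perturbs
the others.

Features of real data deliberately *not* modelled: diploidy and
heterozygosity, somatic-vs-germline distinction, indel sequencing errors,
base qualities, repeat families beyond planted tandem tracts, GC bias, and
contamination. Passing tests therefore demonstrate the pipeline's logic and
numerics — truth recovery under the stated noise model — not robustness to
every artefact of real sequencing; the PAF, depth-TSV and VCF-like
adapters are the intended entry points for real data.

## Problem sizes used by tests and the acceptance script

Unit tests run on a reduced design (2–8 samples, 12–24 genes on 40–60 kb
chromosomes). The acceptance properties and `scripts/acceptance.R` run the
full reference design above (50 samples, 126 genes, ~300 kb per genome),
subsample 800 evenly strided reads per sample for the mapping-rate
comparison (enough that every insertion carrier contributes
cassette-interior reads), use 200 replicates for the null-FDR and power
simulations, and enumerate every 2×2 table with row sums ≤ 30 for the
Fisher oracle. Statistical assertions allow three Monte-Carlo standard
errors around their expectations; exact assertions (truth recovery,
placement error ≤ 14 bp = k − 1, oracle deviations ≤ 1e-12) carry no slack.

## Known limitations

* The seed aligner cannot represent gapped alignments; genomes with indel
  divergence need an external aligner via PAF.
* A cassette below ~5% of every carrier contig's length would evade
  extraction entirely (the 95/95 rule absorbs those contigs); only
  assembly fragmentation makes discovery possible.
* The repeat scanner detects perfect tandems only; diverged repeats need an
  external mask.
* `fisher_exact_two_sided()` enumerates the hypergeometric support, which
  is exact but slow for cohort sizes in the thousands.
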