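---
title: "TIP maps from pangenome structural variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIP maps from pangenome structural variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the tests do and do not establish.

## The pipeline in one paragraph

A sequence-resolved SV catalog (full REF/ALT sequences, as produced by
pangenome-graph deconstruction) is classified into insertions, deletions
and allelic variations; every SV allele is matched against a
non-redundant pan-TE library under the 80–80 family rule; overlapping
annotations are reduced by a retention cascade; SVs whose focal allele is
sufficiently covered by TE sequence become TIP sites. TIPs are then
related to gene models (events, TIP genes, density profiles, subspecies
conservation), the genome is partitioned into pTE/cTE/non-TE space for
histone-mark and methylation quantification, expression matrices are
screened for cold-responsive genes and TEs and for ±TE expression
contrasts, a consensus co-expression network links TEs to genes, and a
genotype panel is scanned for TIP–phenotype associations.

## Coordinates and formats

All internal coordinates are 0-based half-open; conversion to the 1-based
inclusive conventions of GFF3 and VCF happens only inside the readers and
writers, so converting in and straight back out is the identity. Symbolic
VCF ALT alleles are rejected rather than tolerated: TE annotation needs
the inserted sequence itself, and a `<INS>` placeholder cannot be
annotated. Missing genotypes are kept missing; no imputation happens in
the I/O layer, because each downstream filter owns its missingness
policy.

## The 80–80 matcher

Two sequences are declared members of one TE family when a local
alignment reaches ≥ 80 % identity over ≥ 80 bp and the aligned length
covers ≥ 80 % of a denominator sequence. Published TIP studies delegate
this decision to blastn-style tools whose scoring is tool-internal; this
package fixes one explicit scheme so the decision is reproducible: match
+1, mismatch −1, gap open −2, gap extend −1, 15-mer seeds, and a banded
affine-gap (Gotoh) extension over the seed diagonals ±30, both strands.
Identity is matches divided by alignment columns. The coverage
denominator is genuinely ambiguous in the field's phrasing of the rule
(query, library entry, or the shorter of the two); the package defaults
to the *shorter* sequence — the permissive reading — and exposes
`coverage_denominator` to switch. The matcher is validated against an
independent full Smith–Waterman oracle (Biostrings) on seeded random
pairs up to 1 kb; hit/no-hit decisions agree on all 200 tested pairs.

Library deduplication is greedy longest-first: an entry is retained iff
it has no 80–80 match to an already-retained entry. Greedy-by-length is
deterministic and keeps the longest exemplar of each family cluster as
its representative.

## Overlap resolution

The retention cascade for overlapping TE annotations on one target:

1. same superfamily → keep the higher score; equal scores → keep the
   longer; still tied → keep the leftmost;
2. different structural groups with one annotation fully nested in the
   other → keep both iff the (inner, outer) pair is a known nesting
   configuration: LTR in Helitron, Helitron in LTR, TIR in LTR, LTR in
   TIR;
3. remaining boundary-crossing overlaps → keep the annotation of higher
   structural priority (LTR > TIR > SINE/LINE > Helitron > other).

Two points were open and are fixed here as package policy. First, SINEs
and LINEs share one priority tier — the natural reading of the ordering
"LTRs first, then TIRs, then SINEs and LINEs, Helitrons, others".
Second, overlaps between *different superfamilies of the same structural
group* (e.g. Gypsy vs Copia) have equal priority and no whitelist entry;
they fall back to the score/length/leftmost chain. The cascade scans
annotation pairs in (start, end) order and restarts after each removal,
which makes the outcome deterministic; chains of overlaps are genuinely
order-sensitive under any pairwise rule, so the scan order is part of
the definition. The suite checks agreement with an independently coded
implementation of the same semantics on random instances of up to 12
annotations, plus idempotence and the subset property.

"Score" in the cascade is this package's alignment score. The original
analyses compared scores produced inside their annotation tool; those
are not reproducible outside it, and any monotone alignment score
preserves the cascade's intent.

## TIP calling

An SV is promoted to a TIP site when the union of resolved annotations
covers at least `min_te_fraction` of the focal allele — the longest
non-reference allele for insertions, the deleted segment for deletions.
The threshold that took TE-containing SVs to TIP sites in the motivating
analyses is not published; the default is 0.8 (consistent with the
80–80 spirit), it is configurable, and it is recorded in the `tip_set`
output. For multi-allelic SVs each non-reference allele is annotated
independently and the site qualifies if any allele passes. The dominant
superfamily is the one with the greatest summed annotated length, ties
broken by the longest single annotation and then lexicographically.

## Events and anchors

An event is one (TIP, gene) co-occurrence within 2 kb, classed
upstream2k / exon / intron / downstream2k with "upstream" meaning 5′ on
the gene's own strand. The anchor of an insertion-type TIP is its
breakpoint; for deletion-type TIPs the midpoint of the deleted span —
a TE spanning a class boundary has no published convention, and the
midpoint rule is deterministic and symmetric. A TIP exactly on a gene
edge counts as inside (half-open convention). A TIP near two genes
yields two events; a gene with two TIPs yields two events; the
unique-insertion gene sets (exactly one event, in a given class) are the
populations on which ±TE expression contrasts are interpretable.

## Epigenome partition

pTE space is TE-annotated sequence overlapping any TIP interval; the
remaining TE space is cTE; everything else non-TE. Labelling is at base
resolution by default (a TE split by a TIP boundary contributes to two
labels); a whole-feature mode exists because figure-level workflows in
the literature do not state which they used, and both bp-weighted and
feature-count-weighted proportions are emitted by the quantifier. The
original derivation used synteny blocks between two genomes; on a single
reference the TIP-overlap definition is equivalent for the purpose of
separating polymorphic from shared TE space, and a synteny-block input
path can be expressed by supplying those blocks as TIP intervals.

## Statistical choices

*Differential expression.* The published criteria are |log2FC| ≥ 1 and
FDR < 0.05. The original used a negative-binomial count framework;
re-implementing that estimator is out of scope here, so the package
tests abundances with a Welch two-sample t on log2(x+1) and
Benjamini–Hochberg adjustment, keeping the published gates. This is a
method substitution and is stated as such: acceptance is on synthetic
truth recovery (type-I ≤ nominal, power ≥ 0.9 at |log2FC| = 3 with 6
replicates and noise SD 0.5), not on matching any external tool's
output. log2FC uses a pseudocount of 1, the same constant the
co-expression preprocessing uses.

*Wilcoxon tests* (±TE contrasts, eQTL scan, haplotype survival,
methylation contrasts) use `stats::wilcox.test`, which is exact for
small untied samples and normal-approximated with continuity correction
otherwise.

*Co-expression.* The published network took edges supported by at least
two of four tools (WGCNA, PCC, CORNET, TEffectR). Two of those are
services or pipelines that cannot be meaningfully re-run here; what the
analysis depends on is the consensus semantics, not the tool roster. The
package therefore votes with three in-house methods — Pearson (|r| ≥
0.55), Spearman (|ρ| ≥ 0.55) and a covariate linear model (gene on TE
plus time-point indicators, adjusted R² ≥ 0.9) — under the same
consensus-of-≥2 rule, with full per-method provenance kept on every
edge. The 100 kb cis window is inclusive and measured edge-to-edge
(distance from feature boundary to feature boundary), the midpoint
alternative being undocumented in the sources that define the rule.

*lncRNA filter.* Candidates are ≥ 200 nt with a longest ORF ≤ 120 aa and
TE overlap. ORFs are scanned on the three forward frames because
assembled transcripts are oriented; a `both_strands` option covers
unstranded input. An ORF without an in-frame stop is counted to the last
complete codon — the conservative choice for a *maximum*-ORF gate.

*Association.* The mixed model is an EMMAX-style approximation rather
than a wrapper: kinship is the centered dosage cross-product scaled by
variant count; the null model's heritability is profiled on a grid
(0–0.99, step 0.01) over the eigendecomposed kinship; each variant is
then tested by GLS in the rotated, whitened space. Heterozygous calls
enter as additive dosage 0/1/2 (the coding the sources leave
unstated); per-variant missing dosages are excluded for OLS and
mean-imputed for the rotated mixed model. PCs are computed on
mean-imputed centered dosages and used only as covariates. With few
variants the tested variant is itself a non-negligible part of the
kinship (proximal contamination), so lm and lmm p-values diverge
slightly at small panel sizes; the suite checks that the two models rank
a causal variant concordantly and that the mixed model collapses to OLS
when the phenotype carries no genetic signal.

## The synthetic pangenome

The generator defines the package's study conditions: two subspecies of
five haplotypes each, 40 genes in fixed-geometry slots on two
chromosomes, a 12-family TE library over six superfamilies (LTR/Gypsy,
LTR/Copia, MITE/Tourist, DNA/Mutator, DNA/Helitron, LINE/L1), 200
planted TE insertions, 10 planted random-sequence (non-TE) insertions,
16 reference TE copies deleted in some haplotypes and 20 consensus
copies deleted in none. Insertion placement follows the
upstream : exon : intron : downstream weights 9131 : 3201 : 4358 : 7686 —
the event proportions of real rice TIP maps — relative to a uniformly
chosen gene. Planted copies carry ≤ 5 % point mutations (default 2 %),
keeping them inside the 80–80 family boundary, and a 0–10 bp target-site
duplication to exercise breakpoint handling. 30 % of insertions are
fixed within one subspecies and absent from the other, giving planted
fixed-differential sites; the rest segregate at 50 % per haplotype.

The slot geometry (gene flanked by dedicated 2 kb zones, reference TE
copies ≥ 2.3 kb from any gene, ≥ 4 kb between neighbouring genes'
windows) guarantees that every planted insertion produces exactly one
event at its planted gene and class, and that deletion-type TIPs produce
none — which is what lets the suite demand *exact* event recovery
rather than approximate. Chromosome length is emergent from the layout
(~190 kb per chromosome at the defaults); supplying `chrom_length` pads
the tail or errors if the layout cannot fit.

Expression: log-normal baselines (log2 mean 5, SD 1), three time points
× three replicates, replicate noise SD 0.5 on the log2 scale. Each gene
with upstream or intron insertions gets *one* designated causal TIP
whose carriers are shifted down by 2 log2 units — one causal TIP per
gene keeps the carrier/non-carrier contrast clean when several TIPs
surround the same gene. A seeded 30 % of features receive a true cold
response (|log2FC| 1.5–3 at 24 h, ×1.2 at 72 h), genes mostly down and
TEs mostly up, mirroring the direction asymmetry reported for cold
stress. Peaks: each pTE interval carries a peak with probability 0.46 at
0 h and 0.66 at 72 h, cTEs 0.27 and 0.30 — the baseline values mirror
the reported ~46 % vs ~27 % marking of pTEs vs cTEs; a single latent
uniform per interval is shared across conditions, so a planted
probability increase is always a peak-count increase. Methylation:
per-cytosine Beta draws — pTE Beta(8, 2), cTE Beta(2, 8), non-TE
Beta(1, 9). Population: 200 accessions in two subpopulations with
Beta(2, 2) allele frequencies differentiated by a Normal(0, 0.15)
offset; the causal TIP at frequencies 0.7/0.3; survival = 50 +
40·dosage/2 + a small polygenic term + Normal(0, 10), truncated to
[0, 100].

Determinism: the master seed drives everything; each sub-generator
derives its stream by a fixed offset (+1000 expression, +2000 epigenome,
+3000 population), so stages are independently reproducible and two
runs with one seed are byte-identical.

What the generator does **not** emulate: read-level noise and mapping
error (inputs are taken as already quantified), genotyping error in the
panel, linkage disequilibrium beyond subpopulation differentiation,
nested or truncated TE insertions, segmental duplications, and reference
bias. Passing the planted-truth suite therefore shows the pipeline's
logic is correct under clean signals of realistic effect sizes; it does
not certify performance on noisy real alignments.

## Numerical conventions and degenerate inputs

Constant expression rows are flagged before quantile normalization
(which would otherwise hide their flatness) and excluded from
correlation methods. Empty genome categories report an undefined (`NA`)
proportion rather than 0. Negative MDA values are returned with a
warning, never clipped. Monomorphic variants are skipped with a reason,
not fitted. All-missing TIP genotypes skip the eQTL pair with a log
entry. BH-adjusted p-values are monotone by construction of
`p.adjust`'s step-up enforcement, and the suite asserts it.

## Problem sizes

The suite and the acceptance script run at the generator's default scale
(226 SVs, 52 expression features, 200 accessions, 215 panel variants),
with 200 alignment-oracle pairs, 60 overlap-resolution instances, 50
null DE simulations, 11 null association panels and 100 causal-ranking
replicates — sizes chosen so every stochastic check has enough
replication to be stable under its stated tolerance while the whole
suite stays desk-scale.

## Known limitations

- The 80–80 matcher reports the best local alignment per (family,
  strand); two tandem copies of one family in a single allele are
  annotated as one hit. TIP calling is unaffected (coverage is a union),
  but per-copy counts inside one allele are not produced.
- The overlap cascade's outcome on overlap *chains* depends on its
  documented scan order; alternative orders can retain different but
  equally rule-consistent subsets.
- The association scan does not model dominance or epistasis, and the
  EMMAX-style variance components are estimated once on the null model,
  as in the original approximation.
- `run_tip_pipeline` orchestrates the simulated end-to-end path; on real
  data the stages are called individually with external files loaded
  through the I/O layer.
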