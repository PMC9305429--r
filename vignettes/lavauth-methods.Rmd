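---
title: "Methods: combined barcode and chemotype authentication of Lavandula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined barcode and chemotype authentication of Lavandula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lavauth)
```

## The problem

Lavender raw material is routinely adulterated: cheap lavandin (*Lavandula
× intermedia*) or spike lavender passed off as fine lavender
(*L. angustifolia*), or unrelated Lamiaceae mixed into dried material.
Chemical fingerprints alone are fragile — metabolite levels shift with
developmental stage, stress and storage — while a single DNA barcode rarely
separates closely related species and cultivars. `lavauth` implements both
evidence lines for an eleven-accession reference panel (ten *Lavandula*
accessions and the outgroup *Perovskia atriplicifolia*) and merges them into
a per-sample authentication verdict.

## Genetic model

Three barcode markers are used: two universal plant barcodes, plastid *rbcL*
(marker B1, 690 bp amplicon) and the *trnH–psbA* intergenic spacer (B2,
273 bp), whose primers carry IUPAC-degenerate positions, plus a
*Lavandula*-specific nuclear ITS marker (Lav, 490 bp) with exact primers.

*In-silico PCR.* A primer binds where every primer position is IUPAC
compatible with the template (a degenerate base matches any base in its
expansion and never counts as a mismatch there), allowing at most
`max_mismatches` incompatibilities (default 2). The lowest-mismatch site
wins; ties go to the smallest position. The amplicon runs from the first
base of the forward site to the last base of the reverse site, primers
included. Coordinates are 1-based and closed throughout, following R and
Bioconductor convention.

*Distances and trees.* Marker amplicons of one locus have equal length
across the panel, so no alignment step is needed; the package refuses
unequal lengths rather than aligning silently, and a global aligner is
deliberately out of scope. Distances are uncorrected p-distances — at the
divergences involved (scale bars of a few substitutions per thousand sites)
model correction is immaterial, and no substitution model is assumed.
Positions where either sequence is ambiguous are excluded from numerator
and denominator. Trees are built with UPGMA (average linkage, node height =
join distance / 2), which matches the ultrametric display convention of
barcoding studies. Because agglomeration order is undefined under ties, the
package fixes a reproducible rule: the pair of clusters whose
(lexicographically sorted) smallest-member labels compare lowest is joined
first. Clade support comes from the nonparametric bootstrap: alignment
columns are resampled with replacement, the tree recomputed, and a clade's
support is the percentage of replicates containing exactly the same leaf
set. Each replicate draws from its own seeded substream, so runs are
reproducible for a given seed.

*Discrimination.* The operative result is not the tree but the
identical-sequence partition: two taxa are indistinguishable by a marker
set when their (concatenated) amplicons are bit-identical. An `N` never
proves identity — a sequence containing `N` is conservatively treated as its
own singleton. A taxon in a singleton group is "fully differentiated". On
the reference panel, the B1+B2 concatenation differentiates 4 taxa and
leaves three shared-haplotype clusters; the ITS marker alone differentiates
5 (splitting *L. angustifolia* 'Blue' from *L. latifolia*); the three-marker
concatenation differentiates 6, leaving two residual groups:
{'White', 'Abrial', 'Grosso'} and {*L. allardi*, *L. dentata*} — the
latter expected, since *L. allardi* is an *angustifolia × dentata* cross.

## Chemical model

Input is a peak table per sample (retention time in minutes, area) from a
20-minute reversed-phase UHPLC run. Each library compound takes the
largest-area peak within ±0.05 min of its reference retention time — a
typical UHPLC retention-time reproducibility window; co-eluting compounds
(the diterpenes at 12.85 min) may share a peak. "Major presence" is not
quantified in the underlying study, so it is operationalised as a relative
area (area over the sample's total matched area) above a configurable
threshold, default 5 %. The seven criteria are:

1. major presence of coumaric acid hexoside (8) *and* ferulic acid
   hexoside (14);
2. major presence of rosmarinic acid (53);
3. presence of both cinnamic-acid-derived compounds 15 and 16;
4. absence of both 15 and 16;
5. presence of the depside family (at least two distinct members, so a
   single spurious retention-time match cannot trigger it);
6. presence of linalyl acetate (93);
7. presence of the diterpene family (any member).

Criteria 3–7 are simple presence tests because the key's footnote states
them as presence, not major presence. Classification is
nearest-reference-profile matching against the packaged eleven-row key
(Hamming distance over the seven criteria, ties to the lowest cluster
number, assignment only within a configurable maximum distance, default 1)
rather than a handwritten decision tree: the narrative cluster descriptions
and the printed key disagree in places, and the printed rows are taken as
authoritative.

Two recorded ambiguities in the key: (a) the printed criterion-6 marks on
the four cluster-1 rows conflict with the narrative statement that linalyl
acetate separates *L. stoechas* from everything else; the key stores them
as printed and `lav_criteria_key(override=)` lets a user flip any cell.
(b) Two rows ('White', 'Abrial') mark neither criterion 3 nor criterion 4.
Since criterion 4 is defined as the joint absence of the pair whose joint
presence is criterion 3, such a profile is realisable only when exactly one
member of the pair is present; the synthetic generator therefore emits a
trace of compound 15 for those taxa, and the criteria pair is tested as
mutually exclusive (never both true) rather than as an exclusive-or.

Retention times for compounds 21 and 37 are not part of the printed
reference set; the library ships nominal values (4.80 and 5.90 min)
consistent with the elution order of their families. Neither compound feeds
a criterion.

## Combining the evidence

Genetics is authoritative: it is unaffected by developmental stage or
storage, so a singleton haplotype group resolves a sample regardless of
chemistry, and chemistry can never overrule it. Within a multi-member
haplotype group, chemistry refines: candidates are the group members whose
key row carries the sample's assigned cluster and matches any named
refinement sub-pattern for that cluster. One refinement rule ships by
default — within chemical cluster 1, joint criteria 2 and 3 separate the
Blue/Grosso chemotype from the White/Abrial chemotype. It is a named,
configurable rule rather than hardcoded logic because the underlying
evidence (rosmarinic-acid levels near background in some samples) is
acknowledged to be stage-dependent. The *dentata*-vs-*allardi* difference
in criterion 1 inside cluster 2 is deliberately **not** used: it rests on
the same fragile compound family, so group G stays unresolved, matching the
reference analysis. A singleton intersection resolves the sample; a smaller
but plural set is reported `group_only` with candidates ranked by Hamming
distance then alphabetically; an empty intersection is a `conflict`,
reported and never auto-resolved.

On the zero-noise panel this yields 7 resolved samples (6 by genetics
alone, plus 'Grosso' by the cluster-1 refinement) and two residual pairs:
{'White', 'Abrial'} and {*allardi*, *dentata*}.

## The synthetic panel

No reference sequences are deposited for the original accessions, so the
generator produces random sequences constrained to the printed structure,
which is all the discrimination analysis depends on: per marker, one
ancestral inter-primer core is mutated independently per haplotype class at
`between_class_divergence` (default 0.02 substitutions per site, consistent
with the reported tree depths), primer binding sites are one concrete
seeded resolution of the degenerate bases, and flanks of 30 bp surround the
amplicon. Within-class divergence is fixed at zero — the clusters are
*defined* by exact sequence identity, so any nonzero value would change the
target partition, not approximate it. Distinct classes are verified to
differ and patched deterministically in the (vanishingly unlikely) case of
a collision. Simulated read pairs cover ~60 % of the reference from each
end (overlap at least 30 bp); substitution errors (default rate 0) are
injected only outside the overlap so merging stays unambiguous.

Peak tables emit area 1000 for major-presence compounds, 400 for the two
extra discriminant compounds (21 for the cluster-1 taxa, 37 for the
cluster-2 taxa), and 30 for presence-only family markers, with Gaussian
retention-time jitter (default sd 0.01 min, well inside the 0.05-min
matching tolerance) and optional noise peaks kept at least three tolerance
widths from every library compound. With these areas exactly the seven
named discriminant compounds exceed the 5 % relative-area threshold in at
least one sample.

What the generator does **not** emulate: sequencing quality scores and
chromatogram traces, indels and length polymorphism, ITS paralogue
variation within a taxon (a single ITS sequence per taxon is assumed),
chromatographic baseline drift, co-elution beyond what the library
retention times imply, and between-replicate biological variance in peak
areas. Passing tests therefore demonstrate that the pipeline's logic
recovers the encoded structure, not that it would be robust to every
artefact of real Sanger or UHPLC data.

## Numerical choices and problem sizes

Ultrametricity is asserted to 1e-9; UPGMA heights are compared to the
independent from-scratch oracle at 1e-12 (the Lance–Williams update and the
mean-over-pairs formulation are algebraically identical but not
bit-identical). Bootstrap replicates default to 1000, the conventional
figure for barcoding studies; the test suite uses 1000 where supports are
asserted and smaller counts where only plumbing is exercised. The
UPGMA-vs-oracle suite runs 100 random matrices of 3–6 taxa; partition
recovery is checked over 20 generator seeds through the full read-merge and
amplification path. These sizes were chosen to exercise every tie-break and
code path at negligible runtime.

## Known limitations

- Equal-length amplicons are assumed per marker; real panels with indels
  need external alignment first.
- The chemotype key is a presence/absence abstraction; it cannot weigh
  quantitative ratios, and samples at intermediate developmental stages may
  legitimately sit between rows (hence the configurable Hamming slack).
- Bootstrap support on near-zero distances is near-deterministic by
  construction and should not be over-interpreted as statistical evidence.
- Mixtures (multi-species raw material) are out of scope; each sample is
  assumed to be a single accession.

```{r}
res <- run_all(seed = 1, bootstrap = 200)
res$report$n_species_resolved
res$report$unresolved_groups
```
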