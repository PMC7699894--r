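---
title: "Scoring somatic mutations in predicted miRNA-binding sites"
author: "mirsitemut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring somatic mutations in predicted miRNA-binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsitemut)
```

## The problem

A miRNA represses a transcript by pairing with a short element, usually in
the 3' UTR, whose core is Watson-Crick complementarity to the miRNA *seed*
(nucleotides 2-8 from the 5' end). A somatic mutation inside such an element
can weaken or abolish the repression, and in lymphoma the genes involved
(e.g. *BCL2*, *EZH2*) are the same genes that drive the disease. This
package implements the desk half of that analysis: predict binding sites in
transcript regions, intersect them with somatic variants, quantify the
binding change between wildtype and mutant alleles, and run the
cohort-level filtering that turns a raw amplicon-panel call set into a
ledger of credible recurrent variants.

## Site prediction

Three layers, each reproducible from sequence alone.

**Seed classes.** A site is anchored by an exact Watson-Crick match to
miRNA positions 2-7 on the target (transcript orientation). The canonical
hierarchy is applied with precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer: m8
adds a Watson-Crick pair to position 8 at the site's 5' end, A1 adds an
adenine opposite position 1 at its 3' end. G:U wobbles stabilize duplexes
but never satisfy a seed class, which is Watson-Crick by definition.

**Seed-weighted duplex alignment.** Each seed match is rescored by a local
alignment (affine gaps) of the miRNA read 3'->5' against a target window
read 5'->3' -- the antiparallel geometry of the duplex. Column scores are
match +5, G:U wobble +1, mismatch -3; gaps open at -8 and extend at -2;
columns pairing miRNA positions 2-8 are multiplied by the seed weight 4.
All values are dimensionless and configurable through `align_params()`. A
site is reported when it has a seed class *and* reaches `min_score = 80`;
a bare 6mer seed already scores 120, so the default threshold admits every
canonical seed class while rejecting incidental partial complementarity.
The window extends one miRNA length 5' of the seed match, where
3'-supplementary pairing (typically positions 13-16) falls, plus a short 3'
margin. The aligner is checked against a brute-force enumeration over all
monotone pairings for every input up to a 10-nt miRNA against a 12-nt
window.

**Duplex free energy.** Stability is a nearest-neighbor sum: one
initiation penalty plus tabulated stacking terms over consecutive paired
columns, with a fixed penalty per interior loop or bulge event. The 16
Watson-Crick dinucleotide stacks carry standard 37 degC free energies
(kcal/mol); any stack involving a G:U wobble uses a single representative
constant (-1.3 kcal/mol) rather than the full wobble table. Two numerical
choices deserve a note:

* `initiation = 0.5` kcal/mol is deliberately smaller than the
  literature-scale duplex initiation (about +4.1). The pipeline only ever
  compares a wildtype duplex against its mutant counterpart, where the
  initiation term cancels; the small default additionally keeps every
  helix of two or more stacked pairs at or below 0 kcal/mol, so the sign
  of `delta_g` is directly interpretable as "stable duplex". Users who
  want literature-comparable absolute energies can set
  `nn_params(initiation = 4.09)`.
* Terminal-AU corrections and length-dependent loop tables are omitted:
  they shift wildtype and mutant by nearly identical amounts and are
  invisible in the difference.

**Confidence filter.** "Most confident" is operationalized as per-miRNA
alignment-score rank -- the only confidence measure the seed and alignment
layers share. Per miRNA, the top `ceiling(0.75 * n)` sites are kept, ties
at the cutoff included, so the filter can only widen, never narrow, under
ties. Raising `keep_fraction` never removes a previously kept site.

## Mutation impact

Variants intersect sites in the genomic frame: an SNV by its substituted
base, a deletion by its deleted span, an insertion by its anchor base (an
inserted base between seed positions still breaks spacing, which the
rescoring captures). Each (variant, site, miRNA) triple is rescored over a
fixed window -- the site extended by one miRNA length each side, so a site
gained adjacent to the original footprint is detectable. Classification:

* `disrupted`: the wildtype window qualifies, the mutant does not;
* `gained`: the reverse;
* `weakened` / `strengthened`: both qualify and the score moves beyond a
  dead zone `tol` (default 0, since default scores are integers);
* `unchanged` otherwise.

Swapping the alleles negates the score delta and exchanges
disrupted/gained and weakened/strengthened, which the test suite checks as
an antisymmetry property.

## The validation ledger

The filter cascade runs in a fixed order, and a variant's recorded fate is
the first filter that removes it:

1. **QC**: a call is kept iff coverage > 30 reads and VAF > 5%, strict
   inequalities per the usual panel phrasing (configurable to >=). A
   variant is dropped only when every one of its per-sample calls fails.
2. **Control pools**: a variant seen in *any* healthy control pool is
   removed for all tumor samples; matching is allele-exact on
   (chrom, pos, ref, alt) after anchored normalization.
3. **Artifact masking**: a variant is removed when a changed base lies
   within 1 base of a homopolymer run of >= 5 identical bases or of >= 3
   tandem copies of a 2-4 nt motif. The source studies never define
   "homopolymer or repetitive region"; these defaults follow common
   amplicon-artifact practice and are configurable
   (`min_homopolymer`, `repeat_units`, `pad`).

Recurrence is counted at the patient level -- paired longitudinal samples
(antecedent + transformed) of one patient count once -- with sample-level
counts reported alongside. Exclusivity labels a patient "tFL" if any of
their samples is a transformed or antecedent sample, and a variant
tFL-exclusive if all its carriers are tFL patients; the exclusive fraction
is reported to the nearest percent.

Gene-set overrepresentation uses the exact hypergeometric upper tail. It
is a transparent stand-in for proprietary ontology tools: the p-values of
such tools depend on curated sets and algorithms that are not public, so
only the test's mechanics, not any published ontology p-value, are
reproduced. Benjamini-Hochberg correction across sets is available and off
by default.

## What the simulator emulates -- and what it does not

`generate_cohort()` produces a fully self-contained cohort: one UTR-like
region per gene (300-600 nt), 10 random 22-mer miRNAs with pairwise
distinct seeds, planted miRNA-response elements, somatic SNVs with
per-call coverage (negative binomial, mean 2270 as for a deep amplicon
panel) and VAF (Beta(8, 12), clonal-ish), 34 longitudinally sampled
transforming patients and 21 non-transforming patients, five healthy
control pools, and a truth table.

Design choices worth knowing:

* **Planted sites are strong sites.** Each mutation-eligible element is an
  8mer seed match preceded by 3'-supplementary complementarity to miRNA
  positions 13-19. Real high-confidence response elements have exactly
  this architecture, and it places planted sites firmly in the
  top-confidence stratum, so the 75% filter removes the weak tail rather
  than the truth. Each gene additionally carries weaker 6mer-only *decoy*
  sites (never mutated, spread evenly over the miRNAs) emulating the
  genome-wide tail of low-confidence sites that the filter is meant to
  discard.
* **Disruption is made well-defined.** The rescoring window of each
  planted site is scrubbed of accidental same-miRNA seed matches, and the
  disrupting allele is chosen so the mutant window retains no canonical
  seed match; the truth label `disrupted` is then unambiguous.
* **Background mutations are nested across rates.** Background positions
  are chosen by comparing fixed per-position uniforms against the rate, so
  raising the rate adds variants without moving existing ones -- a
  monotonicity the tests exploit.
* **Contamination knobs.** A configurable fraction of variants is copied
  into control pools, and a fraction of background variants receives an
  adjacent planted 6-base homopolymer run.

What it does not emulate: read-level errors, alignment artifacts,
multi-exon UTR structure, indel-rich loci, germline/somatic ambiguity
beyond the control pools, or sequence composition of a real genome. A
passing recovery test therefore demonstrates that the pipeline's logic is
sound under its own model assumptions, not that its defaults are tuned for
any particular sequencing chemistry.

The worked-example fixtures (`fl_recurrent_variants()`,
`fl_candidate_sites()`, `fl_candidate_regions()`) carry published genomic
coordinates, alleles and patient tallies of a follicular-lymphoma cohort;
all flanking sequence around those coordinates is synthetic and seeded, so
they exercise coordinate and strand logic, not real hg19 content. One
printed tFL/ntFL split is internally inconsistent with its printed total;
the fixture preserves the numbers as printed. Similarly,
`make_validation_fixture()` rebuilds the published filtering arithmetic
(85 variants, 36 control-pool hits, 26 artifact-context variants, 23
survivors in 21 genes, 10 tFL-exclusive) as *planted composition*: the
filters themselves recompute every count from the synthetic calls,
contexts and pools.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design: 20
genes of 300-600 nt, 10 miRNAs, and 8-20 simulation seeds per
recovery experiment -- enough for the binomial noise on a rate bounded at
5% to be visible, while a full run stays in the minutes range on one core.
Every random step is governed by a single integer seed; identical seeds
give byte-identical output files, and reruns of the discovery arm on fixed
inputs are byte-identical.

## Known limitations

* Confidence is alignment score only; conservation, context scores and
  site accessibility are out of scope.
* The energy model ranks duplexes sensibly and differences are meaningful,
  but absolute values are not literature-grade folding energies.
* Overlapping sites of the same miRNA merge to the best-scoring
  representative; a variant hitting two merged registers is counted once.
* HGVS c.-numbering is carried as annotation only; no CDS model is built.
* Complex substitutions (REF and ALT both multi-base without a shared
  anchor) are rejected rather than normalized.

## A small end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 6, p_site_mutation = 1, rng_seed = 3)
cohort <- generate_cohort(cfg)
disc <- run_discovery(cohort$variants, cohort$regions, cohort$mirnas)
table(disc$calls$impact)

val <- run_validation(cohort$variants, cohort$meta, cohort$controls,
                      cohort$reference)
val$ledger
val$summary
```
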