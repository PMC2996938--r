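---
title: "Methods and models behind mescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind mescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mescan)
```

# Scope

`mescan` implements the analysis pipeline of a targeted
mobile-element-scanning assay — identification and presence/absence
genotyping of insertions of one retrotransposon subfamily from indexed,
pooled, paired 2×36-bp junction/flank libraries — together with a simulator
that emulates the wet-lab protocol closely enough that every pipeline stage
can be validated against a known truth. This vignette records the models,
the parameters that matter, the numerical conventions, and the design
choices that were genuinely open.

# Read geometry and the junction endpoint identifier

The sequencing primer anneals 16 bp inside the element's 5' end, so a
junction read carries 16 nt of element sequence and then crosses the 5'
junction into 20 nt of genomic flank. The flank read starts with the 5-nt
sample index and the 'T' ligated during adapter attachment, then 30 nt of
genomic sequence from the fragment's far end. A locus is identified by the
reference coordinate of the junction read's **final** sequenced base,
roughly 20 bp beyond the junction inside the flank. Two properties make
this identifier robust:

* it exists in the reference even when the insertion does not, so
  reference-present and novel insertions share one coordinate system;
* it is invariant to whether the pair mapped intact or with the leading
  16 nt trimmed — the trimmed read ends at the same reference base. This
  invariance is computed from the CIGAR string (`POS + reference-consumed
  length − 1` on the forward strand) and is tested on simulated pairs.

For reverse-strand alignments the final sequenced base is the *leftmost*
reference coordinate (`POS`). The assay's library geometry makes junction
reads map in a fixed orientation per insertion strand, so the published
description never needed a reverse-strand convention; stating it this way
makes the two strands exactly symmetric, which the simulator's
mirror-image test verifies.

# Decision rules and their boundaries

All thresholds are inclusive at their stated boundary and are configurable
through `default_config()`:

| rule | default | notes |
|---|---|---|
| index correction | ≤ 1 substitution | ambiguity (two valid indexes at distance 1) → unassigned; 'N' counts as a mismatch |
| low complexity | > 85% one base | fraction over A/C/G/T |
| N calls | > 2 per read | |
| oligo contamination | ungapped local score > 60 | match +5 / mismatch −4, so >60 ≈ ≥13 consecutive matches; the element-specific 3' 20 nt of the amplification primer is excluded from screening |
| pair insert window | 100–1000 bp outer distance | covers the 650–700 bp size selection with margin; the original aligner's window is internal to it |
| per-read edit bound | ≤ 3 mismatched + unmatched bases | substitutions plus inserted/deleted/clipped bases |
| endpoint merge | ≤ 3 bp, singletons only | absorbed into the most numerous neighbour; ties → nearer, then lower coordinate |
| locus support | ≥ 10 pairs | summed over samples and experiments |
| motif fraction | ≥ 50% | denominator: all supporting junction reads, pooled before the rule |
| per-sample presence | ≥ 1 pair | configurable to study the sensitivity–coverage trade-off |
| primer-site spacing | 224 ± 15 bp | between plus-strand start coordinates, bounds inclusive |
| list comparison | ≤ 50 bp | greedy nearest matching, each locus used once |

Three rules needed an interpretation the published description leaves
open:

* *"matched the expected element sequence at 10 bp"* is implemented as
  identity over the **first** 10 bases of the motif (the alternative — any
  10 identities — is subsumed by the alignment-score criterion for all but
  pathological inputs). The printed motif is 15 nt although junction reads
  carry 16 nt of element sequence; the motif is configurable and the
  16th base is simply not screened.
* The singleton-absorption tie-break (equal counts, equal distance) goes to
  the lower coordinate, making grouping deterministic.
* The ligated 'T' at flank position 6 is trimmed but never validated; a
  non-'T' there increments a diagnostic counter only.

# Mapping model

`toy_map()` is a deliberately small end-to-end read mapper for desk-scale
references: exact k-mer seeding with `max_mismatch + 1` disjoint seeds per
read (`k = floor(len / (max_mismatch + 1))`), followed by full verification.
By the pigeonhole principle every placement within the substitution bound
contains at least one clean seed, so the mapper provably reports *all*
placements with ≤3 substitutions — there is no sensitivity heuristic to
tune, and the test suite checks equality with a brute-force all-offset scan
and with an independent string-matching library. Mapping quality is
reduced to the only distinction the pair filters use: 37 for a unique
best-scoring placement, 0 for ties. Gapped alignment is out of scope; in
36-nt reads indels are rare and the edit-bound filter absorbs them.
Externally produced alignments enter through `ingest_sam()` (headerful SAM;
proper-pair state taken from the aligner's flag values 99/147 and 83/163;
edit distance = `NM` + soft-clipped bases), so any real aligner can replace
the internal one without touching downstream stages.

# Primer-site scanning and the putatively fixed set

`scan_pbs()` scores the primer against both strands at every offset where
the full footprint fits (ungapped; gaps are effectively forbidden exactly
as in the original search settings) and reports the best contiguous
segment per offset. The exhaustive scan is a superset of word-seeded
search and identical to it at the default thresholds, where any reportable
hit must contain a 7-mer exact match. Scores use the legacy nucleotide
scoring +1/−3. The published selection thresholds (32.2 and 46.1) are
bit-like scores of a particular legacy search program whose normalisation
constants are not recoverable; the package therefore uses **raw** score
thresholds — 16 for the 20-nt amplification primer site and 23 for the
27-nt sequencing primer site, the Karlin–Altschul conversions of the
published values under +1/−3 — and documents them as user-calibrated.
A perfect site scores its full length (20 or 27), so the defaults tolerate
roughly one internal mismatch, and the zero-mismatch rule over each site's
3'-terminal 10 bases does the real discriminating work, exactly as in the
published criteria.

The spacing criterion (start positions separated by 224 ± 15 bp) is
measured between plus-strand footprint start coordinates. Because the two
primers differ in length, the same planted element measures 224 in one
orientation and 217 in the other; both lie comfortably inside the window,
which is presumably why the published tolerance is as wide as it is.

# The simulator

The generator emulates, at configurable scale, the conditions the assay
was characterised under:

* **Reference**: random background chromosomes; planted target elements
  carrying the exact amplification and sequencing primer binding sites at
  the offsets that give the canonical 224-bp spacing; decoy older-family
  elements with one mismatch in each site's 3' 10 bp (they pass the score
  gates but fail the clean-3'-end rule, and their junction motif carries 3
  substitutions by default — detectable, as for real older elements);
  poly-A tails and TSD lengths recorded for realism (defaults 20 and
  15 nt) but not affecting junction geometry.
* **Segmental duplications**: for selected target loci the 600 bp of flank
  adjacent to the 5' junction is copied to a distant location at 99.5%
  identity, with the divergence confined to the 100 bp nearest the element.
  The far-flank region that read pairs actually sample is therefore copied
  exactly, so every pair from such a locus has tied best placements and is
  removed by the mapping-quality filter — the duplication-driven
  false-negative mechanism. Placing divergence inside the sampled window
  would instead let most pairs map uniquely, which is not how recent
  (locally exact) duplications behave.
* **Cohort**: loci are fixed (two copies in everyone), polymorphic
  (Hardy–Weinberg at a per-locus allele frequency drawn from a configurable
  range), or singletons (one copy in one individual); novel loci absent
  from the reference are placed in clear sequence and exercise the
  trimmed-mapping path.
* **Coverage**: negative binomial per locus × sample with mean proportional
  to pooling proportion and genotype dosage and variance = `dispersion` ×
  mean (default 10). Amplified fragment libraries show variances at least
  an order of magnitude above Poisson; a Poisson model cannot reproduce
  that, and `dispersion = 1` recovers it as a special case. Heterozygotes
  emit at half the homozygous mean.
* **Fragments**: lengths uniform in the size-selection window (default
  650–700 bp). No published fragment-length distribution exists for the
  post-selection library; uniform-in-window is an assumption and is
  configurable.
* **Errors**: independent per-base substitutions at a constant rate
  (default 10^-3); no indel errors (rare in 36-nt reads and absorbed by the
  filters), no quality-score profile beyond a constant Phred value, no PCR
  chimeras or adapter dimers. Optional corruption knobs plant
  low-complexity, many-N, adapter-bearing and index-corrupted pairs with
  recorded truth categories, for exercising the quality screen.

What passing simulated tests does **not** show about real data: real
libraries have position-dependent error and quality profiles, chimeric
fragments, polymorphic primer-site variants, and reference annotation
errors, none of which are modelled. The simulator validates the *logic* of
the pipeline (filters, coordinates, accounting, estimator algebra), not the
biochemical error structure.

# Evaluation statistics

The metric functions return raw values; reports display rates at 3
significant figures and sensitivity at 1 decimal. The adjusted sensitivity
keeps the confirmation-rate product unrounded before summation:
`FN = n_dup + n_no_motif + confirm_rate × n_residual`, sensitivity
`= 100 (n_total − FN)/n_total`. The replication failure rate is the mean of
the two per-replicate miss fractions, `100 (miss_a + miss_b)/(2 n_union)`,
symmetric in the replicates. Truth-based evaluation scores the
presence/absence matrix over (locus, sample) cells of the simulated cohort,
matching called loci to truth loci within ±3 bp; called loci explained by
sporadic non-specific amplification of decoy elements are excluded from
the universe (they are real reference elements, not insertion genotype
errors), and called loci matching nothing are false positives in every
sample where they are called.

# Problem sizes used by the test suite

The package's own validation runs at desk scale, chosen so the whole suite
exercises every code path in a few minutes: the end-to-end recovery
property uses a 1 Mb reference with 300 target loci (100 of them
polymorphic, 50 of those novel), 4 samples and ~24,000 read pairs — about
20 pairs per locus and sample, a proportional scale-down of the
~355,000-pairs-per-sample depth at which the assay reaches its headline
performance. Index-proportion recovery uses 10^5 pairs over the 5-sample
4/4/4/16/72% pooling design. Oracle-equivalence checks run on ≤50 kb
references, 10^4 endpoints and 10^3 random 16-mers.

# Known limitations

* Dominant genotyping only: no diploid 0/1/2 inference, by design.
* The internal mapper is substitution-only and desk-scale; genome-scale
  use is expected to go through `ingest_sam()` with a production aligner.
* Primer-site score thresholds are raw-score calibrations, not bit-score
  reproductions; users changing the scoring matrix must recalibrate them.
* The simulator does not model 5'-truncated elements; decoys with a
  divergent junction motif stand in for the motif-detection failure path.
* Loci closer than ~500 bp to a chromosome end cannot be screened for
  upstream duplication (`flag_upstream_duplication()` requires the full
  window and says so).
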