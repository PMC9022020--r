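---
title: "Strain tracking and pathway presence/absence patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain tracking and pathway presence/absence patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkstrack)
```

## The problem

Dominant gut commensal strains — *Bacteroides vulgatus* and *B. uniformis*
are the motivating examples — are generally unique to an individual and
stable over time. Two questions arise from longitudinal stool metagenomes:

1. **Is the strain in sample A the same strain as in sample B?** Answered by
   window-based SNV similarity (WSS) against a species reference, with a
   per-species cutoff separating related from unrelated pairs.
2. **Given a shared strain, is its metabolic gene content drifting?**
   Answered by the pattern of presence/absence of KEGG pathways for the
   selected strain (PKS): a binary vector over a fixed species-specific
   pathway list, compared across time points by Hamming distance.

Persistently *identical* PKS vectors at multiple time points (clusters),
especially ones that go extinct and reappear, are read as a slowing of the
community's intrinsic rate of change — an autocorrelation-like state that
may be an early warning of strain-level dysbiosis. A healthy series tends to
*resolve*: it ends on a pattern seen only once.

## The WSS score

Both samples' SNV calls against one reference are reduced to sets of
`(position, alternate allele)` pairs. The genome is tiled into consecutive
1000-bp windows (1-based inclusive, last partial window included). Every
window where at least one sample has a call is *informative* and contributes
its Jaccard similarity $|A_w \cap B_w| / |A_w \cup B_w|$; the score is

$$\mathrm{WSS}(A,B) = \frac{100}{|W|}\sum_{w \in W} J_w,$$

the unweighted mean over informative windows $W$, in $[0,100]$. The score is
symmetric, equals 100 for identical non-empty profiles, 0 for profiles with
no shared call in any shared window, and ignores windows where both samples
are silent (so it is insensitive to the uncalled bulk of the genome).

The windowed-Jaccard form with *equal window weighting* is this package's
formalization: the upstream WSS programs publish the windowing idea but not
a normative weighting, and weighting windows by call count would let a
single SNV-dense region dominate the genome-wide comparison.

### Cutoff calibration and the relatedness call

Cutoffs are data, not constants: they are calibrated per species from
labelled score sets. Candidate thresholds are midpoints between consecutive
sorted unique pooled scores; the cutoff maximizes Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$, with sensitivity counting related
pairs scoring *strictly above* the candidate. Ties take the largest
candidate, making calibration deterministic. A pair is **related iff its
score is strictly greater than the cutoff** — a score exactly at the cutoff
is unrelated, since only scores *above* the cutoff indicate relatedness.

```{r}
calibrate_cutoff(c(90, 95), c(40, 50), "B_vulgatus")$cutoff
```

## Parsimonious pathway inference

Gene annotations arrive as GFF3 with Prokka-style `eC_number` attributes.
The observed enzyme set is the *set* of distinct EC numbers — presence, not
abundance, because the downstream comparison is binary. A pathway database
maps KEGG map IDs to EC sets; partial ECs with trailing dashes
(`2.7.1.-`) match full ECs field-wise, with the dash as a wildcard.

The inferred pathway call set is a **minimum-cardinality set cover**: the
smallest set of pathways that together contain every observed EC matched by
at least one pathway (MinPath-style parsimony — the pathways that would
carry a `minpath` flag of 1). Observed ECs matching nothing are reported as
orphans and cannot influence the cover. The solver is an exact branch and
bound (branching always on the uncovered EC with fewest covering pathways),
followed by enumeration of all covers at the optimal size to apply a
deterministic tie rule: maximal summed per-pathway coverage of observed ECs
first, then the lexicographically smallest sorted map-ID tuple. Exactness is
property-tested against exhaustive subset enumeration.

## PKS profiles, differences and summaries

A species' **standard pathway list** is the union of pathways called in
samples that participate only in WSS-related pairs, at a fixed read depth,
sorted lexicographically. Each sample's call set projects onto this list as
a 0/1 vector; pathways called outside the list are ignored with a logged
count. Two profiles differ by their Hamming distance, with signed
per-pathway deltas (+1 gain, −1 loss) relative to the first profile.

Cohort summaries report the share of related pairs with zero changes.
Percentages are rounded **half away from zero to one decimal** — the
convention under which 13/35 prints as 37.1% and 6/34 as 17.6%.
`shared_pattern_groups` collects groups of two or more pairs with identical
*nonzero* delta patterns; zero-change pairs are counted separately and not
grouped, since every zero pair trivially shares the all-zero delta and the
field's usage treats "no differences" and "shared change patterns" as
distinct findings.

## Clusters, extinction, reappearance, resolution

Within one individual's day-ordered series, a **cluster** is a maximal
group of ≥ 2 time points with bitwise-identical vectors. Because clusters
are maximal, any time point lying between two members of a cluster
necessarily carries a different pattern, so each internal gap is one
extinction/reappearance episode; a cluster's reappearance count is its
number of such gaps. A series is *shared* iff it has at least one cluster,
and *resolved* iff its final pattern occurs exactly once in the series.

Cluster identity requires the full vector to match. Near-identical patterns
are deliberately not merged: "almost the same pathway complement" has no
principled threshold at list lengths of 23–40, and exact identity is what
makes the planted-truth recovery test sharp.

```{r}
g <- generate_longitudinal_series(days = c(2, 5, 6, 7, 14, 21, 28),
                                  list_length = 8,
                                  cluster_spec = list(c(2, 14, 21, 28)),
                                  seed = 7)
find_clusters(g$profiles)
```

## Read QC and subsampling

The QC rule drops reads shorter than 50 bases and truncates at the start of
the first 50-base sliding window (advancing one base at a time) whose mean
Phred quality is below 20, i.e. Trimmomatic `SLIDINGWINDOW:50:20` +
`MINLEN:50` semantics, in that order. The truncate-then-filter reading was
an open choice — the stated rules name both filters but not whether a
failing window discards the read; truncation is what the named tool does.
Reads shorter than one window are judged on their whole-read mean.

Subsampling draws exactly `min(n, total)` reads uniformly without
replacement and preserves input order; the sampled index set is a function
of `(seed, total, n)` only, keeping paired files mate-consistent. It fills
the role of `seqtk sample -s1000` but is not bit-compatible with seqtk's
stream — the contract is determinism, not byte equality with another tool.

## Rarefaction depth selection

Sweeping subsampling depths (conventionally 2.5, 5 and 10 million reads,
with repeats seeded `base_seed + repeat − 1` so the first pass reproduces
the main seed 1000) yields a curve of the zero-difference percentage.
"Leveling off" is formalized as: choose the smallest depth whose mean value
is within `tol` (default 1.0 percentage point) of the deepest depth's
value. This rule is monotone in `tol`. Because the reported analyses fixed
5 million reads even though the plateau spanned 2.5–10 M, `select_depth()`
also takes an explicit `override` rather than hard-coding that choice.
Alignment and variant calling are outside the package, so the depth sweep
takes a pluggable per-sample closure
`pipeline(reads, sample_id) -> list(snv, pathways)`.

## What the synthetic world does and does not establish

The generators emit the real on-disk formats (FASTQ, VCF, GFF3, TSV) so the
I/O paths are exercised, with planted ground truth:

* `generate_pathway_db()` — EC sets with controlled pairwise overlap;
  overlap 0 gives disjoint sets, under which set cover recovers a planted
  pathway set uniquely.
* `generate_strain_pair()` — profiles sharing exactly
  `floor(shared_frac · n_snv)` calls; 0.9 vs 0.1 gives WSS distributions
  separated by tens of points, so calibration recovers labels perfectly.
* `generate_longitudinal_series()` — series whose identical-pattern
  structure equals the requested cluster spec exactly; non-members get
  globally unique vectors.
* `simulate_cohort()` — a full on-disk cohort. Defaults state the
  synthetic world once: 95% shared calls within an individual's strain
  (comfortably related), ~150 SNVs on a 50-kb reference (a few calls per
  1-kb window), a zero-overlap pathway DB, and a WSS cutoff of 60 chosen
  a priori between the ~85–90 expected for related pairs and ~0 for
  unrelated ones.

Green tests establish algorithmic correctness on this stated world — exact
cover minimality, exact cluster recovery, seed determinism. They do not
establish robustness to real-data pathology: sequencing error, uneven
coverage, cross-mapping between related species, partially assembled genes,
or EC mis-annotation. In particular the synthetic DB's zero overlap makes
pathway inference unambiguous, which real KEGG content is not; the
reported cohort pathway lists (23 for *B. vulgatus*, 40 for *B. uniformis*)
are reproducible only from the external accessions and are documented, not
tested.

## Numerical choices and degenerate inputs

* Empty read → rejected, not an error; empty VCF → empty profile; two
  profiles with no calls anywhere → `"no informative windows"` error (no
  score is defensible).
* Duplicate VCF positions with conflicting alternates violate the one-alt-
  per-position invariant and are an error, not a silent merge.
* All percentages use `round_half_up()`; base R's round-to-even would print
  18.15 as 18.1.
* All generator and subsampling randomness goes through an isolated RNG
  (Mersenne-Twister, rejection sampling) that saves and restores the
  caller's `.Random.seed`.
* Pipeline outputs carry no timestamps, so a rerun with the same config and
  seed is byte-identical.

## Known limitations

* WSS consumes VCFs; producing them (alignment, realignment, calling) is
  upstream and out of scope, as are host-read removal, assembly and
  annotation.
* Equal window weighting and the strict-greater cutoff rule are package
  decisions where upstream practice is unpublished; both are documented
  above and tested as stated.
* `zero_diff_curve()` can only be as realistic as the supplied pipeline
  closure; with real data it would wrap the external calling workflow.
* Cluster statistics are descriptive; no significance model is attached to
  cluster counts, and pathway function is never interpreted.
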