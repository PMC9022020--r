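# pkstrack

Strain tracking and pathway presence/absence pattern analysis for
longitudinal metagenomes.

## What this is for

Longitudinal stool metagenomes let you ask two things about a dominant
commensal strain (think *Bacteroides vulgatus* or *B. uniformis*):

1. **Is it still the same strain?** Two samples' SNV calls against one
   species reference are compared by **window-based SNV similarity (WSS)**:
   the genome is tiled into 1000-bp windows, each window where either sample
   has a call contributes the Jaccard similarity of the two
   `(position, alt)` call sets, and the score is 100 × the mean over those
   informative windows. Pairs scoring strictly above a per-species
   calibrated cutoff are *related* (same strain).
2. **Is its metabolic gene content drifting?** Each sample's EC-number gene
   annotations are explained by a **minimum set of KEGG pathways**
   (MinPath-style parsimony, solved exactly), projected onto a fixed
   species-specific standard pathway list as a 0/1 vector — the **pattern of
   presence/absence of KEGG pathways for the selected strain (PKS)**.
   Profiles are compared by Hamming distance; an individual's day-ordered
   series is scanned for **clusters** of identical patterns, their
   **extinction/reappearance** episodes, and whether the series **resolves**
   to a final pattern seen only once.

Unique, churning patterns are the healthy norm; persistent identical-pattern
clusters suggest a slowing of strain variation — a candidate early-warning
sign of strain-community dysbiosis. The package also ships seeded FASTQ
QC/subsampling, rarefaction-depth selection, synthetic generators with
planted ground truth, a YAML-driven pipeline, and a `pks` CLI.

Intended users: microbiome bioinformaticians with per-sample VCF (SNV calls
vs a species reference) and GFF3 (Prokka-style `eC_number` annotations) in
hand; alignment, variant calling and assembly are deliberately upstream of
this package.

## Worked example

```r
library(pkstrack)

## -- strain relatedness ---------------------------------------------------
a <- snv_profile("B_vulgatus", 3000, data.frame(pos = c(100, 1500), alt = c("T", "G")))
b <- snv_profile("B_vulgatus", 3000, data.frame(pos = c(100, 2500), alt = c("T", "A")))
res <- compute_wss(a, b)
res
#> <wss_result> B_vulgatus: score 33.33 over 3 window(s) [undecided]
```

Window 1 has the identical call `(100, T)` (Jaccard 1); windows 2 and 3 each
hold one private call (Jaccard 0); the score is 100 × (1+0+0)/3 = 33.33.

```r
model <- calibrate_cutoff(c(90, 95), c(40, 50), "B_vulgatus")  # cutoff 70
classify_pair(res, model)
#> [1] "unrelated"
```

```r
## -- parsimonious pathway calls -------------------------------------------
db <- pathway_db(list(map00010 = c("2.7.1.1", "5.3.1.9"),
                      map00030 = c("2.7.1.1"),
                      map00051 = c("5.3.1.9", "2.7.1.11")))
minimal_pathway_set(c("2.7.1.1", "5.3.1.9"), db, sample_id = "day0")$pathways
#> [1] "map00010"
```

One pathway (glycolysis) explains both observed enzymes, so the two
single-enzyme alternatives are never called: that is the parsimony rule.

```r
## -- longitudinal clusters ------------------------------------------------
g <- generate_longitudinal_series(days = c(2, 5, 6, 7, 14, 21, 28),
                                  list_length = 8,
                                  cluster_spec = list(c(2, 14, 21, 28)),
                                  seed = 7)
find_clusters(g$profiles)
#> <cluster_report> shared: 1 cluster(s), 4 member time point(s), 1 reappearance event(s), not resolved
#>   days 2, 14, 21, 28 (1 reappearance event(s))
```

The day-2 pattern goes extinct over days 5–7 and reappears on days 14, 21
and 28 (one extinction/reappearance episode); the series does not resolve,
because the final day's pattern is part of the cluster.

Cohort summaries print the zero-change share of related pairs with
half-away-from-zero rounding (13 of 35 → 37.1%):

```r
summarize_related_pairs(diffs)   # diffs: 35 pair_difference objects, 13 with 0 changes
#> <pks_summary> 35 pair(s): 13 (37.1%) with 0 changes, 22 (62.9%) with changes; ...
```

## Pipeline and CLI

```sh
Rscript -e 'pkstrack::pks_cli()' simulate --out demo --seed 7
Rscript -e 'pkstrack::pks_cli()' run --config demo/config.yaml --out demo_out
# demo_out/: wss.tsv  pks_grid.tsv  clusters.json  summary.tsv  run.log
```

Subcommands: `qc`, `subsample`, `wss`, `pathways`, `compare`, `clusters`,
`select-depth`, `simulate`, `run` (run any of them with no options for
usage; the installed shim is `system.file("cli", "pks.R", package =
"pkstrack")`). Re-running `run` with the same config and seed produces
byte-identical outputs.

## Scope

Host-read removal, assembly (MEGAHIT), annotation (Prokka) and real KEGG
content are upstream/user-supplied; this package consumes their outputs.
See `vignettes/pks-methods.Rmd` for the models, defaults, tie-breaks,
synthetic-world assumptions and limitations.
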