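# symits2

Within-sample OTU clustering and metacommunity analysis for
*Symbiodinium* ITS2 metabarcoding.

## The problem

ITS2 is the standard marker for profiling the symbiotic algae
(*Symbiodinium*) of reef corals, but it is a multi-copy marker: one genome
carries several ITS2 variants (one numerically dominant), while the
dominant variants of *different* symbiont species can be more than 97%
similar to each other. Conventional OTU building therefore fails in both
directions — unique-sequence "100% OTUs" overcount taxa by counting
intragenomic variants, and pooled 97% clustering undercounts them by
collapsing distinct species into one OTU whose identity is set by
whichever sample dominates the pool.

`symits2` implements the strategy that resolves this: cluster sequences at
97% identity **independently within each sample** (collapsing variation
that is plausibly intragenomic), then merge clusters across samples **only
when their representative sequences are 100% identical** (keeping
variation that is plausibly interspecific). Around that core it provides
the full pipeline: paired-read merging with quality checks, primer
trimming, greedy abundance-sorted centroid clustering under three
strategies, Needleman–Wunsch taxonomy assignment against a named reference
database, count filtering, Bray–Curtis / PERMANOVA / multivariate-
dispersion ("symbiotic flexibility") statistics, bipartite host–symbiont
networks for dominant (>50%), abundant (>1%) and background (<1%) niches,
and a seeded synthetic metacommunity generator with ground truth that
makes the whole chain testable offline.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on result types.

## Worked example

The built-in scenario plants two host species whose symbionts' dominant
ITS2 variants are 98% identical, plus a shared background symbiont below
1% — the regime where clustering strategy decides the answer.

```r
library(symits2)
library(dplyr)

sc <- scenario_fig2(seed = 1)
within <- cluster_within_samples(sc$variant_tables, metadata = sc$manifest) |>
  filter_otu_table()
across <- cluster_across_samples(sc$variant_tables, metadata = sc$manifest) |>
  filter_otu_table()

glance(within)$n_otus   # 4
glance(across)$n_otus   # 3

relative_abundance(within) |> filter(rel_abund > 0.5) |> distinct(otu_id) |> nrow()
#> 2
relative_abundance(across) |> filter(rel_abund > 0.5) |> distinct(otu_id) |> nrow()
#> 1
```

Within-sample clustering recovers one dominant OTU per planted symbiont
species (2); across-sample clustering collapses them into a single OTU
(1), exactly the failure mode the method is designed to avoid. The
flexibility metric and PERMANOVA run on the same table:

```r
d <- bray_curtis(within)   # sqrt-transformed counts by default
species <- within$metadata$species[match(attr(d, "Labels"),
                                         within$metadata$sample_id)]
beta_dispersion(d, species, n_perm = 999, seed = 1)
#> Multivariate dispersion: F = 14.259, p = 0.1000 (999 permutations)
#> # A tibble: 2 × 6
#>   group      n mean_dist       se letters singleton
#>   <fct>  <int>     <dbl>    <dbl> <chr>   <lgl>
#> 1 host01     3   0.0348  0.00873  a       FALSE
#> 2 host02     3   0.00171 0.000603 a       FALSE
```

(With three samples per group, 0.1 is the smallest attainable permutation
p.) Networks come from the relative-abundance table:

```r
rel <- relative_abundance(within)
net <- build_niche_network(rel, sc$manifest, "dominant")
autoplot(net)
```

A full run — FASTQ in, tables/taxonomy/statistics/networks out — goes
through `run_config()` + `run_pipeline()`, or the thin CLI in
`inst/scripts/symits2.R`:

```sh
Rscript inst/scripts/symits2.R simulate --scenario fig2 --seed 1 --out demo/
Rscript inst/scripts/symits2.R run --config run.yaml
```

## Scope notes

Chimera removal is a hook (`run_config(chimera_ids = ...)`), not an
implementation; sub-90% taxonomy matches are flagged `unassignable`
rather than sent to BLAST; the primer sequences for a real study must be
supplied by the user. See `vignettes/within-sample-clustering.Rmd` for
the model, parameter meanings, generator assumptions, and known
limitations.
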