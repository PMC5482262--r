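---
title: "Within-sample OTU clustering for Symbiodinium ITS2 metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-sample OTU clustering for Symbiodinium ITS2 metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symits2)
library(dplyr)
```

## The problem

ITS2 of the nuclear ribosomal DNA array is the work-horse marker for
profiling *Symbiodinium* communities in reef corals, but it sits inside a
tandem repeat: a single genome carries several distinct ITS2 variants, one
of them numerically dominant. At the same time, the dominant variants of
*different* *Symbiodinium* species can be more similar to each other than
intragenomic variants are to their own dominant. This breaks both naive
ways of building operational taxonomic units (OTUs):

* treating every unique sequence as a taxon (100% OTUs) overestimates
  diversity, because intragenomic variants inflate the count;
* clustering all samples together at 97% identity underestimates it,
  because closely related dominants from different species collapse into
  one OTU whose identity is then set by whichever sample was sequenced
  most deeply.

The strategy implemented here — *within-sample clustering* — exploits two
ecological assumptions: most coral colonies are dominated by a single
symbiont, and different numerically dominant variants mark different
symbiont taxa even at one nucleotide of difference. Sequences are
clustered at 97% identity *independently inside each sample* (so
co-occurring near-identical variants, most plausibly intragenomic,
collapse), and clusters from different samples are merged into one OTU
*only when their representative sequences are exactly identical* (so
similar-but-distinct dominants in different samples stay apart).

## Pipeline model

Raw paired reads pass four quality rules before clustering: each mate
needs at least 66% of bases at Phred ≥ 30; the mates must overlap by at
least 150 bp with at most 3 mismatches (disagreements resolved toward the
higher-quality base, forward mate winning ties); both primers must be
found with at most 3 mismatches each (IUPAC codes in primers match any
compatible base, N in a read matches nothing); and the trimmed amplicon
must be at least 250 bp. The overlap search is exhaustive over all
offsets, preferring the longest qualifying overlap, then fewest
mismatches, then the smallest offset; primers are searched only within 5
nt of the sequence ends, since amplicon reads begin at primers. Chimera
detection is deliberately external: `run_config()` accepts a list of read
ids to exclude, produced by whatever chimera tool the study uses.

Greedy centroid clustering processes dereplicated variants in decreasing
count order (ties broken toward the lexicographically smaller sequence, so
results are reproducible). Each variant joins the best-matching existing
cluster whose centroid identity is at least the threshold, ties going to
the earliest-created cluster, otherwise it founds a new cluster; after all
assignments each cluster's representative is re-elected as its
highest-count member. Identity between two sequences is defined from the
Needleman–Wunsch global alignment (match +5, mismatch −4, gap opening 10,
gap extension 1 per base; N never matches anything) as matching columns
over the alignment columns excluding terminal-gap overhangs. The paper
trail behind this scoring is thin in the field — alignment-based OTU tools
rarely print their matrices — so the scheme is a declared package default,
chosen to favour substitutions over gaps at ITS2 scale, and configurable
through `align_params()`. One consequence of excluding terminal overhangs
is that a sequence strictly contained in another scores identity 1; for
same-length amplicons, which is the operative case, identity 1 implies
equality.

The three strategies differ only in scope: `cluster_denovo100()` merges
exact duplicates globally; `cluster_across_samples()` pools counts across
samples before the greedy pass; `cluster_within_samples()` runs the greedy
pass per sample and then merges clusters whose representatives are
identical strings. Singleton clusters (total count 1) are dropped at
formation. The count filters then remove OTUs seen fewer than 10 times
and, afterwards, samples with fewer than 200 remaining reads — in that
order, which matters because the OTU filter can push a sample below the
read floor; the order is declared here because the filters could also be
read in the opposite order.

Taxonomy assignment aligns each representative against every entry of a
named reference database (`>B1`-style headers, clade = leading letter).
The best alignment score wins; exact matches take the reference name
(ties joined with "/"), sub-100% matches at or above 90% identity get the
best name plus a `_v<k>` suffix unique per distinct representative (a
plain-text rendering of a superscript, stable through TSV/FASTA
round-trips, allocated in lexicographic order of the representatives),
and matches below 90% are flagged unassignable rather than being sent to
an external BLAST. Ties spanning clades are flagged ambiguous and named
by the lexicographically first reference.

## Community statistics

Bray–Curtis dissimilarities are computed on square-root transformed
counts (via `vegan::vegdist`); the transform is applied uniformly for
both PERMANOVA and dispersion and is switchable. The one-factor PERMANOVA
partitions squared dissimilarities (`SS_total = Σ d²/n`, within-group
analogues per group) and tests the pseudo-F against label permutations
with the +1 convention and a default of 999 permutations, so p can never
be 0 and results are bit-reproducible under a fixed seed.

The "symbiotic flexibility" metric is the multivariate dispersion of a
host species' samples: distance to the group centroid in principal
coordinate space. Principal coordinates retain negative-eigenvalue axes
(Bray–Curtis is semimetric) as imaginary axes, and a sample's distance
combines the two blocks as `sqrt(max(0, d_real² − d_imag²))`; the
truncation at zero guards the rare case of imaginary dominance. On purely
Euclidean inputs this reduces exactly to naive distance-to-centroid, which
the tests assert to 1e−8, alongside agreement with an independent
implementation of the same estimator. Group differences are tested by
permuting the distances under a one-way ANOVA F statistic, overall and
pairwise, and summarised as a compact letter display: letters are the
maximal cliques of the non-significance graph at α = 0.05, so two species
share a letter exactly when their dispersions are not significantly
different.

## Networks

The bipartite host–symbiont networks use per-individual relative
abundances. For the abundant (>1%) and dominant (>50%) niches an edge
joins species to OTU when the OTU exceeds the threshold in at least one
individual, weighted by the proportion of individuals in which it does —
the proportion convention is used rather than the raw individual count,
which differs only by per-species scaling and is recorded in the output.
Background edges (present at >0 and <1%) are unweighted; clade-D OTUs
merge into a single node and symbiont nodes connected to two or fewer
host species are pruned. Presence requires at least one read: the
background niche is never inferred from absence. The `<1%` bound is read
as strict inequality. Layouts are Fruchterman–Reingold under a caller
seed; rendering is left to `autoplot()` and GraphML export.

## The synthetic generator

`make_species_pool()` builds genomes as one dominant variant plus minor
intragenomic variants inside a 97%-identity radius; defaults are 300 nt
amplicons, three variants per genome at frequencies 0.70/0.20/0.10, and
minors at 2 and 4 substitutions from their dominant — values chosen to
mimic a marker where one repeat variant dominates the array. The
divergence plan is realised as a star: each later species' dominant
differs from species 1's by substitutions at disjoint position sets, so
the identity to species 1 hits the target within one substitution and
pairwise identities among the others are determined too (a full matrix of
arbitrary pairwise targets is not generally realisable, so the star is
the declared design). `simulate_sample()` draws reads multinomially over
(species × variant) cells and applies i.i.d. substitution errors at 1e−3
per base by default, with constant Q40 qualities when FASTQ output is
requested. Indels, chimeras, and realistic Illumina error profiles are
deliberately out of scope, so passing tests say nothing about indel-rich
platforms or chimera-heavy libraries.

`scenario_fig2()` builds the regime where strategy choice matters: two
host species, three samples each at 2,000 reads, each sample at 0.992 of
its host's own symbiont whose dominant variants are 98% identical between
the two symbiont species, plus a distant clade-D background symbiont
shared by all samples at 0.008. Within-sample clustering recovers two
dominant OTUs; across-sample clustering collapses them to one.

## Numerical and design choices worth knowing

* All clustering is deterministic: ties in abundance break
  lexicographically, ties in identity break toward the earliest centroid.
* The greedy pass is evaluated centroid-by-centroid with one vectorised
  alignment call per centroid; this is an exact reformulation of the
  sequential definition (a variant can only join clusters founded before
  its position), not an approximation, and the tests replay the
  sequential definition independently to confirm the partitions match.
* The OTU-count ordering `across ≤ within ≤ 100%` is asserted on filtered
  tables, the quantity the pipeline reports. On unfiltered tables rare
  violations occur by construction: when two dominants merge under pooled
  clustering, an error-variant cloud near one of them can fall below the
  threshold against the merged centroid and found an extra cluster. The
  count filter removes these clouds in almost all runs, and the
  acceptance script reports the observed violation count rather than
  assuming zero.
* Problem sizes in the tests (2,000-read scenarios, 400-read ordering
  datasets, 500 calibration simulations at 199 permutations) were chosen
  to make each property measurable with comfortable statistical margins
  on a single CPU.
* PERMANOVA p-values at 199 permutations are multiples of 1/200, so the
  nominal 0.05 level is attained exactly under exchangeability; the
  type-I calibration check relies on this.
* The identity between a representative and a reference is reported from
  the score-optimal alignment; when several alignments are co-optimal the
  reported identity is that of the alignment Biostrings returns, with the
  argument order canonicalised so the value is symmetric.

## Worked example

```{r example, eval = FALSE}
sc <- scenario_fig2(seed = 1)
within <- cluster_within_samples(sc$variant_tables, metadata = sc$manifest) |>
  filter_otu_table()
across <- cluster_across_samples(sc$variant_tables, metadata = sc$manifest) |>
  filter_otu_table()
glance(within)
glance(across)

rel <- relative_abundance(within)
rel |> filter(rel_abund > 0.5) |> distinct(otu_id) |> nrow()  # 2
relative_abundance(across) |>
  filter(rel_abund > 0.5) |> distinct(otu_id) |> nrow()       # 1

d <- bray_curtis(within)
species <- within$metadata$species[
  match(attr(d, "Labels"), within$metadata$sample_id)]
beta_dispersion(d, species, n_perm = 999, seed = 1)
```

## Limitations

The method inherits the assumptions it encodes: samples genuinely
dominated by two very closely related symbionts will still be collapsed
within a sample, and co-dominant intragenomic variants can flip which
variant represents an OTU between otherwise similar samples. Taxonomy is
only as good as the reference database, and sub-90% matches are flagged
rather than resolved. The PERMANOVA is single-factor by design; the
shore analysis runs it per host species rather than fitting interactions.
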