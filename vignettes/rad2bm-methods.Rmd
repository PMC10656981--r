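---
title: "Marker-based microbiome quantification from type IIB restriction tags: models and design choices"
author: "rad2bm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based microbiome quantification from type IIB restriction tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad2bm)
```

## The method

Type IIB restriction enzymes such as BcgI cleave on both sides of their
recognition site and excise a fragment of fixed length. Digesting a genome
therefore yields a reproducible set of equal-length tags, and sequencing only
those tags gives a reduced-representation view of a microbial community at a
fraction of shotgun cost. If a tag's sequence occurs exactly once in its
genome of origin and in no genome of any other species, it is a
*species-specific marker*: observing it in a sample is evidence for exactly
one species. `rad2bm` implements this workflow — in-silico digestion, marker
database construction, read assignment with a false-positive screen, and
marker-normalized relative abundance — together with the ecology and
biomarker statistics typically applied to the resulting species-by-sample
abundance table in case-control microbiome studies.

### In-silico digestion

An enzyme is described by its geometry (`enzyme_spec`): an IUPAC recognition
pattern plus the number of flanking bases retained on each side. The shipped
BcgI default uses the double-stranded core `CGANNNNNNTGC` with 10-bp flanks,
giving 32-bp tags. Published descriptions of BcgI's excision differ on
whether the single-stranded overhang bases count toward the sequenced tag
(a 34-nt convention also exists); the geometry is therefore fully
configurable per enzyme, and 32 bp — the double-stranded core of the
excised duplex — is the package default rather than a claim about the
enzyme's chemistry. Both strands are scanned; overlapping matches are all
reported, because the model is in-silico tag sampling rather than physical
digestion kinetics. Every tag is stored in *canonical orientation*, the
lexicographic minimum of the sequence and its reverse complement, so that a
site read from either strand has a single identity. Tags overlapping
non-ACGT bases are dropped (and tallied), since they cannot be matched
exactly.

### The marker database

Given genomes with a genome-to-species taxonomy, a canonical tag becomes a
marker for species $s$ when it (i) occurs exactly once within every genome
in which it occurs at all, and (ii) occurs in genomes of no species other
than $s$. When one species has several assemblies the package uses
union-of-genomes semantics — the single-copy requirement is enforced per
genome, and cross-species exclusion across all genomes; how the original
pipeline merged multiple assemblies per species is not documented, so this
is a deliberate, recorded choice. $T_i$ is the number of distinct markers of
species $i$. Species left with zero markers stay in the index and are
reported, since their absence from profiles is diagnostic information.

### Quantification: G score and relative abundance

Reads are truncated to the tag length, canonicalized, and matched *exactly*
against the marker index (the tags are short and the database already
demands uniqueness; approximate matching is deliberately not attempted).
For species $i$ in a sample, $S_i$ is the number of reads assigned to its
markers and $t_i$ the number of distinct markers observed. The false-positive
screen uses

$$G_i = \sqrt{S_i \times t_i},$$

which is small both for species with few reads and for species whose reads
pile onto a handful of markers — the signature of spurious hits — and grows
when many markers are independently observed. Species with $G_i \ge 5$
(inclusive by default, so the printed boundary value of exactly 5 passes; a
strict mode is available) are retained as candidates. Relative abundance is
the marker-normalized read depth renormalized over candidates:

$$a_i = \frac{S_i / T_i}{\sum_j S_j / T_j}.$$

The denominator $T_i$ defaults to the species' marker total in the
*database*, which removes the bias whereby genomes with more restriction
sites attract proportionally more reads. The source description defines
$t$ and $T$ with identical wording, so a literal reading (divide by the
markers *observed*, $t_i$) is also implemented as
`denominator_mode = "observed"`; at saturating depth ($t_i = T_i$) the two
coincide, and the package logs which mode produced a profile.

### Ecology statistics

Alpha diversity (Chao1, Shannon, Simpson) is computed per sample. Chao1 is
an estimator of unseen richness from singleton/doubleton counts and is
undefined on proportions, so it runs on the integer read counts $S_i$;
Shannon and Simpson use the same counts renormalized. Beta diversity
supports Bray-Curtis and Euclidean distances on relative abundances (so
samples of different depth are comparable) and binary Jaccard on
presence/absence, all via `vegan::vegdist`. Group separation is tested with
a one-way PERMANOVA implemented in the package: the pseudo-F is built from
among/within sums of squared distances and the p-value from explicit
seeded label permutations with the add-one convention $(1 + b)/(1 + m)$,
which avoids zero p-values and makes the minimal attainable p at 999
permutations exactly 0.001. (`vegan::adonis2` is used as an independent
cross-check in the test suite, never as the implementation, so the
permutation scheme stays fully under the package's seed control.) Two-group
comparisons of univariate indices use the Wilcoxon rank-sum test — exact
enumeration when both groups have at most ten observations and no ties, the
tie-corrected normal approximation otherwise. A paired mode exists, but
unpaired is the default: a 26-vs-18 design cannot be paired, whatever the
original description says. Shared/unique species counts (`venn_counts`) call
a species detected in a group when it is screened-in in at least one sample
of that group, and inter-kingdom association (`correlation_network`) computes
Spearman correlations between bacteria and fungi after summing species
abundances to the requested rank.

### Biomarker discovery

Four complementary tools rank species by their ability to separate cases
from controls:

* `indval` — the Dufrene-Legendre indicator value, the product of group
  specificity $A$ (share of the species' mean abundance found in the group)
  and fidelity $B$ (fraction of the group's samples where it is detected),
  with significance by seeded label permutation.
* `lefse_lite` — a deliberately simplified effect-size ranking:
  Kruskal-Wallis screening at $\alpha = 0.05$, then
  $\log_{10}(|\bar{x}_1 - \bar{x}_2| \cdot 10^6 + 1)$ signed toward the
  enriched group. The bootstrap-LDA internals of published LEfSe are not
  reproduced; the published procedure is used for ranking and display, and
  this deterministic score preserves that role.
* `ensemble_importance` — a random forest (`randomForest`, `mtry =
  \lfloor\sqrt{p}\rfloor`, 500 trees by default, seeded) reporting both mean
  decrease in Gini impurity and mean decrease in out-of-bag accuracy.
* `roc_auc` — single-feature diagnostic value, with AUC computed by the
  Mann-Whitney rank formulation (half credit for ties) and the ROC curve
  swept over observed score values only.

## The synthetic-data generator

The study that motivates this package did not deposit its raw cohort data,
so every stage is validated on synthetic inputs whose truth is known:

* `make_genome` builds a random background and plants an exact number of
  recognition sites at non-overlapping positions; incidental matches are
  scrubbed by point mutations that cannot damage a planted recognition
  core, so the planted count is exact by construction.
* `simulate_reads` draws each read's species with probability proportional
  to *proportion × tag count* — a genome-copy model in which genomes with
  more restriction sites contribute proportionally more tags. This is
  exactly the bias the $S/T$ normalization corrects, which keeps the
  `denominator_mode` comparison meaningful. Strand is random; substitution
  errors are applied per base.
* `make_case_control` generates a two-group abundance study: per sample,
  base proportions times the case fold changes, perturbed by per-taxon
  log-normal noise $\exp(N(0, \sigma^2))$, renormalized, and thresholded at
  a detection limit before a final renormalization; integer counts are drawn
  multinomially at the design depth.

### Default study conditions

The default design mirrors the motivating cohort: 26 cases vs 18 controls
over 30 taxa (25 oral bacteria with a geometric rank-abundance profile plus
5 fungi), one fungal taxon enriched tenfold in cases and one depleted
tenfold, log-normal noise $\sigma = 0.5$, depth 50 000 reads, and a
detection limit of $10^{-3}$ relative abundance.

The detection limit deserves its own justification. Real marker-based
profiles are zero-inflated: the G-score screen removes species whose
evidence in a sample is weak, so low-abundance taxa appear as exact zeros
(the motivating study likewise reports its key fungal biomarker as entirely
undetected in one group's samples). The generator reproduces this by
flooring each sample's proportions at the limit. It also shapes the planted
signal realistically: the enriched fungus (base 2%) is always detected and
becomes a clean quantitative discriminator, while the depleted fungus's
base abundance (0.15%) sits near the limit, so its depletion manifests as
an *imperfect* presence/absence signal — detected in most but not all
control samples, absent in cases. Without this mechanism both planted taxa
would be equally perfect classifiers (a tenfold fold change is ~4.6 standard
deviations of the noise), and which of the two a random forest ranks first
would be a coin flip — unlike any real cohort, where one biomarker
dominates.

What the generator does *not* emulate: quality-dependent or indel
sequencing errors, host-DNA contamination, compositional correlations
beyond those induced by renormalization, strain-level variation within a
species, and incomplete reference databases. Passing the recovery tests
therefore shows that the estimator is correct under its own model, not that
real oral samples will yield AUCs like the synthetic ones.

## Numerical choices and degenerate inputs

* Permutation p-values always use the add-one convention; permutations are
  drawn with an explicit seed and all results are bit-reproducible under a
  fixed seed and parameter set.
* A distance matrix with no variation at all (all samples identical) makes
  the PERMANOVA pseudo-F 0/0; the package returns `NaN` with p = 1 instead
  of failing, since "no variation" cannot contradict the null.
* Species with zero reads are never screened in, whatever the threshold;
  a sample in which no species passes the screen has undefined (NA)
  abundances rather than a silently renormalized profile.
* Chao1 rejects non-integer input rather than rounding silently.
* Random-forest importance ties are broken by species name so output
  ordering is reproducible.
* The paired Wilcoxon contract returns p = 1 for identical vectors (no
  nonzero differences) instead of erroring.
* `canonicalize` refuses non-ACGT input; ambiguous tags are excluded
  upstream, at extraction.

## Problem sizes used in validation

The bundled checks run the digestion oracle on one hundred 10-kb random
sequences, marker-database construction on ten genomes over five species,
composition recovery at 100 000 reads over ten seeds, false-positive
control at 50 000 reads over one hundred seeds, PERMANOVA calibration on
two hundred null replicates at 99 permutations, and biomarker recovery on
one hundred replicates of the default 26/18 design. These sizes were chosen
so the full validation runs comfortably on a laptop while keeping every
Monte-Carlo estimate's standard error well below the margins being
asserted.

## Known limitations

* The registry ships only the BcgI geometry; other type IIB enzymes must be
  supplied by the user (the format accepts any IUPAC pattern and flank
  lengths).
* Exact matching only: sequencing errors shed reads rather than being
  corrected, so very high error rates depress $S$ (the G-score screen is
  what keeps this from creating false positives).
* The simplified LEfSe score ranks taxa like the published tool but its
  absolute values are not LDA effect sizes.
* PERMANOVA is one-way only (two or more groups, no covariates); use
  `vegan::adonis2` for richer designs.
* Genus-level fallback markers (for reads matching no species-specific
  marker) are out of scope.
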