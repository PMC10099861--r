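---
title: "Methods: reaction-level microbiome expression, producibility and added value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction-level microbiome expression, producibility and added value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoscope)
```

`holoscope` analyses holobiont meta-omics experiments in which a host
organism carries a community of bacterial metagenome-assembled genomes
(bins), each with a genome-scale metabolic network, observed under a crossed
design of microbial community and an environmental factor (here: salinity,
100% vs 15% natural seawater). This vignette documents the models and
procedures, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Why reaction space?

Metatranscriptome coverage of individual microbial genes in host-dominated
samples is typically far below what per-gene, per-organism testing requires:
most sequenced material is host and rRNA, and the bacterial remainder spreads
over tens of genomes. Two poolings make the data usable:

* **Reaction aggregation.** Counts of all genes annotated to the same
  metabolic reaction are summed across all bins. The unit of analysis becomes
  the expression of a metabolic function by the entire microbiome. A gene
  annotated to $k$ reactions contributes its full count to each of them; we
  deliberately do not split counts, because the gene's transcripts genuinely
  support each annotated function and any split rule would be arbitrary. The
  provenance of every reaction row (which bin, which gene) is recorded so
  sums remain auditable, and the conservation identity
  $\sum_r K(r,s) = \sum_g k(g,s)\,m_g$ (with $m_g$ the number of reactions
  gene $g$ maps to) is enforced by tests.
* **Bin activity.** Counts summed per bin, divided by a per-sample
  denominator, give each bin's transcriptomic activity fraction. Two
  denominators are supported because they answer different questions: the
  total mapped read pairs of the sample (activity relative to everything
  sequenced — the heat-map view) and the bacterial total (activity relative
  to the microbiome — the membership rule's view). The active-member rule
  uses the bacterial-total denominator.

Reactions with no mapped gene are omitted rather than zero-filled: a row
that cannot ever receive counts carries no information and would only dilute
multiple-testing corrections.

### The active-member rule

A bin is active in a (community, salinity) condition if its bacterial-total
activity fraction is at least 0.002 in at least 3 of the condition's 4
replicates. Both comparisons are inclusive ("at least"), which the tests pin
down at the exact boundaries (a fraction of exactly 0.002 counts; 2 of 4
replicates does not). The artificial leftover bin of unbinned contigs, when
present, participates in denominators but is excluded from active sets by
default (`exclude_bins = "unbinned"`), since it is not an organism.

## The negative-binomial Wald engine

Counts are modelled per feature (reaction or gene) as
$y_{s} \sim \mathrm{NB}(\mu_s, \alpha)$ with $\mathrm{Var} = \mu + \alpha\mu^2$
and $\log \mu_s = x_s^\top\beta + \log \sigma_s$, where $\sigma_s$ are
median-of-ratios size factors. Estimation is deliberately plain and fully
documented, rather than a re-implementation of any particular tool's
shrinkage machinery:

* **Size factors**: for each sample, the median over reference features of
  the ratio of the sample's count to the feature's geometric mean across
  samples. Reference features are those positive in all samples; a
  pseudo-reference fallback (geometric means over positive counts only) is
  available for very sparse matrices.
* **Dispersion**: per feature, maximum likelihood via coordinate ascent —
  IRLS for $\beta$ at fixed $\alpha$ alternating with a one-dimensional
  likelihood maximisation in $\log\alpha$ — started from a method-of-moments
  estimate. $\alpha$ is clamped to $[10^{-8}, 10]$ to stabilise the
  optimisation at both extremes; values at the floor correspond to
  effectively Poisson features, the ceiling guards against degenerate fits
  on near-empty rows.
* **Wald tests**: $z = \hat\beta_j/\mathrm{SE}(\hat\beta_j)$ with standard
  errors from the expected information $X^\top W X$,
  $W = \mu/(1+\alpha\mu)$; two-sided normal p-values;
  Benjamini–Hochberg adjustment. The linear predictor is capped at
  $|\eta| \le 30$ so that separated features (e.g. a group of all zeros)
  produce finite estimates with very large standard errors instead of
  diverging — such features are reported, never falsely significant.
* **Significance**: adjusted $p < 0.05$ *and* $|\log_2 \mathrm{FC}| >
  \log_2 1.5$. The fold-change rule is applied to the raw (unshrunken)
  estimate; the thresholds are configurable through `de_config()`.

Three designs cover the study's comparisons: salinity within each community
(`~ salinity` per community), the pooled two-factor model
(`~ tolerance * salinity` with treatment coding and references "tolerant" and
seawater, so the interaction coefficient is the intolerant-specific salinity
response), and a two-community comparison with salinity as an additive
cofactor. Pooling the tolerant communities makes the interaction contrast
invariant to which of them is listed first, which is tested.

Features whose total count in the tested samples falls below
`min_total_count` (default 1, i.e. all-zero rows) are dropped before testing
and reported in the result's `dropped` attribute.

**Pathway summarisation.** A pathway is flagged when strictly more than 50%
of its *tested* reactions are significant. The denominator is a genuine
choice: a pathway can contain reactions that never received counts. We use
tested reactions (a pathway should not escape flagging because half of its
annotation was unobservable) but report the annotated-reaction denominator in
the same table so readers can apply either convention.

**Ordination.** `transform_for_ordination()` uses a shifted log,
$\log_2(y/\sigma + 1)$, followed by feature-centred SVD. This is an ordinary
log-PCA: regularised-log and variance-stabilising transforms are
intentionally out of scope, and the transform is documented as such.

## Producibility: network expansion

The scope of a network given a seed set is the fixed point of: a reaction
*fires* forward once all its substrates are in the available set (backward
once all its products are, if reversible), and firing adds its outputs.
Stoichiometric coefficients are ignored (boolean availability) and
compartments are carried as labels but play no role — the standard
network-expansion convention for qualitative producibility. The
implementation examines each reaction direction at most once per closure and
is order-independent; tests verify exact agreement with a naive
repeated-pass oracle on hundreds of random networks and with the generator's
construction-time reachable sets.

* **Community scope** is the scope of the merged member networks ("mixed
  bag": members exchange metabolites freely). Reactions shared between
  members must agree in stoichiometry and reversibility — a disagreement is
  a data error, reported with both definitions, never silently resolved.
* **Added value** of a community for the host is
  $\mathrm{scope}_{host}(S \cup C) \setminus \mathrm{scope}_{host}(S)$
  where $S$ is the seed set and $C$ the community's producible set. The
  community metabolites themselves are part of the augmented medium, so the
  added value contains both community products the host could absorb and the
  compounds the host can only synthesise from them. The result object
  reports all four sets so either reading (everything newly available vs
  only host-synthesised end products) can be extracted.
* **Seed medium.** The default is glucose as sole carbon source plus a small
  inorganic complement (water, phosphate, ammonium, sulfate, O2, CO2) — the
  minimal abstraction of a glucose growth medium. Any analysis against real
  deposited networks should state its seed file; `read_seeds()` accepts TSV
  and JSON.

`compare_producibility()` partitions the union of per-condition producible
sets by exact membership pattern (the computation behind an upset plot);
pattern counts always sum to the union size.

## GC–MS feature-table statistics

The pipeline order is fixed — blank subtraction, presence filtering,
normalisation, testing — because the steps do not commute (a feature absent
after blank subtraction must not survive via its pre-subtraction
intensities). Choices the upstream literature leaves open are resolved as
follows and recorded in the objects: negative post-subtraction intensities
clip to zero; the log offset (default 1, so zeros map to 0) is stored in the
table; multiplicity adjustment is Benjamini–Hochberg; Shapiro–Wilk failures
*flag* features rather than excluding them, since non-normal residuals
typically just mean a feature absent in one condition — which is itself the
interesting signal. Degenerate Welch cases use the conventions $p = 1$ for
identical zero-variance groups and $p = 0$ for distinct zero-variance
groups. Annotation tiers use inclusive lower bounds: R ≥ 800 annotated,
[700, 800) "?", [600, 700) "??", below 600 or missing "unknown".

## The synthetic-data generator

The generator emulates the study conditions: 3 communities × 2 salinities ×
4 replicates; by default 30 bins with 40 reactions each (a scale at which
the full pipeline runs in well under a minute, which is also the scale the
acceptance script uses); negative-binomial counts with dispersion 0.1 and
base means uniform on [20, 200]; log-normal sequencing-depth factors
(sd 0.2); and a bacterial read fraction of 0.7% used to fill the design's
total-mapped column. Its key property is *exact recorded truth*:

* Networks are random production chains rooted at the seeds, so each
  network's reachable set is known by construction. Cross-feeding reactions
  consume another bin's exclusive product (never a shared seed-rooted
  product, which the bin could reach itself), making some metabolites
  community-producible that no member produces alone. "Dead" reactions
  require a blocked metabolite nothing can produce and contribute nothing.
  A vitamin-K-like motif is always planted: the host carries the terminal
  reaction of a pathway whose precursor only one bacterial bin can make.
* Each bin has a home community where its genes are expressed at full rate;
  elsewhere expression is reduced by a factor 0.002, separating active from
  inactive bins by roughly two orders of magnitude in activity fraction —
  generous, deliberate separation for rule-recovery tests. Planted
  differential effects are applied multiplicatively per reaction, including
  interaction effects confined to the intolerant community's low-salinity
  samples, and one bin-condition pair can be zeroed to emulate a function
  absent from one community in one condition.
* Feature tables plant blank contaminants (blank maximum set to half the
  feature's sample maximum, so the three-fold subtraction removes the
  feature entirely), singletons, isotope flags and group shifts.

What passing these tests shows is that each stage implements its stated rule
exactly and that the statistical engine is calibrated at the study's
replication level. What they do not show: performance under real-data
pathologies the generator does not emulate — annotation errors in
gene–reaction maps, compositional shifts where a large fraction of features
move in one direction (median-of-ratios normalisation then absorbs part of
the signal), batch effects, or zero-inflation beyond the negative binomial.

## Simulation sizes and calibration criteria

Calibration simulations use 2000 features for null false-positive rates
(the Benjamini–Hochberg significant fraction must stay within two binomial
standard errors of the nominal 0.05), 100 planted features at
$\log_2\mathrm{FC} = 2$ among 2000 for power (> 0.8) and bias (within
±0.25) — the planted fraction is kept at 5% so size-factor estimation is
essentially undistorted — and 60 interaction-planted features among 800
under the full design, checking both interaction power and the absence of
leakage into the pooled salinity contrast. Scope equivalence is checked on
200 random networks of up to 40 reactions, and the added-value motif on 100
generated holobionts.

## Known limitations

* The DE engine fits per-feature dispersions without information sharing
  across features; at 4 replicates per cell its raw p-values are mildly
  liberal (as for any Wald NB test without shrinkage), which the BH step and
  the fold-change rule absorb in practice — the tests quantify this at the
  study's sample sizes.
* Scope is qualitative: no stoichiometric balancing, flux feasibility, or
  thermodynamics, and the mixed-bag community model ignores transport
  limits. Conclusions are about what is structurally reachable, not about
  rates or yields.
* SBML support covers level 2/3 core with notes- or fbc-encoded gene
  associations — the subset genome-scale network archives actually use —
  not the full SBML feature set.
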