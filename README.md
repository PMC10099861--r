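# holoscope

Reaction-level metatranscriptomics and metabolic complementarity analysis for
host–microbiome ("holobiont") systems.

## The problem

In holobiont experiments — for example, a macroalgal host carrying a few dozen
bacterial metagenome-assembled genomes (bins) under crossed experimental
factors such as microbial community and salinity — metatranscriptome coverage
of individual microbial genes is usually far too sparse for gene-by-gene,
organism-by-organism differential expression. `holoscope` implements the
analysis strategy that makes such data tractable:

1. **Aggregate to reaction space.** Each bin carries a genome-scale metabolic
   network with gene annotations. Read-pair counts of all genes annotated to
   the same metabolic reaction are summed *across* bins, giving the
   microbiome-wide expression of each metabolic function:
   `K(r, s) = Σ_{(b,g): g ∈ genes_b(r)} k(g, s)`.
2. **Bin activity and active members.** Counts summed per bin and normalised
   per sample give each bin's transcriptomic activity fraction; a bin is
   *active* in a condition when its fraction is ≥ 0.2% of the bacterial total
   in ≥ 3 of 4 replicates.
3. **Differential expression.** A negative-binomial Wald engine
   (median-of-ratios size factors; per-feature ML dispersion with
   `Var = μ + αμ²`; Wald tests with Benjamini–Hochberg adjustment) supports
   per-community salinity contrasts, a two-factor tolerance × salinity model
   with interaction term, and direct community comparisons with salinity as a
   cofactor. Features with adjusted *p* < 0.05 and fold change > 1.5 are
   called significant; pathways with > 50% significant tested reactions are
   flagged.
4. **Producibility ("scope") and added value.** A network-expansion engine
   computes the metabolites reachable from a seed medium (glucose plus a
   small inorganic complement by default): a reaction fires once all of its
   inputs are available, to a fixed point. Community producibility uses
   mixed-bag semantics (scope of the merged member networks), and the
   host's *in-silico added value* is what becomes newly producible for the
   host when the community's producible set is added to its medium.
5. **GC–MS feature tables.** Blank subtraction (3 × the per-feature blank
   maximum), presence/isotope filtering, dry-weight + log10 normalisation,
   Welch tests with Shapiro–Wilk residual flags, and annotation tiering from
   reverse match scores (R ≥ 800 annotated, 700–800 "?", 600–700 "??",
   otherwise unknown).

A synthetic-data module generates full holobiont datasets (toy networks with
known producible sets, negative-binomial counts with planted effects, feature
tables with planted contamination) whose ground truth is recorded exactly, so
every stage is testable end to end.

## Worked example

```r
library(holoscope)

holo <- generate_holobiont(n_bins = 9, reactions_per_bin = 12, seed = 13)
sim  <- simulate_counts(holo$catalog, seed = 13)

# reaction-space aggregation and active-member selection
rc  <- aggregate_gene_to_reaction(sim$counts, holo$catalog)
act <- bin_activity(sim$counts, holo$catalog, denominator = "bacterial_total")
sel <- select_active_bins(act, sim$design, "MC1", "NSW15")
sel
#> ActiveCommunity (MC1, NSW15): 3 active bins [>= 0.002 in >= 3 of 4 replicates]

# two-factor DE with interaction
res <- nb_fit_test(rc$counts, sim$design, model = "tolerance_x_salinity")
names(res)
#> [1] "microbiome"  "salinity"    "interaction"
head(res$salinity[, c("feature_id", "log2_fold_change", "padj", "significant")], 3)
#>       feature_id log2_fold_change padj significant
#> 1 SHARED-RXN-003     2.512936e-16    1       FALSE
#> 2  BIN01-RXN-001    -4.811922e-01    1       FALSE
#> 3  BIN01-RXN-002    -6.242448e-01    1       FALSE

# community producibility and host added value
av <- added_value(holo$host, holo$catalog$networks[sel$active_bins], holo$seeds)
av
#> AddedValueResult: host alone 27, community 50, host+community 72, added value 45
"VITAMIN-K" %in% av$added_value   # planted precursor-dependency motif
#> [1] TRUE
```

No effects were planted in this small simulation, so nothing is significant:
the salinity coefficients sit near zero with adjusted *p* ≈ 1. The
interaction table reads as community-specific salinity responses: a
significant positive `log2_fold_change` there would mean a reaction induced in
the intolerant community in low salinity beyond the response of the tolerant
communities. In the added-value result, `VITAMIN-K` is producible by the host
only when an active bacterium supplies its precursor — the host alone lacks
every route to it (and in conditions where the precursor-producing bin is not
active, it drops out of the added value again).

The whole pipeline can also be driven through `run_pipeline(pipeline_config(...))`
or the wrapper script in `inst/scripts/run_pipeline.R`, which writes every
stage output as TSV plus a manifest with checksums.

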