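---
title: "Methods: gene-family evolution analysis with famevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolution analysis with famevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famevo analyses the evolution of a protein gene family — the motivating
case is the Wnt ligand family (Pfam PF00110) and the DIX-domain family
(PF00778, i.e. Dishevelled, Axin and Dixin) of the Wnt signalling pathway
in mouse — through a chain of classical comparative-genomics stages. This
vignette records the models, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## Family identification from domain hits

Membership is decided from `hmmsearch` per-domain tabular output
(domtblout), parsed by column index exactly as HMMER3 lays the file out.
The filter keeps hits with full-sequence E-value ≤ 1 × 10⁻⁵ **and**
full-sequence bit score ≥ 0, both comparisons inclusive. These thresholds
are the standard permissive first pass for single-domain families; a flag
switches the filter to the per-domain independent E-value for
multi-domain architectures where a single strong domain should not carry a
weak protein. Isoform redundancy is resolved to one representative per
gene by the longest-isoform rule, ties broken by lexicographically
smallest protein id — deterministic, and the longest isoform is the usual
proxy for the canonical protein.

## Physicochemical properties

Molecular weight is the sum of average (not monoisotopic) residue masses
plus one water (18.015 Da), matching the ExPASy Compute pI/Mw convention;
`X` contributes the mean of the twenty residue masses. The isoelectric
point is the root of the Henderson–Hasselbalch net charge

$$Z(\mathrm{pH}) = \sum_{b}\frac{n_b}{1+10^{\,\mathrm{pH}-pK_b}}
 - \sum_{a}\frac{n_a}{1+10^{\,pK_a-\mathrm{pH}}}$$

over the basic groups (N-terminus, H, K, R) and acidic groups
(C-terminus, D, E, C, Y), using a Bjellqvist-style pK set (N-term 7.5,
C-term 3.55, D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0). The
pK table is an explicit argument, so an alternative scale can be swapped
in. Because $Z$ is strictly decreasing in pH and every chain carries both
termini, a root always exists; it is found by bisection on \[0, 14\] to a
default tolerance of 10⁻³ pH units. The test suite checks the bisection
against an independent 10⁻⁴-step grid search, and the mass sum against
seqinr's independent implementation. `X` is ignored for charge.

Dunnett-adjusted group comparisons (e.g. vertebrate vs invertebrate Mw or
pI) use classical one-way ANOVA with the adjustment delegated to
`multcomp`, which evaluates the exact multivariate-t quantiles for
many-to-one contrasts; this is preferable to any Monte-Carlo or
Bonferroni approximation of the same null.

## Tandem duplication

The tandem rule is positional, not distance-based: family genes that are
*consecutive in the genome-wide gene order* on a chromosome — no spacer
gene of any kind between them — form a tandem group, and runs of three or
more chain into a single group (transitive closure). Gene order is
computed over **all** annotated genes, ranked by start coordinate (ties
by end, then id); strand is ignored. No base-pair cutoff is imposed by
default because adjacency is the defining criterion; `max_gap_bp` adds an
optional distance condition for annotations with sparse gene models.

## Neighbor joining and bootstrap

Distances from a consumed protein alignment use pairwise gap deletion;
the default model is the Poisson correction $d = -\ln(1-p)$ (the standard
protein default of distance-based packages), with the raw p-distance
selectable. Saitou–Nei neighbor joining then iteratively joins the pair
minimising $Q_{ij} = (n-2)d_{ij} - r_i - r_j$; ties are broken by the
lowest (row, column) index so results are reproducible across platforms.
Negative branch-length estimates — a normal occurrence for near-zero
edges — are clamped to 0, with the number of clamped edges recorded on
the returned tree. On an additive matrix NJ is exact: the suite verifies
topology and path lengths against 500 random additive matrices and a
four-point-condition oracle, and cross-checks topologies against ape's
independent NJ.

Bootstrap supports resample alignment columns with replacement, rebuild a
tree per replicate, and score each internal edge of the full-data tree by
the fraction of replicates containing the same bipartition (counted with
`ape::prop.clades`). Replicates whose resampled columns saturate a pair
(p = 1 under Poisson) are dropped and the effective count recorded;
supports are reported in \[0, 1\]. The default is 1000 replicates, the
conventional figure for NJ trees.

## Phylostratigraphy

A gene's ortholog presence across the ladder zebrafish → sea urchin →
nematode → yeast dates its origin: presence in yeast gives `++++` (as old
as eukaryotes) down to `----` (no ortholog anywhere, lineage-specific).
The classifier uses the *deepest-present* rule, so a non-nested vector
(e.g. present in nematode, absent in sea urchin) — which the five nested
symbols cannot represent — is labelled by its most distant presence and
flagged `non_nested` rather than rejected. Percentages are reported to
two decimals; the "post-vertebrate-split" aggregate (`+---` plus `----`)
is defined as the sum of the two already-rounded per-stratum percentages
so that a printed table and its printed total are always consistent.
Family-vs-genome background comparison reports per-stratum ratios as the
primary output, with a supplementary two-sided Fisher exact p-value from
the 2×2 in/out-of-stratum table. Cross-species family-size association is
the plain Pearson correlation with the t-distribution p on n − 2 df.

## MirrorTree co-evolution

The co-evolution score between a member of family A and a member of
family B is the Pearson correlation of their ortholog-set distance
matrices, restricted to shared species, over the strict upper triangles.
Distances are Poisson-corrected pairwise distances from each member's
ortholog alignment — the original server's internal settings are not
recoverable, so the package's own distance stage is used consistently.
Pairs with fewer than 4 shared species (configurable) are reported as
missing with a reason rather than as a meaningless coefficient, and are
excluded from the family-level mean. A 19 × 6 family pair therefore
yields 114 coefficients. Background phylogenetic signal is *not*
partialled out (a pMirrorTree-style correction is a documented
extension), which is why even independently evolving families on a shared
tree show positive mean correlation; the synthetic benchmark below is
designed around differences, not absolute values.

## Differential expression

The expression stage consumes an already-normalised log2 matrix (e.g.
RMA output) and applies a fully specified classifier instead of a
moderated-statistics fit: log2 fold change is the difference of group
means; a gene is `up` when log2FC ≥ 1, `down` when ≤ −1, otherwise
`unchanged`. The default `fc_only` mode uses the fold change alone;
`welch` mode additionally requires a Welch two-sample t-test p < 0.05 and
needs at least two samples per group. The thresholds (1 log2 unit, α =
0.05) are the field's conventional defaults; published proportion tables
are reproduced from their printed counts by the same proportion
arithmetic, not by re-calling genes from raw data.

## Synthetic data: what it emulates, and what it does not

Every stage is testable without downloads against seeded generators:

* **Trees** — equal-rates random topologies with i.i.d. exponential
  branch lengths, mean 0.3 substitutions/site: a realistic mid-range
  protein divergence that keeps pairwise distances well away from
  saturation at the alignment lengths used below.
* **Sequences** — a 20-state equal-rates (Jukes–Cantor-style) model:
  along a branch of length $t$ a site ends in a different state with
  probability $\tfrac{19}{20}(1-e^{-\frac{20}{19}rt})$, the new state
  uniform over the other 19. This is the exact CTMC, so the saturation
  limit of the p-distance is 19/20 — a closed-form check used in the
  tests. No indels are simulated.
* **Co-evolving family pairs** — all members share one tree; each
  member's per-branch log rate multipliers mix a branch-wise component
  shared across families with a member-specific one, with mixing weight
  √ρ so that the log-rate correlation across families is exactly ρ (σ of
  log rates = 1, mean-one multipliers). ρ = 1 gives identical rate
  profiles; ρ = 0 independent ones. The benchmark asserts that the mean
  MirrorTree score increases with planted ρ ∈ {0, 0.3, 0.6, 0.9} (50
  replicates each, 8 taxa, 2 × 2 members, 150 sites) — a rank property,
  robust to the background-signal offset discussed above.
* **Genomes** — planted tandem groups are laid out adjacently with at
  least one spacer between any two family units, so detection must
  recover the planted groups exactly; 1000 random layouts are checked.
* **Ortholog tables and expression matrices** — planted stratum counts
  and planted up/down genes (default design: 19 genes, 3 up, 7 down,
  effect 3 log2 units, noise SD 1, 5 samples/group) are recovered by
  deterministic counting and by the classifier respectively.

Two honest limits of the synthetic benchmark are worth recording. First,
topology recovery from finite alignments is bounded by identifiability:
under the exponential branch-length prior roughly one tree in eight
contains an internal edge shorter than the distance sampling noise at
5,000–10,000 sites, so the suite asserts ≥ 75% overall recovery and
≥ 90% recovery among trees whose internal edges are all ≥ 0.05 — the
observed rates are ≈ 83% and ≈ 96%. Second, classifier recovery on the
planted expression design is assessed per gene (≥ 90% of gene calls
correct across 100 seeded replicates) and as exact recovery of the
planted up/down sets under the default fold-change-only mode; demanding
every gene of every replicate be correct under the significance-tested
mode would fail ~17% of replicates purely through the n = 5 t-test's
false-positive/negative rates, which is a property of the design, not of
the implementation.

Passing these suites shows the operations are correct under the stated
models; it does not show that real proteomes satisfy those models —
real families have indels, rate variation across sites, non-uniform
amino-acid frequencies, and ortholog tables with detection noise.

## Problem sizes and determinism

The default test run uses 6–10-taxon trees, 150–5,000-site alignments,
50-replicate ρ grids, 1,000 synthetic genomes and 100-seed classifier
replicates — sizes at which every property above is measurable in a few
minutes on one CPU. All generators take an explicit seed and are bitwise
reproducible; the pipeline orchestrator (`run_pipeline()`) writes a
timestamp-free JSON summary so a rerun of the same config is
byte-identical.

## Known limitations

* The Dunnett comparison assumes homoscedastic groups (classical ANOVA).
* MirrorTree scores are uncorrected for shared-tree background signal.
* The Clustal reader accepts the common dialect only; alignments are
  otherwise consumed as aligned FASTA.
* The tandem rule depends on the completeness of the gene annotation:
  a missed spacer gene in the input merges two neighbouring groups.
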