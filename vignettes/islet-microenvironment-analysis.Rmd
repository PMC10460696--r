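---
title: "Analysing voxel-grid spatial proteomics of the islet microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing voxel-grid spatial proteomics of the islet microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The data model

`isletgrid` analyses spatial proteome images of pancreatic tissue produced by
laser-capture microdissection of a 3 × 3 grid of tissue "voxels", each voxel
of roughly 200 μm × 300 μm, processed as one TMT plex and quantified as log2
reporter-ion ratios. One voxel per image contains an islet of Langerhans; the
surrounding eight voxels are acinar tissue. A study pools several such images
(seven in the motivating design, 63 voxels in all) over the union of their
protein identifiers.

Voxels are annotated by proximity to the islet: the islet voxel itself,
`proximal` voxels adjacent to it, and `distal` voxels elsewhere on the grid.
Adjacency uses 8-connectivity (diagonals included) because an islet voxel in
the middle of a grid edge then has exactly five neighbours, reproducing the
canonical 5 proximal / 3 distal split of the design; the annotation
nevertheless handles every islet position (proximal counts 3, 5 or 8 on a
3 × 3 grid). Coordinates are 0-based `(row, col)`, row-major — fixed so that
file I/O round-trips exactly.

Distance from the islet is the Euclidean distance between voxel centroids in
micrometres using the physical voxel pitch (200 μm across columns, 300 μm
across rows); a unit-grid Chebyshev metric is available as a fallback when
physical pitch is meaningless.

```{r, eval = FALSE}
library(isletgrid)
g <- voxel_grid(islet = c(0, 1))
table(annotate_voxels(g))
voxel_distances(g)
```

# What the synthetic generator emulates — and what it does not

Every stage of the pipeline is exercised on data from `generate_study()`,
whose defaults *are* the study conditions: 7 images × 3 × 3 voxels, 2000
proteins, 2% islet-marker proteins elevated by 2.0 log2 units in the islet
voxel only, 5% gradient proteins varying linearly with physical distance at
−0.002 log2/μm, a per-plex location shift with SD 0.3 log2 units, Gaussian
measurement noise with SD 0.5 log2 units, and a baseline missingness rate of
2% at the reference abundance. The protein count is kept at 2000 (the real
instrument quantifies ~6000+) purely to keep simulation studies quick; all
rates and effect sizes are per-protein, so nothing downstream depends on the
total. Baseline log2 abundances are drawn from N(0, 1.2²), a typical spread
for median-centred TMT reporter ratios.

Missingness is *not* missing-completely-at-random: each entry drops out with
probability `plogis(qlogis(0.02) − 0.8 · true_abundance)`, a logistic
left-censoring model in which low-abundance signals vanish first, the
mechanism usually seen in reporter-ion proteomics. The real acquisition
process does not document its missingness mechanism; the logistic dropout is
an explicit modelling assumption, and `expected_missing_fraction()` exposes
the model's own Monte-Carlo expectation so realized rates can be checked
against it.

One global seed drives everything; per-image substreams are derived
deterministically from it, so studies are bit-reproducible.

Features of real data the generator does **not** emulate: peptide-to-protein
roll-up noise, carrier-channel ratio compression, correlated protein blocks
(co-regulation), spatial autocorrelation beyond the planted monotone
gradients, and non-Gaussian heavy tails. Passing tests therefore demonstrate
that the statistical machinery is correct and calibrated under the declared
generative model, not that the biological conclusions drawn from any real
tissue are right.

# Preprocessing: missingness, imputation, and the decision not to centre

`missingness_summary()` counts missing entries per voxel over the study-wide
protein index (a protein absent from an entire plex is missing in each of its
nine voxels) and summarises each image by its median voxel count.

Missing values are imputed by `impute_median()`: each protein's missing
entries are replaced by the median of its observed values pooled across *all*
voxels of *all* images. The pooled (rather than per-image) median matches the
downstream model, which treats image as a covariate and pools voxels across
plexes; whether imputation happened before or after pooling is not observable
from the method description we follow, and pooling is the choice consistent
with a single study-wide completed matrix. Even-count medians are the
midpoint of the central pair. The operation never alters observed entries and
is idempotent. Proteins observed nowhere cannot be imputed and are dropped
with a warning.

No cross-plex centring is applied anywhere in the default pipeline. Log-ratio
distributions in this design are not symmetric enough for median centring to
be safe, and plex-level location differences are instead absorbed by the
image covariate of the differential model. `median_center_plexes()` exists,
off by default, so the evaluation that led to this choice can be repeated.
`pca_embedding()` provides the standard QC view: voxel scores on the first
two mean-centred principal components, where one expects clustering by plex
along with separation of the islet voxels.

# Pooled differential expression

For each protein, `fit_region_model()` fits
`abundance ~ 0 + region + image` by least squares over all 63 voxels. The
image term absorbs TMT batch structure; region has levels
islet/proximal/distal. Because each image contributes exactly one islet
voxel, the pooled model is what makes islet inference possible at all — each
image acts as a biological replicate. Confounded designs (a region level
present in a single image, or any rank deficiency) are rejected with the
offending term named.

Per-protein residual variances are shrunk towards a pooled prior with the
standard empirical-Bayes inverse-chi-square scheme, as implemented by limma
(`lmFit`/`contrasts.fit`/`eBayes`); a plain-t fallback (`moderate = FALSE`)
computes ordinary t-statistics from the same fits. Proteins whose residual
variance is exactly zero inherit the prior scale through moderation; in the
fully degenerate case (prior scale also zero, e.g. identical groups) the
statistic is defined as t = 0, p = 1.

Four contrasts cover the region comparisons: `islet_vs_proximal`,
`islet_vs_distal`, `proximal_vs_distal`, and `islet_vs_rest`, the last
comparing islet against the unweighted mean of proximal and distal. "Corrected
p" is Benjamini–Hochberg throughout (the field default; no other procedure is
specified by the source methods), applied per contrast across proteins.
`overlap_counts()` reports upset-style exact-combination counts of the
contrast significance sets.

# Pathway enrichment in two modes

`enrichment_in_sets()` is classical over-representation: a one-sided
hypergeometric tail for each pathway, with both the selected set and the
pathway membership restricted to the quantified-protein background (not all
pathway members genome-wide — proteomics coverage bias makes the quantified
universe the honest background). Sets with no quantified member are reported
untested rather than silently dropped.

`enrichment_in_order()` ranks proteins by an arbitrary score and compares
in-set against out-of-set ranks with a tie-corrected normal-approximation
rank-sum test, reporting a signed z (positive = concentrated at high scores).
Tests are two-sided: distance-correlation scores are signed, and pathways
concentrated at either extreme are of interest; the direction column carries
the sign. Mid-ranks make the statistic invariant to permuting tied entries,
and rank-based scoring makes it invariant to any strictly monotone transform
of the scores. Sets with fewer than two scored members (or non-members) are
skipped with a warning.

# Spatial gradients and the cross-image consensus

Two protein scorings feed the rank-based mode. `protein_variance_scores()`
ranks proteins by their sample variance across all voxels — pathways whose
members vary most across the tissue. `distance_correlation()` computes, per
image, the Spearman rank correlation between each protein's abundance and the
voxel distance to the islet, the "sphere of influence" analysis. Region
labels play no role here; distance is continuous by design, as this analysis
is the deliberate alternative to the discrete-region contrasts.

With nine voxels per image, large-sample p-value approximations are not
defensible, so p-values are exact: the full permutation distribution of rho
over all 9! orderings. Two observations make this cheap. The null
distribution depends only on the multisets of the two rank vectors, so for
continuous (untied) abundances a single enumeration serves every protein of
an image — and every image with the same distance geometry; results are
cached. Tied rows fall back to a per-tie-pattern enumeration. Equality with
the enumerated tail is tested directly (|rho| = 1 has probability exactly
2/9!). For more than nine observations the t-approximation takes over.

The per-protein score passed to enrichment is the signed normal quantile of
the two-sided permutation p (the "z-score of the test statistic"), not raw
rho: it is monotone in |rho| within an image while being comparable across
images with different tie structures. `consensus_pathways()` then flags
pathways whose rank enrichment is significant — BH-adjusted within each image,
p < 0.05 by default — in at least 4 of the images. Adjusted p is the default
because the per-image tests span the whole pathway collection; raw p is
exposed as a flag (`use_adjusted = FALSE`) since the source description is
ambiguous on this point. `pathway_protein_profiles()` extracts the
abundance-by-distance profiles of a flagged pathway's significantly
correlated members.

# Network integration

Differential proteins are integrated over a confidence-weighted interactome
(STRING-like edge list, confidences in (0, 1]) by a prize-collecting Steiner
forest heuristic. Up- and down-regulated proteins are handled as two separate
prize assignments, giving two networks. Prizes are |logFC| of proteins
passing the adjusted-p threshold (the source does not state its prize
definition; |logFC| is the natural magnitude scale and −log p is a trivial
user-side substitution). Edge cost is `1 − confidence + ε` with ε = 0.01, a
strictly decreasing map with a positive floor so that even perfect-confidence
edges are not free.

The objective is `Σ edge costs + β · Σ prizes of uncaptured prized nodes`,
where a prized node is captured when at least one solution edge touches it;
prized nodes that cannot be captured profitably are returned as singleton
trees for visibility but still count as uncaptured. β defaults to 1; ω (the
dummy-edge cost, default: median positive prize) controls how aggressively
prized nodes are merged into shared trees rather than served separately.

The solver is deliberately a deterministic, oracle-testable heuristic rather
than a reimplementation of message-passing or integer-programming solvers:
(1) a dummy root is joined to every prized node at cost ω; (2) terminals are
merged along shortest cost-weighted paths (MST of the metric closure,
re-expanded and re-spanned); (3) strong pruning removes every subtree whose
edge cost exceeds the prize it captures; (4) any tree that is beaten by
serving its prized nodes individually is disbanded; and (5) each prized node
still uncaptured is attached through its cheapest incident edge whenever that
edge costs less than β times its prize. Node processing order is
lexicographic, so solutions are reproducible. Steps (4) and (5) mean a leaf
can occasionally be an unprized *capture partner* of an adjacent prized node;
every other leaf is prized. On exhaustive-search comparisons over small
random instances the heuristic is exact in the large majority of cases and
bounded well inside twice the optimum (the test suite and acceptance script
recompute both numbers).

Zero-prize nodes that appear in a solution are the *Steiner* (implicated)
proteins — not differential themselves but recruited to connect those that
are; `classify_nodes()` separates them from the prized terminals.

# Numerical and design choices, collected

* Median of an even count = midpoint of the central pair.
* BH for all multiple-testing correction.
* Moderated t via limma's empirical-Bayes scheme; plain-t fallback flag.
* Exact Spearman permutation p for n ≤ 9; t-approximation above; two-sided
  throughout; capped into (0, 1] before the normal-quantile transform.
* Constant proteins are excluded (flagged) from correlation rankings;
  all-constant distance vectors are an input error.
* Interactome edges: self-loops dropped, duplicates collapsed to maximum
  confidence, lexicographic canonical order.
* Missing-value convention in TSV files: empty cell or `NA` accepted on
  read, `NA` written.
* One global seed; derived substreams everywhere; identical configuration and
  seed give byte-identical pipeline outputs (timestamps go to the console
  log, never into result files).

Problem sizes used by the test suite and the acceptance script — 2000-protein
studies, 20-seed consensus sweeps, 100 random 9-node network instances, 1000
permutations for the rank-sum null — were chosen to make Monte-Carlo noise
small relative to the tolerances tested while keeping a full run to a few
minutes.

# Known limitations

* The islet voxel is a single TMT channel per image; islet-level inference
  leans entirely on pooling across images, and nothing corrects for partial
  islet capture or islet heterogeneity.
* Median imputation understates variance for heavily missing proteins; the
  differential model does not propagate imputation uncertainty.
* The distance analysis assumes a monotone radial signal; non-monotone
  spatial patterns (rings, anisotropy) will score poorly by construction.
* The PCSF heuristic has no approximation guarantee; its quality is
  established empirically on small instances only.
* Pathway and interactome inputs are taken at face value; no gene-identifier
  mapping or versioning is attempted.
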