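---
title: "Non-semantic labelling: self-information spectra and co-spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-semantic labelling: self-information spectra and co-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cospectra)
library(tibble)
```

## The representation model

Sequence datasets are high-entropy objects. To find structure in them we
must throw information away, and most useful summaries can be read as
*entropy-reducing representation operators* applied element-wise to a
dataset: the collection mean (`op_mean()`) and standard deviation
(`op_sd()`) map every element to a single shared point; the rank operator
(`op_rank()`) maps each element to its position under an ordering model;
binning operators (`op_bin()`, `op_freq()`) map each element to its parent
bin's centre and occupancy; and the self-information operator
(`self_information()`) maps each element to its "surprise"

\[ h = -\ln p \]

in nats, under an empirical probability model of the data. Scalar
operators alone reveal little. The useful construction is *tensorial*:
given a panel of models \(m_1,\dots,m_M\) and a panel of operators, the
representation is an \(N \times M \times K\) array
(`tensor_representation()`). Its row slices are **spectra** — one data
element described across the whole model panel — and its column slices are
**co-spectra** — one model described across the whole dataset. The two are
exactly transposes of each other (`spectrum_of()`, `cospectrum_of()`); the
package computes the tensor once and both views are index flips, so the
duality holds to the last bit, not to a tolerance.

The representation is deliberately *non-semantic*: sequences, taxonomy
names and k-mers enter only as opaque bin keys. All structure that the
downstream metrics and embeddings recover comes from the pattern of
probabilities, ranks and identities, never from interpreting the labels.

A model-fitting operator (representing each element by a fitted value
under a general model) belongs to the same algebra but has no canonical
instantiation; `op_fit()` is an explicit extension point that errors with
a pointer here. Custom operators can be supplied to
`tensor_representation()` as functions of `(payload, model, ids)`.

### Conventions that needed fixing

* **Logarithm base.** All self-information is natural-log (nats). The
  base is recorded as `log_base` on models and tensors.
* **Unobserved bins.** An element absent from a probability model has no
  finite \(-\ln p\). We assign the half pseudo-count probability
  \(p^* = 0.5/(\text{total\_count}+0.5)\), which is finite, decreases
  monotonically as the model's sample grows, and — critically — every such
  cell carries an `unobserved` flag so downstream consumers can exclude or
  re-weight it instead of trusting it.
* **Ties in ranks.** Tie handling is genuinely open. The default is
  deterministic: ordinal ranks with a lexicographic tie-break on element
  ids (`tie_rule = "ordinal-lexicographic"`); `"average"` is available
  where fractional shared ranks are preferable.

## Front-ends

**k-mers** (`count_kmers()`): all overlapping k-length windows of a read
set, k = 6 by default (4096 possible words). Subsampling keeps whole reads
(Bernoulli per read, seeded), matching how sequencing files are thinned in
practice; windows containing non-ACGT symbols are skipped. Words are
counted as written by default — adapter contamination is strand-specific,
and folding strands (`canonical = "lexmin"`) would dilute exactly the
signal the diagnostics look for.

**Alignment depth** (`windowed_depth_model()`): for a panel of reference
assemblies, each query's empirical probability under reference \(j\) is
the number of queries best-aligned within a window centred on its own
alignment position (half-open, \([c - w/2, c + w/2)\), never crossing a
contig boundary), divided by the total aligned to that reference. The
window is centred per query rather than fixed genome bins, and the width
(default 2000 bases) is an explicit, exposed parameter — there is no
principled universal value; it should be of the order of the query length
times the expected local alignment scatter. These per-query probabilities
deliberately do not sum to one (windows overlap), so the model is built
unnormalised; self-information and pseudo-count behaviour are unchanged.

**Taxonomy counts** (`taxa_information_cospectra()`): each sequencing
batch is a probability model over the union of taxonomy names observed
across *all* batches, one count per sampled read's top hit. Names are
opaque strings, trimmed of whitespace only. `cumulative_update()` grows
the store; adding batches never changes existing batches' probabilities,
it only pads their co-spectra with flagged zero-count cells.

## Zipfian co-spectra and the turning-point detector

Combining the rank and self-information operators for one k-mer model
gives an ordered list of (rank, h) pairs (`zipfian_cospectrum()`), a
function from \(\ln r\) to \(h\). DNA word frequencies approximately
follow power laws, so the curve is near-linear; its slope tracks repeat
content (repeat-rich genomes have more co-abundant words, hence steeper
rises), and sharp turning points indicate *non-biological* artefacts: an
untrimmed adapter plants a plateau of co-abundant words followed by a
cliff.

`detect_turning_points()` works on a uniform grid in \(\ln r\) (256
points):

1. **Cell means, not interpolation.** h is averaged within each grid
   cell. High-rank cells contain hundreds of words whose integer counts
   form tiny staircases; interpolating through every knot lets those
   staircase kinks dominate the curvature estimate, while the per-cell
   mean is stable.
2. **Smoothing.** A centred moving average, default 9 grid points.
3. **Curvature.** Discrete second differences of the smoothed curve with
   respect to \(\ln r\), evaluated only where the full smoothing window
   applied (asymmetric edge windows curve even exact lines).
4. **Thresholding.** A point is reported when it is a local extremum of
   |curvature| and exceeds both 3x the median absolute curvature
   (scale-free, robust) and an absolute floor `min_curvature = 10` nats
   per unit \((\ln r)^2\). The floor is set from the analytic scale of the
   features of interest: a plateau-edge step of \(\Delta h \gtrsim 0.5\)
   nat concentrated within one smoothing window produces curvature of
   order \(\Delta h/(w\,\mathrm{d}x^2) \approx 50\), whereas the gentle
   global curvature of clean power-law-ish samples and residual
   count-discreteness kinks stay an order of magnitude below 10 at
   realistic depths (we calibrated this on simulated clean lanes of
   3000 x 64 bp reads, where clean-sample curvature peaked near 5).

An exact power law yields zero curvature and an empty result by
construction. The floor is depth-dependent in principle: at very low
coverage (hundreds of reads) count noise rises and the detector should be
treated as indicative only.

`assemble_enriched_kmers()` closes the loop on adapter findings: the
selected co-abundant words are merged greedily by maximal exact
suffix–prefix overlap (default minimum k-1), ties broken by higher
combined count then lexicographically. A band of words planted by an
adapter tiles it and reassembles into the full contaminant; selections
polluted by a few background words still return the contaminant as the
longest contig unless a background word happens to extend it.

## Metrics

Three distances are provided, each over a different representation:

* `euclidean_distances()` on spectra or co-spectra, with a
  pairwise-complete option that restricts each pair to mutually observed
  coordinates and rescales by \(\sqrt{L/L_\text{used}}\).
* `cluster_projection_distances()` on co-spectra: the element spectra are
  k-means clustered (seeded k-means++ initialisation, so runs are
  reproducible; 300 clusters by default) and each co-spectrum is projected
  to its vector of within-cluster means before taking Euclidean
  distances. Plain Euclidean distance weights an expression cluster by
  its size; the projection gives each cluster of co-varying elements
  roughly equal weight. With `n_clusters = N` the projection is the
  identity and the metric reduces exactly to the Euclidean one (this is
  tested, not assumed). An empty cluster triggers one re-seed, then a
  `degenerate-clustering` error.
* `zipfian_distance()` on matrix-valued (rank, h) co-spectra:
  \[ d(a,b) = \sqrt{\sum_w \frac{(h_a(w) - h_b(w))^2}{\bar r(w)}},
     \qquad \bar r(w) = \tfrac{1}{2}(r_a(w) + r_b(w)), \]
  summed over the union of word universes; words absent from one
  co-spectrum take that model's pseudo-count h and rank \(D+1\). The
  inverse-rank weight focuses the comparison on abundant words, which
  carry the slope. Averaging the two ranks is our convention — any
  symmetric combination would do, and the choice is recorded here rather
  than attributed elsewhere.

**A caveat on metric axioms.** The zipfian distance's weight depends on
the pair being compared (ranks are properties of each co-spectrum), so it
is not an inner-product metric, and adversarially constructed triples can
violate the triangle inequality. On random and realistic instances we
have never observed a violation — the test suite checks hundreds of random
triples to 1e-9 — but callers doing exact metric-tree indexing should use
the Euclidean or cluster-projection metrics instead.

## Embedding and display

`mds_embed()` is classical (Torgerson) MDS: deterministic, exact on
Euclidean-embeddable inputs (a 3-4-5 triangle is reproduced to numerical
precision), with a sign convention (first nonzero loading positive) so
coordinates are reproducible; Kruskal stress-1 is reported. An iterative
stress majoriser could fit non-Euclidean distance matrices slightly
better, but determinism and testability won.

`heatmap_order()` clusters rows and columns independently
(average-linkage), orders leaves smaller-subtree-first with a
lexicographic-label tie-break (making the order equivariant under input
permutation), and serialises dendrograms as Newick with branch lengths
equal to merge-height differences.

## The synthetic generator: what it does and does not emulate

All three input classes are generated from seeded pure functions, so the
full pipelines are testable without downloads.

```{r synth-example}
profiles <- default_species_profiles()
cfg <- lane_config(
  tibble(sample_id = c("bio1", "bio2"),
         profile = list(profiles$smooth, profiles$repeatrich),
         n_reads = 200L, read_length = 64L),
  seed = 1)
reads <- simulate_reads(cfg)
vapply(reads, length, integer(1))
```

Reads are order-1 Markov chains over ACGT. Two reference profiles are
built in: `smooth` (transition rows are cyclic permutations of
0.28/0.26/0.24/0.22 — mild bias, shallow zipfian slope) and `repeatrich`
(rows of 0.40/0.27/0.18/0.15 plus a 12 bp repeat family in 1% of reads —
strong bias, steep slope, emulating a repeat-rich fungal genome). Reads
are 64 bp by default, a typical reduced-representation tag length.
Adapter read-through replaces the 3' end of a read with the 38 bp
`adapter_sequence()` (33 distinct 6-mers, all internal 5-mers distinct so
greedy assembly is unambiguous) at the configured rate. Negative controls
draw from a uniform composition, giving the flat co-spectrum curves that
distinguish no-template wells. The studies the package validates itself
on use these fixed conditions: a 192-sample lane (150 + 42 of the two
species, 300 reads each) for species-cluster recovery, and single
3000-read samples at adapter rates 0.05 versus 0 for the contamination
diagnostics.

Hit tables place two-thirds of queries in a dense 20 kb cluster on a 1 Mb
virtual genome, the rest sparse, with an empty reserved gap; a reference
transform relocates a 200 bp slice of the dense cluster into the gap.
Inside the slice, window depth drops from the cluster's (about 40 per
2 kb window at the default 600 queries) to the slice's own (about 4), an
expected self-information shift of \(\ln 10 \approx 2.3\) nats, while no
query outside moves by more than about \(\ln(40/36) \approx 0.1\) — which
is what makes the planted rearrangement recoverable from off-diagonal 2D
sub-spectra with a 1-nat criterion.

Taxa tables draw per-batch multinomials from Dirichlet-perturbed
species-level base profiles over an opaque taxon pool.

What the generator does **not** emulate: sequencing quality scores,
realistic error profiles (only an optional uniform substitution rate),
higher-order genomic composition, paired-end structure, PCR duplicates,
or real taxonomies. Passing the recovery studies therefore demonstrates
that the representation and metrics recover *planted* compositional and
positional structure at realistic scales — it does not certify behaviour
on any particular real instrument's quirks.

## Numerical choices and degenerate inputs

* Probability models validate \(\sum p = 1\) to 1e-9 (except the
  explicitly unnormalised depth models).
* Zipfian rank ties (equal probabilities) break lexicographically by
  word, so ranks are deterministic.
* k-means: seeded k-means++ initial centres, then `stats::kmeans` with
  `iter.max = 100`; `n_clusters = N` bypasses clustering (singleton
  assignment) since duplicate centres would be degenerate.
* Empty datasets, unknown ids, kind-mismatched operator/model pairs,
  zero-count batches, unreadable records and no-overlap pairs all raise
  classed conditions (`"empty-dataset"`, `"unknown-id"`,
  `"operator-model-kind-mismatch"`, `"empty-batch"`, `"parse-error"`,
  `"no-overlap"`, ...), so callers can test for the failure mode rather
  than matching message text.
* An all-zero distance matrix embeds to all-zero coordinates with zero
  stress rather than erroring.

## Problem sizes used by the validation suite

The self-checks run at deliberately desk-sized scales: oracle
equivalences on up to 10 kb of reads and 1000 alignment hits;
metric-axiom checks on hundreds of random triples; the recovery studies
at the fixed conditions above, each judged over 20 seeds with an
18-of-20 success criterion for the stochastic parts. These sizes are the
package's own validation design; the methods themselves stream much
larger inputs (k-mer counting is linear in bases, the zipfian machinery
is bounded by \(4^k\)).

## Known limitations

* The zipfian distance is not provably a metric (see above).
* The turning-point detector's absolute floor assumes per-word counts
  large enough that count noise stays below the artefact scale; at very
  low coverage, prefer visual inspection of `plot_zipfians()` output.
* Windowed depth uses best hits only; multi-mapping structure is
  invisible to it.
* `op_fit()` (model-fitting representation) is unimplemented by design.
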