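---
title: "Trio motifs in signed microbiome co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio motifs in signed microbiome co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionet)
```

## The model

Diversity indices summarise a microbial community as a species-abundance
distribution and ignore who interacts with whom. trionet works on the
co-occurrence *network* instead: OTUs are nodes, and a signed edge connects
two OTUs whose abundance profiles are significantly correlated across the
samples of one treatment group. On that network the package counts
**trios** — triangle motifs — under a three-level scheme anchored on a
focal node, by default the **MAO** (most abundant OTU, the OTU with the
largest summed relative abundance in the group):

1. **Class**: does the focal node touch the triangle from outside (a
   *handle*) or not?
2. **Category**: for handle-free triangles, whether the focal node is a
   member (*with MAO* vs *without MAO*); for handled triangles, the number
   of focal links — single (SLM), double (DLM) or triple (TLM).
3. **Type**: the sign pattern. With-MAO triangles split by internal signs
   into Type-1 (`+ - -`, *dominantly inhibitive*), Type-2 (`+ + -`),
   Type-3 (`- - -`) and Type-4 (`+ + +`, *fully facilitative*); Type-1 and
   Type-2 further split by the signs of the two focal-incident edges
   (1A/2A vs 1B/2B — mixed vs pure strategy of the MAO). Handle trios are
   typed by the multiset of handle-link signs alone.

This yields exactly 6 + 4 + 2 + 3 + 4 = 19 types
(`trio_type_labels()`). The five categories are mutually exclusive and
exhaustive, so category totals always sum to the triangle count — a
package invariant that the test suite checks on every input.

Two treatments (diseased vs healthy) are compared with the **RDHT**, the
ratio of disease to healthy counts per type and per category, with the
conventions 0/0 = `NA` and x/0 = `Infinite`. Ratios are held at full
precision and rounded half-up to two decimals only in reports.

## The pipeline and its parameters

`run_pipeline()` executes, per group independently:

| step | function | parameter (default) |
|------|----------|---------------------|
| normalisation | `to_relative_abundance()` / `rarefy()` | `normalization = "relative"` |
| correlation | `pairwise_correlation()` | `method = "spearman"` |
| FDR control | `adjust_fdr_bh()` | pooled over all N(N−1)/2 pairs of the group's network |
| network | `build_network()` | `alpha = 0.05` on the adjusted q; `min_abs_rho = 0` |
| census | `identify_focal()`, `trio_census()` | `focal_rule = "mao"` |

Choices that were genuinely open, and how they were settled:

* **Threshold on q, not p.** The 0.05 threshold is applied to the
  BH-adjusted value; thresholding raw p would make the FDR step a no-op.
  `use_q = FALSE` keeps raw-p thresholding available for sensitivity
  analysis.
* **FDR pooling.** p-values are pooled within each treatment's network
  (each group is its own family of N(N−1)/2 tests), not across
  treatments.
* **Per-treatment OTU sets.** Each group's network uses that group's
  samples only; OTUs with zero variance there carry no rank information
  and are dropped with a warning before testing.
* **Spearman p-values** come from the t approximation
  t = ρ√((n−2)/(1−ρ²)) with average ranks for ties; the exact permutation
  distribution is out of scope. Pearson uses the same t form. Both are
  cross-checked against `stats::cor.test(exact = FALSE)` in the tests.
* **Sign of an edge** is the sign of ρ. A pair with ρ exactly 0 that
  passes the threshold (pathological) has no sign and is excluded.
* **Type-2A/2B sub-labelling** mirrors the stated 1A/1B rule (focal
  incident `{+,+}` vs `{+,-}`). Type-2 and Type-3 are empirically absent
  from real surveys, but no structural prohibition is enforced — the
  classifier supports all 19 labels.
* **Handle trios are typed by handle signs only**; internal triangle
  signs are recorded in the trio records for inspection but do not enter
  the label.
* **Focal ties** break lexicographically by OTU id, so the MAO choice is
  deterministic. A degree-0 focal node is legal: every triangle then
  falls in the without-MAO category (logged).
* **Unequal groups.** `balanced_census()` implements the resampling
  protocol: draw `n_per_group` samples without replacement, run the whole
  pipeline, repeat (default 50 times) and average the per-type counts.
  The averaged, possibly fractional censuses feed `rdht()` directly.

Note the geometry of handled trios: a DLM or TLM "trio" is really a
four-node structure, and the focal node plus two linked triangle members
always close a with-MAO triangle of their own. A census of a network with
planted handle motifs therefore legitimately reports those companions.

## The synthetic generator

`make_otu_counts()` emulates the statistical structure the pipeline
assumes: a latent multivariate Gaussian with block correlation structure,
pushed through the Gaussian copula into negative-binomial counts
(`dispersion = 10`, mean library size `depth = 5000`). Because the
count transform is monotone in the latent variable, planted blocks
surface as Spearman correlations of the planted sign. One OTU can be
boosted (`mao_boost`) so that it is the abundance maximum and becomes the
MAO. Blocks accept a full correlation sub-matrix, which is how mixed-sign
trios (Type-1A: MAO `+` to one partner, `-` to the other, partners `-`)
are planted; the assembled matrix is checked for positive definiteness
and rejected otherwise. Frustrated sign patterns (an odd number of
negative correlations around a triangle) bound how strong the planted
correlations can be — e.g. the `+/-/-` triangle at ±0.6 is fine, while a
double-link handle with opposing signs needs ±0.35/0.5 to stay positive
definite.

`make_signed_graph()` skips the abundance layer entirely: an
Erdős–Rényi background of signed edges plus requested motifs planted on
fresh, disjoint nodes. Planted counts are lower bounds that are exact
when `edge_prob = 0`, which gives the test suite cheap ground truth, and
random graphs feed the brute-force oracle-equivalence harness.

What the generator does **not** emulate: real taxon composition,
library-size distributions, zero-inflation beyond what the negative
binomial produces, and — deliberately — the compositional closure of
relative abundances. Synthetic samples have independent library sizes, so
raw counts are the faithful normalisation for recovery experiments; we
run the planted-motif harness with `normalization = "counts"`. Converting
a table with a strongly boosted MAO to relative abundance induces
spurious negative correlations with the dominant OTU (the classical
compositionality artefact), which is a property of real 16S data too —
passing recovery tests therefore show that the pipeline recovers planted
rank-correlation structure, not that relative-abundance networks on real
data are artefact-free. Compositionality-aware estimators are explicitly
out of scope; the method uses plain Spearman/Pearson.

## Verification strategy and problem sizes

* Census correctness: equality with an exhaustive classifier over all
  C(n,3) triples on 50 random signed graphs of 30–60 nodes, plus the
  category-partition, sign-mirror (global sign negation maps 4↔3, 1A↔2B,
  1B↔2A, ... and fixes `DLM:-+`), relabeling-invariance and
  focal-independence properties.
* BH adjustment: equality with the step-up definition on 1000 random
  p-vectors of length 1–500.
* End-to-end: six planted designs (Type-4, 1A, 1B, `SLM:-`, `DLM:-+`,
  `TLM:+++`) at 200 samples and 11–12 OTUs, 20 seeds each, requiring the
  planted label in ≥ 90% of runs.
* RDHT arithmetic: the bundled published trio counts for six human
  microbiome case studies (15 treatments) must reproduce the
  corresponding published category and type ratio tables exactly at
  two-decimal rounding.

These sizes keep the default suite under half a minute while the
brute-force oracles stay exhaustive.

## Known limitations

* Spearman/Pearson on relative abundances inherits compositional bias;
  interpret negative edges with a dominant MAO cautiously.
* The t-approximation p-values are asymptotic; with very few samples
  (near the minimum of 3) they are crude, and the FDR step inherits that.
* Handle semantics assume the focal node is unique and external to the
  triangle; alternative focal definitions (most dominant OTU, hubs) are
  supported only through `focal_rule = "explicit"`.
* Motifs larger than a triangle plus handle are out of scope; general
  motif search is computationally prohibitive and the trio scheme is the
  point.
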