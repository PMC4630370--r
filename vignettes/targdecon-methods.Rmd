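---
title: "Methods: target deconvolution and time-course iTRAQ quantification"
author: "targdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target deconvolution and time-course iTRAQ quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targdecon)
```

targdecon implements the two computational arms of a chemical +
expression proteomics study of a peptide drug, as a pipeline of small,
individually testable stages. This vignette is the package's account of
the underlying methods: the models, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical decisions taken where the methodology left
room.

## The chemical-proteomics arm

An AP-MS pull-down identifies every protein retained on the drug-loaded
matrix, which is dominated by background. The deconvolution chain applies
three operations in order, each shrinking or annotating the profile:

1. **Nonspecific subtraction** — proteins also retained on the unloaded
   matrix (sticky binders) are removed. Accessions are compared at the
   root level: isoform (`-2`) and version (`.3`) suffixes are stripped
   first, the more conservative reading when control and drug lists come
   from separate search runs.
2. **Central-proteome subtraction** — members of the ubiquitously
   expressed "central proteome" are removed and kept as a flagged set for
   reporting. Set difference commutes, so the order of steps 1–2 affects
   only provenance flags, never the survivor set (this is asserted by a
   property test).
3. **CRAPome annotation** — every accession the chain touched is annotated
   with its average spectral count in AP-MS contaminant repositories. A
   count *strictly greater than* the threshold (default 2) flags a
   frequent contaminant. This step is annotation-only by default because
   the filtered target count is defined by the central-proteome
   subtraction alone; `crapome_filter = TRUE` additionally removes flagged
   members for users who want a harder filter.

Complex overlap then reports catalog complexes with at least
`min_members` (default 2) members in the surviving profile.

### emPAI and affinity scores

The abundance of each pulled-down protein is estimated by the
exponentially modified protein abundance index,
$\mathrm{emPAI} = 10^{\mathrm{PAI}} - 1$ with
$\mathrm{PAI} = n_\mathrm{observed} / n_\mathrm{observable}$.
Observable peptides are enumerated by in-silico tryptic digestion
(cleavage C-terminal to K or R except before P) and counted as distinct
bare sequences whose monoisotopic mass falls in a window.

* **Mass window, default [798, 5997] Da.** The instrument surveys
  400–2000 m/z and triggers on 2+/3+ precursors; the corresponding
  neutral-mass envelope is roughly (400·2 − 2·1.00728) to
  (2000·3 − 3·1.00728) Da. The window is configurable because
  observable-peptide definitions differ between search engines.
* **Missed cleavages for observability, default 0.** Database searches
  commonly allow one missed cleavage for matching, but observability is
  conventionally counted on the fully cleaved peptide set; also
  configurable.
* **Distinctness by bare sequence.** Modified forms of one peptide count
  once.

Affinity of the drug for its targets is taken to be proportional to the
amount of protein recovered, i.e. to emPAI, max-normalised so the most
abundant target has affinity 1. `forced_full_affinity` pins named
accessions (e.g. a target validated by orthogonal experiments but poorly
expressed in the lysate) to affinity 1.

The packaged reference table of 55 filtered targets ships the published
emPAI values as data: the observed/observable counts behind them came from
the search engine and are not published, so they are fixtures, not
recomputation targets.

### Subnetwork perturbation

A functional subnetwork is a connected fraction of the interactome whose
proteins share one annotation term. When a term's induced subgraph is
disconnected the largest component is kept (the definition demands
connectedness; `all_components = TRUE` scores every component separately
instead). The perturbation score of subnetwork $V_f$ by the weighted
target set $T$ is

$$S_{net} = \frac{\sum_{t \in T \cap V_f} a_t
  + \sum_{t \in T \setminus V_f} a_t\, e(t, V_f)/\deg(t)}{|V_f|}$$

Direct members contribute their full affinity; a peripheral target
contributes in proportion to the fraction of its interactions pointing
into the subnetwork, which realises the direct/indirect perturbation
mechanism with a single smooth weighting. Two choices here are this
package's own: the $e/\deg$ peripheral weight and the $1/|V_f|$
normalisation that makes scores comparable across subnetwork sizes. A
target inside the subnetwork contributes only its direct term — direct
membership supersedes any peripheral contribution from its outside edges.
$S_{net}$ is zero iff no target touches the subnetwork, is monotone in
every affinity and in peripheral edges, and is bounded by (touching
targets)$/|V_f|$; the test suite checks all of these plus exact agreement
with a brute-force edge-loop recomputation on generated instances. The
packaged reference scores of the ten published subnetworks are fixtures:
recomputing them would require the original interactome and annotation
snapshots.

### Enrichment

Term over-representation uses the hypergeometric upper tail
$P(X \ge k)$ for $k$ query hits among $n$ query proteins, $K$ annotated
proteins in a background of $N$, with Benjamini–Hochberg q-values across
the tested terms (those with at least one query hit). The default
background is the set of all proteins identified in the experiment — the
standard choice for proteomics over-representation, since the detectable
proteome, not the genome, is what was sampled. Annotation is a flat
term-to-accession mapping; no ontology-graph propagation is applied
(callers can pre-close their annotations if they want it).

## The expression arm

### Reporter-ratio fitting

Each 4-plex reporter-region spectrum is modelled as a non-negative linear
combination of four channel templates on a common m/z grid. Templates are
built from the isotopic envelope of a configurable elemental composition
(default C6H13N2, a reporter-sized ion), placed 1 Da apart, so adjacent
channels genuinely overlap and quantification requires deconvolution; the
exact isotope-impurity matrices of commercial tag lots are out of scope.
Coefficients are fitted by non-negative least squares, and fit quality is
the goodness-of-fit coefficient

$$\mathrm{GOF} = 1 - \tfrac12 \sum_i |\hat{o}_i - \hat{f}_i|$$

on the unit-area observed and fitted envelopes — total-variation
similarity, bounded in [0, 1], equal to 1 exactly for a perfect shape
match, symmetric, and invariant to joint rescaling. Quantifications with
GOF below 0.8 are discarded; the boundary (GOF = 0.8 exactly) is
retained. Ratios are reported relative to channel 114 (untreated control)
when that channel is detected; a channel counts as detected when its
coefficient exceeds `detect_tol` (default 1e-6) times the largest
coefficient.

The isotopic envelopes themselves come from iterated convolution of
per-atom isotope distributions (binary exponentiation over atom counts),
pruning peaks below a relative intensity (default 1e-8) and merging peaks
closer than `merge_tol` (default 1e-3 Da).

### From peptides to calls

* **Aggregation**: peptide ratios of one protein are averaged by
  geometric mean — the symmetric choice for ratio data
  (mean of $r$ and $1/r$ is 1). Whether the original workflow averaged
  arithmetically is not recoverable; the geometric mean is the defensible
  default.
* **ON/OFF**: a protein is ON at a time point when its control channel is
  below detection in every contributing peptide while the treated channel
  is detected, and OFF in the reverse case. ON/OFF states carry no
  numeric ratio and are excluded from normalisation and thresholding.
* **Normalisation**: each time-point column is divided by its median
  ratio, so the post-normalisation median is exactly 1. This is the
  median-centring that matches the use of the population median in the
  threshold.
* **Thresholds**: on the normalised log2 population,
  $\tau_{\log_2} = |\mathrm{median}| + z \cdot \mathrm{SD}$ with
  $z = \Phi^{-1}(1 - p/2) = 1.6449$ at $p = 0.1$. Two-sided is the right
  reading because both up- and downregulation are called. The threshold
  is reported on the symmetric fold-change scale as $2^{\tau_{\log_2}}$.
* **Calls**: significant iff $|\mathrm{FC}| \ge \tau$ (inclusive — forced
  by the reference table, where an entry equal to its threshold is
  called) and $|\mathrm{FC}| > 1 + 10^{-8}$, or ON/OFF. The second
  condition is a degenerate-input guard: in a zero-variance population
  $\tau \to 1$, and without it every unchanged protein (and every
  $1 \pm 10^{-9}$ round-off from the least-squares fit) would be called.
* **Trends**: trajectories are discretised per time point to
  down/none/up/ON/OFF and grouped by pattern, largest groups first.

The packaged 72-protein reference table replays through this calling rule
with its published thresholds (2.6, 2.6, 2.4): every published per-cell
significance call is reproduced, which pins down the inclusive comparison
and the ON/OFF semantics.

## The synthetic-data module

The generators define the conditions under which the pipeline is tested;
they are deterministic functions of their configuration and a seed, and
they always emit the ground truth needed to score downstream callers.

* **Pull-down fixtures** reproduce the study's cardinalities (265
  identified, 104 sticky, 106 central among the remainder, leaving
  161 and then 55) with random sequences and Poisson observed-peptide
  counts. CRAPome counts are log-normal: high for central
  (meanlog 1.8, ~87% above count 2, echoing how dominantly central
  proteins look like frequent contaminants) and sticky proteins, low and
  sparse elsewhere.
* **iTRAQ experiments** plant a fraction of regulated proteins (true
  ratio $\mathrm{fc}^{\pm 1}$ at a random non-empty subset of the three
  time points, direction per protein), ON proteins (control channel
  absent), and OFF proteins (treated channel absent at one time point).
  Peptide-level log2 ratios are the protein value plus Gaussian noise —
  the standard noise model for ratio data; the source workflow states
  none. Because one 4-plex spectrum shares its control channel across
  all three time points, ON is planted at all time points of a protein;
  per-time-point ON patterns as seen in real data arise from multiple
  spectra across runs and are not simulated.
* **Network fixtures** build a connected simple graph (random spanning
  tree plus rejection-sampled extra edges), terms grown by randomised
  breadth-first expansion so every term induces a connected subgraph, and
  targets with recorded placement (inside a term, adjacent to a term, or
  random), affinities uniform with the maximum pinned to 1.

What the generators do *not* emulate: raw LC-MS/MS spectra, retention
times, search-engine scoring, shared peptides (the peptide-to-protein map
is one-to-one by construction), isotope-impurity leakage between tag
lots, and the fold-change distribution of the real treated proteome,
which is unpublished — the defaults are plausible placeholders, not
estimates of the study. Passing tests therefore demonstrate correctness
of the computations under known ground truth, not instrument-level
realism.

## Problem sizes and costs

The test suite and the acceptance script run at deliberately desk-sized
scales: pull-downs of up to 265 proteins, iTRAQ experiments of 100
proteins × 2 peptides (200 spectra; fitting 2 000 spectra for a
658-protein experiment is equally feasible), networks of up to 200 nodes
with brute-force score verification, hypergeometric enumeration up to
N = 30, and threshold recovery on populations of 10 000 log2 ratios
averaged over 10 replicates (one draw's Monte-Carlo error is of the same
order as the 2% comparison band; the average measures the estimator).

## Known limitations

* Protein inference is out of scope: the peptide-to-protein manifest is
  authoritative, and shared peptides are not modelled.
* The reporter templates are generic isotopic envelopes, not
  lot-calibrated tag impurity matrices; absolute ratio accuracy on real
  instruments will be limited by that calibration, not by the fit.
* The published emPAI and $S_{net}$ reference values are replayed as
  fixtures; they cannot be recomputed without the original search-engine
  internals and database snapshots.
* Enrichment treats annotation as flat sets; ontology propagation, term
  redundancy reduction and annotation evidence codes are the caller's
  responsibility.
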