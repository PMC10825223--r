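---
title: "Models and methods behind stamper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stamper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical models, its
generative simulator, and the design decisions a careful user should
know about. Function-level usage lives in the help pages; here we explain
*why* each piece works the way it does.

## 1. The assay being modelled

An RNA base editor (rBE) — a C-to-U deaminase of the APOBEC family, an
A-to-I deaminase of the TadA/ADAR family, or a dual-modality enzyme — is
fused to an RNA-binding protein or tethered to a reporter through an
MS2/PP7 coat-protein interaction. Wherever the fusion dwells on an mRNA,
substrate bases on nascent reads are converted, so sequencing reads carry
C→T (or A→G) mismatches near binding sites. Three experiment shapes
recur, and the package's three pipeline presets mirror them:

1. **Reporter screen** — a GFP-like CDS with stem-loops in the 3'UTR;
   per-position editing profiles, spillover onto the CDS, and the
   on/off-target ratio grade candidate enzymes.
2. **RBP fusion profiling** — transcriptome-wide edit clusters mark the
   RBP's targets; free (untethered) editor controls define background.
3. **Translation profiling** — a ribosome-protein fusion writes edits in
   proportion to ribosome occupancy; per-gene edits-per-read (EPR) is the
   readout, and an mTOR inhibitor contrast (strongest on 5'TOP mRNAs)
   is the canonical perturbation.

## 2. The generative model

`enzyme_model()` describes an editor by four interpretable parameters.
For a substrate base at distance $d$ bp from the midpoint of the nearest
bound site, the per-read editing probability is

$$ p(d) \;=\; \min\!\bigl(1,\; \text{peak\_rate} \cdot K(d) \cdot
w(\text{up},\text{down})\bigr) \;+\; \text{background\_rate} \cdot
w(\text{up},\text{down}), $$

capped at 1, with a Gaussian recruitment kernel
$K(d) = \exp(-d^2 / 2h^2)$ truncated to zero beyond $4h$
(`kernel_halfwidth` $h$, in bp), and a flanking-context weight
$w \in [0,1]$ over the 16 (upstream, downstream) base pairs.

Decisions worth recording:

* **The kernel is Gaussian.** Published editing profiles show a smooth
  decay around tether sites without a stated functional form; a
  truncated Gaussian is the simplest monotone kernel with a single scale
  parameter, and the truncation keeps simulated editing strictly local.
* **Context weights multiply the background term too.** Sequence-context
  preference is an intrinsic property of the deaminase — free editors
  display the same flanking biases as fusions, which is precisely what
  the context-PCA and classifier modules are built to detect. A
  context-blind background would make free-editor bias characterisation
  impossible by construction.
* **Dual enzymes** carry independent C2U and A2I parameter sets. When
  two enzymes are co-simulated, an optional `interference` factor
  $\le 1$ scales the targeted (kernel) component, modelling mutual
  hindrance of co-recruited editors; its magnitude is not quantified
  anywhere we trust, so the default is 1 (off) and the knob is exposed.
* **Sequencing error** is substitution-only at rate $10^{-3}$ per base
  (typical Illumina scale), applied after editing; indels, PCR
  duplicates, paired ends and splicing are out of scope. Reads are
  single-end 100 bp, sense-strand, placed uniformly (or by per-gene
  load), and emitted pre-aligned (ungapped SAM) so no external aligner
  is needed.

The transcriptome generator (`simulate_transcriptome()`) draws lognormal
CDS and 3'UTR lengths, per-gene GC around a global mean
(sd 0.07 by default), and lays sequence down in compositional segments
(mean 150 bp, per-segment GC sd 0.12). The segments emulate the local
composition structure of real mRNAs — AU-rich elements, GC-rich
stretches — which is what lets composition-sensitive analyses (cluster
base content, classifier windows) behave realistically; i.i.d. bases
would make every 200-bp window look alike. Binding motifs (default
GCAUG as DNA `GCATG`) are planted non-overlapping at random 3'UTR
positions of a target-gene subset, and a TOP flag marks a random
`top_fraction` of genes. What the generator does *not* emulate —
isoforms, expression-level skew beyond length weighting, strand mixtures,
alignment artefacts — bounds what simulation-based validation can show:
passing tests demonstrate the statistics behave as designed under the
stated model, not that any particular biological dataset satisfies it.

## 3. Edit calling

`pileup_counts()` tallies A/C/G/T per position from bases with Phred
quality ≥ 20 (the field's conventional floor), excluding unmapped,
secondary and supplementary reads; SAM/BAM goes through Rsamtools, and
simulated in-memory read tables take a native path tested to agree with
it exactly. `call_edits()` reports a site when the reference base is the
channel's substrate, coverage ≥ 5, at least one read carries the edited
base, and the position is not in an optional SNV mask.

Each site's **confidence** is the posterior probability that the true
editing fraction exceeds the sequencing-error scale: with a uniform
Beta(1,1) prior and a binomial likelihood,

$$ \text{confidence} = P(\pi > e \mid k, n) =
1 - I_{e}(k + 1,\, n - k + 1), $$

with `error_rate` $e = 10^{-3}$ by default. This is a deliberately
self-contained replacement for external editing-confidence scores: the
conventional 0.9 threshold keeps its role, the score is monotone in the
edit count at fixed coverage, and every quantity in it is visible in the
output table. It does not model strand artefacts or mapping quality —
inputs here are either simulations or pre-filtered alignments.

## 4. Cluster calling

Per replicate and editing channel: confident sites (> 0.9) are assigned
to genes; every gene exhibiting at least one edit is tiled with fixed
30-bp bins from its 5' end (terminal partial bins kept); each bin's
`edited_count` (confident sites, or edited-read observations in
`count_mode = "reads"`) is tested against $\lambda = q \cdot n$, where
$n$ is the bin's count of substrate positions with coverage ≥ 5 and $q$
is the **background rate** — the unweighted mean per-bin editing
fraction. The p-value is the one-sided upper tail
$P(X \ge k),\ X \sim \text{Poisson}(\lambda)$; BH adjustment is applied
within channel; bins with $q$-value strictly below 0.1 are kept and
merged when separated by ≤ 15 bp; cluster p/q are the minima over member
bins (minimum rather than a combination rule: cluster boundaries come
from merging, and member bins are strongly dependent, so any
combination would overstate precision). Replicate cluster sets are
intersected (≥ 1 bp overlap, first replicate's coordinates kept), and
clusters replicating in the free-editor control are subtracted.

Two decisions deserve emphasis:

* **Zero-edit bins of edited genes are retained.** Restricting the
  background mean to bins that already contain an edit conditions the
  estimate on $X \ge 1$, which at realistic per-bin expectations
  ($\lambda < 1$) inflates it several-fold and destroys power — we
  measured a ~12× overestimate in simulation. "Regions exhibiting
  edits" is therefore resolved at the gene level: edited genes
  contribute all their bins, unedited genes contribute none.
* **Site counts versus read counts.** Site counting (the default) keeps
  the test's units identical to the background definition (fraction of
  editable positions edited), but saturates: a 30-bp bin holds only
  ~5–10 substrate positions, and at depth ≥ 50× even weak background
  editing eventually marks most of them, compressing rate contrasts.
  Read counting (`count_mode = "reads"`) preserves the full dynamic
  range and is the right choice for deep data or graded (free-editor)
  signals; the validation suite's planted-site power study runs in this
  mode for exactly that reason. When the background is zero but edits
  exist, $\lambda$ is floored at $10^{-6} n$ to avoid p = 0 artefacts.

## 5. Context characterisation and enzyme attribution

Flanking contexts are the single bases at site ± 1 (16 = 4 × 4 pairs;
a ±2-base window would give 256 sparsely-populated contexts, so the
16-way table is the default and edge/N sites are skipped and tallied).
PCA runs on proportion-normalised, mean-centred counts without
unit-variance scaling: the counts are compositional, and the loadings
are meant to be read directly as per-context contributions (A/U-philic
versus G/C-philic enzymes then separate on PC1 with loadings of opposite
sign for the two context classes — the structure the validation suite
asserts).

The attribution classifier is a two-layer 1-D convolutional network —
16 filters of width 8 per layer, ReLU, global max pooling, one sigmoid
unit — trained with full-batch Adam (learning rate 0.01) on binary
cross-entropy over one-hot 200-bp windows centred on cluster midpoints,
positives from one enzyme's clusters and an equal number of subsampled
negatives from the others'. Training stops once validation loss improves
by less than 1e-4 for 5 consecutive epochs (after a 20-epoch floor that
lets the loss settle), with a stratified seeded 70/15/15 split; the
reported AUC is the Mann–Whitney rank statistic on the held-out split,
which the suite checks against trapezoidal ROC integration to 1e-9. The
network is implemented in vectorised base-R matrix operations (im2col),
small enough to train in seconds on one CPU; determinism is at the level
of fixed seeds on a given platform. Filter counts, widths, optimiser and
split fractions are declared configuration, not tuned claims.

## 6. Translation (EPR)

EPR is `edit_count / read_count` per gene, for genes with ≥ 10 reads; a
read counts toward a gene when its span overlaps the gene's exons,
multi-gene reads are discarded as ambiguous, and region-restricted EPR
uses the read-midpoint rule (a read belongs to CDS or 3'UTR by where its
midpoint falls, avoiding double counting at the junction). Fold changes
are Welch two-sided t-tests on replicate EPRs per gene (no named
per-gene test is available to follow, and the figure-level convention in
this literature is a two-sided t-test), BH-corrected, with
$\log_2$ fold changes offset by $\varepsilon = 10^{-6}$ so
zero-EPR genes stay finite; genes must be quantifiable in every
replicate of both conditions. The TOP contrast is a Welch test of group
versus complement log2 fold changes, reported with a decrease-oriented
sign (`t_decrease` > 0 when the group drops more). The generator's
treated condition reduces TOP-gene ribosome load 4-fold and other genes
1.25-fold; `epr_scale` defaults to 0.005 per substrate base per unit
load, putting control EPR near 0.1, and `cds_bias = 3` weights CDS
positions over 3'UTR, so the CDS/3'UTR ratio of means has a known
target in simulation.

## 7. Interval permutation tests

Enrichment of clusters in a reference peak set is tested by re-placing
each query interval, length-preserved, uniformly over all admissible
positions in a placement domain — by default the transcribed regions of
the annotation, since that is where clusters can occur at all; a
whole-genome domain is a caller choice. A domain region is selected with
probability proportional to its number of fitting start positions, the
empirical p-value uses the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\}) / (1 + N)$ so p is never zero,
and enrichment is observed over null mean. Overlap is ≥ 1 bp and
strand-aware when both sets carry strands. Because the overlap fraction
of $m$ query intervals is discrete on a $1/m$ grid, the null p-value
distribution is exactly uniform only in the large-$m$ limit; the
calibration scenario uses 150 query intervals so the Kolmogorov–Smirnov
diagnostic is meaningful.

## 8. Validation scenarios and their sizes

The test suite and `scripts/acceptance.R` run the same documented
scenarios (`?scenarios`), chosen to finish in minutes on one CPU while
leaving clear margins: edit-caller fidelity on a 20-gene transcriptome
at 50× depth with sequencing error off; cluster calibration on 30
background-only genes (three replicates, ~3,000 bins) and power on 100
simulations of a site edited at 20× a 0.005 background at 50× depth;
context/classifier studies on 120 genes at 40× with two free editors of
opposite 100:1 context preference, three replicates each; translation
contrasts on 200 genes at 30× with 3 + 3 replicates (null calibration
on 120); permutation calibration with 100 trials of 200 permutations.
The suite states what it can: that each statistical guarantee (no false
positives without error, calibrated type-I error, near-certain detection
of strong planted signal, recoverable context structure, a well-behaved
null) holds under the generator's model at those sizes.

## 9. Known limitations

* Transcript-space only: one exon per transcript, no splice junctions or
  isoform ambiguity; cluster bins do not split across junctions.
* The confidence score ignores mapping quality and strand artefacts.
* Poisson bin tests assume independent edits; read-count mode is
  overdispersed when single reads carry several edits, making its
  p-values anticonservative in absolute terms (ranking and FDR control
  across bins remain serviceable, and the site-count default avoids the
  issue).
* CNN determinism is seed-level, not bit-level across BLAS builds.
* The permutation null preserves interval lengths but not composition;
  GC- or coverage-matched nulls are out of scope.
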