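---
title: "A cross-attention multiple-instance model of HLA class II peptide presentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cross-attention multiple-instance model of HLA class II peptide presentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

HLA class II molecules (DR, DP and DQ heterodimers of an alpha and a
beta chain) present peptides of 8–26 residues to CD4+ T cells. Mass
spectrometry of eluted ligands tells us which peptides *were*
presented, but (i) it gives no negatives, (ii) most samples are
polyallelic — any of up to 14 alleles may explain each peptide — and
(iii) the 9-residue binding core inside each peptide is unobserved.
`hla2present` models all three ambiguities at once: negatives are
synthesised as length-matched proteome decoys, and both the
peptide→allele assignment and the core location are treated as latent
through multiple-instance learning (MIL) with maximum aggregation.

## The model

For a peptide of length $L$ the model enumerates all $M = L - 8$
contiguous 9mer windows — the candidate binding cores. Each allele is
represented by its 34-residue pseudo-sequence: the 15 alpha-chain plus
19 beta-chain residues lining the binding groove.

Three encoder stacks process these inputs:

1. **Peptide encoder** — learned residue embeddings plus learned
   positional embeddings, then $T$ transformer encoder blocks
   (multi-head self-attention, residual + layer norm, position-wise
   feed-forward with ReLU, residual + layer norm). Padding positions
   (peptides are padded to 30) are masked out of every attention step,
   so scores are invariant to the pad length. The 9mer windows are cut
   from the *encoded* peptide, so each window representation carries
   full-peptide context.
2. **Allele encoder** — the same architecture over the 34
   pseudo-sequence positions.
3. **Interaction encoder** — a stack of cross-attention blocks in
   which the 9 window positions are queries and the 34 encoded allele
   positions provide keys and values, each block followed by a
   position-wise feed-forward and layer normalisation, mirroring a
   standard encoder block.

The final block's output for a window–allele pair is flattened to
$9 \times d$ features (1152 at the default $d = 128$), passed through
dropout and a single sigmoid output node, giving a presentation
likelihood $s_{am} \in (0, 1)$ per pair. The sample-level score is

$$s = \max_{a \le N,\; m \le M} s_{am},$$

the MIL step: a presented peptide needs only one explaining
window–allele pair, and the argmax pair names the predicted binding
core and allele. Because the sigmoid is monotone, the max over pair
scores equals the sigmoid of the max over pair logits, and training
gradients flow only through the argmax pair.

Default configuration (all tunable via `hla2_config()`): 8 blocks and
8 heads in every stack, latent width 128 everywhere including
embeddings, dropout 0.1 in embedding, attention-residual,
feed-forward-residual layers and before the output head, peptides
padded to 30 residues, at most 14 alleles per sample.

### Design choices the architecture leaves open

* **Positional information.** Self-attention is permutation-invariant
  without it, yet core registers and groove positions are inherently
  positional, so both encoders add *learned* positional embeddings;
  `positional = FALSE` removes them for ablations.
* **Embedding tables.** The peptide and allele encoders keep separate
  residue embedding tables by default (`share_embedding` switches).
* **Interaction head depth.** The post-attention "stack of linear
  layers and layer normalisation" is realised as one position-wise
  feed-forward (d→d, ReLU) plus layer norm per cross-attention block;
  `n_int_blocks` sets the depth.
* **Argmax ties** break to the smallest allele index under canonical
  (sorted) allele-name order, then the smallest window offset, so
  reported cores are reproducible under allele permutation.
* **Unknown residues** (B, J, O, U, X, Z) map to a dedicated unknown
  token with a warning; padding has its own token.

## Training protocol

Training minimises weighted binary cross-entropy
$\sum_i w_i\,\mathrm{BCE}(s_i, y_i) / \sum_i w_i$ with AdamW
(`weight_decay` 0.01), gradient clipping at global norm 1.0, and batch
size 200.

* **Decoys.** Every epoch draws one fresh decoy per presented peptide
  from the background proteome, exactly length-matched, inheriting the
  positive's sample and loss weight, so classes stay balanced and the
  natural decision cutoff is 0.5. Scenario 1 draws freely; scenario 2
  additionally rejects candidates sharing any 9mer with *any*
  presented peptide (screening is global, not per-sample, since decoy
  leakage is a corpus-level concern). The two scenarios yield two
  models whose per-pair score matrices are averaged at prediction
  before the max — max-of-mean keeps a single consistent argmax core;
  mean-of-max is available via `aggregate = "mean_of_max"`.
* **Cluster weights.** Eluted-ligand corpora are dominated by
  near-duplicate peptides. Peptides are clustered at 0.8 ungapped
  identity (greedy star clustering by decreasing length; an MMseqs2
  `easy-cluster` TSV can be imported instead) and each record is
  weighted by the inverse of its cluster's total record count, so
  every cluster contributes unit weight. The weighted loss is exactly
  invariant to replicating a record $k$ times at weight $w/k$.
* **Allele dropout.** In polyallelic samples, each step masks
  $\lfloor N/2 \rfloor$ alleles' score rows out of the max (the
  wording "half of the alleles" is interpreted as a floor rather than
  per-allele Bernoulli draws, which keeps monoallelic samples
  untouched and the masked count deterministic). Masking acts on the
  aggregation, not on the encoder input.
* **Schedule.** Learning rate decays by 0.7 when validation loss
  plateaus, a plateau being two consecutive epochs without an
  improvement greater than 1e-4; training stops once validation has
  not improved for 5 epochs *and* at least 2 decays have occurred. The
  best-validation checkpoint is kept. Validation decoys are drawn once
  (epoch 0 of the decoy stream) and held fixed so the early-stopping
  signal is not re-randomised every epoch.
* **Determinism.** Three named RNG streams (init, decoys,
  dropout/shuffle) derive from the single `seed` argument and are
  recorded in the checkpoint; two runs from the same seed produce
  identical logs and parameters.
* **Learning rate.** The published schedule's 1e-5 suits a ~600k
  peptide corpus; on the compact synthetic studies below we use 1e-3,
  chosen once as appropriate for a 2-block, 32-dimensional model on a
  few thousand examples.

Peptides of 8 residues occur in eluted-ligand data but have no 9mer
window; rather than fabricate a padded core we exclude them (the
`filter_length()` lower bound is 9) and say so.

## The synthetic world

`generate_world()` plants a 9-position probability matrix per
synthetic allele: anchor rows (default positions 1, 4, 6, 9, the
classic DR registers) concentrate mass on 1–3 preferred residues with
peakedness `concentration` (row $\propto$ background ·
concentration^u, u halving across preferred residues — background at
concentration 1, one-hot in the limit); non-anchor rows get mild
concentration-scaled jitter. Positives embed a motif-sampled core in
background flanks at a uniform offset; lengths follow a unimodal 9–26
distribution peaked near 15, as in eluted-ligand data. Samples hold
1–14 alleles; ground truth (core offset, source allele) is retained.
The default `concentration = 100` puts roughly 0.77 of anchor mass on
the top residue — strong but not degenerate anchors, in the range of
real DR anchor preferences.

For weighting studies, `dominant_frac` routes that fraction of
positives through near-duplicates (at most one substitution) of a few
template peptides carrying the first allele's motif, reproducing the
skewed cluster-size distributions of real corpora where most peptides
sit in large similarity clusters.

The generator's `oracle_scorer()` is the Bayes-optimal
log-likelihood-ratio scorer (max over windows and alleles, sigmoid
squashed so 0.5 sits at even odds): the ceiling against which trained
models are judged, and a deterministic stand-in scorer for screening
fixtures.

What the generator does **not** emulate: mass-spectrometry
detectability bias, cleavage signatures, shared cores presented by
multiple alleles, and real pseudo-sequence similarity structure
(synthetic alleles get random 34mers). Passing the synthetic studies
therefore demonstrates that the architecture and training loop can
deconvolve planted polyallelic motifs and localise cores — not that
any particular accuracy transfers to real immunopeptidomes.

## Reference studies and problem sizes

`recovery_benchmark()` trains the compact configuration (2 blocks, 2
heads, width 32) on a 5-allele monoallelic world of 2,000 positives
(8:1:1 split by shared-9mer components, 8 epochs) and evaluates
held-out ROC-AUC, F1 and core-offset accuracy against the oracle
ceiling and an untrained floor. `weighting_ablation()` trains the same
model with and without cluster weights on an 80%-dominant world of
1,000 positives and compares held-out AUC between large-cluster and
small-cluster bins; weighting shrinks the spread. These sizes were
chosen once as the smallest worlds on which the planted signal is
cleanly recoverable; the test suite runs both studies over three
seeds.

## Screening and downstream analyses

* **Epitopes** are unique non-germline predicted cores: chains are
  windowed at sizes 9 and 12–19, each window scored against the panel
  (default: the nine common DR alleles, all sharing the invariant DRA1
  alpha chain), windows at or above 0.5 keep their predicted core, and
  cores found verbatim in the germline database are dropped. Germline
  membership is tested at the 9mer-substring level against whole
  germline sequences, which conservatively covers junction-spanning
  cores. Per-residue hotspots take the maximum score over covering
  cores; observed (MAPPs) peptides are aligned by exact substring
  match, every occurrence counting, and coverage is normalised by its
  maximum.
* **Thresholds.** "Above 0.5" is implemented inclusively (≥ 0.5), and
  neoantigen tiers are [0.5, 0.95) low-likelihood and [0.95, 1]
  high-likelihood, boundaries inclusive at the lower edge; tier
  boundaries are configurable since figure captions and text differ on
  0.9 versus 0.95.
* **Cutoff calibration** (`loo_cutoff()`) is leave-one-out: per fold
  the epitope-count cutoff maximising Youden's J on the discovery set
  (smallest count on ties), the overall cutoff being the fold mean and
  F1 coming from the pooled held-out calls. Epitope counts are totalled
  across heavy and light chains, with per-chain counts also reported.
* **Entropy** of binding cores is reported in bits (base 2, the usual
  convention for sequence logos; configurable).
* **Contacts** use minimum heavy-atom distance strictly below 5 Å
  (hydrogens are absent from most crystal structures). Attention–
  contact agreement marks each core position's top-3 attended pseudo
  positions per layer/head (a global top-k mode exists; the exact
  aggregation behind the published figure is not specified, so neither
  mode claims to replicate it) and reports the recovered fraction of
  contacts restricted to pseudo positions — contacts elsewhere are
  invisible to the model and excluded from the denominator, giving NA
  when none remain.

## Numerical notes and limitations

* Layer norm uses eps 1e-5; softmax subtracts row maxima; BCE clamps
  scores at 1e-12. Dropout is inverted (scaling at train time) and
  wholly disabled in evaluation, including allele dropout.
* Gradient correctness of the hand-derived backward pass is enforced
  by finite-difference checks in the test suite.
* The greedy clusterer is O(n · representatives); for very large
  corpora import an external clustering instead.
* The shipped groove-position table follows the NetMHCIIpan-3.0
  residue selection and is editable data; every pseudo-sequence-derived
  result is conditional on it. Synthetic studies bypass it entirely.
* The package does not fetch sequences from IMGT or other databases;
  chains, germlines and proteomes are consumed as FASTA. Full-scale
  training on real corpora is computationally out of reach of a pure-R
  implementation and is not attempted here.
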