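---
title: "Federated batch-effect correction: model, protocols, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated batch-effect correction: model, protocols, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedscbatch)
```

## The model

`fedscbatch` removes batch effects from single-cell RNA-seq data by latent
space arithmetic on a variational autoencoder, trained either centrally or
across clients that each hold one batch and never share raw data.

The VAE is a fully connected encoder/decoder pair. The encoder maps a
log-normalized expression profile $x \in \mathbb{R}^d$ through ReLU hidden
layers to a posterior mean $\mu(x)$ and log-variance $\log\sigma^2(x)$ over
a $k$-dimensional latent variable; the decoder mirrors the encoder in
reverse with a linear output layer. Training samples
$z = \mu + \sigma \odot \varepsilon$ (the reparameterization trick) and
minimizes

$$\mathcal{L} \;=\; \underbrace{\tfrac{1}{md}\sum_{i,j}(x_{ij}-\hat x_{ij})^2}_{\text{reconstruction (MSE)}}
\;+\; \alpha \,\underbrace{\tfrac{1}{m}\sum_i \tfrac12\sum_{l}\bigl(e^{s_{il}} + \mu_{il}^2 - 1 - s_{il}\bigr)}_{\text{KL to } \mathcal N(0, I)},$$

with $s = \log\sigma^2$. The networks, backpropagation, Adam, dropout and
batch normalization (in the downstream classifier) are implemented directly
in R matrix algebra; gradients are verified against numerical
differentiation in the test suite.

**Correction.** After training, cells are encoded *deterministically*
($z = \mu(x)$; no sampling). A cell type is *shared* if it occurs in at
least two batches, *standalone* otherwise. For each shared type $t$ the
*dominant batch* $b^* = \arg\max_b N_b^t$ supplies a reference mean latent
vector $M^t$, and each cell $i$ of type $t$ in batch $b$ is shifted by the
type- and batch-specific delta vector

$$z_i' = z_i + \bigl(M^t - \bar z^{t,b}\bigr),$$

where $\bar z^{t,b}$ is the centroid of batch $b$'s own type-$t$ cells.
This moves every batch's type centroid exactly onto the dominant batch's —
the defining fixed point of the method: after one application the per-batch
centroids of every shared type coincide, and a second application is a
no-op. Standalone types are never shifted, since no cross-batch reference
exists for them. Corrected expression is the decoder image of the shifted
latents, clipped at zero.

A widely circulated shorthand writes the correction as
$Z^t_{\mathrm{corrected}} \leftarrow Z^t - M^t$, i.e. subtracting the
dominant mean from all cells of the type. Read literally that centers every
type at the origin rather than aligning batches, and destroys the
between-type geometry the metrics reward. We implement the delta-shift form
above as the default because only it removes batch effects while preserving
type separation; `correct_latent(..., literal_subtraction = TRUE)` provides
the verbatim reading for comparison.

## Federated protocols

**Training (FedAvg).** All clients start from identical initial parameters
(seeded initialization). Each communication round $r$, client $c$ trains
locally for $e$ epochs and uploads $\theta_c$ and its cell count $N_c$; the
coordinator forms $\theta_{r+1} = \sum_c (N_c/\sum N)\,\theta_c$ and
broadcasts. Two design choices matter for testability:

* *Local optimizer state persists across rounds.* Only parameters are
  averaged; each client keeps its own Adam moments. With a single client
  the average is the identity, so federated training with $R$ rounds of $e$
  epochs is **bitwise identical** to uninterrupted local training for
  $R\cdot e$ epochs — the strongest possible correctness oracle for the
  orchestration, and a legitimate cross-silo choice (clients are stateful
  silos, not ephemeral devices).
* *Deterministic seed streams.* The epoch seed is
  `mix_seed(client_seed, global_epoch_index)` with the epoch index running
  across rounds, so minibatch order, dropout masks and reparameterization
  noise replay exactly between the segmented (federated) and uninterrupted
  (centralized) runs.

**Correction.** Three steps per shared type: (1) the dominant client is
identified from per-client counts; (2) it encodes its own type-$t$ cells
and broadcasts their latent mean $M^t$ (an aggregate over at least one full
batch of cells — no per-cell data leaves the site); (3) every client
applies the delta shift locally and decodes. Held-out clients that never
trained may join step 1–3; the model is never fine-tuned on them. A
`public_means` artifact (model digest + per-type means, nothing per-cell)
lets a new site correct entirely offline when dominance is unaffected.

**Secure aggregation.** With `secure = TRUE`, uploads are additive secret
shares over the ring $\mathbb{Z}_{2^{64}}$ with 16 fractional fixed-point
bits: all but one share are uniform ring elements, so any proper subset is
independent of the plaintext. Clients share $N_c\,\theta_c$ and $N_c$;
three computational parties add shares element-wise; the coordinator
reconstructs only the two share-sums and divides. The fixed-point encode
error is $\le 2^{-16}$ per element, and the end-to-end divergence between
secure and plaintext training after 8 rounds is below $10^{-6}$ in
practice (asserted at $10^{-3}$ in tests). Dominant-batch detection shares
the counts and reveals only the *signs* of pairwise share-space
differences; this leaks the pairwise ordering of clients for that type to
the aggregator — more than the bare argmax identity, but never a count —
which we document as the protocol's known disclosure. Ties go to the
smallest client id everywhere, so the secure and plaintext paths agree
exactly. The ring arithmetic is in C++ (`src/`), since R has no native
64-bit integers.

## Preprocessing

The standard pipeline, in fixed order with layer-state guards: cells with
fewer than 200 expressed genes (strictly positive entries; exactly 200 is
kept) are dropped; cells are scaled to a common total of 10,000 counts;
highly variable genes are kept when the mean lies strictly inside
$(0.0125, 2.5)$ and the normalized dispersion (variance/mean, z-scored
within 20 equal-frequency mean bins — the Seurat-flavor definition whose
default thresholds these are) exceeds 0.7; finally $x \mapsto
\min(\log(1+x), 10)$. HVG selection is global rather than per-batch.

Three cell-type inclusion scenarios mirror common practice: *All* keeps
everything; *Combined* relabels minority types (global count below 10 by
default — the threshold is configurable since conventions differ) and
standalone types to `"others"` without changing cell counts; *Dropped*
removes their cells, shrinking batches.

## The synthetic generator

Since the package must be exercisable without external downloads, the test
substrate is generated: counts are negative binomial with mean =
(cell-type program) × (gene-wise batch factor) × (library size), then
zeroed with a constant dropout probability. Choices, made once:

* Gene baselines are log-normal with `sdlog = 1.5` over a 1,200-gene
  panel, reproducing the heavy-tailed abundance profile of real data —
  necessary for the preprocessing thresholds above to carve out a sensible
  HVG set (~100–150 genes) while all cells clear the 200-gene floor.
* Cell-type programs shift a random 20% of genes by ±4-fold; batch effects
  are gene-wise multiplicative log-normal factors, `sigma_batch = 1`
  meaning "strong" (raw-data kBET acceptance ≈ 0) and `0.8` "moderate".
  Multiplicative-in-counts is additive in log space, the structure a
  latent shift can capture — matching the method's own assumption, which
  is precisely what a recovery experiment should grant.
* NB dispersions are log-uniform on $[0.1, 1]$; library sizes log-normal
  with `sdlog = 0.3`; dropout 0.1.

What the generator does *not* emulate: platform-specific chemistry,
continuous trajectories, ambient RNA, doublets, batch effects that differ
per cell type. Passing recovery tests therefore shows the stack corrects
the class of batch effects the model assumes, at desk scale — not that it
matches benchmark numbers on real atlases.

The presets encode the study designs used throughout: `two_batch_shared`
(1,000 cells, 4 shared types, strong effect), `five_batch_hp_like`
(5 batches whose shared types have different dominant batches),
`standalone_type`, `minority_types`, and `held_out` (a third batch that
dominates one type and joins only at correction).

## Evaluation suite

All metrics run on a 20-PC centered embedding (deterministic sign
convention) of whichever matrix is being judged — decoded corrected
expression by default, corrected latents optionally.

* **kBET acceptance**: per cell, a Pearson $\chi^2$ test of the k-NN batch
  composition against global proportions at $\alpha = 0.05$; acceptance =
  fraction of cells not rejected; median over neighborhood sizes 5–25% of
  $n$ (a single small fraction can be passed for very large data). The
  original package's $k_0$ heuristics and subsampling are deliberately not
  replicated; the explicit-χ² variant is what the neighborhood sizes above
  define.
* **iLISI / cLISI**: inverse Simpson's index of batch (resp. type) labels
  under perplexity-calibrated Gaussian neighbor weights (perplexity 30);
  iLISI restricted to cells of shared types. These two are reported on
  their native $[1, \#\text{labels}]$ scale.
* **ASW_C** $= (\bar s + 1)/2$ with type-label silhouettes; **ASW_B** is
  cell-type-stratified and reversed, $\mathrm{mean}_t\,
  \mathrm{mean}_i(1 - |s_i|)$ with batch-label silhouettes within each
  type spanning ≥ 2 batches. Both conventions are reported side by side in
  the sense that `asw_cell`/`asw_batch` expose the mapped values while raw
  silhouettes are available from `cluster::silhouette` directly.
* **ARI** between Louvain clusters (15-NN graph, resolution 1) and type
  labels; **NMI** (arithmetic normalization) maximized over resolutions
  0.1–2.0 in steps of 0.1; **ILF1**: best-cluster F1 (harmonic mean of
  precision and recall) for isolated labels (types in the fewest batches;
  none when all types span the same batches), scanned over the same grid;
  **EBM**: Shannon entropy of 15-NN batch labels over 50 pools of 100
  sampled cells, normalized by $\log(\#\text{batches})$ (the base cancels);
  **GC**: per-type largest-connected-component fraction of the type's own
  15-NN graph; **kNN accuracy**: per-cell neighbor label agreement,
  macro-averaged over types.
* **Comparison harness**: per (metric, dataset) pair a two-sided
  Wilcoxon–Mann–Whitney test over per-seed values, one joint BH correction
  across all pairs, significance at adjusted $p < 0.05$; the performance
  difference $\Delta_m$ is simply federated minus centralized, in
  $[-1, 1]$ for unit-interval metrics.

## Numerical and degenerate-input choices

Zero-sum cells survive normalization as zeros. Ties in dominant-batch
detection go to the lexicographically smallest batch (centralized) or
smallest client id (federated) — consistent because clients are ordered by
batch label. kBET with a single batch returns 1; EBM with a single batch
returns 0 with a warning; neighborhood sizes smaller than the number of
batches are skipped with a warning. LISI reduces the perplexity when a
dataset is too small. PCA keeps fewer components with a warning when rank
runs out. Decoded expression is clipped at zero. `correct_latent` raises a
contract error when a type spanning two batches has no mean-map entry. The
KL term is exactly zero at $\mu = 0, \log\sigma^2 = 0$ and verified
non-negative over random grids.

## Problem sizes and defaults

Desk-scale experiments use the 1,000-cell two-batch preset, a narrow VAE
(`hidden_dims = c(64, 64)`, latent 10) and a total budget of 100 training
epochs — the same epoch budget the centralized reference configuration
uses; at 2 local epochs per round that is 50 communication rounds. Shorter
federated runs (8 rounds × 2 epochs) already mix batches well but leave
the autoencoder blurrier, which costs cell-type purity (cLISI); the
100-epoch budget preserves it. The published architecture
(`hidden_dims = c(800, 800)`) is the default of `vae_config()` and is what
real-data runs should use. `kl_weight` defaults to 0.005: large enough to
regularize the posterior, small enough that reconstruction dominates — the
weighting factor is a free parameter here, and the correction depends only
on encoder geometry, not on a calibrated ELBO. Early-stopping defaults
(patience 20, `min_delta` 0, validation fraction 0.1) implement the usual
plateau rule; the mechanism is available but not used inside federated
rounds.

## Known limitations

The simulated secret sharing runs in-process: it demonstrates and tests the
*protocol arithmetic* (share algebra, fixed-point error, what each role can
see, via inspectable transcripts), not network security; there is no
malicious-adversary protection and no share-space multiplication. The
secure-max protocol reveals the pairwise client ordering per type, as noted
above. Correction assumes batch effects are expressible as latent
translations per (type, batch); effects that rotate or rescale local
structure, or types mislabeled across batches, violate that assumption.
Standalone types pass through uncorrected by design. The downstream
classifier treats test-fold cells of types unseen in training as errors,
which is conservative.
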