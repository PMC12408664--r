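---
title: "Transferring bulk drug-response knowledge to single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring bulk drug-response knowledge to single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-response labels are abundant for bulk cancer cell lines (databases
such as GDSC and CCLE annotate thousands of line x drug pairs as sensitive
or resistant), but almost never available per cell. Single-cell RNA-seq,
on the other hand, is what reveals the heterogeneity that decides whether
a tumour subpopulation survives treatment. `scdrp` bridges the two: it
pre-trains a drug-sensitivity predictor on labelled bulk expression and
transfers it to unlabelled single-cell profiles, scoring every cell with a
probability of being drug-sensitive.

## The model

Three trainable parts per domain pair:

* **Denoising autoencoders.** The bulk matrix $X_g$ (samples x genes) is
  corrupted by binomial masking — each entry is zeroed with probability
  equal to the configured noise rate — and an encoder $E_g$ / decoder
  $D_g$ pair (ReLU hidden layers, linear bottleneck and output) is trained
  to minimize the mean squared error between the clean input and the
  reconstruction of the corrupted input. A second autoencoder
  ($E_t$, $D_t$) does the same for the single-cell matrix $X_t$.
* **Attention predictor.** Each bottleneck vector is reshaped into
  `n_tokens` tokens of width `token_dim`; multi-head scaled dot-product
  attention ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ per head,
  concatenated and projected) mixes the tokens; the flattened result feeds
  a ReLU MLP with a single sigmoid output, the sensitivity probability.
  There is no positional encoding — latent coordinates are unordered, and
  the block is permutation-equivariant in the tokens. With zero heads the
  predictor is a plain MLP, the reference arm of the head-count sweep.
* **Joint objective.** After pre-training, the two encoders and the
  predictor minimize
  $\mathcal{L} = \mathcal{L}_{\text{class}} + \omega\,\mathrm{MMD}^2(E_g(X_g), E_t(X_t)) + \theta\,R$,
  where $\mathcal{L}_{\text{class}}$ is the binary cross-entropy on bulk
  labels, the squared maximum mean discrepancy (biased V-statistic,
  multi-scale Gaussian kernel at bandwidths = median pairwise distance
  $\times\{0.25, 0.5, 1, 2, 4\}$) aligns the two latent distributions, and
  $R$ is a cluster-coherence penalty: the mean over cells of one minus the
  cosine similarity between a cell's embedding and the centroid of its
  Louvain cluster. Louvain communities are detected once, on a
  k-nearest-neighbour graph of the single-cell latents after the
  single-cell autoencoder stage, and held fixed; recomputing them every
  epoch would make the objective non-stationary and the run
  non-reproducible. Decoders are frozen during the joint phase — the
  objective is minimized over $E_g$, $E_t$ and the predictor only.

Scores in $[0,1]$ are used directly by the threshold-free metrics (AUC,
average precision); the 0.5 binarization (ties to *sensitive*, taking the
closed upper interval) exists only for downstream interpretation.

## Design choices that were genuinely open

* **Noise semantics.** The corruption rate is the probability of *zeroing*
  an entry. The alternative reading (probability of keeping) is the
  mirror image; one had to be pinned, and zeroing matches how masking
  noise is used in denoising autoencoders generally.
* **Predictor input.** The predictor is trained on the encoder's *noisy*
  pass: embeddings are recomputed each epoch from a freshly corrupted
  input. Besides matching the training-time composition
  $P(E_g(X'_g))$, this is a strong regularizer — the decision boundary
  is learned under the same kind of corruption that single-cell dropout
  later inflicts, which measurably improves transfer.
* **Warm start of the single-cell autoencoder.** By default $E_t, D_t$
  are initialized from the trained $E_g, D_g$ rather than independently.
  The MMD term matches *distributions*; it is blind to a rotation of the
  latent space, so two independently initialized encoders can agree
  distributionally while disagreeing semantically, and the transferred
  decision boundary is then arbitrary. Anchoring both encoders in one
  coordinate frame removes that degeneracy; the single-cell denoising fit
  and the joint phase then only refine it. Set `warm_start_sc = FALSE`
  for fully independent training.
* **Gentle refinement.** The single-cell autoencoder stage and joint
  phase default (in the examples and study runs) to few epochs at a small
  learning rate. Aggressive refinement lets the reconstruction objective
  rotate the single-cell latents away from the shared frame faster than
  MMD can pull them back — measurably degrading transfer.
* **Per-gene standardization.** `fit_transfer(scale_genes = "zscore")`
  standardizes each gene within its domain before the autoencoders, the
  usual practice before deep models of expression. It removes the
  per-gene affine component of the bulk/single-cell gap; the parameters
  are stored in the bundle and re-applied at prediction and attribution
  time. `"center"` and `"none"` are available. One consequence worth
  spelling out: standardization already closes affine domain gaps, so an
  ablation meant to isolate the MMD term (alignment on vs off under a
  planted shift) must run with `scale_genes = "none"` — otherwise the
  gap never reaches the latent space and the comparison measures noise.
  The MMD term earns its keep on whatever gap survives preprocessing.
* **Tokenization.** A per-sample latent vector has no token structure;
  reshaping the bottleneck into `n_tokens` x `token_dim` (default 8
  tokens at bulk scale) preserves all information, keeps attention
  non-degenerate, and makes the zero-head arm comparable. Head counts
  must divide the token width (`d_k = token_dim / n_heads`); invalid
  counts are rejected at configuration time and skipped with a warning in
  sweeps.
* **Cluster regularizer reading.** The published form of the cluster term
  is not computable as written (a cosine between a cluster id and a
  matrix); we implement the evident intent — keep predicted cell clusters
  coherent in latent space — as mean (1 - cosine(cell, cluster
  centroid)), which lies in [0, 2], is scale-invariant, and is zero for
  perfectly coherent clusters. Gradients treat the centroids as
  constants, recomputed from the current batch each step.
* **DEG procedure.** Two-sided Wilcoxon rank-sum per gene with
  Benjamini-Hochberg adjustment, ranked by adjusted p then absolute
  log-fold-change, 0.25 minimum effect — the standard scRNA-seq recipe;
  the method itself does not prescribe one.
* **Integrated gradients.** The default baseline is the origin of the
  space the model consumes: zero expression when genes are not
  standardized, the per-gene average profile (an "average cell") when
  they are. An explicit baseline can be given in raw expression units.
  The path integral uses the midpoint Riemann rule starting at 50 steps
  with per-cell adaptive refinement: any cell whose attributions do not
  sum to $F(x) - F(\text{baseline})$ within 1% + 1e-4 is re-integrated at
  doubled step counts (the integrand is piecewise smooth because of ReLU
  kinks, so refinement is the standard remedy). The per-cell residuals
  and step counts are stored in the result.
* **Null test estimator.** The random-gene-set test uses the add-one
  permutation estimator $p = (1 + \#\{r_{\text{null}} \ge r\})/(1 + n)$,
  so p-values are valid and never exactly zero, and $p < 0.001$ is
  attainable with 1,000 trials.

## Preprocessing contract

Single-cell counts go through droplet QC in a fixed order — cells with
fewer than 200 detected genes, then genes detected in fewer than 3 cells,
then cells above 10% mitochondrial counts (all strict inequalities,
mitochondrial genes recognized by a configurable id prefix, `MT-` by
default) — followed by per-cell scaling to 10,000 counts and `log1p`. The
order matters for the marginal counts, so it is fixed and recorded in the
QC report. Class balancing (SMOTE interpolation or duplication
oversampling, seeded) applies to bulk *training* data only; single-cell
data and test splits are never resampled. Bulk expression is consumed on
whatever log-like scale it arrives; the layer tag records it.

## The synthetic study

`simulate_paired()` generates what the method assumes: two domains
sharing a linear-Gaussian latent model. One latent axis is the
sensitivity axis; the binary label is its sign relative to an empirical
quantile threshold (so class shares hit the configured imbalance), with a
small annotation noise (sd 0.1) that flips only borderline cells — labels
are essentially pinned to the factor. Marker genes (10 per class by
default) load only on that axis at magnitude `effect_size`; the other
genes load on nuisance factors, so `effect_size = 0` removes every trace
of label signal from expression. Single-cell profiles additionally get a
per-gene affine distortion (scaled by `domain_shift`), Bernoulli dropout
(rate 0.3) and Poisson count noise — the minimal gap the MMD term can
demonstrably close, plus the sparsity the QC/normalization stages need.

It does **not** emulate realistic library-size distributions, batch
effects beyond the single planted shift, doublets, or non-linear
gene-gene dependencies. Passing the recovery tests therefore shows the
machinery is sound under the model's own assumptions — not that any
particular real dataset will reach the same accuracy.

Study-scale runs in the tests and the acceptance script use 300 genes,
400 bulk samples, 400 cells, effect size 3, and a compact network
(128-wide encoder, bottleneck 16 = 4 tokens x 4, two heads, 32-wide MLP;
150 autoencoder epochs, 300 predictor epochs, 5 single-cell refinement
epochs at learning rate 1e-4, 100 joint epochs at 1e-4, batch 256).
These sizes were chosen so a full five-seed study trains in minutes on
one CPU while leaving a clear margin between signal and noise; the
bulk-scale defaults in `default_config()` (bottleneck 512, encoder
256/128, predictor 128/64, dropout 0.3, 500 epochs) are what one would
use on real data.

## Numerical notes

* All randomness flows through explicit integer seeds; a master seed
  fans out to per-stage seeds (`stage_seed()`), so every stage and the
  whole pipeline reproduce bit-for-bit, and a run can be replayed from
  its manifest alone.
* Cross-entropy scores are clipped to `[1e-7, 1 - 1e-7]`; attention
  softmaxes subtract the row maximum; MMD distances are floored at zero
  before the kernel; zero-norm embeddings score cosine 0 with a warning;
  zero-variance genes z-score to 0 with a warning.
* AUC uses midranks (ties count one half); average precision groups tied
  scores at a single threshold, matching the step-sum definition.
* Adam is the optimizer throughout (lr defaults 1e-3, pretraining; 1e-4,
  refinement), with He initialization for ReLU layers.

## Known limitations

* The joint phase draws independent same-size mini-batches from the two
  domains; no pairing or class-conditional matching is attempted, so MMD
  aligns marginal latent distributions only. With strongly mismatched
  class proportions between domains this can misplace mass; balancing
  the bulk training data mitigates but does not remove this.
* H5AD containers are not read directly (no HDF5 bindings in the R
  dependency set); export to MTX/CSV first.
* Pseudotime and UMAP are deliberately out of scope; the package exports
  scores and labels in plain tables that those tools ingest.
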