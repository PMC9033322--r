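# icafeat

Feature extraction and two-class emotion classification for multichannel
EEG, built around fixed-point independent component analysis (ICA) and an
entropy feature family, validated entirely on synthetic signals with ground
truth.

EEG electrodes record linear mixtures of underlying sources, so features
computed per channel blend the rhythm of interest with everything else —
including high-power artifacts. `icafeat` implements the full pipeline:

* **ICA core** — PCA whitening ($V = D^{-1/2}E^\top$ after centring) and
  the fixed-point negentropy iteration with the logcosh contrast:
  $w^{+} = \mathrm{E}[z\,\tanh(a_1 w^\top z)] -
  \mathrm{E}[a_1(1-\tanh^2(a_1 w^\top z))]\,w$, renormalised each step,
  with Gram–Schmidt deflation (or symmetric orthogonalisation) to a full
  orthonormal unmixing matrix. Scale/permutation-invariant evaluation via
  best-match $|r|$ and the Amari index.
* **Epoching** — trial timing rules (63-s trials, last 40 s analysed, 5-s
  non-overlapping windows by default), half-open windows, 0-based samples.
* **Features** — per-window periodogram band energies over a configurable
  rhythm scheme (delta through gamma with a three-way beta split), averaged
  across windows; sample entropy, approximate entropy and composite
  multiscale entropy (Richman–Moorman / Pincus / composite coarse-graining
  definitions; C++ kernels) per channel segment.
* **Synthetic data** — a mixed-sources benchmark with ground truth, and a
  two-class (calm vs. pressure) EEG generator: bursty band-limited latent
  components, per-dataset spatial mixing, pink background, optional
  spatially low-rank artifact, and valence/arousal ratings from truncated
  normals.
* **Classification** — ratings-to-labels box rule, stratified k-fold
  linear SVM ($C = 1$, per-fold standardisation), per-channel evaluation,
  and seed-matched fold-paired comparison of ICA-component vs. raw-channel
  features.

Everything is tibble-first: feature tables, per-unit accuracies and
comparisons are tibbles; fitted objects have `tidy()`/`glance()` methods
and results have `autoplot()` methods.

## Worked example

Recover three mixed sources (8 Hz sine, 13 Hz sawtooth, uniform noise,
60 s at 128 Hz, seeded random mixing):

```r
library(icafeat)

bench <- make_bss_benchmark(seed = 42)
fit <- fit_ica(bench$recording$data, seed = 42)
S <- unmix(fit, bench$recording$data)
round(abs(cor(t(S), t(bench$ground_truth$S))), 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.020 0.002 1.000
#> [2,] 0.999 0.027 0.016
#> [3,] 0.040 1.000 0.002
amari_index(fit$W %*% fit$whitening$V, bench$ground_truth$A)
#> 0.01776641
```

Each recovered component matches exactly one true source with $|r| \ge
0.999$ (rows/columns are permuted — ICA cannot know the source order), and
the Amari index of the product of the estimated unmixing with the true
mixing is 0.018 on a 0–1 scale where 0 means a perfect scaled permutation.

The channel-selection benchmark shows where unmixing pays off. On a
dataset whose pressure class doubles the beta2 rhythm while a strong
beta-overlapping artifact contaminates every electrode, classify from one
unit at a time:

```r
res <- run_selection_benchmark(seed = 1)
res$per_unit_ica
#>   channel accuracy n_used
#> 1 IC1        0.396     48
#> 2 IC2        0.833     48
#> 3 IC3        0.917     48   # <- the separated beta rhythm
#> ...
res$per_unit_raw
#>   channel accuracy n_used
#> 3 ch3        0.646     48   # best raw channel
#> ...
res$comparison
#> <condition_comparison> 'ica' - 'raw': mean per-fold difference +0.280 (5+/0-/0=)
```

The best single component reaches 0.917 cross-validated accuracy while the
best single raw channel manages 0.646: no single channel can cancel an
artifact it shares with the signal, but a separated component can be clean.
(With *full* multichannel feature vectors the two conditions are close to
linearly equivalent — see the methods vignette,
`vignettes/icafeat-methods.Rmd`, which also documents every model
assumption, default and numerical convention.)

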