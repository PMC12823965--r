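---
title: "Detecting cognitive load from EEG with empirical Fourier decomposition and entropy features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive load from EEG with empirical Fourier decomposition and entropy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emfdeeg)
```

## The problem

Mental effort changes the EEG: arithmetic and other working-memory tasks
enhance frontal theta (4--7 Hz) activity, modulate alpha (8--12 Hz), and make
the signal less regular. `emfdeeg` turns that physiology into a binary
task-versus-rest classifier, and asks *where* on the scalp the discriminative
information lives, by grouping electrodes into cortical lobes under the 10--20
placement system.

The analysis unit is a 4-s window of a band-limited recording. Each window is
processed per channel in three stages:

1. **Empirical Fourier decomposition (EMFD)** splits the window into $N$
   band-limited intrinsic modes.
2. **Five entropy measures** summarize each mode's irregularity and scale.
3. **Cross-validated classification** (overall, and restricted to each lobe's
   electrodes) measures how well the two conditions separate.

## Empirical Fourier decomposition

Let $\hat x(\omega)$ be the DFT of the windowed signal, realized on the bins
$\omega_k = 2\pi k/n$, $k = 0..\lfloor n/2\rfloor$, of the window itself (no
zero padding). The spectrum is adaptively partitioned:

* Candidate peaks are the magnitudes at $\omega = 0$, at the Nyquist bin, and
  at every strict local maximum of $|\hat x|$ (plateaus count once, at their
  left-most bin).
* The $N$ largest candidates (ties broken toward lower frequency, for
  determinism) become band centres $\Omega_1 < \dots < \Omega_N$.
* Each interior boundary $\omega_i$ is the frequency of the minimum magnitude
  strictly between $\Omega_i$ and $\Omega_{i+1}$; the outer boundaries are
  pinned at $0$ and $\pi$. Adjacent centres with an empty interior collapse
  onto the later centre, and duplicate boundaries are removed (reducing the
  realized mode count).

Mode $i$ is the inverse DFT of the spectrum masked to
$[\omega_{i-1}, \omega_i)$ -- a *zero-phase filter bank* of binary indicator
masks, the last interval closed at $\pi$, each mask mirrored onto the negative
frequencies so modes stay real. Half-open intervals matter: closed intervals
on both sides would double-count shared boundary bins, while a true partition
gives three exact identities that the test suite checks at machine precision:

* reconstruction: $\sum_i x_i(t) = x(t)$ (relative error $< 10^{-10}$);
* energy: $\sum_i \lVert x_i\rVert^2 = \lVert x\rVert^2$ (Parseval over
  disjoint bands, $< 10^{-9}$);
* spectral disjointness: masked spectra of different modes never overlap.

The DC bin belongs to mode 1. When a narrowband window offers fewer than $N$
candidates, $N$ is clamped with a warning rather than an error, so batch
feature extraction never aborts mid-dataset.

**How many modes?** There is no universally right mode count for EEG --
published workload analyses use anywhere from five to ten -- so `emfd()`
defaults to `N = 10` and everything downstream takes `N` as a parameter.
The built-in synthetic benchmark uses `N = 5`: with three
oscillator bands plus a 1/f background there are rarely more than five
well-supported spectral segments per 4-s window, and the feature space halves.

## Entropy features

Per mode, five measures (defaults in parentheses; `entropy_params()` collects
them all):

* **Approximate entropy** (m = 2, r = 0.2 x sample SD): Pincus'
  $\Phi_m(r) - \Phi_{m+1}(r)$ with Chebyshev template distance,
  self-matches included. Natural log.
* **Fuzzy entropy** (m = 2, r = 0.2 x SD, exponent n = 2): Chen's variant --
  baseline-removed templates, membership $e^{-(d/r)^n}$ in place of the hard
  threshold, self-matches excluded. The two template statistics use the same
  count ($n - m$) so the lengths compare like for like. Offset-invariant by
  construction.
* **Differential entropy**: the Gaussian closed form
  $\tfrac12\ln(2\pi e\,\sigma^2)$. It is exact only under Gaussianity; on a
  narrowband mode it behaves as a log-power feature, which is precisely what
  makes it sensitive to theta enhancement and alpha suppression. Scaling a
  signal by $a$ shifts it by exactly $\ln|a|$.
* **Quadratic Renyi entropy**: $h_2 = -\ln \mathrm{IP}$ with the information
  potential $\mathrm{IP} = P^{-2}\sum_{j,k} B_\sigma(y_k - y_j)$, normalized
  Gaussian kernel, width by Silverman's rule on the mode's samples. The
  information potential alone is not a scalar entropy, hence the $-\ln$.
* **Fractal-dimension entropy** (0.5-s sub-windows, 50% overlap, Higuchi
  estimator with kmax = 10, 10 bins over [1, 2]): Shannon entropy (base 2,
  matching the definition's $\log_2$) of the distribution of per-sub-window
  fractal dimensions. Zero when all sub-windows agree; $\log_2 M$ at equal
  occupancy. Dimensions are clamped to [1, 2] before binning (the Higuchi
  slope can leave that range on short, noisy sub-windows).

Template entropies tie $r$ to each mode's own SD, which makes them
offset- and scale-invariant; differential entropy deliberately is not. A mode
with (near-)zero variance gets the degenerate values the definitions imply
(0 for the template entropies; differential entropy at a documented variance
floor, default $10^{-15}$) instead of NaN, so feature matrices stay finite.

Feature columns are named `<channel>__imf<k>__<entropy>` in deterministic
(channel, mode, entropy) order: 19 channels x 10 modes x 5 entropies = 950
columns for the 19-channel montage, 14 x 10 x 5 = 700 for the 14-channel one.

**Scaling and reduction.** Min-max scaling and the optional
variance/correlation feature filter are *fitted inside each training fold
only* -- test rows are transformed with training statistics and never clipped;
fitting per fold is the only choice that cannot leak. Feature reduction (drop
variance $\le 10^{-12}$, then the later of any pair with $|r| \ge 0.98$) is
off by default: it is a generic collinearity filter, useful for the slower
classifier families, not a tuned selection method.

## Lobe montages

Electrode-to-lobe assignments follow 10--20 nomenclature
(FP*/AF*/F* frontal, C* central, T* temporal,
P* parietal, O* occipital), midline electrodes to their letter's lobe. The
14-channel montage has no central-line electrodes; its fronto-central pair
FC5/FC6 is assigned to the frontal lobe (there is no central lobe to receive
them). Both presets are validated as partitions at construction, and custom
mappings can override everything.

## Classification and evaluation

Fourteen classifier families cover the span practitioners actually compare
(gradient-boosted trees for the boosted ensemble, bagged
trees as a full-feature random forest, random-subspace ensembles over k-NN
and LDA, four SVM kernels, k-NN, Gaussian naive Bayes, LDA/QDA, logistic,
CART). Exact parity with any particular GUI implementation is a non-goal;
the evaluation harness is the point:

* **Stratified k-fold CV** (default k = 10): per class, shuffled indices are
  dealt round-robin, so fold class proportions are within one sample of
  global. Every row is scored exactly once out-of-fold. `task` is the
  positive class throughout. Headline Ac/Se/Sp/Pr/Fs come from the pooled
  confusion; mean/SD and the 95% CI (t on k-1 df) come from per-fold
  accuracies -- both styles are reported because both are conventional.
* **Grouped CV** (`group_by_subject = TRUE`) keeps all of a subject's
  segments in one fold. Segment-level CV is the default (the common choice
  in workload studies) but it lets a classifier exploit
  subject-specific gains; the synthetic generator's inter-subject
  variability exists precisely so the two modes differ measurably.
* **ROC/AUC** by threshold sweep with tie grouping and trapezoid area.
* **Permutation test**: labels permuted wholesale, full CV re-run each
  iteration, add-one p-value $(1 + \#\{\text{perm} \ge \text{obs}\})/(n+1)$
  -- never zero, super-uniform under the null.
* **Learning curve**: stratified subsampling of training folds at given
  fractions, averaged over repeats.
* **Bayesian optimization**: GP surrogate (squared-exponential kernel on the
  unit cube, fixed length-scale 0.25, nugget $10^{-6}$) with expected
  improvement over 500 random candidates per step; objective is inner 5-fold
  CV accuracy; default budget 30 evaluations. The running best is monotone
  by construction and the whole history is returned.

One top-level seed deterministically derives every stage seed (fold
assignment, model fits, permutations, candidate draws), so a configuration
reproduces byte-identical report tables.

## Synthetic EEG

`synth_config()` generates two-condition multichannel EEG: 1/f background
(spectrally shaped white noise, exponent 1, 20 uV RMS) plus
narrowband-filtered-noise oscillators -- theta 4--7 Hz at 5 uV, alpha
8--12 Hz at 10 uV (alpha dominant, as at rest), beta 13--30 Hz at 3 uV --
with per-subject log-normal band gains (SD 0.2) shared across conditions.
Oscillators are filtered noise rather than pure tones so the entropy features
are non-degenerate. Under `task`:

* frontal-lobe channels get theta amplitude x `frontal_theta_gain`;
* all channels get alpha amplitude x `alpha_suppression`;
* broadband noise with RMS `irregularity_delta` x background RMS is mixed in.

The `strong` preset (gain 2.5, suppression 0.7, irregularity 0.1, 20
subjects, 40 s per condition on the 14-channel/128 Hz montage -> 400
segments) is the package's workload benchmark; the `null` preset switches
every effect off, making conditions exchangeable. The irregularity default
of 0.1 reflects that task-related broadband changes are subtle relative to
frontal theta enhancement; the frontal effect is what makes the benchmark's
lobe contrast meaningful. Benchmark problem sizes (40-s recordings, N = 5
modes, 128 Hz montage) were fixed once as a compact configuration with
enough segments (400) for stable 10-fold estimates.

What the generator does *not* emulate: eye-blink/EMG artifacts, volume
conduction and channel correlation structure, non-stationarity within a
recording, realistic topography beyond the frontal/other split. Passing the
benchmark therefore demonstrates that the pipeline recovers a known,
lobe-localized spectral effect end-to-end -- not that any particular accuracy
will transfer to real recordings.

## Numerical choices and caveats

* **Filtering** is zero-phase forward-backward Butterworth (order 4; 0.5--45
  Hz for the 500 Hz preset, 1 Hz high-pass plus common-average reference for
  the 128 Hz preset), implemented with odd-reflection padding and
  steady-state initial conditions (verified against a reference
  implementation). Caveat: reflecting a truncated oscillation creates a
  local kink whose in-band energy appears near window edges -- a property of
  all time-domain zero-phase filtering. Whole recordings are filtered before
  slicing, so 4-s analysis windows are unaffected except at recording ends;
  attenuation claims are checked on the designed response and away from
  edges.
* **Spectral ties** in the peak sort break toward lower frequency; boundary
  argmin scans take the first minimum. Both choices are arbitrary but fixed,
  which is what determinism requires.
* **Degenerate inputs**: constant signals are rejected by
  `differential_entropy()` (the entropy diverges) unless a variance floor is
  supplied; batch extraction always uses the floor. Windows shorter than
  `2N` samples are rejected by `emfd()`.
* **SVM scores** are oriented decision values (the decision-column name
  fixes the sign); hard labels come from the SVM's own prediction, since a
  fixed threshold on decision values is not calibrated.
* **Gradient boosting** places split thresholds at training-data boundaries,
  so a held-out point beyond its class's training range can be missed even
  on perfectly separable data -- visible as one stray error in otherwise
  perfect benchmarks.

## Limitations

Binary task-versus-rest only (no graded workload levels); no artifact
removal beyond band-limiting; EMFD's mode count is fixed per run, not
adapted per window; lobe montages are label-driven (no source localization);
and the classifier families are generic R implementations, so results from
GUI classification suites with their own tuning conventions are not expected
to reproduce number-for-number.
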