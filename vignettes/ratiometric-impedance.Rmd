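---
title: "Ratiometric finger-pair impedance features: model, simulator and benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric finger-pair impedance features: model, simulator and benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zratio)
```

## The circuit model

A finger pair measured between two fingertip electrodes is modelled as four
Z-blocks, each a series resistance with a parallel RC branch,

$$Z_\mathrm{block}(f) = R_s + \frac{R_p}{1 + i\,2\pi f\,R_p C_p},$$

where $R_s$ captures extracellular-fluid (and, for the interface blocks,
skin) resistance, $R_p$ intracellular-fluid resistance and $C_p$
cell-membrane capacitance. At DC the block reads $R_s + R_p$; at high
frequency the membrane capacitance shorts the intracellular branch and the
block tends to $R_s$, so every block magnitude decreases monotonically with
frequency — as does the whole two-terminal RC network.

The four blocks are wired as

$$Z_\mathrm{pair}(f) = Z_1(f) + \bigl(Z_2(f) \,\|\, Z_3(f)\bigr) + Z_4(f),$$

with $Z_1, Z_4$ the two electrode/epidermis interfaces, $Z_2$ the dermis
path and $Z_3$ the sweat-gland/duct path. The wiring itself is a modelling
choice: we follow the standard electrode–skin equivalent-circuit tradition
in which the two interfaces are in series with the interior and the sweat
ducts shunt the deeper tissue. Only magnitudes $|Z|$ are exposed, because
the measurement hardware being modelled records RMS voltage; phase is not
observable. The observation grid is 20–500 kHz in 20 kHz steps (25 points);
frequencies below 20 kHz are excluded from the geometry because contact
pressure and skin hydration perturb them.

### State scaling and ratio invariance

Common physiological drift is modelled as every resistance scaling by $s$
and every capacitance by $1/s$. This convention is not arbitrary: it is the
unique elementwise scaling under which every $R_pC_p$ time constant is
preserved, so that

$$Z_\mathrm{pair}(f; s) = s \cdot Z_\mathrm{pair}(f; 1) \quad \text{at every } f,$$

and hence the ratio of any two pair spectra under the *same* state is
exactly invariant to $s$. The package tests verify this cancellation to
relative $10^{-12}$, and the simulator exploits the identity (a session's
drift is applied as one multiplicative factor rather than by rebuilding
every scaled circuit — the results are equal to machine precision).

## The synthetic cohort generator

No component values or cohort data are published for real fingers, so
`generate_dataset()` emulates the *statistical structure* the method
assumes, not any particular hand:

- **Stable anatomy.** Each subject draws, per finger, an
  electrode/epidermis, dermis and sweat-duct block plus a body resistance,
  log-normally around configurable medians (`cohort_config()`). The
  medians are order-of-magnitude tissue values ($R$ of $10^2$–$10^3\,\Omega$,
  $C$ of a few to tens of nF); the dispersion default (sdlog 0.35) makes
  subjects clearly distinct while keeping all 10 pair spectra in one
  decade, which is what published raw-spectra figures show. Pairs sharing
  a finger share that finger's parameters exactly, inducing realistic
  inter-pair correlation.
- **Session drift.** Each (subject, session) draws one multiplicative
  drift factor, log-normal with sdlog `drift_sigma` (default 0.2), shared
  by all 10 pairs — the common-mode premise.
- **Temperature.** Hand temperature is drawn uniformly on 29–37 °C (the
  range over which the inverse dependence was established with a climate
  chamber) and enters the session scale linearly:
  $s = \mathrm{drift}\cdot(1 + \gamma\,(T_\mathrm{ref} - T))$ with
  $\gamma = 0.02$/°C and $T_\mathrm{ref} = 33$ °C. Only the inverse
  monotone dependence is established empirically; the linear form and
  coefficient are the package's choice, sized so the 8 °C range moves mean
  impedance by ±8 %.
- **Placement noise.** Every record multiplies each pair's spectrum by
  $e^\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ i.i.d. per (record,
  pair), default $\sigma = 0.02$ — a stand-in for electrode re-placement
  and contact variation, whose magnitude is not published.

What the generator does *not* emulate: frequency-dependent (non-common-mode)
drift, humidity or circadian structure, electrode polarization, contact
pressure effects, or heavy-tailed outliers. Passing benchmarks on this
generator therefore demonstrates that the pipeline recovers identity
whenever drift is predominantly common-mode — the method's stated premise —
and cannot certify performance on real hands.

Default geometry mirrors the emulated study (41 subjects × 5 sessions × 10
placements); tests and the acceptance benchmark use 8 × 3 × 5 = 120
records, a size at which every property checked is already expressed and
the full suite runs in seconds.

## Ratiometric features and combination selection

A record's ratiometric vector divides, at each frequency, the magnitude of
each combination's numerator pair by its denominator pair: 10 combinations
× 25 frequencies = 250 elements, the same length as the raw concatenation.
Orderings are fixed by convention (combinations in set order, canonical
lexicographic pair order for raw features, frequencies ascending) since no
element order is published. Ratios are formed on linear magnitudes.

Because each pair appears exactly once as numerator and once as
denominator, the product of the 10 ratio features at any fixed frequency
telescopes to 1 — a useful structural check (asserted to $10^{-9}$).

`published_combination()` returns the fixed assignment reported with the
method (a single 10-cycle through the pairs) and is the default
everywhere; data-driven selection is opt-in. `select_combinations()`
formalizes the published verbal criterion — each pair combined so its
feature deviates least from the average of the others — as a balanced
assignment on the log scale: with $M_p$ the training mean of
$\log|Z_p(f)|$, minimize $\sum_p (M_p - M_{\sigma(p)})^2$ over
fixed-point-free permutations $\sigma$. The log scale makes numerator and
denominator roles symmetric and makes the target average well defined
(zero, by the telescoping identity). Whether the original selection used
linear or log ratios, pooled or per-subject data, is unstated; this
formalization is documented as the package's own. The optimum is exact:
depth-first branch-and-bound with a row-minimum lower bound over the
1 334 961 derangements of 10 items (milliseconds in practice), with ties
broken lexicographically; an exhaustive-enumeration path is kept as the
test oracle for $n \le 6$.

## The identification benchmark

`loso_split()` holds out one (subject, session) at a time — enrolment never
sees the probe day. `evaluate()` featurizes, fits the classifier per fold,
pools scores across folds, and reports top-score accuracy plus the
threshold-sweep metrics.

**Classifiers and hyperparameters.** The four families and their settings
are taken as given from the emulated protocol: linear and quadratic-kernel
SVM with box constraint $C = 1$ and kernel scale 16, 1-NN with Euclidean
distance, and 30 bagged Gini trees with at most 2165 splits. The quadratic
kernel is implemented as $(1 + u\cdot v)^2$ on scale-divided features, with
one-vs-one decomposition.

**SVM standardization.** The SVM families standardize each feature on
training statistics before dividing by the kernel scale. Two observations
force this choice. First, $16 \approx \sqrt{250}$ is exactly the customary
automatic kernel-scale heuristic for *standardized* predictors, and the
MATLAB classification tooling these settings come from standardizes its
SVM learners by default — so the stated hyperparameters presuppose it. Second, without standardization the
one-vs-one linear SVM on O(1) ratio features collapses (every training
point becomes a support vector and held-out accuracy falls below chance):
with ~30 samples per duel the slack budget cannot pay for the margin the
unscaled geometry requires. 1-NN and bagged trees are scale-equivariant
enough and use the features as-is; ratiometric features are never
standardized outside the SVM kernel, since combination selection already
balances their scales.

**Score calibration.** The acceptance-threshold sweep needs a continuous
per-class score. SVM one-vs-one decision values are mapped through a
sigmoid into soft votes and summed per class (raw decision-value sums are
incomparable across duels); 1-NN uses a softmax of negative per-class
nearest distances (raw 1-NN votes are 0/1 and cannot be swept); bagged
trees use ensemble vote fractions. All scores are normalized to sum to 1
per sample.

**ROC conventions.** Genuine scores are those assigned to the true class,
impostor scores those assigned to other enrolled classes, pooled across
folds (verification-style). The threshold sweep runs over the observed
score set with $\pm\infty$ endpoints; FAR is the fraction of impostor
scores at or above the threshold, FRR the fraction of genuine scores
below. The EER interpolates linearly between the two thresholds bracketing
the FAR/FRR crossing; AUC is the trapezoid over (FAR, 1−FRR), which equals
the Mann–Whitney statistic with ties counted half. Both are verified
against brute-force enumeration to $10^{-9}$.

`finger_pair_classification()` is the within-subject variant: classes are
the 10 finger pairs (raw mode: one pair's 25-point spectrum per sample) or
the 10 ratio combinations (ratiometric mode), with the same
leave-one-session-out protocol.

## Numerical and degenerate-input choices

- Component values, scales and noise parameters must be strictly positive;
  a session scale that a temperature/coefficient combination would drive
  to zero or below is an error, not a clamp.
- Frequencies are stored as integer hertz in the CSV interchange format to
  avoid floating-point key drift; impedances round-trip to better than
  $10^{-9}$ relative (15 significant digits).
- Derangement ties (exact, e.g. a reversed cycle under the symmetric cost)
  resolve to the lexicographically smallest assignment; the brute-force
  oracle accumulates its objective in the same double-precision order so
  tie resolution is bitwise reproducible.
- Degenerate inputs error early with named offenders: single-session
  subjects in `loso_split()`, single-class training sets, empty score
  sets, missing pairs in a record.

## Known limitations

The directional claim the benchmark supports — ratiometric features reduce
LOSO identification error relative to raw features under common-mode drift
— is reproduced on synthetic cohorts only; the published headline numbers
(94.14 % accuracy, EER near 3 %) come from a private 41-subject dataset and
are not reproducible here, so no attempt is made to match them
numerically. If real drift had a strong pair- or frequency-dependent
component the ratio transform would cancel less of it; the generator's
`drift_heterogeneity` argument breaks the common-mode premise per pair for
such robustness studies, but frequency-dependent drift is not modelled. Spoofing and
liveness questions are likewise out of scope: the package evaluates
discrimination among enrolled subjects and open-set rejection, nothing
about presentation attacks.
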