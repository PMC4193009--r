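---
title: "Event-locked dynamic connectivity of a small brain network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked dynamic connectivity of a small brain network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Interictal epileptic discharges (IEDs) are brief electrical events that occur
between seizures. A long-standing question is whether the intrinsic
functional connectivity of the default mode network (DMN) — the resting-state
network most consistently disturbed in epilepsy — changes around the moment
of a discharge: is the network reconfigured *before* the event, perturbed
*during* it, and does it recover *after*?

`woiconn` implements an event-locked dynamic functional-connectivity
analysis for this design. Around each event at volume $t$ (in TR units),
four tapered windows of interest (WOIs) of length $L$ TRs are cut from
region-level BOLD time series:

* before: $[t-L,\,t)$
* during: $[t,\,t+L)$
* after: $[t+2L,\,t+3L)$
* baseline: $[t+4L,\,t+5L)$

An event is analyzable only if all four windows lie inside one acquisition
run and no other event onset falls within $7L$ TRs of $t$ — the span of the
four windows plus a $2L$ trailing guard, applied symmetrically so that a
"before" window can never overlap the windows or guard of a preceding event.
Invalid events are flagged with a reason and excluded from *all four*
conditions, keeping the design paired by event.

The default window length is $L = 8$ TRs (16 s at TR 2 s), with the
supported sensitivity range $L \in \{6, 8, 10\}$.

## From windows to connectivity

**Taper.** Each window is weighted by the convolution of a length-$L$
rectangle with a unit-area Gaussian ($\sigma = 2$ TRs, sampled on integer
offsets over $\pm 4\sigma$, where the truncation discards $< 10^{-4}$ of the
kernel mass), keeping the $L$ central samples and normalizing to unit sum.
The weighted covariance

$$S_{jk} = \sum_i w_i\,(x_{ij}-\bar x_j)(x_{ik}-\bar x_k),
\qquad \textstyle\sum_i w_i = 1$$

is the windowed estimate. Its expectation is $(1-\sum_i w_i^2)\,\Sigma$
because of the within-window mean subtraction; the factor cancels in every
downstream quantity, all of which consume correlations.

**Sparse precision estimation.** With $N = 14$ regions and only $L = 8$
samples per window, the sample covariance is singular; the pipeline
estimates the precision matrix $\Omega$ by the graphical lasso, maximizing

$$\log\det\Omega \;-\; \operatorname{tr}(S\Omega) \;-\; \lambda\,\lVert\Omega\rVert_1$$

with the $\ell_1$ penalty over all entries including the diagonal (an
off-diagonal-only switch exists but is off by default). The solver is a
block coordinate descent written in C++. Convergence is certified by a true
duality gap: the dual problem maximizes $\log\det \widetilde W + p$ over
$\lVert\widetilde W - S\rVert_\infty \le \lambda$, so projecting the working
covariance into that box yields a non-negative gap that vanishes exactly at
the optimum. (The superficially attractive expression
$\operatorname{tr}(S\Omega)+\lambda\lVert\Omega\rVert_1-p$ is *not* a valid
certificate here: with $\Omega$ maintained as the exact inverse of the
working covariance it vanishes after every sweep regardless of optimality.)
Fits that fail to close the gap within the iteration budget are flagged, not
silently accepted.

**Penalty selection.** $\lambda$ is chosen per subject by
leave-one-window-out cross-validation *matched to how the penalty is used*:
for each candidate $\lambda$ the model is fitted to every window
individually, and each held-out window $S_{\text{ho}}$ is scored by the mean
Gaussian log-likelihood $\log\det\Omega - \operatorname{tr}(S_{\text{ho}}\Omega)$
of the other windows' fits. This matters: fitting on the *average* of ~39
training windows produces a well-conditioned matrix that needs almost no
penalty, so that scheme selects a near-zero $\lambda$ which then leaves the
actual single-window fits unregularized — their correlations saturate near
$\pm 1$ and the Fisher transform amplifies them without bound. Scoring
single-window fits selects the regularization a window of this length
actually needs to generalize. The grid is 20 log-spaced values in
$[10^{-3}, 1]\cdot\max_{j\neq k}|\bar S_{jk}|$; ties go to the smaller
penalty, and penalties with non-convergent fits are removed from contention.
The fits walk the grid from the largest penalty down with warm starts, and
the walk stops once the held-out score has failed to improve on its running
maximum for four consecutive penalties — the score curve is concave in
$\log\lambda$ in this regime, and the smallest penalties are by far the
costliest fits on near-singular window covariances. Selection-stage fits
use a looser duality-gap tolerance ($10^{-4}$) than the final per-window
fits at the chosen penalty ($10^{-5}$); only the argmax of the score curve
is consumed.

**Condition means.** Each window's regularized covariance $W = \Omega^{-1}$
is normalized to a correlation matrix, Fisher-transformed ($\operatorname{atanh}$,
entries clipped to $\pm(1-10^{-7})$, zero diagonal), and a general linear
model with one indicator column per condition is fitted to the vectorized
upper triangles. With an indicator design the coefficients equal the
per-condition means, which the code asserts as a cross-check. The result is
one symmetric condition-mean matrix $M$ per subject and condition.

## Graph measures

* **Integration** $I = -\tfrac12 \log\det R$, with $R$ the correlation
  matrix implied by the condition matrix ($\tanh$ back-transform, unit
  diagonal). This is non-negative, zero only under independence, and
  invariant to per-region variance rescaling. The signed
  $+\tfrac12\log\det M$ variant is available as `mode = "literal"` because
  the two conventions circulate in the literature; the default is the one
  consistent with positive reported group values of order 1, since
  $\tfrac12\log\det$ of a correlation-like matrix is necessarily $\le 0$.
* **Node strength** $k_i = \sum_j E_{ij}$ on signed weights
  $E = \tanh(M)$.
* **Clustering coefficient**
  $C_i = \sum_{j,h}(w_{ij}w_{ih}w_{jh})^{1/3} / (k_i(k_i-1))$ on weights
  $w = |\tanh(M)|$ normalized by their maximum, with $k_i$ the *binary*
  degree, following the Brain Connectivity Toolbox convention; the
  literal strength-based denominator circulates too, but the toolbox
  convention keeps $C_i \in [0,1]$.
* **Density** $D$ = significant edges / $\binom{N}{2}$.

## Group inference

All tests are nonparametric, as dictated by groups of six subjects.

**Network and node level.** Exact Wilcoxon signed-rank tests by full
enumeration of all $2^n$ sign assignments (mid-ranks for ties). With $n=6$
the smallest attainable two-sided p is $2/64 = 0.03125$, so asymptotic
approximations are never used. False discovery rate control is
Benjamini–Hochberg, one family per display unit: the 6 pairwise network
tests form one family; each (measure × condition pair) family holds the 14
node p-values. A q < 0.1 trend mask is reported alongside the q < 0.05 mask.

**Edge level.** The network-based statistic for the paired design: per-edge
paired t statistics on within-subject condition differences, thresholded at
the two-sided critical value for the primary p (default 0.05, df $= S-1$).
Connected components are formed separately among positive and among
negative supra-threshold edges — components never mix signs. The
permutation null flips the sign of whole subjects' difference matrices
(equivalent to swapping condition labels within subject); the null
statistic is the maximum component extent over *both* signed graphs per
flip, so a single null distribution protects components of either sign
simultaneously (a one-sided null would let the union of both directions
exceed the nominal family-wise level) and the p-values are exactly
invariant to a global sign flip of the data. All $2^S$ flips are enumerated
whenever $2^S \le$ the permutation budget (default 10000), making the test
deterministic for $S \le 13$. The identity flip and its global complement
both reproduce the observed graph, so the smallest attainable p under full
enumeration is $2/2^S$ — 0.03125 at $S = 6$, the same floor as the exact
two-sided sign test at that group size. With sampled permutations the
identity is always among the draws, bounding p below by $1/\#\text{draws}$.

**Static group integration.** For whole-series analyses a Bayesian sampling
scheme summarizes group integration: each subject's covariance is drawn from
its inverse-Wishart posterior under a Jeffreys prior ($\mathrm{IW}(n,\,n\hat S)$
for $n$ observations), integration is computed per draw, and the group mean
over subjects is recorded for (by default) 1000 draws. The prior is a
documented choice: sampling schemes of this kind are usually named without
a prior being fixed, and the Jeffreys prior is the standard
minimally-informative default for a covariance.

## The synthetic cohort

No patient data are distributable, so the package ships a generator whose
output is, by construction, exactly the quantity the pipeline estimates.
Defaults emulate the study conditions: TR 2 s, six runs of 300 volumes, 12
events per subject with at least 40 TRs (80 s) between onsets, $N = 14$
regions. Each volume's innovation is multivariate normal with the covariance
of whatever WOI the volume falls in (baseline elsewhere); innovations pass
through a variance-preserving AR(1) filter ($\phi = 0.3$) and a sinusoidal
scanner drift (amplitude 0.5, period 128 s) is added. Both noise components
are stand-ins for BOLD noise structure, not a claim about any particular
scanner, and both can
be set to 0 for exact-distribution tests.

The baseline covariance is a 14-node equicorrelation matrix with $r = 0.2$
(integration 0.81 nats, the same order as reported group values); condition
effects add 0.05 / 0.015 / 0.035 to every off-diagonal covariance for
before / during / after, reproducing the qualitative
before > after > during ≈ baseline ordering with a planted
before-vs-baseline integration increase of 0.34 nats. All randomness flows
from one integer seed through counter-based per-subject child seeds, and
identical spec + seed gives bit-identical output.

What the generator does **not** emulate: hemodynamic response convolution,
spatial structure within regions, physiological noise spectra, motion, and
inter-subject variability in network topology. Passing tests on synthetic
cohorts therefore demonstrate the *estimator chain* is correct and
calibrated, not that real recordings carry effects of the planted size.

### A statistical limitation worth stating plainly

With $L = 8$ samples per window, 14 regions, and roughly 8–10 analyzable
events per subject, a condition's effective sample size is about 60 volumes.
For a Wishart-distributed covariance estimate the variance of
$\log\det\hat\Sigma$ is approximately $2N/n_{\mathrm{eff}} \approx 0.48$,
i.e. a per-condition integration standard error of ~0.35 nats, and ~0.5
nats for a between-condition difference — larger than the 0.34-nat planted
effect. No estimator can make a 6-subject sign test on such differences
reliably significant under these conditions; the pipeline's recovery tests
measure, and report, exactly this ceiling. Detecting effects of this size
reliably would need either several times more valid events per subject or
longer windows.

## Numerical choices

* PD repairs are explicit and warned about: generator covariances are
  eigenvalue-floored at $10^{-6}$; integration inputs at $10^{-8}$; a
  singular windowed covariance receives a $10^{-8}$ diagonal jitter before
  an unpenalized fit.
* Fisher-transform inputs are clipped at $\pm(1-10^{-7})$.
* Zero differences are dropped from Wilcoxon tests (standard convention);
  all-zero inputs give p = 1 with a warning.
* Zero-variance edges are excluded from the NBS with a message; a region
  with zero variance keeps its row (zeroed and flagged) so that $N$ stays
  fixed.
* Event onsets map to volumes by `floor(onset / TR)`: a discharge at time
  $t$ affects the volume being acquired.
* Two spacing rules coexist in this design: the 80-s eligibility rule for
  event trains and the stricter $7L$ window-validity guard (for
  $L = 8$–$10$ the guard dominates). The guard decides what is analyzed;
  the eligibility report carries the 80-s check separately.

## Problem sizes used by the test suite

The packaged tests run the full pipeline on 6-subject cohorts at the
generator defaults: 50 replicate cohorts for effect recovery, 500 null
cohorts for the family-wise error calibration of the NBS (full 64-flip
enumeration), and one cohort across $L \in \{6, 8, 10\}$ for the
window-length sensitivity check. Oracle comparisons (closed forms,
brute-force graph metrics, full Wilcoxon enumerations, a projected-gradient
reference for the graphical lasso) use small dimensions ($p \le 3$ for the
solver reference, $n \le 8$ nodes, $n \le 10$ pairs) where the reference
computations are exact or effectively exact.

## A short example

```{r, eval = FALSE}
library(woiconn)

cohort <- simulate_cohort(cohort_specs(n_subjects = 6, seed = 1))
results <- lapply(cohort, function(s) run_subject(s$series, s$events))
group <- run_group(results)
group$mean_integration
group$network
```
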