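---
title: "Quantifying the dynamic structure of single-cell migration trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the dynamic structure of single-cell migration trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Free-crawling amoeboid cells (the motivating system is *Amoeba proteus*,
with and without a nucleus, migrating under electric fields and peptide
gradients) do not perform simple random walks.  Their paths carry
structure on many time scales: step lengths are serially correlated over
minutes, displacement grows superdiffusively, and the move-step sequence
is far more regular than chance.  `migstats` implements the statistical
toolkit used to quantify that structure on tracked trajectories, plus a
synthetic-motion generator so that every stage of the pipeline can be
validated against inputs with known ground truth.

The analysis unit is a `trajectory`: a uniformly sampled sequence of 2D
positions in micrometres, by default 4,100 frames at 2 Hz (0.5 s per
frame, 34 min 10 s total), mirroring a stereomicroscope recording
protocol.  From it we derive the *move-step series* — the per-frame
displacement magnitudes — which feeds the series-level statistics.

## The statistics

**rmsf (root mean square fluctuation).**  Build the cumulative profile
$y(k)=\sum_{j\le k}(x_j-\bar x)$ of the move-step series and measure
$F(l)=\mathrm{sd}\{y(k+l)-y(k)\}$ over all overlapping windows.  A power
law $F(l)\sim l^{\alpha}$ signals long-range interdependence:
$\alpha = 0.5$ for uncorrelated steps, $\alpha > 0.5$ for persistent
ones.  The *correlation time* is estimated from the same curve: local
log–log slopes are evaluated in sliding half-decade windows on a
50-frame (25 s) grid, and the crossover is the largest scale up to which
every local slope stays above $0.5 + \text{margin}$ (margin 0.05 by
default, configurable).  The result is reported in minutes and is a
multiple of 25 s by construction.

**MSD (mean squared displacement).**  Time-averaged
$\mathrm{MSD}(\tau)=\langle|\mathbf r(t+\tau)-\mathbf r(t)|^2\rangle_t$
with overlapping windows; the log–log slope $\beta$ classifies the
motion ($\beta=1$ normal diffusion, $1<\beta<2$ superdiffusion,
$\beta=2$ ballistic).

**DFA (detrended fluctuation analysis).**  Canonical DFA-1: integrate
the mean-subtracted series, split the profile into non-overlapping boxes
of size $n$ (forward and reversed, both contributing), remove the
per-box least-squares line, and report the RMS residual $F(n)\sim
n^{\gamma}$.  For noise-like input $\gamma=0.5$ is neutral; for
Brownian-class input the neutral value is 1.5 and $1.5<\gamma<2$ means
trend-reinforcing memory.  At the trajectory level DFA is applied to
each Cartesian coordinate series separately and the two exponents are
averaged; this routing reproduces the observed regime pattern
(experimental paths near $\gamma\approx1.8$, collapsing to
$\approx0.5$ after position shuffling) and treats the coordinates as the
Brownian-class signals they are.

**ApEn (approximate entropy).**  Pincus' regularity statistic
$\Phi^m(r)-\Phi^{m+1}(r)$ with self-matches included, natural log,
Chebyshev distance, $m=2$ and $r=0.2\,\mathrm{SD}$ of the analysed
window by default.  The growing-window profile evaluates ApEn on
prefixes growing by 50 frames — 82 windows at the default protocol —
and flags windows shorter than 300 points as invalid, since ApEn needs
at least $10^m$ points to be meaningful.  The template-counting kernel
is $O(n^2)$ and implemented in C++; the test suite pins it to a naive
R transcription of the definition at $10^{-12}$.

**Kinematics.**  Displacement cosine against the stimulus axis (chamber
convention: $+x$ toward the cathode, peptide source toward $-x$, so
galvanotaxis gives cosines near $+1$ and chemotaxis near $-1$); sector
histograms over eight half-open 45° bins; intensity of response (net
displacement, reported in mm); directionality ratio (net over total
path length); average speed (path length over duration, µm/s).

**Cohort statistics.**  Median/IQR (type-7 quartiles) for every metric;
two-sided Wilcoxon rank-sum tests with a signed, continuity-corrected
$Z$ for pairwise comparisons (exact enumeration for small tie-free
samples, normal approximation with tie correction otherwise);
Kruskal–Wallis across scenarios; and a Kolmogorov–Smirnov normality
gate that routes the analysis to the nonparametric path.  Because the
KS reference uses the sample's own mean and SD, its p-value is
conservative; it is used only as a gate.

## Numerical choices

**Finite-size (bridge) correction for rmsf.**  Subtracting the sample
mean from the steps pins the cumulative profile to zero at both ends.
For a series with Hurst exponent $H$ this suppresses the expected
squared fluctuation at scale $l$ by roughly $1-(l/n)^{2-2H}$, which
biases the raw log–log slope downward — by as much as $-0.1$ at
$H=0.9$, $n=4100$.  `fit_scaling_exponent()` therefore divides rmsf
curves by the square root of that factor and iterates to
self-consistency in $\alpha$ (on by default for rmsf curves; exact
synthetic curves are untouched).  With the correction, recovery of
$H\in\{0.6, 0.75, 0.9\}$ from fractional Gaussian noise is unbiased to
better than 0.02.

**Fit ranges.**  rmsf and DFA exponents are fitted on log-spaced scales
in $[8, N/8]$ frames and MSD on lags $[1, N/10]$ — the usual compromise
between small-scale discreteness and large-scale noise.  The rmsf curve
itself extends to $N/4$ so the correlation-time crossover can be probed
beyond the fit window.  Doubling all coordinates (a unit change) leaves
every fitted exponent invariant.

**Degenerate inputs.**  Constant series (zero fluctuation), stationary
trajectories (zero MSD), zero net displacement (undefined direction)
and zero-SD series with a fractional ApEn tolerance are rejected or
flagged rather than silently patched; the pipeline records such
failures per trajectory and continues.  Missing frames in track files
are an error, never interpolated, because gap-filling would alter the
very dynamics being quantified.

## The synthetic generator

Four models with increasing structure:

* `gen_ballistic` — noise-free constant velocity; the calibration limit
  $\beta=2$, DR $=1$.
* `gen_brownian` — iid Gaussian displacements (per-axis step SD
  `speed_mean * dt / sqrt(2)`); the null for $\beta\approx1$,
  $\alpha\approx\gamma\approx0.5$.
* `gen_persistent` — the cohort emulator.  The heading diffuses on the
  circle with relaxation time `persistence_time` (velocity
  autocorrelation $e^{-t/\tau}$), with an optional restoring drift of
  amplitude `bias_strength` toward the stimulus axis (stationary
  heading concentration $\approx$ `bias_strength * persistence_time`).
  Speed follows an Ornstein–Uhlenbeck process with the *same*
  relaxation time, truncated at zero.  An iid speed draw would make the
  move-step series white and no rmsf correlation time could ever
  recover the walker's persistence; coupling the speed process to the
  same time scale is the minimal change that gives the move-step series
  the long-range correlation, finite correlation time and low entropy
  that the experimental series exhibit.
* `gen_fgn_steps` — exact fractional Gaussian noise by Davies–Harte
  circulant embedding, shifted to nonnegative step lengths (shift by
  the deficit, clip at zero; the clip slightly biases the marginal at
  very low $H$ but leaves the autocorrelation untouched).  Ground truth
  for exponent recovery.

Scenario presets encode the four experimental conditions as directional
envelopes: no bias (Sc1, cosine median near 0), strong cathode bias
(Sc2, near $+0.97$), moderate peptide bias (Sc3, near $-0.70$), and a
58/42 peptide/cathode mixture (Sc4).  Default kinematics —
`speed_mean` 1.5 µm/s, `speed_sd` 0.5 µm/s, `persistence_time` 540 s —
sit inside the reported ranges (median speeds ≈ 1.3–1.7 µm/s,
correlation times of order 8–10 min).  The bias amplitudes (0.004,
5e-4 and 0.004 rad/s for Sc2–Sc4) were set once by matching the
stationary cosine medians to those envelopes.  These are emulation
targets, not fits to any real data set: the generator reproduces the
statistical envelope of the experiments, not the marginal speed
distribution, pseudopod mechanics, cell–cell interactions or
measurement noise of real recordings — so passing tests demonstrate
the correctness of the *analysis*, not biological fidelity.

## Surrogates

Each surrogate is a uniform random permutation — of the position order
for trajectory-level metrics (MSD, DFA, kinematics) and of the
move-step values for rmsf/ApEn.  A uniform permutation is the
distributional fixed point of repeated random transpositions, so a
nominal transposition count (the conventional $2\times10^5$) is kept
only as a configuration echo.  Permutation preserves the value multiset
exactly, hence mean, SD and all order statistics of the null are those
of the data.  The expected signature, verified in the acceptance suite,
is $\beta\to0$, $\gamma\to0.5$, $\alpha\to0.5$ and ApEn sharply up.

## Problem sizes

The test suite and the acceptance script run cohorts of 50–100
replicates of 4,100-frame series for the stochastic calibrations (means
of fitted exponents), 50 persistent walkers for the surrogate
contrasts, and $n\le1000$ series for the brute-force ApEn equivalence.
The analysis drivers under `analysis/` simulate 25 walkers per scenario
and cell type.  These sizes give Monte-Carlo standard errors well below
the acceptance tolerances while keeping a full run in minutes on one
core.

## Known limitations

* The persistent walker's $\gamma$ sits near 1.99 and its ApEn near
  0.15 — inside the superdiffusive, low-entropy regime but not
  numerically identical to published cohort medians ($\gamma\approx1.8$,
  ApEn $\approx0.002$), which depend on the real cells' speed
  fluctuation spectrum.
* The correlation-time grid is capped by the rmsf curve's maximum scale
  ($N/4$ frames by default, 8.54 min at the default protocol); longer
  correlation regimes saturate at the cap.
* `classify_dfa_regime` requires the caller to say whether the input is
  noise-like or Brownian-class; the package does not guess.
* The KS normality gate inherits the estimated-parameter caveat and is
  deliberately conservative.
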