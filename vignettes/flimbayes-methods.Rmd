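---
title: "Bayesian FRET-fraction estimation from FLIM histograms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian FRET-fraction estimation from FLIM histograms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimbayes)
```

## The measurement and the model

Time-domain FLIM measures, for each detected photon, the arrival time
relative to a periodic excitation pulse, accumulated into a histogram of
`n_bins` time bins.  When a fraction of donor fluorophores undergoes FRET,
the emission-time density is a mixture of two exponentials — a short
lifetime $\tau_S$ for the FRETting population and a long lifetime $\tau_L$
for the rest — plus a uniform background from dark counts and stray light:

$$p(t \mid \theta) = f_S\, p_S(t \mid \tau_S) + f_L\, p_L(t \mid \tau_L)
  + f_B\, p_B(t), \qquad f_B = 1 - f_S - f_L .$$

The fractions here are *photon-count* fractions: the probability that a
recorded photon originated from each source.  `decay_params()` stores this
parameter vector and enforces the simplex constraint and the lifetime
ordering $\tau_S < \tau_L$.

Three experimental realities enter the likelihood:

1. **Discretization.**  Arrival times come binned.  The model therefore
   works with exact bin-integrated probabilities: for a bin $[t_l, t_r)$
   the single-exponential mass is proportional to
   $e^{-t_l/\tau} - e^{-t_r/\tau}$, never a midpoint approximation
   (`periodic_decay_density()`).

2. **Periodic excitation.**  With an 80 MHz laser ($T = 12.5$ ns) a
   fluorophore excited by one pulse may emit after a later one.  Summing
   the pulse train turns $e^{-t/\tau}$ into a geometric series with closed
   form $e^{-t/\tau}/(1 - e^{-T/\tau})$ on one period.  The prefactor is
   constant in $t$, so it cancels in the per-component normalization; the
   package exploits this and the tests verify the closed form against a
   brute-force truncated pulse-train sum to $10^{-10}$.

3. **Instrument response.**  The measured arrival time is the emission
   delay plus the timing response of the detection chain.  Each component
   density is convolved with the measured IRF, treated as a discrete
   distribution on the same bin grid (`flim_irf()`, `read_irf()`; IRFs on
   finer grids are rebinned by edge-aligned aggregation).

The recorded TAC window can be shorter than the period (the default
acquisition records 10 of 12.5 ns).  Bins outside the window are masked
out, each component distribution is renormalized over the masked-in bins
(a conditional multinomial, which is exact), and the uniform background is
supported on the recorded window only — only recorded bins enter the
likelihood, so the background normalization must match the observation
window.

For a histogram with counts $P_i$, the log-likelihood is the multinomial
$\sum_i P_i \log p_i(\theta)$ over masked-in bins, up to a
$\theta$-independent combinatorial constant that cancels in the posterior.

### Convolution convention

The paper-level model does not fix what happens to decay mass that drifts
past the end of the recorded window.  Because periodic excitation makes
the steady-state arrival distribution periodic, the package convolves each
component with the IRF *modulo the excitation period*: when $T$ is an
integer number of bin widths (320 bins for the default acquisition) the
decay density is evaluated on the full-period grid, circularly convolved
with the zero-padded IRF, truncated to the recorded window, and
renormalized (`component_density()`).  This is the physical choice — the
long-lifetime tail that outlasts the window re-enters at the start of the
next period — and it makes the binned likelihood exactly consistent with
the per-photon simulator, which wraps arrival times modulo $T$.  The
exported `convolve_irf()` additionally provides the plain mod-window
circular convolution for grids that span a full period.  For periods not
commensurate with the bin width the convolution falls back to wrapping at
the window edge; the discrepancy is confined to the few bins reached by
the wrapped tail.

## Posterior evaluation

With lifetimes fixed at reference values (the dye calibration setting),
the free parameters are the two fractions under a uniform prior on the
simplex, so the posterior is proportional to the likelihood
(`grid_posterior()`).  All evaluation is in the log domain with
max-subtraction before exponentiation: at $5\times 10^7$ photons raw
likelihoods underflow by thousands of orders of magnitude.  Bin
probabilities are floored at $10^{-300}$ before the log so extreme
lifetimes cannot produce $-\infty$.

### Grid resolution and adaptive refinement

The base lattice is 201 uniformly spaced points per fraction axis on
$[0,1]$ (resolution 0.005), filtered to the simplex.  That resolution is
ample for low-photon work, but the low-fraction studies estimate
dispersions of order $10^{-4}$ at $5\times10^7$ photons — far below any
affordable fixed lattice.  `flim_fit()` (and the internal study fitter)
therefore refines adaptively: after each pass it takes the region whose
joint log-density is within 18 of the maximum (a $\pm 6\sigma$ cut for a
Gaussian), re-grids it with 81 points per axis, and repeats until the
lattice spacing is below one fifth of the current posterior standard
deviation on every axis.  At spacing $h = \sigma/5$ the lattice
approximation error of a Gaussian mean or s.d. is negligible (aliasing
decays like $e^{-2\pi^2\sigma^2/h^2}$), while each stage shrinks the
spacing by roughly a factor of 15, so three stages reach $10^{-6}$
resolution.  The refinement threshold and lattice sizes are fixed design
constants, not data-dependent tuning.

### Estimators, intervals, and the mode/mean distinction

Marginals are obtained by summing normalized mass over the other axes
(`marginalize()`); point estimates are the mass-weighted mean or the
lattice mode with ties broken toward the smallest value
(`post_estimate()`), and intervals are equal-tail discrete quantiles
(`credible_interval()`).  Near the simplex boundary the posterior is
skewed and truncated, so mode and mean genuinely differ at low photon
counts; both are reported throughout, and the study drivers aggregate
both.

### MCMC

`mcmc_posterior()` samples the same posterior by random-walk Metropolis:
independent Gaussian proposals per coordinate, reflected at the box
bounds (keeping the proposal symmetric), simplex and lifetime-ordering
violations rejected through the prior.  Proposal scales start at a tenth
of each box width and are re-tuned every 100 burn-in iterations toward an
acceptance rate of 20–50%, then frozen; the first 20% of the chain is
burn-in.  The sampler exists for two reasons: it cross-checks the grid
(the test suite requires Kolmogorov–Smirnov distance below 0.05 between
grid and MCMC marginals) and it scales to the four-parameter problem with
free lifetimes, where a dense grid would be wasteful.

## Amplitude fractions and the least-squares baseline

Conventional decay-fitting software reports pre-exponential *amplitudes*
rather than photon fractions.  The photon count collected from component
$j$ in the recorded window is proportional to $a_j \kappa_j$ with
$\kappa_j = \int_{\text{window}} e^{-t/\tau_j}\,dt$, so
`amplitude_fraction()` converts via
$a_S = (f_S/\kappa_S)\,/\,(f_S/\kappa_S + f_L/\kappa_L)$; with equal
lifetimes it reduces to the photon fraction, and for a full window with
$T \gg \tau$ it reduces to the familiar $f_j/\tau_j$ weighting.
`least_squares_fractions()` implements the comparison baseline: weighted
nonlinear least squares on model counts with weights $1/\max(P_i, 1)$,
optimized over the smooth reparametrization $f_S = qr$, $f_L = q(1-r)$ so
the simplex becomes a box.  `boxcar_fit_image()` applies either estimator
per pixel after pooling histograms over a centered window truncated at
the borders, and summarizes the long-lifetime amplitude-fraction map over
pixels exceeding a photon floor (default 100 pooled photons).

## The synthetic-data generator

`simulate_histogram()` draws bin counts multinomially from the model's
bin probabilities — exact for any analysis that only sees binned data and
fast enough for $5\times10^7$-photon studies.  `simulate_photons()` is
the slower generative check: component choice by fraction, exponential
emission delay added to an IRF-sampled offset, wrap modulo $T$, rejection
within each component until the photon lands in the recorded window.
Conditioning within the component (rather than redrawing the component
too) matches the per-component window renormalization of the likelihood,
and with the default acquisition the two simulators agree exactly in
distribution (verified by two-sample chi-square at $10^6$ photons).

Default synthetic acquisition: 256 bins over 10 ns, $T = 12.5$ ns,
Gaussian IRF with $\sigma = 0.1$ ns centered 0.5 ns into the window,
$\tau_S = 0.48$ ns, $\tau_L = 4.03$ ns (the reference-dye values), and a
background fraction of 0.02 unless stated.  Master curves — the
high-count empirical histograms that the resampling protocols subsample —
are rendered deterministically as expected counts at $10^9$ effective
photons (`master_curve()`).  For the low-fraction mixing study the
short-only and long-only masters carry a background fraction of 0.005:
dye solutions measured at high count rates are bright, and a few per
mille of background is a realistic contamination level.  This choice is
made once, up front; since a master's background photons dilute the
short-lifetime content of every draw taken from it, the background level
is also the main driver of the small (~0.5%) departure of the
estimated-versus-prescribed slope from exactly 1.

What the generator deliberately does *not* emulate: detector dead-time,
afterpulsing and pile-up; photon-by-photon (TTTR) streams;
non-monoexponential dye photophysics; and any intensity dependence of the
detection chain.  Passing the validation studies on synthetic data
therefore demonstrates the statistical machinery — not immunity to those
instrumental effects, which in real data produce small biases of their
own.

## The validation studies and their problem sizes

* **Low-photon study** (`low_photon_study()`): a mixture master with
  $f_S = 0.5$, $f_L = 0.48$, $f_B = 0.02$ is subsampled 300 times at each
  of 10 log-spaced photon counts from 30 to $3\times10^4$ (the roughly
  three decades of the published protocol; the exact lattice is not
  printed, so a 10-point log lattice is used).  Per-condition bias and
  sample s.d. of the posterior-mean and posterior-mode estimates are
  aggregated, and `fit_power_law()` fits $a\,n^b$ on log-log axes
  excluding the four lowest counts, where boundary truncation flattens
  the curve.  The expected exponent is the central-limit $-1/2$.

* **Low-fraction study** (`low_fraction_study()`): mixed histograms at
  prescribed short fractions $2^{-1}\ldots2^{-10}$, $5\times10^7$ photons
  each, fitted with lifetimes fixed; the per-condition mean estimate is
  regressed on the prescribed fraction.  30 replicates per fraction give
  a slope standard error near $10^{-4}$.  The adjacent-difference
  analysis (`delta_fraction_study()`) regresses estimated on prescribed
  differences, where any additive bias cancels exactly.  The s.d.-scaling
  arm fixes $f = 2^{-7}$ and varies $n \in \{5\times10^5, 5\times10^6,
  5\times10^7\}$ with 200 replicates per condition — the replicate count
  is set so the chi-square noise of a sample-s.d. estimate
  ($\mathrm{se}(\log_{10} s) \approx 0.434/\sqrt{2(n-1)}$) stays well
  inside the width of the published confidence band on the exponent.

* **Image study** (`boxcar_fit_image()`): a uniform synthetic field is
  fitted per pixel under growing boxcar windows; dispersion falls as
  pooling grows, the Bayesian map is tighter than the least-squares map
  at ~10³ pooled photons, and the two methods' means converge at high
  photon counts.  The in-vivo numbers of the original study come from
  external cell data and are not reproduced here.

Which estimator feeds the s.d.-versus-$n$ curves is not fixed by the
published protocol; the mean-based estimate is used, with the mode-based
aggregates reported alongside.

## Numerical and degenerate-input policy

* Probability floor $10^{-300}$ before any log; log-sum-exp with max
  subtraction everywhere a normalization is computed.
* A zero-photon histogram yields the prior (uniform over the grid).
* All-masked-out binnings, empty grids after simplex exclusion, all-zero
  IRFs, and zero-acceptance chains raise typed errors rather than
  returning quietly wrong objects.
* Every stochastic entry point takes an explicit seed; studies are
  reproducible bit for bit from configuration plus seed, and the CLI
  embeds a configuration hash in every output artifact.

## Known limitations

Lifetimes are treated as fixed in the grid path (free lifetimes go
through MCMC); model selection between mono-, bi- and tri-exponential
decays is out of scope, as are spatially regularized priors across
pixels, vendor binary formats, and IRF color/time-shift fitting.  The
recorded-window mask is assumed contiguous-in-effect for the background
(uniform over masked-in bins, wherever they lie).  For periods not an
integer multiple of the bin width the mod-$T$ convolution is
approximated by mod-window wrapping.
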