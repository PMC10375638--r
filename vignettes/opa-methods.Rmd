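---
title: "Pattern-constrained FLIM-FRET analysis: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-constrained FLIM-FRET analysis: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opaflim)
```

## The problem

Time-domain FLIM records, for every pixel, a histogram of single-photon
arrival times after pulsed excitation. When a FRET acceptor sits close to the
donor, the donor's excited state is quenched and its lifetime drops. The
conventional readout — a free multi-exponential fit summarised by the
amplitude-weighted mean lifetime — compresses two distinct biological
quantities into one number: *how many* donor molecules sit in a
FRET-competent complex, and *how close* the fluorophores are within that
complex.

Many popular donors (mVenus, GFP variants) are themselves bi-exponential:
a dominant slow component near 3 ns and a minor fast component around
1–2 ns. A free three-component fit of FRET data from such a donor is badly
under-determined, and a fit that pretends the donor is mono-exponential
misreads the donor's own fast component as FRET.

One-pattern analysis (OPA) resolves this by splitting the work:

1. **Calibration.** The donor-only decay is fitted freely once per
   construct/batch; its component lifetimes *and* relative amplitudes are
   frozen as the *pattern*.
2. **Analysis.** Each FRET-sample ROI is fitted with the donor internals
   fixed to the pattern and a single additional FRET component. Two numbers
   come out: **BINDING** `B`, the relative pre-exponential amplitude of the
   FRET component (a molecule-fraction proxy, hence an affinity readout), and
   the **FRET efficiency** `E` (a proximity/orientation readout).

## The model

With pattern components `(tau_j, alpha_j)` (amplitudes normalised to 1), the
per-photon arrival density is

```
p(t)  ∝  (1 - B) * sum_j alpha_j exp(-t / tau_j)  +  B * exp(-t / tau_F),
tau_F = (1 - E) * tau_ref
```

convolved with the instrument response, integrated over each half-open time
bin, mixed with a time-uniform background fraction, and scaled to the photon
total. Counting noise in TCSPC is Poisson, so fitting maximises the Poisson
likelihood (equivalently minimises the deviance); the overall scale is
profiled out by matching the observed photon total. A weighted-least-squares
loss (variance `max(counts, 1)`) is retained behind `opa_options(loss =
"wls")` purely for cross-checks.

**Reference lifetime.** `E` compares the FRET component against the
unquenched donor. For a multi-exponential donor there is no single "donor
lifetime"; the amplitude-weighted mean `tau_m = sum alpha_j tau_j` is the one
number consistent with how the mean lifetime is defined and is the default
(`tau_ref = "weighted"`); the slowest component is available as
`tau_ref = "longest"`. The choice is recorded in every fit result
(`tau_ref_ns`).

**Bounds.** During fitting, `E` is constrained to 10–80%: below ~10% the
FRET component is indistinguishable from the donor itself, above ~80% it
collapses into the IRF. `B` is allowed down to −0.5: on donor-only data the
maximum-likelihood estimate of `B` scatters around zero, and clamping it at
zero would bias the null upward. Negative BINDING is therefore an expected
*fit artefact*, never a simulated truth. The background fraction is bounded
at 0.5.

**Cut-off.** When fitted BINDING falls below 10%, there are too few FRET
photons to localise `E`, which then drifts to the fit limits. Such
efficiencies are reported numerically but flagged `valid_efficiency = FALSE`,
and every downstream summary excludes them. The exclusion is *strictly
below*: `B = 0.10` exactly is valid.

### Why efficiencies of low-BINDING fits pile up at *both* limits

`B` is an amplitude fraction, so the FRET component's share of detected
photons is `B * tau_F / (B * tau_F + (1 - B) * tau_m)` — it shrinks as `E`
grows. A consequence worth knowing: at fixed `B`, the model's mean arrival
time is *not* monotone in `E`. It decreases up to roughly `E ≈ 0.6` (for the
reference pattern at `B = 0.3`) and then turns back towards the donor-only
value, because the ever-faster FRET component carries ever fewer photons.
Near `B ≈ 0` the likelihood is almost flat in `E` with weak minima at either
end — which is exactly why fitted efficiencies of no-FRET data accumulate at
the 10% and 80% bounds, and why the cut-off is needed at all. The package's
monotonicity test therefore covers the `E ≤ 0.55` range where the property
genuinely holds.

### The mono-exponential-donor comparison

`fit_mono_donor()` reproduces the classical analysis that ignores the
donor's fast component: the donor is collapsed to a *single* fixed lifetime
and the FRET component is fitted as usual. The collapse uses the pattern's
**longest** component by default. That choice is deliberate: an analyst who
believes the donor is mono-exponential describes it by its principal (slow)
lifetime, and the donor's fast component then has nowhere to go but the FRET
term — apparent BINDING inflates towards the fast component's amplitude
(~10% for the default pattern), producing false positives in a substantial
fraction of donor-only replicates. Collapsing to the amplitude-weighted mean
instead (`collapse = "weighted"`) produces a qualitatively different, less
instructive failure: the fixed donor is then *faster* than the true slow
component and the fit escapes into negative BINDING. Both collapses are
available; the default demonstrates the failure mode that motivates OPA.

## Calibration fits

`fit_multiexp()` fits 1–3 free exponentials plus background by the same
Poisson likelihood. Lifetimes are bounded in 0.05–10 ns, amplitudes
parameterised on the simplex (stick-breaking), initialisation from the mean
arrival time with geometrically spread starts. Two fitted lifetimes within 5%
of each other raise a degenerate-fit error recommending fewer components —
no automatic model selection is attempted; the reduced deviance is reported
so the user can choose. `aggregate_patterns()` pools several donor-only fits
by photon-weighted, rank-matched averaging; the intended calibration unit is
one pattern per donor construct per batch.

At 10^6 photons the short, low-amplitude component of the default pattern is
estimated essentially at its Cramér–Rao bound, with per-fit scatter on the
order of ten percent and a small positive finite-sample bias; tests of
3%-level recovery therefore run at 10^7 photons, where the bound is
comfortably inside that band.

## Numerical choices

- **Bin integration.** For delta excitation the per-bin photon mass is the
  exact analytic integral `alpha * tau * (exp(-t0/tau) - exp(-t1/tau))`. For
  a Gaussian IRF the model is the exponentially-modified Gaussian; its CDF is
  evaluated in a numerically stable form via the scaled complementary error
  function (`erfcx`), with an asymptotic series above the range where the
  library implementation overflows, so bins integrate exactly at any IRF
  width (a vanishing-width Gaussian reproduces delta excitation to < 1e-3).
  Empirical IRFs use discrete convolution on a 4x oversampled grid.
- **Tail fitting.** Without an IRF, fits start at the histogram peak
  (delta-excitation model from the peak bin's left edge); with an IRF,
  reconvolution over the full window. Both modes share all other machinery.
- **Optimiser.** Bounded L-BFGS-B from the best point of a 5x5 coarse grid
  over (B, E) — the multi-start matters precisely because of the flat-ridge
  geometry near `B = 0`. A restart from the returned optimum that cannot
  improve the objective is accepted as converged (the line-search
  occasionally aborts *at* the optimum). `opa_grid_search()` provides a
  brute-force cross-check of the same likelihood on a 0.005-step grid.
- **Guards.** Expected counts are floored at 1e-12 (negative densities are
  mathematically unreachable for `B >= -0.5` with `tau_F` below the slowest
  donor component, but the guard is kept defensive); histograms below 10^4
  photons error by default and can be admitted down to lower counts with a
  warning (`opa_options(min_photons = )`), reflecting low-count acquisitions.
- **Periodic excitation.** Wrap-around of incomplete decays is *not*
  modelled; a window shorter than 3x the slowest lifetime warns. The default
  grid is 250 bins of 50 ps (12.5 ns, a typical 80 MHz configuration).

## The simulator and what passing tests mean

`simulate_histogram()` draws from the exact model expectation —
multinomially (photon total exact) or Poisson per bin — through one seeded
generator that never touches the caller's RNG state. `simulate_flim_image()`
arranges elliptical nuclei with per-nucleus BINDING/efficiency, carves out
concentric nucleolus regions (labelled with the negative of the nucleus
label, excluded from pooling), can add short-lifetime plastid-like spots and
a uniform background, and returns the ground truth alongside. Per-nucleus
seeds derive from the master seed and the label, so ROIs are independently
reproducible.

Defaults mirror the studied conditions: donor pattern 3.0 ns / 1.2 ns at
amplitudes 0.9 / 0.1; FRET efficiencies inside the model's 10–80% limits;
2% uniform background where noise matters; 10^5–10^6 pooled photons per ROI
for the high-count regime and 10^3–10^4 for low-expression material. Fixture
problem sizes used throughout the tests (50 donor-only replicates at 5x10^5
photons; a 12-cell recovery grid at 10^6 photons, 10 seeds per cell; 48x48
two-nucleus scenes at ~10^5 photons per nucleus) keep every run deterministic
and fast.

The simulator emulates shot noise, IRF blur, uniform background and the ROI
geometry conventions — it does **not** emulate detector afterpulsing, dead
time, pile-up, autofluorescence spectra, bystander FRET from crowding, or
acceptor-channel decays (acceptor photons are carried only as a scalar
concentration proxy per ROI). Passing tests therefore demonstrate that the
estimator recovers what the model defines under ideal counting statistics;
they say nothing about instrument-specific artefacts in real recordings.

## Statistics conventions

Group comparisons use the tie-corrected Kruskal–Wallis H with its chi-squared
approximation, followed by Fisher's least-significant-difference criterion on
the rank means (Conover's pairing), *protected* by the omnibus test at the
same alpha (default 0.05) — no further multiple-testing correction by
default, with a Bonferroni-style switch intentionally left out of the default
path. Letters are the maximal cliques of the not-significantly-different
graph, so sharing a letter is exactly equivalent to a non-significant
pairwise difference; the report verifies this by construction. Efficiency
summaries are computed only over `valid_efficiency` results (SE uses the
sample SD over sqrt(n)); bleach pairs use the exact Wilcoxon signed-rank for
n ≤ 25 with the all-zero case reported as "no change, p = 1"; the
BINDING-vs-acceptor relation uses Spearman's rank correlation (Pearson via
argument).

## Known limitations

- A single collective FRET component: if the two donor sub-populations were
  quenched at distinct rates, one `tau_F` is a weighted compromise.
- ROI-pooled fitting only; no per-pixel BINDING maps.
- The fast-lifetime map is the uncorrected photon-weighted mean arrival time
  relative to an origin (default: the pooled-histogram peak); it is biased
  low by window truncation and is intended for display and pixel filtering,
  not for inference.
- 16-bit TIFF payloads bound per-pixel-per-bin counts at 65535; masks store
  signed labels offset-binary; the time axis travels in a JSON sidecar (or an
  explicit `bin_width_ns` argument).
- B and E are anti-correlated along a likelihood ridge (a slightly slower
  FRET component at higher amplitude mimics a faster one at lower amplitude);
  at photon totals of a few 10^4 this leaves sizeable scatter in single-ROI
  estimates, which should be read as distributions, not point values.
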