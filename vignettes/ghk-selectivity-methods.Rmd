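---
title: "Inferring ion selectivity from dilution-potential recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ion selectivity from dilution-potential recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghkselect)
```

## The scientific problem

Cys-loop ligand-gated ion channels can be anion- or cation-selective, and a
handful of pore-lining residues decides which. The standard way to measure
charge selectivity in whole-cell voltage clamp is the dilution-potential
experiment: record agonist-evoked currents at a ladder of holding potentials,
locate the reversal potential $E_{rev}$ (the zero-current potential), dilute
the NaCl on one side of the membrane, and watch which way $E_{rev}$ moves. A
chloride-selective channel follows the Cl$^-$ Nernst potential (depolarizing
shift on external dilution); a sodium-selective channel follows the Na$^+$
Nernst potential (hyperpolarizing shift). Intermediate selectivities land in
between, and the Goldman–Hodgkin–Katz (GHK) voltage equation interpolates
between the two Nernst limits with a single parameter, the permeability
ratio $P_{Cl}/P_{Na}$:

$$E_{rev} = \frac{RT}{F}\,
\ln\!\frac{P_{Na}\,(a_{Na})_o + P_{Cl}\,(a_{Cl})_i}
          {P_{Na}\,(a_{Na})_i + P_{Cl}\,(a_{Cl})_o}$$

with $(a)_o$ and $(a)_i$ the extracellular and intracellular activities.
Note the anion asymmetry — internal Cl$^-$ in the numerator, external in the
denominator — which is what lets one equation cover both charge classes.
$P_{Cl}/P_{Na} \gg 1$ marks an anion channel, $\ll 1$ a cation channel.

This package implements that analysis end to end for a tyramine-gated
channel studied in symmetric-NaCl dilution conditions, together with a
synthetic-recording generator so the whole chain can be exercised and
validated without biological data: measured reversal potentials from real
cells depend on liquid-junction potentials, seal quality and expression
levels and are not recomputable at a desk; the inference machinery is.

## Solution accounting

Solutions are salt recipes. Each salt carries an electroneutral
stoichiometry (CaCl$_2 \rightarrow$ {Ca$^{2+}$: 1, Cl$^-$: 2}) and per-ion
totals are stoichiometric sums. The built-in registry transcribes the
recording solutions used throughout: a K-rich pipette solution (I1) and
standard/low-Na$^+$/low-Cl$^-$ externals (ES1–ES3) for I-V experiments;
high-K$^+$ (ES4) and high-Ca$^{2+}$ (ES5) variants for the monovalent/
divalent analysis; and a NaCl pipette solution (I2) with a 145 / 72.5 /
36.25 mM NaCl external series for the dilution-potential experiments,
osmotically balanced with sucrose.

Three bookkeeping choices deserve a note:

* **Neutral species.** HEPES, glucose, sucrose, EGTA/BAPTA and the
  nucleotide additives are modelled as uncharged single species. Their
  protonation states are pH-dependent and unspecified; they are excluded
  from ionic strength. This slightly underestimates ionic strength (HEPES
  is partially deprotonated at pH 7.2) but by amounts that move Davies
  activity coefficients only in the third digit.
* **Titrants.** The NaOH used to set pH is not in the recipe totals (the
  amount is not stated); an explicit `titrant` argument exists for users
  who know it. The low-Cl$^-$ external is shipped in two variants because
  the printed recipe (45 mM Cl$^-$) and the printed one-line summary
  (30 mM Cl$^-$) disagree; the package takes no position on which was used
  and exposes both (`ES3_recipe`, `ES3_legend`).
* **Activities.** The fits default to activity = concentration (`unity`).
  The ratio-defining quantities are activity *ratios* across a NaCl
  dilution of otherwise near-identical solutions, where activity
  coefficients largely cancel; a Davies model
  ($\log_{10}\gamma = -A z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)$, $A = 0.509$)
  is available for sensitivity analysis and for plotting shift curves
  against Cl$^-$ activity rather than concentration. Switching models moves
  the x-coordinates of the dilution curve, not the measured shifts.

```{r solutions}
reg <- solution_registry()
c(ES1_Cl = ion_total(reg$ES1, "Cl"), ES2_Cl = ion_total(reg$ES2, "Cl"))
ionic_strength(reg$ES1)
```

## GHK machinery

Temperature defaults to 22 °C (room temperature, the only temperature the
experimental description mentions); $RT/F \approx 25.4$ mV is always
computed from the constants. Three computations are provided:

* `ghk_erev_two_ion()` — the closed-form two-ion voltage equation above.
  It depends on the permeabilities only through their ratio and reduces to
  the Na$^+$ (ratio $\to 0$) and Cl$^-$ (ratio $\to \infty$) Nernst
  potentials.
* `ghk_current_density()` — the constant-field flux equation per ion,
  $P z^2 \frac{VF^2}{RT}\frac{a_i - a_o e^{-zVF/RT}}{1 - e^{-zVF/RT}}$,
  summed over the channel's permeant ions. The removable singularity at
  $V = 0$ is patched with a series expansion of $u/(1-e^{-u})$ below
  $|u| = 10^{-4}$ (both branches agree to $\sim 10^{-10}$ relative there).
  Conventions: potential is inside minus outside, outward current positive.
* `ghk_erev_multi()` — the zero of the summed flux on $[-150, 150]$ mV by
  bracketing root search, for channels where divalents make a closed form
  unavailable. For monovalent channels it agrees with the closed form to
  well below 0.01 mV (tested on random draws).

Ca$^{2+}$ is handled through the $z^2$ flux term only. No bi-ionic divalent
voltage equation is attempted: the biological conclusion the analysis mirrors
is that Ca$^{2+}$ permeation is negligible, which appears here as "E$_{rev}$
is unchanged by a 1 → 25 mM external Ca$^{2+}$ swap when $P_{Ca} = 0$".

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` produces tidy sweep sets: per condition, per
replicate, per holding potential (−60…+60 mV in 20 mV steps), a 50 ms zero
baseline followed by a 250 ms agonist window. The waveform is the simplest
shape consistent with a desensitizing macrocurrent: an instantaneous (or
optionally linear-ramp) rise to the peak followed by a single-exponential
decay $I(t) = I_o e^{-t/\tau_d} + I_\infty$. The peak is the GHK flux at the
holding potential times a conductance scale times a per-replicate lognormal
amplitude factor (mean 1, CV 0.2 by default — whole-cell expression
variability; lognormal keeps peak signs consistent). Gaussian noise is added
per sample. Identical seeds give bit-identical output.

Defaults and their reasoning:

* `conductance_scale = 0.07` in the pipeline maps the wild-type-like
  channel's flux to ≈500 pA peaks at ±60 mV in the symmetric dilution
  condition — a typical whole-cell macrocurrent amplitude.
* `trace_sd = 5` (pA) is ~1 % of that peak, a clean but realistic recording.
* $\tau_d = 100$ ms and plateau fraction 0.3 are plausible for a
  desensitizing Cys-loop receptor but are *configuration values*: no kinetic
  constants are asserted, and the selectivity analysis is insensitive to
  them (it uses peaks, not kinetics).
* Replicates per condition default to 4–5, matching the replicate structure
  the analysis assumes.

The generator deliberately omits series-resistance and capacitance
artifacts, liquid-junction potentials, rundown, and state-dependent gating.
Passing tests on synthetic data therefore demonstrate that the *inference
chain* is correct and well-conditioned under the stated statistical
structure — not that any particular biological recording is free of those
confounds. In particular junction potentials, which offset absolute
$E_{rev}$, are the reason the fit targets *shifts* (see below).

## The analysis chain

**Peaks.** The peak is the signed extremum of baseline-subtracted current in
the agonist window (baseline = mean of all pre-agonist samples). Taking an
extremum of a noisy trace biases |peak| up by a fraction of the noise SD;
at 1 % noise this is negligible, and it cancels to first order in the
normalized I-V.

**Decay fits.** `fit_decay()` fits $I_o e^{-t/\tau_d} + I_\infty$ to the
post-peak segment (time re-zeroed at the peak) by `nls` (port algorithm)
with a `minpack.lm::nlsLM` fallback; starts come from the tail mean and a
log-linear slope. Constant traces are rejected as unidentifiable rather
than silently returning a plateau-only fit.

**Replicate QC.** The discard rule — an experiment is dropped when replicate
peak values differ by more than 80 % — is read as the maximum pairwise
relative difference $|p_i - p_j| / \max(|p_i|, |p_j|)$, the denominator
being the larger magnitude (the rule's denominator is not otherwise
defined); the threshold is configurable. At the experiment level the rule is
evaluated per holding potential but only where the mean |peak| is at least
half the condition's maximum: peaks recorded near $E_{rev}$ are
noise-dominated, and a relative-difference criterion applied to noise would
discard every experiment regardless of quality. A single replicate passes
vacuously (flagged); all-zero peaks are discarded as "no response".

**I-V curves and E$_{rev}$.** Per potential, the first three QC-passing
replicate peaks are averaged (order immaterial under exchangeability; fewer
available replicates are used and flagged), then all means are normalized to
$I_{max} = \max_V |\bar p(V)|$. $E_{rev}$ is located by linear interpolation
between the sign-change bracket; with several sign changes the pair nearest
0 mV is used and flagged. Averaging before normalizing versus after is
immaterial for $E_{rev}$ (both are positive rescalings). An optional local
quadratic refinement exists but is off by default — the 20 mV grid makes
linear interpolation err by well under 1.5 mV for these curves (≈0.4 mV at
the dilution conditions), and the simpler estimator is exactly reproducible.
This interpolation error is the dominant systematic in the full synthetic
chain: it maps to roughly ±10–20 % on the fitted ratio at $P_{Cl}/P_{Na}
\approx 19$, where the shift curve is already flattening toward the Nernst
limit. Analytic round-trip fits (below) are exact because they bypass the
grid.

**The permeability fit.** Dilution curves are $\Delta E_{rev} =
E_{rev}(\text{dilution}) - E_{rev}(\text{reference})$ against external
Cl$^-$ activity. Fitting shifts rather than absolute potentials removes any
additive offset common to all conditions (junction potentials, electrode
offsets). The fit minimizes squared shift residuals in $\log(P_{Cl}/P_{Na})$
— positivity for free, symmetry between the anion and cation regimes — by a
coarse 81-point grid over ratios $10^{-5}$…$10^{5}$ followed by Brent
polishing of the bracketing interval. On noiseless data the objective is
unimodal (verified by grid scan in the tests) and the grid-plus-polish
scheme is insensitive to the flat Nernst limits that defeat naive local
optimizers. Round trips recover generating ratios across
$[10^{-2}, 10^{2}]$ to better than $10^{-4}$ relative.

Uncertainty comes from a parametric bootstrap: shifts are resampled from
Gaussians with the per-point standard errors (or the residual RMSE when no
SEs are supplied), the reference's self-difference pinned at zero, and the
fit repeated (1000 resamples by default). In a seeded simulation with
1.5 mV E$_{rev}$ noise averaged over five experiments, empirical coverage of
the nominal 95 % interval is ≈90 % — the mild undercoverage expected from
three-point curves. When neither standard errors nor replication are
available the RMSE fallback can make the interval severely overconfident (a
one-parameter model can pass almost through three points); it should then be
read as fit precision, not accuracy. Classification uses configurable
thresholds, by default
anion-selective above 5 and cation-selective below 0.5, placing ratios near
18.8 and 0.19 on their respective sides with a wide margin.

**Monovalent/divalent shifts.** For the K$^+$/Ca$^{2+}$ analysis the
comparison is between multi-ion GHK reversal potentials in the low-Na$^+$,
high-K$^+$ and high-Ca$^{2+}$ externals against the K-rich pipette solution.
For a channel with $P_K = P_{Na}$ and $P_{Ca} = 0$, raising external K$^+$
depolarizes $E_{rev}$ by tens of mV while the Ca$^{2+}$ swap moves it by
less than 2 mV — the signature of a monovalent-cation channel. Monovalent
cations are pooled with equal permeability in K-rich conditions, the
standard treatment; the NaCl dilution fits use Na$^+$ alone, per the I2
recipe.

```{r shifts}
res <- run_shift_study(channel_model(c(Na = 1, K = 1, Ca = 0)))
round(unlist(res$erev), 2)
```

## Reproducibility and problem sizes

Every stochastic step is seeded; a master seed spawns per-stage substreams
(`derive_seeds()`), so a stored `pipeline_config()` reproduces every output
byte for byte, and output files carry a provenance block naming the config
hash and seed. The validation suite runs at deliberately modest sizes — 100
random draws for the closed-form/root-find equivalence, 25–50 Monte-Carlo
seeds for noisy recovery, 30 × 200 for bootstrap coverage, 3–5 replicates
per simulated condition — chosen so the whole suite completes in well under
a minute while keeping the Monte-Carlo error of each check far from its
pass margin.

## Known limitations

* The closed-form fit is two-ion (plus pooled monovalents); channels with
  genuinely mixed divalent permeation need the root-finding path and are
  only classified qualitatively.
* The 7-point, 20 mV protocol bounds $E_{rev}$ interpolation accuracy
  (≲1.5 mV) and hence full-chain ratio accuracy; finer protocols can be
  configured where tighter recovery matters.
* Activity handling ignores ion pairing and assumes a single global Davies
  model when enabled; at ionic strengths ≈0.15–0.17 M the Davies equation
  itself is an approximation.
* Absolute reversal potentials from biological recordings include junction
  potentials the package does not model; only shift-based quantities should
  be compared against it.
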