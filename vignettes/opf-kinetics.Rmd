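---
title: "Modelling oxidative protein folding kinetics with opfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidative protein folding kinetics with opfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opfkin)
```

## The system and the model

Disulfide-bonded secretory proteins are oxidized in the endoplasmic
reticulum by a short electron-transfer chain: substrate thiols (or, in the
reconstituted assay, glutathione) reduce protein disulfide isomerase
(Pdi1p); reduced Pdi1p is reoxidized by the ER oxidase Ero1p; Ero1p passes
the electrons via its FAD cofactor to molecular oxygen, producing hydrogen
peroxide.  A Clarke electrode reads the oxygen concentration of the assay
cell over time, so the whole pathway is observable as an O2-consumption
trace.

`opfkin` implements this chain as a mass-action reaction network over
thirteen species.  Pdi1p is modelled with a single catalytic site in three
states: active-site disulfide (`PDI_ox`), glutathionylated intermediate
(`PDI_mix`) and dithiol (`PDI_red`).  Ero1p occupies four states: both
regulatory disulfides intact and hence inactive (`ERO_rr`), one regulatory
disulfide reduced (`ERO_r1`), and the activated enzyme with its active site
oxidized (`ERO_act_ox`) or reduced (`ERO_act_red`).  The reactions are:

* **Activation** (`ka1`, `ka2`): two sequential reductions of the Ero1p
  regulatory disulfides by reduced Pdi1p.  This step produces the lag phase
  seen at the start of every assay.  Reduction is irreversible in the
  model; there is no re-oxidation of regulatory disulfides.  A
  configuration switch (`gsh_activation`) makes glutathione the activating
  reductant instead; the default uses reduced Pdi1p, reflecting the
  biochemical evidence that the regulatory disulfides are made and broken
  by PDI.
* **Catalytic exchange** (`kox`): reduced Pdi1p reduces the active site of
  activated, oxidized Ero1p.
* **Terminal oxidation** (`k1`): reduced, activated Ero1p reacts with O2 to
  form H2O2.  In reality a multi-step flavin reaction; modelled as a single
  fast step.
* **Glutathione reduction of Pdi1p** (`kg`, twice): two chemically similar
  sequential steps through the glutathionylated intermediate, assumed to
  share one rate constant.
* **DTT branch** (`kdtt`): in Pdi1p-free calibration assays DTT reduces any
  Ero1p disulfide with a common rate.
* **Electrode-cell O2 exchange** (`kdiff`): the open assay cell exchanges
  oxygen with the environment with first-order kinetics toward `o2_sat`.

Hydrogen peroxide is an inert accumulating product: a peroxide/Pdi1p
inhibition reaction was considered during model development in the
literature this network follows, found to leave the behaviour unchanged,
and is not part of the network.

Units are microMolar and seconds everywhere; 40 mM glutathione enters as
40000 uM.  `o2_sat` defaults to 258 uM, the air-saturation level of water
near 25 degrees C; it is a configurable physical constant, not a fitted
one.

## Simulation

`opf_simulate()` integrates the network with `deSolve::lsoda` (compiled
right-hand side, relative tolerance 1e-8, absolute tolerance 1e-10 uM).
Reagent additions mid-run -- the Ero1p injection that starts a GSH assay at
100 s, or the DTT injection of a calibration assay -- are handled by
stopping the integrator at the event time, incrementing the injected
species and restarting; output grids never interpolate across an event.
Conservation of the Pdi1p pool, the Ero1p pool and the glutathione moieties
holds to better than 1e-9 relative at every output point, and an explicit
electron ledger (`electron_balance()`) checks that thiol equivalents plus
two per accumulated peroxide stay constant.

```{r simulate}
cond <- gsh_assay_conditions(pdi = 5, ero = 1)   # 40 mM GSH, Ero1p at 100 s
traj <- opf_simulate(cond, opf_constants())
max_consumption_rate(trajectory_trace(traj))
```

## Trace statistics

Measured and simulated traces share one summary pipeline:
`strip_baseline()` removes the 100-s stabilisation period and re-zeroes
time; `windowed_rate()` estimates the consumption rate as minus the
least-squares slope of O2 against time in a 10-s window sliding one sample
at a time; `max_consumption_rate()` reports its maximum.  Sliding
least-squares windows (rather than endpoint differences or disjoint bins)
are robust to the additive electrode noise and add no smoothing of their
own, which would silently bias maximum rates.  For a symmetric window the
estimator is exact for quadratic traces at the window centre.

## Calibration and fitting

Fitting every constant to GSH-assay traces alone leaves the model
underdetermined, so two constants are calibrated from dedicated
experiments and then fixed:

* `calibrate_diffusion()` fits `O2(t) = O2_sat (1 - exp(-kdiff t))` to a
  dithionite depletion/recovery trace of the open cell.
* `calibrate_ero1_dtt()` jointly estimates `k1` and `kdtt` from a DTT
  titration series (Ero1p and DTT only), by Nelder-Mead least squares in
  log space.

`opf_fit()` then estimates the free constants (`kox`, `ka1`, `ka2`, `kg`)
by minimising the unweighted sum of squared O2 deviations over all
experiments of a titration series, after the baseline cut, with the model
evaluated directly on each trace's time grid.  The search is a seeded
differential evolution in log10-parameter space (bounds 1e-8 to 1e3 for
the second-order constants, population 24 by default, per-generation
dithering of the differential weight) followed by a Nelder-Mead polish;
a repeat stops when the relative objective improvement stays below 1e-8
for 50 generations or after 20000 evaluations.  The whole search is
repeated ten times from independent random starts (repeat r seeds the RNG
with `seed + r`), results are ranked by average per-experiment RMSD, and
the per-constant spread across repeats is the identifiability diagnostic:
a constant the data constrain lands in a narrow range every time, an
unconstrained one scatters.  With 40 mM glutathione the Pdi1p reduction
steps are far from rate limiting, so `kg` is exactly such an unconstrained
constant -- repeats agree on the objective while disagreeing on `kg` by
orders of magnitude.  No weighting is applied across experiments, and no
confidence intervals are computed: the repeat-to-repeat spread stands in
for them.

## Default constants

The deposited parameterisation of this network is not redistributable with
the package, so the defaults of `opf_constants()` were calibrated once
against the published in vitro observables of the yeast system and then
frozen:

* `k1 = 0.005814` per uM per s, so that the terminal reaction ceiling
  `k1 * 258 uM * [Ero1p]` equals the observed saturating maximum of
  ~1.5 uM O2/s per uM Ero1p;
* `kdtt = 1.82e-4`, so that the default DTT assay (1 uM Ero1p, 10 mM DTT)
  yields the observed maximal 0.8 uM O2 per uM Ero1p per second through
  the windowed-rate extractor;
* `kox = 1.41` and `ka1 = ka2 = 0.02`, jointly reproducing the predicted
  1.4-fold capacity gain of 10x Pdi1p overexpression at the 5 uM Pdi1p /
  1 uM Ero1p / 40 mM GSH reference condition, with a visible activation
  lag of a few tens of seconds;
* `kg = 0.001` -- deliberately arbitrary within its unidentifiable range
  (at 40 mM GSH any value above ~1e-4 gives indistinguishable traces);
* `kdiff = 0.002` per s, a slow exchange typical of a stirred, nominally
  closed electrode cell; `o2_sat = 258` uM.

The two activation constants are set equal: the activation lag constrains
their symmetric combination, and with a shared true value the pair is
recoverable without the label-swapping ambiguity two unequal sequential
steps would have.

## The in vivo calculus

`molecules_to_concentration()` converts reported copy numbers (28,000
Pdi1p, 5,200 Ero1p per cell) into ER concentrations; with the default ER
volume of 0.3 um^3 -- the midpoint of the reported 0.2-0.4 um^3 range and
the one volume consistent with both printed concentrations (155 and
29 uM) -- `k_cys()` evaluates the proteome-wide demand

k_Cys = sum_i A_i * floor(Cys_i / 2) * (k_i + ln 2 / t_d),

the number of disulfide bonds per minute needed to balance degradation and
growth dilution (doubling time 120 min by default).  Odd cysteines cannot
pair, hence the floor; the estimate is an upper bound because it assumes
every pair is enzymatically oxidized.  `pdi_capacity()` gives the supply
side, copies times ~15 bonds/min/molecule, reported additionally at one
significant figure.  `predict_overexpression()` scales the Pdi1p or Ero1p
total of the reference assay by a fold grid, re-simulates, and reads
capacity off as the maximum windowed consumption rate (one O2 consumed is
one disulfide formed); curves are normalised to fold 1.  Whether capacity
should instead be a cumulative O2 consumption over a horizon is a genuine
design fork; the maximum rate was chosen because it is the same statistic
the titration figures report.  The in vitro reference concentrations
(5/1 uM) are the default baseline; the in vivo pair (155/29 uM) can be
passed as `base_conditions`.

## Synthetic data

Every input of the pipeline can be generated from known ground truth:
`generate_trace()` adds seeded iid Gaussian noise (default sd 1 uM -- a
placeholder magnitude, since true electrode noise is not reported -- plus
optional linear drift, no autocorrelation) to simulated traces;
`generate_titration_series()` produces the three titration designs with
their canonical grids; `generate_proteome()` samples log-normal abundances
(median 1000 molecules/cell, sdlog 1.5), Poisson cysteine counts (mean 5)
and log-normal half-lives (median 300 min, sdlog 0.8) for 4000 proteins.
Those proteome defaults were chosen once so that the synthetic secretory
proteome's demand lands at the order of magnitude of the published
~269,000 cystines/min estimate; they emulate the shape of real abundance
and turnover distributions, not any measured proteome, and conclusions
about real cells should rest on a real table read with
`read_proteome()`.

What passing tests on synthetic data do show: the estimator recovers known
constants from noise-free and noisy traces, the identifiability contrast
is reproduced, and conservation laws hold.  What they cannot show: that
the network is the true mechanism, that electrode noise is Gaussian and
uncorrelated, or that the in vivo extrapolation holds beyond its stated
assumptions.

## Numerical choices and problem sizes

Stiff-capable `lsoda` with rtol 1e-8 / atol 1e-10; tiny negative
excursions (within 1000x the absolute tolerance) are clamped to zero and
anything worse is an error.  During the global search the solver runs at
rtol 1e-6 / atol 1e-8 for speed; all reported RMSDs are re-evaluated at
the tight tolerances.  Ties in the RMSD ranking break by repeat index.
The test suite exercises the fitting protocol on reduced problem sizes --
three-trace titrations of 300 s at 2-s sampling with per-repeat budgets of
a few thousand objective evaluations -- which recover the identifiable
constants to well under the tolerances asserted; the full 900-s,
six-trace, 10-repeat protocol is the documented default for real data.

## Limitations

One Pdi1p active site (no isomerase load), no pH dependence, no explicit
protein substrate species (glutathione is the electron source), no
peroxide chemistry downstream of H2O2, irreversible activation.  The
capacity calculus treats every O2 reduction as one productive disulfide
and ignores futile cycling and isomerisation, so supply figures are upper
bounds in the same spirit as the demand figure.
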