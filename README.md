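# opfkin

Kinetic modelling of the yeast oxidative protein folding (OPF) pathway.

Secretory proteins acquire their disulfide bonds in the endoplasmic
reticulum through a short electron-transfer chain: substrate thiols (or
glutathione, in the reconstituted assay) reduce protein disulfide
isomerase (Pdi1p); reduced Pdi1p is reoxidized by the ER oxidase Ero1p;
Ero1p hands the electrons via its FAD cofactor to molecular oxygen,
yielding H₂O₂.  In a Clarke electrode cell the whole chain is observable
as an O₂-consumption trace.  `opfkin` is for biochemists and systems
biologists who want to simulate those assays, extract rate statistics from
measured traces, fit the network's rate constants, and translate the in
vitro kinetics into whole-cell supply/demand estimates.

The core is a mass-action ODE model over 13 species.  Ero1p activation
(sequential reduction of two regulatory disulfides by reduced Pdi1p, rate
constants `ka1`, `ka2`) produces the lag phase of every assay; the
catalytic cycle is `PDI_red + ERO_act_ox → PDI_ox + ERO_act_red` (`kox`)
and `ERO_act_red + O₂ → ERO_act_ox + H₂O₂` (`k1`); oxidized Pdi1p is
re-reduced by two identical-rate glutathione steps (`kg`) through a
glutathionylated intermediate; a DTT branch (`kdtt`) drives Ero1p in
Pdi1p-free calibration assays; and the open cell exchanges O₂ with the
environment (`kdiff`, saturation `o2_sat`).

On the in vivo side, the proteome-wide disulfide demand is

    k_Cys = Σᵢ Aᵢ · ⌊Cysᵢ/2⌋ · (kᵢ + ln2/t_d)

(abundance × pairable cysteines × turnover-plus-dilution), compared with
the Pdi1p supply capacity (copies × per-molecule rate).

## Worked example

```r
library(opfkin)

k <- opf_constants()               # calibrated default rate constants

# the reference GSH-driven assay: 5 uM Pdi1p, 40 mM GSH, 1 uM Ero1p
# injected after the 100-s baseline
cond <- gsh_assay_conditions(pdi = 5, ero = 1)
traj <- opf_simulate(cond, k)
max_consumption_rate(trajectory_trace(traj))
#> [1] 0.9871894

# DTT-driven Ero1p calibration assay: 1 uM Ero1p, 10 mM DTT
dtt <- generate_trace(k, dtt_assay_conditions(ero = 1, dtt_mM = 10),
                      noise_spec(sd = 0))
max_consumption_rate(dtt)
#> [1] 0.8000813

# predicted capacity gain on overexpression
predict_overexpression(k, folds = c(1, 2, 10), scan = "pdi")
#>   fold capacity_uM_s fold_change
#> 1    1     0.9871894    1.000000
#> 2    2     1.1669423    1.182086
#> 3   10     1.3822870    1.400225
```

The first number is the maximal O₂-consumption rate (µM/s) of the
reference assay, read off with a 10-s sliding least-squares window after
the baseline cut.  The DTT assay reproduces the observed 0.8 µM O₂ per µM
Ero1p per second.  The overexpression table says a 10-fold increase in
Pdi1p raises pathway capacity only 1.4-fold (Ero1p, not Pdi1p, is the
bottleneck at the reference stoichiometry; a 10× Ero1p scan more than
doubles capacity).

Fitting works from an experiment set (measured or synthetic):

```r
exps <- generate_titration_series(k, "pdi_scan", noise_spec(sd = 1, seed = 1))
fit  <- opf_fit(exps, n_repeats = 10, seed = 1)
summary(fit)     # per-constant spread across repeats = identifiability
coef(fit)        # rank-1 (lowest average RMSD) constants
```

The in vivo calculus:

```r
round(molecules_to_concentration(c(28000, 5200), 0.3))  # 155, 29 uM
pdi_capacity(cell_parameters())$rounded                  # 4e+05 bonds/min
prot <- generate_proteome(proteome_config(seed = 1))     # or read_proteome()
capacity_report(prot)
```

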