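# pdzavidity

Kinetic modelling and assay analysis for bivalent scaffold–receptor binding
on cell membranes.

PDZ-domain scaffold proteins such as the PICK1 dimer carry two identical
binding domains. When such a homobivalent ligand ("aa") meets a pair of
identical membrane-embedded target sites ("AA"), the apparent binding
strength measured on supported cell membrane sheets can exceed the intrinsic
single-domain affinity by orders of magnitude — the avidity effect. This
package implements the mass-action kinetic model of that process together
with the full analysis stack used around such experiments: sigmoidal
saturation and competition fits, association and one-/two-phase dissociation
fits with AICc model comparison, fluorescence-polarization (FP) binding
models, and quantification of two-channel microscopy ROI intensities with
labeling-degree, background and PMT-gain corrections. A synthetic-data
module generates every input class with known ground truth, so the whole
pipeline can be validated without any external data.

## The model

A target pair populates four occupancy states: free (**U**), singly bound
(**G**, pooled AAaa + aaAA), bivalently bound (**R**, aAAa) and the ternary
complex with two singly bound ligands (**B**, aaAAaa). With bulk ligand
concentration [aa] held constant (ligand excess) the scheme is

```
dU/dt = −s1·k1·[aa]·U + k_off·G
dG/dt =  s1·k1·[aa]·U − k_off·G − k2·G + s2·k_off·R − s3·k1·[aa]·G + s4·k_off·B
dR/dt =  k2·G − s2·k_off·R
dB/dt =  s3·k1·[aa]·G − s4·k_off·B
```

where `k1` and `k_off` are the intrinsic association and dissociation rate
constants and `k2 = k1·[L]/f` is the composite first-order rate of
intramolecular closure: the still-free second domain of a singly bound
ligand sees its target at the local concentration `[L]` of one molecule in a
half-sphere of the inter-domain reach radius `r`, reduced by a penalty
factor `f` for steric hindrance, restricted rotation and entropic cost.
`s1..s4` are the statistical factors (path multiplicities) of the pooled
formulation; see the methods vignette for the shipped convention. The
bound-ligand readout per target pair is `G + R + 2B` (each ternary complex
carries two ligands); a complex-count alternative `G + R + B` is available.

For the PICK1 parameter set (`k1 = 1.85e5 M⁻¹min⁻¹`, `k_off = 0.0085
min⁻¹`, `r = 180 Å`, `f = 185`) this gives `[L] = 136 µM`, `k2 = 0.136
min⁻¹` and an intrinsic Kd of 45.9 nM.

## Worked example

```r
library(pdzavidity)

p <- pick1_parameters()
p
#> Homobivalent binding rate parameters
#>   k1     = 1.85e+05 M^-1 min^-1   (intrinsic association)
#>   k_off  = 0.0085 min^-1        (intrinsic dissociation)
#>   r      = 180 angstrom      (inter-domain reach)
#>   f      = 185               (penalty factor)
#>   [L]    = 0.000136 M             (local concentration)
#>   k2     = 0.136 min^-1        (composite rebinding)
#>   Kd_int = 4.595e-08 M             (k_off / k1)
#>   statistical factors (s1..s4): 2, 2, 2, 1

# 120-min saturation curve on a 1-1000 nM log grid, variable-slope fit
sat <- simulate_saturation_curve(p, 10^seq(0, 3, length.out = 12) * 1e-9)
fit <- fit_dose_response(data.frame(conc = sat$conc, signal = sat$total_signal),
                         variable_slope = TRUE)
fit$derived$ec50 * 1e9
#> [1] 48.62590
```

The simulated curve is half-maximal near 50 nM even though the intrinsic
single-domain Kd is 45.9 nM and the bivalent complex is much longer-lived —
the avidity gain shows up in the shallow, biphasic shape (fitted Hill slope
0.84) rather than a large EC50 shift. The concentration at which the
two-ligand ternary complex overtakes the bivalent one:

```r
find_species_crossover(p) * 1e9
#> [1] 226.0091
```

Washout (dissociation) behaviour depends on the pre-incubation
concentration. After 120 min at 200 nM the ternary complex is populated and
its fast single-bond unbinding produces a distinct fast phase:

```r
wash <- gen_mechanistic(p, mode = "washout", preincubation_conc = 200e-9,
                        seed = 1)
compare_decay_models(wash)
#> Dissociation model comparison (AICc)
#>   one-phase AICc = -131.14
#>   two-phase AICc = -140.79
#>   delta AICc (one - two) = 9.65
#>   preferred: two-phase
```

At 20 nM pre-incubation the ternary pool is marginal and the same comparison
prefers a single slow phase.

Empirical assay fits work the same way on real tables
(`read_dose_table()`, `read_timecourse_table()`, `read_fp_table()`,
`read_roi_table()` define the CSV dialects), e.g. FP competition:

```r
d <- gen_fp("competition", kd = 9e-6, ki = 2.1e-6, noise_sd = 0)
fit_fp_competition(d, rt = attr(d, "truth")$rt, kd = 9e-6)$derived$ki
#> [1] 2.1e-06
```

A thin command-line front-end over the pipeline functions
(`run_simulate()`, `run_fit()`, `run_quantify()`) ships in
`inst/cli/pdzavidity.R`.

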