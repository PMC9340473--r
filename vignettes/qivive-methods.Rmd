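---
title: "Models and methods behind qivive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qivive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qivive)
library(dplyr)
```

qivive implements quantitative in vitro to in vivo extrapolation (QIVIVE):
given a concentration measured (or derived) in an in vitro test system, find
the external human dose that produces the matching internal exposure, using a
physiologically based kinetic (PBK) model parameterized as far as possible
from in vitro and in silico inputs. This vignette explains the models, their
assumptions, the tunable parameters, and the design choices made where the
methodology left genuine freedom.

## The PBK model

The whole-body model is a mass-balance ODE system over anatomically defined
compartments connected by blood flow. The circulation is closed: venous blood
passes through the lung to arterial blood, arterial blood perfuses the
tissues, tissue outflows collect in the venous pool. The gut drains through
the portal vein into the liver, which is the only eliminating organ; oral
absorption is first order from a gut-lumen depot into the portal inflow.

For a flow-limited (well-stirred) tissue with volume $V_t$, blood flow $Q_t$
and tissue:blood partition coefficient $K_{p,t}$,

$$V_t \frac{dC_t}{dt} = Q_t \left(C_{art} - \frac{C_t}{K_{p,t}}\right).$$

A permeability-limited tissue is split into a vascular and an extravascular
sub-compartment separated by a diffusional barrier with permeability–surface
area product $PS$; exchange follows the unbound gradient
$PS\,(fu_{plasma} C_{vas} - fu_{tissue} C_{tis})$. In the limit
$PS \to \infty$ this reduces to a flow-limited tissue with
$K_p = fu_{plasma}/fu_{tissue}$, a property the test suite checks
numerically.

Hepatic elimination is either a constant clearance ($CL \cdot C$) or
Michaelis–Menten kinetics
$V_{max} C / (K_m (1 + I/K_i) + C)$ with optional competitive product
inhibition. The concentration driving elimination is configurable: the liver
venous-equilibrium concentration $C_{liver}/K_p$ (the conventional
well-stirred choice and the default), the total tissue concentration, or the
unbound tissue concentration (for permeability-limited livers). With a
flow-limited liver the model produces well-stirred extraction behaviour
automatically: an intrinsic clearance far above hepatic blood flow yields an
effective clearance capped near $Q_h$, and `build_model()` warns when
$CL > Q_h$ rather than erroring, since nothing in the mathematics breaks.

**Numerics.** States are compartment amounts in mg, so repeated doses are
additive solver events (the integrator restarts at dose times, avoiding
discontinuity artefacts). Integration uses a stiff-capable solver (`lsoda`)
at relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ mg. The
default output grid is 0.1 h, refined to 0.01 h for half an hour after each
dose. Mass balance (administered = in body + eliminated + unabsorbed) is
audited at every output time; the suite requires agreement within 0.5% and
the solver typically delivers $10^{-10}$.

**Physiology.** Reference parameter tables (ICRP-style adult male, 70 kg,
cardiac output 390 L/h; adult female, 60 kg, 354 L/h) ship as delimited text
in `inst/extdata`. Organ blood flows sum exactly to cardiac output, with a
lumped `rest` compartment carrying the residual, so venous return always
equals cardiac output. The liver entry carries the microsomal scaling
factors: MPPGL 32 mg microsomal protein per g liver and liver mass 1493 g
(male) — values chosen so the packaged scaling conventions reproduce the
standard organ-clearance arithmetic for the worked antiarrhythmic example
(4.12 nmol/h/mg over 38.85 µM scales to 5.07 L/h).

**Pregnancy.** `apply_pregnancy()` extends the adult female physiology to
the end of the first trimester: +40% blood-pool volume, +20% cardiac output,
and a 0.05 L flow-limited fetal compartment perfused at 2 L/h with a
fetal:maternal partition coefficient of 1.46. The partition default was
back-derived from published paired maternal/fetal chlorpyrifos
concentrations (e.g. 10.7/7.33 ng/mL); the volume and output increments are
standard early-pregnancy physiology. All are overridable. The extension
never decreases total distribution volume, which is why a single oral dose
yields a lower maternal Cmax in the pregnant model.

## Partition coefficients

Two routes provide tissue:blood partition coefficients $K_p$.

*Empirical*: `kp_from_in_vitro()` is simply the cell-lysate:medium
concentration ratio at near-steady state. Note that under ongoing metabolism
the observed ratio is $K_p/(1 + CL \cdot K_p / CL_{ex})$, slightly below the
thermodynamic value; the synthetic generator defaults to exchange fast
relative to metabolism so the readout recovers the configured $K_p$ within
2%.

*Mechanistic*: `predict_kp_schmitt()` is a composition-based algorithm in
the tradition of tissue-composition predictors. A tissue's capacity per unit
of unbound neutral compound in plasma water sums four contributions —
tissue water (all ionization species, Henderson–Hasselbalch at
intracellular pH 7.0), neutral lipid (neutral species, affinity
$10^{\log P}$), phospholipid membranes (both species, affinity from the
membrane-affinity regression $\log MA = 0.81 \log P + 0.98$) and tissue
protein (both species, an association constant per ionization class: 3700
for acids, 200 for bases, 60 for neutrals — acids bind albumin-like
intracellular and interstitial proteins far more strongly). The blood-side
denominator is the aqueous capacity of plasma at pH 7.4 divided by the
unbound fraction, so **predicted $K_p$ is proportional to $fu$**: lowering
the protein content of the matrix (as in protein-free culture medium) raises
the predicted cell:matrix partition, the behaviour that explains why in
vitro partition ratios exceed in vivo ones for highly bound drugs. The acid
protein-association constant was fixed once against hepatic tissue
distribution of an acidic NSAID (predicted liver $K_p \approx 3.0$ at
$fu = 0.01$, near the post-mortem liver:blood ratio of 2.7) and is not a
per-compound tuning knob. Composition fractions for ten tissues ship as
delimited text. Red-cell partitioning is neglected (blood:plasma ratio 1),
so tissue:plasma and tissue:blood coincide unless overridden.

The algorithm's known limitations: affinities grow as powers of $\log P$,
so for very lipophilic compounds ($\log P > 5$) predicted adipose and liver
$K_p$ become large and should be treated as order-of-magnitude; for such
compounds (the antiarrhythmic case) the case configurations use explicit
stand-in partition sets rather than predictions, and only ratio properties
are asserted.

## Clearance scaling

`scale_intrinsic_clearance()` converts microsomal parameters to organ
intrinsic clearance by exact unit reduction:
$(V_{max}/K_m)\,[\mathrm{mL/h/mg}] \times MPPGL\,[\mathrm{mg/g}] \times
M_{liver}\,[\mathrm{g}] / 1000$. Vmax unit tags (`nmol/h/mg` vs
`nmol/min/mg`) are mandatory — per-minute and per-hour rates differ by a
factor of 60 and are never guessed. Multiple pathways sum.

## Reverse dosimetry

`optimize_dose()` searches dose space so that the simulated exposure matches
a target: a full concentration–time profile (objective = sum of squared
differences at the target's own sampling times, the simulation interpolated
onto them, never the reverse) or a scalar AUC/Cmax over a window (objective
= absolute difference). The search mirrors fixed-increment iterative dose
finding: coarse grids narrow hierarchically until the user-stated dose step
is reached, and the final grid is aligned to multiples of that step (10 mg
for the hepatotoxicity case, 0.01 mg for the neurotoxicity case). Ties at
equal objective break toward the lower dose — the conservative choice — with
a warning. Default bounds are $[0, 100\,d_1]$, where $d_1$ is a first guess
from the linear relation between dose and the target metric at a probe dose.
Under linear kinetics the machinery is exact: a forward-simulated exposure
is recovered to within one grid step, and optimized dose is proportional to
the target AUC (the property behind comparing dose pairs for AUC targets of
1.00 and 1.99 µg·h/mL, whose ratio must be 1.99).

`concentration_response_to_dose_response()` re-indexes an in vitro
concentration–response table on the per-concentration optimized doses; the
mapping must be monotone (it always is under linear kinetics) and the
response columns are untouched, so response ordering is preserved.

## Benchmark-dose modeling

`fit_bmd()` handles continuous summary data (per-group mean, SD, n) by
maximum likelihood under normal residuals with a single residual SD
estimated jointly; a lognormal option transforms the summary statistics for
strictly positive endpoints. Families are a 3-parameter exponential
$a e^{bx}$, a 4-parameter Hill, and a linear model; when several are
requested the best AIC wins (no model averaging in this version — a
documented simplification relative to full model-averaging practice).

The benchmark response is an effect size of `bmr_factor` (default 1)
standard deviations of the background response, on the adverse direction;
the BMD solves $|f(BMD) - f(0)| = BMR \cdot \sigma$. Because the ML residual
SD is biased low in small samples (the curve's parameters are unaccounted),
the SD defining the BMR is the degrees-of-freedom-corrected
$\hat\sigma\sqrt{N/(N-p)}$; without this correction a simulation study
showed the profile interval covering the true BMD only ~86% of the time at
nominal 90%, with the misses concentrated above the upper bound, and with it
coverage sits at 88–91% with balanced misses (`bmd_coverage_study()`
reproduces this: 500 replicate datasets, 5 groups of 6, exponential truth).

BMDL and BMDU are the two-sided 90% profile-likelihood bounds (level
configurable): for a candidate BMD value the remaining curve parameters are
re-optimized with the residual SD tied to the curve through the BMR
definition, and the bounds are where the constrained deviance exceeds the
minimum by $\chi^2_{1,0.90}$. Degenerate inputs fail loudly: a flat fitted
response or a benchmark response not reached within 10× the highest dose is
"BMD not identifiable"; a BMD above the tested range is returned but flagged
as extrapolated. `assess_bmd_quality()` reports the BMDU/BMDL ratio
(default acceptability ≤ 50) and the BMDL's distance below the lowest tested
dose (default ≥ 1/10), the two diagnostics used to decide whether an
endpoint's interval is usable.

## The synthetic-data generator

No laboratory datasets ship with the package; the generator emulates the two
data shapes the pipeline consumes.

*Biokinetic time courses* (`simulate_in_vitro()`): a medium and a cell
compartment exchanging at clearance $CL_{ex}$ toward the equilibrium ratio
$K_p \cdot fu_{medium}$, with intracellular metabolic loss (linear or
Michaelis–Menten). Re-dosing every 24 h for 14 days emulates full medium
replacement: the medium amount resets to the nominal dose while
cell-associated amounts persist — the replacement protocol is a documented
choice, configurable, since published protocols rarely state it. With a
product-inhibition constant on the metabolic parameters the accumulating
metabolite competitively inhibits the parent's metabolism, reproducing the
phenomenon where a hepatocyte culture's apparent clearance collapses between
day 1 and day 14 (with $K_i$ = 12.1 µM the packaged scenario shows a
day-14:day-1 depletion-rate ratio of ~0.13). Default sampling uses a
0.25 h grid; the exchange default $CL_{ex} = 10\,V_{cell}K_p$ equilibrates
in well under 1 h, consistent with reported near-partition-equilibrium
ratios. Mass is conserved to solver accuracy (dose in = medium + cells +
metabolized + discarded medium).

*Dose–response tables* (`generate_dose_response()`): group means are the
true curve plus normal error with standard error $\sigma/\sqrt{n}$, and
group SDs are drawn from the scaled chi-square sampling distribution of a
sample SD — exactly the summary-data structure the BMD likelihood assumes.
The design true BMD travels in an attribute for recovery and coverage
studies. Measurement noise (`add_noise()`) is mean-unbiased multiplicative
lognormal at a stated CV, reproducible under a fixed seed.

What the generator does **not** emulate: binding kinetics to plastic and
serum constituents, cytotoxicity feedback on metabolic capacity, metabolite
disposition beyond a single inhibitory species, and inter-well variability.
Passing tests therefore demonstrate the pipeline's internal consistency and
statistical calibration, not the fidelity of any particular laboratory
system.

## Case studies and problem sizes

`run_case_study()` chains the modules for three scenarios: an NSAID
hepatotoxicity case (8-organ flow-limited model, profile-matching reverse
dosimetry at 10 mg steps), an antiarrhythmic case split into a liver part
(clearance scaling, in vitro product inhibition) and a brain part
(permeability-limited liver, AUC-target reverse dosimetry at 0.01 mg steps,
BMD on a translated dose–response, nominal-concentration corrections), and
an organophosphate pregnancy case (pregnant model, fetal:maternal ratio
under sustained exposure, margin between converted in vitro BMDUs and
simulated fetal concentrations). Report rows label each quantity
`reproducible`, `ratio_only`, `qualitative` or `context`; context anchors
are printed benchmark values whose recomputation would require unpublished
raw data (e.g. absolute optimized doses for the brain case, which depend on
a rodent-derived permeability parameter set that was never printed — the
shipped partition set is an explicitly labelled synthetic stand-in, and only
the dose ratio is asserted).

Problem sizes are desk scale by design: 24–48 h simulated spans for
dose-finding, a 240 h sustained-exposure run for the fetal ratio, 500
replicates for the BMD coverage study, and grid-search traces of 60–250
model evaluations. The dimensionally unusual "multiply by 100/fu" binding
correction used in one published dose conversion is reproduced as printed
(its downstream benchmark depends on it), with the conventional `dose/fu`
available behind an explicit option.

```{r example, eval = FALSE}
# the pregnancy case end to end
run_case_study("cpf")
```

## Known limitations

- No lymphatic, biliary or enterohepatic recirculation; no metabolite PBK
  sub-model (metabolites appear only as in vitro inhibitor/readout).
- No population variability: physiology is a fixed reference individual.
- The mechanistic partition algorithm is calibrated for moderately
  lipophilic ionizable drugs; very lipophilic compounds need measured or
  stand-in partition sets.
- The intestinal model is a one-parameter first-order absorption (`ka`
  either given or derived from effective permeability via
  $k_a = 2 P_{eff}/r$ with r = 1.75 cm); no transit or dissolution model.
- BMD model averaging is not implemented; families are compared by AIC.
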