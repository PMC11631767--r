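---
title: "Models and methods in lockrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lockrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lockrtools is a desk-scale toolkit for the computational side of LOCKR
biosensor engineering: an equilibrium model of the two-component switch and
its mutational tuning, enumeration of sensing-motif placements in the latch
helix, and the quantification procedures used on the readout side —
ratiometric FRET timecourses, puncta and co-localization statistics, and
proximity-labeling proteomics tables. This vignette records the models, the
conventions, and the design choices made where the procedures are commonly
described only informally.

## The five-state switch model

A LOCKR sensor has two components: a **Cage** whose groove is occupied by
its own **latch** (with a target-binding domain, TBD, embedded in the
latch), and a free **Key** peptide that competes for the groove. We model a
single cage as occupying one of five states:

1. *closed* — latch in the groove, TBD occluded;
2. *open, empty* — the reference state, statistical weight 1;
3. *open, target-bound* — weight $[T]_\mathrm{free}/K_d^{target}$;
4. *key-bound, no target* — the false-positive state that sets sensor
   background, weight $[K]_\mathrm{free}/K_d^{key}$;
5. *key- and target-bound* — the product of the two binding weights.

The closed state has weight $e^{-\Delta G_{close}/RT}$, where
$\Delta G_{close} = G(\mathrm{closed}) - G(\mathrm{open})$ in kcal/mol
(negative favors closed). Two structural assumptions close the scheme: the
closed cage binds neither target (the TBD is fully occluded) nor key (no
ternary latch+key state), and once open, key and target bind independently.
The readout-generating quantity — the **signal** — is the key-bound
fraction, states 4 plus 5; an optional linear readout model maps it to a
FRET-like ratio between `R_min` and `R_max`. Whether a real FRET ratio is
linear in key occupancy is an assumption, not a measurement; every
comparison the package makes is monotone, so any monotone readout map
preserves the conclusions.

$RT$ is computed from the configured temperature with
$R = 1.9872 \times 10^{-3}$ kcal/(mol K), giving 0.593 kcal/mol at the
298.15 K default — the standard biochemical convention.

### Finite concentrations

At finite concentrations the free key and target satisfy mass balance,

$$K_{tot} = K_{free} + C_{tot}\,(P_4 + P_5), \qquad
  T_{tot} = T_{free} + C_{tot}\,(P_3 + P_5),$$

with the $P_i$ the normalized state probabilities at
$(K_{free}, T_{free})$. Each balance equation is strictly monotone in its
own free variable, so the solution is unique. `solve_equilibrium()` uses a
damped fixed-point iteration on the substitution form
$K_{free} = K_{tot} / (1 + C_{tot}(1+b)/(K_d^{key} Z))$ (damping 0.5,
relative tolerance $10^{-12}$, at most 10,000 iterations), which stays in
$(0, K_{tot}]$ by construction; any instance that fails the $10^{-9}$
relative-residual contract falls back to a nested bisection. The solver is
vectorized over parameter sets, which is what makes the exhaustive
mutation-subset search and the sweep-style tests cheap. The test suite
validates populations against an independently written coarse-to-fine
grid-bisection oracle on random instances.

### Mutational tuning

Interface-weakening mutations are modeled as additive free-energy
perturbations: a latch mutation adds its $\Delta\Delta G$ to
$\Delta G_{close}$; a key mutation multiplies $K_d^{key}$ by
$e^{\Delta\Delta G / RT}$. Additivity across mutations on the same
interface is assumed — multi-mutation constructs are named in the
engineering literature without interaction terms, and nothing finer is
identifiable from the data the model consumes. Two directional laws follow
from the model and are asserted as properties: weakening the latch raises
background (and maximum) signal; weakening the key lowers both background
and stimulated signal. `tune_switch()` searches all subsets of a mutation
library (at most 20 effects) for the subset maximizing
$\mathrm{signal}(T_{hi}) - \mathrm{signal}(T_{lo})$ under a background cap
at zero target, with deterministic tie-breaks (fewer mutations, then
lexicographic names). $\Delta\Delta G$ values are user inputs; the package
does no structure-based prediction.

`fit_kd_target()` refits only $K_d^{target}$ (on a log10 scale, 1-D
least squares via `optimize()`) with the remaining parameters held at
their design values — the use case is calibrating a sensor's target
affinity from a titration, not joint inference, and at 8 doses x 3
replicates the other parameters are not separately identifiable anyway.

## Motif grafting

`enumerate_placements()` threads every prefix (default lengths 7-11) of a
binding motif into every start offset of a latch segment (e.g. the
35-residue span at cage residues 610-644), giving
$\sum_L (\mathrm{span} - L + 1)$ candidates in a deterministic order. We
read "all helical registers" as *every* start offset: the heptad class
(offset mod 7, an approximation to the 3.6-residue-per-turn helical face)
is attached as a label but never filters candidates, because any
energy-based down-selection to a handful of placements requires structure
calculations that are out of scope here. Coordinates are 1-based residue
numbers externally and 0-based offsets internally; FASTA headers carry
both.

## FRET quantification

Conventions, in pipeline order:

* **Background**: per frame and per channel, subtract the *mean* intensity
  of a cell-free ROI. Values may go slightly negative; they are not
  clipped, and a non-positive donor mean within a cell flags that frame's
  ratio undefined (a trace fails if more than 20% of frames are
  undefined).
* **Ratio orientation**: $R$ = FRET channel (donor excitation, acceptor
  emission) divided by donor channel — the yellow-over-cyan convention.
  The literature is not always consistent about the order; the arguments
  `numerator`/`denominator` make it explicit.
* **R0 anchor**: the single frame immediately preceding stimulation, not a
  baseline average, so `normalize(mode = "r0")` maps that frame exactly
  to 1.
* **Dataset normalizations**: `minmax` pools all traces in the dataset and
  maps the pooled extremes to 0 and 1; `ref_min` shifts the dataset so the
  pooled minimum (attained in the condition with the largest decrease)
  maps to 0.
* **SNR**: maximum post-stimulus $R_t - R_0$ divided by the sample s.d. of
  the baseline window; an exactly constant baseline is reported as
  infinite and flagged rather than silently dropped.
* **Brightness QC**: cells whose direct-acceptor intensity exceeds the
  population mean by strictly more than 3 s.d. are excluded. The strict
  inequality is a documented convention: a cell at exactly the threshold
  is kept. Note that with $n$ cells the maximum attainable z-score is
  $(n-1)/\sqrt{n}$, so the rule cannot fire at all for $n \le 10$.

Pixel-wise ratio images mask non-positive donor pixels and render with a
spectral lookup table; the numeric field is returned separately from the
rendering.

## Puncta and co-localization

`detect_puncta()` thresholds (Otsu within the supplied cell mask by
default — the particle-analysis literature rarely states the threshold
algorithm, so it is pluggable), labels connected components with
**8-connectivity**, and filters on circularity $4\pi A/P^2 > 0.5$ and area
$> 1\,\mu m^2$, both strict. The perimeter uses the 4-direction Crofton
(integral-geometry) estimator computed from 2x2 pixel-configuration
counts; unlike boundary-pixel counting it is asymptotically unbiased for
smooth shapes, but digitized circularity still reads low for small
objects (about 0.88 for a 5-pixel-radius disk, 0.97 at 20 px, 0.99 at
80 px) and can slightly exceed 1 near the resolution limit — hence the
documented estimator tolerance in the invariants.

Pearson's coefficient is the sample correlation over masked pixels;
Manders' $M_1$ is the fraction of channel-A intensity in pixels where
channel B exceeds its threshold, over the *total* masked channel-A
intensity ($M_2$ symmetric), with Otsu-per-channel defaults. Zero-variance
or zero-intensity channels return flagged `NA` rather than a number.
Nucleus exclusion, where needed, is the caller's responsibility via the
mask.

## Proteomics processing

The pipeline mirrors the Perseus-style convention for MaxQuant
proteinGroups tables: zeros are missing (below detection), flagged rows
(potential contaminant, reverse, only-identified-by-site) are dropped,
each sample column is log2-transformed and median-centered (idempotent;
post-condition |median| < 1e-9), replicate QC computes pairwise Pearson r
over mutually observed proteins and excludes — in a single, non-iterative
pass and only when an experiment has at least 3 replicates — any replicate
whose mean pairwise r deviates from the experiment mean by more than 0.25.
The wording of that rule in the source literature is ambiguous between
"deviation of a replicate's mean r" and "any single pairwise r"; we chose
the mean-r reading because it is stable when one bad replicate drags down
every pairwise r it participates in.

Missing values are imputed from a per-sample normal distribution
downshifted by 1.8 sample s.d. with width 0.2 sample s.d. — the bare
numbers 1.8 and 0.2 are interpreted in units of the per-sample standard
deviation, the convention of the software that popularized them.
Imputation never overwrites observed cells and is reproducible from its
seed.

**Test choice.** For differential enrichment the default is limma's
moderated (empirical-Bayes) t-test with Benjamini-Hochberg adjustment. At
the replicate depths these experiments actually use (3-4 per condition) a
per-protein Welch test has ~6 degrees of freedom, and a 4-fold enrichment
with 0.5 log2-unit replicate noise sits right at the BH threshold — in
simulation, plain Welch recovers only ~15-50% of such planted effects at
q < 0.05, while the moderated test, which borrows variance information
across the thousand-protein panel, recovers essentially all of them at an
empirical FDR near its nominal level. Welch (`method = "welch"`) and a
label-permutation test (`method = "permutation"`) remain available;
permutation granularity at n = 4 vs 4 makes the latter useful only for
ranking.

## The synthetic generators

Every input the analysis modules consume can be generated with known
ground truth: microscopy timelapses (elliptical cells on a grid, per-cell
ratio step at the stimulus frame, optional circular puncta with a ratio
multiplier, signal-proportional Gaussian noise plus an additive floor, a
per-cell direct-acceptor brightness scale for planting QC outliers), dose
titrations (equilibrium signal times lognormal noise), and
MaxQuant-dialect intensity tables (log-normal baselines near 2^26, planted
log2 enrichments, intensity-dependent logistic or threshold censoring,
optional planted flag rows). Generators are bit-reproducible from their
seed, and configs are echoed into the returned truth so tests never
hard-code them.

What the generators deliberately omit: optics (no PSF, no photobleaching,
no spectral bleed-through), cell morphology beyond ellipses, MS peak
structure, and peptide-level inference. Passing the recovery tests
therefore demonstrates that the *quantification procedures* are correct
and calibrated, not that they are robust to every artifact of real
acquisitions.

### Problem sizes and default study conditions

The recovery experiments run at the sizes the package's checks use: 100
random parameter sets for the equilibrium oracle; 1,000 instances for the
directional tuning sweep; 100 repeated titrations (8 doses spanning
10^-9.5 to 10^-6 M, 3 replicates, 5% CV) for target-affinity recovery
with the true sensor at $\Delta G_{close} = -2$ kcal/mol,
$K_d^{key} = 100$ nM, $K_d^{target} = 10$ nM and 100 nM cage/key —
a nanomolar-range operating point typical of an intracellular sensor;
20-cell timelapses at 2% noise for step recovery; and 1,000-protein
matrices (4 vs 4 replicates, 0.5 log2-unit noise, 50 planted 4-fold
effects) for enrichment. These sizes were chosen as the smallest at which
the distributional contracts are sharp.

## Known limitations

* Equilibrium only: no kinetics, no maturation or degradation, no
  photophysics; cellular timecourses are outside the model.
* Whether target binding to the *closed* cage is strictly zero or merely
  weak is not empirically settled; the model takes it as zero, which is
  the conservative reading of the occlusion mechanism.
* The ratio-readout map is assumed linear in key occupancy.
* The heptad register label is an approximation to a 3.6-residue helix;
  it is provided for bookkeeping, not selection.
* Realized FDR of any BH-controlled analysis fluctuates around its
  expectation; single-dataset empirical FDR above the nominal level is
  not by itself evidence of miscalibration.
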