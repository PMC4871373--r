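---
title: "Standard component models of the budding yeast cell cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard component models of the budding yeast cell cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmcycle)
```

## The standard component formalism

`scmcycle` simulates protein regulatory networks built from three standard
component classes, separated by reaction time scale:

* **Class 1** — protein totals changing slowly by synthesis and degradation,
  with pseudo-linear kinetics `dX/dt = A - B X`. The rates `A` and `B` are
  themselves sums of terms `coef * (regulator values) * V^k`, so
  transcription-factor and protease regulation stays linear in the state.
* **Class 2** — protein activities changed quickly by phosphorylation and
  dephosphorylation: `dY/dt = gamma (Y_T H(sigma W) - Y)`, where
  `H(x) = 1/(1 + exp(-x))` is the soft-Heaviside (logistic) function and
  `W = ±w0 + Σ w_k Y_k − Σ w_l Y_l` is a weighted influence sum. `H`
  phenomenologically lumps whatever generates ultrasensitivity (multisite
  phosphorylation, zero-order effects); `sigma` sets the steepness and
  `gamma` the relaxation rate. For `gamma`, `sigma` large the variable is a
  de facto Boolean switch; for `gamma` large only, it can be replaced by its
  quasi-steady value `Y_T H(sigma W)`.
* **Class 3** — tightly bound complexes equilibrating fast, resolved
  algebraically: free partner `max(0, Y_T - I_T)` for a single inhibitor; a
  proportional split when one inhibitor serves two partners; a priority rule
  when it strongly prefers one; and `min(a, b)` for an obligate heterodimer.

`network_spec()` holds a declarative description of such a network and
`scm_simulate()` integrates any of them in plain R. The two bundled yeast
models additionally dispatch to compiled (C++) integrators with identical
semantics; the test suite verifies step-by-step agreement between the two
implementations to ~1e-9, which is the package's primary guard against
transcription errors in either copy of the equations.

### Numerical scheme

All integrators use explicit fixed-step Euler with `dt = 0.01` min, the same
scheme for deterministic and stochastic runs so the two code paths differ
only by the noise terms. Halving `dt` moves deterministic event times by
less than 1% (asserted in the tests). After each step, quasi-steady class-2
activities are recomputed algebraically (in declaration order), then class-3
values in a fixed topological order; class-2 values are clamped to
`[0, Y_T]` and class-1 values to `>= 0`, because an explicit method can
overshoot on stiff segments. Volume is advanced by its exact exponential
factor `exp(mu dt)` rather than an Euler step, removing a needless
discretization error from size thresholds. Event crossings are located by
linear interpolation inside the step; when several event rules fire in one
step they are applied in the order bud, DNA-synthesis, spindle, relicensing,
division, so a division step sees fully updated flags.

## The Start-transition model

The Start model tracks molecule numbers of Cln3 (synthesis proportional to
`V^2`, giving the size signal), the lumped S-phase cyclin ClbS (SBF-driven
promoter with gene activity `SBF/(SBF + k_dg V/k_ag)`), total and active
Whi5, the phosphatase Hi5 and total SBF, with free SBF the class-3 excess of
total SBF over active Whi5. mRNA levels are frozen at their steady state
`k_sm/k_dm` in the deterministic model. From the newborn state (10 fL, all
Whi5 active, all SBF complexed) the model executes Start ([SBF] rising
through 15 nM) at about 145 min and G1/S ([ClbS] through 37.5 nM) at about
153 min; both times fall as birth size rises while their gap stays nearly
constant. Concentrations use `[S] (nM) = N / (0.6 V_fL)`.

With growth frozen, volume is a bifurcation parameter: the model is bistable
between fold points near 6.5 and 31 fL. `bifurcation_scan()` finds branches
by relaxation from a newborn-like and a post-Start initial state per volume
(corroborated by optional random multi-starts), and bisects each fold to
0.1 fL. The right fold is the threshold size for Start.

### The multisite-phosphorylation reference model

The MultiP model unfolds the Start model back into 19 mass-action species:
explicit mRNAs, seven sequentially and distributively (de)phosphorylated
Whi5 forms (the first three bind SBF essentially irreversibly; the complexes
can be phosphorylated in place, with the third phosphorylation releasing SBF
at once), and two-state gene switching for the ClbS gene. Four elementary
rate constants have no counterpart in the Start model's parameter table:
per-site phosphorylation by Cln3- and ClbS-kinase (`kp_n3`, `kp_bS`, their
ratio fixed to the corresponding influence-weight ratio 6.2:0.33), per-site
dephosphorylation by Hi5 (`kdp`), and SBF:Whi5 association (`ka_cmp`). With
the supplementary values unavailable, these four were calibrated once so
that the deterministic MultiP model reproduces the reference timings
(Start/G1/S at 142/152 min from a 10 fL newborn); the calibrated model then
independently shows a bistable window (folds at ~8 and ~27 fL) overlapping
the Start model's, and the same monotone timing-vs-size dependence. The
`simulate_multip_ssa()` Gillespie implementation treats volume
quasi-statically, re-evaluating propensities with the current volume at each
reaction event — accurate here because single-reaction waiting times are
milliseconds to seconds while the volume doubles in 100 min.

## The full cell-cycle model

The full model is formulated in normalized concentrations (each species
scaled by a characteristic concentration; volume in units of 28 fL, the
average birth size of wild-type daughters). Its 24 dynamic variables cover
the Start module (Cln3, Bck2, Cln2, active Whi5/SBF), the S/G2/M module
(Clb5, Clb2, CKI with a phosphorylated subpool, Swi5, Cdh1, APC, Mad2,
Cdc20) and the mitotic-exit module (Pds1, PPX, Net1, Polo, Tem1, Cdc15, with
free Esp1, Cdc14 and the Tem1:Cdc15 MEN complex as class-3 values), plus
three progress variables (BUD, ORI, SPN) that trigger the event rules:

1. bud emergence when BUD reaches 1;
2. onset of DNA synthesis when ORI reaches 1 while origins are licensed
   (which unlicenses them and engages the spindle checkpoint input);
3. spindle-assembly completion when SPN reaches 1 (checkpoint release);
4. division when free Clb2 falls through `K_EZ = 0.4`, splitting the cell
   `(1-f):f` with daughter fraction `f = 0.3364 exp(22.2/T_d)` (58:42 in
   glucose, 61:39 in galactose/raffinose) and resetting BUD, SPN and both
   checkpoint flags;
5. origin relicensing when total Clb activity falls through `K_EZ2`.

A newborn cell is assumed to have licensed origins and no replicated DNA or
spindle (`b_oriflag = 1`, `b_udna = b_spc = 0`); the published initial-value
table is silent on the flags, and this is the only assignment consistent
with the relicensing semantics of rule 5. Class-3 initial values are
recomputed from their defining identities rather than taken from the table
(one tabulated complex value is slightly inconsistent with the others).

Four printed equations required interpretation, resolved from the
surrounding narrative: the securin degradation bracket uses the basal
degradation constant (the printed synthesis symbol there is a typo, since
the bracket multiplies total securin and the degradation constant is defined
in the parameter table); the Clb2 equation's Cdh1-mediated term reads
`Cdh1_A` (Cdh1 is the protein described as degrading Clb2); the Net1
influence's last term reads `omega (Cdc15_A - Tem1_A:Cdc15_A)`, i.e.
MEN-independent activity of free Cdc15; and the weight printed as
`omega_i,whi5,b2` binds to the Swi5 influence (no other equation references
it). The Cdc20 complex chain is evaluated in the fixed order: free Cdc20
(total minus active Mad2), then `Cdc20:APC_P = min(Cdc20_A, APC_P)`, then
`Cdc20:APC` from the remainders.

Deterministically the wild-type daughter settles on a limit cycle with
`T1 = 57` min (birth to Start, defined as free SBF first reaching 50% of its
per-cycle maximum), and mother/daughter cycle times average to the 100-min
mass-doubling time, as balanced exponential growth requires.

## The stochastic layer

Class-1 species are propagated as molecule numbers
(`N = [S]_n c_S 0.6 V_fL`) with two Langevin noise terms per step: the
chemical-Langevin protein term `sqrt(A + B N) zeta_1 sqrt(dt)` and a lumped
mRNA-inherited term
`N sqrt(2B) sqrt(B/((B + k_dm)(<m> + <m_min>))) zeta_2 sqrt(dt)`, whose
stationary contribution to the squared coefficient of variation approximates
the two-stage gene-expression result `(1/<m>) tau_m/(tau_m + tau_p)`. In the
Start model `<m>` is the deterministic mRNA level (for ClbS, scaled by the
instantaneous gene activity — the low-SBF situation is exactly what the
`<m_min>` floor was introduced for); in the full model, which carries no
mRNA species, `<m> = A/(k_tr V_fL)` with the translation rate
`k_tr = 0.15` molecules per mRNA per fL per min, mRNA turnover
`k_dm = 0.7`/min, and a floor of 5 mRNAs for the five low-abundance cyclin/
inhibitor genes. Class-2 and class-3 variables carry no noise: modification
and binding equilibrate fast enough to regress fluctuations to the mean.
Negative Langevin excursions are clamped at zero (well under 0.1% of steps
in wild type; the clamp count is reported). Division adds extrinsic noise: the
daughter fraction is drawn from a normal law (mean from the medium's
division rule, SD 0.05) truncated to (0.05, 0.95), molecule numbers are
split in proportion to volume, and a hysteresis gate (`K_flag = 0.8`)
prevents re-division until Clb2 has risen above `K_flag` again. An optional
explicit-mRNA variant of the Start model promotes the four mRNAs to
Langevin species.

The test suite validates the lumped term against exact Gillespie simulation
of a two-stage birth-death process at mRNA means of 2, 5 and 20, in the
kinetic regime of the model's species (protein half-lives several-fold
longer than mRNA half-lives). One caveat worth recording: the multiplicative
lumped term inflates the stationary CV² by a factor `1/(1-q)` with
`q = B/((B+k_dm)<m>)`, so for hypothetical species with `<m> ~ 2` *and*
protein turnover as fast as mRNA turnover the approximation degrades to
~20%; no species of the bundled models lives in that corner.

### Sampling frame for single-cell statistics

Published single-cell statistics come from time-lapse pedigrees of growing
microcolonies, in which every cell appears once; short cycles are therefore
over-represented relative to the stationary distribution of a single-lineage
chain (a daughter-following chain is *forced* to a mean cycle time of
`-mdt log2(f) = 126` min by balanced growth, regardless of dynamics).
`simulate_pedigree()` reproduces the experimental frame: both progeny are
continued at every division, each as an independent simulation with its own
random stream (so population size never perturbs an individual lineage), a
thinning cap keeps the live population bounded with weight compensation, and
the first five generations are discarded as burn-in. On this frame the
stochastic wild type gives daughters a mean `T1` of ~31 min (vs 57
deterministic — molecular noise triggers Start well below the deterministic
threshold size), a `T_G1` CV near 50%, a mean birth size of 28 fL, and a
~13 min lag between bud emergence and origin firing. Dropping the
mRNA-inherited term lengthens mean `T1` to ~50 min and division-fraction
noise alone gives ~57 min, reproducing the published ordering of noise
contributions.

Asynchronous-population snapshots draw one age fraction per completed cell
from the density `f(theta) = ln 2 * 2^(1-theta)` (newborns twice as likely
as dividers; inverse-CDF `theta = 1 - log2(1 + u)`) and interpolate the
cell's buffered state at that age. Mothers and daughters are pooled in equal
number, which is exact for budding yeast (every division creates one of
each). Whole-cell totals are reported; whether a bud should be counted
separately is not specified by the source data and is ignored.

### Size control

`size_control_fit()` regresses `mu * T_G1` on `ln(V_birth/Vbar_m)` (birth
volume relative to the mean mother birth volume): slope −1 is a perfect
sizer, 0 no size control. Cells are binned in 2-fL birth-volume intervals
and the fit uses the bin means, weighted by occupancy so sparse extreme-size
bins cannot dominate. Daughters get a two-segment fit with a free
breakpoint; the breakpoint is discovered by a grid search over interior bin
boundaries (segments constrained to join at the break — the segmented-
regression convention — which makes the breakpoint far better identified
than two unconstrained lines), restricted to breakpoints holding at least
10% of the cell mass on each side. Mothers get a single line. Typical
wild-type results: daughter slopes near −0.7 (small cells) and −0.4 (large
cells) with the break near `ln(V_birth) = −0.4`, mothers near −0.25 —
strong size control only in small daughters.

## Mutant screening

`apply_mutation()` rewrites the wild-type parameter vector: gene deletion
zeroes synthesis constants, overexpression adds a constitutive synthesis
rate, destruction-box deletion zeroes the corresponding regulated
degradation constants, and the growth medium resets the growth rate and
division asymmetry. Viability requires at least three successive divisions
with bounded division size within a 1000-min per-cell horizon (three periods
distinguish sustained cycling from a transient at either growth rate);
arrests are staged from the event history — no Start means G1 arrest, Start
without origin firing G1/S arrest, spindle assembly without division
telophase arrest.

Two alleles needed values beyond the wild-type table. The CLB2 destruction-
box deletion removes recognition by Cdc20-APC in both APC phosphorylation
states and leaves Clb2 only partially degradable by Cdh1; the residual
Cdh1-mediated rate (0.045/min, 7.5% of wild type) was calibrated once so the
clb5-deleted double mutant arrests in telophase on glucose but is partially
rescued on raffinose. With it, the stochastic model reproduces the partial
viability quantitatively: ~25% of raffinose cells undivided 300 min after
birth, dividing mothers averaging ~150 min cycles (SD ~50), under 10%
completing the cycle on glucose, and >90% division within 250 min when
SIC1 is overexpressed from the GAL promoter (implemented as a constitutive
CKI synthesis rate of 0.12/min, about the conventional ten-fold basal rate).
A known deviation: dividing *daughters* of the raffinose strain average
~190 min here versus ~155 reported — in this reconstruction the small
daughter cells pay both the longer G1 of their size and the full
mitotic-exit delay. The reduced Net1:Cdc14 association alleles (net1-ts,
TAB6-1) use a stoichiometry factor of 0.5 (any value below 1 expresses the
reported weakened binding; both strains remain viable).

## Problem sizes and reproducibility

Default analysis sizes were chosen to estimate each statistic comfortably:
pedigrees of 2 founders to generation 11–12 (≈4,000–8,000 cells per role)
for wild-type statistics, 12 founders to generation 8 for the partially
viable mutant (≈600 dividing mothers), 100-point volume grids with 0.1-fL
fold bisection for bifurcation scans, and ~10⁶-step stationary runs for the
noise-law checks. Every stochastic entry point takes an integer seed and is
bit-reproducible for a fixed seed on a given platform; per-cell streams are
derived by hashing (seed, cell id).

## Known limitations

* The soft-Heaviside influence weights are phenomenological, not measurable
  rate constants; the max/min complex rules assume strong, fast binding.
* The MultiP model is a narrative-based reconstruction whose four elementary
  rates were calibrated to the reference timings; its stochastic behaviour
  is structurally, not quantitatively, matched.
* No tau-leaping, no extrinsic noise beyond division variability, no
  growth-rate heterogeneity, and no Whi5-dilution alternative for size
  sensing.
* Synthetic-data helpers emulate lineage bookkeeping, not microscopy: tests
  passing on them certify the estimators, not the biology of real images.
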