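---
title: "Selective Gaussian-accelerated MD on toy systems: models and methods"
author: "selgamd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective Gaussian-accelerated MD on toy systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selgamd)
```

## The method

Gaussian accelerated molecular dynamics (GaMD) flattens energy barriers
by adding a harmonic boost to the potential energy whenever it falls
below a threshold:

$$\Delta V(V) = \tfrac{1}{2}\,k\,(E - V)^2 \quad \text{for } V < E,
\qquad \Delta V = 0 \text{ otherwise.}$$

Because the boost depends on the coordinates only through $V$, the
biased force is the unbiased force scaled by
$\lambda = 1 - k\,(E - V)$, and because the boost distribution stays
near-Gaussian in well-behaved systems, the unbiased free-energy surface
can be recovered by reweighting with a second-order cumulant expansion.

The *selective* variant implemented here applies independent boosts to
user-chosen subsets of the potential-energy terms.  The beads of a
system are partitioned into $N$ groups; the package then monitors
exactly $N$ bonded terms, $N$ self-nonbonded terms and $N(N-1)/2$
inter-group nonbonded terms (`build_catalogue()`), plus one dihedral
term per group when dual boosting is requested.  *Acceleration regions*
(`acceleration_region()`, `validate_regions()`) are sets of these term
indices sharing one $(E, k)$ pair; in the compact notation, `"1-1"`
names the bonded and self terms of group 1 and `"1-2"` the group-1 /
group-2 interaction.  Terms claimed by no region simply evolve
unbiased.  Dual boosting gives the torsional part of a region its own
$(E_\mathrm{dih}, k_\mathrm{dih})$.

Boost parameters come from search statistics under the lower-bound
rule: $E = V_\mathrm{max}$ and $k = k_0/(V_\mathrm{max} -
V_\mathrm{min})$ with

$$k_0 = \min\!\left(1,\;
\frac{\sigma_0}{\sigma_V}\,
\frac{V_\mathrm{max} - V_\mathrm{min}}{V_\mathrm{max} - V_\mathrm{avg}}
\right),$$

where $\sigma_0$ (default 10 kJ/mol, per region) caps the boost spread
so reweighting stays reliable.  `run_protocol()` stages a run the
standard way: an unbiased conventional-MD search collecting per-region
statistics, an adaptive GaMD search re-estimating the parameters every
update interval (default one fiftieth of the search length) from the
*cumulative* statistics, and a production run with parameters frozen at
their final search values.  The upper-bound threshold mode is not
implemented.  Whether production parameters should instead be re-derived
from the full search statistics is an open choice; freezing the last
search estimate is what the staging here does, and with cumulative
statistics the difference is only the final update.

## Toy systems instead of atomistic ones

The method's correctness is independent of any force field, so the
package tests it on two kinds of analytic systems:

* `potential_surface` — 1D analytic potentials (cosine series, Gaussian
  wells, optional harmonic term).  `make_double_well(barrier)` is the
  workhorse: two equal minima at $\pm 90^\circ$, barrier height as
  stated, and — decisive for validation — a *closed-form* PMF (for one
  degree of freedom the PMF is the potential itself).  The default
  validation barrier is 20 kJ/mol, a mid-range value for a hindered
  dihedral (roughly 8 $k_\mathrm{B}T$ at 300 K): high enough that plain
  MD essentially never crosses on the tested time scales, low enough
  that a boosted run equilibrates quickly.
* `bead_system` — small particle systems with harmonic bonds, cosine
  torsions on bead quadruples and a 12-6 repulsive-plus-well pair
  interaction, energy-shifted to zero at the cutoff so conservation
  checks are clean.  `make_solute_solvent()` builds the canonical
  two-group fixture: a bonded chain (group 1) in a bath of free beads
  (group 2), mirroring the solute / solute–solvent vs solvent–solvent
  region split.  Bonds and torsions may not cross group boundaries;
  the decomposition splits only nonbonded terms across groups, and an
  ambiguous assignment would silently break the conservation
  invariant, so it is an error.

Dynamics use a BAOAB-split Langevin leapfrog at constant temperature
(kB fixed at 0.008314463 kJ/mol/K).  There is no barostat, no
constraint algorithm and no pair-list machinery — none of these affect
what is being validated.  One seeded random stream drives each run and
bias providers consume none of it, which is what makes the
selective-vs-monolithic comparison reproducible bit for bit.  The
surface coordinate's effective inertia (default $10^{-4}$
kJ mol$^{-1}$ ps$^2$ deg$^{-2}$) and the friction (2 ps$^{-1}$) only
set how fast configuration space is explored — no equilibrium
distribution depends on them — and are chosen so the coordinate
diffuses quickly relative to both trajectory lengths and the local
elevation deposition rate.

## Reweighting and its reliability diagnostic

`pmf_cumulant()` estimates the unbiased bin probability as
$p(j) \propto p_\mathrm{biased}(j)\,
\exp\!\big(\beta\,\overline{\Delta V}_j + \tfrac{\beta^2}{2}\,
\sigma^2_{\Delta V, j}\big)$ (population variance per bin);
`pmf_exponential()` uses the exact exponential average
$\langle e^{\beta \Delta V}\rangle_j$ instead, max-shifted before
exponentiation to avoid overflow.  For per-bin Gaussian boosts the two
agree analytically ($\ln E[e^{\beta X}] = \beta\mu + \beta^2\sigma^2/2$);
for heavy-tailed boosts the exponential average is dominated by rare
large values and the estimates diverge — the tests construct both
cases.  PMFs are anchored to zero at their occupied minimum; empty bins
carry `NA`, and bins with fewer than 10 samples are flagged (not
dropped) in the `reliable` field.

The anharmonicity $\gamma = S_\mathrm{gauss} - S_\mathrm{emp}$ compares
the differential entropy of a Gaussian with the sample variance against
a histogram estimate of the empirical entropy (Freedman–Diaconis bin
width, $-\sum p \ln p + \ln w$).  Since the Gaussian maximises entropy
at fixed variance, $\gamma \ge 0$ up to estimator noise (negatives are
clamped); $\gamma \approx 0$ means cumulant reweighting is safe.  The
exact estimator used by the established reweighting tools is not
restated in the sources this package follows, so this definition is an
explicit, swappable convention.  `boost_summary()` reports the boost as
mean ± population standard deviation, the conventional format.

One caveat the test suite makes explicit: on a *one*-degree-of-freedom
system the potential-energy distribution is chi-square-like, not
Gaussian — near a minimum $p(V) \propto V^{-1/2} e^{-\beta V}$ — so the
boost built on it has $\gamma \approx 0.4$ no matter how well the
protocol works, while the PMF recovery is still accurate because the
per-bin boost is nearly deterministic.  The near-zero anharmonicities
reported for atomistic systems arise from total energies that are sums
of thousands of terms.  The corresponding test therefore asserts the
Gaussianity property where its premise holds (a region energy that *is*
near-normal) and the double-well protocol check reports the honest,
large $\gamma$ of a 1-DOF system.

## Local elevation umbrella sampling

`leus_bias()` holds an $N_l$-dimensional periodic visit-count grid
(defaults $N_g = 36$ cells, $\sigma = 360^\circ/N_g$, $c = 0.005$
kJ/mol per visit, $N_l \le 2$).  During the LE phase every integration
step increments the cell containing the current CV value; the bias is

$$B(Q) = \sum_k c\, n_k\, g\big(\mathrm{MI}(Q - Q^*_k)\big),\qquad
g(d) = \big(1 - (d/2\sigma)^2\big)^2 \; H(2\sigma - |d|),$$

a finitely supported polynomial bump with $g(0) = 1$.  The kernel shape
matters more than it looks: a kernel whose value or slope jumps at the
cutoff injects steps that the integrator never feels as force, and with
realistic visit counts those steps reach tens of kJ/mol and corrupt the
umbrella phase systematically.  Both $g$ and $g'$ vanish at $2\sigma$
here, which keeps the US phase clean.  Cells are centre-labelled and
assignment is floor-based with boundary ties going to the lower cell.
After the LE phase the bias is frozen (`freeze_bias()`; updates then
error), making the biased Hamiltonian time independent, and
`reweight_us()` recovers the PMF with per-sample weights
$e^{+\beta B(Q)}$.

The LE phase should run long enough to fill the wells and no longer:
once the landscape is level, further deposition only stiffens the grid
(curvature grows with $n_k$) and degrades integration accuracy.  On the
20 kJ/mol double well, $4\times10^5$ LE steps reach the flat-histogram
regime — the per-cell occupancy of the final LE quarter stays within a
factor of ~2 — and a $3\times10^6$-step US phase makes the statistical
reweighting error a small fraction of $k_\mathrm{B}T$.  Per-linkage
biases built on fragments and recombined are out of scope; one bias per
CV subspace.

## Conformer strings and event analytics

`linkage_definition()` maps each glycosidic-linkage conformer letter
(A–D) to a rectangular region on the torus of its dihedrals (periodic
intervals; an interval with `lo > hi` wraps through ±180°).  The
shipped regions are synthetic fixtures — the curated per-linkage minima
of real glycan landscapes are not reproduced here — and are fully
editable.  `encode_conformers()` assigns every frame a letter per
linkage; tuples outside all regions go to the nearest region centre by
periodic distance (the paper-style encoding assigns every frame), or to
`"X"` with `unassigned = "mark"` for strict encoding.  On top of the
strings: `count_clusters()` (cumulative distinct-string curve),
`count_transitions()` (frame-to-frame changes and per-ns rate on the
recorded grid, no interpolation), `dwell_filter()` (strings with a
contiguous run of at least τ, default 10 ps; a run of `n` frames counts
as `n × frame_dt`, so a run of exactly τ qualifies, and a cumulative
mode is available since the sources do not pin the reading down),
`hamming()` distances, and `detect_events()` (maximal intervals below
or above a threshold lasting at least a minimum lifetime — the
folding-event criterion when applied to an RMSD-like CV with 0.3 nm
and 100 ps).

## What the toys do and do not show

Passing tests demonstrate that the decomposition is exhaustive and
exact, the boost law and its force scaling are implemented correctly,
the selective machinery is a strict generalisation of single-boost GaMD
(bit-identical at $M = 1$), the staged protocol's estimates recover a
known PMF through cumulant reweighting to better than 0.5
$k_\mathrm{B}T$, and LEUS converges to a flat histogram and reweights
correctly.  They do not show anything about force-field quality,
water models, constraint dynamics, pressure coupling, or the actual
conformational thermodynamics of peptides and glycans — the toy
landscapes have one or a few degrees of freedom and smooth analytic
interactions.  Quantities like folding-event counts or conformer totals
produced here characterise the synthetic fixtures only.

## Numerical choices

* Timestep 0.002 ps against well frequencies of order 10 ps$^{-1}$
  ($\omega\,\Delta t \approx 0.02$); BAOAB's configurational bias at
  this ratio is far below the tolerances tested.
* Acceptance-scale runs: 1 ns cMD search, 3 ns adaptive search
  (updates every search/50 steps), 4 ns production for the double-well
  protocol; LE/US as above.  These lengths were chosen so that
  statistical errors sit comfortably below the asserted bounds.
* Per-term accumulation uses one scatter-add per interaction class;
  region energies are plain ordered sums over member terms so that the
  $M=1$ region sum reproduces the monolithic total bit for bit.
* Degenerate search statistics ($V_\mathrm{max} = V_\mathrm{min}$)
  disable the boost with a warning rather than dividing by zero; dual
  boosting on a region without torsions warns and contributes zero.
* Chain torsions exist only for chains of four or more beads; shorter
  solutes simply have no torsional coordinate.

## A worked example

```{r example, eval = FALSE}
dw <- make_double_well(20)                      # barrier 20 kJ/mol
cfg <- integrator_config(timestep = 0.002, temperature = 300,
                         friction = 2, output_stride = 100, seed = 7)
res <- run_protocol(dw, cfg,
                    stage_steps = list(cmd = 5e5, search = 15e5,
                                       production = 2e6))
res$params                                      # E = v_max, k = k0/(vmax-vmin)
cv <- res$production$cv[, 1]
dv <- res$production$boost[, "dV_total"]
fes <- pmf_cumulant(((cv + 180) %% 360) - 180, dv, bins = 36,
                    range = c(-180, 180))
fes_rms(fes, dw, max_pmf = 5 * kB * 300)        # RMS vs analytic PMF
boost_summary(dv)                               # mean ± sd boost
anharmonicity(dv)                               # reliability diagnostic
```

The same quantities, recomputed from scratch for every module, are what
`scripts/acceptance.R` writes.
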