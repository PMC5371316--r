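---
title: "Methods: helix propensity scanning with a coarse-grained Calpha model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helix propensity scanning with a coarse-grained Calpha model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixscan)
```

## The problem

Intrinsically disordered regions (IDRs) often fold into helices only upon
binding a partner, and the *intrinsic* helix propensity of a segment — how
much helical structure it samples while free in solution — modulates its
binding. `helixscan` estimates per-segment helix propensity by free-energy
methods on a coarse-grained peptide model, and independently from NMR
secondary chemical shifts, so the two routes can be compared on the same
residue ranges.

The pipeline mirrors how such a study is run at all-atom resolution: split
the region of interest into 10-residue peptides, sample each peptide's
helix-coil equilibrium along a helicity reaction coordinate under umbrella
restraints with replica exchange, reconstruct the free-energy profile by
WHAM, and integrate the helical basin. The all-atom machinery (force
fields, explicit water, an MD engine) is replaced by a Calpha-only model
cheap enough that every stage is exercised and tested on a desk.

## The reaction coordinate

Helicity is measured by a distance RMSD over the Calpha(j)-Calpha(j+3)
pairs,

$$ R = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} (d_i - d_{i,0})^2 }, $$

with every reference distance $d_{i,0} = 0.5$ nm, the i,i+3 spacing of an
alpha-helical Calpha trace. $R = 0$ is the fully helical peptide; growing
$R$ measures unfolding. Sampling is confined to a window around a target
$R_0$ by the quadratic bias $V = \tfrac12 k_0 (R - R_0)^2$. Units are nm
and kJ/mol throughout the restraint layer (the sampler converts to kBT at
its configured temperature); `kB = 0.0083144621` kJ/(mol K).

The gradient of $R$ is singular at $R = 0$ (the square root); the package
raises a typed error there and exposes the gradient of $R^2$ as the
fallback, which is what a restraint force needs in the limit.

## The coarse-grained model

One bead per residue at the Calpha position, fixed virtual bonds of
0.38 nm. The reduced potential (kBT units at the 300 K reference) is

* harmonic pseudo-bond-angle terms about 91 degrees
  (`k_angle = 300` kBT/rad^2, i.e. ~3 degree fluctuations — a Calpha trace
  in a helix is stiff);
* a periodic double well in each Calpha pseudo-dihedral: a helical minimum
  at +50 degrees whose depth is the per-residue helix bias `h_j`, and an
  extended minimum at -170 degrees of fixed depth 0.8 kBT; Gaussian wells
  of width 0.25 rad;
* for pairs at least 4 apart in sequence: a square-well attraction of
  depth `eps_c` inside 0.62 nm and soft-core repulsion inside 0.30 nm.

With bond 0.38 nm, angle 91 degrees and dihedral +50 degrees the ideal
helix has d(i,i+3) = 0.508 nm (within 0.01 nm of the 0.5 nm reference) and
d(i,i+4) = 0.619 nm, so every i,i+4 pair of a helix counts as a contact.
The stiffness constants were calibrated once so that the model's limits
bracket the helix-coil transition cleanly: with `h = 0` unbiased sampling
is essentially coil (helicity < 0.05), with `h = 6` kBT it is
helix-dominated (> 0.85), and the ideal helix is the energy minimum
already at `h = 1`. They were fixed before the end-to-end analyses and are
not tuned per scan.

Sampling is Metropolis Monte Carlo: one attempted pivot per pseudo-dihedral
per sweep (rotating the chain tail about the bond axis, which changes
exactly one dihedral) plus two crankshaft rotations of short interior
stretches (which also relax the bond angles). Both proposals are
symmetric, so detailed balance holds. Monte Carlo is used instead of
dynamics because only equilibrium ensembles enter the analysis; it removes
every integrator and thermostat decision. Each replica owns a
counter-based random stream derived from the master seed by a fixed
offset, so runs are bit-reproducible and adding windows never perturbs
existing streams.

Temperature enters by rescaling the reduced Hamiltonian by $300/T$: well
depths are defined in kBT at 300 K, so heating flattens the landscape and
the mean energy rises, as it must.

### Sequence to bias

Per-residue helix bias is derived from sequence through an experimental
helix-propensity scale (free-energy penalties relative to alanine,
converted to a 0..1 score by `exp(-dG / 0.6 kcal/mol)`), scaled to a
5 kBT full depth for alanine. Proline and glycine get essentially no
helical well, which is what makes proline-rich linkers coil-like in the
scan.

### Water-model surrogate variants

The four presets (`V-TIP3P`, `V-TIP4P-s`, `V-TIP4P-ws`, `V-TIP4P-D`) stand
in for four water force fields. The literature gives no quantitative
mapping from a water model to helix stabilisation, so the presets encode
only the orderings the comparison rests on: helix stabilisation
`V-TIP4P-ws >= V-TIP3P > V-TIP4P-s > V-TIP4P-D` (multipliers 1.10, 1.00,
0.60, 0.25 on the sequence bias) and compaction, with `V-TIP4P-D` given
the weakest nonlocal contacts (0.2 kBT vs 1.0 for `V-TIP3P`) so it samples
the most extended ensembles. Magnitudes are surrogate choices; every
cross-variant claim the package makes is an ordering, never a magnitude.

## Umbrella sampling with replica exchange

Default protocol: 12 windows, $R_0$ equally spaced over 0.0-0.5 nm
*including both endpoints* (the spacing convention had to be chosen; the
endpoint-inclusive reading makes the first window restrain to the fully
helical state and the last to 0.5 nm exactly), one force constant
`k0 = 1000` kJ/(mol nm^2) for all windows (no value is prescribed by the
protocol this mirrors; 1000 gives window widths of ~0.05 nm, ample overlap
at 0.045 nm spacing, and is exposed in the configuration, per-window if
needed). Neighbour swaps are attempted every 500 sweeps, alternating
even/odd pairs — the standard replica-exchange schedule. Because all
replicas share one Hamiltonian and differ only in bias, the swap criterion
uses bias energies alone:
$\min\{1, \exp(-\beta[V_a(x_b)+V_b(x_a)-V_a(x_a)-V_b(x_b)])\}$.

A 1D harness (`sample_windows_1d()`) samples a scalar coordinate under the
same window machinery; it exists to validate the statistics against closed
forms: restraint-only marginals are Gaussian with variance $1/(\beta k_0)$,
and an analytic double well must be recovered by WHAM within small
fractions of kBT.

## WHAM

The free-energy profile is reconstructed with standard binned
self-consistent WHAM (bin width 0.01 nm, relative tolerance 1e-7 on the
window constants, both configurable). Binning matches how such profiles
are presented and inspected; MBAR would serve equally and the estimator is
deliberately isolated behind one function. Bins with zero counts stay
undefined rather than interpolated. With a single unbiased window the
update reduces, on the first iteration, to direct Boltzmann inversion of
the histogram — a degenerate case the tests pin down exactly.

Uncertainty is a Bayesian bootstrap over each window's sample weights
(default 50 replicates when requested). Because Monte Carlo output is
autocorrelated, weights are drawn per *block* of consecutive frames
(`boot_block`), not per frame; treating correlated frames as independent
understates the error several-fold.

The helical population integrates the Boltzmann weight below the boundary
R = 0.15 nm, splitting the boundary bin proportionally. The boundary is
the conventional choice calibrated against a helicity-vs-R curve: mean
helicity decays roughly linearly with R and crosses 50% near there.
`helicity_vs_R()` recomputes that calibration curve for any run; at this
model's resolution the crossing lands near 0.10-0.15 nm depending on the
bias level, and the boundary is a configuration knob, not a constant
buried in code.

Convergence is checked by splitting each window's samples into four
contiguous quarters and re-running WHAM per quarter: profiles from the
later three quarters should agree (default threshold 0.5 kBT). A bin
enters the comparison only with at least `min_count = 100` samples in
every quarter — the shot noise on a bin free energy is ~$1/\sqrt{n}$ kBT,
so sparse bins measure noise, not drift. A fraction of initial samples
(default 10%) is discarded as equilibration before any analysis; the
fraction is a configuration knob.

## Ensemble observables

*Helicity.* DSSP needs backbone N, C and O atoms that a Calpha model does
not have, so helicity is geometric: residue j (2 <= j <= n-2) is helical
when its pseudo-dihedral lies in [30, 80] degrees and, where defined,
d(j, j+3) in [0.44, 0.56] nm. The two windows are calibrated so the ideal
helix scores 1 and the extended chain 0. Termini lack the geometric
context and are excluded from the denominator — which also covers the
role of terminal capping groups, since a Calpha model has no chemistry to
cap.

*Radius of gyration* uses unit masses. *H-bonds* are not resolvable at
this resolution; the surrogate counts i,i+4-or-farther Calpha contacts
within 0.62 nm, which the ideal helix satisfies for exactly its i,i+4
pairs. Side-chain observables (salt bridges) are out of scope at Calpha
resolution.

*Clustering* is the Daura (GROMOS) greedy neighbour-count algorithm under
Kabsch least-RMSD (proper rotations only), ties broken by lowest structure
index, cluster sizes reported in non-increasing order. The RMSD cutoff
defaults to 0.1 nm but is configurable: at Calpha-trace resolution a
10-mer often needs ~0.25 nm before non-singleton clusters form, and the
reporting layer uses that when pooling variants. *Dominance analysis*
marks, for every cluster with more than 100 structures (strict), each
variant as dominated (> 80% share), neglected (< 1%), or neutral, with the
expected share under uniform contribution reported alongside; "neglected"
is evaluated per (cluster, variant) pair so counts can be summed over
variants.

## NMR secondary-shift stage

Secondary shifts are observed minus random-coil reference per nucleus; the
packaged random-coil Calpha/Cbeta table follows the Wishart-style
reference sets. The per-residue secondary structure propensity is
$\mathrm{SSP} = \Delta\delta C_\alpha - \Delta\delta C_\beta$; consecutive
positive values indicate helix, negative sheet. The neighbour-corrected
calculator used on real data is a web tool whose internals are not
published, so the package implements a transparent approximation: a
centred 3-residue moving average that skips missing entries, then
normalisation by the packaged full-helix difference of 3.5 ppm
(+3.1 ppm Calpha, -0.4 ppm Cbeta) and clipping to [-1, 1] with clipping
reported. Glycine has no Cbeta (the Calpha term is used alone); proline
rows are flagged because amide-detected experiments typically miss them.

Fractional helicity of a region is the ratio of mean native SSP to mean
SSP of a helix-stabilised reference profile over that region — the role a
TFE-titrated sample plays experimentally — clipped to [0, 1].

## Synthetic data: what it does and does not emulate

The package is fully testable without downloads because both inputs are
generated:

* `sample_unbiased()` / `run_hremd()` generate conformational ensembles
  with tunable per-residue helix propensity and tunable compaction, the
  stand-in for the four water models.
* `generate_shift_table()` produces Calpha/Cbeta shift tables from a known
  helical-population profile plus Gaussian noise. With zero noise the SSP
  stage inverts it exactly (for non-glycine residues), which turns the
  whole NMR stage into a round-trip test.

The packaged scan sequence (residues 380-490 in full-length numbering) is
a *synthetic*, Axin-1-like stand-in — the deposited study sequence is not
reproduced here — designed to carry the same propensity architecture:
helix-prone binding regions around residues 391-420 (including Arg-Glu
spacings of the kind that stabilise those helices) and 461-480, and a
Pro/Gly-rich linker over 431-460. Scans segment from residue 381 so the
segment starts (391, 401, ..., 481) match the convention of 10-residue
segments through 490.

What passing tests therefore show: the estimators (WHAM, populations,
clustering, dominance, SSP) are correct on ensembles whose ground truth is
known, and the end-to-end contrasts (binding regions above linker; helix
suppression and chain expansion under the `V-TIP4P-D`-like preset) follow
from sequence through sampling to analysis. What they cannot show:
anything about real Axin-1 magnitudes, real water models, or all-atom
energetics — the surrogate encodes orderings, not physics at that
resolution.

## Numerical choices and degenerate inputs

* dRMSD gradient at R = 0: typed error, `squared = TRUE` fallback.
* WHAM: log-space window constants; disconnected window histograms raise
  an error naming the gap; non-convergence raises with the residual.
* Population with undefined interior bins below the boundary: a warning,
  and the bootstrap SD is doubled.
* Daura ties: lowest structure index wins; the partition is deterministic
  and permutation-stable up to that rule.
* Kabsch: proper rotations only (mirror images keep positive RMSD); RMSD
  computed by applying the rotation, not by the trace shortcut, for
  numerical robustness near zero.
* Overlapping beads (< 1e-6 nm) are a singular-geometry error in energy
  evaluation; the sampler additionally carries a short-range penalty
  guard so proposals cannot step into the singular region.
* Chains are built from internal coordinates, so virtual bonds are exact
  to machine precision; PDB round trips relax the bond check to the
  format's 1e-4 nm coordinate resolution.

## Problem sizes

The shipped tests and the reproduction script run 10-residue peptides with
12 windows, a few thousand sweeps per replica (thinned), 40-60k steps for
the 1D closed-form checks, 1e5 swap attempts for the acceptance statistic,
and a full 11-segment x 2-variant scan at 2500 sweeps per cell. These
sizes were chosen so each check has comfortable statistical margin while
the whole suite stays interactive; all of them are configuration
arguments, and production-quality profiles simply use more sweeps.

## Known limitations

* The helicity criterion is geometric, not energetic; absolute populations
  are not comparable to DSSP-based numbers, only orderings are.
* Variant presets are orderings, not fitted water models.
* The square-well contact term makes energies discontinuous in
  coordinates; fine for Metropolis sampling, unsuitable for dynamics.
* WHAM uncertainty is bootstrap-based and window-local; it does not model
  exchange-induced cross-window correlation (block weights mitigate the
  within-window part).
* The SSP neighbour correction is a plain masked moving average, an
  approximation to the published web tool's (unpublished) weighting.
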