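---
title: "Predicting DEER and PRE data from protein ensembles with a rotamer library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DEER and PRE data from protein ensembles with a rotamer library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinlabelr)
```

## The problem

Double electron-electron resonance (DEER) and paramagnetic relaxation
enhancement (PRE) both report on distances to a nitroxide spin label attached
at an engineered cysteine. The label itself is flexible: its unpaired
electron sits about 0.7 nm away from the backbone at the end of a mobile
arm. Any back-calculation from a structural model therefore has to model the
probe's conformational ensemble, not just the protein's.

`spinlabelr` does this with a rotamer-library approach. A library supplies a
finite pool of probe conformers, each with an intrinsic Boltzmann
probability $p_i^{int}$ obtained from clustering label simulations. At a
given site in a given protein conformation, every conformer is rigidly
superposed onto the backbone (N, CA, C) triad and re-weighted by its steric
energy against the protein:

$$p_i = \frac{p_i^{int} e^{-\epsilon_i^{ext}/kT}}{Z}, \qquad
  Z = \sum_i p_i^{int} e^{-\epsilon_i^{ext}/kT}.$$

$Z$ is the steric partition function: it is 1 for a fully exposed site with
no contacts, and collapses toward 0 where the probe cannot be accommodated.
Frames with $Z$ below a cutoff (default 0.05) are excluded from ensemble
averages, and the same quantity, scanned along the sequence with
`site_z_scan()`, is a practical screen for choosing labelling positions.

## Steric energy

$\epsilon^{ext}$ is a pairwise 6-12 Lennard-Jones sum over label and protein
heavy atoms within a 1 nm cutoff, with Lorentz-Berthelot combination and the
pair $\sigma$ scaled by a factor (default 0.5) that softens the repulsive
wall to mimic protein relaxation around the probe. Parameters are assigned
per element with representative CHARMM36-like values (`lj_default_table()`);
a user table with the same columns overrides them. Three choices here are
deliberate:

* The label's backbone triad atoms are excluded from the sum. After
  superposition they coincide with protein backbone atoms, so including them
  would count bonded-pair self-clashes.
* The environment contains all protein heavy atoms except the labelled
  residue's own side chain (conceptually replaced by the probe); its
  backbone stays. For a two-label DEER run the sites are placed
  independently and never see each other's rotamers.
* Attractive tails are kept: the full 6-12 form is evaluated, so
  $\epsilon^{ext}$ can be slightly negative and $Z$ can marginally exceed 1
  at a favorable surface site. Some established implementations clamp the
  energy at zero instead; keeping the tail is the mathematically plain
  reading of the potential. Energies above 700 kT are treated as hard
  clashes (weight exactly zero) to avoid exponent underflow.

Temperature (default 298 K) enters only through the kJ/mol to kT
conversion.

## DEER

For each frame and each rotamer pair $(i, j)$ across the two sites, the
distance between the nitroxide N-O bond midpoints (the paramagnetic
centers) is deposited with weight $p_i p_j$ into a histogram with half-open
bins of width $dr = 0.05$ nm covering $[0, 12)$ nm. Frame histograms are
averaged with uniform or user-supplied weights (e.g. to unbias enhanced
sampling), after $Z$-cutoff filtering, and the average is smoothed once with
a unit-area Gaussian of standard deviation 0.05 nm (user-settable;
$\sigma = 0$ is the identity). Filtering after, not before, averaging keeps
the per-frame records exact for reweighting.

The dipolar signal is
$$S(t) = \int P(r)\, K(r, t)\, dr, \qquad
  K(r,t) = \sqrt{\frac{\pi}{6\omega t}}\left[\cos(\omega t)\,
  \mathrm{C}\!\left(\sqrt{\tfrac{6\omega t}{\pi}}\right) +
  \sin(\omega t)\, \mathrm{S}\!\left(\sqrt{\tfrac{6\omega t}{\pi}}\right)\right],$$
with Fresnel integrals C, S and the dipolar frequency
$\omega = (\mu_0/4\pi) g^2 \mu_B^2 / (\hbar r^3)$ (52.04 MHz at 1 nm). The
kernel is the closed form of the powder average
$\int_0^1 \cos[(3x^2 - 1)\omega t]\,dx$, and the test suite holds the two
routes to within $10^{-6}$ of each other. $K(r, 0) = 1$ by the continuous
limit. The quadrature in $S(t)$ is trapezoidal on the uniform grid (the
rule is not dictated by the physics; it is documented so results are
reproducible to the digit). The form factor is
$V(t) = 1 + \lambda[S(t) - 1]$ with the modulation depth
$\lambda \in [0.02, 0.5]$; given a background-corrected experimental trace,
$\lambda$ has the closed-form least-squares estimate
$\sum(V-1)(S-1) / \sum(S-1)^2$, clipped to the physical range with a
warning. Default time grid: 0.01 to 5.5 microseconds in 0.01 steps, both
endpoints included.

## PRE

For a single labelled site, the same placement machinery yields
electron-proton distances $r_i$ from each rotamer center to every backbone
amide proton (atom name `H`, `HN` accepted; the labelled residue is
excluded, and residues without an amide proton are skipped and reported).
Treating the rotamers as a discrete jump model, the generalized order
parameter factors into radial and angular parts,

$$S^2_{radial} = \frac{\langle r^{-3}\rangle^2}{\langle r^{-6}\rangle},
\qquad
S^2_{angular} = \sum_{i,j}\left[\tfrac{3}{2}\cos^2\Omega_{ij} -
\tfrac{1}{2}\right] p_i p_j,$$

with $\Omega_{ij}$ the angle between the proton-to-center unit vectors.
These enter the model-free spectral density

$$J(\omega) = \langle r^{-6}\rangle\left[
  \frac{S^2 \tau_c}{1 + \omega^2\tau_c^2} +
  \frac{(1 - S^2)\,\tau_t}{1 + \omega^2\tau_t^2}\right]$$

and the Solomon-Bloembergen transverse rate
$\Gamma_2 = \tfrac{1}{15}(\mu_0/4\pi)^2 \gamma_I^2 g^2 \mu_B^2\,
s_e(s_e+1)[4J(0) + 3J(\omega_I)]$, $s_e = 1/2$. The interface takes
$(\tau_c, \tau_t)$ directly, matching how practitioners quote them
($\tau_c$ from protein tumbling, typically 1-10 ns; $\tau_t$ additionally
folds in the internal label motion of 0.1-0.5 ns, so $\tau_t \le \tau_c$ is
enforced). Angular averaging is within-frame across rotamers; across frames
only $\Gamma_2$ is averaged ($\langle\Gamma_2\rangle = \sum_k w_k
\Gamma_{2,k}$), which assumes label motion is fast compared to protein
conformational exchange. Frames below the $Z$ cutoff are excluded; if all
frames are excluded the result is an explicit missing value, never a silent
zero.

Intensity ratios follow
$I_{para}/I_{dia} = R_2^{red} e^{-\Gamma_2 t_d} / (R_2^{red} + \Gamma_2)$,
with the INEPT delay $t_d$ (default 10 ms) used verbatim as the exponent's
time constant and $R_2^{red}$ the diamagnetic-state rate (default
12.6 s$^{-1}$, proton Larmor frequency default 750 MHz).

A comparison mode (`mode = "cbeta"` / `cbeta_gamma2()`) places the electron
at the labelled residue's C-beta instead, the common shortcut in simulation
restraints. With a single electron position $S^2 = 1$ and only $\tau_c$
enters. Because the shortcut ignores the roughly 0.7 nm probe arm, it can
mis-state electron-proton distances by several Angstrom, which the
$\langle r^{-6}\rangle$ dependence amplifies; the mode exists to quantify
exactly that.

## Files and containers

Rotamer libraries are bundles: a weights text file (one non-negative number
per line, `#` comments ignored), a topology PDB, conformer coordinates as a
DCD trajectory or multi-model PDB, and a YAML manifest mapping the library
name to the files and to the triad/nitroxide atom names (naming differs
between libraries, so it is configurable per entry). Bundle files use the
PDB/DCD native Angstrom; everything inside the package is nm, microseconds
(DEER) and seconds (PRE). Library conformers are used in whatever canonical
frame the bundle ships - placement aligns triads directly, so no axis
convention is imposed on load.

A synthetic 46-conformer library (`toy46`) ships with the package for
examples and the command line; it is schematic (a jittered linear arm ending
in an N-O pair), not a parameterization of any real probe.

Runs write the field's conventional file set: `res-<i>-<j>.dat` (r, raw and
filtered $P(r)$), `res-<i>-<j>-trace.dat` (t, S, V), `res-Z-...dat`
(per-frame partition functions), a per-frame binary container (`.rds`) from
which ensemble averages can be recomputed exactly under new weights, and a
YAML run manifest recording every parameter. Trajectories are read from DCD
or multi-model PDB; XTC is not supported and is rejected with a clear
message. Insertion codes are unsupported; chain IDs may be omitted only for
single-chain files (ambiguity is an error, never a silent first match).

## What the synthetic fixtures do and do not show

All tests run on generated data: ideal helix/extended backbones, toy
libraries with controlled arm directions, and a two-chain, two-state
trajectory whose inter-label center distance is constructed to be exactly
$d_1$ or $d_2$ per frame. That construction makes the expected ensemble
$P(r)$ known to machine precision (masses $f$ and $1-f$ in single bins),
so the pipeline's bookkeeping - pair weighting, $Z$ filtering, frame
weights, normalization - is checked exactly. What these fixtures do not
exercise is chemical realism: real MTSSL rotamer geometry and weights,
crowded protein surfaces, and experimental noise and background. Passing
tests therefore validate the mathematics and the plumbing, not agreement
with any particular experiment.

Problem sizes were chosen to keep the whole suite fast while still covering
the combinatorics: libraries of 1-46 conformers, structures of 3-10
residues, ensembles of 1-100 frames, 100-seed property sweeps for
normalization and 1000-draw sweeps for the order-parameter bounds.

## Numerical choices

* Superposition is Kabsch least-squares on exactly the three triad atoms,
  equal weights, reflections forbidden (the smallest singular direction is
  flipped when the determinant is negative).
* The Gaussian filter is evaluated as a discrete convolution (FFT-backed)
  with the kernel truncated at $6\sigma$ and renormalized, so mass leaking
  off the grid edge cannot break normalization.
* The kernel's removable singularity at $t = 0$ is handled by returning 1
  for $\omega t < 10^{-10}$.
* Histogram bins are half-open; a pair distance at or beyond 12 nm is
  dropped with a warning naming the lost probability mass.
* Physical constants are CODATA 2018 values kept in one table
  (`spin_constants()`), with $g = 2.0023$ and
  $\gamma_I = 2.67522 \times 10^8$ rad s$^{-1}$ T$^{-1}$.

## Limitations

No electrostatics or solvation in the placement energy; no intermolecular
background correction or regularized inversion of time traces (this package
only goes forward, from structure to signal); no longitudinal PRE, non-proton
nuclei or cross-correlated relaxation; libraries are loaded, never built
(library construction from label simulations is a separate problem).
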