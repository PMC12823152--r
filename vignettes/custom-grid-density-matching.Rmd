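---
title: "Custom-grid sedimentation velocity analysis and D2O density matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Custom-grid sedimentation velocity analysis and D2O density matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedgrid)
```

## The problem

Sedimentation velocity in the analytical ultracentrifuge (AUC) measures the
radial transport of solutes in a spinning sector cell. For lipid
nanoparticles (LNPs) and similar soft nanocarriers the particle density is
close to — and sometimes below — the solvent density, so the buoyancy term
$1 - \bar{v}\rho$ can take either sign within one sample: part of the
population sediments while the rest floats. Classical grid analyses assume a
single, known partial specific volume $\bar{v}$ and cannot represent this
regime. `sedgrid` implements a *combined grid* over both buoyancy signs: the
basis spans sedimentation coefficients $s$ of both signs and $\bar{v}$ values
on both sides of $1/\rho$, at a fixed frictional ratio, so one basis fits
purely sedimenting, purely floating, and mixed samples without
reconfiguration. Repeating the experiment over a series of D2O-graded
solvent densities and extrapolating each boundary fraction's
viscosity-corrected $s$ to zero then yields the particle density (the
*density-matching* analysis), and from it molar mass and hydrodynamic radius
distributions.

## Model and relations

Transport of each ideal species follows the Lamm equation

$$\frac{\partial C}{\partial t} =
  -\frac{1}{r}\frac{\partial}{\partial r}
  \left[s\omega^2 r^2 C - D r \frac{\partial C}{\partial r}\right],
  \qquad m < r < b,$$

with zero flux at the meniscus $m$ and bottom $b$. The data model is a
non-negative linear combination of such solutions plus optional systematic
offsets (below). The per-species parameters are tied together by the
Svedberg relation $s = M(1-\bar v\rho)/(Nf)$, the Einstein relation
$D = RT/(Nf)$, the Stokes relation $R_h = f/(6\pi\eta)$, and the
minimal-sphere construction: the particle volume $V = M\bar v/N$ defines the
radius $R_0$ of the equal-volume sphere, $f_0 = 6\pi\eta R_0$, and the
frictional ratio $\alpha = f/f_0 \ge 1$. Holding $\alpha$ fixed makes $D$ a
closed-form function of $(s, \bar v)$ and the solvent:

$$D = \frac{RT}{N\,18\pi(\alpha\eta)^{3/2}}
      \left(\frac{s\,\bar v}{2(1-\bar v\rho)}\right)^{-1/2}.$$

All internal arithmetic is CGS (cm, g, s, poise, erg); $s$ is stored in
seconds and displayed in Svedberg ($10^{-13}$ s). $\bar v$ is the *apparent*
particle value including hydration and bound ions; no anhydrous correction
is applied anywhere. Conversions are refused inside a buoyancy exclusion
band $|1-\bar v\rho| < 10^{-4}$ (configurable), where the parameterization
degenerates and implied masses diverge.

```{r hydro}
w <- solvent_state(0.99823, 0.010016, 293.15)   # water, 20 C
sol <- solute_from_mass(1e8, 0.98, 1.1, w)
c(s_svedberg = to_svedberg(sol$s), Rh_nm = sol$Rh * 1e7)
```

## Solvent model

Densities and viscosities of H2O/D2O mixtures come from embedded handbook
tables (0–40 °C), combined linearly in D2O volume fraction; salts enter as a
constant density increment (default 0.0046 g/mL for 1x PBS, applied at every
D2O fraction because the salt is reconstituted in D2O) and a viscosity
multiplier. Explicit overrides bypass the tables, so any externally computed
solvent state can be injected; this also absorbs any residual table
inaccuracy. Temperatures outside the tabulated range are refused.

## Numerical choices

**Lamm solver.** Fixed uniform radial grid (default 600 nodes for
simulation, 240 for fitting bases), conservative finite-volume
discretization with Scharfetter–Gummel exponential-fitting fluxes, and
adaptive backward-Euler stepping controlled by step-doubling with a local
error target of $10^{-6}$ of the loading concentration ($10^{-5}$ for
fitting bases — far below the experimental noise floor of ~3 mOD).
This scheme conserves mass to machine precision, is positivity preserving
(the implicit matrix is an M-matrix), handles flotation with no special
casing, and is exact for the equilibrium exponential steady state. Moving
meshes (as in ASTFEM) are deliberately avoided: the fixed conservative
scheme is simpler and is validated in the test suite against the
method-of-characteristics limit ($D \to 0$), the radial-dilution law, and
the closed-form equilibrium profile. The rotor is at speed from $t = 0$; no
acceleration phase is modeled.

**NNLS.** Amplitudes are found by a Lawson–Hanson active-set solver written
for this package, operating on the design matrix with QR subproblem solves
and exact KKT termination (gradient tolerance $10^{-12}$ relative to the
initial gradient). Working on the design matrix rather than the normal
equations matters here: neighboring basis solutes are nearly collinear, and
squaring the condition number would cap amplitude accuracy far above the
noise-free recovery the test suite requires. Warm starts across repeated
solves make Monte Carlo refits cheap. The solver is cross-checked against an
independent reference implementation in the tests.

**TI/RI noise.** Time-invariant (per-radius) and radially-invariant
(per-scan) offsets are estimated jointly with the amplitudes by projecting
the noise-reachable subspace out of both the data and the basis (the
balanced two-way additive-model projector) before the NNLS solve. This
lands in one pass on the fixed point that the classical alternating scheme
(NNLS, then per-radius residual means, then per-scan residual means)
approaches only slowly when slow solutes correlate with the TI vector. The
RI vector is constrained to zero mean, with the absorbed offset moved into
the TI vector — a pure reporting convention that changes the noise vectors
but never the fitted signal model.

**Iterative refinement.** The combined grid is partitioned into interleaved
subgrids that each span the full $(s,\bar v)$ range; partitions are fitted
in sequence, with the surviving nonzero solutes carried into the next fit,
and passes repeat until the support set stabilizes. Because every candidate
set contains the previous support, the rmsd is non-increasing along the
schedule. This sequential accumulation stands in for a parallel
merge schedule; results are by construction independent of partition
execution order at the fixed point.

**Meniscus/bottom refinement.** Grid search with a full fit per candidate,
followed by parabolic interpolation of the rmsd minimum along each axis; an
edge minimum is flagged as not bracketed.

**Monte Carlo.** Synthetic replicates are the model prediction plus
homoscedastic Gaussian noise with $\sigma$ equal to the fit rmsd (residual
resampling is available as an option). Each iteration refits over the
converged model's candidate solute set — a desk-scale simplification of
refitting the full grid, justified because the candidate set is exactly the
support the full refinement converged to. Iteration seeds are derived from
the master seed, so ensembles are reproducible regardless of execution
order.

## Density matching

For each D2O fraction, the (Monte Carlo) sedimentation distribution is
corrected for buffer viscosity only — $s' = s\,\eta/\eta_{\mathrm{ref}}$ —
which makes an ideal species' $s'$ exactly linear in solvent density, since
the viscosity dependence of the frictional coefficient divides out. The
distribution is then cut into boundary fractions: equal-signal quantile
slices of the cumulative (signed-$s$-ordered) distribution, after excluding
a 2% tail on each side (defaults: 100 fractions, 2% tails; both
configurable). Fractions are paired across densities by quantile rank,
taken in the direction of each condition's dominant transport: when a
condition's signal-weighted mean $s$ has the opposite sign to the
reference's — the whole sample has crossed its match point and the signed-s
ordering has therefore reversed — its fraction order is flipped before
pairing. With this orientation rule the pairing is exact whenever all
species share one $\bar v$ (even across the match point) and for any
mixture whose mobility rank order is density-independent; it remains
approximate for conditions in which only part of the sample has crossed
the match point, and for samples with uncorrelated size and density —
the method's central assumption. Per fraction, ordinary (unweighted) least
squares of $s'$ on $\rho$ gives the zero crossing $\rho_m$, i.e.
$\bar v = 1/\rho_m$; a non-negative slope or a crossing outside
(0.9, 1.3) g/mL marks the fraction unmatchable. Molar mass and
hydrodynamic radius are then derived at the reference condition (the least
dense solvent, which carries the largest $|s|$ signal) through the
fixed-$\alpha$ parameterization; fractions whose reference buoyancy falls
inside the exclusion band are skipped and counted.

## The synthetic-data generator

`make_density_series()` emulates an LNP density-matching experiment:
particles drawn lognormal in hydrodynamic radius and normal in $\bar v$
(truncated at 2 sd), independently — the true size–density correlation
within a formulation is unknown, and this independence is a stated
simplification. Four presets cover empty, protein-conjugated, mRNA-loaded,
and conjugated-plus-loaded LNP archetypes, with density windows near
0.991, 0.985, 0.982 and 0.979 mL/g respectively, masses between $3\times
10^5$ and $1.2\times 10^8$ Da, and a fixed frictional ratio of 1.1
(near-spherical particles). The mRNA-loaded preset, measured in 1x PBS at
0/10/15/20% D2O, reproduces the canonical regime sequence: all-sedimenting
at 0–10%, mixed sedimenting/floating at 15%, all-floating at 20%.

Scans default to 30 krpm, 20 °C, a 5.9–7.2 cm column, 10 h of scans, and
three noise components: i.i.d. Gaussian noise (default sigma 0.003 signal
units, a realistic shot-noise level for ~0.8 OD loading), a smooth
time-invariant Gaussian bump over radius (a window artifact), and zero-mean
per-scan offsets. Observation radii exclude 0.03 cm at each end of the
column by default, mirroring the usual practice of trimming the meniscus
and back-of-cell regions where floating or pelleting material accumulates
in thin layers. Everything is seeded; the ground-truth population and the
per-density solute tables ship with the scan sets, so no injected quantity
is unrecoverable.

What passing recovery tests on these simulations does **not** show: realism
of optical artifacts beyond the TI bump, concentration-dependent
non-ideality ($s(C)$, $D(C)$), solvent compressibility, H/D exchange
effects on $\bar v$, or correlated size–density structure. Results on real
data inherit the assumptions above, most importantly rank-preserving
fraction pairing across densities.

## Grid configuration across a density series

A subtlety of fitting every density with "the same grid": a fixed numeric
$\bar v$ range cannot be sign-consistent at every solvent density (a
sedimenting-block bound of 0.999 mL/g is buoyant in 15% D2O). `lnp_grid()`
therefore treats the grid as a *specification* — s range, $\bar v$ windows,
point counts, fixed $\alpha$ — and realizes it per buffer, clipping each
block's $\bar v$ bound to the buoyancy-valid side of $1/\rho$. Grid points
violating sign consistency are errors, never silently dropped, so a
mis-specified block fails loudly. The default LNP configuration (s from
1 to 100 S on each side, $\bar v$ 0.94–0.999 and 1.003–1.05 mL/g, 200
s-points split between the blocks in proportion to their spans, 120
$\bar v$-points per block) realizes 24 000 basis solutes. The examples and
acceptance analyses in this package use reduced grids (tens of s-points,
10–25 $\bar v$-points per block, logarithmic |s| spacing) whose resolution
matches the information content of the reduced synthetic data sets they
fit; these problem sizes keep a full density-matching pipeline in minutes
on one CPU.

Two grid lower bounds on $|s|$ are used deliberately. Density-series fits
use $|s| \ge 1$ S: a basis solute that traverses only a few percent of the
column over the whole run is numerically degenerate with the TI noise
vector, and NNLS will park large spurious amplitudes on such members,
inflating the fitted signal and distorting the cumulative-signal quantiles
that density matching pairs on. Conversely, when the goal is fit quality on
a near-match condition — where real species legitimately have $|s| < 1$ S —
a slow-coverage grid (down to 0.15 S, with fine $\bar v$ resolution near
$1/\rho$) is the right tool, because those species must be representable
for the residuals to reach the noise floor. The mixed-regime demonstration
uses the slow grid; the density-matching pipeline uses the $\ge 1$ S grid.

The s-point count of a density-matching grid follows from the precision
demanded of the molar mass: $M \propto s^{3/2}$, so recovering $M$ within
$\pm 15\%$ requires the s discretization's mid-step error
($\approx$ half the relative step) to stay near 5% — hence $\sim$76
logarithmically spaced points per sign block over 1–40 S. The $\bar v$
axis can stay coarse (8 points per block) because the extrapolated
matching density, not the basis $\bar v$, carries the density estimate.

## Open choices made here

* The literature grid bounds "−100 to −1 s" are read as Svedberg, the only
  physically sensible unit for nanoparticle work.
* 200 s-points over two sign blocks are split proportionally to each
  block's span; the $\bar v$ budget applies per block (hence
  $100 \times 120 \times 2 = 24\,000$).
* PCSA is implemented for straight-line $\bar v(s)$ families only, with a
  deterministic tie-break (smallest $|$slope$|$, then smallest intercept);
  sigmoidal parameterizations are out of scope. The PCSA default fixes
  $\alpha = 1.1$, matching the combined-grid analyses.
* Extrapolation to zero sedimentation is linear in $\rho$, which the
  Svedberg relation makes exact after viscosity-only correction; no
  higher-order model is offered.
* Fractions whose $s$ changes sign across densities are ordered by signed
  $s$ throughout.

## A worked pipeline

```{r pipeline, eval = FALSE}
# simulate an mRNA-LNP-like density series (reduced sizes for speed)
series <- make_density_series(lnp_presets()[["LNP-mRNA"]],
                              d2o_fractions = c(0, 0.10, 0.15, 0.20),
                              times = seq(1200, 36000, length.out = 20),
                              n_radii = 240, seed = 7)

fits <- lapply(series$scans, function(data) {
  grid <- lnp_grid(buffer_state(data$buffer),
                   s_limits = c(1, 40), n_s = 152, n_vbar = 8,
                   vbar_sed = c(0.955, 0.999), vbar_float = c(0.97, 1.005),
                   s_spacing = "logarithmic")
  fit <- iterative_refine(data, grid, n_partitions = 6,
                          fit_ti = TRUE, fit_ri = TRUE)
  on.exit(clear_basis_cache())
  monte_carlo(data, fit, n_iterations = 20, seed = 11)
})

result <- density_match(fits, series$buffers, n_fractions = 20)
head(result$fractions)
plot_match_histograms(result)
```

The same pipeline is exercised end-to-end, with recovery checks against the
generating ground truth, by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

## Known limitations

* Basis caching stores one vector per (solute, experiment signature); very
  large grids multiply memory — `clear_basis_cache()` bounds it between
  experiments.
* The quantile-rank pairing biases fractions where the s rank order
  changes between densities (broad $\bar v$ *and* broad size in one
  sample); errors appear mostly in the outermost fractions.
* Near the density-match point the fixed-$\alpha$ parameterization is
  singular; species inside the exclusion band are represented only through
  their diffusion signature and are skipped in mass derivation.
* Intensity-optics specific noise structure, regularized inversions, and
  genetic-algorithm refinement are not implemented.
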