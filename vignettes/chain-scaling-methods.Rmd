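---
title: "Scaling exponents and fractal dimensionality of folding chains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling exponents and fractal dimensionality of folding chains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainscaling)
```

## The model

A linear polymer of $N$ segments of length $a$ obeys a size-scaling law
$R \sim a N^{\alpha}$, where the exponent $\alpha$ encodes how the chain
fills space: $\alpha = 1$ for a fully stretched (one-dimensional) chain,
$\alpha = 1/2$ for the ideal chain at the theta point, $\alpha \approx
0.588$–$0.6$ for an excluded-volume coil in good solvent, and $\alpha = 1/3$
for a compact globule. The reciprocal $D = 1/\alpha$ is a fractal
dimensionality that runs from 1 (line) through 2 (ideal chain) to 3
(globule) as a protein folds.

The package's central quantity is the radius of gyration
$$R_g^2 = \frac{1}{N}\sum_{k=1}^{N} (\mathbf r_k - \mathbf r_C)^2,$$
computed with equal bead masses. Two geometries anchor closed forms:
the stretched chain, $R_{g0} = L/\sqrt{12}$ with contour length $L = a N$,
and the ideal chain, $R_g = a\sqrt{N/6}$. Writing $R_g = k(\alpha)\,a
N^{\alpha}$ and interpolating the prefactor between these anchors as
$k(\alpha) = 1/\sqrt{12\alpha}$ gives the forward prediction
$$R_g(\alpha) = R_{g0}\,\alpha^{-1/2} N^{\alpha-1},$$
implemented in `rg_from_alpha()`. The interpolated $k(\alpha)$ is an
assumed form: it is exact only at its two anchors, and everything the
package infers between them inherits that assumption. Taking logarithms,
$$\ln\frac{R_g}{R_{g0}} = -\tfrac12\ln\alpha + (\alpha - 1)\ln N,$$
which `alpha_from_rg()` inverts numerically: given an observed $R_g$ and
the chain parameters, the per-frame exponent — and hence $D(t)$ — can be
tracked through an entire folding trajectory.

Flory theory supplies an independent account of the coil exponent. With an
excluded volume $v$ per segment, the (proportional, dimensionless) free
energy $F(L) \sim N^2 v / L^3 + L^2/(N a^2)$ balances two-body repulsion
against entropic elasticity; its stationary point is $L^* = ((3/2) N^3 v
a^2)^{1/5} \propto N^{3/5}$, i.e. $\alpha = 3/5$. `flory_minimize()`
locates the minimum numerically (coarse log-spaced bracket scan, then
golden-section/parabolic refinement via `optimize()`) and carries the
analytic stationary point alongside as a cross-check; `flory_exponent()`
fits $\ln L^*$ against $\ln N$ and recovers the slope $0.6$ to machine-level
accuracy because the law is exact.

## Numerical choices in the inversion

The left side of the log relation is monotone increasing in $\alpha$ only
for $\alpha > 1/(2\ln N)$; below that it turns over, and a given $R_g$ can
correspond to two roots. Root-finding is therefore restricted to the
increasing branch, bracketed on
$[\max(1/(2\ln N) + 0.01,\ 0.20),\ 1.25]$, and solved with `uniroot()` at
tolerance $10^{-12}$ (equation residuals are below $10^{-9}$; the
$\alpha \leftrightarrow R_g$ round trip is exact to $10^{-8}$ across
$\alpha \in [0.35, 1]$).

Observed radii outside the attainable range of the branch do occur in
practice — discrete stretched chains have $R_g = a\sqrt{N(N+2)/12} >
L/\sqrt{12}$, and trajectory frames fluctuate — so out-of-range values are
clamped to the bracket edge and flagged `clamped_low` / `clamped_high`
rather than raised as errors. Exponents found slightly above 1
(over-stretched frames) are reported as found, but the dimensionality is
capped at $D = 1$ and the frame is flagged, since $D = 1/\alpha$ is only
meaningful on $\alpha \le 1$.

Two reporting conventions coexist. `report_mode = "full_precision"`
(default) carries unrounded $\alpha$ and $D = 1/\alpha$. `report_mode =
"paper_rounding"` rounds $\alpha$ to two decimals *before* forming $D$;
this is the convention under which an inverted folded-state radius of
$6.97$ Å at $N = 20$, $L = 73.61$ Å reads $\alpha = 0.52$, $D = 1.92$
(unrounded: $\alpha = 0.518$, $D = 1.93$). A related convention choice: the
worked-example closed forms quote the segment length at its printed
precision $a = L/N = 3.68$ Å; at that value the globule prediction
($\alpha = 1/3$ exactly — not its two-decimal rounding $0.33$, which
shifts the answer by $0.02$ Å) is $4.99$ Å, while the unrounded $a =
3.6805$ Å gives $5.00$ Å.

Two further prefactor decisions. The gyration radius of the embedding
sphere uses the about-centre solid-sphere value $R_g = \sqrt{3/5}\,R$,
which is the one consistent with the unweighted second-moment definition
above (the about-an-axis value $\sqrt{2/5}\,R$ is a different quantity and
does not reproduce the companion volume bookkeeping: $V = a^3 N \approx
997$ Å$^3$ embeds in a sphere of radius $6.2$ Å whose gyration radius is
$4.8$ Å). And when no excluded volume is supplied, $v = a^3$.

## What the synthetic generators emulate

No external structures are required: seeded generators produce ensembles
for every chain class the theory describes, so all estimators are testable
end to end.

* `make_stretched()` — the exact discrete rod; its $R_g$ exceeds the
  continuous $L/\sqrt{12}$ by the finite-size factor $\sqrt{(N+2)/N}$,
  which is why an analyzed rod frame lands just above $\alpha = 1$ and is
  flagged rather than reading exactly 1.00.
* `make_fjc()` — freely jointed chains with exact bond lengths and uniform
  random orientations; $\langle R_{ee}^2\rangle \to N a^2$ and
  $\langle R_g^2\rangle \to N a^2/6$.
* `make_saw()` — self-avoiding walks on the simple cubic lattice sampled by
  the pivot algorithm: random non-identity octahedral symmetries applied to
  chain suffixes, proposals rejected on any site collision. The pivot
  algorithm was chosen because naive chain growth fails beyond $N \approx
  50$, and a lattice walk makes the self-avoidance check exact (integer
  site keys). Defaults: burn-in $10N$, stride $N$, both overridable. At
  $N \in \{20, 40, 80, 160\}$ with 2000 retained samples per length, the
  fitted $\ln \bar R_g$ vs $\ln N$ slope lands near $0.59$; small-$N$
  corrections to scaling keep it slightly above the asymptotic $0.588$.
* `make_globule()` — compact chains grown sequentially with exact bond
  length, a $0.8a$ minimum non-bonded separation, confined to a sphere of
  radius $1.1\times$ the embedded-globule radius. Placement backtracks on
  dead ends; if the stochastic budget is exhausted the chain falls back to
  a deterministic spherical space-filling spiral honouring the same
  constraints (shells $0.85a$ apart, swept in alternating direction so the
  bond-length hop from one shell lands at the start of the next scan).
  Mean sizes scale with exponent $\approx 0.35$ at these lengths —
  compatible with the compact $1/3$ plus surface corrections.
* `make_folding_trajectory()` — frames that follow a prescribed
  $\alpha(t)$ schedule: seeded crankshaft rotations (preceded by a small
  Gaussian jitter, $\sigma = 0.02a$, without which crankshaft moves leave
  the initial collinear chain invariant) decorrelate the geometry, then a
  radial rescale about the centroid pins the frame $R_g$ to
  $R_g(\alpha_j)$ exactly. The rescale does not preserve bond lengths;
  that is acceptable because only $R_g$ enters the exponent estimator.
  Real folding has no construction like this — the synthesizer is a
  parameter-recovery harness, not a physical model.

What passing tests on these ensembles show — and do not show. They verify
the estimators: exact inversion round trips, rigid-motion invariance,
recovery of known exponents from ensembles constructed to have them. They
do not show that real proteins follow the interpolated $k(\alpha)$ between
its anchors, nor do the generators model heteropolymer sequence effects,
hydrophobic cores, secondary structure, solvent, or energetics of any
kind. Applying the pipeline to a real MD trajectory tests the theory;
applying it to these ensembles tests the code.

## Trajectory analysis and conventions

`analyze_trajectory()` reports, per frame: $R_g$, end-to-end distance,
optimal-superposition RMSD against an optional reference (Kabsch algorithm
via SVD, reflections corrected by flipping the smallest singular-value
axis), $\alpha$, $D$ and the clamp flag. Chain parameters resolve as:
explicit $L$, else $N \times a$, else the maximum observed end-to-end
distance (announced via a message — the $\alpha$ scale depends on
$R_{g0} = L/\sqrt{12}$, so a silently guessed $L$ would be hazardous).
`n_segments` defaults to the bead count. Frames are numbered from 0;
missing times fall back to the frame index.

File formats: multi-MODEL PDB is read through bio3d with C-alpha selection
(altloc blank or `A`) or all atoms; XYZ is the interchange format for
synthetic beads (no atom identities), written at 6 decimals with an
optional `t=` time token; profiles are TSV with a fixed header and
4-decimal floats, byte-stable under reruns. RMSF superposes each member
onto a user-supplied reference (default: the first member) and uses the
population (divide-by-$m$) convention. B-factor confidence classes use
strict thresholds: below 30 confident, above 60 disordered, boundaries
intermediate.

Determinism: every generator draws from streams derived from one root seed
by fixed increments, so ensembles are bit-identical under the same seed and
earlier samples survive an increase of `n_samples`.

## Problem sizes and limitations

The shipped tests and the acceptance script use the sizes stated above:
$10^4$ freely jointed samples at $N = 100$, $4 \times 2000$ pivot samples
at $N \le 160$, globule ensembles of 4–10 chains per length, 50-frame
synthetic trajectories. These run in well under a minute except for the
pivot sampler (tens of seconds). Known limitations: the exponent estimate
is only as good as the supplied contour length; the interpolation is
uncontrolled between its anchors; lattice walks at $N \le 160$ carry
corrections to scaling of order $N^{-1/2}$; and the globule generator's
exponent band ($0.30$–$0.38$) reflects surface effects at small $N$, not a
failure of the compact limit.
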