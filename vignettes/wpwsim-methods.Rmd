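---
title: "Modelling pre-excited 12-lead ECGs: methods and design notes"
author: "wpwsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pre-excited 12-lead ECGs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `wpwsim`, the
parameters that matter, the numerical choices, and — importantly — what
the synthetic anatomy does and does not stand in for.

## What the package models

An antegrade accessory pathway (AP) is a short atrioventricular bypass
tract: excitation enters the ventricles at the pathway's ventricular
exit site before the His–Purkinje system fires, producing ventricular
pre-excitation and the delta wave of WPW syndrome. The package
represents an AP by seven parameters

\[
\omega_{AP} = \{x_{atria}(\alpha,\gamma,\beta),\; CV_{AP},\;
x_{ven}(\rho,z,\phi)\},
\]

an atrial insertion site, a cable conduction velocity and a ventricular
exit site, all in universal cardiac coordinates (UCC) so that sites are
mesh-independent. The pre-excitation time is
\(t_{ven} = t_{atria} + d / CV_{AP}\), with \(t_{atria}\) the sinus
activation time at the insertion and \(d\) the geodesic length of the
tract. Exemplar septal pathways may instead prescribe \(t_{ven}\)
directly (the simulator accepts either form, mirroring the two usage
modes of such studies).

## The synthetic anatomy: what it emulates, what it does not

`buildAnatomy()` constructs a fully procedural stand-in for a
patient-specific biventricular model:

* two truncated ellipsoids truncated at a common base plane — a
  thick-walled LV (endocardial semi-axes 22/22/60 mm, 10 mm wall) and a
  thinner RV (18/18/48 mm, 5 mm wall) placed on the septal side with a
  2 mm septal gap bridged by short electrical edges (the shared septum
  of a real heart);
* analytic UCC on both chambers: apicobasal \(z\in[0,1]\) (0 apex),
  rotational \(\phi\in(-\pi,\pi]\) with \(\phi = 0\) at mid-septum
  increasing towards the anterior wall, transmural \(\rho\in[0,1]\)
  (0 endocardial). The rotational registration is a package convention:
  it is chosen once so that printed septal exemplar angles near
  \(-0.5\) rad land in septal bullseye sectors, and it is configurable;
* an electrically isolated atrial shell capping each base ring
  (isolation enforced by omitting atrio-ventricular electrical edges),
  with a sinoatrial node on the right shell and a fast (2 m/s)
  interatrial connection standing in for Bachmann's bundle;
* five His–Purkinje fascicular root sites (three LV, two RV) activating
  150 ms after sinoatrial onset, plus a fast endocardial layer
  (\(\rho < 0.15\), 1.5 m/s vs 0.6 m/s bulk) as the standard desk-scale
  surrogate for the distal Purkinje arborization — this default makes a
  \(t_{ven}\) of 125 ms pre-excite the ventricles while keeping a
  realistic PR interval;
* an electrically inert right-ventricular-outflow-tract sector
  (basal RV, 0.7 rad wide by default), excluded from propagation and
  from pathway sampling;
* nine torso-scale electrodes: V1–V6 on an anterior arc from
  right-parasternal to left-lateral, limb electrodes far outside the
  tissue.

What it does **not** emulate: patient image-derived wall geometry and
trabeculation, rule-based myocardial fibres (conduction is isotropic by
default), a physiological His–Purkinje tree, torso/lung conductivity
heterogeneity, and any personalization to a measured ECG. Consequences:
simulated amplitudes and exact transition leads are *not* comparable to
patient values; directional and ordinal statements (which leads flip
polarity when a pathway moves, which side has the steeper V2 S-wave
downstroke) are the quantities the model is designed to preserve.
Passing tests therefore certify the machinery and the mechanistic
orderings, not patient-level predictive accuracy.

## Activation and membrane voltages

The eikonal problem is discretized as shortest paths on the mesh edge
graph (26-neighbourhood of the structured chamber grids, so metric
error stays well below one edge length on convex regions); the edge
travel time is length over the harmonic mean of the endpoint
conduction velocities. This choice makes the solver exactly testable
against an independent Dijkstra oracle, at the cost of a small
anisotropic metric error that is irrelevant at the package's fidelity.
Activation from multiple sources is the minimum over sources of onset
plus travel time — adding a source can never delay activation, a
property the test-suite asserts.

Membrane voltages are recovered without diffusion by shifting a
stylized action-potential template to each node's activation time:
1 ms linear upstroke, plateau at +30 mV for 40% of the APD, cosine
repolarization back to −85 mV. The APD follows the linear mapping
\(APD(x) = apd_0 + s\,(\tau(x) - \min\tau)\) with defaults
\(apd_0 = 280\) ms and \(s = -0.3\), clipped at 120 ms; the defaults
are generic textbook-scale values (the mapping's published coefficients
live in prior calibration work and are not reproduced here). Beats are
700 ms at a 1 ms sample period.

## The pseudo-ECG and its gain

Electrode potentials use the homogeneous infinite-medium pseudo-ECG
\(\varphi = -k \int \nabla V_m \cdot \nabla(1/r)\,dV\), discretized on
the edge graph as the weighted Laplacian quadratic form
\(\varphi = -k \sum_{uv} w_{uv} (V_u - V_v)(1/r_u - 1/r_v)\) with
\(w_{uv} = \bar V_{uv} / \ell_{uv}^2\) (lumped node volumes). Because
the map is linear in \(V_m\), each electrode reduces to a per-node
weight vector computed once per anatomy; a beat's nine electrode traces
are then a single matrix product. The sign convention makes a wavefront
travelling towards an electrode deflect it positively, and the global
gain \(k = 0.028\) is calibrated once so sinus QRS amplitudes are of
order 1 mV before scaling. Torso lead fields with heterogeneous
conductivities are deliberately out of scope; the homogeneous medium
preserves the wavefront-direction-vs-electrode mechanisms the package
studies.

The 12 leads are assembled classically (Einthoven limb leads,
Goldberger augmented leads, Wilson central terminal for V1–V6), then
low-pass filtered at 150 Hz and scaled by 0.32. The filter is a
4th-order Butterworth applied forward-backwards (zero phase): the
clinical specification names only the 150 Hz cutoff, so order and
zero-phase application are package decisions. Clinical 50 Hz bandstop
and 0.05 Hz high-pass stages apply to measured ECGs, not to these
noise-free simulations, and are not applied. Both stages are lead-wise
linear, so the lead identities II = I + III and aVR + aVL + aVF = 0
survive postprocessing exactly.

## The database sweep

`sampleAPs()` draws Latin-hypercube samples of \(\omega_{AP}\):
exits over the sampled band \(z \in [0.5, 1]\), full rotation, full
wall depth; insertions over the whole atrial shell;
\(CV_{AP} = 2.0\) m/s (the fast, Purkinje-like conduction reported for
such tracts). Samples are rejected (not resampled) when the localized
pair is more than 60 mm apart — keeping tracts short and exits near
the atrioventricular junction — or when the exit resolves into the
inert RVOT; the acceptance rate is recorded. Batches are drawn until
the requested accepted count is reached, deterministically under the
seed. The default of 500 accepted pathways per ventricle is a
desk-scale choice: region coverage saturates (all 12 regions per
ventricle are hit from a few hundred samples) while a full database
builds in minutes; the tests use 150 per ventricle for the directional
morphology properties and the acceptance script's surrogate study uses
500 synthetic signals.

## Sensitivity analysis

The PCE surrogate uses a tensorized orthonormal Legendre basis on the
affinely normalized box of (ρ, z, φ, \(t_{ven}\)), total-degree
truncated, fitted by least squares per lead and timepoint; fits demand
at least twice as many samples as basis terms. Default degree is 5
where the sample budget allows; the in-package analyses use degree 3–4,
which the residual diagnostics justify at database sizes of a few
hundred beats (degree is a configuration, not a constant). Sobol
indices are read off the coefficients: the variance share of the terms
whose multi-index support equals a parameter combination. Following the
σ-weighting approach, \(\hat S_i(t) = S_i(t)\,\sigma(t)\) expresses
sensitivity as measurable millivolts of signal change;
\(\hat S_i = \int \hat S_i(t)\,dt\) (trapezoidal rule on the signal
grid, reported in mV·s) ranks overall importance, and division by
\(\int\sigma(t)\,dt\) yields proportions that sum to one per lead.
Indices are masked where \(\sigma(t) < 10^{-9}\) mV. The analysis runs
separately per ventricle. The surrogate reconstruction error is the
per-beat L2 mismatch normalized by the dataset's signal variance;
pooled-over-leads normalization is the default (per-lead is available)
since the pooled form is the natural single-number convergence
diagnostic. The surrogate is a sensitivity tool only: no inverse
(ECG-to-location) use is attempted or supported.

## Localization trees

Both implemented trees are deliberately *partial*: only branches whose
outcomes are printed in the literature this package engages with are
encoded, and everything else returns "indeterminate" with the
unresolved branch named. Completing the trees from their primary
publications is out of scope, and indeterminate outputs are first-class
results (they are what the evaluation harness counts). The delta wave
is measured as the mean deflection over the 40 ms after QRS onset
(configurable; the source algorithms do not define a measurement
window). QRS windows default to simulation ground truth (earliest
ventricular activation − 5 ms to latest + 10 ms); a slope-threshold
detector is the fallback for external signals. One reading noted in the
tree description: the phrase "three positive precordial leads" in the
printed septal walk-through is interpreted as the three *inferior*
leads (II, aVF, III), consistent with the tree's own branching
variable.

## Numerical and degenerate-case choices

* Zero-length edges are prevented by the septal gap and a 0.25 mm
  bridging-edge floor; pseudo-ECG edge weights floor the length at
  0.5 mm.
* UCC inversion solves a monotone radial equation by bisection
  (`uniroot`, tolerance 1e-10); points up to 4 mm outside the wall are
  projected, farther points raise an out-of-domain error.
* Nearest-neighbour localization uses the UCC metric
  \((\Delta z)^2 + (\Delta\phi/\pi)^2 + (\Delta\rho)^2\) with angular
  wrap-around, restricted to the requested chamber label; requests
  resolving into the inert RVOT are rejected rather than silently
  moved.
* Eikonal ties (equidistant sources) resolve to the minimum and are
  order-independent; sampling ties in nearest-node search resolve to
  the lowest index, making runs bit-reproducible.
* Beats whose \(t_{ven}\) exceeds the horizon fail validation; a
  horizon too short for full repolarization raises a truncation error
  rather than returning a clipped trace.
* The bullseye mid/apical boundary is z = 0.5 with the basal/mid split
  at 0.75 (two equal bands over the sampled half; the source
  regionalization names the bands but not a numeric boundary). The
  ordinal numbering of the 12 regions is not standardized, so regions
  are exported by name (`LV_basal_anteroseptal`, ...), never by index.

## Known limitations

Single beats only (no re-entry, no retrograde conduction, no multiple
simultaneous pathways); isotropic conduction; an analytic two-ellipsoid
geometry whose septum is a bridged gap rather than shared muscle;
uncalibrated absolute amplitudes; decision trees restricted to printed
branches. The deposit adapter (`readZenodoDatabase`) sniffs tabular
layouts; binary scientific containers it does not recognise produce an
explicit error listing what was found.
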