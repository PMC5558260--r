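---
title: "Methods: voxel FEM dosimetry for transcranial electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel FEM dosimetry for transcranial electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcranial electrical stimulation (tES/tDCS) delivers milliamp-level
currents through scalp electrodes, but the fraction of that current that
actually reaches a cortical target varies widely between electrode
configurations and between individuals — skull density, which varies by
sex and by skull region, is a dominant factor. `tesdose` implements a
complete forward-dosimetry analysis of this problem on synthetic head
phantoms: it models how much current density (µA/cm²) arrives in a 10 mm
sphere of cortex directly under a stimulating electrode for three montage
families (non-cephalic, bi-cranial, ring) at 0.5/1.0/2.0 mA, and analyses
a cohort of such measurements with a mixed-effects ANOVA on the log scale.

## Model chain and assumptions

1. **Phantom cohort.** Each head is a set of nested ellipsoids (scalp,
   skull, CSF, brain) plus a cylindrical neck stub reaching the domain
   floor, voxelized at 1 mm. The geometry is deliberately analytic: it is
   sufficient to exercise every pipeline stage (surface extraction,
   montage geometry, heterogeneous conduction, target sampling) while
   staying reproducible. Tissue water fractions are: scalp 0.70, CSF 1.00,
   brain 0.80, neck 0.70, and skull drawn per subject from a Beta
   distribution whose mean depends on sex — female 0.08, male 0.15
   (concentration 60). Sex enters the generator *only* through this skull
   water draw: the modelled sex difference is cranial density, not
   cranial thickness. The frontal skull sector (anterior quarter) is
   multiplied by a modifier with mean 0.7 (denser frontal bone), jittered
   per subject (log-normal, cv 0.12) so frontal and central skull are not
   perfectly coupled. Shell radii receive a log-normal jitter (cv 0.04)
   truncated at ±2.5 sd — bounded anthropometric variation that also
   guarantees the head fits its grid. No quantitative sex gap in skull
   density was available to calibrate against; these values are stated
   configuration, not ground truth.

2. **MRI simulation and combination.** T1/T2/PD-like channels are fixed
   monotone maps of water fraction w: PD ∝ w, T2 ∝ √w, T1 ∝ (1 − w) on
   head voxels, each with optional truncated Gaussian noise.
   `combine_mri()` inverts each map — PD and T2 gains recovered from the
   channel maximum (attained in CSF where w = 1), the T1 gain by
   least-squares against the PD-derived estimate — and averages with
   weights (PD 0.5, T2 0.25, T1 0.25), clamping to [0, 1]. A percentile
   min-max normalization was considered and rejected: clipping rescales
   the channels and breaks the exact noiseless round-trip
   (water fraction → triplet → combined v) that the pipeline's
   verification relies on. Air is detected as voxels dark in both PD and
   T1 (bone is T1-bright, fluid is PD-bright, air is neither) and set to
   v = 0.

3. **Resistivity.** R(v) = K·(1−v)^E + D with K = 16000, E = 4, D = 65.
   The output unit is taken as Ω·cm: D = 65 then matches CSF-like
   resistivity, and the resulting brain current densities land in the
   µA/cm² range typical of tES dosimetry. Conductivity is σ = 1/R (S/cm);
   air is excluded from the conduction domain.

4. **FEM solve.** Trilinear hexahedral (voxel) elements, Galerkin
   assembly with per-voxel σ; the reference element matrix is integrated
   with 2×2×2 Gauss quadrature (exact for this integrand, verified in the
   tests against an independent 4-point rule). The pure-Neumann operator
   is solved with Jacobi-preconditioned conjugate gradients; the constant
   null-space mode is projected out of the preconditioned residual every
   iteration and the potential is reported in the zero-mean gauge. This
   is algebraically the same gauge as "pin one node, then re-centre" but
   avoids modifying the sparse matrix. Default relative tolerance 1e-8
   (the acceptance script relaxes it to 1e-6 for runtime; doses are
   stable well beyond either). Units are fixed and locked by a dedicated
   test: σ in S/cm, currents in mA, geometry in mm → potential in mV,
   current density J = −σ∇φ in µA/cm² after a factor 1000.

5. **Montages.** 10–20 sites are placed by angular parametrization of the
   scalp: C3/C4 at 40% of the vertex-to-ear arc (36°), F3/F4 on the arc
   18° anterior; the placement convention only needs to be reproducible
   across subjects because the target sits directly under the electrode.
   Electrodes are 10 mm discs realized as the set of scalp-surface voxels
   within 5 mm geodesic distance and the corner nodes of their exposed
   faces; current is split uniformly over those nodes (perfect
   electrode-skin contact, no impedance model). Ring cathodes sit at
   30 mm geodesic (surface) distance, 90° apart, each carrying −I/4; the
   bi-cranial return is the contralateral homologue at −I; the
   non-cephalic return is the neck-stub base patch on the domain floor
   (torso truncation). Every montage sums to exactly zero net current.

6. **Target and dose.** The 10 mm target sphere is found by marching
   inward along the electrode normal to the brain surface, then one
   radius deeper, so the sphere is tangent to the brain surface under the
   electrode; on tight phantoms it is pushed deeper (≤ 8 mm) until fully
   inside brain. Membership is voxel-centre-within-radius (515 voxels on
   an integer-aligned centre; the count is grid-offset dependent within
   [480, 560]). The dose statistic is the mean of per-voxel |J| —
   magnitude first, matching dosimetry convention, rather than the
   magnitude of the mean vector. The same sphere is reused for all 18
   conditions of a subject.

7. **Statistics.** The 18-rows-per-subject table (3 configurations × 2
   sites × 3 intensities) is modelled on the natural-log scale:
   `log_dose ~ configuration + sex + site + intensity + (1 | subject)`,
   REML via `lme4`, with reference levels ring / female / C3 / 0.5 mA.
   Natural log (not log10) is required for internal consistency of
   exponentiated coefficients read as fold-changes (exp(0.70) ≈ 2).
   Intensity is a 3-level factor, not a covariate. Wald 95% CIs and
   normal-approximation p-values are reported; the exact flavour of
   p-value is not an acceptance surface. An optional model adds the three
   two-way interactions (configuration×site, configuration×sex,
   site×sex). Because the design is balanced, the mixed-model fixed
   effects equal the corresponding contrasts of cell means of log dose —
   an identity the tests assert to 1e-8.

## One solve per condition family

The problem is linear in the injected current, so each subject needs only
one solve per configuration × site (at 1 mA); 0.5 and 2.0 mA doses are
exact scalar multiples. This is both a 3× saving and the mechanism behind
the doubling law: the exponentiated intensity coefficients are forced to
2 and 4 on any forward-modelled cohort, matching the reported 2.012 and
3.995 to well within 1%. A configuration flag (`independent_solves`)
forces per-intensity solves for verification.

## What the generator does and does not emulate

The synthetic world reproduces: the tissue-shell structure and its
resistivity contrasts, a sex difference carried purely by skull water
content, a denser frontal bone narrowing the sex gap at F3, individual
morphological variability, and the full 18-condition design. It does
*not* emulate cortical folding, anisotropy, real skull porosity maps,
scanner artefacts, or regionally independent skull variation — in
particular, because one skull-water parameter (plus a jittered frontal
modifier) drives a whole head, cross-site (C3 vs F3) correlations are
structurally high in the phantom world, unlike the weak correlations
observed on real heads. A green qualitative test therefore establishes
that the pipeline produces the expected *structure* (configuration
ordering, male > female in every cell, exact doubling), not the
magnitudes measured on real-head cohorts: fold-changes of that size
(≈2.8 bi-cranial, ≈9.7 non-cephalic, ≈1.9 male) require full-size heads
with thick resistive shells and are compressed at desk scale, where
heads are smaller and shells thinner.

## Numerical choices

- CG tolerance 1e-8 (default) / 1e-6 (acceptance runs); Jacobi
  preconditioner; non-convergence is an error, never a silent result.
- The slab oracle uses consistent (area-weighted) nodal loads so the
  linear closed form lies exactly in the FE space; electrode loads on
  heads use uniform nodal splitting per the perfect-contact assumption.
- The homogeneous-sphere oracle compares against the Legendre series for
  two surface point electrodes, evaluated at interior voxel centres with
  r ≤ 0.85 R, excluding 4 mm balls around the singular injection points;
  measured relative RMS error at 1 mm resolution is ≈ 2%.
- Degenerate inputs fail loudly: non-nested shells are resampled a
  bounded number of times then error; grids too small for the head, the
  ring, or the target sphere raise sizing errors naming the constraint;
  disconnected conduction domains are reported at assembly.
- Seeds: every stochastic draw derives from one master seed via a fixed
  integer map (kept below 2^31); morphology is deterministic given
  (seed, subject index) independent of cohort order.

## Design decisions taken where the contract was open

- Config files are JSON (no YAML parser in the supported dependency set).
- NIfTI I/O is a minimal NIfTI-1 float32 reader/writer implemented in the
  package, as no NIfTI-capable R package is available in the supported
  environment.
- The non-cephalic return uses the whole neck-stub base patch rather than
  a 10 mm disc: the stub base is the truncation boundary standing in for
  the torso.
- Cross-site correlations default to the 2.0 mA doses.

## Limitations

Beyond the generator limitations above: electrode–skin interfaces are
ideal; the inferior domain truncation is insulating except at the neck
return; only isotropic conductivity is supported; and the dose metric is
the sphere mean of |J| (no percentile/peak metrics, no tangential/radial
decomposition).
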