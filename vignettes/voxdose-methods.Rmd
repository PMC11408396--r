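---
title: "Methods: voxel Monte Carlo CT dosimetry and truncated-model comparisons"
author: "voxdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel Monte Carlo CT dosimetry and truncated-model comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxdose)
```

## The problem

Patient-specific CT organ doses are best estimated by Monte Carlo photon
transport through a voxel model built from the patient's own CT images. In
clinical practice, however, images exist only for the reconstructed scan
range. A voxel model truncated to that range misses three things relative
to the patient's whole body: the volume of organs extending beyond the
range, scatter from the rest of the body, and the helical overscan. voxdose
implements the complete machinery to quantify these effects on synthetic
whole-body phantoms: if the same scan is simulated on the truncated and the
whole-body model, the per-organ differences isolate each deficiency.

Five scenario doses are computed per organ:

* `d_a` — truncated (anatomy-specific) model, no overscan;
* `d_b` — `d_a` rescaled to the entire organ volume;
* `d_c` — whole-body model, no overscan;
* `d_d` — whole-body model with overscan (the best estimate of the truly
  received dose);
* `d_e` — `d_a` rescaled to the ICRP reference organ volume.

The comparisons C1 = (`d_a` vs `d_b`), C2 = (`d_b` vs `d_d`), C3 = (`d_d`
vs `d_c`), C4 = (`d_a` vs `d_d`), C5 = (`d_e` vs `d_d`) are percentage
differences with the second member as reference, averaged over a cohort
with the sample standard deviation. An organ wholly outside the truncated
model enters C2/C4/C5 with a zero dose estimate (−100%); C1 is undefined
for it.

## Organ dose aggregation

A dose grid and a segmentation mask give per-slice contour areas $A_i$,
in-contour mean doses $M_i$ and fractional areas $f_i = A_i / \sum_i A_i$;
the organ dose is

$$D_T = \sum_{i=1}^{N} f_i \, M_i .$$

With uniform slice thickness this is algebraically the voxel mean over the
mask, and the test suite checks the equivalence to $10^{-10}$ relative.
Volume corrections are energy-spreading rescales: the entire-organ-volume
correction $D_{full} = D_T \, V_{in}/V_{total}$ assumes zero dose outside
the modelled part, and the ICRP variant replaces $V_{total}$ by the
reference organ volume, $D_{ref} = D_T \, V_{in}/V_{ref}$. Reference
volumes derive from ICRP 89 masses and ICRP 110/145 densities
(`reference_organ_table()`); ribs and spine masses come from fractions of
the total skeletal mass (male 10.5 kg: 7% / 19%; female 7.8 kg: 5.6% /
20.4%). An optional tissue-weighted sum (`effective_dose()`, ICRP 103
weights) is provided and flagged partial when organs are missing.

Doses are normalised per photon per mm of table travel during the scenario
runs (so all five scenarios share a scale) and, after calibration, to mGy
per 100 mAs. Typical mean tube current–time products for absolute-dose
reporting are available as `default_mean_mas()` (141 mAs chest, 112 mAs
cardiac). TCM weights are normalised to the mean mAs of the supplied
table; supplying the whole-body table to every scenario keeps their scales
identical, while restricting the table to the scan range would give
per-scan-mean normalisation instead.

## Beam model

**Spectrum.** A tabulated 120 kV tungsten base spectrum (1 keV bins,
bundled, synthetic: Kramers bremsstrahlung behind inherent aluminium plus
K lines) is hardened by a virtual aluminium thickness chosen by bisection
so its first half-value layer matches a measured value
(`equivalent_spectrum()`). The HVL itself solves
$K(t)/K(0) = \tfrac12$ with
$K(t)=\sum_E w(E)\,E\,(\mu_{en}/\rho)_{air}(E)\,e^{-\mu_{Al}(E)t}$ by
bisection to $10^{-4}$ mm. This is the standard equivalent-spectrum
construction for CT scanners whose true spectrum is proprietary.

**Bowtie.** A lateral air-kerma profile measured in 1 cm steps from the
isocenter maps each distance to a fan angle
$\gamma=\arctan(d/\mathrm{FID})$ and each relative kerma to an equivalent
aluminium thickness (bisection on the same kerma integral), linearly
interpolated in $\gamma$ and completed symmetrically. During emission the
bowtie multiplies the photon weight by $e^{-\mu_{Al}(E)t(\gamma)}$ rather
than rejecting photons — identical expectation, lower variance.

**Helical source.** The focal spot is a point on a 595 mm circle; the full
fan angle is $2\arctan(250/595)=0.7957$ rad for the 500 mm scan FOV; table
feed per rotation is pitch × collimation (0.7 × 19.2 mm). Fan and cone
angles are sampled uniformly; energy from the spectrum; the tube-current
weight is the per-slice mAs over the table mean. Only longitudinal
modulation is modelled, because per-slice DICOM values are
angular averages; the focal spot has no extent and no heel effect.

**Overscan.** The `overscan` parameter is interpreted as the additional
*irradiated length* beyond the reconstructed range per side. Because the
collimated beam already spills `collimation/2` beyond the outermost table
position, the tube travel extends by `overscan − collimation/2` (2.4 mm for
the default 12 mm overscan and 19.2 mm collimation). The raw table-travel
reading is available as `overscan_mode = "table"`. The irradiated-length
reading was adopted because the with/without-overscan dose differences it
produces have the few-percent magnitude reported for clinical helical
protocols, while the table-travel reading roughly quadruples them.

## Monte Carlo transport

Voxels are classified from HU (air < −950 ≤ lung < −200 ≤ soft tissue <
120 ≤ bone) with density from the standard two-segment ramp anchored at
water ($\rho = 1000(1+HU/1000)$ up to HU 100, then a shallower bone
segment). Transport uses Woodcock (delta) tracking against a single
grid-wide majorant per energy. At a real collision, the interaction type
is drawn from tabulated partial fractions; photoelectric absorption
deposits the photon's remaining energy locally; Compton scattering samples
the Klein–Nishina angular distribution for a free electron by rejection,
deposits $E-E'$, and continues; coherent scattering redirects the photon
with a $(1+\cos^2\theta)$ angular model and deposits nothing. Histories
end below a 10 keV cutoff (depositing the remainder) or on grid exit.

These are deliberate desk-scale simplifications: the kerma approximation
(no electron transport) is appropriate below 150 keV where CT electron
ranges are sub-voxel; binding effects (incoherent scattering functions,
coherent form factors) and fluorescence after photoabsorption in low-Z
tissue are ignored. They shift absolute doses slightly but cancel to first
order in the paired comparisons, which are ratios of doses computed with
the same physics.

The attenuation fixture tabulates NIST-style total and energy-absorption
coefficients at reference energies, log-log interpolated to 1 keV. Its
partial fractions are made self-consistent by computing the incoherent
part from the Klein–Nishina cross section per electron; a side effect is
that the small photoelectric fraction of light materials vanishes above
roughly 40 keV instead of being a few tenths of a percent. Statistical
uncertainty comes from 10 independent batches; the per-voxel relative
standard error scales as expected with the photon budget where the dose is
well resolved.

**Randomness.** Emission sampling draws from R's RNG under `set.seed()`;
transport uses counter-based splitmix64 streams keyed by the protocol seed
and photon index. Two simulations with the same seed therefore see
identical photons *and* identical per-history randomness wherever their
geometries coincide — the scenario pairs (truncated vs whole-body, with vs
without overscan) become common-random-number estimates, and the
with/without-overscan contrast is computed from a single run whose
deposits are tagged by emission position (core range vs overscan margin),
making C3 strictly positive whenever any margin photon deposits in the
organ. This pairing replaces the enormous photon budgets a production code
would use to beat independent-run noise.

**Calibration.** Dose is scored in eV/g per source photon.
`air_kerma_free_in_air()` estimates the kerma per photon at the isocenter
of a phantom-free axial rotation with a track-length estimator in a small
spherical cell; the ratio of a measured air kerma (mGy per 100 mAs) to
this value calibrates the grid to mGy per 100 mAs. No measured kerma for
the modelled scanner is bundled; calibration is configuration.

## Synthetic phantoms

`default_adult_spec()` arranges ellipsoids, tubes and shells inside an
elliptical trunk (plus neck and head) on a default 64 × 64 × 180 grid at
4 × 4 × 6 mm — a desk-scale stand-in for 512 × 512 clinical models, which
are also supported. The body cross-section scales as $\sqrt{w/h}$, so
heavier phantoms at fixed height have larger water-equivalent diameter.
The reference anatomy places the lungs across 24% of the modelled length;
the heart (with a great-vessel stub whose superior extent serves as the
aortic-arch landmark — a proxy, since synthetic phantoms have no true
arch) entirely within both scan ranges; the liver straddling the lung base
with roughly 40% inside the chest range; the kidneys ~116 mm long with
only the upper poles above the lung-base plane (a few percent in range);
the thyroid straddling the lung apex, mostly inside the chest range and
entirely above the cardiac range; ribs and spine as bone (HU 700), lungs
at HU −700, breast (female) at HU −50, soft organs at HU 40–55. A seeded
jitter (4% sizes, 0.5% positions) provides cohort variation; cohort
heights and weights are drawn from truncated normals emulating an adult
referral population (female 1.50–1.74 m, 39–94 kg; male 1.60–1.95 m,
51–126 kg).

Scan ranges come from mask extents snapped outward to whole slices —
reconstructed CT exists as whole slices — with the convention that slice
$i$ (0-based) occupies $[z_0 + i\,dz,\ z_0+(i+1)\,dz)$ and the grid origin
is its inferior corner. The chest range spans the lungs; the cardiac range
runs from the heart apex to the aortic-arch landmark.

What the generator does **not** emulate: real organ shapes (no domed
diaphragm, no lobulated organs), segmentation noise, arms, metal, contrast
agent, or the tails of clinical size distributions. Passing the cohort
tests therefore demonstrates that the pipeline reproduces the *structure*
of truncation effects — structural zeros for fully covered organs, −100%
for absent organs, overscan strictly adding dose, scatter-and-overscan
deficits for covered organs, and the ordering of overestimates by
out-of-range fraction — not that its cohort statistics equal any clinical
cohort's values, which depend on real anatomy.

## Problem sizes and numerical choices

Defaults chosen for desk-scale work: photon budgets of $10^6$–$10^7$ per
simulation (production codes use $10^{10}$; the common-random-number
pairing above is what makes the smaller budgets informative), 10 batches,
10 keV cutoff, 1 keV energy resolution, bisection tolerances $10^{-4}$ mm
(HVL) and 0.5% (equivalent spectrum) / 1% (bowtie fit round trip). The
bundled test suite runs cohorts of 5 phantoms at $10^6$ photons per
simulation and single-phantom checks at $2\text{–}4\times10^5$; the
acceptance script uses 3 phantoms for the chest cohort. Ties and
degenerate inputs: empty masks error; organs absent from a crop are
flagged rather than erroring in the cohort driver; single-phantom cohorts
report SD 0 with a flag; HU below −1024 clamp; zero-length or inverted z
ranges error.

## Known limitations

* Absolute doses inherit the simplified physics and the synthetic spectrum;
  only calibrated relative comparisons should be trusted.
* The aortic-arch landmark is a proxy; cardiac ranges on real images would
  use the anatomical arch.
* Scatter from anatomy outside the modelled 0.55 × height length (arms,
  legs) is absent.
* The kidneys' coverage fraction is voxel-quantised on the coarse default
  grid, which widens the cohort spread of kidney C1/C4 — mirroring, at
  smaller scale, the large inter-patient spread such organs show.
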