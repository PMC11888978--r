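---
title: "Methods: zonal quantification of SHG/TPEF liver sections"
author: "hepzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zonal quantification of SHG/TPEF liver sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Label-free two-channel microscopy of unstained liver sections gives two
registered rasters: second harmonic generation (SHG), emitted by fibrillar
collagen, and two-photon excitation fluorescence (TPEF), the
autofluorescence of hepatocyte cytoplasm. Because sections are
deparaffinized, every lumen and lipid vacuole is a dark "hollow" on TPEF.
Three readouts of hepatic remodeling can be computed from such a pair:

1. **Zone-wise collagen deposition.** The hepatic acinus is partitioned
   into portal tract (PT), periportal (PP), transitional (TS), pericentral
   (PC) and central vein (CV) zones; collagen is quantified as the share of
   total SHG-positive pixels per zone, the within-zone areal density, and
   the total areal fraction of tissue.
2. **Steatotic-hepatocyte fraction**: the proportion of hepatocytes bearing
   a triacylglycerol vacuole.
3. **PT/CV foci density**: detected portal-tract and central-vein
   structures per mm^2 of tissue, a structural remodeling readout.

`hepzone` implements this pipeline together with a synthetic section
generator carrying full ground truth, so every stage is verifiable by
parameter recovery at desk scale, and a longitudinal endpoint simulator
feeding the same group-comparison statistics used for in vivo endpoints.

## Segmentation

Intensities are quantized to 8 bits and thresholded with Otsu's
between-class-variance criterion on the exact 256-bin histogram
(`otsuThreshold`); ties go to the lowest qualifying level, and the
operation is property-tested against an exhaustive search. The tissue mask
comes from TPEF; holes under 400 µm² are filled (intracellular dark spots
— larger holes are candidate cavities and must survive), and fragments
under 10,000 µm² are discarded. SHG noise removal discards signal outside
the tissue mask (stray bright specks beyond the specimen) and connected
components under 5 µm² (sub-fibril speckle); connectivity is 8-connected
throughout so thin diagonal fibrils stay intact.

Cavity detection operates on the *section support*: the tissue mask after
morphological closing (15 µm radius) and hole filling. Closing bridges the
mouths of cracks that open onto the section edge, so they become enclosed
cavities and can be detected and border-flagged rather than silently merged
with the background. Per cavity we compute area, area-equivalent diameter,
circularity $4\pi A/P^2$ — with the perimeter estimated from the chain-code
contour length scaled by Kulpa's corrective coefficient (0.9481), and the
value clamped at a 1.05 discretization ceiling — convex solidity, the
collagen coverage of a 5 µm outer annulus ("surrounding collagen"), and a
border-contact flag.

## Cavity classification

A binary decision tree assigns each cavity to {PT, CV, vessel/duct, crack,
lipid vacuole}. The default, fully inspectable rule tree encodes the
morphological contrasts: border contact ⇒ crack; area > 2,000 µm² with a
bare rim (ring < 0.2) ⇒ CV; a collagen-wrapped lumen (ring ≥ 0.5, area
300–20,000 µm²) ⇒ PT; a round hollow (circularity ≥ 0.6, diameter 5–40 µm)
with a bare rim ⇒ vacuole; everything else ⇒ vessel/duct. A CART
alternative (`fitTree`, Gini impurity via rpart) can be trained on labeled
synthetic objects; border-flagged objects are never classified as vacuoles
under either tree. The 0.2/0.5 ring cutoffs deliberately bracket the
generator's vessel rings (~0.3 measured coverage), so vessels are neither
vacuoles nor portal tracts.

## Zonation

PT and CV zones are the classified landmark objects' own pixels. PP (PC)
is all tissue within 100 µm Euclidean distance of any PT (CV) object
boundary, measured with an exact Euclidean distance transform from the
object pixel set; a pixel within band of both classes goes to the nearer
landmark, with exact ties resolved periportally — a deterministic,
configurable convention (the portal bias is conservative for
portal-centric contrasts). Remaining tissue is transitional. The same
routine produces the generator's ground-truth zone map, so geometry has a
single source of truth, and the labels are oracle-tested against a
per-pixel brute-force nearest-boundary computation.

Distances are measured from the object boundary, not the centroid: a
"100 µm area from the PT" reads as a band around the structure, and
centroid-based bands would shrink for large tracts.

## Quantification

Collagen quantities are exact pixel counts over the zone map. Group
contrasts are reported as ratios of group means of the total collagen
areal fraction, mirroring how ECM collagen differences are reported.

Steatosis counts one steatotic hepatocyte per vacuole-class object
(adjacent vacuoles merged by connectivity count once; multi-vacuole cells
are out of reach without cell boundaries, a documented bias). The
denominator is an area quotient: TPEF images cytoplasm rather than nuclei,
so hepatocytes cannot be counted directly, and the number of hepatocytes
is estimated as hepatocyte-occupiable area / 450 µm² (area-equivalent cell
diameter 24 µm, configurable). Occupiable area is the section support
minus *non-vacuole* cavity pixels: a steatotic cell's own vacuole still
occupies that cell's footprint, so subtracting vacuole area would
systematically inflate the fraction by ≈ 1/(1 − 0.32·p) and break the
linear-recovery property the test suite enforces (slope 1 ± 0.1 across
planted fractions 0.01–0.35).

Foci density divides PT-class and CV-class object counts by tissue area in
mm²; counting is exact when planted landmarks are separated by more than
twice the detection scale.

## The synthetic generator

The generator emulates the features the analysis must cope with, not
photorealism:

* **Geometry.** PT as a dark lumen disc (radius 25 µm) wrapped in a dense
  collagen annulus; CV as a larger bare disc (radius 40 µm) — the
  learnable contrast is the surrounding collagen. Vessels (radius
  10–18 µm) get a sparse ring (35% coverage) as confounders; one crack per
  section opens onto the tissue edge. The paper-facing parameters (foci
  densities, steatotic fraction, collagen totals) come from built-in
  group × day condition profiles transcribed from the reported means.
* **Hepatocytes and vacuoles.** Cell sites sit on a jittered hexagonal
  lattice at one site per 450 µm², the same nominal cell area the
  steatosis denominator uses — this consistency is what makes steatotic
  fractions recoverable. Sites become steatotic by independent Bernoulli
  draws with the profile's fraction; vacuole diameters are log-normal
  (median 12 µm, log-sd 0.35, truncated to 5–40 µm, a macrovesicular
  scale). Vacuole radii are capped so that discs keep a ≥ 2.7 µm bright
  gap from structures, the tissue edge and each other: under 8-connected
  labeling a single diagonal contact would merge two cavities, and the
  recovery tests require the one-vacuole-one-cavity mapping to be exact.
  Boxed-in sites are nudged a few pixels up the clearance gradient rather
  than dropped, keeping site density uniform.
* **Collagen budget.** Profiles parameterize collagen as a total areal
  fraction plus zonal share weights (PT 0.05, PP 0.50, TS 0.30, PC 0.10,
  CV 0.05) rather than absolute per-zone densities, because the reported
  group contrasts are ratios of totals and must be invariant to the
  realized landmark geometry. After the structural rings are stamped, the
  remaining budget is placed as 3 × 3 µm fibril blocks inside each zone,
  with weights renormalized over zones that can host fibrils and a top-up
  pass compensating overlap and clipping losses; the planted total matches
  the profile target to well under a percent. The realized per-zone
  densities are recorded in the ground truth. The absolute baselines
  (e.g. 0.8% of tissue for the unsupplemented day-4 arm) are package
  choices — only the ratios are reported quantities.
* **Noise.** Additive Gaussian noise (σ = 5/255) on both channels, plus
  ~600 bright salt specks outside the tissue on SHG to exercise noise
  removal. The SHG tissue background equals the slide background so the
  dark mode stays unimodal; the specks also anchor the Otsu split when a
  section carries no collagen at all, which is why a zero-collagen profile
  yields an exactly empty collagen mask.

What the generator does **not** emulate: inflammation and ballooning,
irregular lobule shapes, uneven illumination, chromatic offsets between
channels, 3-D structure, and biological collagen texture (fibril
anisotropy, bundles). Passing recovery tests therefore demonstrates the
correctness of the measurement pipeline under controlled conditions, not
its robustness to every artifact of real acquisitions.

## Endpoint simulator and statistics

Each condition profile carries the reported endpoint means ± SEM (remnant
liver weight / body weight, AST, ALT, albumin, PCNA-positive percentage)
with group size n = 6 (group sizes are not reported; 6 is a declared
default, flagged in reports). Mouse × day values are Gaussian with SD =
SEM·√n, split into a shared per-mouse random intercept (ICC 0.5, the
package's default for within-mouse correlation) plus residual noise.
AST/ALT are simulated log-normally with moment matching, since
transaminases are strictly positive and right-skewed; albumin was reported
only as "comparable between groups", so a constant 3.5 ± 0.1 g/dL is used
for both arms. Profiles exist exactly for the reported group × day cells;
unreported endpoints stay NA.

Group comparisons use the Welch t test for two groups and one-way ANOVA
with Tukey HSD beyond that. The repeated-measures group effect comes from
a random-intercept model (`endpoint ~ group + day + (1|mouse)`). The
default test is the Satterthwaite F (lmerTest): at n = 6 per group its
null p-value distribution is uniform (the suite checks a
Kolmogorov–Smirnov test over 300 null simulations and a type-I error
within [0.03, 0.07] over 2,000 replicates), whereas the maximum-likelihood
likelihood-ratio chi-square is measurably anticonservative at this size;
the LRT remains available via `method = "lrt"`. Singular-fit and
convergence notes are collected and returned, never silently swallowed.

Stars follow the conventional p < 0.05/0.01/0.001 thresholds. The source
protocol also states a 2-tailed α of 0.1 alongside p < 0.05 significance —
an internal inconsistency that the package documents rather than resolves;
the decision rule here is p < 0.05.

## Numerical choices and problem sizes

* 8-bit quantization before thresholding makes the 256-bin histogram
  contract exact and the brute-force oracle meaningful.
* The Euclidean distance transform is exact (verified against brute force);
  zone assignment needs no approximation.
* Tie-breaks: Otsu ties → lowest level; PP/PC band overlap → nearer
  landmark, exact tie → PP; ROI selection → greedy by tissue fraction,
  ties by (row, col), thinned by a seeded uniform draw.
* Degenerate inputs error loudly: single-level histograms, blank images,
  sub-tile images, zero tissue area, infeasible landmark packings,
  non-positive cell areas.
* All randomness flows through explicit seeds; identical inputs give
  bit-identical sections and tables, and no global RNG state leaks.

Unit tests run on 0.5–0.7 mm sections at 1 µm/pixel; recovery checks use
ten 1 mm² sections for steatosis, five per arm for the collagen ratio, and
n = 1,000 cohorts for endpoint means — sizes at which the binomial and
sampling tolerances (3 SE) are tight enough to catch percent-level biases
while the whole suite stays in the minutes range.

## Known limitations

* One vacuole = one steatotic hepatocyte undercounts multi-vacuole cells
  and overcounts extracellular fat, both unresolvable without cell
  boundaries.
* The hepatocyte denominator is an area quotient with a fixed nominal cell
  area; hypertrophy or anisotropic swelling would bias it.
* The rule tree's thresholds are tuned to the generator's geometry; real
  sections would favor `fitTree` on curated labels.
* Zonation assumes detected landmarks are trustworthy; a missed PT
  reassigns its band to TS.
* The acquisition-protocol defaults (200 µm tiles, 5 × 5-tile ROIs, 10–15
  ROIs per slide) are honored by the tiling/ROI module but the recovery
  tests operate on whole synthetic sections, where tiling is exercised
  separately.
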