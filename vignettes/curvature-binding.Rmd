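---
title: "Membrane curvature reconstruction and ion-binding enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane curvature reconstruction and ion-binding enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`curvbind` analyzes how ions (calcium being the motivating case) bind to
curved lipid membranes. Given coordinate frames of a membrane system it

1. reconstructs each monolayer surface from one *marker atom* per lipid
   (by default the phosphate phosphorus) and assigns every lipid a local
   normal, principal curvatures $k_1 \ge k_2$, mean curvature
   $K_m = (k_1 + k_2)/2$, Gaussian curvature $K_g = k_1 k_2$ and a Voronoi
   surface area;
2. detects ion–lipid contacts by a heavy-atom distance cutoff and derives
   coordination-number distributions, canonical chemical-group binding
   patterns, and residence times; and
3. combines the two into the curvature histograms $P_\mathrm{lip}(K_m)$
   (all lipids) and $P_\mathrm{Ca}(K_m)$ (ion-contacted lipids) and the
   enrichment profile $p(K_m) = P_\mathrm{Ca}(K_m)/P_\mathrm{lip}(K_m)$:
   $p > 1$ marks curvatures where ions preferentially bind, $p = 1$ no
   preference.

A synthetic generator produces flat, buckled, cylindrical and spherical
bilayer lattices with *analytic* curvature ground truth and a
curvature-biased ion adsorption model, so every stage of the pipeline is
testable against closed forms and known placement statistics rather than
against another simulation.

# Surface reconstruction

## Model

Around every marker we fit a local quadric in Monge form,

$$z = a x^2 + b y^2 + c\,x y + d\,x + e\,y + f,$$

in a frame whose $z$-axis is the current working normal. The initial
normal is the smallest principal axis of the covariance of the markers
within the patch radius, oriented along the lipid's outward (head-minus-
tail) axis; after each least-squares fit the frame is re-aligned to the
fitted normal at the origin and the fit repeated until the normal rotates
by less than 0.5° in an iteration (at most 10 iterations). Curvatures
follow from the standard Monge-patch formulas evaluated at the origin
with gradient $(d, e)$; the mean curvature uses the full
$(1+|\nabla z|^2)^{3/2}$ denominator, so small frame misalignment is
harmless.

Because the raw second fundamental form is evaluated against the local
frame, we fix the sign convention explicitly: curvature is reported
against each leaflet's *outward* (water-side) normal such that a leaflet
bending toward its own water side — concave as seen from the adjacent
water, forming a water pocket — has $K_m < 0$. On a buckled bilayer the
leaflet under a crest therefore reports negative curvature and the
leaflet above it the mirror-image positive value; the outer leaflet of a
sphere of radius $R$ reports $K_m = +1/R$.

## Neighborhoods and periodic images

The patch neighborhood contains all markers of the same leaflet within
`patch_radius` (default 1.5 nm, chosen to give roughly 10–20 neighbors at
a typical area per lipid of 0.65 nm²; the radius grows by 25%, at most
twice, if fewer than 7 points are found). Distances are minimum-image on
periodic axes — and, importantly, when a periodic box dimension is
smaller than twice the patch radius a marker may contribute *several*
periodic images to the same neighborhood. Including all images is not an
optimization but a correctness requirement: narrow ribbon-like leaflets
otherwise present only two distinct transverse coordinates to the fit,
which confounds the $b y^2$ term with the constant and destroys the
curvature estimate.

## Areas

Per-lipid areas use the Voronoi construction in each lipid's own tangent
plane: neighbors (Newton-projected onto the fitted quadric) and the
periodic images of all same-leaflet markers are candidate sites; the cell
of the center is cut from a clipping square by half-plane intersection
with the perpendicular bisectors; its vertices are lifted onto the
quadric and the area measured by fan triangulation. On an exact flat
lattice of spacing $s$ every cell is exactly $s^2$, and per-leaflet areas
tile the periodic box exactly for arbitrary (jittered) configurations;
on a sphere the per-lipid cells total $4\pi R^2$ to within 2%
(the tangent-plane construction is locally flat, so cells of different
lipids overlap only at second order in spacing/$R$).

## Per-frame versus trajectory-mean curvature

`compute_surface()` estimates curvature independently per frame. For a
membrane whose shape evolves this is the only meaningful choice, and it
is the default for the binding histograms. The synthetic benchmarks,
however, have a *static* mean geometry with i.i.d. positional noise; the
per-frame estimate then carries estimator noise (about 0.06 /nm RMS at
0.05 nm jitter and the default patch radius) that acts as classical
errors-in-variables and attenuates any fitted curvature dependence.
`curvature_histograms(..., km_estimate = "lipid_mean")` bins each sample
at the lipid's trajectory-mean curvature instead, which is a consistent
estimator of the static per-lipid curvature and removes the dilution.
The bias-recovery benchmark uses this mode; the null benchmark uses the
per-frame default (the unit enrichment is invariant to estimator noise,
since both histograms are binned identically).

A related numerical point: when regressing $\log p$ on curvature, the
abscissa is the occupancy-weighted mean curvature of each bin, not the
nominal bin center. Curvature densities on periodic buckled surfaces
peak at the extreme curvatures (the arcsine-like density of a sinusoid),
so edge bins are populated asymmetrically and the nominal center can
overstate $|K_m|$ by tens of percent, biasing the slope.

# Ion-binding analysis

An ion contacts a lipid when any heavy atom of the lipid lies strictly
within the cutoff (default 0.3 nm, minimum-image). The contacted region
set of a lipid is the set of its contacted group labels among the three
analysis classes — `head` (serine moiety), `po4` (phosphate), `carbo`
(ester carbonyls) — with tail-only contacts recorded as an empty set.

Binding patterns canonicalize one ion-frame: each contacted lipid
contributes a token (its groups joined with `+`, so one lipid touched at
head and phosphate is `head+po4`, distinct from the two-lipid
`head-po4`), tokens are sorted and hyphen-joined, and no contact is
`free`. Published pattern strings are usually flat multisets
(`"head po4 po4"`); because they do not state whether repeated group
mentions belong to distinct lipids, the canonical form keeps per-lipid
identity and `pattern_flat()` provides the lossy flat export. Tail
tokens are dropped from the three-group report by default.

Coordination numbers (distinct lipids per ion per frame), pattern
abundances (percent of all ion-frames, filtered at 1% for display) and
residence times (maximal runs of bound frames, with a configurable gap
tolerance defaulting to 0, censored at trajectory ends) all follow from
the contact maps. Statistical errors throughout are the standard
deviation over the three equal contiguous thirds of the trajectory — a
deliberate block estimator rather than a bootstrap, as it is robust to
the strong frame-to-frame correlation of binding states.

For bent bicelle-like systems, `central_sector_mask()` restricts all of
the above to the central bilayer sector, excluding a configurable margin
near the membrane edges located by the extreme arc-length coordinates of
the markers (the generator flags its edge rows, which the mask recovers).

# Enrichment

$P_\mathrm{lip}$ accumulates one sample per lipid per frame;
$P_\mathrm{Ca}$ one sample per (ion, contacted lipid) pair per frame, the
literal per-contact reading of a contact count (an ion coordinating three
lipids contributes three samples; a per-bound-lipid weighting would
differ only where coordination correlates with curvature). Both are
normalized to densities on shared edges — default bin width 0.05 /nm over
the observed range — so that leaflet-size differences cancel in the
ratio. Bins with fewer than `n_min = 50` lipid samples are masked: the
ratio of two sparse densities is unstable, and profiles are conventionally
truncated at extreme curvatures for exactly this reason. On valid bins
the change-of-measure identity
$\sum_K p(K) P_\mathrm{lip}(K) \Delta K = 1$ holds whenever all contact
samples fall in valid bins; it is asserted in the tests as a
normalization audit.

# The synthetic generator

The generator is a *statistical stand-in* for molecular dynamics, not a
physical model: its purpose is to produce configurations whose correct
analysis output is known exactly.

* **Geometries.** Flat periodic patches; buckled membranes as a
  single-mode sinusoid $z = A\sin(2\pi x/\lambda)$ extruded along $y$
  (defaults $A = 2$ nm, $\lambda = 20.5$ nm — the box length at which
  buckled patches are typically simulated — giving $|K_m|$ up to about
  0.1 /nm); cylindrical sectors (the bent-bicelle central sector, default
  nominal curvature 0.2 /nm) and spheres for closed-form validation.
  Markers are laid out quasi-uniformly at the requested area per lipid
  (default 0.65 nm²), leaflets separated by 3.8 nm (a typical
  phosphate-to-phosphate distance).
* **Leaflet offsets.** For the buckle, the two leaflet lattices are
  *vertical* offsets of the same sinusoid, so both carry the midline's
  closed-form curvature (with opposite signs under the leaflet-outward
  convention) — the property the validation oracles rely on. True normal
  offsetting would rescale curvature by $1/(1 - K t)$ and forfeit the
  closed form. Cylinder and sphere leaflets are concentric, each carrying
  the exact $\pm 1/r$ of its own radius, with the convex leaflet at
  exactly the nominal radius; single-leaflet lattices are available for
  the curvature oracles.
* **Lipids.** Reduced to collinear labeled heavy-atom sites (3 head, 2
  phosphate — the first being the `P` marker — 2 carbonyl, 4 tail sites)
  along the inward axis, plus isotropic Gaussian jitter (default
  0.05 nm, a modest sub-atomic-scale disorder). Contact and pattern
  analysis only needs labeled heavy positions, so no internal
  conformational model is attempted.
* **Ions.** `round(ratio × n_lipids)` ions (default ratio 1:2) split
  evenly between leaflets. Each ion chooses between staying free —
  weight $n f/(1-f)$, where $f$ (default 0.2) is the nominal free
  fraction at zero bias — and binding lipid $i$ with weight
  $\exp(-\alpha K_m^{(i)})$ against the analytic curvature. This single
  competition reproduces, for $\alpha > 0$, all three qualitative
  signatures of curvature-sensitive binding at once: bound-lipid
  curvature distributions shift negative; the denser concave leaflet
  yields higher coordination numbers; and the realized free fraction
  rises near convex leaflets (smaller lipid weights there). Bound ions
  sit `contact_distance` (0.25 nm, inside the 0.3 nm cutoff) from a
  random head/phosphate site of the host; free ions are placed in the
  solvent region at least twice the cutoff from any lipid heavy atom.
  Solvent is never instantiated as atoms — water enters no analysis in
  scope.
* **Determinism.** One RNG stream seeded from the spec; identical specs
  give byte-identical emitted files.

What the generator does *not* emulate — thermal undulations, lipid
conformational disorder, correlated ion dynamics, realistic binding
kinetics — bounds what passing tests show about real trajectories: they
validate the estimators and bookkeeping, not force-field physics.
Residence-time analysis is therefore benchmarked against an explicit
two-state Markov chain (mean completed episode $= 1/k_\mathrm{off}$)
rather than against the generator, whose frames are temporally
independent.

# Numerical choices and degenerate inputs

* Strict inequality at the contact cutoff; bitwise stable.
* $k_1 \ge k_2$ by sorting; umbilic points need no tie-break.
* Curvature is evaluated at each marker's own patch origin; no averaging
  across neighboring patches.
* Quadric fits require at least 7 points (center included); collinear
  neighborhoods are reported as rank-deficient fit errors, and lipids
  with failed fits are excluded from histograms (a frame with more than
  10% failures is flagged).
* Newton projection onto the quadric falls back to vertical projection
  after 50 non-converging steps.
* Leaflet assignment uses the fixed reference axis when every lipid axis
  clearly aligns with it, and otherwise the radial rule around the
  least-squares intersection point of the lipid axes — the robust
  estimate of the bending center for cylindrical or closed geometries.
* Only orthorhombic boxes are supported.

# Benchmark problem sizes

The validation suite runs, per criterion: oracle lattices of ~130–1900
lipids (single frames); a 128-lipid buckled bilayer over 200 frames for
the null-enrichment check (≥ 10⁴ ion-frames); a 400-lipid buckled
bilayer over 200 frames with 200 ions for bias recovery at
$\alpha \in \{1, 2, 4\}$ nm; 45-frame bent-bilayer runs for the
qualitative sign checks; and ~10⁴ completed episodes for the
residence-time closed form. These sizes were chosen so each check's
sampling error sits comfortably below its assertion tolerance.

# Limitations

* The quadric estimator smooths over the patch radius; curvature
  features sharper than ~1.5 nm are attenuated.
* Voronoi areas near open (non-periodic) edges are clipped by the
  neighborhood square, not by a physical boundary; edge lipids should be
  excluded via the sector mask.
* The enrichment ratio needs well-populated bins on *both* sides;
  `n_min` masks but cannot rescue sparsely sampled curvature extremes.
* Per-frame curvature under strong marker noise dilutes fitted
  curvature-dependences (see above); prefer `lipid_mean` only when the
  geometry is genuinely quasi-static.
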