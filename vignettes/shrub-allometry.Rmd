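---
title: "A volume-based allometric model of shrubs versus trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A volume-based allometric model of shrubs versus trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistem)
```

## The question and the model

Why do multi-stemmed shrubs hold their own against trees in so many habitats?
One candidate answer is purely geometric: for the *same above-ground woody
volume*, a plant that partitions its wood over several short stems exposes
more cross-sectional sapwood at its stem bases, more bark (epidermis and
cambium) surface, and more twigs than a plant that invests the same wood in a
single tall stem. All of these areas plausibly scale with the capacity to
assimilate carbon and to sprout, so the short multi-stemmed form should grow
faster while both plants are small. `multistem` implements this model and its
comparisons.

Each plant is assembled from idealised segments. A stem or branch of length
$L$ (cm) is a truncated cone with basal radius

$$ r_\mathrm{base}(L) = \max(b\,L,\; r_\mathrm{tip}) $$

and tip radius $r_\mathrm{tip}$; when $b L < r_\mathrm{tip}$ the segment is a
cylinder of radius $r_\mathrm{tip}$. Branching is recursive: a parent of
length $L \ge l_\mathrm{min}$ carries $a$ children of length $pL$; each child
branches in the same way when it is long enough. To keep total volume a
continuous function of stem length, children do not appear fully formed:
they begin growing (from length $0$) when the parent reaches
$\tfrac{2}{3} l_\mathrm{min}$ and ramp linearly to $p\,l_\mathrm{min}$ at
$l_\mathrm{min}$, after which they follow the proportional rule. Since
$p < 1$, child lengths decrease geometrically and the recursion terminates on
its own; no depth cap is needed.

A shrub with $n$ stems is exactly $n$ independent copies of the single-stem
architecture, so total volume satisfies $V(h, n) = n\,V(h, 1)$ identically.
An immediate consequence is the growth-rate corollary: to *match a tree's
height*, an $n$-stemmed shrub must accumulate above-ground woody volume
exactly $n$ times as fast ($g_s = n$). The package's `g_s` parameter is a
static multiplier on the shrub's volume in any comparison; time dynamics are
out of scope.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `n` | number of stems | 1 | — |
| `a` | children added per parent per branching step (the parent's tip is not itself counted as a child) | 2 | — |
| `p` | child/parent length ratio | 0.5 | — |
| `l_min` | length at which a parent carries its full children | 20 | cm |
| `r_tip` | tip radius of every segment | 0.1 | cm |
| `b` | basal radius / length ratio | 0.0075 | — |
| `g_s` | shrub/tree growth-rate (volume) ratio | 1 | — |

The defaults describe a small temperate woody plant and are the reference
values for every result below; all of them can be varied freely through
`plant_params()`. The sprouting-area helper exposes its stem fraction
(default the lower 25% of each stem) as an argument, since the cut-off is
illustrative rather than structural.

## Height from volume, and the comparisons

`plant_volume()` is continuous and strictly increasing in stem length, so
$V(h) = v$ has a unique solution. `height_from_volume()` brackets the root by
geometric expansion and solves with Brent's method plus a bisection fallback,
enforcing a relative volume residual of $10^{-12}$ (the kinks at the ramp
joints rule out derivative-based methods, and bracketing is insensitive to
them). `compare_trait()` then evaluates a trait for a tree and a shrub at
equal volume and reports the shrub's percent advantage:

```{r}
for (n in c(3, 5, 7))
  print(compare_trait("cross_section", 500, plant_params(n = n)))
for (n in c(3, 5, 7))
  print(compare_trait("surface_area", 500, plant_params(n = n)))
```

At 500 cm^3 the model yields cross-sectional-area advantages of about 39%,
61% and 76% for 3, 5 and 7 stems. The published account of this model prints
39/61/75 for this triplet — agreement to within a point — and 35/53/74 for
the bark-surface triplet, where this implementation yields 43/67/89. The
discrepancy deserves a frank note. The side area of a truncated cone is
$\pi (r_1 + r_2) \sqrt{L^2 + (r_1 - r_2)^2}$; at these slenderness ratios the
slant correction is below $10^{-5}$ relative, so the choice of slant versus
length is immaterial, and no option is exposed. We examined every natural
alternative reading (cylinder at basal radius, cone tapering to a zero tip,
tip-radius cylinders for the smallest segments, branches-only areas) and none
reproduces 35/53/74 while remaining consistent with the heights that the
cross-section triplet pins down: writing the per-generation side area as any
combination of a quadratic taper term and linear tip terms and imposing the
three published values produces mutually incompatible linear constraints for
the 5- and 7-stem cases. We therefore keep the geometrically correct
truncated-cone formula and report its honest outputs; the qualitative
claim — the surface advantage exists and grows with $n$ — holds in all
readings. Cambium area and stem-photosynthetic area are interpretations of
the same quantity and are not duplicated as separate traits.

At 500 cm^3 with the default parameters all stems are far above
$l_\mathrm{min}$, so the comparisons barely depend on how the ramp is glued;
we verified that replacing the ramp with a hard threshold (no children below
$l_\mathrm{min}$) moves the 3-stem cross-section percentage by under a point
and leaves the 5- and 7-stem comparisons unchanged, because only the 3-stem
shrub has a generation inside the ramp zone at this volume.

The `curve_sample()` grid defaults to 200 log-spaced volumes between 1 and
1000 cm^3, matching the "small plants" domain where the model is meant to
apply (it contains no within-individual thinning, so large plants are out of
scope — as are foliage and roots). Note that the ordering of the area curves
by stem count holds once stems are past the branching threshold; in the
cylinder limit $v \to 0$ the curves coincide exactly, so tests sample from
20 cm^3 upwards.

## The height–diameter (Niklas–Spatz) mode

A proportional radius–length rule is simplest, but an empirical alternative
relates stem length and basal diameter as $L = k_5 D^{2/3} - k_6$.
`plant_params(radius_mode = "niklas_spatz", ns = niklas_spatz_params(k5, k6))`
derives each segment's basal radius by inverting this relation (with the same
tip-radius floor). The constants are species- and dataset-specific and are
deliberately left without defaults; the package only claims — and its tests
check — that the tree-taller-than-shrub and increasing-with-$n$ orderings are
unchanged in this mode.

## Bending moments

The biomechanics component works in SI units (metres, kilograms, newtons). A
stem is a curve parameterised by arc length $s$ with horizontal offset
$x(s)$, loaded by its own weight; the magnitude of the bending moment about
the base is

$$ M = \int_0^L \rho\, g\, \pi\, r(s)^2\, x(s)\, \mathrm{d}s . $$

Two path shapes are provided: *straight* stems leaning at a fixed angle
($x(s) = s \sin\theta$) and *uprising* stems that lean until their horizontal
offset reaches a cutoff and then grow vertically ($x(s)$ capped at the
cutoff, with a sharp corner — the integrand's only non-smooth point, at which
the quadrature domain is split). Branches and foliage are excluded, so the
moments are lower bounds for real crowned stems; wind and snow loading are
likewise out of scope. The default taper is the conical rule above
(converted to metres, $r_\mathrm{tip} = 0.001$ m); a height–diameter taper
$D(s) = ((L - s + k_6)/k_5)^{3/2}$ is available as an alternative. Wood
density (600 kg m^-3, a typical green-wood figure) and $g = 9.81$ m s^-2 are
parameters, because the source account does not state the constants behind
its moment figures; accordingly the package treats absolute newton-metre
values as configuration-dependent, and all of its tests are closed-form
(uniform cylinder: $\rho g \pi r^2 \sin\theta \, L^2/2$), oracle-based
(million-panel Riemann sums) or ordering-based:

```{r}
bending_moment_curve(c(2, 6, 10))
```

The uprising stem starts off costlier than a gently leaning straight stem
(larger angle near the base) but its moment grows only linearly in $L$ once
the offset saturates, while a straight leaning stem grows faster than
quadratically — the curves cross exactly once, which is the geometric case
for calling upright multi-stemmed plants "trees" rather than shrubs.

## The evidence table

The faster-growth prediction was screened against the published comparisons
of shrub and small-tree growth known to us: 14 studies, each graded `++`
(good support), `+` (support), `+/-` (inconclusive) or `-` (against). The
table ships as a plain TSV (`load_studies()`), grades are validated on load,
and `tally_support()` performs the vote count:

```{r}
tally_support(load_studies())
```

## Numerical choices and limitations

* Tolerances: volume inversion to $10^{-12}$ relative residual; quadrature to
  $10^{-10}$ relative. Both are far below any quantity interpreted
  scientifically.
* Junction geometry is ignored: parent and child cones overlap at
  attachment points by a volume of order $r^3$, negligible at these
  slendernesses and absent from the model's definition.
* Segment positions and angles are not modelled in the architectural part
  (volumes, areas and counts do not need them); the biomechanics part models
  a single unbranched stem's path instead.
* The tip-radius floor makes newborn (ramp-phase) children cylinders of
  radius $r_\mathrm{tip}$ regardless of whether the floor is applied before
  or after the ramp; the two orders are observationally identical at the
  default parameters.
* The generator of comparisons is deterministic end to end; re-runs are
  byte-identical, and the CLI exports numbers at 10 significant digits.
* What the model does *not* say: it contains no foliage, roots, thinning,
  mortality, or any physiology beyond areas-as-proxies. Passing its tests
  shows the geometry and its orderings are computed correctly — not that
  real shrubs grow faster; that question belongs to the evidence table and
  to field work.
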