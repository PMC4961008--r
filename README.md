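# multistem

A volume-based allometric model of why small multi-stemmed shrubs can outgrow
small single-stemmed trees.

## The model

Stems and branches are truncated cones: a segment of length *L* (cm) has
basal radius `max(b·L, r_tip)` and tip radius `r_tip` (segments thinner than
the tip radius are cylinders). Branching is recursive — a parent of length
*L ≥ l_min* carries `a` children of length `p·L`, and children branch the
same way — with a linear "ramp" between `(2/3)·l_min` and `l_min` so that
total volume is continuous in stem length. An *n*-stemmed shrub is *n*
independent copies of the single-stem architecture, so `V(h, n) = n·V(h, 1)`
exactly, and matching a tree's height requires an *n*-fold volume growth rate
(`g_s = n`).

Given a common above-ground woody volume *v*, the package solves the
monotone equation `V(h) = v` for each growth form and compares them on:

* total basal cross-sectional (sapwood) area,
* total bark/epidermis surface area (also a proxy for cambium and
  stem-photosynthetic area),
* sprouting area on the lower stems,
* twig counts (outermost branch generation),
* height.

A biomechanics component integrates the gravity bending moment
`M = ∫ ρ g π r(s)² x(s) ds` of straight leaning stems and of "uprising"
stems that turn vertical after a fixed horizontal excursion, and a packaged
14-study literature table supports a vote count of the empirical evidence
for the faster-shrub-growth prediction.

## Worked example

```r
library(multistem)

tree  <- plant_params(n = 1)          # a = 2, p = 0.5, l_min = 20 cm,
shrub <- plant_params(n = 5)          # r_tip = 0.1 cm, b = 0.0075

height_from_volume(500, tree)         # 177.8852 cm
height_from_volume(500, shrub)        # 100.9919 cm

compare_trait("cross_section", 500, shrub, tree)
#> cross_section at 500 cm^3 woody volume (n = 5 stems, g_s = 1):
#>   tree 5.59181, shrub 9.01187  ->  shrub +61.16%
```

At the same 500 cm^3 of wood, the 5-stemmed shrub is about half as tall as
the tree but exposes 61% more cross-sectional area at its stem bases — the
geometric core of the faster-growth hypothesis. Across 3, 5 and 7 stems the
cross-section advantages are 38.9/61.2/76.0% and the bark-surface advantages
43.0/67.1/89.1%. The literature vote count:

```r
tally_support(load_studies())
#> 14 studies: 12 supportive (3 with good support), 2 inconclusive, 0 against
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "multistem.R", package = "multistem"))')
Rscript $CLI compare  --volume 500 --n 3,5,7 --out compare.csv
Rscript $CLI curves   --config params.yaml --out curves.csv
Rscript $CLI bending  --max-length 10 --out bending.csv
Rscript $CLI evidence --out tally.json
```

Config files are flat YAML with the model's parameter names
(`a_t`, `a_s`, `p`, `l_min`, `r_tip`, `b_t`, `b_s`, `g_s`, `n`).

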