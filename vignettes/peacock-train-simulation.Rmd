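---
title: "Simulating the peacock's train: zigzag follicle lattices, fan expansion, and pattern statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the peacock's train}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavotrain)
```

## The model

Peafowl train coverts are anchored on the uropygium, whose ventral face
carries the imprints of the follicle insertion points: tightly packed rows of
10 or 11 follicles, alternating, with consecutive rows staggered by half the
within-row spacing — a zigzag, the planar analogue of densest packing. New
rows are added annually at the anterior (ventral-bottom) end, so follicle
size grades from small/anterior/new to large/posterior/old. When the train is
erected, each follicle row becomes an arc of the display fan and each feather
tip presents one eyespot, so the condensed developmental layout maps
one-to-one onto the adult ornament.

`pavotrain` implements that mapping as a generative simulation:

1. **Lattice** (`build_lattice()`): follicle centres on the anchor plate,
   midline at x = 0, anterior row at y = 0, rows at multiples of `row_pitch`,
   follicles at multiples of `within_row_pitch`. Four arrangements are
   available for contrast: 10/11 zigzag (the observed one), 10/11 parallel,
   and constant 10/10 or 11/11 in either alignment.
2. **Expansion** (`expand_train()`): row *r* lands on the arc of radius
   `base_radius + r * radial_pitch`; lattice x maps to angle through one
   common scale, `fan_span / (lattice width + within_row_pitch)` degrees per
   unit. Because the scale is shared by all rows, the half-pitch stagger
   becomes exactly half the angular pitch — the property that produces
   hexagonal eyespot packing — and a 360° span tiles the circle without a
   duplicate point at the wrap.
3. **Classification** (`classify_feathers()`): the oldest (outermost) 3–5
   rows carry eyespot-less fishtail feathers, the newest (innermost) 2–3
   rows carry small "minor" eyespots, the remainder the full eyespot field.
4. **Metrics** (`pattern_metrics()`): statistics that make the visual
   zigzag-vs-parallel contrast assertable (below).
5. **Growth** (`growth_trajectory()`), **eyespot rings**
   (`build_palindrome()`), and **synthetic specimens**
   (`generate_specimens()`).

```{r overview}
lat <- build_lattice(arrangement_scheme("zigzag", "alt_10_11"), n_rows = 18)
pat <- classify_feathers(expand_train(lat), n_fishtail_rows = 4, n_minor_rows = 2)
pat
pattern_metrics(pat)
```

## Zigzag with exact bilateral symmetry

Every construction in the package is exactly mirror-symmetric about the
midline, because bilateral symmetry of the display is the phenomenon being
modelled. For alternating 10/11 rows, symmetry and stagger come for free:
centred 11-rows occupy the integer grid (one mid-feather on the midline, five
feathers on either side) and centred 10-rows occupy the half-integer grid.
For constant row sizes the two requirements conflict — an even-size row
shifted by half a pitch is no longer symmetric, and a symmetric odd-size row
must keep a point on the midline. The package resolves this in favour of
symmetry:

* constant even sizes alternate between the half-integer grid and the
  integer grid without zero; every follicle is still exactly half a pitch
  from the nearest follicle of the neighbouring row;
* constant odd sizes keep the mid-feather on the midline in every row and
  stagger the flanking feathers onto gap midpoints, so the midline column is
  the one place where the half-pitch offset is waived.

## Pattern statistics

* **Hexagonality**: the fraction of interior points whose Delaunay neighbour
  degree is exactly 6. "Interior" means farther than `1e-4` × extent from
  the convex-hull boundary (hull *vertices* alone are not enough: points on a
  straight hull edge are boundary too). A parallelogram-form triangular
  lattice scores exactly 1.
* **Nearest-neighbour CV**: SD/mean of nearest-neighbour distances; lower is
  a more even eyespot field.
* **Symmetry error**: mean distance from each point to the nearest mirror
  image, normalised by the mean nearest-neighbour distance.
* **Radial lines**: angular clusters split at gaps larger than a quarter of
  the within-row angular pitch. Grid angles and stagger-midpoint angles are
  half a pitch apart, so a *half*-pitch tolerance would sit exactly on the
  decision boundary; a quarter pitch separates the zigzag's 21 lines
  (11 grid + 10 midpoint) from the 10 lines of a 10/10 parallel fan
  robustly.

### Numerical choices

Triangulations of lattices are full of co-circular quadruples (any
rectangle). Ties are broken by a deterministic jitter of magnitude
`1e-5` × extent with the fixed seed `20250923`. The magnitude is chosen so
the induced in-circle decisions are resolved identically by any
double-precision triangulation — at much smaller jitters the decision margin
falls below what floating-point circumcircle arithmetic distinguishes, and
two correct implementations can disagree — while staying four orders of
magnitude below any inter-point spacing, so non-degenerate patterns are
unaffected. A consequence worth knowing: for degenerate-rich inputs the
tie-break depends on coordinates, so hexagonality is rotation-invariant only
for point sets in general position; the evenly-spaced fan patterns contain
some near-ties, and rotating them can flip a few diagonals. The
nearest-neighbour CV and the symmetry error are rotation- and
scale-invariant without qualification.

### When does zigzag win?

Under the default display geometry (half-disc fan, `fan_span = 180`°,
`radial_pitch = 1`, `base_radius = 5`), the zigzag 10/11 pattern has higher
hexagonality and lower nearest-neighbour CV than the 10/11 parallel pattern,
and 21 radial lines against 10–11 for parallel constant schemes. Sweeping
geometry shows the ordering holds throughout the display-like region —
spans of roughly 150° and up with arc spacing at least ~2.5× the radial
spacing — and can invert for narrow, radially stretched fans (span ≤ 120°
with `radial_pitch` ≥ 1.2), a regime no displaying peafowl occupies. The
property tests sweep the display-like region; the default-geometry contrast
is asserted on its own.

## The growth model

Rows accrete annually: `rows_at_age()` is
`min(rows_per_year * age, max_rows)` with `max_rows = 19` by default (the
top of the observed 17–19 range; pass `Inf` for the uncapped lifetime
scenario, where 20 rows sum to 210 follicles). Eyespot counts follow by
enumerating the alternating row sizes and subtracting the fishtail and minor
rows — so within an age class the count is a constant, and all variance sits
between cohorts. Train length uses the saturating exponential
`L(a) = asymptote * (1 - exp(-rate * a))`; the observations say only
"asymptotic", so the package uses the simplest monotone bounded form, with
`asymptote = 150` cm and `rate = 0.3`/yr as defaults (plausible against
published covert lengths of 47–160 cm and behavioural maturity around four
years). Both are exposed; nothing downstream depends on the functional form
beyond monotonicity and boundedness.

```{r growth}
growth_trajectory(growth_params(), ages = c(1, 4, 10, 18, 20))
```

## The eyespot ring palindrome

An 11-feather row reads as a palindrome: five structurally distinct follicle
types mirrored around a central type (`T5 … T1 C T1 … T5`). Mapping type at
distance *i* from the centre to concentric zone *i* turns the row into the
eyespot's ring structure — centre plus five colour rings by default
(`palindrome_to_rings()`). The zone count convention (types + centre) is the
package's choice; whether the centre counts as a "ring" is a matter of
bookkeeping, and only the ordering is meaningful. Colours are abstract
labels; `render_eyespot_svg()` palettes are presentation only.

## What the specimen generator emulates — and what it does not

`generate_specimens()` produces records shaped like a museum series: row
count uniform on {17, 18, 19}, fishtail rows on {3, 4}, minor rows on
{2, 3}, deterministic lattice-predicted counts per draw, independent
per-feather damage (`damage_rate = 0.02` by default; published accounts
attribute count spread to breakage and handling but give no rate), and
feather lengths from zero-truncated Normals with the published means/SDs
(ESL 112.68 ± 25.58 cm, FTL 134.15 ± 32.17 cm for *P. cristatus*; the
*P. muticus* preset uses its published values). Damage-corrected counts
(each damaged feather counted as if present — the published counting
convention) are reported alongside raw counts. Summaries use the sample SD
(n − 1).

The generator emulates *summary statistics*, not birds: it has no
age–length correlation, no seasonal moult state, no between-population
structure, and damage is independent across feathers rather than clustered
by mishandling. Passing tests therefore show that the pipeline reproduces
the published table's location/spread under its stated inputs, not that real
specimen variation arises this way.

## Sizes and determinism

Everything is seeded and deterministic: `generate_specimens()` requires an
explicit seed, metric tie-breaks use a fixed documented seed, and the SVG
writers compose text directly so identical input yields byte-identical
output. The test suite runs on 18-row lattices (189 points), sweeps
1–25 rows for symmetry, and cross-checks the metrics against naive
O(n^4) brute-force oracles on instances of up to 50 points; specimen
statistics use 10^3–10^4 draws. Everything completes in seconds on one core.

## Limitations

* Geometry is 2-D throughout: the fan is a flat polar plane, the imprint of
  a display compressed onto a flat surface. The convex anchor plate and the
  train's 3-D curvature are out of scope.
* No feather-shaft/barb geometry, no iridescence or spectral modelling, and
  no mate-choice or fitness computation; those claims are conceptual, not
  simulational.
* Whether the oldest row has 10 or 11 follicles is unrecorded in the
  anatomy; `first_row_size` is a parameter (default 10) and every count the
  package reports is either parity-invariant or tested for both parities.
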