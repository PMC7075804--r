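---
title: "Nutrient density scoring and ingredient-rule classification of snack foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient density scoring and ingredient-rule classification of snack foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snacknrf)
```

## The model

Nutrient profiling condenses a food's composition into a single
nutrient-density number. The family of Nutrient Rich Food indices used here,
NRFn.3, balances *n* nutrients to encourage against the three nutrients of
public-health concern, on a fixed basis of 100 kcal of food:

$$\mathrm{NR}_n = \sum_{i=1}^{n} \min\!\left(\mathrm{cap},\;
  \frac{\mathrm{Content}_i}{\mathrm{DV}_i}\times 100\right), \qquad
\mathrm{LIM} = \sum_{i=1}^{3}
  \frac{\mathrm{Content}_i}{\mathrm{MRV}_i}\times 100, \qquad
\mathrm{NRF}n.3 = \mathrm{NR}_n - \mathrm{LIM},$$

where $\mathrm{Content}_i$ is the amount of nutrient $i$ per 100 kcal,
$\mathrm{DV}_i$ is its daily value and $\mathrm{MRV}_i$ its maximum
recommended value. The shipped default is NRF8.3: protein (50 g), fiber
(28 g), vitamin A (800 µg), vitamin C (80 mg), vitamin D (15 µg), calcium
(1000 mg), iron (18 mg) and potassium (4700 mg) against saturated fat
(20 g), added sugar (50 g) and sodium (2400 mg). A single set of US-based
reference amounts is applied to all markets so that products from different
countries are comparable.

Key modelling choices, with their rationale:

* **Per-100 kcal basis.** Label amounts per 100 g are rescaled by the
  product's energy density, `amount_per_100kcal(x, ed) = x * 100 / ed`.
  This makes the score independent of a joint rescaling of mass and energy
  (a property-tested invariant) but undefined for near-zero-energy foods,
  hence `ED_MIN` below.
* **Capping (%DV only).** Qualifying %DVs are truncated at 100 so a single
  fortified nutrient cannot dominate; LIM components are deliberately *not*
  capped — truncation is defined only for nutrients to encourage — so
  essentially-all-sugar products can and do exceed 100 %MRV for added
  sugar. The cap is applied per product, before any aggregation; applying
  it after averaging would mix products' truncation states and is not
  reproducible from per-product scores.
* **Total sugar.** A %MRV for total sugar (50 g reference) is computed and
  reported but never enters LIM, because total sugars include those
  naturally present in fruit and dairy; only added sugar is penalized.
* **`ED_MIN` = 1 kcal/100 g.** Products below this energy-density floor
  raise an explicit unscorable-product error naming the product, rather
  than returning infinities. Every snack category in the calibration
  targets has mean energy density of at least 40 kcal/100 g, so the floor
  is orders of magnitude below real snacks. Beverages are treated per 100 g
  with 1 mL ≡ 1 g.
* **Missing nutrients** contribute 0 to the sub-scores with a logged
  warning. Label panels genuinely omit nutrients, and no imputation source
  is bundled; contributing zero is conservative for NR (it can only lower a
  product's score) and anti-conservative for LIM, which is why the warning
  lists the affected products.
* **Configurability.** The qualifying set accepts 1–15 nutrients (NRF6.3
  through NRF15.3 in the published family); the limiting set is fixed at
  three. Standards round-trip through a small YAML file.

## Ingredient-list rules

Back-of-pack ingredient lists are ordered by predominance, which makes the
*first* ingredient informative about composition without any quantitative
declaration. The parser splits on top-level commas, treats parenthesized
and square-bracketed groups as nested sub-ingredient lists, and extracts
QUID percentages (`"whole milk (59.5%)"`, or the bare `"raspberry 5%"`
form seen inside sub-lists). QUID values are stored but play no role in
classification: the rules use order, not quantity.

Three rules are implemented:

* **dairy-first** — milk, yogurt or cheese as the first ingredient.
  Exclusions (milk chocolate, milk powder, milk solids) are checked before
  inclusions, so "skim milk powder" never matches through "milk". **Cream
  is deliberately not a dairy term**: the rule enumerates milk, yogurt and
  cheese only, so cream-first ice creams classify as neither-first. This is
  the single most consequential lexicon decision and is documented in the
  lexicon file itself.
* **fruit-first** — a fruit or fruit puree first, or second after water
  (the juice-from-concentrate pattern "water, oranges"), but never after
  sugar or any other ingredient. Concentrates, jams, pectins, flavors,
  powders and leathers are excluded before matching.
* **FVN presence** — any fruit, vegetable, nut, peanut or seed at any
  nesting depth, after the same fruit exclusions. Starchy vegetables
  (potato, corn) never qualify: the shipped vegetable lexicon omits them
  entirely (conservative), and in the chip categories (WWEIA
  5002/5004/5008) they are excluded even from user-extended lexica.

The published rule descriptions name exemplar terms but no exhaustive term
list; the lexica shipped under `inst/extdata/lexicons/` (plain text, one
term per line, `#` comments) are this package's concrete rendering of the
rules and are the main place a user may want to extend behaviour — for
example adding legume terms to FVN, or French terms for untranslated
labels. Matching is case-insensitive on whole words with light plural
folding ("strawberries" matches "strawberry"); multi-word terms match as
consecutive words. Only the top-level first token is eligible for the
first-ingredient rules; a compound first ingredient such as "fruit
preparation (strawberries, sugar)" does not classify fruit-first, because
order of predominance applies within the sub-list too and the compound's
own name is what the label leads with.

## Category aggregation and group comparison

Products map to 24 WWEIA snack categories by their 4-digit code (an
editable CSV partition; overlapping code sets are rejected). Summaries
report n, mean and sample SD (n − 1 denominator; SD of a single-product
category is reported as 0) for energy density, LIM and NRF, plus a pooled
total row whose means are the n-weighted category means — an identity the
tests assert exactly.

The two ingredient-defined contrasts (fruit-or-dairy-first vs neither; FVN
vs not) are compared variable-by-variable with a classical one-way ANOVA
(`stats::lm`/`anova`, equal variances — not Welch), which for two groups
is identical to the pooled-variance t test ($F = t^2$, tested to 1e-12)
and agrees with a permutation test within Monte-Carlo error. SEM is
SD/√n. Raw p-values are stored for all 16 rows (eight %DVs, four %MRVs
including total sugar, energy density, NR, LIM, NRF); rendered tables add
the conventional `<0.05` / `<0.001` labels. No multiple-testing correction
is applied across the 16 rows — the comparison table is descriptive, and
consumers who need familywise control can apply `p.adjust` to the stored
column.

## The synthetic-data generator

The product-level data the calibration tables summarize are proprietary
marketing-research data and cannot be redistributed, so the package ships
a seedable generator that emulates their statistical structure. What it
reproduces, in order of priority:

1. **Group-level nutrient means.** Each product belongs to one of five
   ingredient-template classes (fruit-first, dairy-first, dairy-first with
   fruit pieces, neither-with-FVN, neither). The two first-ingredient
   classes draw their per-100 kcal nutrient content (in %DV / %MRV units)
   from the published fruit-or-dairy and neither group rows, with SDs
   reconstructed as SEM·√n. Group means of the scored synthetic data are
   therefore unbiased for the published rows, and the first-ingredient
   NRF8.3 gap is 30 points in expectation (within ±5 at the default
   n = 261; within ±1.5 at 20× scale, both tested).
2. **Category structure.** The 24 categories carry their published product
   counts and energy-density mean/SD targets; energy density is drawn per
   category.
3. **Exact group sizes.** Template classes are allocated as fixed counts
   per category (e.g. all 16 nut products are neither-first FVN; 8 of 21
   whole-milk yogurts carry fruit pieces), summing to the published
   115/146 and 88/173 partitions. Fixed counts rather than per-product
   probabilities make the group sizes — and hence the contrast tables —
   structurally reproducible, at the cost of not modelling sampling
   variation in group membership, which nothing downstream uses.

Numerical design of the draws:

* **Location-solved truncated normals.** All amounts are truncated normals
  (at 0, or at `ED_MIN` for energy density). Naive truncation inflates the
  mean — badly where the target mean is small relative to the SD (the
  vitamin D "neither" row, mean 0.31 and SD ≈ 1.3, would inflate more than
  threefold; sodas' energy density 59 ± 55 would shift by ~15 kcal/100 g).
  The generator therefore solves (by `uniroot` on the Mills-ratio
  expression) for the location parameter whose *truncated* mean equals the
  target. The nominal SD is kept as the scale parameter; the realized SD
  is somewhat smaller than SEM·√n. Means are the calibration contract;
  SDs are descriptive.
* **Added vs total sugar.** Added sugar — the score-relevant quantity — is
  drawn calibrated to its group mean; total sugar is derived as added
  sugar divided by a uniform fraction (0.42–0.72 for the fruit/dairy
  class, 0.85–1.00 for the rest), so added ≤ total holds for every record.
  The published "neither" column actually prints added sugar (11.66 %MRV)
  *above* total sugar (10.62 %MRV), which no product-level data satisfying
  added ≤ total can reproduce; the generator calibrates the added-sugar
  mean and lets total sugar land where the fraction puts it (≈ 12 %MRV for
  that class).
* **Labels.** Each template class emits ingredient strings imitating real
  label phrasing (QUID percentages, nested sub-lists, the water-leading
  juice pattern, chip labels whose potato/corn must *not* earn FVN
  credit), constructed so the classifier provably recovers the intended
  flags — an exact, all-products test.

What the generator does **not** emulate, and hence what passing tests do
not show about real data:

* Per-category LIM and NRF means. The two published tables summarize
  different partitions of the same unavailable data and cannot both be
  matched by a single product-level distribution; group-level calibration
  wins, so sodas, for instance, get the "neither" class's added-sugar mean
  rather than their much higher real one. Only the category energy-density
  means (recovered within 3 SE at 100× scale, tested) and counts are
  category-level targets.
* The magnitude of the FVN contrast. FVN membership is emergent (fruit
  classes plus nut/fruit-containing others), and with class-level nutrient
  profiles the synthetic FVN increment comes out around 6–9 points rather
  than the published 22 — the right sign, attenuated, because within-class
  nutrient differences between FVN and non-FVN products are not modelled.
  The pipeline computes it either way; its value is reported, not asserted.
* Within-group covariance between nutrients, country-level differences
  (country labels are cosmetic, uniform by default), brand names, serving
  sizes, and label text beyond what the classifier consumes.

A fixed default seed (2020) ships with the configuration so documentation
examples are stable; every generation call is reproducible byte-for-byte
from (config, seed).

## Problem sizes and runtime choices

The default dataset is the study-sized n = 261, which every pipeline stage
handles in well under a second. Law-of-large-numbers checks of the
generator's calibration run at 20× (property tests) and 100× (energy
density recovery, scoring ~26k products in a few seconds); bulk
classification at 100× is the slowest path (tens of seconds) and is
exercised at default scale where the flag-agreement guarantee is exact
anyway. The permutation check of the ANOVA p-value uses 10,000 draws at
n = 26.

## Known limitations

* English-only lexica; untranslated French labels will under-classify.
  Lexica are user-extendable files precisely for this.
* The first-ingredient rules read only the top-level first token (see
  above); products leading with a compound fruit preparation are
  classified conservatively.
* Whether cream-first premium ice creams should count as dairy-first is
  genuinely ambiguous in the rule as stated; this package excludes them
  and documents the choice rather than guessing.
* Scores are computed per 100 kcal only (energy density is reported per
  100 g); no per-serving variant and no RACC logic.
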