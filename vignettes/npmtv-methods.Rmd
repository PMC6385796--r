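---
title: "Methods: nutrient-profile classification and TV exposure analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-profile classification and TV exposure analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmtv)
```

## The decision model

The engine implements a category-based nutrient profile model of the kind
used to regulate food marketing to children in the WHO Eastern Mediterranean
Region: products are assigned to one of 18 food categories (beverages split
into subcategories 3a–3e), and a product's marketing verdict is determined
entirely by its category and its composition per 100 g (solids) or 100 mL
(liquids). The rules are applied in a fixed order:

1. **Auto-prohibited categories.** Chocolate and sugar confectionery (1),
   fruit juices (3a), energy drinks (3d), edible ices (4), cakes and sweet
   baked goods (6), and processed meat and poultry (14) are not permitted
   regardless of composition. Their verdict is composition-invariant — a
   property the test suite fuzzes directly.
2. **Industrial trans fat.** More than 1 g of industrially produced trans
   fatty acids per 100 g of *total fat* fails. We read the rule's
   denominator as total fat, not product mass, and name the field
   `industrial_tfa_g_per_100g_fat` to make the unit unambiguous.
3. **Alcohol.** At least 0.5 % of total energy from alcohol fails; the
   boundary itself (exactly 0.5 %) fails, matching the "at least" phrasing.
4. **Non-sugar sweeteners.** A boolean per product; fails only in categories
   that prohibit sweeteners. How sweetener presence is detected (ingredient
   list vs. label claim) is a coding decision left to data entry.
5. **Nutrient thresholds.** Any applicable nutrient strictly above its
   category maximum fails; a value exactly at the threshold passes. The six
   nutrient keys are fixed: `energy_kcal`, `total_fat_g`,
   `saturated_fat_g`, `total_sugars_g`, `added_sugars_g`, `salt_g`.

A product is **permitted** exactly when no rule fires; the returned
`violations` list-column records every fired rule with the observed value
and threshold. Composite or restaurant meals are evaluated component-wise
and permitted only if every component is — the conjunction is verified
against a brute-force oracle in the tests.

Three deliberate design choices:

* **Missing is not zero.** A missing value for any nutrient applicable to
  the product's category yields an `insufficient_data` status (an error in
  the scalar API), never a verdict. Field studies fill such gaps from
  manufacturer data or food composition tables rather than assuming
  absence, and the engine should not decide what the coder has not measured.
* **Thresholds live in data, not code.** The engine is threshold-agnostic:
  categories and maxima come from a schema-validated YAML/JSON file. The
  shipped instance carries the true taxonomy and auto-prohibition flags but
  *synthetic* threshold values (its filename says so); all engine behaviour
  is tested against the schema, not against any particular published
  number.
* **Salt, not sodium.** Inputs are salt grams; a loader convenience accepts
  sodium and converts at salt = sodium × 2.5, flagging converted rows so
  the provenance survives.

Extension categories — alcoholic drinks ("19") and coffee ("20") — occur in
broadcast corpora but sit outside the model. The engine marks them
non-assessable; the exposure layer decides how to count them (below).

## Exposure statistics

All analytics are exact integer-ratio computations on the coded corpus:

* **Food-ad share**: food ads / all ads × 100, overall or by program rating
  (C = children's, G = general audience, PG = parental guidance) and study
  week.
* **Hourly frequency**: food ads ÷ analyzed broadcast hours, from an
  analyzed-hours table keyed by channel × week × rating.
* **Category distribution**: shares within a rating normalize by the sum of
  *categorized* food ads in that rating (the column-sum convention of
  category tables); uncategorized food records are excluded with a warning.
* **Permitted share**: under the `emr18` basis the denominator excludes
  extension-category ads; under the `extended` basis all food ads count and
  extension products are deterministically not permitted. Data-insufficient
  products are reported in their own column inside the denominator. The
  identity *not-permitted(extended) = not-permitted(emr18) + #extension
  ads* is property-tested on simulated corpora.
* **Claim/disclaimer shares** use food-ad denominators per stratum.
* **Intercoder reliability** is percent agreement,
  100·a/(a + d), on pre-tallied counts; no double-coding workflow is
  modeled.

Rounding is half-up (ties away from zero), one decimal for shares,
frequencies and permitted tables, two decimals for claim/disclaimer tables —
the printed conventions of this literature. `round_half_up()` is exported
because R's `round()` rounds half to even.

## The synthetic generator

`sim_config()` defaults encode the emulated study conditions: 3 channels, 4
study weeks of three weekdays (15:00–22:00) plus one weekend day
(08:00–22:00), about 20.6 analyzed hours per channel-week split over ratings
roughly 5/59/36 % (C/G/PG), ≈19.9 ads per analyzed hour, per-rating food-ad
probabilities 0.432/0.320/0.288, a 17-category mixture dominated by
confectionery and sweet baked goods with alcohol and coffee present, and
claim/disclaimer rates 0.179/0.039 among food ads. Block ad counts are
Poisson in the analyzed hours; food status, category, claims and disclaimers
are independent draws. Generated catalogues straddle the category
thresholds at a configurable margin (default 25 %), so both verdicts occur
in every non-auto category; auto-category products get random composition
since their verdict cannot depend on it.

The generator reproduces the *statistical* structure of an ad stream, not
its temporal texture: no program titles, no brand names, no ad-break
clustering, no day-of-week scheduling effects, and claims are independent
of category, which real corpora are not. Passing tests therefore
demonstrate correctness of the accounting and the decision logic, not
realism of any particular broadcast market.

Seeding is mandatory and corpora are byte-identical under equal seeds
(`withr::with_seed` isolates the RNG). Rate-recovery properties are checked
against binomial 99 % confidence intervals in streams of at least 10⁴
draws — the law-of-large-numbers regime the property is stated for; smaller
strata are not asserted against.

## The reference corpus

`reference_corpus()` builds, without randomness, a corpus whose margins are
fixed: 4,510 ads (1,393 food) over 226.46 analyzed hours, with every
rating × week total, category count, claim/disclaimer count and
permitted/not-permitted count pinned to an embedded reference table. Only
the margins are pinned. The joint allocation — which week a given
confectionery ad airs in, which ads carry claims, how hours split across
channels — is a deterministic greedy fill (categories in id order zipped
against week slots; largest-remainder channel assignment proportional to
each channel's analyzed hours; claims assigned to the first records in
order) and is documented as non-unique.

One inconsistency is inherent to the reference tabulation and surfaced
rather than hidden: per-category counts sum to 36/845/555 per rating while
the food-ad totals are 35/818/540. The main `ads` table follows the food-ad
totals (reducing the model-category counts by a deterministic
decrement-the-largest rule, leaving the alcohol/coffee counts exact), and a
separate `category_ads` view carries the per-category counts exactly for
use with `category_distribution()`. `fx$meta` records both count sets.

The catalogue behind the corpus is built *against the shipped model file*
so that the permitted counts (0/35 C, 88/596 G, 80/397 PG under the
18-category basis) emerge from the decision engine at run time — permitted
ads map to products below their category thresholds, the rest to products
above them or in auto-prohibited categories. Nothing in the pipeline looks
the verdicts up.

## Numerical and degenerate-input choices

* Percent rounding uses a 10⁻⁹ guard before the half-up floor so exact
  binary ties (e.g. 16.35) round as printed.
* Zero-valued thresholds are meaningful ("no added sugars"): a value of 0
  passes (equality), any positive value fails.
* Empty corpora, empty catalogues and zero-food strata return empty or
  zero-valued tables; zero analyzed hours is an error, not an `Inf`.
* Validation is total: every malformed row of an ads CSV yields one
  row-numbered diagnostic and the file is rejected whole.
* Reports embed a run manifest (tool version, inputs, timestamp); the data
  files themselves are byte-stable across reruns, and the determinism test
  compares those.

## Problem sizes

The test suite runs the full 4,510-record reference corpus end-to-end
(< 1 s to build), fuzzes the engine against a brute-force oracle on 260
random products plus 40 with injected missingness, and exercises the
generator at its default frame (≈4,500 ads) and at a widened 10-channel
frame (≈36,000 ads, > 10⁴ food ads) for rate recovery. These sizes were
chosen to put every property in its intended statistical regime while
keeping the suite fast enough to run habitually.

## Known limitations

* The shipped threshold values are synthetic; conclusions about real
  products require a model file populated from the official publication.
* Category assignment is coder input; the package does not infer categories
  from product names (and whether, e.g., nectars count as fruit juices is a
  coding decision).
* No inferential statistics are provided — the analytics are descriptive,
  as in the underlying study design.
* The generator's independence assumptions (claims independent of category,
  no temporal clustering) make it unsuitable for studying anything but the
  accounting it was built to test.
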