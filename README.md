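# npmtv

Nutrient-profile classification of TV food advertising to children.

Television remains the dominant channel through which food and drink are
marketed to children, and exposure to such marketing is linked to unhealthy
dietary patterns and childhood obesity. The WHO Regional Office for the
Eastern Mediterranean published a regional nutrient profile model for
restricting this marketing: foods are assigned to 18 categories (with
beverage subcategories), each carrying per-100 g/mL maxima for energy, total
fat, saturated fat, total sugars, added sugars and salt; six categories —
chocolate and sugar confectionery, edible ices, cakes and sweet baked goods,
processed meat and poultry, fruit juices and energy drinks — are prohibited
from child-directed marketing outright, regardless of composition.

`npmtv` is for public-health nutrition researchers and policy analysts who
run TV food-marketing content analyses against such a model. It provides:

* **a threshold-table-driven decision engine** — a product with composition
  *x* (per 100 g or 100 mL) in category *c* is **not permitted** iff
  *c* is auto-prohibited, or TFA > 1 g/100 g of total fat (industrially
  produced trans fat), or alcohol ≥ 0.5 % of total energy, or non-sugar
  sweeteners are present in a category that prohibits them, or
  *x<sub>k</sub>* > *t<sub>c,k</sub>* for any applicable nutrient *k*
  (comparison strict: equal to threshold passes). Composite meals are
  permitted iff every component is. Missing composition raises an
  insufficient-data flag, never a verdict;
* **exposure analytics** — food-advertisement shares
  (*n*<sub>food</sub>/*n*<sub>total</sub> × 100) overall, by C/G/PG program
  rating and by study week; hourly frequencies against analyzed broadcast
  hours; category distributions; permitted/not-permitted shares under the
  18-category basis and an extended basis counting alcohol and coffee ads as
  not permitted; health-claim and disclaimer shares; and intercoder percent
  agreement, 100·*a*/(*a* + *d*);
* **a seeded synthetic generator** of broadcast logs, analyzed-hours tables
  and product catalogues with the sampling frame of a multi-channel
  children's-viewing-time study, plus a deterministic reference corpus whose
  marginal counts are fixed, for end-to-end testing.

Every function takes and returns tidy tibbles, so pipelines compose with the
pipe. Model files are YAML/JSON; corpora are plain CSV.

The shipped model instance (`emr_model_file()`) carries the real category
taxonomy and auto-prohibition flags but **synthetic threshold values**; for
regulatory use, populate a model file from the officially published limits.

## Worked example

```r
library(npmtv)

fx <- reference_corpus()   # deterministic 4,510-ad benchmark corpus

food_ad_share(fx$ads, by = "rating")
#> # A tibble: 3 × 4
#>   program_rating n_food n_total   pct
#>   <chr>           <int>   <int> <dbl>
#> 1 C                  35      81  43.2
#> 2 G                 818    2553  32
#> 3 PG                540    1876  28.8

permitted_share(fx$ads, fx$products, fx$model, basis = "emr18")
#> # A tibble: 4 × 7
#>   program_rating n_food n_permitted pct_permitted n_not_permitted
#>   <chr>           <int>       <int>         <dbl>           <int>
#> 1 C                  35           0           0                35
#> 2 G                 596          88          14.8             508
#> 3 PG                397          80          20.2             317
#> 4 overall          1028         168          16.3             860

intercoder_reliability(97, 3)
#> [1] 97
```

Reading: 43.2 % of advertisements during children's (C-rated) programs are
for food or drink, against 32 % and 28.8 % in general-audience and
parental-guidance programs. Of the 1,028 food ads for products inside the
18-category model, only 16.3 % are for products whose marketing to children
the model permits; during children's programs, none are. The intercoder
agreement of 97 % is the percent-agreement statistic on a double-coded
sample with 97 agreements and 3 disagreements.

To score your own catalogue and corpus:

```r
decisions <- run_profile("products.csv", "model.yaml", out_dir = "report/")
tables <- run_analyze("ads.csv", "blocks.csv", "products.csv", "model.yaml",
                      basis = "emr18", out_dir = "report/")
```

or from a shell via the thin front-end `inst/cli/npmtv.R`
(`profile`, `analyze`, `simulate` subcommands).

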