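---
title: "Methods: reformulation-price monitoring on matched label databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reformulation-price monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reformprice)
```

## The problem and the design

Reformulation monitoring compares the *same* packaged product at two time
points and asks (a) how much its nutrient composition changed and (b) whether
that change is associated with a price change. The design controls
confounding structurally rather than statistically: matching on product code,
retailer **and container size** removes retailer pricing differences, unit
price effects of bulk sizes, and shrinkflation (a container-size change
breaks the key on purpose — a 450 g relaunch of a 500 g product is not the
same offer); working on within-product price *changes* removes each
product's price level; and comparing changes *between* reformulation groups
removes inflation, which shifts all groups equally.

That last argument is not left as prose. Because every model here has the
form

$$\Delta p_i = \alpha + \boldsymbol\beta^\top x_i + \gamma\,\text{size}_i +
\boldsymbol\delta^\top \text{brand}_i + u_{r(i)} + \varepsilon_i,$$

with an intercept always present, adding a constant \(c\) to every
\(\Delta p_i\) changes only \(\hat\alpha\); all exposure coefficients are
invariant. The suite asserts this metamorphically (shift all deltas, refit,
compare to 1e-8).

## Pipeline stages and their contracts

**Matching.** Exact equality on `(product_code, retailer_id, container_size,
unit)`. A key occurring more than once within a year is *ambiguous* and is
excluded, never resolved arbitrarily — conservative, reproducible, logged.
When a product carries both a UPC and a retailer-specific code, the caller
supplies whichever is authoritative in `product_code`; UPC is preferred
because it is globally unique.

**Exclusions.** Four named stages in the narrative order of the study design:
TRA categories W and X (children's food and meal replacements face bespoke
composition rules); missing/nonpositive prices; incomplete core nutrition
(energy, fat, saturated fat, carbohydrate, sugars, protein, sodium — the
monitored set; the exact membership is a documented, configurable choice);
and FSANZ ineligibility (missing fibre, FVNL %, or calcium for cheese
candidates). Each stage is idempotent and appends a reconciled audit row.

**Normalization.** Price per 100 uses container size; nutrients per 100 use
serving size (that is how Nutrition Facts data are printed). Deltas are
year-2 − year-1; positive means an increase over time.

**Classification.** The five groups use the front-of-pack labelling
thresholds — 5 % of the Daily Value ("a little") and 15 % ("a lot"). The
printed bands are rounded to one decimal ("−4.9 % to +4.9 %"), so the bands
are implemented as a gap-free tiling of the real line with ±5 and ±15
belonging to the larger-magnitude group, matching the printed "≥ −15 %" and
"+5 % to +14.9 %". Whether the study divided deltas by the DV or by the 2017
value is genuinely ambiguous in the source material (the Methods name the DV;
a Discussion comparison reads like relative change), so both modes are
provided; `percent_of_dv` is the default because it follows the Methods
wording, and it is also better behaved (no division by near-zero baselines).

**Daily Values.** The DV denominators are data, not code
(`inst/extdata/dv_table.csv`, versioned, recorded into every report): energy
2000 kcal (the reference intake anchoring the %DV footnote), fat 75 g,
saturated fat 20 g, carbohydrate 275 g, sugars 100 g, sodium 2300 mg.
Canadian labelling has no protein %DV, so the 50 g reference standard is
used; being an editable input, a different convention is one file edit away.

**FSANZ NPSC.** The scorer is entirely table-driven
(`inst/extdata/npsc_tables.json`): baseline points for energy (kJ),
saturated fat, sugars and sodium; modifying V (FVNL %), P (protein) and F
(fibre) points; the protein gate (P withheld when baseline ≥ 13 unless
V ≥ 5); category pass thresholds (< 1 beverages, < 4 other, < 28
cheese/fats/oils); and the TRA→category mapping (B → beverages, H → category
3, D gated by calcium > 320 mg/100 g). Two transcription choices deserve
note. First, steps are applied *inclusively* (points awarded at value ≥
threshold) so that a value equal to a printed band edge earns that band's
points; this differs from the standard's strict ">" only on a measure-zero
set and makes boundary tests deterministic. Second, the category-3 extended
sodium ladder is encoded as 90× the published saturated-fat ladder (the
schedules share one geometric progression); the file is versioned precisely
so such entries can be revised without touching code, and the shipped
fixtures avoid depending on those high bands. Energy arrives in kcal (as
printed on Canadian labels) and is converted at 4.184 kJ/kcal before lookup.

## Statistical choices

* **Wilcoxon signed-rank**: zero differences dropped (standard convention),
  exact null for n ≤ 25 with untied ranks, otherwise normal approximation
  with continuity and tie correction. All-zero differences are reported as a
  degenerate comparison with p = 1 rather than an error, because matched
  label data genuinely produce identical price vectors.
* **Mixed models**: retailer is a random intercept; container size enters
  continuously, standardized internally for conditioning (the estimate is
  reported on the model's own scale; the exposure coefficients are what
  matter and are coding-invariant); brand type is a four-level factor with
  multinational as reference. Reformulation groups with fewer than 5 pairs
  are dropped before fitting and reported; singular random-effect fits fall
  back to a fixed-intercept OLS fit with a logged flag (and the suite proves
  the degenerate single-retailer case reproduces OLS to 6 decimals).
* **Inference**: Wald t intervals and p-values using residual-style degrees
  of freedom (for the mixed fit, n − fixed parameters − number of
  retailers). The normal reference is anticonservative in the small
  per-category cells this design produces (a 10–30 observation cell with six
  fixed parameters); the t reference restores null calibration, which the
  suite verifies by simulation.
* **Multiple testing**: BH step-up within each analysis family, and the
  family definitions are recorded in the report because the source material
  states only that adjustment happened "within the same sample". Families:
  (1) all reformulation-group coefficients across the seven nutrients;
  (2) all FSANZ-slope cells, overall plus per-category, as one family;
  (3) price-comparison cells per grouping. Note a structural fact the
  calibration test respects: under a global null each BH family's
  any-discovery rate is ≈ α, so a union over several families is ≈ kα by
  construction — per-family calibration and the pooled proportion of
  significant terms are the meaningful quantities, and those are what the
  acceptance suite bounds at 7 %.
* **FSANZ-change models**: cells under 10 pairs are skipped (the source
  design dropped a 9-pair cell), as are constant-predictor cells.

## The synthetic supply: what it emulates and what it does not

The generator states a world resembling the monitored Canadian supply:
3 retailers, 22 analysed TRA categories (plus ~3 % mass in the excluded
W/X), four brand types dominated by multinationals, lognormal per-100
nutrients and prices (per-100 price mean $1.52, sd $1.78 — the published
price distribution; right-skew is what label data show), sodium as the
most-reformulated nutrient at prevalence 0.178 with 47 % of events being
increases, other nutrients at 0.10–0.13, reformulation magnitudes drawn as
% of DV (mean 12, sd 6, truncated above the 5 % threshold so an event always
leaves the little-change band), 1.5 % inflation (the 2017–2021 food-CPI
range was roughly 0–3 %), ±$0.02/100 g retailer offsets, $0.10/100 g price
noise, 2 % shrinkflation, 30 % one-year-only products, 1 % missing prices,
and enough nutrition missingness that about two-thirds of matched pairs are
nutrition-complete. Defaults are conveniences stating plausible magnitudes,
not claims about the real supply.

Three construction rules matter for testability. Deltas are drawn as % of DV
and mapped back to absolute per-100 amounts, so ground-truth groups follow
by construction and the classifier must reproduce them *exactly*. A drawn
decrease is capped at the baseline (reformulation to zero) when the baseline
supports at least a 5 % DV drop and flipped to an increase otherwise, so the
realized changed-fraction equals the event rate exactly — at the cost of a
mild upward drift for nutrients whose baselines sit near the 5 % DV floor
(visible as a slowly rising mean NPSC score; real supplies need not drift).
Inflation is multiplicative on price while injected reformulation effects
are additive on the per-100 price change, so the inflation-cancellation
invariant can be asserted exactly.

What the generator does **not** emulate: real marginal distributions per
category, product-name text, correlated nutrient changes within a
reformulation event, relaunches under new UPCs, promotions, or regional
pricing. A green test therefore establishes that the pipeline's logic and
inference behave as specified under a known data-generating process — not
that any substantive finding about a real food supply would replicate.

## Numerical and degenerate-input decisions

* Container-size match uses exact numeric equality after unit normalization
  (g and ml kept distinct); no tolerance, since none is stated for the
  design being emulated.
* Unparseable numeric CSV cells become missing values, are counted in a
  parse report, and never abort a read; missing mandatory *columns* do.
* `satfat > fat` and `sugars > carb` are validation warnings, not
  rejections — printed labels genuinely contain such inconsistencies.
* Relative-mode percent change with a zero baseline is missing, logged, and
  excluded from classification.
* Classification of a missing delta is missing; non-finite percentages are a
  hard error.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical config + seed reproduces byte-identical
  databases and report tables (the provenance timestamp is the single
  non-deterministic output, kept out of the table files).

## Known limitations

* The NPSC transcription is as shipped; jurisdictions revise the schedules,
  and the category-3 extended sodium bands are encoded from the schedules'
  geometric ladder rather than checked against a live regulator calculator
  (unavailable offline). The table file's version string travels with every
  report so a revised transcription is traceable.
* FVNL % must be supplied as data; the package does not estimate it from
  ingredient lists.
* No fuzzy matching: products relaunched under a new code or size are
  unmatched by design and counted, not recovered.
* Mixed-model inference uses Wald t with a residual-style df, not
  Satterthwaite/Kenward–Roger; for the cell sizes this pipeline retains
  (≥ 10) the difference is small and the calibration simulations bound it.
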