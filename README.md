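# gdistinct

Re-identification risk analysis of demographic quasi-identifiers.

## What problem this solves

Stripping names and ID numbers from a patient table is not anonymization:
the remaining combination of **date of birth, gender and residence** still
singles out a large share of most populations once it can be linked against
an outside source. Data custodians — hospital data offices, registries,
privacy officers — need a number, not a feeling, before sharing such a
table: *how many patients are unique in their quasi-identifier combination,
and how much does a given generalization policy shrink that set?*

`gdistinct` computes that number for tables with a hierarchical,
Chinese-style address (province / city / district) standing in for
low-quality postal codes. It implements:

* **Geocoding** of address triples into fixed-width 9-digit *surrogate ZIP
  codes* (2-digit provincial division + 3-digit city + 4-digit district)
  via an exact-match gazetteer, plus partitioning by provincial-level
  administrative division (PAD);
* **Generalization policies**: the *limited dataset* view (full DOB,
  gender, full ZIP) and the HIPAA-safe-harbor-style view (birth year,
  gender, 6-digit ZIP prefix), plus arbitrary custom sweeps
  (day/month/year/decade granularity, prefix 0–9, optional age top-coding);
* **The g-distinct statistic**: an individual is *g-distinct* when at most
  g−1 others share their tuple. With `|bin(i)|` the number of equivalence
  classes of size `i`,

  ```
  h(g) = Σ_{i=1..g} i·|bin(i)|
  ```

  counts the patients in classes of size ≤ g; `h(g)/N` is the at-risk
  fraction, `h(1)/N` the uniquely identifiable share;
* **Stratified analysis**: per-PAD 1-distinct percentages versus PAD
  population, with a Spearman trend statistic;
* **A seeded synthetic population generator** (records + matching gazetteer
  + ground truth) so the whole pipeline is testable without protected
  health data.

## A worked example

```r
library(gdistinct)

bundle <- generate_population(scenario_presets()$tiny)  # 1,000 records, seeded
res <- run_risk_analysis(bundle$records, bundle$gazetteer)
res
#> g-distinct risk analysis
#>   records: 1000 in, 947 retained after filtering, 947 mapped to ZIP codes
#>   nonempty PADs: 33
#>   policy 'limited':   1-distinct: 100.00%  (N = 947, max class size 1)
#>   policy 'safe_harbor': 1-distinct:  87.43%  (N = 947, max class size 3)

res$filter_report
#> Record filter report
#>   n_input           : 1000
#>   n_missing_address : 41
#>   n_sentinel_dob    : 12
#>   n_retained        : 947

res$policies$safe_harbor$histogram
#> Equivalence-class size histogram: N = 947, 3 distinct class size(s)
#> # A tibble: 3 × 2
#>   class_size num_bins
#>        <int>    <int>
#> 1          1      828
#> 2          2       58
#> 3          3        1
```

Reading this: 53 of 1,000 raw records were excluded (41 with an incomplete
address, 12 carrying the `1900-01-01` sentinel DOB). Under the limited view
every one of the 947 retained patients is unique — full DOB plus a
district-level code is nearly a personal identifier. The safe-harbor view
merges patients into 887 classes (828 singletons, 58 pairs, one triple), so
87.43% remain unique at this small scale. The gap between the two policies
widens rapidly with sample size; at the 100,000-record `paper_like` preset
the limited view stays ~99.8% unique while safe harbor drops to ~7%, and
the per-PAD tables show uniqueness falling as PAD population grows under
both policies.

Individual stages are available as plain functions
(`read_records()`, `filter_records()`, `load_gazetteer()`,
`encode_addresses()`, `partition_by_pad()`, `apply_policy()`,
`compute_bins()`, `risk_curve()`, `g_for_fraction()`, `pad_risk_table()`,
`trend_statistic()`), all with delimited-text import/export. See the
vignette in `vignettes/reidentification-risk.Rmd` for the model, the
generator's design and its limitations.

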