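---
title: "Measuring re-identification risk with g-distinct analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring re-identification risk with g-distinct analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(gdistinct)
```

## The problem

Removing names and ID numbers from a patient table does not make it
anonymous. The combination of date of birth, gender and place of residence —
the classic demographic *quasi-identifier* triple — singles out a large share
of most populations once an attacker can link it against an external source
(social-network profiles, registries, leaked databases). Disclosure-control
practice therefore asks a quantitative question before data are shared: *how
many patients in this table are unique, or nearly unique, in their
quasi-identifier combination, and how much does a given generalization policy
reduce that number?*

This package answers that question for hospital-style demographic tables
with a hierarchical Chinese-style residence address (province / city /
district) in place of a usable postal code. Because real tables of this kind
are protected health information, the package also ships a seeded synthetic
population generator, so that every stage of the pipeline can be exercised,
tested and benchmarked without any real data.

## The risk statistic

Patients are grouped into *equivalence classes* ("bins"): two patients share
a bin exactly when their quasi-identifier tuples are identical under the
active policy. Write $|bin(i)|$ for the number of bins containing exactly
$i$ patients. An individual is *g-distinct* when at most $g-1$ others share
their tuple; 1-distinct means unique. The cumulative count

$$h(g) = \sum_{i=1}^{g} i\,|bin(i)|$$

is the number of patients lying in bins of size at most $g$, and $h(g)/N$ is
the fraction of the population at risk at threshold $g$. The package's core
object is the class-size histogram $\{i \mapsto |bin(i)|\}$, from which
`h_of_g()`, `risk_curve()`, `unique_fraction()` and threshold queries
(`g_for_fraction()`) all derive. Conservation ($\sum_i i\,|bin(i)| = N$),
monotonicity of $h$, and the terminal value $h(g_{\max}) = N$ are enforced
invariants, not conventions.

Keys are compared as exact tuples of canonical strings (trimmed, Unicode
NFC). Hashing is an implementation detail; equality is the contract, so no
collision tolerance exists anywhere in the statistic.

## The pipeline

The preprocessing mirrors standard practice for this kind of audit:

1. **Read and validate** (`read_records()`): ISO 8601 dates only — any other
   dialect becomes missing with a warning rather than being guessed, because
   silently reinterpreting `31/12/1980` risks corrupting birth years.
   Duplicate record identifiers are a hard error.
2. **Filter** (`filter_records()`): two exclusion rules, applied in a fixed
   order for deterministic reports — records missing any address component,
   then records whose DOB is a sentinel placeholder (default
   `1900-01-01`, the configurable hallmark of data-entry defects). Records
   with missing gender or a missing-but-plausible DOB are *retained* here
   and only dropped (and counted) at binning time, keeping the statistic
   well defined without inventing exclusions the workflow does not call for.
3. **Encode** (`encode_addresses()`): exact gazetteer lookup maps each
   (province, city, district) triple to a 2+3+4-digit code triple,
   concatenated into a 9-digit *surrogate ZIP code*. Codes are opaque digit
   strings — never integers — so leading zeros survive. Unmapped triples are
   counted and excluded, never fuzzily matched; free-text address parsing is
   deliberately out of scope so the pipeline stays auditable.
4. **Partition** (`partition_by_pad()`): records group by the first two ZIP
   digits, the provincial-level administrative division (PAD).
5. **Generalize** (`apply_policy()`): the *limited dataset* policy keeps
   full DOB, gender and the full 9-digit ZIP; the *safe harbor* policy
   generalizes DOB to birth year and truncates the ZIP to its first 6
   digits. `policy_spec()` exposes the whole sweep space (day / month /
   year / decade granularity, prefix length 0–9, optional age top-coding).
6. **Evaluate** (`compute_bins()` and friends, `pad_risk_table()`,
   `trend_statistic()`).

`run_risk_analysis()` chains all of this for the common two-policy
comparison.

## Parameters that matter

* `zip_prefix_len` (digits, default 9 limited / 6 safe harbor). Note that a
  6-digit prefix spans PAD (2) + city (3) + only the *first* district digit;
  with districts numbered sequentially inside a city that digit is almost
  always `0`, so the safe-harbor view effectively retains city-level
  geography. The prefix is configurable precisely because this boundary is
  a policy choice, not a law of nature.
* `dob_granularity` (`day`, `month`, `year`, `decade`). Decade floors the
  birth year (`1969 → "1960s"`); any monotone convention would do, this one
  is documented and kept.
* `topcode_age_at` (years, default off). The HIPAA-style "ages over 89"
  pooling is implemented but disabled by default, because the two named
  policies modelled here generalize only DOB and ZIP. Turning it on
  requires a `reference_date`.
* `sentinel_dobs` (default exactly `1900-01-01`): the only placeholder named
  by the workflow this package models; extendable for local conventions.

### Coarsening

`is_coarsening(fine, coarse)` formalizes "policy B merges A's classes": it
is `TRUE` when B's view is a deterministic function of A's (granularity
coarser or equal, prefix shorter or equal, top-coding reproducible). A pooled
DOB component can never be un-pooled, and exact ages are recoverable only
from day-granular views, so top-coding compatibility is: both off, both at
the same threshold, or the fine view is day-granular. When
`is_coarsening(A, B)` holds, $h_B(g) \le h_A(g)$ for every $g$ — merging
bins can only grow class sizes — which is why safe harbor's unique count can
never exceed the limited dataset's on the same records. The test suite
checks the functional-dependence definition against an exhaustive oracle on
a witness-dense record grid.

## The synthetic population generator

`generate_population()` emulates the statistical *shape* of a national
hospital sample, not any real population:

* **Geography**: `n_pads` provincial divisions (default 33, matching the
  convention that one of China's 34 PADs is typically empty in mainland
  hospital samples), each with cities and districts whose codes are
  generated sequentially. PAD populations follow Zipf weights (default
  exponent 1.0), emulating the heavy skew of regional sample sizes;
  city and district choices are uniform within their parent.
* **Demographics**: DOB uniform over calendar days in 1930–2010 by default
  (a `year_weighted` hook exists for age-pyramid emulation but ships with
  uniform weights); binary gender with `gender_prob = 0.5`.
* **Defects**: with probability `missing_address_rate` (default 0.05) one
  address component, chosen uniformly, is blanked; with probability
  `sentinel_dob_rate` (default 0.01) the DOB is overwritten by the sentinel.
  The defaults are single-digit-percentage rates typical of address and
  date-entry quality in electronic hospital records; they are package
  defaults chosen once, not fitted quantities.
* **Reproducibility**: one seeded stream, consumed in a fixed documented
  order (gazetteer shape, then PAD → city → district → DOB → gender →
  defects per record), so a config plus seed pins the bundle bit-for-bit.
  Each bundle carries a `truth` table (record → assigned PAD and ZIP,
  recorded before defects), which gives the geocoding stage an end-to-end
  oracle.

### Scenario presets and the scaled-down design argument

`scenario_presets()` ships `tiny` (n = 1,000, unit tests), `paper_like`
(n = 100,000) and `stress` (n = 1,000,000). The `paper_like` scenario is a
desk-scale stand-in for a ~0.83M-record national sample spread over 33 PADs
and roughly 2,600 districts. Its geography uses 5 cities per PAD × 16
districts per city (2,640 districts). The split is the one deliberately
*scaled* choice: the contrast between the limited and safe-harbor views is
governed by the occupancy of the safe-harbor cells (PAD × city × birth-year
× gender, since the 6-digit prefix erases the district). A sample an eighth
of the real scale over the real ~330 prefecture cities would dilute those
cells far below the regime such audits operate in, washing out the
policy contrast the scenario exists to exhibit; proportionally fewer cities
per PAD restores comparable per-cell occupancy while keeping the district
count, PAD count, Zipf skew and DOB span at their stated values.

What the generator does *not* emulate: age pyramids (uniform DOB understates
birth-year collisions relative to real cohorts), within-PAD population
skew, correlated defects, or disease attributes (diagnosis plays no role in
the statistic). Passing tests on synthetic data therefore validate the
*machinery* — conservation, monotonicity, coarsening, trends — and the
qualitative orderings, not any real population's headline percentages: real
uniqueness levels depend on real attribute distributions, which are private.

## Stratified analysis

`pad_risk_table()` computes, per PAD, the population and 1-distinct
percentage under a policy, sorted by ascending population with PAD code as
the tie-break (deterministic exports). Binning is **within-PAD**. Because
every PAD's surrogate ZIPs are prefix-disjoint from every other PAD's, a key
collision across PADs is impossible whenever the policy keeps at least two
ZIP digits — so within-PAD and nationwide-then-restricted binning coincide
for both named policies; that equality is itself a unit test, and the
within-PAD choice stays meaningful for prefix lengths 0 and 1.

`trend_statistic()` is Spearman's rank correlation between PAD population
and unique percentage (computed by `stats::cor`; an independent
rank-then-Pearson route cross-checks it in the tests). Bigger samples give
every tuple more chances to recur, so on homogeneous synthetic populations
the correlation is negative. Fewer than three PADs, constant populations or
constant percentages are reported as undefined (`NA` with a warning) rather
than silently coerced to a number.

## Numerical choices and degenerate inputs

* Fractions are ratios of exact integer counts; formatting is a reporting
  concern (percentages conventionally printed to two decimals).
* `risk_curve()` materializes every `g` up to the maximum class size;
  `write_risk_curve(log_thin = TRUE)` exports a log-spaced subset (always
  keeping `g = 1` and the endpoint) because strongly generalized views can
  have class sizes in the thousands.
* Empty inputs: filtering and binning accept them (zero counts, empty
  histogram); `risk_curve()` and `unique_fraction()` refuse an empty
  population with a pointer to upstream filters, since a fraction of zero
  patients is meaningless.
* `g_for_fraction(curve, 1)` returns the maximum class size exactly — the
  terminal fraction is computed as `N/N` and is exactly 1 in floating point.
* A record failing both filter rules is attributed to the missing-address
  rule (first match wins), so report counts always reconcile.

## Problem sizes used by the checks

The shipped tests run the oracle-equivalence suite on 200 seeded key sets of
up to 500 keys against a naive O(n²) pairwise implementation; coarsening
monotonicity, the policy gap and the within-PAD equality on one `paper_like`
run; and the population trend on ten `paper_like` seeds. These sizes keep
the full suite under a couple of minutes on a single core while leaving the
statistic's asymptotics visible; `stress` exists for larger ad-hoc runs.

## A worked example

```{r example}
bundle <- generate_population(scenario_presets()$tiny)
res <- run_risk_analysis(bundle$records, bundle$gazetteer)
res

# threshold query: what g covers 95% of the population under safe harbor?
g_for_fraction(res$policies$safe_harbor$curve, 0.95)
```

At a thousand records nearly everyone is unique under the limited view —
full DOB plus a district-level code is close to a personal identifier — while
the safe-harbor view already merges a visible share of patients. The gap
widens rapidly with scale, which is exactly the point of running the
analysis before sharing any dataset.

## Limitations

* Exact-match geocoding presumes a curated gazetteer; real address data
  need upstream standardization this package deliberately does not attempt.
* Synthetic calibrations are stylized (see above); use them to test
  machinery and orderings, not to forecast a real table's risk.
* The package scores *distinctness* only. It does not construct
  k-anonymous releases, nor compute l-diversity, t-closeness or
  differential-privacy guarantees.
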