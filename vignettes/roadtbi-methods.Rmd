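---
title: "Methods: linking collision dynamics to traumatic brain injury risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking collision dynamics to traumatic brain injury risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadtbi)
```

## The problem

Road traffic collisions are a leading cause of traumatic brain injury (TBI),
yet the relationship between what happens to a vehicle or a struck person
during an impact and the specific brain pathology they sustain is poorly
quantified. In-depth collision databases combine crash reconstruction
(vehicle crush profiles, trajectories, impact speeds) with clinical records,
which makes that relationship analysable — but those databases are
access-restricted, oversample serious collisions, and record injury detail
only as free text scattered through ambulance notes, radiology reports and
post-mortem summaries.

`roadtbi` implements the full analysis chain such a study needs:

1. **Free-text TBI extraction** — a lexicon-driven search with negation
   filtering, followed by Mayo severity classification.
2. **Collision dynamics** — total delta-V from lateral/longitudinal
   components, delta-V for vulnerable road users (VRUs), dominant-component
   flags, and eligibility rules.
3. **Cohort statistics** — prevalence tables, relative risk with log-scale
   intervals, and the chi-square / Fisher / Mann–Whitney / Kruskal–Wallis /
   Shapiro–Wilk tests the analyses rely on.
4. **National scaling** — post-stratification weights mapping the biased
   in-depth sample onto national casualty data.
5. **Risk curves** — bootstrapped cumulative delta-V distributions and
   repeated, stratified cross-validated logistic injury-risk curves with ROC
   AUC.
6. **A synthetic cohort generator** with known ground truth, because the
   real databases cannot be redistributed; every stage is validated by
   parameter recovery against that truth.

## Free-text extraction and Mayo classification

Clinical narratives are scanned for lexicon terms (case-insensitive,
word-bounded regular expressions). The lexicon (`read_lexicon()`) is a JSON
config, not code: each entry carries a canonical term, category (pathology,
symptom, treatment, indicator), a pathology code (SDH, SAH, EDH, focal, DAI,
skull fracture), synonyms, acronyms and a *fixed misspelling-variant table*.
Misspellings are enumerated rather than modelled as random edits so that
extraction of generated text is decidable — a misspelled mention is either
in the table (and found) or it is not a supported variant.

Sentence segmentation is deliberately simple: periods, semicolons and
newlines end sentences; colons do not, so list-style shorthand ("CT: SDH and
SAH") stays in one sentence. This matches the regex-level character of the
algorithm and avoids any NLP dependency.

**Negation.** A hit is discarded as a false positive when a negation cue
("no", "not", "denies", ...) occurs in the same sentence, *before* the
match, within a window of three tokens, with no intervening comma or colon.
The window size is a design choice — published descriptions of this style of
algorithm rarely specify one — and the clause-punctuation rule is what makes
"Not obviously related: subarachnoid haemorrhage present" keep its hit while
"no skull fracture" loses it. Discarded hits are retained in the audit log
with a `negated` flag rather than silently dropped.

**Mayo classification.** Severity is the maximum over a subject's evidence:

* *moderate–severe*: death due to TBI, loss of consciousness ≥ 30 min,
  post-traumatic amnesia ≥ 24 h, worst GCS < 13, or any intracranial
  pathology (SDH, SAH, EDH, focal injury, DAI);
* *mild (probable)*: briefer LOC or amnesia, or a skull fracture;
* *symptomatic (possible)*: at least one symptom (headache, confusion,
  dizziness, nausea, blurred vision, dazed, focal neurological signs);
* otherwise *none*.

The thresholds live in a rule table (`mayo_rules()`) so they are auditable
and overridable. Two decisions are worth flagging: missing clinical fields
never satisfy a criterion (classification is conservative under incomplete
records), and DAI counts as intracranial pathology, i.e. DAI alone is
moderate–severe — defensible on clinical grounds, though source datasets
differ in their coding. A skull fracture without intracranial pathology is
mild-level evidence.

## Collision dynamics

Total delta-V combines the lateral and longitudinal components by the
Euclidean norm. Reconstruction tools report components and totals without
always stating the composition rule; the norm is the standard vector
interpretation and gives testable invariants (symmetry, positive
homogeneity, total ≥ each component).

For struck VRUs the working assumption is that the person is accelerated to
the speed of the impacting vehicle: pedestrian delta-V is the vehicle impact
speed, and cyclist delta-V adds the component of cyclist velocity parallel
to the vehicle's travel. The sign convention is that a positive
`vru_parallel_fraction` opposes the vehicle (head-on adds speed) and
negative is same-direction travel; the result is floored at zero. Whether
same-direction travel should subtract is genuinely open — the additive
head-on form is the documented one — so the signed fraction makes the
convention explicit and controllable.

Eligibility excludes run-over VRUs (the acceleration assumption fails),
multi-impact collisions without a clearly injury-causing phase, and records
missing the dynamics their road-user type requires. Car occupants with
exactly equal components are labelled `tie` and excluded from
dominance analyses, which need a strict direction.

Units are km/h throughout; every threshold in the package (8, 19, 20,
28 km/h) is on that scale.

## Cohort statistics

Relative risk uses the standard epidemiological formulas: `RR =
(a/A)/(b/B)`, `SE(ln RR) = sqrt(1/a + 1/b − 1/A − 1/B)`, and the asymmetric
interval `exp(ln RR ± 1.96·SE)`. When a zero cell makes the interval
undefined it is flagged as such, with no silent continuity correction — no
corrections are applied anywhere by default, and none are exposed as
defaults. Display rounding is one decimal for percentages and two for risk
ratios; computations keep full precision.

The Mann–Whitney U test is hand-built because the contract requires midrank
tie handling *and* exact enumeration for small samples, a combination base
`wilcox.test` does not provide (its exact mode refuses ties). For pooled
sizes up to 20 the p-value enumerates all assignments of the pooled ranks to
the groups — the randomisation p-value, observed arrangement included, so a
1-vs-1 comparison gives p = 1, not 0.5 — and larger samples use the
tie-corrected normal approximation without continuity correction.
`wilcox.test` serves as an independent cross-check in the test suite, as do
brute-force enumeration oracles for Fisher's exact test, the rank-formula
Kruskal–Wallis H, and pairwise-concordance AUC.

## National scaling

The in-depth sample is deliberately biased towards serious collisions, so
raw in-depth rates overestimate national prevalence. The correction is
post-stratification: cluster both tables by one or two shared categorical
fields, and weight each in-depth cluster by `p_national / p_indepth`.

*Field selection* replaces a recursive-partitioning fit with an exhaustive
search over all single fields and unordered pairs, scoring each clustering
by the cross-validated misclassification rate of a
majority-class-per-cluster predictor of overall severity. With seven
candidates the space is 7 + 21 candidates — small enough that the exhaustive
search is fully deterministic and auditable, with ties broken towards fewer
fields then lexicographic order. In the pipeline, weights are additionally
computed within overall-severity strata whenever severity is not itself
selected, since severity is the axis the in-depth sampling distorts.

*Sparse clusters.* Clusters with fewer than five in-depth members are merged
into the largest neighbouring cluster differing in exactly one field level
before weighting, so sampling noise cannot produce unbounded weights; the
floor and the merge rule are deterministic. A cluster with national mass but
no in-depth members even after merging gets an undefined weight and is
excluded from estimates; if such exclusions cover more than 5% of records
the estimate is refused as a coverage failure rather than quietly
renormalised further.

The scaled count for an outcome is `national_total × Σ_c p_national(c) ×
rate_c`, annualised by the observation period. The quoted standard error
treats cluster rates as independent binomials — adequate for the recovery
properties tested here; no further uncertainty propagation is attempted.

## Cumulative distributions and risk curves

Empirical cumulative delta-V distributions carry pointwise percentile bands
from 10 000 bootstrap resamples by default. Resampling is implemented as
multinomial draws over the distinct observed values (distributionally
identical to resampling raw values) which keeps the computation vectorised;
bands are seeded and reproducible, and are clipped to contain the point
estimate.

Injury-risk curves come from unpenalized maximum-likelihood logistic
regression (gradient tolerance 1e-8, iteration cap 500). Complete separation
is reported via `converged = FALSE` — detected when every fitted probability
collapses to the 0/1 boundary — instead of returning divergent coefficients.
Validation uses outcome-stratified k-fold cross-validation, k = 5, repeated
200 times: each repeat shuffles with a prespecified seed (`base_seed + r`,
logged), fits one model per training split, and evaluates predicted risk on
a 0–100 km/h grid (1 km/h steps, covering the 20–70 km/h range where risks
are usually reported). The 1000 fold-curves are summarised pointwise by
their median and 2.5th/97.5th percentiles; ROC AUC is computed on each
held-out fold — held-out-only, not pooled, the stricter of the two readings
— and summarised the same way. Folds stratify on the outcome only, the
minimal reading of "account for unbalanced groups". A repeat whose folds
lack an outcome class is reshuffled with the next seed and counted in the
result. The `N = 10k/p` sample-size guideline is checked up front and
violations warn.

## The synthetic generator and what it does (not) show

`generate_cohort()` draws a national table carrying only the broad shared
fields (road user, age band, lighting, speed limit, road class, vehicle age,
overall severity) and an independently drawn in-depth population thinned by
acceptance sampling with per-severity-stratum odds (defaults 30 : 10 : 2 : 1
for fatal : serious : slight : uninjured), reproducing the "generally more
severely injured" character of in-depth databases with one parameter per
stratum. Key calibration defaults, chosen once from published quantities and
not revisited:

* delta-V per road user is gamma-distributed (non-negative, right-skewed
  like crash severity data): shape 2, scale 15/14/14/10/10/8 km/h for
  pedestrians/cyclists/motorcyclists/car/van/HGV occupants;
* moderate–severe TBI follows a logistic in total delta-V with intercept
  −2.244 and slope 0.0374 per km/h for VRUs — passing through 26% risk at
  32 km/h and 39% at 48 km/h — and a VRU-vs-car log-odds gap of ln 6.84;
  dominant-lateral impacts add ln 2.19 to the log-odds;
* key pathologies occur only above road-user-specific delta-V thresholds
  (19 km/h for car occupants and 8 km/h for VRUs; focal injury higher at 28
  and 16 km/h), with conditional probabilities given moderate–severe TBI
  read off published group counts;
* overall severity comes from a proportional-odds link on delta-V (slope
  0.05 per km/h; cutpoints 0.5/3.2/6.0), floored so that a moderate–severe
  TBI is at least a serious casualty and any TBI at least slight — this is
  what gives the scaling stage's field selection real signal;
* helmeted cyclists get a 0.2 multiplier on skull-fracture and SDH
  probabilities, mirroring the protective effect seen in cyclist cohorts;
* narratives are rendered from the truth flags through the same lexicon the
  extractor uses, with acronym substitution (rate 0.3), table-driven
  misspellings (0.1) and negated mentions of absent pathologies (0.25);
  a named fracture subtype is always written out in full so the subtype
  survives extraction.

The seven shared fields are drawn independently given severity; their joint
distribution in real data is unknown to us, so no claim of realism is made
there — the scaling recovery results exercise the estimator, not the realism
of the covariate structure. More generally, passing round-trip and recovery
tests on this generator shows the *pipeline* is correct under its stated
assumptions; it does not show that real clinical text is as regular as the
generated notes (real narratives contain negation forms, abbreviations and
misspellings outside any fixed table), nor that real TBI risk is exactly
logistic in delta-V. The published validation figure of ≥ 99.4% extraction
agreement on real records is not reproducible without the restricted data;
the analogue here is exact recovery at zero narrative noise and ≥ 99%
at default noise.

## Numerical choices and degenerate inputs

* Ties in dominance are excluded downstream; ties in ranks use midranks.
* Fisher's two-sided p sums tables no more probable than observed (the R
  and scipy convention). On the published cyclist helmet counts this gives
  0.0075 for skull fracture — printed as 0.008 in the study report, an
  artefact of rounding 0.0075 — and 0.006 for SDH exactly.
* Empty groups report missing percentages, not zero; single-class outcomes,
  empty samples, constant samples and zero marginals raise errors rather
  than returning placeholders.
* All randomness (generator, bootstrap, cross-validation shuffles, fold
  assignment) flows from named integer seeds; identical seeds give
  byte-identical outputs after serialisation.

## Problem sizes used in validation

The packaged validation runs use: 1000 synthetic subjects for classifier
round-trips; 100 seeded replicates of a 50 000-subject national table with a
5000-subject in-depth sample for scaling recovery (weighted estimates cover
the realised national truth in ≥ 90% of replicates while unweighted rates
overestimate in ≥ 95%); 5000 subjects for risk-curve recovery (the
cross-validated median curve stays within ±0.05 of the generative logistic
on a 0–70 km/h grid); and 50 seeded replicates of 20 000 subjects for
recovery of the VRU-vs-car odds ratio within three standard errors. These
sizes were chosen so each property is tested well inside its sampling noise
while the whole suite stays quick to run.

## Known limitations

* The lexicon ships with a compact default vocabulary; production use on
  real clinical text would extend it (and its misspelling table) per corpus.
* Negation handling is window-based, not syntactic; hedged or distant
  negations ("no evidence, on today's imaging, of ...") are out of scope.
* Vehicle delta-V reconstruction itself (crush-profile / trajectory
  analysis) is out of scope: the pipeline consumes delta-V components as
  inputs.
* Scaled national estimates carry binomial-cluster standard errors only.
* The logistic risk model inherits the non-zero-risk-at-zero-delta-V
  artefact that arises when uninjured exposure is underrepresented; no
  parametric alternative (e.g. Weibull) is provided.
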