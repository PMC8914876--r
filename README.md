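# roadtbi

Traumatic brain injury (TBI) risk from road traffic collision dynamics.

`roadtbi` is an R implementation of the analysis chain used to relate what
happens to a vehicle or a struck person during a collision — the change in
velocity during the impact phase, *delta-V* (km/h), decomposed into lateral
and longitudinal components — to the brain injuries people sustain. It is
aimed at injury epidemiologists and vehicle-safety researchers working with
in-depth collision databases, which combine crash reconstruction with
clinical free text, are biased towards serious collisions, and cannot be
redistributed.

The package covers, end to end:

* **Free-text TBI extraction** — lexicon-driven term search over clinical
  narratives (synonyms, acronyms, a fixed misspelling table), sentence-level
  context, negation filtering ("no subdural haematoma" is a false positive),
  and Mayo severity classification. Mayo assigns *moderate–severe* on death
  due to TBI, loss of consciousness ≥ 30 min, post-traumatic amnesia ≥ 24 h,
  GCS < 13 or intracranial pathology (SDH/SAH/EDH/focal/DAI);
  *mild (probable)* on briefer LOC/PTA or skull fracture; *symptomatic
  (possible)* on symptoms alone.
* **Collision dynamics** — total delta-V as the Euclidean norm of the
  components; VRU (pedestrian/cyclist) delta-V from the vehicle impact speed
  plus the parallel component of the rider's velocity; dominant-component
  flags; eligibility rules (run-overs and unclear multi-impact cases
  excluded).
* **Cohort statistics** — prevalence tables; relative risk
  `RR = (a/A)/(b/B)` with `SE(ln RR) = sqrt(1/a + 1/b − 1/A − 1/B)` and the
  asymmetric interval `exp(ln RR ± 1.96·SE)`; chi-square, Fisher exact,
  one-sided Mann–Whitney U (exact enumeration for small samples, midrank
  ties), Kruskal–Wallis and Shapiro–Wilk tests.
* **National scaling** — post-stratification weights
  `w(c) = p_national(c) / p_indepth(c)` over clusters of one or two shared
  fields (selected by exhaustive search for the best severity predictor),
  with sparse-cluster merging and annualised national estimates.
* **Risk curves** — empirical cumulative delta-V distributions with
  10 000-resample bootstrap percentile bands, and injury-risk curves from
  unpenalized logistic regression under outcome-stratified 5-fold
  cross-validation repeated 200 times (1000 fold-models; pointwise median
  and 2.5/97.5 percentile bands; held-out ROC AUC).
* **A synthetic cohort generator** with known logistic ground truth,
  road-user-specific delta-V thresholds below which key pathologies do not
  occur, severity-biased in-depth subsampling, and noisy clinical
  narratives — so the whole pipeline is testable without restricted data.

## Worked example

```r
library(roadtbi)

cfg <- pipeline_config(
  generator = generator_config(n_national = 20000, n_indepth = 2000, seed = 7),
  risk = list(repeats = 50, n_boot = 2000, grid = 0:70, seed = 7))
bundle <- run_pipeline(cfg)

bundle$prevalence$modsev_by_road_user
#>          group n_group n_outcome proportion percent
#> 1 car_occupant    1025       160  0.1560976    15.6
#> 2      cyclist     216       111  0.5138889    51.4
#> 3 hgv_occupant      77        10  0.1298701    13.0
#> 4 motorcyclist     231       119  0.5151515    51.5
#> 5   pedestrian     331       179  0.5407855    54.1
#> 6 van_occupant     120        18  0.1500000    15.0

bundle$relative_risk
#> RR = 3.42 (95% CI 2.95-3.96)  [409/778 vs 188/1222]

bundle$national_estimates
#>   outcome indepth_rate weighted_rate scaled_count annual_count        se
#> 1     tbi       0.4415     0.2522467     5044.934     5044.934 189.17350
#> 2  modsev       0.2985     0.1050440     2100.881     2100.881  62.27385
```

Reading the output: in the severity-biased in-depth sample, vulnerable road
users (pedestrians, cyclists, motorcyclists) sustain moderate–severe TBI at
51–54% against 13–16% for vehicle occupants, a relative risk of 3.42
(classified from the generated clinical narratives, not from the hidden
truth labels). The raw in-depth TBI rate (44.2%) overstates the national
rate because serious collisions are oversampled; after post-stratification
the weighted national estimate is 25.2% — against a ground-truth national
rate of 25.1% in this simulation — i.e. ~5045 of the 20 000 national
casualties. The fitted car-occupant risk curve puts moderate–severe TBI risk
at 45 km/h total delta-V at 0.202 (0.190–0.216 across fold-models).

The printed-count reproduction table recomputes the published summary
percentages from raw counts:

```r
head(reproduce_paper_tables(), 4)
#>                   claim computed printed match
#> 1    tbi_prevalence_pct     20.2    20.2  TRUE
#> 2      modsev_share_pct     52.9    52.9  TRUE
#> 3        mild_share_pct     22.4    22.4  TRUE
#> 4 symptomatic_share_pct     24.4    24.4  TRUE
```

A thin command-line wrapper with `generate` / `all` / `reproduce`
subcommands is installed at `inst/scripts/roadtbi-pipeline.R`.

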