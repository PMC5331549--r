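# recall24

A headless, scriptable engine for **self-administered online 24-hour
dietary recalls** using the multiple-pass interview method, for nutrition
and epidemiology researchers who need recall machinery that is fully
testable without a web front end.

A multiple-pass recall walks a respondent through the previous day three
times: free listing of all foods and drinks by meal, a detail pass
(database matching, portion-size estimation, targeted probes), and a
final review before submission. The probes are where interviewers earn
their keep — associated foods (butter on bread, ketchup with chips, sugar
in tea), drink-free meals, long gaps between meals, and implausibly low
energy days (strictly below 500 kcal). `recall24` implements the whole
interview as a deterministic prompt-queue state machine, plus:

* a food database layer (JSON foods + CSV per-100 g composition table)
  with validation, search with synonym expansion, and four portion-size
  estimation models (as-served photo ladders of at most 7 images, guide
  photos, drink sliding scales, standard units);
* sandwich and salad **wizards** that decompose composite items into
  component foods so the bread can never be forgotten;
* nutrient computation (`weight/100 ×` per-100 g composition) with exact
  additivity from entries to meals to the day;
* the evaluation statistics of dietary method-comparison studies:
  per-respondent test/reference **agreement ratios** (1 = perfect
  agreement, < 1 under-estimation) with arithmetic and geometric
  summaries, **System Usability Scale** scoring (0–100), and
  **Kruskal–Wallis** tests across testing rounds;
* researcher-facing CSV export, activity reports and survey lifecycle
  management;
* a synthetic food database and a simulated-respondent model (omission
  by item class, respondent-level multiplicative portion error, prompt
  recovery) for end-to-end testing with no external data.

## Worked example

Simulate 20 respondents with a 20% (log-scale) portion-reporting error,
replay their answer scripts through the engine, and summarise agreement
against the reference recall:

```r
library(recall24)
db <- generateFoodDb()
model <- respondentModel(portion_sdlog = 0.2)
study <- simulateStudy(db, model, n = 20, seed = 7)
study$summary[study$summary$nutrient %in%
                c("energy_kJ", "protein_g", "vitamin_C_mg"), ]
#>       nutrient  n   mean     sd geo_mean geo_sd        direction
#> 3    energy_kJ 20 0.9095 0.1751   0.8922  1.229 under-estimation
#> 5    protein_g 20 0.9025 0.1931   0.8789  1.284 under-estimation
#> 7 vitamin_C_mg 20 0.9633 0.1870   0.9468  1.208 under-estimation
```

Respondents omit some items (condiments most often, 30% by default);
prompts recover part of that, portions carry the injected multiplicative
error, so mean ratios sit a little below 1 (net under-estimation) and the
geometric SD reflects the portion-error spread (`exp(0.2) ≈ 1.22`).

Search intercepts composite foods and routes them to the wizard:

```r
head(lookupFood(db, "tuna butty"), 3)
#>            target score               matched_text
#> 1 SANDWICH_WIZARD   Inf          Build my sandwich
#> 2            MTF1   100      Tuna, canned in brine
#> 3    MISSING_FOOD     0 My food is not in the list
```

Usability scoring:

```r
susScore(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # maximal favourable: 100
susScore(rep(3, 10))                        # all-neutral: 50
```

A thin command-line front end over the same functions ships in
`inst/cli/recall24.R` (subcommands `validate-db`, `lookup`, `run`,
`simulate`, `sus`, `evaluate`); an example database lives in
`inst/extdata/` (`foods.json`, `composition.csv`).

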