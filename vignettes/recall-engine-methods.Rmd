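---
title: "A scriptable multiple-pass 24-hour dietary recall engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A scriptable multiple-pass 24-hour dietary recall engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recall24)
```

## The problem

Self-administered online 24-hour dietary recalls aim to reproduce what a
trained interviewer achieves in a multiple-pass interview: the respondent
first lists everything eaten and drunk from waking to sleeping, is then
probed for detail and quantities, and finally reviews the whole day before
submitting. The interviewer's real value lies in the probes — "did you have
butter on that bread?", "nothing at all between lunch and dinner?" — which
recover the items people most often forget: condiments, drinks, and the
structural parts of composite foods (the bread of a "tuna sandwich").

`recall24` implements this interview as a headless state machine. There is
no user interface; the engine exposes a single uniform prompt loop
(`nextPrompt()` / `answerPrompt()`), so an interactive front end and a
scripted batch replay drive exactly the same code. That design makes the
whole interview testable: a JSON *answer script* replays a respondent's
session deterministically, and a simulation module generates such scripts
from a behavioural model of misreporting.

## The interview model

A session holds a meal list (each meal a name and clock time) and, per
meal, an ordered list of food entries. Entries carry their provenance:
`USER_ENTERED` (typed in the first pass), `WIZARD_ADDED` (emitted by the
sandwich/salad wizards) or `PROMPT_ADDED` (accepted from a targeted
prompt). The prompt loop serves, in a fixed priority order:

1. **Matching** — each free-text entry is matched to a database food (or
   flagged through the missing-food fallback).
2. **Portion estimation** — each matched entry receives a portion answer.
3. **Associated foods** — foods carry links to commonly co-consumed items
   (butter on bread, ketchup with chips, sugar in tea); each link asks
   once.
4. **Missing drinks** — any meal with no drink entry asks once.
5. **Meal gaps** — consecutive meals further apart than
   `gap_threshold_minutes` (default 180) ask once per pair. The default
   makes the canonical five-hour lunch-to-dinner gap fire.
6. **Low-energy day** — once all portions are resolved, a day total
   strictly below `energy_deficit_threshold_kcal` (default 500 kcal) asks
   once. The inequality is strict: a day of exactly 500 kcal does not
   fire.
7. **Custom end-of-recall questions** from the survey configuration.

Every (rule, target) pair fires at most once per session, whatever the
respondent answers — declining is final. Matching and portion steps are
modelled as prompt rules too (`MATCH_FOOD`, `PORTION`) so that one queue
with one priority order describes the entire interview; this is the main
place where the interview order was genuinely open, and the chosen order
(resolve entries fully before targeted rules, energy check only after all
portions are known) is the one an interviewer would follow. Declined gap
prompts do not re-fire after later meal edits.

Submission (`reviewAndSubmit()`) requires the queue exhausted and every
entry resolved; it produces an immutable record with per-entry, per-meal
and per-day nutrient totals and the completion time. Session clocks are
injected (`now =` arguments) so completion times are deterministic under
test.

## Portion estimation

Four methods map answers to grams:

| method | answer | weight |
|---|---|---|
| as-served ladder | image index | ladder weight at that index |
| guide photo | object index, count | object weight × count |
| drink scale | fill fraction ∈ (0,1] | volume × fill × density |
| standard units | unit index, amount | unit weight × amount |

As-served ladders hold at most seven strictly increasing weights and are
constructed (by `asServedLadder()`) as evenly spaced quantiles between the
5th and 95th centile of a lognormal serve-weight distribution — the
convention for photographic portion ladders. Selection is
nearest-image only; no between-image interpolation is attempted, because
respondents choose among depicted portions. Drink density defaults to
1 g/ml. Whether drink scales should also capture leftover amounts was an
open modelling point; fill level only is captured.

## Nutrient computation

Composition is per 100 g, keyed by databank code; an entry's nutrient
vector is `weight / 100 ×` the composition record, with the weight itself
carried as a component so food weight aggregates like any nutrient. Energy
is tracked in both kJ and kcal (factor 4.184; a composition table
supplying only one column has the other derived, and tables inconsistent
beyond 1% fail validation). Aggregation is plain componentwise addition,
so day totals equal meal sums equal entry sums to floating-point
tolerance; the seven mandatory quantities are food weight, energy (kJ and
kcal), carbohydrate, protein, fat, vitamin C and iron.

## Search and the wizards

Lookup normalises queries (lowercase, punctuation stripped, digits kept so
"50/50" stays findable), expands synonyms from data shipped with the
database, and ranks foods by a single scoring function: exact description
match ≫ all-tokens-matched ≫ token prefix ≫ edit-distance-1 fuzzy match,
ties broken alphabetically then by food code. Ranking was unspecified by
the interview design and is deliberately isolated in one function. A query
containing a sandwich trigger term (sandwich, roll, butty, wrap — shipped
as configuration, not code) surfaces the sandwich wizard at rank 1;
likewise "salad". A missing-food fallback entry is always appended last.

The wizards decompose composite items into components so nutrient totals
are component sums — enumerating every sandwich variant in a database is
infeasible, and entering composites as single foods historically lost the
bread. Sandwich stages run bread → spread → meat/fish → cheese/dairy →
extra fillings (repeating until "no more") → sauce/dressing; every stage
except bread accepts "I didn't have any". Bread is mandatory by design:
the wizard exists because omitted bread was the motivating error, so a
breadless sandwich is unrepresentable. The spread stage takes a single
selection (the question is singular; further items belong in extra
fillings). Salads run a repeating items stage then a sauces stage, and
each component receives its own portion prompt.

## Evaluation statistics

For method comparison, each respondent's **agreement ratio** is the
test-method intake divided by the reference-method intake, per nutrient;
1 is perfect agreement, below 1 under-estimation. Components with zero
reference intake are undefined and excluded pairwise (a day can genuinely
contain no vitamin C), with per-nutrient n reported. Summaries report
*both* the arithmetic mean/SD and the geometric mean/SD: published
agreement tables often leave the family unstated, and SDs larger than the
mean around ratios near 1 are the signature of multiplicative spread, so
both are computed and labelled explicitly rather than guessing.

The **System Usability Scale** score follows the standard formula: ten
Likert items in 1–5, odd (positively-worded) items contribute
`score − 1`, even (negatively-worded) items `5 − score`, scaled by 2.5
onto 0–100. **Kruskal–Wallis** comparisons across testing rounds use the
tie-corrected rank statistic with the chi-square approximation; the
computation is delegated to `stats::kruskal.test` (the suite checks it
against an independently coded textbook rank-sum formula), with the
all-values-identical degenerate case defined as H = 0.

## The synthetic database and respondent model

`generateFoodDb()` builds a small validated database with the structural
features the engine needs exercised: a four-size apple guide and a
23-item sweets guide; as-served ladders of at most seven images from
stated lognormal serve distributions; sandwich component categories
including brand-named breads ("Hovis 50/50", "Warburtons seeded batch");
salad items; associated links butter↔bread, ketchup↔chips, sugar↔tea and
coffee; drinks on sliding scales; a composite dish assigned to two food
groups with explicit fractions. Composition values are plausible per-100 g
figures for each food; the database is deliberately tiny (31 foods) and
deterministic.

`simulateRespondent()` draws a true day from meal templates (a typical
three-meal day: cereal, milk, tea with sugar and buttered toast; a tuna
sandwich with cola; chips, chicken, ketchup and juice — roughly
1500–2500 kcal depending on draws), then degrades it into an answer
script:

* each item is omitted with a class-specific probability (mains, drinks,
  condiments — condiments are the most forgotten class, which is why the
  defaults are 0.05/0.15/0.30);
* all reported portions are scaled by **one respondent-level**
  multiplicative lognormal factor (parameters `portion_bias`,
  `portion_sdlog`) and snapped to the nearest representable portion
  answer. The error is respondent-level, not per-item, by design:
  systematic individual portion-estimation bias is the dominant error
  mode, and it makes day-level intake ratios inherit the stated spread
  directly (independent per-item errors would average out across a day,
  shrinking the day-level geometric SD below `exp(portion_sdlog)`);
* an omitted condiment whose trigger food was reported gains an accepting
  associated-food prompt response with probability `prompt_recovery`;
  an omitted drink that leaves its meal drink-free likewise gains an
  accepting missing-drink response.

The reference recall equals the truth: the interviewer-led comparison arm
is modelled as able to elicit everything, and interviewer error is out of
scope. True portions are drawn from each method's representable answer
set, so in the no-error limit the scripted replay reproduces the
reference exactly and all agreement ratios are identically 1 — the
end-to-end identity the test suite asserts through the full
engine-to-evaluation path.

Random streams are arranged so that paired runs differing only in
`prompt_recovery` share identical truths and omission patterns
(recovery draws are consumed unconditionally), making prompt-efficacy
comparisons properly paired.

## Numerical choices and problem sizes

Additivity assertions use a relative tolerance of 1e-9; the no-error
identity uses 1e-12. Test simulations use 15–100 respondents (the
parameter-recovery check uses n = 100 at `portion_sdlog` 0.2, the
prompt-efficacy pairing n = 50 per arm), sizes at which the full suite
runs in well under a minute while the stochastic assertions sit far from
their tolerance boundaries. Guide-answer snapping searches object counts
1–10; drink fills are clamped to [0.01, 1].

## What passing tests do and do not show

The simulator emulates omission, systematic portion error and prompt
recovery on a small fixed food set. It does not emulate: foods missing
from the database (every simulated item is matchable), free-text spelling
noise, interviewer error in the reference arm, within-day correlation of
omissions, per-item portion noise, or real composition data. Results on
synthetic respondents therefore validate the machinery — prompt
scheduling, portion arithmetic, nutrient conservation, statistic
computation — not the field accuracy of any particular database or
population.

## Session example

```{r example}
db <- generateFoodDb()
model <- respondentModel(portion_sdlog = 0.2)
study <- simulateStudy(db, model, n = 20, seed = 7)
study$summary[study$summary$nutrient %in%
                c("energy_kJ", "protein_g", "vitamin_C_mg"), ]
```
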