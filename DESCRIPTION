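Package: recall24
Title: Scriptable Multiple-Pass 24-Hour Dietary Recall Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless engine for automated self-administered 24-hour
    dietary recalls using the multiple-pass interview method: meal-list
    management, free-text food lookup with synonym expansion, guided
    sandwich and salad entry wizards, photographic and standard-unit
    portion-size estimation models, targeted prompts (associated foods,
    missing drinks, meal-time gaps, low-energy days), and per-food,
    per-meal and per-day nutrient computation against a per-100 g food
    composition table. Includes the evaluation statistics used in
    dietary-assessment method comparisons (test/reference agreement
    ratios with arithmetic and geometric summaries, System Usability
    Scale scoring, Kruskal-Wallis tests), researcher-facing CSV export
    and activity reporting, and a synthetic food database plus simulated
    respondents with configurable omission and portion-error behaviour
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
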