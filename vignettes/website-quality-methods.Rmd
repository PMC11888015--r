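---
title: "Methods: scoring, adjudication, and ranking of health-website quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, adjudication, and ranking of health-website quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webqual)
```

## What this package models

`webqual` evaluates a corpus of patient-facing health websites on four axes
and combines them into one ranked quality score. The procedure mirrors how
structured website-quality studies are run: two trained raters score each
site on standardized instruments, disagreements are adjudicated, raw page
text is scored for readability, and a weighted composite drives a "best
sites" table plus cohort comparisons. The package takes the *ratings as
inputs* — the human judgment inside each DISCERN or rubric item is out of
scope — and mechanizes everything downstream of them.

## Readability

Three classic formulas are computed from four counts (sentences `S`, words
`W`, syllables `Y`, polysyllables `P`, i.e. words with 3+ syllables):

* Flesch Reading Ease `206.835 − 1.015·W/S − 84.6·Y/W` (higher = easier,
  not clamped to [0, 100]);
* Flesch–Kincaid grade `0.39·W/S + 11.8·Y/W − 15.59`;
* SMOG `1.0430·√(30·P/S) + 3.1291`.

The formulas are exact; all ambiguity lives in tokenization, so the
tokenizer is deliberately simple and fully specified:

* **Sentences** end at `.`, `!`, `?` followed by whitespace and a capital or
  digit. A fixed abbreviation stop-list (Dr., Mr., Mrs., Ms., Prof., St.,
  vs., etc., e.g., i.e., et al., Fig., No.) is protected first. HTML-ish tags
  and URLs are stripped before tokenization because web text is noisy and
  a URL would otherwise be syllabified meaninglessly.
* **Syllables** are dictionary-first: a packaged hand-counted table (common
  English words, domain words such as *delirium* = 4, and every word used by
  the test fixtures and the text generator). Unknown words fall back to
  vowel-group counting with silent-e and `-le`/`-ed` adjustments, floored at
  1. Numerals count as one word and one syllable per digit group; mixed
  tokens add their digit groups to the letter-part count.
* SMOG is calibrated for 30-sentence samples. Shorter texts are scored
  anyway (whole pages have unknown length) and flagged with
  `short_text_warning` rather than refused.

Grade-6 compliance (`meets_grade6`, the AMA/NIH recommendation) is an
inclusive threshold — a grade of exactly 6.0 complies — and defaults to the
Flesch–Kincaid grade because that is the metric reported per site in
top-10-style tables; it can be switched to SMOG. Corpus-level readability
medians published for real cohorts are *not* bit-reproducible by any
reimplementation (the original tokenizer is never specified), so the test
suite treats such values as distributional plausibility checks only and
anchors correctness instead on constructed fixtures whose counts are known
by construction, plus a second, independently written reference tokenizer
that must agree within 0.5 grade.

## Instruments and adjudication

* **DISCERN**: 16 items on 1–5, total 16–80, with bands very poor [16, 27),
  poor [27, 39), fair [39, 51), good [51, 63), excellent [63, 80]. Published
  band tables stop at 75, but instrument usage labels scores up to 80
  "excellent", so the top band is closed at 80. Bands are half-open on the
  real line because rater means produce fractional totals.
* **JAMA benchmark**: 4 booleans, total 0–4.
* **Content rubric**: 6 items in {0, 1, 2} (definition, risk factors,
  outcomes, signs/symptoms, delirium-vs-dementia, prevalence), total 0–12.

Adjudication follows the duplicate-review design. DISCERN totals within 4
points are averaged over the two raters; a gap of **5 or more** requires a
third rating and the final total is the mean of all three. The threshold
applies to totals, not items, because that is how DISCERN scores are
reported. JAMA and content items are adjudicated **per item**: agreement
stands; disagreement is settled by majority with the third rating; when all
three differ (possible only for 0/1/2 items) the third — resolving — rater
decides. "Resolution by discussion" is modeled as the third-rating path:
a discussion outcome enters as a third rating, since only its output is
mechanizable. Consensus, not averaging, is used for item-level instruments;
means are not offered there. A ≥ 5-point gap with no third rating available
is a hard, named error — never silently averaged.

## Composite score and ranking

Each component is min–max normalized: DISCERN, content, and JAMA over their
*possible* ranges ([16, 80], [0, 12], [0, 4]); readability over the range
*observed in the analyzed corpus*, reverse-scaled because lower grades are
better. Default weights are 0.30 readability / 0.30 content / 0.30 DISCERN /
0.10 JAMA; they must be non-negative and sum to 1 (tolerance 1e-12). The
weighted sum is scaled to 0–100.

Consequences worth knowing:

* Scores are **corpus-relative** through the readability normalization:
  adding a new best-readability site rescales everyone's readability
  component. This is tested, not hidden.
* Whether "readability" means FK, SMOG, or FRE in the composite is a
  genuinely open choice; the package defaults to the FK grade (the per-site
  metric in report tables) and exposes `grade_metric = "smog"`/`"fre"`
  (FRE automatically un-reverses since higher FRE is better).
* A degenerate observed range (every site at the same readability) cannot be
  normalized; the readability component is then set to 1.0 for all sites and
  the substitution is logged.
* Ties are broken deterministically: weighted score desc, DISCERN desc,
  content desc, readability asc, then id. Report tables round the weighted
  score to 1 decimal; ranking always uses full precision.

## Cohort statistics

Summaries use type-7 (linear-interpolation) quartiles — the convention of
mainstream statistics packages, stated here so medians/IQRs are reproducible
— and sample SDs (n−1), reported blank for single-site categories. The
Kruskal–Wallis test uses the tie-corrected rank statistic with a chi-square
p on k−1 degrees of freedom; with every observation tied the statistic is
defined as 0 with p = 1. No exact small-sample tables are used: with
category sizes in the 4–21 range the chi-square approximation is standard,
and the test suite pins the implementation against an exhaustive permutation
oracle (all 1680 assignments of a 9-observation, 3-group instance, where the
approximation is known to be rough — the exact p there is ≈ 0.004 vs 0.027
approximate, which is why the suite asserts exact agreement on H, agreement
on the α = .05 decision, and closeness of p only at a moderate sample size),
against `stats::kruskal.test` under heavy ties, and with type-I/power
simulations. No multiple-testing adjustment is applied across the score
comparisons, deliberately matching how such cohort tables are reported.

## The synthetic corpus: what it does and does not establish

`generate_corpus()` produces a full stated world: 106 sites split across the
eight categories at the observed cohort proportions (21/20/19/16/14/6/6/4 of
106); per-category latent DISCERN/JAMA/content means set at the observed
category medians (e.g. DISCERN 37.5 for hospital-affiliated, 52.5 for
academic) with between-site SDs of 8 / 1 / 2; target FK grade N(10, 2.5²)
truncated to [1, 22]; 23% missing update dates; engagement patterns at the
observed proportions (all-three 62/106, inform+activate 22/106, inform-only
17/106, and the 5 unreported sites assigned to inform+collaborate). Values
not reported anywhere (the SDs, the 15% forced-disagreement rate, rater
noise SD 2 on the DISCERN scale) were chosen once as realistic for trained
raters on these instruments and are documented, not tuned.

Mechanics chosen to make contracts testable:

* **Latent-to-item allocation** spreads a total across items by equal base +
  random remainder under per-item caps, so the noiseless case reproduces
  latent totals *exactly* rather than approximately.
* **Disagreement is a coin flip, not an emergent event**: with probability
  `disagreement_rate` the pair is forced to a ≥ 5 gap (and a third rating
  near the latent value is attached); otherwise the gap is clamped to ≤ 4.
  Third-rater traffic is therefore exactly Binomial(n, rate), which the
  acceptance suite checks against exact binomial bounds.
* Rater noise is specified on the DISCERN scale and scaled by range ratio
  (4/64, 12/64) for JAMA/content totals.
* **Text is word salad**: sentences sampled from 1- and 3-syllable
  dictionary word banks, with words/sentence and polysyllable fraction
  solving the FK formula for the target grade (achieved within ±1 at 30+
  sentences). It has correct readability *statistics*, not meaning, layout,
  or the long-tail vocabulary of real pages — so a green readability test
  establishes formula and tokenizer correctness, not robustness to arbitrary
  web prose. Replicate-heavy statistical checks disable text generation
  entirely (`with_text = FALSE`) since text never feeds the rating
  statistics.

Everything is reproducible from the single config seed; identical
config + seed yields byte-identical report files (all report numerics are
written with fixed 4-decimal formatting, 1 decimal for the composite in the
top-N table).

## Degenerate inputs and error policy

Every contract violation raises a classed condition (`wq_validation_error`,
`wq_adjudication_required`, `wq_unresolved_disagreement`,
`wq_degenerate_range`, `wq_undefined_statistic`, ...) naming the offending
website/rater/item or column; nothing is silently coerced or dropped. The
pipeline removes partial output files on error, and every exclusion or
substitution (single-rated sites, short-text SMOG, degenerate readability
range, ignored third ratings) is written to the run log. Year-only dates are
completed to July 1 and flagged; time-since-update is floored whole calendar
years.

## Known limitations

* The packaged syllable dictionary is a curated few-hundred-word table, not
  an exhaustive lexicon; rare words fall to the heuristic, which can be off
  by a syllable (e.g. `-ium` endings outside the dictionary). All generator
  and fixture words come from the dictionary, so this affects only
  user-supplied text at the margins typical of any rule-based counter.
* Chi-square Kruskal–Wallis p-values are approximate for very small groups;
  the smallest default category has 4 sites, which is standard practice but
  still an approximation.
* The composite's meaning depends on the corpus at hand (readability is
  normalized to observed range); scores are comparable within a run, not
  across corpora.
* Inter-rater reliability coefficients (kappa/ICC) are not computed, and no
  post-hoc pairwise category comparisons are offered.
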