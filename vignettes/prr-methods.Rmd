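---
title: "Disproportionality screening with pvprr: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening with pvprr: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvprr)
```

## The problem

Spontaneous reporting systems collect voluntary reports of suspected
adverse drug events (ADEs). Each report names one or more drugs (in messy
verbatim form), one or more reaction terms, an indication, and partial
demographics. There is no denominator: we never observe how many patients
took a drug uneventfully. Screening therefore relies on
*disproportionality*: whether an event makes up a larger share of one
drug's reports than of the other drugs' reports.

`pvprr` implements that screen end to end for a hypertension cohort
treated with ACE inhibitors (ACEIs) and angiotensin II receptor blockers
(ARBs), scored on a fixed list of thirteen pulmonary ADEs
(`pulmonary_events()`), together with a synthetic report generator whose
ground truth makes the screen's operating characteristics measurable.

## The statistic and its two CI variants

Let `r_ij` count distinct (report, drug *j*, event *i*) triples,
`n_j = Σ_i r_ij`, `T_i = Σ_j r_ij`, and `N = Σ_j n_j`, all within the
analysis universe (the 16 study drugs × 13 pulmonary events). Then

$$\mathrm{PRR}_{ij} \;=\;
\frac{r_{ij}/n_j}{\,(T_i - r_{ij})/(N - n_j)\,}.$$

The comparator is deliberately *the other drugs of the analysis universe*,
not the whole database; a configuration option widens the drug universe.
The counting unit is the distinct triple, so a report with one drug and
two listed events contributes one count to each of two cells, and margins
satisfy `n_j = Σ_i r_ij` by construction.

The 95% interval is taken on the log scale,
$\exp(\ln \mathrm{PRR} \pm 1.96\,\mathrm{SD})$, with two SD forms:

* **as_printed** (default):
  $\mathrm{SD} = \sqrt{\frac{n_j - r_{ij}}{n_j r_{ij}} + \frac{N - n_j}{n_j N}}$.
  This is the published formula the package reproduces. Note its second
  term equals $1/n_j - 1/N$.
* **delta_standard**: the textbook delta-method standard error of the log
  PRR on the corresponding 2×2 table,
  $\sqrt{1/r_{ij} - 1/n_j + 1/c - 1/(N-n_j)}$ with $c = T_i - r_{ij}$,
  whose second pair of terms is $1/c - 1/(c+d)$ instead.

The two agree closely when the comparator is large relative to the drug
margin and diverge otherwise. Both are implemented; `as_printed` is the
default for fidelity, `delta_standard` is cross-checked in the tests
against an independently coded oracle. Whether the published form's second
term is a transcription slip of the delta form is not decidable from the
formula alone, so neither variant is silently "corrected".

**Zero and degenerate cells.** `r_ij = 0` gives PRR 0 with an undefined CI
(a value, not an error); an empty drug column or empty comparator gives an
undefined PRR. No continuity correction is applied by default; a Haldane
0.5 add-on is available behind a flag and off because the source analysis
never mentions one.

**Flagging.** A pair is flagged iff all three hold: `r_ij > 3`
(strictly more than 3 occurrences), `PRR > 2`, and lower CI bound `> 1`.
All three inequalities are strict; `criteria_code` counts how many hold.
The third criterion is read as "lower 95% bound above one"; the
accompanying clause "PRR greater than the lower bound" is tautological
under a log-symmetric interval and is not coded as a condition.

## Name normalization

Verbatim drug strings are lowercased; parenthesized content, dosage tokens
(numbers with or without mg/ml/mcg units), and formulation/salt tokens
(tablet, capsule, solution, hcl, hydrochloride, …) are removed; whitespace
is collapsed. Cleaned names are matched exactly against a brand-alias
dictionary, then by nearest Levenshtein distance with threshold
`max_dist = 2`. Two guards keep fuzzy matching honest:

* names of ≤ 4 characters must match exactly (short names collide);
* a name tied between aliases of *different* ingredients is left unmapped
  — the package never guesses.

`max_dist = 2` pairs with the generator's corruption model (at most 2 random
edits) and stays below the smallest cross-ingredient alias distances in the
bundled dictionary. The dictionary (16 ingredients, common brands) is a
bundled CSV and fully user-replaceable. Reaction strings are mapped through
a small preferred-term-like vocabulary (synonyms first, then exact match,
case-insensitive); it is a stand-in vocabulary, not licensed MedDRA, and is
likewise replaceable.

Cohort filtering keeps reports whose free-text indication matches
`hypertension` but not the pulmonary-arterial or intracranial exclusion
patterns. Reports with a missing indication are dropped by default (a
config flag keeps them), a choice made here because the upstream analysis
is silent on the point.

## The covariate robustness check

The unadjusted PRR is trustworthy when
$\Pr(\text{event}\mid\text{drug},\text{age},\text{weight},\text{sex})
\approx \Pr(\text{event}\mid\text{drug})$. The package checks this with
the conventional change-in-estimate rule: fit logistic regressions of
event presence on exposure, crude and adjusted for age group
([0,18), [18,45), [45,65), [65,130]), weight group ([0,60), [60,90),
[90,700] kg) and sex, and declare confounding *negligible* when the
exposure coefficient moves by less than 10% (relative to
`max(|crude|, 0.05)`; the floor guards near-zero crude effects). Bins are
coarse on purpose — they keep every cell populated at simulation scale.
Complete-case analysis applies to this check only; reports with missing
covariates are never dropped from the PRR pipeline. Separation,
non-convergence or an empty arm yields a `non-estimable` record rather
than an error. Under the generator, 50 null runs at n = 5,000 give
"negligible" essentially always, and a generator in which male sex adds
+1 log-odds to both exposure and event rate is caught essentially always
(both measured by `scripts/acceptance.R` and the test suite).

## Friedman comparisons and a structural limitation

Group comparisons (ACEIs-beta = ACEIs minus quinapril and trandolapril;
ARBs; quinapril; trandolapril) are Friedman rank tests: each group is
collapsed to a pseudo-drug (counts summed) and its per-event PRR against
the rest of the universe forms one column; the thirteen events are the
blocks; within-block ranks use average ranks with the standard tie
correction. The chi-square approximation is the default; an exact
permutation p-value enumerates the within-block orderings completely up to
10^6 combinations and samples them beyond that. Undefined pooled PRRs are
imputed as 0 for ranking (with a warning): this preserves complete blocks
without inventing magnitude. Raw p-values are reported, with a Bonferroni
column (times the eight emitted comparisons) alongside.

One structural property deserves emphasis: within a fixed event universe,
each drug's event shares sum to one. A drug over-represented on some
events is therefore *necessarily* under-represented on the rest, so a
blocked rank test comparing whole profiles can never see a uniformly
shifted column. Even a perfectly consistent pattern — the signal drugs
ranked top on their boosted blocks and bottom elsewhere — caps the 4-group
omnibus statistic near Q ≈ 8.6 (p ≈ 0.035), and two-group comparisons
reduce to sign tests needing ≥ 11 of 13 same-direction blocks. The
comparisons are emitted for completeness and their machinery is fully
tested (exactness, tie handling, null uniformity), but at desk scale they
are a weak instrument for share-renormalized signals, and results on real
data inherit the same caveat whenever the margins are restricted to the
whitelisted events.

## PCA of PRR profiles

`pca_prr()` centers the drugs × events PRR matrix (undefined PRRs imputed
as 0 upstream), optionally unit-scales columns (off by default, matching
the centering-only convention of the tooling the analysis describes), and
keeps `min(drugs − 1, events)` components. For reproducibility across
linear-algebra backends each loading vector is oriented so its
largest-magnitude element is positive. Biplot arrows use the
correlation-biplot convention (loadings scaled by component standard
deviations). Zero-variance columns are dropped (with a warning) only when
scaling would divide by zero.

## The synthetic generator

Each report draws: age ~ Normal(60, 15) truncated to [18, 100] years;
weight ~ Normal(80, 18) truncated to [40, 200] kg; sex ~ Bernoulli(0.5);
a quarter label; an indication; one drug from usage weights `w_j`
(optionally tilted by covariate→exposure log-odds); an event count
`m = 1 + Poisson(λ)` truncated at the universe size; and `m` distinct
events with probabilities ∝ `p_i · θ_ij` (optionally tilted by
covariate→event log-odds), where the multiplier θ is 1 except on injected
signal pairs. Drug mentions are rendered verbatim as the canonical name,
a brand alias, or a corrupted string (probabilities 1−ρ, ρ/2, ρ/2);
corrupted strings carry at most `max_edits` random edits, keep ≥ 5 cleaned
characters, and are rejection-sampled so they never land within
`max_edits` of a *different* ingredient's alias — normalization accuracy
therefore has a clean ceiling. One drug per report is the default (a
config switch allows more) because it keeps the PRR ground truth
analytically tractable; the signal module itself handles multi-drug
reports.

The recorded truth `E[r_ij] = n · w_j · E[m] · p_{i|j}` is exact under
exchangeable event weights and first-order otherwise; because events are
sampled *without replacement* within a report, large shares saturate
(inclusion probabilities cannot exceed 1), pulling realized PRRs of
heavily boosted events slightly toward 1. The default
`lambda_events = 0.5` (mean 1.5 events per report — typical of
single-system ADE reports) keeps this saturation mild. The asymptotic PRR
of a boosted pair is `θ_ij / Σ_k p_k θ_kj` (`prr_asymptote()`), verified
to within 10% at n = 100,000 in the tests. Since the Poisson has unbounded
support, the validator rejects configurations whose mean event count
`1 + λ` exceeds the universe size, and sampled counts are truncated at the
universe size.

`acei_arb_config()` bundles the study shape: the 16 drugs with plausible
US usage weights, the 13 pulmonary events with realistic relative
frequencies, ~5,000 reports, 10% alias/corruption rendering, and two
injected signal drugs — quinapril ×5 on pleural effusion, pulmonary edema
and sinusitis; trandolapril ×3 on the disjoint pair dysphonia and
pneumonia aspiration. The boosted subsets deliberately cover a modest
share of baseline event mass (0.14 and 0.06): boosting events that carry
most of the mass renormalizes away (the whole-profile normalizer
approaches θ, so per-event PRRs approach 1), which is the same
share-sum-to-one arithmetic discussed under the Friedman section. With
these subsets the implied asymptotic PRRs are ≈ 3.2 and ≈ 2.7 — far enough
above the PRR > 2 flag threshold that recovery is a property of the
method, not of luck. Disjoint subsets also produce the three separated
drug clusters the PCA checks look for.

What the generator does *not* emulate: reporting-lag dynamics, duplicate
case versions across quarters, stimulated-reporting time trends,
polypharmacy correlations, and indication-driven channeling. Passing tests
on generated data therefore demonstrate the *screen's* correctness and
calibration, not robustness to those real-data artifacts.

## Numerical and engineering choices

* All randomness flows from a single integer seed; the pipeline
  (`run_pipeline()`) is a pure function of (inputs, config, seed), and
  reruns are byte-identical.
* Problem sizes in the test suite and acceptance script: the exhaustive
  PRR oracle grid covers all 2×2 tables with `a ≤ 30` and margins ≤ 50
  (~1.4M tables); null calibration uses 20 seeds × 20,000 reports; signal
  recovery 20 seeds × 5,000; the covariate check 50 runs per scenario at
  n = 5,000; Friedman null uniformity 500 simulations. These sizes give
  stable Monte-Carlo estimates in a few minutes on one core.
* Ages are assumed already in years (legacy decade/month age codes are out
  of scope); sex values outside M/F become U; `$` in free text becomes a
  space on write because the FAERS-style dialect has no quoting.
* Each report_id is treated as unique; versioned deduplication of cases
  across quarters is explicitly out of scope and noted as a gap.

## Known limitations

* The PRR is a screen, not an effect estimate; flags are hypotheses.
* The within-universe comparator makes all shares relative to the 13
  whitelisted events; conclusions about "more pulmonary ADEs overall" are
  outside what this statistic can express, and blocked rank comparisons of
  whole profiles are weak by construction (see above).
* The bundled vocabulary is a stand-in; real MedDRA hierarchies (SOC/HLT
  levels) and combination-product mapping are not implemented; ambiguous
  or combination drug names are deliberately left unmapped.
* The change-in-estimate check conditions on three demographics only;
  unmeasured confounding (comorbidity, disease stage, channeling) is
  untouched.
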