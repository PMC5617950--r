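---
title: "Mining cohort-predictive terms from radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining cohort-predictive terms from radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumour genotype — for instance KRAS mutation status in metastatic
colorectal cancer — changes prognosis and treatment, and it may leave a
linguistic footprint in the free-text radiology reports written about the
patients: a more aggressive radiophenotype tends to be described with
words like "innumerable" or "confluent", a less aggressive one with "few"
or "no discrete ...". `radbayes` quantifies that footprint. Given two
cohorts of labelled reports (`MUTANT` / `WILDTYPE`), it asks, for every
word: *if a report contains this word, what is the probability it belongs
to a mutant-genotype patient?*

The unit of counting is the **report**, and the feature is **presence**:
a term's document frequency `df` in a cohort is the number of that
cohort's reports containing the term at least once. Within-report
multiplicity, tf-idf weighting and per-patient aggregation are
deliberately out of scope — the analysis is a document-frequency
comparison, nothing more.

## The model

For a term \(W\) with document frequencies \(d_m, d_w\) in cohorts of
\(N_m, N_w\) reports, the per-term naive Bayes posterior is

\[
P(M \mid W) \;=\;
\frac{P(W \mid M)\, P(M)}
     {P(W \mid M)\, P(M) + P(W \mid W\!T)\, P(W\!T)},
\]

the classic single-feature spam-filter form with the mutant cohort in the
role of "spam". The likelihoods are smoothed document frequencies

\[
P(W \mid M) = \frac{d_m + \alpha}{N_m + 2\alpha},
\]

with add-\(\alpha\) (Laplace) smoothing, default \(\alpha = 1\): the raw
ratio is undefined when a term is absent from both cohorts' denominators
and degenerate (posterior exactly 0 or 1) when absent from one, so a
pseudo-count is structurally required; it is exposed, defaulted and
echoed in the run summary. The prior \(P(M)\) is empirical by default
(\(N_m / (N_m + N_w)\), appropriate for near-balanced designs) with a
fixed-prior mode (`bayes_config(prior_mode = "fixed")`) reproducing the
spam-filter convention of \(P(M)=0.5\).

The WILDTYPE posterior is the complement, so ranking terms by absolute
posterior difference \(|P(M|W) - P(W\!T|W)| = |2 P(M|W) - 1|\) is ranking
by distance from 0.5. **Predictor sets** are the top-\(k\) such terms with
the own-cohort posterior *strictly* above 0.5 (a term at exactly 0.5
carries no signal and joins neither set); the defaults \(k_{mut} = 6\),
\(k_{wt} = 4\) mirror a six-term mutant / four-term wild-type panel and
are configurable.

For frequency reporting the package also computes the symmetric percent
difference \(100\,|f_m - f_w| / \frac{f_m + f_w}{2}\). The mean-relative
form was chosen over the asymmetric alternatives because it is symmetric
in the cohorts and scale-free; a max-relative variant
(`method = "max"`) is provided for sensitivity analysis. Reported
frequencies \(f = d/N\) are **unsmoothed** — smoothing exists only inside
the posterior, so printed frequencies keep their counting definition.

## Text processing

Reports pass through three deterministic stages.

**Tokenization.** Text is lowercased and split into word tokens;
sentence punctuation (`. ; : ! ? ,`) is kept as sentinel tokens so that
negation scopes can end at clause boundaries. Tokens containing digits
(measurements, dates, sequence labels like "t2") and single characters
are dropped: the descriptors of interest are alphabetic words.

**Stemming.** The Porter (1980) algorithm, implemented in the package,
conflates conjugation variants ("hypoattenuating"/"hypoattenuated" →
`hypoattenu`, "recurrent"/"recurrence" → `recurr`). One extension was
added for medical vocabulary: a terminal *-is* is removed when the
remaining stem has Porter measure > 1, so Greek/Latin noun pairs
("metastasis"/"metastases", "diagnosis"/"diagnoses",
"stenosis"/"stenoses") map to one stem — under the classic rules the
singular and plural stem apart, which would split one clinical term's
document frequency in two. Displayed term surfaces are the modal surface
form observed for each stem (ties broken lexicographically), prefixed
with `"[no] "` for negated terms.

**Negation tagging.** A proximity check in the NegEx tradition, reduced
to its minimal form: after a cue from the lexicon (`no`, `not`,
`without`, `absent`, `free of`, `negative for`) the next `window`
(default 3) word tokens are marked negated; the scope is cut short by a
terminator (sentence punctuation or `but` / `however`) and restarted by a
new cue. Multi-word cues are matched longest-first; cues and terminators
emit no terms; punctuation that is not a terminator (the comma, by
default) is transparent — it neither ends the scope nor consumes a window
position. "No discrete mass" therefore yields the terms `[no] discrete`
and `[no] mass`, distinct from their un-negated counterparts, and the two
may co-occur in one report ("no discrete mass but discrete
calcification"). There is no hedge/uncertainty detection and no report
section segmentation; those are different problems.

Each report is reduced to its **distinct** term set before counting, so
every downstream number is a document frequency.

## Group-level test

A selected predictor panel is summarised by its mean own-cohort and
other-cohort posteriors and a Wilcoxon signed-rank test on the per-term
pairs. The implementation drops zero differences (the classic
convention, rather than Pratt's), uses midranks for ties, reports the
smaller of the two signed-rank sums, and computes the exact null of
\(W^+\) by convolution over the ranks — algebraically identical to
enumerating all \(2^n\) sign assignments — whenever \(n \le 25\), with a
tie- and continuity-corrected normal approximation beyond. Two-sided
p-values double the smaller tail. The default alternative is two-sided.

One caveat is inherent to the design and worth stating plainly: because
the two posteriors of a term are complements, all pair differences share
a sign, so the exact p-value of a panel is a deterministic function of
the panel size (e.g. \(2 \cdot 2^{-6} = 0.03125\) two-sided for six
terms). The test is therefore reported as a descriptive group summary; it
cannot be read as the probability that a patient carrying all panel terms
has the genotype. No multiple-testing correction is applied across the
two panels.

## The synthetic corpus generator

Real institutional report corpora are not redistributable, so validation
rests on a generator whose statistical content matches exactly what the
analysis measures:

* each **marker** word is included in a report as a Bernoulli event with
  cohort-specific probability (`q_mut`, `q_wt`) — presence/absence,
  because document frequency is all the pipeline sees;
* markers flagged `negated` are planted inside a `"no <word>; ..."`
  phrase, so the tagger must recover them as `[no] <stem>`;
* **background** words are pronounceable consonant–vowel nonsense
  (e.g. `bakodu`), built so their Porter stems are unique and disjoint
  from the marker stems — zero collision by construction;
* sentence templates carry `{w}` (marker) and `{bg}` slots, and every
  `{bg}` is filled with a fresh uniform draw from the background
  vocabulary. Fixed English filler was rejected on purpose: a fixed
  co-word in a marker template inherits the marker's cohort differential
  and ties with it in the predictor ranking. For the same reason the
  default negated template closes the scope immediately after the marker
  (`"no {w}; {bg} {bg}."`): filler inside the negation window would
  create rare spurious `[no] <background>` terms whose smoothed
  posteriors are extreme. Both effects are properties of the analysis the
  generator feeds, not quirks of this implementation.

Under the generator the population posterior of a marker is available in
closed form, \(\pi = q_m \rho / (q_m \rho + q_w (1 - \rho))\) with
\(\rho\) the mutant prior, giving exact ground truth for parameter
recovery. The default study conditions are 2,000 reports per cohort, a
background vocabulary of 500 words with a Poisson mean of 40 background
words per report, and three markers — `innumerable` (0.30 / 0.10),
`confluent` (0.25 / 0.12) and negated `discrete` (0.10 / 0.30), i.e.
analytic posteriors 0.75, ≈0.676 and 0.25 under balanced cohorts. At
that size the binomial sampling error of a posterior estimate is below
±0.02, so recovery within ±0.03 is the expected behaviour, and the test
suite checks it at a fixed seed.

What the generator does **not** emulate: radiology grammar, report
sections, co-occurrence structure between descriptors, per-patient
report correlation, hedged language. Passing the recovery suite
therefore demonstrates that the pipeline measures what it claims on data
satisfying its own assumptions — it says nothing about how strongly real
reports violate those assumptions.

## Corpus ingestion and filtering

The input contract is a header-bearing CSV/TSV manifest (`report_id`,
`patient_id`, `cohort`; delimiter sniffed) plus one UTF-8 text file per
report. Duplicate report ids, unknown cohort labels, missing files and
patients with reports in both cohorts are hard errors. Exclusion of
clinically irrelevant documents is substring-based and config-driven
(defaults: `billing`, `charges`, `scheduling`) with a 50-character
minimum length guarding against placeholder documents; real EHR exports
need locally tuned rule sets, which is why the rules are data, not code.

## Reproducibility and problem sizes

All randomness in a run flows from one seed through one RNG stream, and
the run summary omits filesystem paths, so identical configuration plus
seed gives byte-identical artifacts (`term_table.csv`,
`term_scores.csv`, `predictor_sets.json`, `group_evaluation.json`,
`run_summary.json`, and for synthetic runs `ground_truth.json` and
`recovery_report.json`). The test suite exercises the full pipeline at
2,000 reports per cohort (the default study conditions), determinism at
300 per cohort, counting oracles at 25 per cohort, and the exact
signed-rank law by complete enumeration up to \(n = 12\) with a
5,000-replicate null calibration at \(n = 10\); the whole suite runs in
well under a minute.

```{r, eval = FALSE}
library(radbayes)
sim <- simulate_and_run(demo_config(out_dir = "demo_run", seed = 101))
sim$recovery
```

## Known limitations

* Unigrams only (plus the negation prefix); multi-word imaging phrases
  ("target lesion") are not modelled.
* The negation tagger is a windowed proximity check; long-range or
  morphological negation ("unremarkable") is not captured.
* Forward classification of a whole new report to a genotype is not
  implemented — the package extracts and evaluates predictor terms from
  a labelled training corpus only.
* The signed-rank panel test is descriptive, as discussed above.
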