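# radbayes

Cohort-predictive term mining from free-text radiology reports with a
per-term naive Bayes posterior.

## What it does, and for whom

Tumour genotype (e.g. KRAS-mutant versus wild-type colorectal cancer)
shapes how disease looks on imaging, and therefore the words radiologists
write. Given two labelled cohorts of reports, `radbayes` finds the terms
whose presence is predictive of cohort membership. It is aimed at
radiogenomics / clinical-NLP researchers who have a labelled report
corpus and want a transparent, fully reproducible document-frequency
analysis rather than a black-box classifier.

The pipeline: filter clinically irrelevant documents → tokenize →
Porter-stem → tag negated context ("no discrete mass" → `[no] discrete`)
→ reduce each report to its distinct term set → count per-cohort document
frequencies → score every term with the single-feature Bayes rule

```
P(M | W) = P(W|M) P(M) / ( P(W|M) P(M) + P(W|WT) P(WT) )
```

with add-α smoothed likelihoods `P(W|M) = (df_mut + α) / (N_mut + 2α)`
(default α = 1, empirical priors) → select the predictor panels (own
posterior strictly > 0.5, ranked by |p_mut − p_wt|) → summarise each
panel with mean posteriors and a Wilcoxon signed-rank test (exact null by
enumeration for n ≤ 25).

Because real institutional corpora cannot be shared, the package ships a
synthetic corpus generator with planted marker terms whose population
posteriors are known in closed form, used for end-to-end validation
(parameter recovery, ranking recovery, negation round-trip).

## Worked example

```r
library(radbayes)
sim <- simulate_and_run(demo_config(out_dir = "demo_run", seed = 101))
sim$recovery[, c("word", "key", "posterior", "posterior_hat", "abs_error")]
```

The demo generates 2,000 reports per cohort with three planted markers
and runs the full analysis. It prints:

```
ingest: 4000 reports (2000 MUTANT, 2000 WILDTYPE)
filter: 4000 -> 4000 reports
process: 503 distinct terms overall
rank: 503 of 503 terms pass min_df = 5
select: 6 MUTANT, 4 WILDTYPE predictor term(s)
recovery: max |posterior error| = 0.0133
         word          key posterior posterior_hat   abs_error
1 innumerable      innumer 0.7500000     0.7588384 0.008838384
2   confluent    confluent 0.6756757     0.6870130 0.011337311
3    discrete [no] discret 0.2500000     0.2366791 0.013320942
```

`posterior` is each marker's analytic ground truth (e.g. a word planted
in 30% of mutant and 10% of wild-type reports has posterior
0.30/(0.30+0.10) = 0.75 under balanced cohorts); `posterior_hat` is what
the pipeline estimated from the generated text, here within ±0.014. The
negated marker is recovered as the composite term `[no] discret`, not as
the bare stem. Ranked terms and panels:

```r
head(sim$result$ranked[, c("display","df_mut","df_wt","f_mut","f_wt","pct_diff","p_mut")], 3)
#>         display df_mut df_wt f_mut   f_wt pct_diff     p_mut
#> 1 [no] discrete    190   615 0.095 0.3075 105.5901 0.2366791
#> 2   innumerable    600   190 0.300 0.0950 103.7975 0.7588384
#> 3     confluent    528   240 0.264 0.1200  75.0000 0.6870130

sim$result$evaluations$mutant
#> <group_evaluation> MUTANT predictors (n = 6): mean own = 0.623, mean other = 0.377, p = 0.03125
```

The three planted markers head the ranking; the remaining panel slots
are filled by background-noise terms just above the 0.5 threshold, which
is exactly what a min_df-filtered ranking should do when only three true
signals exist. Every run writes `term_table.csv`, `term_scores.csv`,
`predictor_sets.json`, `group_evaluation.json` and `run_summary.json`
(plus `ground_truth.json` and `recovery_report.json` for synthetic runs)
to the output directory; identical config + seed gives byte-identical
files.

To analyze your own corpus, point a YAML config at a manifest
(`report_id,patient_id,cohort` CSV/TSV) and a directory of
`<report_id>.txt` files, then:

```r
run_pipeline(read_run_config("my_config.yaml"))
```

or from a shell, via the thin wrapper installed in `exec/`:

```sh
Rscript exec/radbayes analyze --config my_config.yaml --out results/
Rscript exec/radbayes demo --seed 101
```

See `vignettes/term-mining.Rmd` for the model, the negation tagger, the
stemmer's medical-plural extension, the generator design and known
limitations.

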