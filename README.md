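# ordermem

Sequence-memory scoring and temporal-contiguity analysis for free-recall
experiments with an explicit ordering task.

## What this is for

In free recall, people tend to successively recall items that were studied
close together — the temporal contiguity effect, the behavioural signature
of a shared, internally-driven temporal context. `ordermem` supports
paradigms that probe whether this shared context leaves a trace in
*explicit* sequence memory: after recalling a 16-word list, participants
are shown pairs of their own recalled words and drag both onto a 16-slot
grid to reconstruct the words' studied positions.

The package takes tidy event tables (study, recall, ordering placements)
and provides the full analysis path:

* **Pair categorization** — each recalled pair is classified by its
  contiguity at encoding and retrieval: `cont_enc_ret` (adjacent at study
  *and* at recall, |lag| = 1), `cont_ret` (adjacent at recall only,
  |lag| ≥ 2), `cont_enc` (adjacent at study only), and `first_three`
  (both members among the first three outputs; excluded from main
  analyses as likely short-term-store retrievals).
* **Exact pair selection** — an item-disjoint subset of candidate pairs
  (no item presented twice) that lexicographically maximizes the minimum
  per-category count, then the total count, found by exact
  branch-and-bound.
* **Order scoring** — per placed pair with studied positions (p_a, p_b)
  and slots (s_a, s_b):
  relative score `1[sign(s_a − s_b) = sign(p_a − p_b)]`;
  absolute score `1 − |s − p| / max(p − 1, L − p)` of the first-placed
  item; signed distance score `|s_a − s_b| − |p_a − p_b|` (negative =
  compressed); and the perfect-pair indicator (relative 1 and distance 0).
* **Temporal clustering score** — each transition's percentile
  `1 − (rank(|lag|) − 1)/(n − 1)` among all still-available lags (average
  ranks for ties), averaged per subject: 1 = maximally contiguous recall,
  0.5 = chance.
* **Group statistics** — repeated-measures ANOVAs across categories with
  condition-difference covariates and Greenhouse–Geisser correction,
  lag-tercile and distance-median splits, a category-by-direction design,
  Pearson and partial correlations with the temporal score, and
  perfect-pair proportions.
* **A participant simulator** — contiguity-structured recall and
  category-dependent placements with known parameters, for calibration
  and recovery testing.

## Worked example

```r
library(ordermem)

# categorize and select pairs from one recall sequence
# (items labelled by study serial position)
seq <- recall_sequence(c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13))
cand <- select_pairs(categorize_pairs(seq, L = 16))
cand[cand$selected, c("item_a_serial", "item_b_serial", "category", "encoding_lag")]
#>    item_a_serial item_b_serial     category encoding_lag
#> 1             16            15  first_three           -1
#> 5             12             4     cont_ret           -8
#> 7              7             8 cont_enc_ret            1
#> 9              2            10     cont_ret            8
#> 12            14            13     cont_enc           NA

unname(temporal_score(seq))
#> [1] 0.64

# simulate a 20-subject session and run the full analysis
sim <- simulate_dataset(simulation_params(n_subjects = 20, seed = 42))
report <- analyze_dataset(sim$dataset)
report$relative_contrast
#> category: F(2, 34) = 51.941, p = 4.608e-11, pes = 0.753
#> n = 20; category means: cont_enc_ret = 0.877, cont_ret = 0.632, cont_enc = 0.809
#> post hoc (Bonferroni):
#>       level_a  level_b     t df        p cohens_d   p_bonf
#>  cont_enc_ret cont_ret  9.93 19 5.91e-09    2.220 1.77e-08
#>  cont_enc_ret cont_enc  3.32 19 3.60e-03    0.742 1.08e-02
#>      cont_ret cont_enc -7.01 19 1.13e-06   -1.567 3.39e-06
```

Reading the output: the five selected pairs are item-disjoint and cover
all four categories; the recall's temporal score of 0.64 sits between
chance (0.5) and perfect contiguity (1). In the simulated session —
generated with shared-context binding switched on — relative order is
best for pairs encoded *and* retrieved contiguously, intermediate for
pairs encoded contiguously only, and worst for pairs merely retrieved
together, while the same report shows no category differences in
absolute placement accuracy (`report$absolute_contrast`). The whole
simulate → extract → score → analyze → report path is also available as
one call, `run_pipeline()`, driven by a config list or YAML file, and as
a thin command-line wrapper in `inst/scripts/ordermem.R`.

The methods vignette (`vignettes/order-memory.Rmd`) documents the score
definitions, the selection algorithm, the statistical conventions and the
generative model behind the simulator.

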