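---
title: "Scoring explicit sequence memory in free recall: models and methods"
author: "ordermem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring explicit sequence memory in free recall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordermem)
```

## The problem

Free recall exhibits the temporal contiguity effect: having recalled one
item, people tend to recall next an item that was studied nearby, with a
bias toward the immediately following (forward, lag +1) item. This
regularity is taken as a signature of an internally-driven temporal
context that items studied close together share. `ordermem` implements an
analysis pipeline for paradigms that follow free recall with an explicit
*ordering task*: a recalled pair is shown and the participant drags both
words onto a 16-slot grid to reconstruct their studied positions. The
scientific question is whether pairs that share temporal context — in
particular pairs both *encoded* and *retrieved* contiguously — carry
better explicit sequence memory, and whether that advantage is specific to
*relative* order (which of the two came first) as opposed to *absolute*
order (where in the list each item sat).

## Pair categories

Each recalled pair of a list is classified from the recall sequence
(items labelled by their study serial position):

* **cont-enc-ret** — recalled at adjacent output positions and studied at
  adjacent serial positions (|lag| = 1);
* **cont-ret** — recalled adjacently but studied non-adjacently
  (|lag| ≥ 2);
* **cont-enc** — studied adjacently, both members recalled, but not at
  adjacent output positions;
* **first-three** — both members among the first three recall outputs,
  regardless of lag. These plausibly reflect dumping from a short-term
  store, so they take precedence over the lag-defined categories and are
  excluded from the main analyses (a `merge_first_three` switch folds them
  back into the lag-defined categories instead).

A boundary case worth stating: when a list has fewer than four correct
outputs, every recalled pair is "among the first three outputs" and the
first-three rule absorbs it. We apply the rule uniformly rather than
special-casing short recalls, because the short-term-store rationale
applies with equal force there.

Transitions are never bridged across intrusions or repeated responses: in
the output sequence `1, <intrusion>, 2` no transition is counted. This is
the conservative reading; the alternative (bridging) would manufacture
contiguity from interrupted retrievals.

## Pair selection

Because one item may fall into several candidate pairs, and no item may be
presented twice in the ordering task, the per-list candidates must be
thinned to an item-disjoint set that (a) maximizes the worst-represented
category and (b) then maximizes the total number of pairs. We solve this
exactly: `select_pairs()` runs a depth-first branch-and-bound (in C++)
over all item-disjoint subsets, seeded with a greedy round-robin incumbent
for pruning, and returns a selection attaining the lexicographic optimum
(minimum per-category count first, total count second). Candidates are
visited in a fixed order — category, earliest recall output, serial
positions — so the result is fully deterministic; a `seed` argument is
accepted for interface uniformity but never consulted. On 16-item lists
the instance sizes (≤ 33 candidates, ≤ 8 selected pairs) make exact search
cheap, and the test suite verifies equality with a brute-force
enumeration on hundreds of random instances.

## Order measures

For a pair with studied positions $(p_a, p_b)$ placed at slots
$(s_a, s_b)$ on an $L$-slot grid:

* **Relative score** $= 1$ iff $\mathrm{sign}(s_a - s_b) =
  \mathrm{sign}(p_a - p_b)$, else 0.
* **Absolute deviation** $= |s - p|$ for one item.
* **Absolute score** $= 1 - |s - p| / \max(p - 1,\, L - p)$. The
  denominator is the largest deviation attainable from position $p$, which
  removes the confound that end-of-list items can err farther than
  mid-list items; the score is 1 at perfect placement and exactly 0 at the
  maximal deviation. The bound is tight for every $p$ (property-tested
  exhaustively for $L = 16$).
* **Distance score** $= |s_a - s_b| - |p_a - p_b|$: zero when the pair is
  placed at its studied distance, negative when compressed, positive when
  expanded. The sign convention (placed minus studied) is fixed by the
  requirement that compression read as negative; for study-adjacent pairs
  the score cannot be negative because two items cannot share a slot.
* **Perfect pair** — relative score 1 *and* distance score 0; the pair
  "sticks together" in the correct order.

Absolute measures are attached to the *first-placed* item only. The second
placement is anchored by the first (participants place the second word
relative to the word already on the grid), so only the first placement
isolates absolute position memory. `score_pairs(include_second = TRUE)`
exposes the second item's scores for exploration, but they never enter the
default pipeline. Placements must be integers on the slot grid; fractional
slots are rejected at validation.

## The temporal clustering score

Each recall transition is scored by ranking the absolute lags of all
still-available items (ties receive their average rank) and converting the
rank of the actually-recalled item to a percentile:
$1 - (\mathrm{rank} - 1)/(n - 1)$ over $n$ available items. The
per-subject score is the mean percentile over all valid transitions.
Perfectly serial recall starting at position 1 scores exactly 1; uniformly
random recall scores 0.5 in expectation — the average-rank tie convention
is precisely what pins the chance level at 0.5, which the test suite
verifies by simulation and by exhaustive enumeration of every
configuration with $L \le 6$.

Three conventions, stated explicitly because the measure is sometimes
implemented otherwise:

* the available set at each transition contains every study item not yet
  correctly recalled (the just-recalled item excluded); intrusions do not
  shrink it;
* transitions with a single available item are skipped (the percentile is
  undefined), not scored as 1;
* transitions are pooled across a subject's lists before averaging
  (transition-weighted), rather than averaging per-list means; this
  stabilizes the estimate for lists with few recalls and makes the score
  invariant to list order.

## Group analysis

The within-subject machinery is the multivariate formulation of the
repeated-measures ANOVA (type III), delegated to `car::Anova` on an `lm`
fit of the subject-by-category matrix. With three or more levels,
Mauchly's test is consulted and the Greenhouse–Geisser correction applied
on violation (corrected degrees of freedom are reported alongside the
epsilon). Between-subject covariates — the order-minus-no-order
differences in mean recall and temporal score, or an experiment indicator
in pooled samples — are mean-centered, so the within-subject effects are
evaluated at the covariate mean; covariates with zero variance carry no
information and are dropped rather than treated as errors. Effect sizes
are partial eta squared for F tests and the paired-standardizer Cohen's
*d* for post hocs, which use Bonferroni-corrected paired t tests.

Inclusion filters mirror standard practice for this task family: the main
contrasts require at least 5 selected pairs per category per subject; the
split sub-analyses require at least 3 pairs per bin or cell. Split
conventions: lag terciles are computed per subject on |lag| of cont-ret
pairs with boundary ties assigned to the lower bin (deterministic and
order-independent); the distance median split assigns pairs at the median
to the "small" bin; both splits partition each subject's pairs exactly.
Degenerate designs are handled explicitly: identical category columns
report F = 0, p = 1; zero-variance paired differences report "no
difference" rather than an undefined t; missing cells are removed listwise
within each analysis and logged.

Correlations between the temporal score and order memory use per-subject
order scores pooled over pairs across the analysis categories (first-three
pairs excluded); the dissociation between relative and absolute order is
probed with first-order partial correlations, computed in closed form and
cross-checked in the tests against a residual-based oracle.

## The participant simulator

`simulate_dataset()` generates study lists, recall sequences and ordering
placements with known parameters, emulating a session of 28 test lists of
16 words drawn without replacement from a 661-word pool, 19 lists carrying
the ordering task (intermixed by default; a blocked schedule places all
no-order lists first).

**Recall** is a minimal lag-based sampler, not a full retrieved-context
model: the analyses consume only contiguity structure, and this is the
smallest model that generates it. The first output comes from the last
three positions with probability `recency_start` (default 0.7, echoing
recency-initiated recall), else uniformly; each next item is drawn without
replacement with weight $\exp(-|\mathrm{lag}|/\tau)$, forward lags
multiplied by `asymmetry` (default 1.5); recall stops with probability
`stop_prob` (default 0.1, giving roughly 8–10 recalls per 16-item list)
per output.

**Ordering** follows a two-part pair-placement model. The first-placed
member (chosen uniformly) lands at its true position plus Gaussian noise
(`placement_noise_sd`, default 1.6 slots), rounded and clipped to the
grid. Because this stage is identical for every category, absolute
measures carry no category signal by construction — the simulator encodes
the relative/absolute dissociation at the mechanism level rather than as a
target to hit. The second member is placed *relative to the first*: a
remembered direction, correct with probability
$\Phi(d / \sigma_{\mathrm{pair}}(d))$, and a remembered magnitude
$\max(1, \mathrm{round}(\kappa d + \varepsilon))$, where $d$ is the
studied distance. The pair noise is Weber-like,
$\sigma_{\mathrm{pair}}(d) = \max(\sigma_p - b \cdot
\mathrm{adj},\,0)\, d^{\gamma}$ with `pair_noise_sd` $\sigma_p$ (default
2.6), `shared_context_bonus` $b$ (default 1.3) applied only to
study-adjacent pairs, and `distance_weber_exp` $\gamma$ (default 1).
$\gamma = 1$ makes direction accuracy independent of $d$
($\Phi(1/\sigma_p)$ for every non-adjacent pair), which is what makes the
bonus-free, glue-free configuration a genuine null for category contrasts;
$\gamma > 1$ makes long-lag pairs noisier and is the configuration used to
exercise the lag-tercile analysis. `distance_compression` $\kappa$
(default 0.65, non-adjacent pairs only) biases remembered distances toward
compression, reproducing the strongly negative distance scores typical of
pairs retrieved contiguously but studied far apart; it must be set to 1 if
one wants noise-free placements to be exactly veridical, since it is a
bias, not a noise term. With probability `glue_prob` (default 0.2) a
cont-enc-ret pair is instead "glued": the second member goes to the
adjacent slot on the correct side, modelling the binding of a
contiguously encoded-and-retrieved pair into one episode. When a drawn
direction points off the grid from a boundary slot, the first item is
shifted one slot inward rather than flipping the placement side, so the
remembered direction always survives — the alternative silently corrects
wrong-direction placements for long-lag pairs and distorts the planted
lag gradient.

A per-subject log-normal fidelity factor (`subject_sd`, default 0.25)
jointly scales contiguity ($\tau$) and both placement noises, producing
between-subject correlations between temporal and order scores of the
kind the correlation analyses consume; because it is a single shared
factor, it yields stronger correlations than human samples typically
show, which is a known simplification. Optional `intrusion_rate` and
`repeat_rate` (default 0) inject flagged responses to exercise the
validators.

Default dispersion parameters were calibrated once, analytically, to the
canonical performance profile of this task family — relative score about
0.8 for study-adjacent pairs and 0.65 for non-adjacent pairs, mean
absolute deviation about 1.3 slots — and then left alone. What passing
simulation tests show is that the pipeline recovers planted structure of
this kind; they cannot show that human data contain such structure, nor do
the simulator's clean-channel defaults (no intrusions, no semantic
structure, no time pressure) reproduce every feature of real recall.

## Reproducibility and problem sizes

Every stochastic stage is seeded; identical `simulation_params` (including
the seed) yield byte-identical CSV outputs, and `run_pipeline()` echoes
its effective configuration so that a single file determines all outputs.
The simulation-based checks in the test suite use deliberately modest
problem sizes chosen to give comfortable Monte-Carlo margins: 500
simulated subjects for the chance-level check, 100 subjects per cell for
the contiguity-recovery grid, 500 replicate datasets of 12 subjects by 8
lists for the null calibration of the category contrasts (rejection rate
required to sit within three binomial standard errors of 0.05), and one
40-subject, 20-list dataset for the qualitative pattern replication.

## Known limitations

* Response matching is exact after trimming and case-folding; typos
  become intrusions. A pluggable matcher hook exists, but no fuzzy
  matching ships, because its behaviour could not be validated against
  anything.
* The recall model has no semantic associations, serial-position effects
  on item availability, or time-pressure dynamics; the ordering model has
  no trial-order or fatigue effects.
* Bayes factors are not computed: they are prior- and backend-dependent,
  and the frequentist statistics are the package's contract.
* The two-way category-by-direction design and the pooled-experiment
  covariate are implemented for the standard 2 x 2 case; more complex
  within-subject designs are out of scope.
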