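---
title: "Multiple unreliable cues and the canalization of word learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple unreliable cues and the canalization of word learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cuecanal` is a simulation testbed for one question: when word–referent
mappings must be learned cross-situationally, what do extra environmental
cues — prosodic emphasis, deictic gesture, distributional category
information — do to the *speed* of learning and to the *robustness*
(canalization) of what is learned once those cues disappear? This vignette
is the package's methodological account: the model and its assumptions,
every tunable parameter and why its default is what it is, what the
synthetic data do and do not emulate, the numerical choices, and the design
decisions taken where the design was genuinely open.

## The task

Each learning event presents two spoken word forms and two visual objects;
exactly one object is named by one of the words. Within a single trial the
mapping is ambiguous — the learner cannot tell which word goes with which
object — but across many trials the target word and its referent always
co-occur, so the mapping is statistically recoverable. On top of this,
three cues can mark the target on any given trial:

* **prosody** (intrinsic): the target word form's input activation is
  doubled, emulating the increased intensity, duration and pitch of
  child-directed naming;
* **gesture** (intrinsic): the target referent's input activation is
  doubled, emulating a point or gaze toward the object;
* **distributional** (extrinsic): a 2-unit layer signals which of two word
  categories the target belongs to, emulating co-occurrence frames; it
  disambiguates without touching either modality's representation.

A *condition* fixes each cue's per-trial presence probability
(`condition_config()`); the standard grid (`cue_conditions()`) crosses a
no-cue baseline, the three single fully reliable cues, and combined cues at
reliability 0.25 / 0.50 / 0.75 / 1.00. Cues are drawn independently per cue
per trial — the grid specifies only marginal rates, and independence is the
minimal assumption consistent with them. Cues never lie: when present they
always mark the true target. Cue conflict is out of scope.

## Representations (the synthetic-data generator)

The lexicon (`build_lexicon()`) is pure pseudopattern: controlled sparsity,
no further structure.

* **Phonology**: an inventory of 10 phonemes; each phoneme is a 5-unit
  binary pattern with 2 active units. Since `choose(5, 2) = 10`, the
  inventory is necessarily the complete set of such patterns. A word form
  concatenates 4 phonemes drawn uniformly *with replacement* (repeated
  phonemes within a word are allowed; the constraint is on the inventory,
  not the word), giving 20 units with 8 active.
* **Referents**: uniform 8-of-20 binary patterns.
* **Semantics**: localist — word *i* is semantic unit *i*. The output layer
  size therefore equals the lexicon size.
* **Categories**: a random half of the words is category A, half B; the
  distributional cue activates unit 1 for A-words and unit 2 for B-words.

Word forms and referents are deduplicated across the lexicon (resampled on
collision). Whether duplicates were excluded in the antecedent work is not
knowable; distinctness is required here so that "which word was named" is
well defined at test, and is recorded as an assumption. No similarity
structure relates forms to referents, and nothing in the generator mimics
phonotactics, semantic features, or corpus statistics — so a green test
establishes that the *learning dynamics* behave as claimed for
controlled-sparsity random patterns, not that any result would survive
realistic representational overlap.

## Network and training

The architecture is hub-and-spoke: an 82-unit input (two 20-unit word
slots, two 20-unit object slots, 2 distributional units) feeds a fully
self-connected integrative layer, which feeds the localist semantic output.
There are no modality-to-modality connections and no feedback from the
output. Dynamics are six synchronous steps with the input clamped and a
one-step delay per connection:

$$h_t = \sigma(W_{in} x + W_{hh} h_{t-1} + b_h), \qquad
  s_t = \sigma(W_{hs} h_{t-1} + b_s), \qquad h_0 = 0.$$

Because the output reads the *previous* hidden state, $s_1$ cannot depend
on the input at all; the earliest output the input can influence is $s_2$
(input to hidden at step 1, hidden to output at step 2). Error is scored
at steps 3–6: the
loss is the sum-squared error between $s_t$ and the localist target over
that window. Error is *injected* at those steps only; the target is never
clamped onto the output, and no activation flows back from the semantic
layer, because the architecture gives the output no return connections.
Whether error should be scored at every window step or only at the final
one is not decidable from the source description; the 4-step window is
implemented (`error_window = 3:6`, configurable).

Gradients are exact discrete-time backpropagation through time over the
unrolled six steps (`bptt_gradients()`), verified against central finite
differences at relative tolerance 1e-5 across random networks. The
continuous-time formulation the original description cites adds nothing
observable at six integer steps, so the discrete unrolling is used.
Learning is online — one SGD step per trial — with hidden state reset to
zero between trials: trials are independent learning situations, and batch
size was never specified. The compiled engine (`src/engine.cpp`) reproduces
the R reference path to machine precision and is tested for exact
agreement; all sampling happens in R's RNG either way, so results are
engine-invariant.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_hidden` | 100 (desk: 60) | units | stated architecture; desk value scales with the 40-word lexicon |
| `n_semantic` | 100 (desk: 40) | units | equals lexicon size (localist) |
| `timesteps` | 6 | steps | stated trial dynamics |
| `error_window` | 3:6 | steps | target presented from step 3 |
| `init_range` | 0.5 | weight | unstated; standard small uniform init for sigmoid nets |
| `learning_rate` | 0.1 (desk: 0.2) | — | unstated; desk value fixed by the calibration protocol below |
| `max_epochs` | 100,000 (desk: 15,000) | epochs | stated cap; desk cap keeps runs in minutes |
| `criterion_run` | 5 | epochs | stated criterion |
| `repeats_per_word` | 10 | test trials | unstated; averages out foil-sampling noise at test |
| replicates | 20 (desk: 5) | models | stated replicate count |

The activation function is the logistic sigmoid on both layers — never
named in the source, but the standard choice for this model family and the
one under which "doubling the activation" has its usual saliency reading.

**Calibration.** The learning rate is the one hyperparameter the phenomena
are sensitive to. `calibrate_learning_rate()` implements the stated
protocol: sweep a coarse grid (0.2, 0.1, 0.05, 0.02) and keep the largest
rate at which (i) a fully reliable intrinsic cue reaches criterion well
before the cap, (ii) the no-cue baseline is slower, and (iii) the no-cue
run is still learning (terminal accuracy above 0.5) rather than diverging.
At desk scale (40 words, 60 hidden, 15,000-epoch cap) the protocol selects
**0.2** (pilot: prosodic criterion at epoch 98, no-cue at 2,534, no-cue
terminal accuracy 0.97), frozen as `desk_learning_rate()`. The protocol
conditions only on the no-cue-versus-single-cue speed profile; the
robustness orderings the acceptance tests assert were not consulted in
choosing it.

## Measurement

Per-epoch accuracy is scored on the epoch's own training trials, each on
the forward pass *before* that trial's update — assessment "during
training", with no held-out set. A trial is correct iff the target's
semantic unit is strictly more active than every other unit at the final
step; ties are incorrect (the strict reading of "more active than any
other"). Time-to-criterion is the first epoch of the first run of 5
consecutive perfect epochs; training stops once that run is confirmed,
since later epochs cannot change either reported measure. Runs that never
qualify are censored and enter analyses at the epoch cap, mirroring how a
never-criterion baseline condition is retained in the stated analyses. The
robustness test presents every word `repeats_per_word` times with fresh
random foils and slots, all cues off, under a dedicated evaluation seed,
with no weight updates.

The matched-training control (`run_matched_training()`) removes the
criterion stop and trains every condition for the same number of epochs
before the robustness test, separating cue effects on robustness from cue
effects on amount of training. The source describes this control as
equating "training trials (100,000)" in one place and implies epochs
elsewhere; a factor-of-100 discrepancy. Epochs are adopted (the
configurable `total_epochs`), as the reading consistent with the stated
epoch cap.

## Seeds and reproducibility

Every replicate derives four seeds from the master seed by a fixed counter
scheme (`replicate_seeds()`): lexicon, initial weights, trial stream,
robustness evaluation. A replicate keeps the same lexicon and starting
weights across conditions — this is what makes the replicate a
within-subject "subject" in the repeated-measures analyses — while each
cue draw consumes a fixed number of uniforms, keeping streams aligned
across conditions. Lexica serialize to JSON (`lexicon_to_json()`) and the
driver writes a manifest with the config hash and master seed, so any run
is replayable bit-exactly.

## Statistics

`rm_anova()` is the textbook one-way within-subject decomposition
(SS~total~ = SS~subject~ + SS~condition~ + SS~error~), with
$F = MS_{cond}/MS_{error}$ on $(k-1, (k-1)(n-1))$ df and partial eta
squared $SS_{cond}/(SS_{cond}+SS_{error})$; no sphericity correction, as
none is reported in the analyses being reproduced. Post hocs are paired
t-tests with Bonferroni correction (p multiplied by the number of pairs,
capped at 1) — the cap at exactly 1 in the reported post hocs is the
Bonferroni signature, though the procedure is otherwise unnamed. Zero
error variance (ANOVA) or zero within-pair variance (t-tests) is reported
as a degenerate case rather than an infinite statistic.

## Limitations

* Full-scale quantitative targets (epochs-to-criterion near 35,000 at 100
  words / 100,000-epoch cap) depend on hyperparameters the source never
  states; the package reproduces the *ordinal* structure of the results at
  desk scale and exposes the calibration protocol for full-scale runs, but
  does not claim the printed means.
* Two words and two objects per scene; no graded cue strength; no cue
  conflict; no cross-trial memory.
* Pseudopatterns only — conclusions about realistic phonological or
  semantic structure are out of reach by design.
* Foil word form and foil referent are drawn independently (they may come
  from different non-target words); whether they were yoked in the
  antecedent work is unstated. The distributional cue is applied
  identically whether or not the foil shares the target's category, so on
  category-concordant trials it marks the category without disambiguating.
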